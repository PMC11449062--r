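# Pairwise dN/dS on one-to-one ortholog pairs: codon-aware alignment,
# maximum-likelihood estimation under the codon model in codon_model.R, and a
# likelihood-ratio test of the free-omega model against omega fixed at 1
# (chi-square, 1 df).  An NG86 counting estimate serves as an independent
# cross-check of the ML estimator.

#' Filter one-to-one ortholog CDS pairs before alignment
#'
#' A pair is removed when both members are incomplete (missing start and/or
#' stop codon) or when the length difference exceeds 20% of the length of
#' either gene.  Pairs whose CDS length is not a multiple of 3 are flagged
#' invalid.
#'
#' @param pairs data.frame with columns pair_id, cds1, cds2, complete1,
#'   complete2 (logical CDS-completeness flags).
#' @return input with logical columns `retained` and `invalid` plus a
#'   `reason` column.
#' @export
filter_ortholog_pairs <- function(pairs) {
  assert_cols(pairs, c("pair_id", "cds1", "cds2", "complete1", "complete2"),
              "pair table")
  l1 <- nchar(pairs$cds1)
  l2 <- nchar(pairs$cds2)
  both_incomplete <- !pairs$complete1 & !pairs$complete2
  too_diff <- abs(l1 - l2) > 0.2 * l1 | abs(l1 - l2) > 0.2 * l2
  invalid <- (l1 %% 3 != 0) | (l2 %% 3 != 0)
  pairs$invalid <- invalid
  pairs$retained <- !both_incomplete & !too_diff & !invalid
  pairs$reason <- ifelse(invalid, "length_not_multiple_of_3",
                  ifelse(both_incomplete, "both_incomplete",
                  ifelse(too_diff, "length_filtered", "")))
  pairs
}

strip_terminal_stop <- function(cds) {
  u <- codon_universe()
  cod <- split_codons(cds)
  if (length(cod) > 0 && cod[length(cod)] %in% u$stop_codons) {
    cod <- cod[-length(cod)]
  }
  paste(cod, collapse = "")
}

#' Codon-aware pairwise alignment of two CDS
#'
#' Translates both sequences, aligns the proteins globally (BLOSUM62, gap
#' open 10 / extend 0.5) and back-translates the gaps in codon triples.
#' Terminal stop codons are stripped first; an internal stop codon flags the
#' pair invalid.
#'
#' @param cds1,cds2 in-frame CDS nucleotide strings.
#' @return list with `seq1`, `seq2` (aligned, gaps as `-`), `valid`, `reason`.
#' @export
codon_align <- function(cds1, cds2) {
  u <- codon_universe()
  cds1 <- strip_terminal_stop(cds1)
  cds2 <- strip_terminal_stop(cds2)
  cod1 <- split_codons(cds1)
  cod2 <- split_codons(cds2)
  if (any(cod1 %in% u$stop_codons) || any(cod2 %in% u$stop_codons)) {
    return(list(seq1 = NA, seq2 = NA, valid = FALSE, reason = "internal_stop"))
  }
  p1 <- Biostrings::translate(Biostrings::DNAString(cds1))
  p2 <- Biostrings::translate(Biostrings::DNAString(cds2))
  aln <- Biostrings::pairwiseAlignment(p1, p2, type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  a1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out1 <- character(length(a1))
  out2 <- character(length(a2))
  i1 <- 0L; i2 <- 0L
  for (k in seq_along(a1)) {
    if (a1[k] == "-") out1[k] <- "---" else { i1 <- i1 + 1L; out1[k] <- cod1[i1] }
    if (a2[k] == "-") out2[k] <- "---" else { i2 <- i2 + 1L; out2[k] <- cod2[i2] }
  }
  list(seq1 = paste(out1, collapse = ""), seq2 = paste(out2, collapse = ""),
       valid = TRUE, reason = "")
}

#' Count variant nucleotide sites in a codon alignment
#'
#' Number of aligned nucleotide columns where the two sequences differ; any
#' column with a gap in either sequence is excluded.
#'
#' @param alignment list with `seq1`, `seq2` as returned by [codon_align()].
#' @return integer count.
#' @export
count_variant_sites <- function(alignment) {
  x <- strsplit(toupper(alignment$seq1), "")[[1]]
  y <- strsplit(toupper(alignment$seq2), "")[[1]]
  stopifnot(length(x) == length(y))
  keep <- x != "-" & y != "-"
  sum(x[keep] != y[keep])
}

drop_gap_codons <- function(alignment) {
  c1 <- split_codons(alignment$seq1)
  c2 <- split_codons(alignment$seq2)
  keep <- !grepl("-", c1, fixed = TRUE) & !grepl("-", c2, fixed = TRUE)
  list(cod1 = c1[keep], cod2 = c2[keep])
}

#' Maximum-likelihood pairwise dN/dS under the Goldman-Yang codon model
#'
#' Fits (t, kappa, omega) by bounded quasi-Newton optimization from three
#' omega starts (0.2, 1, 3) and refits with omega fixed at 1; the
#' likelihood-ratio statistic 2(lnL_free - lnL_fixed) is referred to
#' chi-square with 1 df.  Codon frequencies are F3x4, estimated jointly from
#' both sequences.  When dS < 1e-6 the omega estimate is capped at 999 and
#' flagged `dS_zero` (operationalizing "infinite" dN/dS at dS = 0).
#'
#' @param alignment list with aligned `seq1`, `seq2` (gaps as `-`).
#' @param pair_id identifier carried into the result.
#' @return one-row data.frame (CodonPairResult): n_codons, n_variant_sites,
#'   omega, dN, dS, kappa, t, lnL_free, lnL_fixed, lrt, p and flag columns.
#' @export
pairwise_dnds_ml <- function(alignment, pair_id = "pair") {
  cod <- drop_gap_codons(alignment)
  if (length(cod$cod1) == 0) stop("no ungapped codon columns")
  nvar <- count_variant_sites(alignment)
  res <- data.frame(pair_id = pair_id, n_codons = length(cod$cod1),
                    n_variant_sites = nvar,
                    omega = NA_real_, dN = NA_real_, dS = NA_real_,
                    kappa = NA_real_, t = NA_real_,
                    lnL_free = NA_real_, lnL_fixed = NA_real_,
                    lrt = NA_real_, p = NA_real_, p_adjusted = NA_real_,
                    identical = FALSE, dS_zero = FALSE,
                    stringsAsFactors = FALSE)
  if (nvar == 0) {
    res$identical <- TRUE
    res$omega <- NA_real_; res$dN <- 0; res$dS <- 0
    return(res)
  }
  pi <- f3x4_frequencies(c(cod$cod1, cod$cod2))
  N <- codon_pair_counts(cod$cod1, cod$cod2)
  free <- gy94_fit(N, pi)
  fixed <- gy94_fit(N, pi, fix_omega = 1, t_start = free$t)
  if (fixed$lnL > free$lnL) {           # neutral fit may rescue a flat surface
    free2 <- gy94_fit(N, pi, omega_starts = 1, t_start = fixed$t)
    if (free2$lnL > free$lnL) free <- free2
  }
  dnds <- gy94_dn_ds(free$t, free$kappa, free$omega, pi)
  res$kappa <- free$kappa; res$t <- free$t
  res$lnL_free <- free$lnL; res$lnL_fixed <- fixed$lnL
  res$lrt <- max(0, 2 * (free$lnL - fixed$lnL))
  res$p <- pchisq(res$lrt, df = 1, lower.tail = FALSE)
  res$dN <- dnds["dN"]; res$dS <- dnds["dS"]
  if (dnds["dS"] < 1e-6) {
    res$omega <- 999
    res$dS_zero <- TRUE
  } else {
    res$omega <- free$omega
  }
  res
}

# --- NG86 counting method (independent cross-check of the ML estimator) ---

ng86_site_counts <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    u <- codon_universe()
    gc_tab <- Biostrings::GENETIC_CODE
    nts <- c("A", "C", "G", "T")
    syn_sites <- numeric(u$n)
    for (i in seq_len(u$n)) {
      cod <- u$cmat[i, ]
      s <- 0
      for (p in 1:3) {
        for (nt in setdiff(nts, cod[p])) {
          mut <- cod; mut[p] <- nt
          mut_c <- paste(mut, collapse = "")
          if (gc_tab[[mut_c]] != "*" && gc_tab[[mut_c]] == u$aa[i]) s <- s + 1 / 3
        }
      }
      syn_sites[i] <- s
    }
    cache <<- syn_sites
    cache
  }
})

# Average synonymous/nonsynonymous differences over all orderings of the
# positions at which two codons differ, skipping pathways through stops.
ng86_pair_diffs <- function(c1, c2) {
  gc_tab <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  perms <- if (length(pos) == 1) list(pos) else
    if (length(pos) == 2) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
  acc <- c(0, 0); nvalid <- 0
  x2 <- strsplit(c2, "")[[1]]
  for (ord in perms) {
    cur <- strsplit(c1, "")[[1]]
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- x2[p]
      ca <- paste(cur, collapse = ""); cb <- paste(nxt, collapse = "")
      if (gc_tab[[cb]] == "*") { ok <- FALSE; break }
      if (gc_tab[[ca]] == gc_tab[[cb]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + c(sd, nd); nvalid <- nvalid + 1 }
  }
  if (nvalid == 0) return(c(NA, NA))
  acc / nvalid
}

#' Nei-Gojobori (1986) dN/dS with Jukes-Cantor correction
#'
#' Counting-method estimate used as an independent cross-check of the
#' maximum-likelihood estimator; returns NaN omega when no synonymous
#' differences are observed.
#'
#' @param alignment list with aligned `seq1`, `seq2`.
#' @return named vector (dN, dS, omega).
#' @export
ng86_dnds <- function(alignment) {
  u <- codon_universe()
  cod <- drop_gap_codons(alignment)
  i <- match(cod$cod1, u$codons)
  j <- match(cod$cod2, u$codons)
  keep <- !is.na(i) & !is.na(j)
  i <- i[keep]; j <- j[keep]
  syn_sites <- ng86_site_counts()
  S <- (sum(syn_sites[i]) + sum(syn_sites[j])) / 2
  N <- 3 * length(i) - S
  sd_nd <- c(0, 0)
  for (k in seq_along(i)) {
    if (i[k] != j[k]) {
      d <- ng86_pair_diffs(u$codons[i[k]], u$codons[j[k]])
      if (!any(is.na(d))) sd_nd <- sd_nd + d
    }
  }
  pS <- sd_nd[1] / S
  pN <- sd_nd[2] / N
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (!is.na(dS) && dS > 0) dN / dS else NaN
  c(dN = dN, dS = dS, omega = omega)
}

#' Benjamini-Hochberg adjustment
#' @param pvalues numeric vector in [0,1].
#' @return adjusted p-values (standard step-up).
#' @export
bh_adjust <- function(pvalues) p.adjust(pvalues, method = "BH")

#' Select candidates under divergent selection
#'
#' Pairs with an omega estimate above 1 and a BH-adjusted LRT p-value below
#' the FDR threshold.
#'
#' @param results data.frame of CodonPairResult rows.
#' @param fdr threshold on the adjusted p-value (default 0.05).
#' @return subset of `results` with `p_adjusted` filled for all rows.
#' @export
select_candidates <- function(results, fdr = 0.05) {
  results$p_adjusted <- bh_adjust(results$p)
  sel <- !is.na(results$omega) & results$omega > 1 &
    !is.na(results$p_adjusted) & results$p_adjusted < fdr
  results[sel, , drop = FALSE]
}

#' Per-scaffold dN/dS distributions and rearranged-vs-rest tests
#'
#' Restricted to pairs with at least `min_variant_sites` variant sites.
#' Each rearranged scaffold's omega distribution is compared to the pooled
#' omega values of all non-rearranged scaffolds with a two-sided
#' Mann-Whitney U test.
#'
#' @param results CodonPairResult rows with finite omega.
#' @param scaffold_map named character vector pair_id -> scaffold.
#' @param rearranged_ids scaffolds classified as rearranged.
#' @param min_variant_sites inclusion threshold (default 5).
#' @return list with `medians` (per-scaffold omega medians) and `tests`
#'   (one stat_result row per rearranged scaffold).
#' @export
scaffold_dnds_compare <- function(results, scaffold_map, rearranged_ids,
                                  min_variant_sites = 5) {
  keep <- results$n_variant_sites >= min_variant_sites & is.finite(results$omega)
  res <- results[keep, , drop = FALSE]
  res$scaffold <- unname(scaffold_map[res$pair_id])
  if (!all(rearranged_ids %in% res$scaffold)) {
    stop("rearranged scaffold absent from results: ",
         paste(setdiff(rearranged_ids, res$scaffold), collapse = ", "))
  }
  med <- tapply(res$omega, res$scaffold, median)
  pooled <- res$omega[!(res$scaffold %in% rearranged_ids)]
  tests <- do.call(rbind, lapply(rearranged_ids, function(sc) {
    x <- res$omega[res$scaffold == sc]
    r <- mann_whitney(x, pooled)
    r$note <- paste0("scaffold=", sc, ";n=", length(x))
    r
  }))
  list(medians = med, tests = tests)
}

#' dN/dS of duplicated orthogroups (1:2:1 and 1:1:2 conformations)
#'
#' For orthogroups with a single outgroup gene and a duplication in exactly
#' one focal species -- and only when the conformation survives the
#' coverage-based size correction -- computes the pairwise omega of the
#' outgroup singleton against each focal-species paralog.
#'
#' @param og `orthogroups` table with corrected counts.
#' @param cds named character vector gene_id -> CDS.
#' @return data.frame of CodonPairResult rows (one per paralog) with
#'   `orthogroup_id` and `conformation` columns; skipped orthogroups are
#'   omitted.
#' @export
duplicate_dnds <- function(og, cds) {
  cf <- ifelse(is.na(og$corrected_F), og$F_count, og$corrected_F)
  cl <- ifelse(is.na(og$corrected_L), og$L_count, og$corrected_L)
  out <- list()
  for (k in seq_len(nrow(og))) {
    if (og$A[k] != 1) next
    conf <- if (og$F_count[k] == 2 && og$L_count[k] == 1) "1:2:1"
            else if (og$F_count[k] == 1 && og$L_count[k] == 2) "1:1:2"
            else next
    # conformation must hold after correction too
    if (cf[k] != og$F_count[k] || cl[k] != og$L_count[k]) next
    anchor <- og$genes_A[[k]][1]
    paralogs <- if (conf == "1:2:1") og$genes_F[[k]] else og$genes_L[[k]]
    if (!anchor %in% names(cds) || !all(paralogs %in% names(cds))) next
    for (pg in paralogs) {
      aln <- codon_align(cds[[anchor]], cds[[pg]])
      if (!aln$valid) next
      r <- pairwise_dnds_ml(aln, pair_id = paste(anchor, pg, sep = "|"))
      r$orthogroup_id <- og$orthogroup_id[k]
      r$conformation <- conf
      out[[length(out) + 1]] <- r
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}
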