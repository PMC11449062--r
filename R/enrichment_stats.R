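# Shared statistical kernels (thin, convention-fixing wrappers over stats::)
# plus the orthogroup-category and GO enrichment frameworks.

#' Chi-square test of independence on a 2x2 table
#'
#' Yates continuity correction is applied by default, mirroring R's 2x2
#' default.  Falls back to p = 1 with a degenerate flag when a margin is
#' zero.
#'
#' @param tab 2x2 non-negative integer matrix.
#' @param continuity apply Yates correction (default TRUE).
#' @return `stat_result` with the odds ratio as effect size.
#' @export
chi_square_2x2 <- function(tab, continuity = TRUE) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(stat_result("chi-square 2x2", statistic = NA, p = 1,
                       note = "degenerate: zero margin"))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = continuity))
  or <- (tab[1, 1] * tab[2, 2]) / max(tab[1, 2] * tab[2, 1], .Machine$double.xmin)
  stat_result("chi-square 2x2", statistic = unname(ct$statistic),
              p = ct$p.value, effect = or,
              note = if (continuity) "Yates correction" else "no correction")
}

#' Fisher's exact test on a 2x2 table
#' @param tab 2x2 non-negative integer matrix.
#' @return `stat_result` with the conditional MLE odds ratio.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(stat_result("Fisher exact 2x2", p = 1, note = "degenerate: zero margin"))
  }
  ft <- fisher.test(tab)
  stat_result("Fisher exact 2x2", p = ft$p.value,
              effect = unname(ft$estimate), note = "two-sided")
}

#' Two-sided Mann-Whitney U test
#'
#' Exact when both samples are at most `exact_threshold` long and tie-free;
#' otherwise the normal approximation with tie correction is used.
#'
#' @param x,y numeric vectors.
#' @param exact_threshold sample-size bound for the exact distribution.
#' @return `stat_result`; statistic is U for `x`, effect the median shift.
#' @export
mann_whitney <- function(x, y, exact_threshold = 20) {
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= exact_threshold && length(y) <= exact_threshold && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact, correct = !use_exact))
  stat_result("Mann-Whitney U", statistic = unname(wt$statistic),
              p = wt$p.value, effect = median(x) - median(y),
              note = if (use_exact) "exact" else "normal approximation, tie-corrected")
}

#' Welch's unequal-variance t test
#' @param x,y numeric vectors of length >= 2.
#' @return `stat_result`; effect is the mean difference.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("Welch's t needs n >= 2 per group")
  if (var(x) + var(y) == 0) {
    return(stat_result("Welch t", statistic = 0, p = 1, effect = mean(x) - mean(y),
                       note = "degenerate: zero variance"))
  }
  tt <- t.test(x, y)
  stat_result("Welch t", statistic = unname(tt$statistic), p = tt$p.value,
              effect = mean(x) - mean(y))
}

#' Shapiro-Wilk normality p-value
#' @param x numeric vector (3..5000 values).
#' @return p-value.
#' @export
shapiro_wilk <- function(x) shapiro.test(x)$p.value

#' Kendall rank correlation (tau-b, tie-corrected)
#' @param x,y numeric vectors of equal length >= 3.
#' @return `stat_result`; effect is tau-b, NA when a series is constant.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    return(stat_result("Kendall tau-b", note = "undefined: constant series"))
  }
  kt <- suppressWarnings(cor.test(x, y, method = "kendall"))
  stat_result("Kendall tau-b", statistic = unname(kt$statistic),
              p = kt$p.value, effect = unname(kt$estimate))
}

#' Orthogroup-category enrichment among DE orthogroups
#'
#' For each relative-size category (F=1:L=1, F>L, F<L, F=L(>1)) builds the
#' 2x2 table [category vs all others] x [DE vs non-DE orthogroups] and
#' applies the chi-square test of independence; for the (small) CAM-related
#' DE subset versus the other DE orthogroups, Fisher's exact test is used.
#' Species-unique orthogroups are excluded.
#'
#' @param og `orthogroups` table with `category` filled
#'   (see [categorize_relative_size()]).
#' @param de_flags logical per orthogroup: contains a DE gene.
#' @param cam_flags optional logical per orthogroup: CAM-related.
#' @return data.frame: one row per category (and per category for the CAM
#'   subset), with counts, proportions, fold enrichment, p and BH-adjusted p.
#' @export
category_enrichment <- function(og, de_flags, cam_flags = NULL) {
  stopifnot(length(de_flags) == nrow(og))
  cats <- c("F=1:L=1", "F>L", "F<L", "F=L(>1)")
  keep <- og$category %in% cats        # drops species-unique orthogroups
  cat_v <- og$category[keep]
  de <- de_flags[keep]
  if (!any(de)) stop("empty DE orthogroup set")
  one_block <- function(flag_in, flag_out, label, test) {
    rows <- lapply(cats, function(cc) {
      a <- sum(flag_in & cat_v == cc); b <- sum(flag_in & cat_v != cc)
      c2 <- sum(flag_out & cat_v == cc); d <- sum(flag_out & cat_v != cc)
      tab <- matrix(c(a, b, c2, d), 2, byrow = TRUE)
      r <- if (test == "chisq") chi_square_2x2(tab) else fisher_exact_2x2(tab)
      prop_in <- a / max(a + b, 1); prop_out <- c2 / max(c2 + d, 1)
      data.frame(subset = label, category = cc, n_in = a, n_out = c2,
                 prop_in = prop_in, prop_out = prop_out,
                 fold = if (prop_out > 0) prop_in / prop_out else NA_real_,
                 statistic = r$statistic, p = r$p, method = r$method,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- bh_adjust(out$p)
    out
  }
  res <- one_block(de, !de, "DE_vs_nonDE", "chisq")
  if (!is.null(cam_flags)) {
    cam <- cam_flags[keep]
    res <- rbind(res, one_block(cam & de, de & !cam, "CAMDE_vs_otherDE", "fisher"))
  }
  res
}

#' GO-term enrichment by Fisher's exact test with ancestor propagation
#'
#' Annotations are propagated up the ontology graph (is_a/part_of parents)
#' before testing; each term is tested with the classic (non-eliminating)
#' one-sided Fisher's exact test of target-vs-background membership and
#' BH-adjusted.
#'
#' @param target_genes character vector (subset of background).
#' @param background_genes character vector of all analyzable genes.
#' @param go_annotations data.frame gene_id, term.
#' @param go_parents optional data.frame term, parent for propagation.
#' @param top_n truncate the report to the strongest terms (default 100).
#' @return data.frame term, n_target, n_background, p, p_adjusted, fold.
#' @export
go_enrichment <- function(target_genes, background_genes, go_annotations,
                          go_parents = NULL, top_n = 100) {
  assert_cols(go_annotations, c("gene_id", "term"), "GO annotations")
  anno <- go_annotations[go_annotations$gene_id %in% background_genes, ]
  if (!is.null(go_parents)) {
    assert_cols(go_parents, c("term", "parent"), "GO parents")
    # transitive closure by iterated joins (the GO DAG is shallow)
    cur <- anno
    repeat {
      up <- merge(cur, go_parents, by = "term")
      if (nrow(up) == 0) break
      up <- data.frame(gene_id = up$gene_id, term = up$parent,
                       stringsAsFactors = FALSE)
      new <- up[!paste(up$gene_id, up$term) %in% paste(anno$gene_id, anno$term), ]
      if (nrow(new) == 0) break
      anno <- rbind(anno, new)
      cur <- new
    }
  }
  anno <- unique(anno)
  terms <- unique(anno$term)
  n_t <- length(unique(target_genes))
  n_b <- length(unique(background_genes))
  rows <- lapply(terms, function(tm) {
    g <- unique(anno$gene_id[anno$term == tm])
    a <- sum(target_genes %in% g)
    b <- n_t - a
    c2 <- length(g) - a
    d <- n_b - n_t - c2
    p <- fisher.test(matrix(c(a, b, c2, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    exp_a <- n_t * length(g) / n_b
    data.frame(term = tm, n_target = a, n_background = length(g), p = p,
               fold = if (exp_a > 0) a / exp_a else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  out <- out[order(out$p), ]
  head(out, top_n)
}

#' Map outgroup candidate gene ids to focal-species genes via orthogroups
#'
#' Used to define e.g. the CAM-related gene set from a published outgroup
#' candidate list: every focal-species gene sharing an orthogroup with a
#' candidate id is returned.
#'
#' @param candidate_ids outgroup (species A) gene ids.
#' @param og `orthogroups` table.
#' @return list with `genes_F`, `genes_L`, `orthogroup_ids` and the unknown
#'   ids that were skipped (with a warning).
#' @export
candidate_gene_lookup <- function(candidate_ids, og) {
  candidate_ids <- unique(candidate_ids)
  all_a <- unlist(og$genes_A)
  unknown <- setdiff(candidate_ids, all_a)
  if (length(unknown) > 0) {
    warning(length(unknown), " candidate id(s) not found in any orthogroup")
  }
  hit <- vapply(og$genes_A, function(g) any(g %in% candidate_ids), FALSE)
  list(genes_F = unique(unlist(og$genes_F[hit])),
       genes_L = unique(unlist(og$genes_L[hit])),
       orthogroup_ids = og$orthogroup_id[hit],
       unknown = unknown)
}
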