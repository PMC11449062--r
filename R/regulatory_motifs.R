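# Circadian cis-element scanning in upstream regions: the Morning Element,
# Evening Element, CCA1-binding site and G-box, counted as overlapping exact
# matches on the promoter's sense strand.

#' Default circadian motif set
#'
#' MOE (Morning Element) CCACAC, EE (Evening Element) AAAATATC, CBS
#' (CCA1-binding site) AAAAATCT, G-box CACGTG.
#'
#' @return named character vector of motif patterns.
#' @export
default_motifs <- function() {
  c(MOE = "CCACAC", EE = "AAAATATC", CBS = "AAAAATCT", `G-box` = "CACGTG")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Extract the strand-aware upstream (promoter) region of a gene
#'
#' For "+" genes the interval [start - length, start) on the forward strand;
#' for "-" genes [end, end + length) reverse-complemented, so the returned
#' sequence always reads 5' to 3' toward the gene.  Clipped at scaffold
#' edges; the realized length is recorded.
#'
#' @param gene one-row `gene_models` entry.
#' @param genome named character vector of scaffold sequences.
#' @param length upstream length in bp (default 2000).
#' @return list(sequence, length).
#' @export
extract_upstream <- function(gene, genome, length = 2000) {
  seqs <- genome[[gene$scaffold_id[[1]]]]
  if (is.null(seqs)) stop("unknown scaffold ", gene$scaffold_id[[1]])
  slen <- nchar(seqs)
  if (gene$strand[[1]] == "+") {
    a <- max(0, gene$start[[1]] - length)
    b <- gene$start[[1]]
    s <- substr(seqs, a + 1, b)
  } else {
    a <- gene$end[[1]]
    b <- min(slen, gene$end[[1]] + length)
    s <- revcomp(substr(seqs, a + 1, b))
  }
  list(sequence = s, length = nchar(s))
}

#' Count overlapping motif occurrences in a sequence
#'
#' Exact string matching on the given (sense) strand; the sequence is
#' uppercased first so soft-masking does not suppress matches, and N never
#' matches.  With `both_strands = TRUE` the reverse complement is also
#' scanned (the G-box is its own reverse complement; the others are not).
#'
#' @param sequence nucleotide string.
#' @param motifs named character vector (default [default_motifs()]).
#' @param both_strands scan both strands (default FALSE).
#' @return named integer vector of counts.
#' @export
count_motifs <- function(sequence, motifs = default_motifs(), both_strands = FALSE) {
  subj <- Biostrings::DNAString(toupper(sequence))
  out <- vapply(motifs, function(m) {
    n <- Biostrings::countPattern(m, subj, fixed = TRUE)
    if (both_strands) {
      n <- n + Biostrings::countPattern(revcomp(m), subj, fixed = TRUE)
    }
    as.integer(n)
  }, 0L)
  names(out) <- names(motifs)
  out
}

#' Per-kb motif frequency over a gene set
#'
#' By default the denominator is the nominal total promoter length
#' (`length_per_gene` x number of genes), matching how published per-kb
#' frequencies are normalized; set `paper_denominator = FALSE` to divide by
#' the realized summed promoter length instead.
#'
#' @param total_counts named vector of summed motif counts over the set.
#' @param n_genes number of genes in the set.
#' @param length_per_gene nominal promoter length in bp (default 2000).
#' @param paper_denominator use the nominal denominator (default TRUE).
#' @param actual_total_bp realized summed promoter length (required when
#'   `paper_denominator = FALSE`).
#' @return named vector of per-kb frequencies.
#' @export
perkb_frequency <- function(total_counts, n_genes, length_per_gene = 2000,
                            paper_denominator = TRUE, actual_total_bp = NULL) {
  if (n_genes == 0) stop("empty gene set")
  kb <- if (paper_denominator) {
    length_per_gene * n_genes / 1000
  } else {
    if (is.null(actual_total_bp)) stop("actual_total_bp required")
    actual_total_bp / 1000
  }
  total_counts / kb
}

#' Percent change in motif frequency between a DE set and background
#' @param freq_de,freq_background per-kb frequencies.
#' @return percent change; NA when the background frequency is zero.
#' @export
frequency_change <- function(freq_de, freq_background) {
  out <- 100 * (freq_de - freq_background) / freq_background
  out[freq_background == 0] <- NA_real_
  out
}

#' Mann-Whitney test of per-promoter motif counts, DE vs background
#'
#' The background is subsampled without replacement to at most
#' `subsample` promoters (stabilizing p-values against the very large
#' non-DE set), then a two-sided Mann-Whitney U test compares per-promoter
#' counts.
#'
#' @param counts_de,counts_bg integer vectors of per-promoter counts.
#' @param subsample background subsample size (default 5000).
#' @param seed subsampling seed.
#' @return `stat_result` (note records the subsample size and seed).
#' @export
motif_mw_test <- function(counts_de, counts_bg, subsample = 5000, seed = 1) {
  stopifnot(length(counts_de) > 0, length(counts_bg) > 0)
  k <- min(subsample, length(counts_bg))
  bg <- with_seed(seed, sample(counts_bg, k))
  r <- mann_whitney(counts_de, bg)
  r$note <- sprintf("background subsampled to %d (seed %d); %s", k, seed, r$note)
  r
}

#' Motif counts for candidate genes and their homologs in both species
#'
#' For each candidate orthogroup, counts each motif in the upstream region
#' (default 3 kb, allowing for distal occurrences) of every member gene in
#' both focal species, side by side.
#'
#' @param candidate_og orthogroup ids of interest.
#' @param og `orthogroups` table.
#' @param genes_F,genes_L `gene_models` tables for the two species.
#' @param genome_F,genome_L named scaffold sequence vectors.
#' @param length upstream length (default 3000).
#' @param motifs motif set.
#' @return data.frame orthogroup_id, species, gene_id, one column per motif;
#'   candidates without a homolog in a species yield a row of NAs.
#' @export
candidate_motif_table <- function(candidate_og, og, genes_F, genes_L,
                                  genome_F, genome_L, length = 3000,
                                  motifs = default_motifs()) {
  rows <- list()
  for (ogid in candidate_og) {
    k <- match(ogid, og$orthogroup_id)
    if (is.na(k)) next
    for (sp in c("F", "L")) {
      gl <- if (sp == "F") og$genes_F[[k]] else og$genes_L[[k]]
      gm <- if (sp == "F") genes_F else genes_L
      gn <- if (sp == "F") genome_F else genome_L
      if (length(gl) == 0) {
        na_row <- as.list(setNames(rep(NA_integer_, length(motifs)), names(motifs)))
        rows[[length(rows) + 1]] <- data.frame(orthogroup_id = ogid, species = sp,
                                               gene_id = NA_character_, na_row,
                                               check.names = FALSE)
        next
      }
      for (g in gl) {
        i <- match(g, gm$gene_id)
        if (is.na(i)) next
        up <- extract_upstream(gm[i, ], gn, length = length)
        cnt <- count_motifs(up$sequence, motifs)
        rows[[length(rows) + 1]] <- data.frame(orthogroup_id = ogid, species = sp,
                                               gene_id = g, as.list(cnt),
                                               check.names = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
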