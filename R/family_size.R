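# Coverage-based correction of orthogroup gene counts.  Haplotig-derived
# gene models split the reads of one biological copy over two loci, so each
# copy sits near half the single-copy coverage; rescaling the summed
# orthogroup coverage by the single-copy mean recovers the true copy number.

#' Mean per-base read coverage over a gene span
#'
#' @param per_base data.frame (scaffold_id, pos, depth) with pos 0-based;
#'   positions without a record count as depth 0.
#' @param gene one-row `gene_models` entry.
#' @param scaffold_lengths named vector for bounds checking (optional).
#' @return arithmetic mean depth over [start, end).
#' @export
mean_gene_coverage <- function(per_base, gene, scaffold_lengths = NULL) {
  assert_cols(per_base, c("scaffold_id", "pos", "depth"), "coverage table")
  if (!is.null(scaffold_lengths)) {
    sl <- scaffold_lengths[[gene$scaffold_id[[1]]]]
    if (is.null(sl) || gene$end[[1]] > sl || gene$start[[1]] < 0) {
      stop("gene interval outside scaffold ", gene$scaffold_id[[1]])
    }
  }
  sel <- per_base$scaffold_id == gene$scaffold_id[[1]] &
    per_base$pos >= gene$start[[1]] & per_base$pos < gene$end[[1]]
  sum(per_base$depth[sel]) / (gene$end[[1]] - gene$start[[1]])
}

#' Mean coverage of single-copy genes in one species
#'
#' The reference coverage for size correction: the average over genes that
#' sit in orthogroups with exactly one gene in every species.
#'
#' @param og `orthogroups` table.
#' @param coverage named numeric vector gene_id -> mean coverage.
#' @param species "F" or "L".
#' @return scalar mean coverage.
#' @export
singlecopy_mean_coverage <- function(og, coverage, species = c("F", "L")) {
  species <- match.arg(species)
  anc_single <- og$A == 1 & og$F_count == 1 & og$L_count == 1
  ids <- unlist(if (species == "F") og$genes_F[anc_single] else og$genes_L[anc_single])
  ids <- ids[ids %in% names(coverage)]
  if (length(ids) == 0) stop("no single-copy genes with coverage for species ", species)
  mean(coverage[ids])
}

#' Classify an orthogroup by per-species copy number
#'
#' Labels per species: single-copy (count 1), multicopy (count > 1),
#' ancestral single-copy (count 1 in all species), ancestral multicopy
#' (count > 1 and equal in all species), unique multicopy (count > 1 with 0
#' in the other species).
#'
#' @param record one-row `orthogroups` entry (or list with A, F_count, L_count).
#' @return named list species -> character vector of labels.
#' @export
classify_orthogroup <- function(record) {
  counts <- c(A = record$A[[1]], F = record$F_count[[1]], L = record$L_count[[1]])
  anc_single <- all(counts == 1)
  anc_multi <- all(counts > 1) && length(unique(counts)) == 1
  lab <- lapply(names(counts), function(sp) {
    n <- counts[[sp]]
    l <- character(0)
    if (n == 1) l <- c(l, "single-copy")
    if (n > 1) l <- c(l, "multicopy")
    if (anc_single) l <- c(l, "ancestral single-copy")
    if (anc_multi) l <- c(l, "ancestral multicopy")
    if (n > 1 && all(counts[setdiff(names(counts), sp)] == 0)) {
      l <- c(l, "unique multicopy")
    }
    l
  })
  setNames(lab, names(counts))
}

#' Coverage-correct the gene count of one orthogroup in one species
#'
#' Correction factor r = (sum of member-gene coverages) / (n x single-copy
#' mean coverage); corrected count = round(n x r) = round(sum cov / mean),
#' rounded half away from zero and clamped to at least 1 when the orthogroup
#' has observed genes with positive coverage.
#'
#' @param member_covs coverages of the orthogroup's genes in this species.
#' @param singlecopy_mean species single-copy mean coverage (> 0).
#' @return integer corrected count.
#' @export
correct_count <- function(member_covs, singlecopy_mean) {
  if (singlecopy_mean <= 0) stop("single-copy mean coverage must be positive")
  if (any(is.na(member_covs))) stop("missing coverage for a member gene")
  n <- length(member_covs)
  if (n == 0) return(0L)
  corr <- round_half_away(sum(member_covs) / singlecopy_mean)
  if (sum(member_covs) > 0) corr <- max(corr, 1)
  as.integer(corr)
}

#' Apply coverage-based size correction across an orthogroup table
#'
#' Corrections are applied only to orthogroups containing multicopy genes
#' (copy number above 1 in at least one focal species); all other
#' orthogroups keep their raw counts.
#'
#' @param og `orthogroups` table.
#' @param coverage_F,coverage_L named numeric vectors gene_id -> coverage.
#' @param singlecopy_F,singlecopy_L optional single-copy means; computed
#'   from the table when omitted.
#' @return `og` with `corrected_F` and `corrected_L` filled.
#' @export
correct_family_size <- function(og, coverage_F, coverage_L,
                                singlecopy_F = NULL, singlecopy_L = NULL) {
  if (is.null(singlecopy_F)) singlecopy_F <- singlecopy_mean_coverage(og, coverage_F, "F")
  if (is.null(singlecopy_L)) singlecopy_L <- singlecopy_mean_coverage(og, coverage_L, "L")
  multicopy <- og$F_count > 1 | og$L_count > 1
  og$corrected_F <- as.numeric(og$F_count)
  og$corrected_L <- as.numeric(og$L_count)
  for (k in which(multicopy)) {
    og$corrected_F[k] <- correct_count(unname(coverage_F[og$genes_F[[k]]]),
                                       singlecopy_F)
    og$corrected_L[k] <- correct_count(unname(coverage_L[og$genes_L[[k]]]),
                                       singlecopy_L)
  }
  og
}

#' Relative family-size category of an orthogroup
#'
#' Categories: F=1:L=1, F>L, F<L, F=L(>1), F-unique (L = 0), L-unique
#' (F = 0).  Species-unique orthogroups keep their label but are excluded
#' from enrichment by [category_enrichment()].
#'
#' @param F_n,L_n (corrected) gene counts in the two focal species.
#' @return category label.
#' @export
categorize_relative_size <- function(F_n, L_n) {
  if (F_n == 0 && L_n == 0) stop("empty orthogroup (F = L = 0)")
  if (L_n == 0) return("F-unique")
  if (F_n == 0) return("L-unique")
  if (F_n == 1 && L_n == 1) return("F=1:L=1")
  if (F_n > L_n) return("F>L")
  if (F_n < L_n) return("F<L")
  "F=L(>1)"
}

#' Categorize every orthogroup in a table
#' @param og `orthogroups` table with corrected counts (raw used when NA).
#' @return `og` with the `category` column filled.
#' @export
categorize_all <- function(og) {
  f <- ifelse(is.na(og$corrected_F), og$F_count, og$corrected_F)
  l <- ifelse(is.na(og$corrected_L), og$L_count, og$corrected_L)
  og$category <- vapply(seq_len(nrow(og)),
                        function(k) categorize_relative_size(f[k], l[k]), "")
  og
}

#' Log-ratio of per-species family size
#'
#' ln(F/L); defined only for orthogroups present in both species.
#'
#' @param F_n,L_n positive gene counts.
#' @return numeric; NA with a warning when a count is zero.
#' @export
family_log_ratio <- function(F_n, L_n) {
  bad <- F_n == 0 | L_n == 0
  if (any(bad)) {
    warning(sum(bad), " orthogroup(s) with a zero count excluded from log-ratio")
  }
  out <- log(F_n / L_n)
  out[bad] <- NA_real_
  out
}

#' Family-size difference z-score of an orthogroup set against background
#'
#' With d = F - L per orthogroup, z = (mean(d_set) - mean(d_background)) /
#' (sd(d_background) / sqrt(n_set)).  Negative scores indicate a tendency
#' toward larger families in species L.
#'
#' @param d_set numeric vector of F - L for the set.
#' @param d_background numeric vector of F - L for the background.
#' @return z-score; NA when the set is empty or the background has zero
#'   spread.
#' @export
family_size_zscore <- function(d_set, d_background) {
  n <- length(d_set)
  s <- sd(d_background)
  if (n == 0 || is.na(s) || s == 0) return(NA_real_)
  (mean(d_set) - mean(d_background)) / (s / sqrt(n))
}
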