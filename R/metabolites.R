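# Diel metabolite statistics on MTIC-normalized GC-MS abundances: the 24-h
# accumulation statistic (max - min per accession), median fold differences
# across time points, the between-species Mann-Whitney test, and PCA.

#' Timepoint labels of the diel sampling design mapped to hours
#'
#' D+1/D+5/D+9 are hours after lights-on; N+1/N+5/N+9 follow a 12-h light
#' period, giving hours 1, 5, 9, 13, 17, 21.
#'
#' @return named numeric vector.
#' @export
diel_timepoints <- function() {
  c(`D+1` = 1, `D+5` = 5, `D+9` = 9, `N+1` = 13, `N+5` = 17, `N+9` = 21)
}

#' Normalize raw compound areas by the per-sample main total ion count
#'
#' @param raw_areas data.frame: species, accession, timepoint, then one
#'   column per compound (summed areas).
#' @param mtic numeric vector of per-sample MTIC values (row-parallel).
#' @return the table with compound columns divided by MTIC; zero-MTIC
#'   samples are dropped with a warning.
#' @export
mtic_normalize <- function(raw_areas, mtic) {
  stopifnot(length(mtic) == nrow(raw_areas))
  bad <- mtic <= 0 | is.na(mtic)
  if (any(bad)) {
    warning(sum(bad), " sample(s) with zero MTIC dropped")
    raw_areas <- raw_areas[!bad, , drop = FALSE]
    mtic <- mtic[!bad]
  }
  meta_cols <- c("species", "accession", "timepoint")
  comp <- setdiff(names(raw_areas), meta_cols)
  raw_areas[comp] <- raw_areas[comp] / mtic
  raw_areas
}

#' 24-h accumulation of a compound in one accession
#'
#' The difference between the highest and lowest abundance across the
#' accession's time series.
#'
#' @param series numeric vector over time points (NAs tolerated).
#' @return max - min; NA for an all-missing series.
#' @export
accumulation <- function(series) {
  v <- series[!is.na(series)]
  if (length(v) == 0) return(NA_real_)
  max(v) - min(v)
}

#' Per-accession accumulations of one compound, per species
#' @param table MTIC-normalized table (species, accession, timepoint, compounds).
#' @param compound compound column name.
#' @return data.frame species, accession, accumulation.
#' @export
accumulation_by_accession <- function(table, compound) {
  assert_cols(table, c("species", "accession", compound), "metabolite table")
  key <- interaction(table$species, table$accession, drop = TRUE)
  acc <- tapply(table[[compound]], key, accumulation)
  meta <- do.call(rbind, strsplit(names(acc), ".", fixed = TRUE))
  data.frame(species = meta[, 1], accession = meta[, 2],
             accumulation = as.numeric(acc), stringsAsFactors = FALSE)
}

#' Fold difference between the peak and trough median abundance
#'
#' Medians are taken per time point across accessions of one species; the
#' fold is max median / min median with peak and trough time points
#' reported.
#'
#' @param table MTIC-normalized table restricted to one species.
#' @param compound compound column name.
#' @return list(peak_time, trough_time, fold, medians); fold is Inf with a
#'   flag when the trough median is 0.
#' @export
median_fold <- function(table, compound) {
  med <- tapply(table[[compound]], table$timepoint, median, na.rm = TRUE)
  med <- med[!is.na(med)]
  if (length(med) < 2) stop("need >= 2 time points with observations")
  peak <- names(med)[which.max(med)]
  trough <- names(med)[which.min(med)]
  fold <- if (min(med) == 0) Inf else max(med) / min(med)
  list(peak_time = peak, trough_time = trough, fold = fold,
       medians = med, trough_zero = min(med) == 0)
}

#' Between-species Mann-Whitney test of 24-h accumulation
#'
#' Exact two-sided test of the per-accession accumulation statistic between
#' the two species (6 vs 6 accessions in the complete design); the fold of
#' species median accumulations is reported as effect.
#'
#' @param table MTIC-normalized table with both species.
#' @param compound compound column name.
#' @return `stat_result` with the median fold as effect.
#' @export
species_accumulation_test <- function(table, compound) {
  acc <- accumulation_by_accession(table, compound)
  sp <- unique(acc$species)
  stopifnot(length(sp) == 2)
  x <- acc$accumulation[acc$species == sp[1]]
  y <- acc$accumulation[acc$species == sp[2]]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 accessions per species")
  r <- mann_whitney(x, y)
  r$effect <- median(x) / max(median(y), .Machine$double.xmin)
  r$note <- paste0(sp[1], " vs ", sp[2], "; effect = fold of median accumulation; ",
                   r$note)
  r
}

#' PCA of metabolic composition
#'
#' Columns (compounds) are median-imputed, centered and scaled to unit
#' variance; zero-variance compounds are dropped with a warning.
#'
#' @param table metabolite table (species, accession, timepoint, compounds).
#' @return list(scores, loadings, variance_explained, dropped).
#' @export
metabolite_pca <- function(table) {
  meta_cols <- intersect(c("species", "accession", "timepoint"), names(table))
  X <- as.matrix(table[, setdiff(names(table), meta_cols), drop = FALSE])
  stopifnot(nrow(X) >= 2, ncol(X) >= 2)
  for (j in seq_len(ncol(X))) {
    X[is.na(X[, j]), j] <- median(X[, j], na.rm = TRUE)
  }
  v <- apply(X, 2, var)
  dropped <- colnames(X)[v == 0]
  if (length(dropped) > 0) {
    warning(length(dropped), " zero-variance compound(s) dropped")
    X <- X[, v > 0, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  list(scores = pc$x, loadings = pc$rotation,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2), dropped = dropped)
}
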