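# From exon-level counts to genes with differential diurnal expression
# profiles between species: summarize, TMM-normalize, filter, and run a
# two-stage polynomial-regression caller (stage 1: overall regression F-test
# with BH correction; stage 2: backward term elimination), then cluster the
# significant profiles.

#' Sum exon counts to gene-level counts
#'
#' @param exon_matrix counts matrix, exons x samples.
#' @param exon_gene gene id per exon row; by default parsed from rownames of
#'   the form `<gene>.exon<k>`.
#' @return gene x sample count matrix.
#' @export
exon_to_gene_counts <- function(exon_matrix, exon_gene = NULL) {
  if (is.null(exon_gene)) exon_gene <- sub("\\.exon\\d+$", "", rownames(exon_matrix))
  if (length(exon_gene) != nrow(exon_matrix) || any(is.na(exon_gene)) ||
      any(exon_gene == "")) {
    stop("exon without parent gene")
  }
  out <- rowsum(exon_matrix, group = exon_gene, reorder = FALSE)
  out[order(rownames(out)), , drop = FALSE]
}

#' TMM normalization factors (trimmed mean of M-values)
#'
#' Between-sample normalization for count libraries: per sample versus a
#' reference (the library whose upper quartile is closest to the mean upper
#' quartile), genes zero in either are dropped, the 30% tails of M
#' (log-ratio) and 5% tails of A (log-abundance) are trimmed, and the
#' remaining M are averaged with inverse approximate variances.  Factors are
#' rescaled to geometric mean 1.  Computed by edgeR.
#'
#' @param gene_matrix gene x sample count matrix (>= 2 samples).
#' @return numeric factors, one per sample.
#' @export
tmm_normalize <- function(gene_matrix) {
  if (ncol(gene_matrix) < 2) stop("TMM needs at least 2 samples")
  if (any(colSums(gene_matrix) == 0)) stop("sample with all-zero counts")
  edgeR::calcNormFactors(gene_matrix, method = "TMM")
}

#' Counts per million under TMM-effective library sizes
#' @param gene_matrix gene x sample count matrix.
#' @param factors TMM factors from [tmm_normalize()].
#' @return cpm matrix.
#' @export
cpm_matrix <- function(gene_matrix, factors) {
  lib <- colSums(gene_matrix) * factors
  t(t(gene_matrix) / lib) * 1e6
}

#' Remove weakly expressed genes (mean cpm below 1)
#' @param gene_matrix gene x sample count matrix.
#' @param factors TMM factors.
#' @param min_mean_cpm threshold; genes with mean cpm >= this are kept.
#' @return filtered count matrix.
#' @export
cpm_filter <- function(gene_matrix, factors, min_mean_cpm = 1) {
  keep <- rowMeans(cpm_matrix(gene_matrix, factors)) >= min_mean_cpm
  gene_matrix[keep, , drop = FALSE]
}

#' Transcripts per million
#'
#' Raw counts divided by exonic length in kb (RPK), rescaled so each sample
#' sums to 10^6.
#'
#' @param gene_matrix gene x sample count matrix.
#' @param exonic_len_kb named vector of exonic lengths (kb) per gene.
#' @return TPM matrix.
#' @export
tpm <- function(gene_matrix, exonic_len_kb) {
  len <- exonic_len_kb[rownames(gene_matrix)]
  if (any(is.na(len)) || any(len <= 0)) stop("missing or zero exonic length")
  rpk <- gene_matrix / len
  t(t(rpk) / colSums(rpk)) * 1e6
}

de_design_matrix <- function(design, degree) {
  S <- as.numeric(design$species != (attr(design, "baseline") %||% "L"))
  tt <- design$time / 24          # scaled to one cycle for conditioning
  X <- cbind(Intercept = 1, S = S)
  for (k in seq_len(degree)) {
    X <- cbind(X, tt^k)
    colnames(X)[ncol(X)] <- paste0("t", k)
  }
  for (k in seq_len(degree)) {
    X <- cbind(X, S * tt^k)
    colnames(X)[ncol(X)] <- paste0("S.t", k)
  }
  X
}

#' Two-stage regression caller for differential diurnal expression
#'
#' Stage 1 fits, on log2(cpm + 1), the full polynomial model
#' y = b0 + b1 S + sum_k (g_k t^k + d_k S t^k) with S = 0 for the baseline
#' species, tests the overall regression with an F-test, and keeps genes
#' with BH-adjusted p <= alpha.  Stage 2 removes terms backward-stepwise at
#' alpha.  A gene is DE iff the final model retains the species term or any
#' species x time interaction, and its R-squared is at least `rsq_min`.
#'
#' @param gene_matrix filtered gene x sample count matrix.
#' @param design data.frame with columns sample, species, genotype, time
#'   (hours into the diel cycle); rows parallel to matrix columns.
#' @param factors TMM factors (recomputed when NULL).
#' @param degree polynomial degree (default 3).
#' @param alpha significance level for both stages (default 0.05).
#' @param rsq_min minimum R-squared of the final model (default 0.6).
#' @param baseline species level coded S = 0 (default "L").
#' @return data.frame (one row per gene): p, p_adjusted, rsq,
#'   selected_terms, species_term, is_DE.
#' @export
timecourse_de <- function(gene_matrix, design, factors = NULL, degree = 3,
                          alpha = 0.05, rsq_min = 0.6, baseline = "L") {
  assert_cols(design, c("species", "time"), "design")
  stopifnot(nrow(design) == ncol(gene_matrix))
  reps <- table(design$species, design$time)
  if (any(reps < 2)) stop("need >= 2 replicates per species x time cell")
  if (degree > length(unique(design$time)) - 1) {
    stop("degree must be at most (number of time points - 1)")
  }
  if (is.null(factors)) factors <- tmm_normalize(gene_matrix)
  attr(design, "baseline") <- baseline
  y <- log2(cpm_matrix(gene_matrix, factors) + 1)
  X <- de_design_matrix(design, degree)
  n <- nrow(X); p <- ncol(X)
  qr_x <- qr(X)
  if (qr_x$rank < p) stop("rank-deficient design")
  # stage 1: overall regression F-test, all genes at once
  resid_full <- t(y) - X %*% qr.coef(qr_x, t(y))
  rss <- colSums(resid_full^2)
  tss <- colSums(scale(t(y), scale = FALSE)^2)
  fstat <- ((tss - rss) / (p - 1)) / (rss / (n - p))
  p1 <- pf(fstat, p - 1, n - p, lower.tail = FALSE)
  p1[tss == 0] <- 1
  padj <- bh_adjust(p1)
  rsq_full <- ifelse(tss > 0, 1 - rss / tss, 0)
  res <- data.frame(gene_id = rownames(y), p = p1, p_adjusted = padj,
                    rsq = rsq_full, selected_terms = "", species_term = FALSE,
                    is_DE = FALSE, stringsAsFactors = FALSE)
  # stage 2: backward-stepwise term elimination for stage-1 survivors
  survivors <- which(!is.na(padj) & padj <= alpha)
  for (g in survivors) {
    keep <- colnames(X)
    yy <- y[g, ]
    repeat {
      Xk <- X[, keep, drop = FALSE]
      fit <- lm(yy ~ Xk - 1)
      sm <- summary(fit)$coefficients
      rownames(sm) <- sub("^Xk", "", rownames(sm))
      cand <- setdiff(rownames(sm), "Intercept")
      if (length(cand) == 0) break
      worst <- cand[which.max(sm[cand, 4])]
      if (sm[worst, 4] > alpha) {
        keep <- setdiff(keep, worst)
        if (length(keep) <= 1) break
      } else break
    }
    final_terms <- setdiff(keep, "Intercept")
    Xf <- X[, keep, drop = FALSE]
    ff <- lm(yy ~ Xf - 1)
    rsq <- 1 - sum(resid(ff)^2) / max(sum((yy - mean(yy))^2), .Machine$double.eps)
    sp_term <- any(final_terms == "S" | grepl("^S\\.t", final_terms))
    res$selected_terms[g] <- paste(final_terms, collapse = "+")
    res$species_term[g] <- sp_term
    res$rsq[g] <- rsq
    res$is_DE[g] <- sp_term && rsq >= rsq_min
  }
  res
}

#' Cluster DE expression profiles
#'
#' Distance is 1 - Pearson correlation between concatenated per-species mean
#' median-centered log-TPM profiles; average-linkage hierarchical clustering
#' cut at K, where K is the smallest k at which the k-means within-cluster
#' sum of squares improves by less than 10% (capped at `k_max`).
#'
#' @param profiles matrix genes x (species x time) of mean profiles.
#' @param k_max cluster-count cap (default 12).
#' @param improvement elbow threshold (default 0.10).
#' @return integer cluster assignment named by gene.
#' @export
cluster_de <- function(profiles, k_max = 12, improvement = 0.10) {
  if (nrow(profiles) < 2) stop("need >= 2 DE genes to cluster")
  k_cap <- min(k_max, nrow(profiles) - 1)
  ctr <- profiles - rowMeans(profiles)
  ctr[apply(ctr, 1, sd) == 0, ] <- 0      # constant profiles: zero-distance row
  wss <- vapply(seq_len(k_cap), function(k) {
    km <- kmeans(profiles, centers = k, nstart = 5, iter.max = 50)
    km$tot.withinss
  }, 0)
  # elbow: improvement measured against the one-cluster dispersion, so
  # near-zero within-cluster SS does not inflate relative gains
  K <- k_cap
  for (k in seq_len(k_cap - 1)) {
    if ((wss[k] - wss[k + 1]) / max(wss[1], .Machine$double.eps) < improvement) {
      K <- k; break
    }
  }
  cc <- suppressWarnings(cor(t(profiles)))
  cc[is.na(cc)] <- 1                       # constant profiles join by convention
  d <- as.dist(1 - cc)
  tree <- hclust(d, method = "average")
  cutree(tree, k = K)
}

#' Expression curves for plotting
#'
#' `mean_sd`: per species x time mean TPM and sd across replicates.
#' `median_centered`: log2(mean TPM + 1) minus the across-genes median at
#' each species x time point.
#'
#' @param tpm_matrix TPM layer, genes x samples.
#' @param design design data.frame (species, time).
#' @param mode "mean_sd" or "median_centered".
#' @return long data.frame gene_id, species, time, value (and sd for
#'   mean_sd mode).
#' @export
expression_curves <- function(tpm_matrix, design, mode = c("mean_sd", "median_centered")) {
  mode <- match.arg(mode)
  key <- interaction(design$species, design$time, drop = TRUE)
  mean_mat <- t(apply(tpm_matrix, 1, function(v) tapply(v, key, mean)))
  meta <- do.call(rbind, strsplit(colnames(mean_mat), ".", fixed = TRUE))
  long <- function(m, valname) {
    df <- data.frame(gene_id = rep(rownames(m), ncol(m)),
                     species = rep(meta[, 1], each = nrow(m)),
                     time = as.numeric(rep(meta[, 2], each = nrow(m))),
                     value = as.vector(m), stringsAsFactors = FALSE)
    names(df)[names(df) == "value"] <- valname
    df
  }
  if (mode == "mean_sd") {
    sd_mat <- t(apply(tpm_matrix, 1, function(v) tapply(v, key, sd)))
    out <- long(mean_mat, "mean_tpm")
    out$sd_tpm <- as.vector(sd_mat)
    return(out[order(out$gene_id, out$species, out$time), ])
  }
  lg <- log2(mean_mat + 1)
  ctr <- sweep(lg, 2, apply(lg, 2, median))
  out <- long(ctr, "centered_log_tpm")
  out[order(out$gene_id, out$species, out$time), ]
}
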