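# Windowed genome-composition statistics on soft-masked assemblies, and the
# spatial distribution of DE genes.  TE content is read directly off the
# soft-masked (lowercase) positions.

seq_base_stats <- function(chunk) {
  r <- charToRaw(chunk)
  lc <- sum(r >= charToRaw("a") & r <= charToRaw("z"))
  up <- toupper(chunk)
  cnt <- vapply(c("A", "C", "G", "T", "N"), function(b) {
    sum(charToRaw(up) == charToRaw(b))
  }, 0L)
  list(length = nchar(chunk), lowercase = lc, counts = cnt)
}

tile_starts <- function(len, window) seq(0L, max(len - 1L, 0L), by = window)

#' Coarse per-window composition: gene count, masked fraction, GC
#'
#' Non-overlapping tiling from position 0; the last partial window keeps its
#' actual length.  Genes are assigned to the window containing their start;
#' GC is computed over A/C/G/T only (N excluded from the denominator);
#' masked fraction is lowercase bases over window length.
#'
#' @param genome named character vector of scaffold sequences.
#' @param genes `gene_models` table.
#' @param window window size in bp (default 1e6).
#' @return data.frame scaffold_id, start, end, gene_count, masked_fraction,
#'   gc_fraction.
#' @export
window_stats <- function(genome, genes, window = 1000000) {
  stopifnot(window > 0)
  rows <- lapply(names(genome), function(sc) {
    s <- genome[[sc]]
    len <- nchar(s)
    st <- tile_starts(len, window)
    en <- pmin(st + window, len)
    gs <- genes$start[genes$scaffold_id == sc]
    gc_f <- numeric(length(st)); mf <- numeric(length(st)); gcnt <- integer(length(st))
    for (i in seq_along(st)) {
      b <- seq_base_stats(substr(s, st[i] + 1, en[i]))
      acgt <- sum(b$counts[c("A", "C", "G", "T")])
      gc_f[i] <- if (acgt > 0) sum(b$counts[c("G", "C")]) / acgt else NA_real_
      mf[i] <- b$lowercase / b$length
      gcnt[i] <- sum(gs >= st[i] & gs < en[i])
    }
    data.frame(scaffold_id = sc, start = st, end = en, gene_count = gcnt,
               masked_fraction = mf, gc_fraction = gc_f, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

merged_coverage_in_window <- function(iv_start, iv_end, w_start, w_end) {
  if (length(iv_start) == 0) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(iv_start + 1L, iv_end))
  win <- IRanges::IRanges(w_start + 1L, w_end)
  sum(IRanges::width(IRanges::intersect(ir, win)))
}

#' Fine per-window composition: TE fraction, GC in/outside repeats, genic
#' and non-robust gene fractions
#'
#' `gc_in_te` is computed only over soft-masked positions (NA when a window
#' has none); genic fraction uses merged gene-interval coverage; the
#' non-robust fraction is non-robust gene positions over all gene positions.
#'
#' @param genome named character vector of (soft-masked) scaffold sequences.
#' @param genes `gene_models` table.
#' @param robust_status named character vector gene_id -> "ROBUST"/"NOT-ROBUST"
#'   (optional; NA fraction when absent).
#' @param window window size in bp (default 1e5).
#' @return data.frame with te_fraction, gc_all, gc_in_te, genic_fraction,
#'   nonrobust_gene_fraction per window.
#' @export
window_stats_fine <- function(genome, genes, robust_status = NULL,
                              window = 100000) {
  stopifnot(window > 0)
  rows <- lapply(names(genome), function(sc) {
    s <- genome[[sc]]
    len <- nchar(s)
    st <- tile_starts(len, window)
    en <- pmin(st + window, len)
    gsel <- genes$scaffold_id == sc
    g_start <- genes$start[gsel]; g_end <- genes$end[gsel]
    nr <- if (!is.null(robust_status)) {
      robust_status[genes$gene_id[gsel]] == "NOT-ROBUST"
    } else rep(NA, sum(gsel))
    out <- data.frame(scaffold_id = sc, start = st, end = en,
                      te_fraction = NA_real_, gc_all = NA_real_,
                      gc_in_te = NA_real_, genic_fraction = NA_real_,
                      nonrobust_gene_fraction = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(st)) {
      chunk <- substr(s, st[i] + 1, en[i])
      wlen <- nchar(chunk)
      ch <- strsplit(chunk, "")[[1]]
      is_mask <- ch %in% c("a", "c", "g", "t", "n")
      up <- toupper(ch)
      acgt <- up %in% c("A", "C", "G", "T")
      out$te_fraction[i] <- mean(is_mask)
      out$gc_all[i] <- if (any(acgt)) mean(up[acgt] %in% c("G", "C")) else NA
      m <- is_mask & acgt
      out$gc_in_te[i] <- if (any(m)) mean(up[m] %in% c("G", "C")) else NA
      gcov <- merged_coverage_in_window(g_start, g_end, st[i], en[i])
      out$genic_fraction[i] <- gcov / wlen
      if (!is.null(robust_status) && gcov > 0) {
        nrcov <- merged_coverage_in_window(g_start[nr], g_end[nr], st[i], en[i])
        out$nonrobust_gene_fraction[i] <- nrcov / gcov
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Kendall correlation of two windowed series with normality diagnostics
#'
#' Kendall's tau-b (tie-corrected) with an asymptotic two-sided p, plus
#' Shapiro-Wilk normality p-values for each series as the diagnostic that
#' motivates the rank-based test.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list(tau, p, shapiro_p_x, shapiro_p_y); tau NA for a constant
#'   series.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  kt <- kendall_tau_b(x, y)
  list(tau = kt$effect, p = kt$p,
       shapiro_p_x = if (sd(x) > 0) shapiro_wilk(x) else NA_real_,
       shapiro_p_y = if (sd(y) > 0) shapiro_wilk(y) else NA_real_)
}

#' Per-scaffold repetitive-to-exonic content ratio and species comparison
#'
#' Ratio = soft-masked bases / exonic bases per scaffold; species are
#' compared with Welch's unequal-variance t test, and the ratio of the two
#' species' mean ratios is reported.
#'
#' @param stats_a,stats_b data.frames with scaffold_id, masked_bases,
#'   exonic_bases per species.
#' @return list(ratios_a, ratios_b, ratio_of_means, test).
#' @export
repetitive_to_exonic <- function(stats_a, stats_b) {
  get_ratios <- function(df) {
    assert_cols(df, c("scaffold_id", "masked_bases", "exonic_bases"))
    bad <- df$exonic_bases == 0
    if (any(bad)) {
      warning(sum(bad), " scaffold(s) with zero exonic bases skipped")
    }
    df$masked_bases[!bad] / df$exonic_bases[!bad]
  }
  ra <- get_ratios(stats_a)
  rb <- get_ratios(stats_b)
  list(ratios_a = ra, ratios_b = rb,
       ratio_of_means = mean(ra) / mean(rb), test = welch_t(ra, rb))
}

#' Spatial distribution of DE genes
#'
#' Per-window DE density (count) and proportion (DE / total genes, NA in
#' gene-free windows), plus the Kendall correlation between per-scaffold DE
#' gene counts and scaffold lengths.
#'
#' @param genes `gene_models` table.
#' @param de_flags logical per gene.
#' @param scaffold_lengths named vector scaffold -> length.
#' @param window window size in bp (default 1e6).
#' @return list(windows = per-window data.frame, scaffold_correlation).
#' @export
de_spatial <- function(genes, de_flags, scaffold_lengths, window = 1000000) {
  stopifnot(length(de_flags) == nrow(genes))
  rows <- lapply(names(scaffold_lengths), function(sc) {
    len <- scaffold_lengths[[sc]]
    st <- tile_starts(len, window)
    en <- pmin(st + window, len)
    sel <- genes$scaffold_id == sc
    gs <- genes$start[sel]; de <- de_flags[sel]
    w <- pmin(gs %/% window + 1L, length(st))
    total <- as.integer(table(factor(w, levels = seq_along(st))))
    nde <- as.integer(table(factor(w[de], levels = seq_along(st))))
    data.frame(scaffold_id = sc, start = st, end = en, de_count = nde,
               gene_count = total,
               de_proportion = ifelse(total > 0, nde / total, NA_real_),
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, rows)
  per_sc <- tapply(de_flags, genes$scaffold_id, sum)
  sc <- intersect(names(scaffold_lengths), names(per_sc))
  corr <- if (length(sc) >= 3) {
    correlate(as.numeric(scaffold_lengths[sc]), as.numeric(per_sc[sc]))
  } else NULL
  list(windows = win, scaffold_correlation = corr)
}
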