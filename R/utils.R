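#' @importFrom stats median sd var quantile rnorm runif rpois rnbinom rmultinom
#' @importFrom stats p.adjust pchisq lm lm.fit pf coef resid wilcox.test t.test
#' @importFrom stats chisq.test fisher.test shapiro.test cor.test optim kmeans
#' @importFrom stats hclust cutree as.dist cor prcomp complete.cases setNames
#' @importFrom utils read.delim write.table head
NULL

# Deterministic child seed per named stream, so adding a stream never
# perturbs the draws of another.  Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Construct a statistical test result record
#'
#' Uniform container for the test statistics reported throughout the
#' pipeline (Mann-Whitney U, chi-square, Welch t, Kendall tau, Fisher).
#'
#' @param method test name.
#' @param statistic test statistic (NA if not defined).
#' @param p two-sided p-value.
#' @param p_adjusted optional multiplicity-adjusted p-value.
#' @param effect optional effect size (odds ratio, fold, tau, shift).
#' @param note free-text method notes (correction used, subsample seed).
#' @return A one-row data.frame of class `stat_result`.
#' @export
stat_result <- function(method, statistic = NA_real_, p = NA_real_,
                        p_adjusted = NA_real_, effect = NA_real_, note = "") {
  if (!is.na(p)) p <- min(max(p, 0), 1)   # guard tiny numeric overshoot
  out <- data.frame(method = method, statistic = as.numeric(statistic),
                    p = as.numeric(p), p_adjusted = as.numeric(p_adjusted),
                    effect = as.numeric(effect), note = note,
                    stringsAsFactors = FALSE)
  class(out) <- c("stat_result", "data.frame")
  out
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
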