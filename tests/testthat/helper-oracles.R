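# Independent brute-force oracles used to cross-check the package's
# implementations.  These deliberately avoid the code paths they verify.

# Sliding-window overlapping exact-match count.
naive_motif_count <- function(seq, motif) {
  s <- toupper(seq)
  L <- nchar(s); w <- nchar(motif)
  if (L < w) return(0L)
  sum(substring(s, 1:(L - w + 1), w:L) == motif)
}

# All-pairs interval overlap count (0-based half-open).
brute_overlap_counts <- function(iv, tes) {
  vapply(seq_len(nrow(iv)), function(i) {
    sum(tes$scaffold_id == iv$scaffold_id[i] &
          tes$start < iv$end[i] & tes$end > iv$start[i])
  }, 0L)
}

# Kendall tau-b by O(n^2) concordant/discordant enumeration.
brute_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) { tx <- tx + 1; next }
    if (dy == 0) { ty <- ty + 1; next }
    if (dx == dy) C <- C + 1 else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (point-probability rule).
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_min <- max(0, r1 + c1 - n); a_max <- min(r1, c1)
  probs <- vapply(a_min:a_max, function(a) {
    dhyper(a, c1, n - c1, r1)
  }, 0)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Matrix exponential by scaling-and-squaring of the truncated Taylor series
# (independent of the eigendecomposition route used in the package).
series_expm <- function(M, k = 30, squarings = 12) {
  M <- M / 2^squarings
  P <- diag(nrow(M)); term <- diag(nrow(M))
  for (i in 1:k) {
    term <- term %*% M / i
    P <- P + term
  }
  for (i in seq_len(squarings)) P <- P %*% P
  P
}

# Brute-force pairwise codon-model log-likelihood: explicit rate matrix
# built by triple loops over codon positions, matrix exponential by series.
brute_gy94_lnL <- function(cod1, cod2, pi, t, kappa, omega) {
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)[gc_tab != "*"]
  n <- length(codons)
  Q <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    ci <- strsplit(codons[i], "")[[1]]; cj <- strsplit(codons[j], "")[[1]]
    dif <- which(ci != cj)
    if (length(dif) != 1) next
    pairnt <- sort(c(ci[dif], cj[dif]))
    is_ts <- identical(pairnt, c("A", "G")) || identical(pairnt, c("C", "T"))
    is_nonsyn <- gc_tab[[codons[i]]] != gc_tab[[codons[j]]]
    Q[i, j] <- pi[j] * (if (is_ts) kappa else 1) * (if (is_nonsyn) omega else 1)
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  P <- series_expm(Q * t / scale)
  ii <- match(cod1, codons); jj <- match(cod2, codons)
  sum(log(pi[ii] * P[cbind(ii, jj)]))
}
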