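# Goldman-Yang-type codon substitution model on the 61 sense codons of the
# universal code.  Instantaneous rates: q_ij = 0 for multi-position changes,
# otherwise pi_j * kappa^[transition] * omega^[nonsynonymous]; Q is scaled to
# one expected substitution per codon per unit time.

codon_universe <- local({
  env <- NULL
  function() {
    if (!is.null(env)) return(env)
    gc_tab <- Biostrings::GENETIC_CODE
    codons <- names(gc_tab)[gc_tab != "*"]
    aa <- unname(gc_tab[codons])
    n <- length(codons)                       # 61
    cmat <- do.call(rbind, strsplit(codons, ""))
    ndiff <- matrix(0L, n, n)
    ts <- matrix(FALSE, n, n)
    nonsyn <- matrix(FALSE, n, n)
    purines <- c("A", "G")
    for (p in 1:3) {
      d <- outer(cmat[, p], cmat[, p], "!=")
      ndiff <- ndiff + d
      is_ts <- outer(cmat[, p] %in% purines, cmat[, p] %in% purines, "==") & d
      ts <- ts | is_ts
    }
    nonsyn <- outer(aa, aa, "!=")
    env <<- list(codons = codons, aa = aa, n = n, cmat = cmat,
                 single = ndiff == 1L, ts = ts & (ndiff == 1L),
                 nonsyn = nonsyn, stop_codons = names(gc_tab)[gc_tab == "*"])
    env
  }
})

# F3x4 codon frequencies: per-position nucleotide frequencies estimated
# jointly from both sequences, multiplied and renormalized over sense codons.
f3x4_frequencies <- function(codon_vec) {
  u <- codon_universe()
  cm <- do.call(rbind, strsplit(codon_vec, ""))
  pi_pos <- lapply(1:3, function(p) {
    f <- table(factor(cm[, p], levels = c("A", "C", "G", "T")))
    f <- as.numeric(f) + 0.5            # light pseudocount guards empty cells
    f / sum(f)
  })
  pi <- pi_pos[[1]][match(u$cmat[, 1], c("A", "C", "G", "T"))] *
    pi_pos[[2]][match(u$cmat[, 2], c("A", "C", "G", "T"))] *
    pi_pos[[3]][match(u$cmat[, 3], c("A", "C", "G", "T"))]
  pi / sum(pi)
}

# Unscaled rate matrix pieces and the symmetric eigendecomposition used to
# evaluate P(t) = exp(Qt).  Returns eigenvectors in the pi^{1/2} metric plus
# the rate scale (expected substitutions per codon at t = 1 before scaling).
gy94_eigen <- function(kappa, omega, pi) {
  u <- codon_universe()
  rate <- matrix(0, u$n, u$n)
  rate[u$single] <- 1
  rate[u$ts] <- kappa
  rate[u$single & u$nonsyn] <- rate[u$single & u$nonsyn] * omega
  Q <- rate * matrix(pi, u$n, u$n, byrow = TRUE)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  sq <- sqrt(pi)
  A <- Q * (sq %o% (1 / sq))               # similar symmetric matrix
  A <- (A + t(A)) / 2                      # mop up roundoff asymmetry
  e <- eigen(A, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, sq = sq, scale = scale, Q = Q)
}

gy94_P <- function(eig, t) {
  # t in expected substitutions per codon; undo the unit-rate scaling here
  lam <- eig$values * (t / eig$scale)
  P <- eig$vectors %*% (exp(lam) * t(eig$vectors))
  P <- P * ((1 / eig$sq) %o% eig$sq)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Log-likelihood of an unordered codon-pair count matrix N under (t, kappa,
# omega): sum_ij N_ij log(pi_i P_ij(t)).
gy94_lnL <- function(N, pi, t, kappa, omega) {
  eig <- gy94_eigen(kappa, omega, pi)
  P <- gy94_P(eig, t)
  M <- pi * P
  sum(N * log(pmax(M, 1e-300)))
}

# Maximize the pairwise likelihood.  `fix_omega` pins omega (the neutral
# null); multiple starts guard against local optima on flat surfaces.
gy94_fit <- function(N, pi, fix_omega = NULL,
                     omega_starts = c(0.2, 1, 3), t_start = NULL) {
  p_obs <- 1 - sum(diag(N)) / sum(N)
  if (is.null(t_start)) t_start <- max(0.05, min(3, -log(max(1 - p_obs, 0.05))))
  lb <- c(log(1e-6), log(0.01), log(1e-4))
  ub <- c(log(50), log(100), log(999))
  best <- NULL
  starts <- if (is.null(fix_omega)) omega_starts else 1
  for (w0 in starts) {
    if (is.null(fix_omega)) {
      par0 <- log(c(t_start, 2, w0))
      fn <- function(p) -gy94_lnL(N, pi, exp(p[1]), exp(p[2]), exp(p[3]))
      opt <- optim(par0, fn, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 200))
      cand <- list(t = exp(opt$par[1]), kappa = exp(opt$par[2]),
                   omega = exp(opt$par[3]), lnL = -opt$value)
    } else {
      par0 <- log(c(t_start, 2))
      fn <- function(p) -gy94_lnL(N, pi, exp(p[1]), exp(p[2]), fix_omega)
      opt <- optim(par0, fn, method = "L-BFGS-B", lower = lb[1:2],
                   upper = ub[1:2], control = list(maxit = 200))
      cand <- list(t = exp(opt$par[1]), kappa = exp(opt$par[2]),
                   omega = fix_omega, lnL = -opt$value)
    }
    if (is.null(best) || cand$lnL > best$lnL) best <- cand
  }
  best
}

# Model-based dN and dS: substitutions per (non)synonymous site, with sites
# counted from the omega = 1 flux under the fitted (t, kappa).
gy94_dn_ds <- function(t, kappa, omega, pi) {
  u <- codon_universe()
  flux_parts <- function(w) {
    eig <- gy94_eigen(kappa, w, pi)
    q <- eig$Q
    off <- q * matrix(pi, u$n, u$n)
    nonsyn_flux <- sum(off[u$single & u$nonsyn])
    syn_flux <- sum(off[u$single & !u$nonsyn])
    c(nonsyn_flux, syn_flux)
  }
  fw <- flux_parts(omega)                  # realized fluxes (sum = scale)
  f1 <- flux_parts(1)                      # mutational-opportunity fluxes
  tot <- sum(fw)
  prop_n1 <- f1[1] / sum(f1)               # fraction of sites nonsynonymous
  dN <- t * (fw[1] / tot) / (3 * prop_n1)
  dS <- t * (fw[2] / tot) / (3 * (1 - prop_n1))
  c(dN = dN, dS = dS)
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) stop("sequence length not a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

# Codon-pair count matrix over the 61 sense codons; gap or ambiguous codons
# are dropped.
codon_pair_counts <- function(cod1, cod2) {
  u <- codon_universe()
  i <- match(cod1, u$codons)
  j <- match(cod2, u$codons)
  keep <- !is.na(i) & !is.na(j)
  N <- matrix(0, u$n, u$n)
  tab <- table(factor(i[keep], levels = seq_len(u$n)),
               factor(j[keep], levels = seq_len(u$n)))
  N[] <- as.numeric(tab)
  N
}
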