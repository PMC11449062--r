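make_pair_df <- function(cds1, cds2, complete1 = TRUE, complete2 = TRUE) {
  data.frame(pair_id = "p", cds1 = cds1, cds2 = cds2,
             complete1 = complete1, complete2 = complete2,
             stringsAsFactors = FALSE)
}

test_that("pair filters implement the 20% length and completeness rules", {
  a300 <- strrep("ATG", 100)
  f <- filter_ortholog_pairs(make_pair_df(a300, strrep("ATG", 121)))
  expect_false(f$retained)                       # 63 > 0.2 * 300
  # exactly 20% is not "more than 20%": retained under the strict rule
  expect_true(filter_ortholog_pairs(make_pair_df(a300, strrep("ATG", 120)))$retained)
  f2 <- filter_ortholog_pairs(make_pair_df(strrep("ATG", 100), strrep("ATG", 116)))
  expect_true(f2$retained)                       # 48 <= 60 and <= 69.6
  f3 <- filter_ortholog_pairs(make_pair_df(a300, a300, complete1 = TRUE,
                                           complete2 = FALSE))
  expect_true(f3$retained)                       # only both-incomplete removes
  f4 <- filter_ortholog_pairs(make_pair_df(a300, a300, complete1 = FALSE,
                                           complete2 = FALSE))
  expect_false(f4$retained)
  f5 <- filter_ortholog_pairs(make_pair_df(substr(a300, 1, 299), a300))
  expect_true(f5$invalid)
})

test_that("codon alignment is gapless for identical CDS and places in-frame gaps", {
  cds <- "ATGGCTGAACGTATTCCTAAGGGATCTTTG"
  aln <- codon_align(cds, cds)
  expect_true(aln$valid)
  expect_identical(aln$seq1, aln$seq2)
  expect_equal(nchar(aln$seq1) %% 3, 0)
  # one in-frame codon insertion -> exactly one 3-column gap
  ins <- paste0(substr(cds, 1, 15), "GGT", substr(cds, 16, nchar(cds)))
  aln2 <- codon_align(cds, ins)
  expect_equal(nchar(aln2$seq2), nchar(cds) + 3)
  expect_equal(nchar(gsub("[^-]", "", aln2$seq1)), 3)
  expect_equal(regmatches(aln2$seq1, gregexpr("-+", aln2$seq1))[[1]], "---")
  expect_equal(gsub("-", "", aln2$seq2), ins)
  # internal stop invalidates, terminal stop is stripped
  expect_false(codon_align("ATGTAACCT", cds)$valid)
  aln3 <- codon_align(paste0(cds, "TAA"), cds)
  expect_true(aln3$valid)
  expect_equal(nchar(aln3$seq1), nchar(cds))
})

test_that("variant-site counting matches a brute-force column scan", {
  aln <- list(seq1 = "ATGAAA", seq2 = "ATGAAA")
  expect_equal(count_variant_sites(aln), 0)
  expect_equal(count_variant_sites(list(seq1 = "ATGAAA", seq2 = "ATGAAG")), 1)
  set.seed(5)
  for (r in 1:20) {
    n <- 30
    s1 <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    s2v <- strsplit(s1, "")[[1]]
    flip <- sample(n, 5)
    s2v[flip] <- sample(c("A", "C", "G", "T"), 5, TRUE)
    gap <- sample(setdiff(1:n, flip), 2)
    s1v <- strsplit(s1, "")[[1]]
    s1v[gap[1]] <- "-"; s2v[gap[2]] <- "-"
    brute <- sum(s1v != s2v & s1v != "-" & s2v != "-")
    expect_equal(count_variant_sites(list(seq1 = paste(s1v, collapse = ""),
                                          seq2 = paste(s2v, collapse = ""))),
                 brute)
  }
})

test_that("identical sequences yield zero divergence and no test", {
  s <- strrep("ATGGCTGAACGT", 5)
  r <- pairwise_dnds_ml(list(seq1 = s, seq2 = s))
  expect_true(r$identical)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_true(is.na(r$p))
})

test_that("transition matrices satisfy the generator identities", {
  pi <- f3x4_frequencies(camevo:::codon_universe()$codons)
  eig <- camevo:::gy94_eigen(2.5, 0.4, pi)
  expect_lt(max(abs(rowSums(eig$Q))), 1e-12)
  for (t in c(1e-9, 0.1, 1, 5)) {
    P <- camevo:::gy94_P(eig, t)
    expect_equal(unname(rowSums(P)), rep(1, 61), tolerance = 1e-10)
    expect_true(all(P >= 0))
  }
  expect_equal(camevo:::gy94_P(eig, 1e-12), diag(61), tolerance = 1e-9)
})

test_that("simulated parameters are recovered by maximum likelihood", {
  pair <- simulate_codon_pair(20000, omega = 0.3, kappa = 2, t = 0.4, seed = 31)
  r <- pairwise_dnds_ml(pair)
  expect_gt(r$omega, 0.27); expect_lt(r$omega, 0.33)
  expect_gt(r$kappa, 1.8); expect_lt(r$kappa, 2.2)
  expect_gt(r$t, 0.36); expect_lt(r$t, 0.44)
  expect_gte(r$lnL_free, r$lnL_fixed)
  expect_equal(r$omega, r$dN / r$dS, tolerance = 1e-6)
  # neutral simulation: estimator near 1
  pair1 <- simulate_codon_pair(50000, omega = 1, kappa = 2, t = 0.5, seed = 32)
  r1 <- pairwise_dnds_ml(pair1)
  expect_gt(r1$omega, 0.95); expect_lt(r1$omega, 1.05)
})

test_that("the pairwise likelihood matches a brute-force oracle", {
  pair <- simulate_codon_pair(40, omega = 0.6, kappa = 3, t = 0.8, seed = 33)
  r <- pairwise_dnds_ml(pair)
  cod <- camevo:::drop_gap_codons(pair)
  pi <- camevo:::f3x4_frequencies(c(cod$cod1, cod$cod2))
  oracle <- brute_gy94_lnL(cod$cod1, cod$cod2, pi, r$t, r$kappa, r$omega)
  expect_equal(r$lnL_free, oracle, tolerance = 1e-6)
  # a coarse grid search never beats the optimizer
  grid <- expand.grid(t = c(0.2, 0.5, 0.8, 1.2), k = c(1, 3, 6),
                      w = c(0.2, 0.6, 1, 2))
  glnl <- apply(grid, 1, function(g) {
    brute_gy94_lnL(cod$cod1, cod$cod2, pi, g[1], g[2], g[3])
  })
  expect_lte(max(glnl), r$lnL_free + 1e-4)
})

test_that("NG86 counting agrees with ML on mildly diverged pairs", {
  s <- strrep("ATGGCTGAACGT", 4)
  expect_equal(unname(ng86_dnds(list(seq1 = s, seq2 = s))[c("dN", "dS")]),
               c(0, 0))
  expect_true(is.nan(ng86_dnds(list(seq1 = s, seq2 = s))[["omega"]]))
  # single synonymous change: omega 0
  s2 <- sub("GAA", "GAG", s)
  r <- ng86_dnds(list(seq1 = s, seq2 = s2))
  expect_equal(r[["dN"]], 0)
  expect_gt(r[["dS"]], 0)
  expect_equal(r[["omega"]], 0)
  # agreement holds where NG86's equal-rate assumption does (kappa = 1);
  # transition bias is a known source of NG86 underestimation
  for (w in c(0.3, 1.5)) {
    pair <- simulate_codon_pair(8000, omega = w, kappa = 1, t = 0.3,
                                seed = 40 + w * 10)
    ml <- pairwise_dnds_ml(pair)
    ng <- ng86_dnds(pair)
    expect_lt(abs(ng[["omega"]] / ml$omega - 1), 0.15)
  }
})

test_that("BH adjustment is the standard step-up and candidates need omega > 1", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(6)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  res <- data.frame(pair_id = c("a", "b", "c"),
                    omega = c(2, 0.5, 3), p = c(0.001, 0.001, 0.2))
  cand <- select_candidates(res)
  expect_equal(cand$pair_id, "a")
})

test_that("per-scaffold comparison uses the variant-site filter and exact MW", {
  res <- data.frame(pair_id = paste0("p", 1:40),
                    omega = rep(seq(0.05, 1, length.out = 20), each = 2),
                    n_variant_sites = c(rep(10, 38), 2, 2),
                    stringsAsFactors = FALSE)
  smap <- setNames(rep(c("chr1", "chr2"), 20), res$pair_id)
  out <- scaffold_dnds_compare(res, smap, "chr1")
  # identical omega multisets on both scaffolds: p = 1
  expect_equal(out$tests$p[1], 1, tolerance = 1e-6)
  expect_equal(unname(out$medians[["chr1"]]), unname(out$medians[["chr2"]]))
  expect_error(scaffold_dnds_compare(res, smap, "chrX"), "absent")
})

test_that("duplicated-orthogroup analysis honors conformation after correction", {
  base <- strrep("ATGGCTGAACGTATTCCTAAGGGATCTTTG", 3)
  mut <- sub("GCT", "GGT", base)
  cds <- c(a1 = base, f1 = base, f2 = mut, l1 = base)
  og <- orthogroups(c("OG1", "OG2"),
                    genes_A = list("a1", "a1"),
                    genes_F = list(c("f1", "f2"), c("f1", "f2")),
                    genes_L = list("l1", "l1"))
  og$corrected_F <- c(2, 1); og$corrected_L <- c(1, 1)
  out <- duplicate_dnds(og, cds)
  # OG2 lost its duplicate after correction and is skipped
  expect_equal(unique(out$orthogroup_id), "OG1")
  expect_equal(nrow(out), 2)
  expect_equal(out$conformation, c("1:2:1", "1:2:1"))
  ident <- out[out$pair_id == "a1|f1", ]
  expect_equal(ident$dN, 0)
  expect_equal(ident$dS, 0)
})
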