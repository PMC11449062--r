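test_that("exon-to-gene summation conserves totals", {
  m <- matrix(c(3, 4, 5, 7), 4, 2,
              dimnames = list(c("gA.exon1", "gA.exon2", "gA.exon3", "gB.exon1"),
                              c("s1", "s2")))
  m[, 2] <- c(1, 1, 1, 9)
  gm <- exon_to_gene_counts(m)
  expect_equal(gm["gA", "s1"], 12)
  expect_equal(gm["gB", ], m["gB.exon1", ])     # single-exon identity
  expect_equal(colSums(gm), colSums(m))
  expect_error(exon_to_gene_counts(matrix(1, 1, 1)), "parent gene")
})

test_that("TMM factors are 1 for identical libraries and depth-invariant", {
  set.seed(2)
  base <- rpois(400, 50)
  m <- cbind(a = base, b = base, c = base)
  f <- tmm_normalize(m)
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-12)
  # doubling depth without composition change is absorbed by library size
  m2 <- cbind(a = base, b = 2L * base)
  f2 <- tmm_normalize(m2)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-6)
  # geometric mean 1 and permutation invariance
  m3 <- cbind(a = rpois(400, 30), b = rpois(400, 60), c = rpois(400, 90))
  f3 <- tmm_normalize(m3)
  expect_equal(exp(mean(log(f3))), 1, tolerance = 1e-12)
  perm <- sample(nrow(m3))
  expect_equal(tmm_normalize(m3[perm, ]), f3)
  expect_error(tmm_normalize(cbind(a = c(0, 0), b = c(1, 2))), "all-zero")
})

test_that("cpm filter keeps the mean-1 boundary and is idempotent", {
  lib <- 1e6
  m <- rbind(keep = c(1, 1), boundary = c(1, 1), drop = c(0, 0))
  colnames(m) <- c("s1", "s2")
  # libraries of exactly 1e6 with factor 1: count 1 -> cpm 1
  m2 <- rbind(m, filler = c(lib - 2, lib - 2))
  f <- c(1, 1)
  out <- cpm_filter(m2, f)
  expect_true(all(c("keep", "boundary", "filler") %in% rownames(out)))
  expect_false("drop" %in% rownames(out))
  expect_equal(cpm_filter(out, f), out)
})

test_that("TPM follows the RPK definition and sums to one million", {
  m <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s"))
  tp <- tpm(m, c(g1 = 1, g2 = 2))
  expect_equal(unname(tp[, 1]), c(2e6 / 3, 1e6 / 3))
  expect_equal(colSums(tp), c(s = 1e6))
  single <- tpm(matrix(5, 1, 1, dimnames = list("g", "s")), c(g = 1.4))
  expect_equal(unname(single[1, 1]), 1e6)
  set.seed(3)
  mm <- matrix(rpois(60, 40), 20, 3,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  tp2 <- tpm(mm, setNames(runif(20, 0.2, 5), paste0("g", 1:20)))
  expect_equal(unname(colSums(tp2)), rep(1e6, 3), tolerance = 1e-9)
  expect_error(tpm(mm, setNames(rep(0, 20), paste0("g", 1:20))), "zero exonic")
})

test_that("the DE caller finds planted species-specific rhythms and not nulls", {
  ids <- sprintf("g%03d", 1:120)
  de <- data.frame(gene_id = ids[1:20], A_F = 1.5, A_L = 0)
  sim <- simulate_diel_counts(ids, de_params = de, seed = 21)
  gm <- exon_to_gene_counts(sim$exon_counts)
  res <- timecourse_de(gm, sim$design, factors = tmm_normalize(gm))
  called <- res$gene_id[res$is_DE]
  expect_gte(mean(ids[1:20] %in% called), 0.9)
  expect_lte(sum(!(called %in% ids[1:20])), 5)
  # DE flag implies an adjusted-p pass, an R2 pass and a species term
  de_rows <- res[res$is_DE, ]
  expect_true(all(de_rows$p_adjusted <= 0.05))
  expect_true(all(de_rows$rsq >= 0.6))
  expect_true(all(de_rows$species_term))
})

test_that("DE calls are invariant to relabeling samples within cells", {
  ids <- sprintf("g%03d", 1:40)
  de <- data.frame(gene_id = ids[1:8], A_F = 1.5, A_L = 0)
  sim <- simulate_diel_counts(ids, de_params = de, seed = 22)
  gm <- exon_to_gene_counts(sim$exon_counts)
  res1 <- timecourse_de(gm, sim$design, factors = tmm_normalize(gm))
  # permute samples (columns + design rows together): same calls
  perm <- sample(ncol(gm))
  res2 <- timecourse_de(gm[, perm], sim$design[perm, ],
                        factors = tmm_normalize(gm[, perm]))
  expect_equal(res1$is_DE, res2$is_DE)
})

test_that("antiphase profile groups separate into two clusters", {
  t6 <- seq(0, 20, 4)
  up <- sin(2 * pi * t6 / 24)
  prof <- rbind(matrix(rep(c(up, up), 6), 6, 12, byrow = TRUE),
                matrix(rep(c(-up, -up), 6), 6, 12, byrow = TRUE))
  prof <- prof + matrix(rnorm(length(prof), 0, 0.01), nrow(prof))
  rownames(prof) <- paste0("g", 1:12)
  cl <- cluster_de(prof)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:6])), 1)
  expect_equal(length(unique(cl[7:12])), 1)
  # duplicate profiles always co-cluster
  prof2 <- rbind(prof, g13 = prof[1, ])
  cl2 <- cluster_de(prof2)
  expect_equal(unname(cl2["g13"]), unname(cl2["g1"]))
})

test_that("expression curves summarize replicates and median-center", {
  tpm_m <- matrix(c(1, 2, 3, 1, 2, 3,
                    4, 4, 4, 8, 8, 8), 2, 6, byrow = TRUE,
                  dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  design <- data.frame(species = rep(c("F", "L"), each = 3),
                       time = rep(0, 6))
  cv <- expression_curves(tpm_m, design, mode = "mean_sd")
  g1F <- cv[cv$gene_id == "g1" & cv$species == "F", ]
  expect_equal(g1F$mean_tpm, 2)
  expect_equal(g1F$sd_tpm, 1)
  mc <- expression_curves(tpm_m, design, mode = "median_centered")
  # per time point, the across-genes median of centered values is 0
  for (sp in c("F", "L")) {
    expect_equal(median(mc$centered_log_tpm[mc$species == sp]), 0)
  }
  # identical genes give all-zero centered curves
  tpm_same <- tpm_m; tpm_same[2, ] <- tpm_same[1, ]
  mc2 <- expression_curves(tpm_same, design, mode = "median_centered")
  expect_true(all(mc2$centered_log_tpm == 0))
})
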