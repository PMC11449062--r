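test_that("mean gene coverage equals the naive per-position mean", {
  gene <- gene_models("g", "s1", 10L, 20L, "+")
  cov <- data.frame(scaffold_id = "s1", pos = c(10:14, 15:19),
                    depth = c(rep(30, 5), rep(0, 5)))
  expect_equal(mean_gene_coverage(cov, gene[1, ]), 15)
  # uniform depth
  cov2 <- data.frame(scaffold_id = "s1", pos = 10:19, depth = 30)
  expect_equal(mean_gene_coverage(cov2, gene[1, ]), 30)
  # positions without a record count as zero; random fixture vs brute force
  set.seed(1)
  pos <- sample(10:19, 6)
  depth <- sample(0:50, 6)
  cov3 <- data.frame(scaffold_id = "s1", pos = pos, depth = depth)
  full <- rep(0, 10); full[pos - 9] <- depth
  expect_equal(mean_gene_coverage(cov3, gene[1, ]), mean(full))
  expect_error(mean_gene_coverage(cov2, gene[1, ], scaffold_lengths = c(s1 = 15)),
               "outside scaffold")
})

test_that("orthogroup class labels follow the count pattern", {
  rec <- function(a, f, l) list(A = a, F_count = f, L_count = l)
  cl <- classify_orthogroup(rec(1, 1, 1))
  expect_true(all(vapply(cl, function(x) "ancestral single-copy" %in% x, TRUE)))
  cl2 <- classify_orthogroup(rec(2, 2, 2))
  expect_true(all(vapply(cl2, function(x) "ancestral multicopy" %in% x, TRUE)))
  cl3 <- classify_orthogroup(rec(0, 3, 0))
  expect_true("unique multicopy" %in% cl3$F)
  expect_false("unique multicopy" %in% cl3$A)
  cl4 <- classify_orthogroup(rec(1, 3, 2))
  expect_true("multicopy" %in% cl4$F)
  expect_true("single-copy" %in% cl4$A)
  expect_false("ancestral multicopy" %in% cl4$F)
})

test_that("coverage correction follows the ratio formula with half-away rounding", {
  expect_equal(correct_count(c(30, 30), 30), 2L)          # identity
  expect_equal(correct_count(c(15, 15), 30), 1L)          # collapsed haplotig
  expect_equal(correct_count(c(30, 30, 15), 30), 3L)      # 2.5 rounds up
  expect_equal(correct_count(c(30, 14), 30), 1L)          # 44/30 rounds down
  expect_equal(correct_count(c(2, 2), 30), 1L)            # floor of 1
  expect_error(correct_count(c(30, NA), 30), "missing coverage")
  expect_error(correct_count(c(30, 30), 0), "positive")
})

test_that("correction is a no-op when every member matches the single-copy mean", {
  og <- orthogroups(c("OG1", "OG2"),
                    genes_A = list("a1", "a2"),
                    genes_F = list(c("f1", "f2", "f3"), "f4"),
                    genes_L = list(c("l1", "l2"), "l3"))
  covF <- c(f1 = 30, f2 = 30, f3 = 30, f4 = 30)
  covL <- c(l1 = 30, l2 = 30, l3 = 30)
  out <- correct_family_size(og, covF, covL, singlecopy_F = 30, singlecopy_L = 30)
  expect_equal(out$corrected_F, c(3, 1))
  expect_equal(out$corrected_L, c(2, 1))
})

test_that("single-copy mean uses only fully single-copy orthogroups", {
  og <- orthogroups(c("OG1", "OG2", "OG3"),
                    genes_A = list("a1", "a2", character(0)),
                    genes_F = list("f1", c("f2", "f3"), "f4"),
                    genes_L = list("l1", "l2", "l3"))
  covF <- c(f1 = 28, f2 = 99, f3 = 99, f4 = 99)
  expect_equal(singlecopy_mean_coverage(og, covF, "F"), 28)
})

test_that("relative-size categories partition every orthogroup", {
  expect_equal(categorize_relative_size(1, 1), "F=1:L=1")
  expect_equal(categorize_relative_size(3, 1), "F>L")
  expect_equal(categorize_relative_size(1, 3), "F<L")
  expect_equal(categorize_relative_size(2, 2), "F=L(>1)")
  expect_equal(categorize_relative_size(3, 0), "F-unique")
  expect_equal(categorize_relative_size(0, 2), "L-unique")
  expect_error(categorize_relative_size(0, 0), "empty")
  # every (F, L) combination gets exactly one label
  for (f in 0:4) for (l in 0:4) {
    if (f == 0 && l == 0) next
    expect_length(categorize_relative_size(f, l), 1)
  }
})

test_that("family log-ratio is antisymmetric and guards zeros", {
  expect_equal(family_log_ratio(2, 2), 0)
  expect_equal(family_log_ratio(4, 1), log(4))
  expect_equal(family_log_ratio(3, 5), -family_log_ratio(5, 3))
  expect_warning(out <- family_log_ratio(c(2, 0), c(1, 1)), "zero count")
  expect_true(is.na(out[2]))
})

test_that("family-size z-score matches its defining formula and sign", {
  set.seed(7)
  bg <- rnorm(200, 0, 2)
  st <- sample(bg, 30)
  z <- family_size_zscore(st, bg)
  expect_equal(z, (mean(st) - mean(bg)) / (sd(bg) / sqrt(30)))
  expect_lt(abs(family_size_zscore(bg, bg)), 1e-10)
  expect_gt(family_size_zscore(rep(2, 10), bg - mean(bg)), 0)
  expect_true(is.na(family_size_zscore(numeric(0), bg)))
  expect_true(is.na(family_size_zscore(st, rep(1, 5))))
})

test_that("planted haplotig inflation is corrected back to truth", {
  r <- recovery_family_size(n_orthogroups = 300, seed = 11)
  expect_gt(r$n_affected, 30)
  expect_gte(r$rate, 0.95)
})
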