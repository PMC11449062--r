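test_that("chi-square 2x2 handles balanced tables and degenerate margins", {
  tab <- matrix(10, 2, 2)
  r <- chi_square_2x2(tab, continuity = FALSE)
  expect_equal(r$statistic, 0)
  expect_gt(r$p, 0.99)
  expect_equal(r$effect, 1)
  # swapping rows and columns together leaves the test unchanged
  tab2 <- matrix(c(12, 3, 5, 20), 2)
  expect_equal(chi_square_2x2(tab2)$p,
               chi_square_2x2(tab2[2:1, 2:1])$p)
  r0 <- chi_square_2x2(matrix(c(0, 0, 5, 7), 2, byrow = TRUE))
  expect_equal(r0$p, 1)
  expect_match(r0$note, "degenerate")
})

test_that("Fisher exact equals hypergeometric enumeration on small tables", {
  tabs <- list(matrix(c(3, 1, 1, 3), 2), matrix(c(5, 0, 2, 8), 2),
               matrix(c(1, 7, 6, 1), 2), matrix(c(4, 4, 4, 4), 2))
  for (tab in tabs) {
    expect_equal(fisher_exact_2x2(tab)$p, enum_fisher_p(tab), tolerance = 1e-10)
  }
  # invariance under simultaneous row and column swap
  tab <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher_exact_2x2(tab)$p, fisher_exact_2x2(tab[2:1, 2:1])$p)
})

test_that("Mann-Whitney exact p for fully separated small samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 2 / choose(6, 3))           # 0.1 by enumeration
  expect_match(r$note, "exact")
  # U + U' = n1 * n2
  x <- c(1.5, 2.5, 7); y <- c(2, 3, 4, 9)
  u1 <- mann_whitney(x, y)$statistic
  u2 <- mann_whitney(y, x)$statistic
  expect_equal(u1 + u2, length(x) * length(y))
  # ties force the corrected normal approximation
  expect_match(mann_whitney(c(1, 1, 2), c(1, 2, 2))$note, "approximation")
})

test_that("Welch t and Shapiro-Wilk wrap the standard tests", {
  x <- c(1, 2, 3, 4)
  expect_equal(welch_t(x, x)$statistic, 0)
  expect_equal(welch_t(x, x)$p, 1)
  expect_error(welch_t(1, x), "n >= 2")
  set.seed(15)
  expect_gt(shapiro_wilk(rnorm(50)), 1e-4)
})

test_that("Kendall tau-b equals the brute-force oracle under ties", {
  set.seed(16)
  for (r in 1:8) {
    x <- sample(1:5, 30, TRUE)
    y <- sample(1:5, 30, TRUE)
    expect_equal(kendall_tau_b(x, y)$effect, brute_tau_b(x, y),
                 tolerance = 1e-12)
  }
})

test_that("category enrichment detects planted skew and respects exclusions", {
  set.seed(17)
  n <- 4000
  cat <- sample(c("F=1:L=1", "F>L", "F<L", "F=L(>1)", "F-unique"), n,
                replace = TRUE, prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
  og <- data.frame(orthogroup_id = sprintf("OG%04d", 1:n), category = cat)
  de <- runif(n) < ifelse(cat == "F>L", 0.3, 0.1)
  res <- category_enrichment(og, de)
  expect_equal(sort(res$category), sort(c("F=1:L=1", "F>L", "F<L", "F=L(>1)")))
  expect_lt(res$p_adjusted[res$category == "F>L"], 0.05)
  expect_gt(res$fold[res$category == "F>L"], 2)
  # species-unique orthogroups are excluded; categories partition the rest
  expect_equal(sum(res$n_in + res$n_out), sum(cat != "F-unique"))
  expect_error(category_enrichment(og, rep(FALSE, n)), "empty DE")
  # CAM subset uses Fisher
  cam <- de & runif(n) < 0.2
  res2 <- category_enrichment(og, de, cam)
  expect_true(any(grepl("Fisher", res2$method[res2$subset == "CAMDE_vs_otherDE"])))
})

test_that("GO enrichment propagates ancestors and ranks the exact term first", {
  genes <- sprintf("g%02d", 1:40)
  target <- genes[1:10]
  anno <- rbind(
    data.frame(gene_id = target, term = "GO:child"),
    data.frame(gene_id = genes[11:40], term = "GO:other"))
  parents <- data.frame(term = c("GO:child", "GO:other"),
                        parent = c("GO:parent", "GO:parent"))
  res <- go_enrichment(target, genes, anno, parents)
  # the term annotating exactly the target set has the smallest p
  expect_equal(res$term[1], "GO:child")
  # ancestor counts >= descendant counts after propagation
  expect_gte(res$n_background[res$term == "GO:parent"],
             res$n_background[res$term == "GO:child"])
  expect_equal(res$n_background[res$term == "GO:parent"], 40)
})

test_that("candidate lookup maps outgroup ids onto whole orthogroups", {
  og <- orthogroups(c("OG1", "OG2"),
                    genes_A = list("a1", "a2"),
                    genes_F = list("f1", "f2"),
                    genes_L = list("l1", "l2"))
  hit <- candidate_gene_lookup("a1", og)
  expect_equal(hit$genes_F, "f1")
  expect_equal(hit$genes_L, "l1")
  # idempotent under duplicated ids; unknown ids warn and are skipped
  hit2 <- candidate_gene_lookup(c("a1", "a1"), og)
  expect_identical(hit2$genes_F, hit$genes_F)
  expect_warning(out <- candidate_gene_lookup("zz", og), "not found")
  expect_length(out$genes_F, 0)
})
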