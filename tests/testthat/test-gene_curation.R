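test_that("robustness rule: all-exons-expressed OR complete CDS >= 50 aa", {
  g <- gene_models("g", "s", 0L, 300L, "+",
                   exons = list(cbind(c(0L, 100L), c(90L, 300L))),
                   cds_len_aa = 49L, has_start_codon = TRUE,
                   has_stop_codon = FALSE)
  # criterion (i) alone: all exons expressed, stop codon missing
  expect_equal(classify_robust(g[1, ], c(TRUE, TRUE)), "ROBUST")
  g$has_stop_codon <- TRUE
  # fails (i) and sits just under the 50 aa boundary of (ii)
  expect_equal(classify_robust(g[1, ], c(TRUE, FALSE)), "NOT-ROBUST")
  g$cds_len_aa <- 50L
  expect_equal(classify_robust(g[1, ], c(TRUE, FALSE)), "ROBUST")
  expect_error(classify_robust(g[1, ], TRUE), "does not match")
})

test_that("robustness is monotone in exon expression", {
  g <- gene_models("g", "s", 0L, 300L, "+",
                   exons = list(cbind(c(0L, 100L, 200L), c(90L, 180L, 300L))),
                   cds_len_aa = 10L, has_start_codon = FALSE,
                   has_stop_codon = FALSE)
  for (i in 0:7) {
    flags <- as.logical(intToBits(i)[1:3])
    if (classify_robust(g[1, ], flags) == "ROBUST") {
      expect_equal(classify_robust(g[1, ], rep(TRUE, 3)), "ROBUST")
    }
  }
})

test_that("classify_robust_all maps exon count rows onto genes", {
  genes <- toy_genes()
  cm <- matrix(0L, 5, 2, dimnames = list(
    c("g1.exon1", "g1.exon2", "g1.exon3", "g2.exon1", "g3.exon1"), NULL))
  cm["g1.exon1", ] <- c(3L, 0L); cm["g1.exon2", ] <- 1L; cm["g1.exon3", ] <- 2L
  cm["g3.exon1", ] <- 5L
  st <- classify_robust_all(genes, cm)
  expect_equal(unname(st["g1"]), "ROBUST")      # all exons expressed
  expect_equal(unname(st["g2"]), "ROBUST")      # complete, 60 aa
  expect_equal(unname(st["g3"]), "ROBUST")      # single expressed exon
  cm["g3.exon1", ] <- 0L
  st <- classify_robust_all(genes, cm)
  expect_equal(unname(st["g3"]), "NOT-ROBUST")  # unexpressed and incomplete
})

test_that("NO_ORTHOLOGY propagates across whole orthogroups, idempotently", {
  genes <- gene_models(paste0("g", 1:4), "s", c(0L, 100L, 200L, 300L),
                       c(50L, 150L, 250L, 350L), "+",
                       functional_labels = list("putative transposase",
                                                character(0), character(0),
                                                "kinase"))
  og <- orthogroups(c("OG1", "OG2"),
                    genes_A = list(character(0), character(0)),
                    genes_F = list(c("g1", "g2"), "g4"),
                    genes_L = list("g3", character(0)))
  flagged <- flag_no_orthology(genes, og)
  expect_setequal(flagged, c("g1", "g2", "g3"))  # whole orthogroup OG1
  # no flagged member in OG2 -> untouched; re-running changes nothing
  genes2 <- genes
  genes2$functional_labels[flagged == "g1"] <- list("transposase")
  expect_setequal(flag_no_orthology(genes, og), flagged)
})

test_that("organellar and ribosomal orthogroups are excluded", {
  genes <- gene_models(paste0("g", 1:3), "s", c(0L, 100L, 200L),
                       c(50L, 150L, 250L), "+",
                       functional_labels = list("40S ribosomal protein",
                                                character(0), character(0)))
  og <- orthogroups(c("OG1", "OG2", "OG3"),
                    genes_A = list(character(0), character(0), character(0)),
                    genes_F = list("g1", "g2", "g3"),
                    genes_L = list(character(0), character(0), character(0)))
  out <- exclude_organellar_ribosomal(og, genes, plastid_hits = "g2")
  expect_equal(out$orthogroup_id, "OG3")
  expect_equal(attr(out, "n_removed"), 2)
  # empty hit lists and no ribosomal labels: identity
  genes$functional_labels <- rep(list(character(0)), 3)
  out2 <- exclude_organellar_ribosomal(og, genes)
  expect_equal(out2$orthogroup_id, og$orthogroup_id)
})

test_that("TF families combine domain and homolog evidence", {
  genes <- gene_models(paste0("g", 1:3), "s", c(0L, 100L, 200L),
                       c(50L, 150L, 250L), "+",
                       functional_labels = list("IPR001471", character(0),
                                                character(0)))
  og <- orthogroups(c("OG1", "OG2", "OG3"),
                    genes_A = list(character(0), character(0), character(0)),
                    genes_F = list("g1", "g2", "g3"),
                    genes_L = list(character(0), character(0), character(0)))
  tf <- identify_tf_families(og, genes, "IPR001471", "g2")
  expect_equal(tf$by_domain, "OG1")
  expect_equal(tf$by_homolog, "OG2")
  expect_equal(tf$overlap_fraction, 0)
  expect_setequal(tf$union, c("OG1", "OG2"))
  tf2 <- identify_tf_families(og, genes, "IPR001471", "g1")
  expect_equal(tf2$overlap_fraction, 1)
  expect_error(identify_tf_families(og, genes, character(0), character(0)),
               "empty")
})
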