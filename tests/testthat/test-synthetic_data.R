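test_that("generation is fully deterministic under a fixed seed", {
  cfg <- list(n_orthogroups = 60, n_scaffolds = 2, scaffold_length = 160000)
  d1 <- generate_genome_pair(cfg, seed = 9)
  d2 <- generate_genome_pair(cfg, seed = 9)
  expect_identical(d1, d2)
  d3 <- generate_genome_pair(cfg, seed = 10)
  expect_false(identical(d1$genome_F, d3$genome_F))
})

test_that("orthogroup truth matches emitted entities and requested mix", {
  d <- small_dataset()
  tr <- d$truth$orthogroups
  # every orthogroup's observed count = true count + haplotig artifacts
  hapF <- table(factor(d$truth$haplotigs$orthogroup_id[
    d$truth$haplotigs$species == "F"], levels = tr$orthogroup_id))
  expect_equal(d$og$F_count, tr$true_F + as.integer(hapF))
  # truth references emitted gene ids
  expect_true(all(d$truth$haplotigs$gene_id %in%
                    c(d$genes_F$gene_id, d$genes_L$gene_id)))
  # genes carry their orthogroup assignment
  k <- which(d$og$F_count > 0)[1]
  g <- d$og$genes_F[[k]][1]
  expect_equal(d$genes_F$orthogroup_id[d$genes_F$gene_id == g],
               d$og$orthogroup_id[k])
})

test_that("realized category proportions track the configured fractions", {
  cfg <- list(n_orthogroups = 5000, n_scaffolds = 10,
              scaffold_length = 2100000, haplotig_fraction = 0,
              te_density = c(`LTR-Copia` = 0, `LTR-Gypsy` = 0, Helitron = 0,
                             `DNA transposon` = 0, other = 0))
  d <- generate_genome_pair(cfg, seed = 5)
  frac <- table(d$truth$orthogroups$category) / 5000
  expect_equal(unname(frac[["single"]]), 0.7, tolerance = 0.02 / 0.7)
  for (cc in c("F_gt_L", "F_lt_L", "F_eq_L_gt1")) {
    expect_lt(abs(frac[[cc]] - 0.1), 0.02)
  }
  # TE density 0 leaves the genome unmasked
  expect_false(any(grepl("[acgtn]", d$genome_F)))
})

test_that("infeasible configurations are refused", {
  expect_error(generate_genome_pair(list(n_orthogroups = 500, n_scaffolds = 1,
                                         scaffold_length = 50000), seed = 1),
               "infeasible")
})

test_that("coverage simulation halves haplotig pairs around the mean", {
  d <- small_dataset()
  cov <- simulate_coverage(d$genes_F, d$truth, "F", mean_cov = 30,
                           noise_sd = 0, seed = 1)
  hap <- d$truth$haplotigs
  halved <- unique(c(hap$gene_id[hap$species == "F"],
                     hap$partner_id[hap$species == "F"]))
  expect_true(all(cov$mean_cov[cov$gene_id %in% halved] == 15))
  expect_true(all(cov$mean_cov[!cov$gene_id %in% halved] == 30))
  expect_error(simulate_coverage(d$genes_F, d$truth, "F", mean_cov = -1),
               "non-negative")
})

test_that("diel counts conserve exon partitions and honor flat nulls", {
  ids <- c("gA", "gB")
  sim <- simulate_diel_counts(ids, n_exons = c(gA = 3L, gB = 1L),
                              n_reps = 2, baseline_mean = 100,
                              null_amplitude_max = 0, seed = 3)
  gm <- exon_to_gene_counts(sim$exon_counts)
  expect_equal(unname(colSums(sim$exon_counts)), unname(colSums(gm)))
  expect_equal(nrow(sim$exon_counts), 4)
  expect_true(all(sim$gene_params$A_F == 0))
  # amplitude 0 in both species: expectation flat, planted-DE set empty
  expect_false(any(sim$gene_params$is_de))
  expect_error(simulate_diel_counts(ids, n_reps = 1), "n_reps")
})

test_that("simulated codon pairs exclude stops and collapse at t = 0", {
  p0 <- simulate_codon_pair(50, omega = 0.5, kappa = 2, t = 0, seed = 2)
  expect_identical(p0$seq1, p0$seq2)
  p <- simulate_codon_pair(2000, omega = 1, kappa = 2, t = 0.5, seed = 2)
  for (s in c(p$seq1, p$seq2)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  }
  expect_false(identical(p$seq1, p$seq2))
})

test_that("motif planting hits its target rates and zero means zero", {
  pm0 <- plant_motifs(50, rates = c(EE = 0), length = 500, seed = 7)
  expect_equal(sum(vapply(pm0$sequences, naive_motif_count, 0L,
                          motif = "AAAATATC")), 0L)
  pm <- plant_motifs(300, rates = c(EE = 2, MOE = 1), length = 1000, seed = 7)
  scanned_ee <- sum(vapply(pm$sequences, naive_motif_count, 0L,
                           motif = "AAAATATC"))
  expect_identical(scanned_ee, sum(pm$planted[, "EE"]))
  expect_error(plant_motifs(5, rates = c(EE = 1), length = 4), "longer")
})

test_that("metabolite simulation emits the full diel design", {
  sim <- simulate_metabolites(seed = 4)
  expect_equal(nrow(sim$table), 2 * 6 * 6)
  expect_equal(sort(unique(sim$table$timepoint)), sort(names(diel_timepoints())))
  expect_true(all(sim$table$malate > 0))
  # the CAM species swings, the flat species does not (on average)
  acc <- accumulation_by_accession(sim$table, "malate")
  expect_gt(median(acc$accumulation[acc$species == "F"]),
            median(acc$accumulation[acc$species == "L"]))
})
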