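# Planted-truth recovery benchmarks: each function generates data with the
# synthetic module at the study's stated conditions, runs the corresponding
# analysis stage, and measures how well the planted truth is recovered.
# These are the package's core self-checks and are reused by the acceptance
# script.

#' Family-size correction recovery on haplotig-inflated orthogroups
#'
#' Generates an orthogroup set with haplotig-inflated counts, simulates
#' per-gene coverage (inflated copies at half coverage) and measures the
#' fraction of affected multicopy orthogroups whose corrected counts equal
#' the true counts.
#'
#' @param n_orthogroups orthogroup count (default 1000).
#' @param haplotig_fraction fraction of inflated orthogroups per species.
#' @param noise_sd relative coverage noise (default 0.1).
#' @param seed RNG seed.
#' @return list(rate, n_affected, n_orthogroups).
#' @export
recovery_family_size <- function(n_orthogroups = 1000, haplotig_fraction = 0.2,
                                 noise_sd = 0.1, seed = 1) {
  cfg <- list(n_orthogroups = n_orthogroups, n_scaffolds = 4,
              scaffold_length = ceiling(n_orthogroups * 1.8 * 2100 / 4),
              haplotig_fraction = haplotig_fraction)
  d <- generate_genome_pair(cfg, seed)
  cov_F <- simulate_coverage(d$genes_F, d$truth, "F", noise_sd = noise_sd,
                             seed = seed)
  cov_L <- simulate_coverage(d$genes_L, d$truth, "L", noise_sd = noise_sd,
                             seed = seed)
  og <- correct_family_size(d$og,
                            setNames(cov_F$mean_cov, cov_F$gene_id),
                            setNames(cov_L$mean_cov, cov_L$gene_id))
  tr <- d$truth$orthogroups
  affected <- (d$og$F_count != tr$true_F | d$og$L_count != tr$true_L) &
    (d$og$F_count > 1 | d$og$L_count > 1)
  ok <- og$corrected_F[affected] == tr$true_F[affected] &
    og$corrected_L[affected] == tr$true_L[affected]
  list(rate = mean(ok), n_affected = sum(affected),
       n_orthogroups = n_orthogroups)
}

#' Relative bias of the ML omega estimator
#'
#' Simulates replicate codon pairs per omega value and reports the relative
#' bias of the mean estimate (averaging separates bias from per-replicate
#' sampling error).
#'
#' @param omegas true omega values (default 0.3, 1, 3).
#' @param n_codons alignment length (default 10000).
#' @param n_reps replicates per omega (default 8).
#' @param kappa,t remaining true parameters.
#' @param seed RNG seed.
#' @return named vector of relative biases (mean estimate/truth - 1).
#' @export
recovery_dnds_bias <- function(omegas = c(0.3, 1, 3), n_codons = 10000,
                               n_reps = 8, kappa = 2, t = 0.4, seed = 1) {
  out <- vapply(seq_along(omegas), function(i) {
    est <- vapply(seq_len(n_reps), function(r) {
      pair <- simulate_codon_pair(n_codons, omegas[i], kappa, t,
                                  seed = child_seed(seed, paste0("bias", i, "_", r)))
      pairwise_dnds_ml(pair)$omega
    }, 0)
    mean(est) / omegas[i] - 1
  }, 0)
  names(out) <- paste0("omega_", omegas)
  out
}

#' Type-I error of the likelihood-ratio test at omega = 1
#'
#' Simulates neutral codon pairs and reports the rejection rate of the LRT
#' at the given level.
#'
#' @param n_pairs number of pairs (default 500).
#' @param n_codons codons per pair (default 300).
#' @param kappa,t nuisance parameters (default 2, 0.5).
#' @param alpha test level (default 0.05).
#' @param seed RNG seed.
#' @return list(rejection_rate, n_pairs).
#' @export
lrt_size_at_neutrality <- function(n_pairs = 500, n_codons = 300, kappa = 2,
                                   t = 0.5, alpha = 0.05, seed = 1) {
  p <- vapply(seq_len(n_pairs), function(i) {
    pair <- simulate_codon_pair(n_codons, 1, kappa, t,
                                seed = child_seed(seed, paste0("lrt", i)))
    pairwise_dnds_ml(pair)$p
  }, 0)
  list(rejection_rate = mean(p < alpha, na.rm = TRUE), n_pairs = n_pairs)
}

#' Empirical FDR and power of the time-course DE caller
#'
#' A pure-null matrix (shared rhythms, no species effect) yields the
#' empirical false-call fraction; a matrix with planted species-specific
#' amplitude (A_F = 1.5 vs A_L = 0 at baseline 500, dispersion 0.1,
#' 6 genotypes x 6 time points) yields power.
#'
#' @param n_null null genes (default 2000).
#' @param n_genes genes in the power run (default 1000).
#' @param n_de planted DE genes among them (default 200).
#' @param seed RNG seed.
#' @return list(fdr, power, n_null, n_de).
#' @export
recovery_de <- function(n_null = 2000, n_genes = 1000, n_de = 200, seed = 1) {
  null_ids <- sprintf("null%05d", seq_len(n_null))
  sim0 <- simulate_diel_counts(null_ids, seed = child_seed(seed, "denull"))
  gm0 <- exon_to_gene_counts(sim0$exon_counts)
  res0 <- timecourse_de(gm0, sim0$design, factors = tmm_normalize(gm0))
  fdr <- sum(res0$is_DE) / n_null

  ids <- sprintf("pow%05d", seq_len(n_genes))
  de <- data.frame(gene_id = ids[seq_len(n_de)], A_F = 1.5, A_L = 0,
                   stringsAsFactors = FALSE)
  sim1 <- simulate_diel_counts(ids, de_params = de,
                               seed = child_seed(seed, "depow"))
  gm1 <- exon_to_gene_counts(sim1$exon_counts)
  res1 <- timecourse_de(gm1, sim1$design, factors = tmm_normalize(gm1))
  power <- mean(ids[seq_len(n_de)] %in% res1$gene_id[res1$is_DE])
  list(fdr = fdr, power = power, n_null = n_null, n_de = n_de)
}

#' Recovery of planted per-kb motif rates
#'
#' Plants the Evening Element at a known rate and measures the relative
#' error of the scanned per-kb frequency.
#'
#' @param n_promoters promoter count (default 1000).
#' @param rate planted per-kb rate (default 2).
#' @param length promoter length (default 2000).
#' @param seed RNG seed.
#' @return list(measured, planted_rate, rel_error).
#' @export
recovery_motif_rate <- function(n_promoters = 1000, rate = 2, length = 2000,
                                seed = 1) {
  pm <- plant_motifs(n_promoters, rates = c(EE = rate), length = length,
                     seed = seed)
  counts <- Biostrings::vcountPattern(default_motifs()[["EE"]],
                                      Biostrings::DNAStringSet(pm$sequences))
  measured <- perkb_frequency(sum(counts), n_promoters,
                              length_per_gene = length)
  list(measured = unname(measured), planted_rate = rate,
       rel_error = unname(measured / rate - 1))
}

#' Power of the subsampled Mann-Whitney motif test at a planted 2x rate
#'
#' Each replicate plants a motif at `rate_bg` per kb in background promoters
#' and twice that in DE promoters, then applies [motif_mw_test()]; the
#' fraction of replicates rejecting at 0.05 is returned.
#'
#' @param n_reps simulation replicates (default 20).
#' @param n_de DE promoters per replicate (default 1000).
#' @param n_bg background promoters per replicate (default 2000).
#' @param rate_bg background per-kb rate (default 1).
#' @param length promoter length (default 1000).
#' @param seed RNG seed.
#' @return list(power, n_reps).
#' @export
motif_mw_power <- function(n_reps = 20, n_de = 1000, n_bg = 2000,
                           rate_bg = 1, length = 1000, seed = 1) {
  rej <- vapply(seq_len(n_reps), function(r) {
    s_de <- plant_motifs(n_de, c(EE = 2 * rate_bg), length = length,
                         seed = child_seed(seed, paste0("mwde", r)))
    s_bg <- plant_motifs(n_bg, c(EE = rate_bg), length = length,
                         seed = child_seed(seed, paste0("mwbg", r)))
    p <- motif_mw_test(s_de$planted[, "EE"], s_bg$planted[, "EE"],
                       seed = child_seed(seed, paste0("mwsub", r)))$p
    p < 0.05
  }, FALSE)
  list(power = mean(rej), n_reps = n_reps)
}

#' Power of the metabolite accumulation test on CAM-like vs flat curves
#'
#' Simulates a 3x-amplitude malate rhythm in one species against a flat
#' profile in the other (lognormal noise, cv 0.2) and reports the fraction
#' of replicates in which the exact between-species Mann-Whitney test on
#' 24-h accumulation rejects at 0.05.
#'
#' @param n_reps replicates (default 40).
#' @param seed RNG seed.
#' @return list(power, n_reps).
#' @export
metabolite_test_power <- function(n_reps = 40, seed = 1) {
  rej <- vapply(seq_len(n_reps), function(r) {
    sim <- simulate_metabolites(seed = child_seed(seed, paste0("met", r)))
    species_accumulation_test(sim$table, "malate")$p < 0.05
  }, FALSE)
  list(power = mean(rej), n_reps = n_reps)
}

#' Null and planted-signal behavior of the category-enrichment framework
#'
#' Null: DE labels assigned at random to orthogroups -- a replicate is
#' "clean" when no category reaches BH-adjusted significance at 0.05.
#' Planted: F>L orthogroups given a 3x overrepresentation among DE
#' orthogroups; detection means F>L is the only significant category.
#'
#' @param n_orthogroups orthogroups per replicate (default 5000).
#' @param n_null_reps null replicates (default 40).
#' @param de_rate baseline DE labelling rate (default 0.1).
#' @param seed RNG seed.
#' @return list(null_clean_fraction, planted_detected,
#'   planted_other_significant).
#' @export
category_enrichment_calibration <- function(n_orthogroups = 5000,
                                            n_null_reps = 40, de_rate = 0.1,
                                            seed = 1) {
  make_og <- function(s) {
    with_seed(s, {
      cat <- sample(c("F=1:L=1", "F>L", "F<L", "F=L(>1)"), n_orthogroups,
                    replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
      og <- data.frame(orthogroup_id = sprintf("OG%05d", seq_len(n_orthogroups)),
                       category = cat, stringsAsFactors = FALSE)
      og
    })
  }
  clean <- vapply(seq_len(n_null_reps), function(r) {
    og <- make_og(child_seed(seed, paste0("catnull", r)))
    de <- with_seed(child_seed(seed, paste0("catlab", r)),
                    runif(n_orthogroups) < de_rate)
    res <- category_enrichment(og, de)
    all(res$p_adjusted > 0.05, na.rm = TRUE)
  }, FALSE)
  og <- make_og(child_seed(seed, "catplant"))
  de <- with_seed(child_seed(seed, "catplantlab"), {
    p <- ifelse(og$category == "F>L", 3 * de_rate, de_rate)
    runif(n_orthogroups) < p
  })
  res <- category_enrichment(og, de)
  sig <- res$category[res$p_adjusted < 0.05]
  list(null_clean_fraction = mean(clean),
       planted_detected = "F>L" %in% sig,
       planted_other_significant = length(setdiff(sig, "F>L")) > 0)
}
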