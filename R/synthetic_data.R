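# Deterministic, seeded generator of a paired-species dataset with planted
# ground truth for every downstream stage: genomes with a GC gradient and
# soft-masked TE intervals, gene models in orthogroups of controlled
# relative-size categories, haplotig-inflated gene counts at half coverage,
# negative-binomial diel counts with species-specific rhythm parameters,
# codon pairs evolved under a chosen omega, promoters with planted motif
# rates, and CAM-like versus flat metabolite curves.
#
# One global seed expands into per-stream child seeds, so adding a stream
# never perturbs the draws of another.

#' Default synthetic-dataset configuration
#'
#' @return list of generator parameters: scaffold count/length, orthogroup
#'   count, category fractions (single 1:1, F>L, F<L, F=L>1, species-unique),
#'   haplotig fraction, TE densities per class (features per Mb), gene/exon
#'   geometry and GC gradient endpoints.
#' @export
synthetic_config <- function() {
  list(
    n_scaffolds = 4,
    scaffold_length = 300000,
    n_orthogroups = 300,
    category_fractions = c(single = 0.7, F_gt_L = 0.1, F_lt_L = 0.1,
                           F_eq_L_gt1 = 0.1, unique = 0.0),
    haplotig_fraction = 0.2,
    te_density = c(`LTR-Copia` = 8, `LTR-Gypsy` = 8, Helitron = 4,
                   `DNA transposon` = 4, other = 2),
    te_known_fraction = 0.85,
    gene_length_range = c(600, 1800),
    gene_spacing = 300,
    max_exons = 8,
    gc_start = 0.42,
    gc_end = 0.34)
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

make_scaffold <- function(len, gc_start, gc_end, block = 10000) {
  starts <- seq(0, len - 1, by = block)
  paste(vapply(starts, function(s) {
    gc <- gc_start + (gc_end - gc_start) * s / max(len - 1, 1)
    random_dna(min(block, len - s), gc)
  }, ""), collapse = "")
}

soft_mask <- function(seqs, tes) {
  for (sc in names(seqs)) {
    sel <- tes$scaffold_id == sc
    if (!any(sel)) next
    ch <- strsplit(seqs[[sc]], "")[[1]]
    for (k in which(sel)) {
      idx <- (tes$start[k] + 1):tes$end[k]
      ch[idx] <- tolower(ch[idx])
    }
    seqs[[sc]] <- paste(ch, collapse = "")
  }
  seqs
}

draw_counts_for_category <- function(cat) {
  switch(cat,
         single = c(A = 1, F = 1, L = 1),
         F_gt_L = { l <- sample(1:2, 1); c(A = 1, F = l + sample(1:2, 1), L = l) },
         F_lt_L = { f <- sample(1:2, 1); c(A = 1, F = f, L = f + sample(1:2, 1)) },
         F_eq_L_gt1 = { n <- sample(2:4, 1); c(A = sample(1:n, 1), F = n, L = n) },
         unique = if (runif(1) < 0.5) c(A = 0, F = sample(2:4, 1), L = 0)
                  else c(A = 0, F = 0, L = sample(2:4, 1)))
}

place_genes <- function(species, n_genes, cfg, seqs) {
  slot <- max(cfg$gene_length_range) + cfg$gene_spacing
  per_scaffold <- cfg$scaffold_length %/% slot
  capacity <- per_scaffold * cfg$n_scaffolds
  if (n_genes > capacity) {
    stop(sprintf("infeasible config: %d genes exceed capacity %d", n_genes, capacity))
  }
  slots <- sample(capacity, n_genes)      # random scattered placement
  sc_i <- (slots - 1) %/% per_scaffold + 1
  off <- ((slots - 1) %% per_scaffold) * slot
  len <- 3 * (sample(cfg$gene_length_range[1]:cfg$gene_length_range[2],
                     n_genes, replace = TRUE) %/% 3)
  start <- off + sample(0:cfg$gene_spacing, n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  n_ex <- sample(1:cfg$max_exons, n_genes, replace = TRUE)
  exl <- lapply(seq_len(n_genes), function(i) {
    k <- n_ex[i]
    if (k == 1) return(cbind(start[i], start[i] + len[i]))
    cuts <- sort(sample(seq(3, len[i] - 3, by = 3), k - 1))
    bounds <- c(0, cuts, len[i])
    ex <- cbind(start[i] + bounds[-length(bounds)], start[i] + bounds[-1])
    # carve introns: shrink interior exon ends by a few codons where roomy
    ex
  })
  complete <- runif(n_genes) < 0.9
  gene_models(
    gene_id = sprintf("%s_g%05d", species, seq_len(n_genes)),
    scaffold_id = sprintf("%s_scaffold%02d", species, sc_i),
    start = start, end = start + len, strand = strand, exons = exl,
    cds_len_aa = len %/% 3,
    has_start_codon = complete, has_stop_codon = complete)
}

make_tes <- function(species, cfg) {
  rows <- list()
  for (sc in seq_len(cfg$n_scaffolds)) {
    for (cl in names(cfg$te_density)) {
      n <- rpois(1, cfg$te_density[[cl]] * cfg$scaffold_length / 1e6)
      if (n == 0) next
      len <- sample(300:3000, n, replace = TRUE)
      st <- sample.int(max(cfg$scaffold_length - max(len), 1), n) - 1L
      rows[[length(rows) + 1]] <- data.frame(
        scaffold_id = sprintf("%s_scaffold%02d", species, sc),
        start = st, end = pmin(st + len, cfg$scaffold_length),
        te_class = cl, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    return(te_features(character(0), integer(0), integer(0), character(0)))
  }
  te_features(df$scaffold_id, df$start, df$end, df$te_class,
              known = runif(nrow(df)) < cfg$te_known_fraction,
              te_id = sprintf("%s_TE%05d", species, seq_len(nrow(df))))
}

#' Generate a paired-species synthetic dataset with planted truth
#'
#' @param config list from [synthetic_config()] (entries may be overridden).
#' @param seed global seed; every stream derives a child seed from it.
#' @return list: genome_F, genome_L (soft-masked sequences), genes_F,
#'   genes_L (`gene_models`), tes_F, tes_L (`te_features`), og
#'   (`orthogroups`, counts including haplotig artifacts), truth (per-
#'   orthogroup true counts and categories, haplotig gene table).
#' @export
generate_genome_pair <- function(config = synthetic_config(), seed = 1) {
  cfg <- utils::modifyList(synthetic_config(), config)
  fr <- cfg$category_fractions
  stopifnot(abs(sum(fr) - 1) < 1e-8)

  truth <- with_seed(child_seed(seed, "orthogroups"), {
    cats <- sample(names(fr), cfg$n_orthogroups, replace = TRUE, prob = fr)
    counts <- t(vapply(cats, draw_counts_for_category, c(A = 0, F = 0, L = 0)))
    data.frame(orthogroup_id = sprintf("OG%05d", seq_len(cfg$n_orthogroups)),
               category = cats, true_A = counts[, "A"],
               true_F = counts[, "F"], true_L = counts[, "L"],
               stringsAsFactors = FALSE)
  })

  # haplotig inflation: an extra artifactual gene model duplicating one real
  # gene, per selected orthogroup and species
  hap <- with_seed(child_seed(seed, "haplotigs"), {
    rows <- list()
    for (sp in c("F", "L")) {
      n_sp <- truth[[paste0("true_", sp)]]
      eligible <- which(n_sp >= 1)
      n_inflate <- round(cfg$haplotig_fraction * length(eligible))
      for (k in sample(eligible, n_inflate)) {
        rows[[length(rows) + 1]] <- data.frame(
          orthogroup_id = truth$orthogroup_id[k], species = sp,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0) {
      data.frame(orthogroup_id = character(0), species = character(0))
    } else do.call(rbind, rows)
  })

  extra <- function(sp) {
    as.integer(table(factor(hap$orthogroup_id[hap$species == sp],
                            levels = truth$orthogroup_id)))
  }
  obs_F <- truth$true_F + extra("F")
  obs_L <- truth$true_L + extra("L")

  genes_F <- with_seed(child_seed(seed, "genes_F"),
                       place_genes("TFas", sum(obs_F), cfg))
  genes_L <- with_seed(child_seed(seed, "genes_L"),
                       place_genes("TLei", sum(obs_L), cfg))

  # assign genes to orthogroups in order; first true_* members are real, the
  # remainder are haplotig artifacts
  assign_genes <- function(genes, obs, true_n) {
    idx <- split(genes$gene_id, rep(seq_along(obs), obs))
    lists <- rep(list(character(0)), length(obs))
    lists[as.integer(names(idx))] <- idx
    n_art <- pmax(lengths(lists) - true_n, 0)
    artifacts <- unlist(lapply(seq_along(obs), function(k) {
      g <- lists[[k]]
      if (n_art[k] > 0) g[(true_n[k] + 1):length(g)] else character(0)
    }))
    partners <- unlist(lapply(seq_along(obs), function(k) {
      if (n_art[k] > 0) lists[[k]][seq_len(n_art[k])] else character(0)
    }))
    list(lists = lists, artifacts = artifacts, partners = partners,
         og_of_artifact = rep(truth$orthogroup_id, n_art))
  }
  asg_F <- assign_genes(genes_F, obs_F, truth$true_F)
  asg_L <- assign_genes(genes_L, obs_L, truth$true_L)
  counter <- 0
  genes_A <- lapply(truth$true_A, function(n) {
    if (n == 0) return(character(0))
    ids <- sprintf("Acom_g%05d", counter + seq_len(n))
    counter <<- counter + n
    ids
  })
  og <- orthogroups(truth$orthogroup_id, genes_A, asg_F$lists, asg_L$lists)
  for (k in seq_len(nrow(og))) {
    if (length(og$genes_F[[k]]) > 0) {
      genes_F$orthogroup_id[match(og$genes_F[[k]], genes_F$gene_id)] <-
        og$orthogroup_id[k]
    }
    if (length(og$genes_L[[k]]) > 0) {
      genes_L$orthogroup_id[match(og$genes_L[[k]], genes_L$gene_id)] <-
        og$orthogroup_id[k]
    }
  }

  tes_F <- with_seed(child_seed(seed, "te_F"), make_tes("TFas", cfg))
  tes_L <- with_seed(child_seed(seed, "te_L"), make_tes("TLei", cfg))

  genome_F <- with_seed(child_seed(seed, "genome_F"), {
    s <- setNames(lapply(seq_len(cfg$n_scaffolds), function(i) {
      make_scaffold(cfg$scaffold_length, cfg$gc_start, cfg$gc_end)
    }), sprintf("TFas_scaffold%02d", seq_len(cfg$n_scaffolds)))
    unlist(s)
  })
  genome_L <- with_seed(child_seed(seed, "genome_L"), {
    s <- setNames(lapply(seq_len(cfg$n_scaffolds), function(i) {
      make_scaffold(cfg$scaffold_length, cfg$gc_start, cfg$gc_end)
    }), sprintf("TLei_scaffold%02d", seq_len(cfg$n_scaffolds)))
    unlist(s)
  })
  genome_F <- soft_mask(genome_F, tes_F)
  genome_L <- soft_mask(genome_L, tes_L)

  hap_table <- data.frame(
    orthogroup_id = c(asg_F$og_of_artifact, asg_L$og_of_artifact),
    gene_id = c(asg_F$artifacts, asg_L$artifacts),
    partner_id = c(asg_F$partners, asg_L$partners),
    species = c(rep("F", length(asg_F$artifacts)), rep("L", length(asg_L$artifacts))),
    stringsAsFactors = FALSE)

  list(genome_F = genome_F, genome_L = genome_L,
       genes_F = genes_F, genes_L = genes_L,
       tes_F = tes_F, tes_L = tes_L, og = og,
       truth = list(orthogroups = truth, haplotigs = hap_table, config = cfg))
}

#' Simulate per-gene mean read coverage with haplotig halving
#'
#' Genes recorded as haplotig artifacts (and their partners) receive about
#' half the genome-wide mean coverage -- the read mass of one biological
#' copy split over two loci -- all with multiplicative Gaussian noise.
#'
#' @param genes `gene_models` table of one species.
#' @param truth truth list from [generate_genome_pair()].
#' @param species "F" or "L".
#' @param mean_cov genome-wide mean coverage (default 30).
#' @param noise_sd relative noise standard deviation (default 0.1).
#' @param seed RNG seed.
#' @return data.frame gene_id, mean_cov.
#' @export
simulate_coverage <- function(genes, truth, species, mean_cov = 30,
                              noise_sd = 0.1, seed = 1) {
  if (mean_cov < 0 || noise_sd < 0) stop("coverage parameters must be non-negative")
  hap <- truth$haplotigs
  halved <- unique(c(hap$gene_id[hap$species == species],
                     hap$partner_id[hap$species == species]))
  base <- ifelse(genes$gene_id %in% halved, mean_cov / 2, mean_cov)
  cov <- with_seed(child_seed(seed, paste0("coverage_", species)), {
    pmax(base * (1 + rnorm(length(base), 0, noise_sd)), 0)
  })
  data.frame(gene_id = genes$gene_id, mean_cov = cov, stringsAsFactors = FALSE)
}

#' Simulate a diel exon-level count matrix for two species
#'
#' Per-gene expectation mu_s(t) = b exp(A_s sin(2 pi (t - phi_s) / 24));
#' genes listed in `de_params` carry species-specific amplitude or phase,
#' all others share one amplitude and phase across species (no species x
#' time interaction).  Counts are negative-binomial; exon counts partition
#' the gene count multinomially over fixed exon weights.
#'
#' @param gene_ids character vector.
#' @param n_exons named integer vector of exon counts per gene (default 1).
#' @param de_params data.frame gene_id, A_F, A_L, phase_F, phase_L for
#'   planted DE genes (empty for a pure-null matrix).
#' @param n_reps genotypes per species (default 6; at least 2).
#' @param timepoints sampling hours into the cycle (default 0,4,...,20).
#' @param baseline_mean NB mean at amplitude 0 (default 500).
#' @param dispersion NB dispersion (default 0.1; size = 1/dispersion).
#' @param null_amplitude_max shared-rhythm amplitude cap for non-DE genes.
#' @param seed RNG seed.
#' @return list(exon_counts matrix, design data.frame, gene_params).
#' @export
simulate_diel_counts <- function(gene_ids, n_exons = NULL,
                                 de_params = NULL, n_reps = 6,
                                 timepoints = seq(0, 20, by = 4),
                                 baseline_mean = 500, dispersion = 0.1,
                                 null_amplitude_max = 0.5, seed = 1) {
  if (n_reps < 2) stop("n_reps must be >= 2 (the DE stage needs replication)")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (is.null(n_exons)) n_exons <- setNames(rep(1L, length(gene_ids)), gene_ids)
  design <- expand.grid(genotype = seq_len(n_reps), time = timepoints,
                        species = c("F", "L"), stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_G%d_T%02d", design$species, design$genotype,
                           design$time)
  with_seed(child_seed(seed, "diel"), {
    A_shared <- runif(length(gene_ids), 0, null_amplitude_max)
    phi_shared <- runif(length(gene_ids), 0, 24)
    params <- data.frame(gene_id = gene_ids, A_F = A_shared, A_L = A_shared,
                         phase_F = phi_shared, phase_L = phi_shared,
                         is_de = FALSE, stringsAsFactors = FALSE)
    if (!is.null(de_params) && nrow(de_params) > 0) {
      m <- match(de_params$gene_id, params$gene_id)
      params$A_F[m] <- de_params$A_F
      params$A_L[m] <- de_params$A_L
      if ("phase_F" %in% names(de_params)) params$phase_F[m] <- de_params$phase_F
      if ("phase_L" %in% names(de_params)) params$phase_L[m] <- de_params$phase_L
      params$is_de[m] <- TRUE
    }
    n_s <- nrow(design)
    gene_counts <- matrix(0L, length(gene_ids), n_s,
                          dimnames = list(gene_ids, design$sample))
    for (g in seq_along(gene_ids)) {
      A <- ifelse(design$species == "F", params$A_F[g], params$A_L[g])
      phi <- ifelse(design$species == "F", params$phase_F[g], params$phase_L[g])
      mu <- baseline_mean * exp(A * sin(2 * pi * (design$time - phi) / 24))
      gene_counts[g, ] <- rnbinom(n_s, mu = mu, size = 1 / dispersion)
    }
    ex_rows <- list(); ex_names <- character(0)
    for (g in seq_along(gene_ids)) {
      k <- n_exons[[gene_ids[g]]] %||% 1L
      if (k == 1) {
        ex_rows[[length(ex_rows) + 1]] <- gene_counts[g, , drop = FALSE]
        ex_names <- c(ex_names, paste0(gene_ids[g], ".exon1"))
      } else {
        w <- runif(k, 0.5, 1.5); w <- w / sum(w)
        split <- vapply(gene_counts[g, ], function(tot) {
          rmultinom(1, tot, w)[, 1]
        }, integer(k))
        ex_rows[[length(ex_rows) + 1]] <- split
        ex_names <- c(ex_names, paste0(gene_ids[g], ".exon", seq_len(k)))
      }
    }
    exon_counts <- do.call(rbind, ex_rows)
    rownames(exon_counts) <- ex_names
    list(exon_counts = exon_counts, design = design, gene_params = params)
  })
}

#' Simulate an aligned codon pair under the Goldman-Yang model
#'
#' A random sense-codon ancestor evolves into a descendant under the
#' instantaneous-rate model (unit expected rate scaling), so `t` is the
#' expected number of substitutions per codon.  Stop codons cannot occur.
#'
#' @param n_codons alignment length in codons (>= 1).
#' @param omega,kappa,t model parameters (> 0).
#' @param pi codon frequencies (default uniform over the 61 sense codons).
#' @param seed RNG seed.
#' @return list(seq1, seq2) of equal-length gapless CDS strings.
#' @export
simulate_codon_pair <- function(n_codons, omega, kappa, t, pi = NULL, seed = 1) {
  stopifnot(n_codons >= 1, omega > 0, kappa > 0, t >= 0)
  u <- codon_universe()
  if (is.null(pi)) pi <- rep(1 / u$n, u$n)
  with_seed(child_seed(seed, "codon_pair"), {
    anc <- sample.int(u$n, n_codons, replace = TRUE, prob = pi)
    if (t == 0) {
      s <- paste(u$codons[anc], collapse = "")
      return(list(seq1 = s, seq2 = s))
    }
    eig <- gy94_eigen(kappa, omega, pi)
    P <- gy94_P(eig, t)
    des <- vapply(anc, function(i) sample.int(u$n, 1, prob = P[i, ]), 0L)
    list(seq1 = paste(u$codons[anc], collapse = ""),
         seq2 = paste(u$codons[des], collapse = ""))
  })
}

scan_any_motif <- function(seqs, motifs) {
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  hit <- rep(FALSE, length(seqs))
  for (m in motifs) {
    hit <- hit | Biostrings::vcountPattern(m, ss, fixed = TRUE) > 0
  }
  hit
}

#' Generate promoter sequences with motifs planted at exact per-kb rates
#'
#' Background sequence is regenerated by rejection until free of spurious
#' motif matches, then each motif is inserted at Poisson-drawn,
#' non-overlapping positions; promoters whose realized scan count deviates
#' from the planted count (insertion collisions) are redrawn.
#'
#' @param n_promoters number of promoters.
#' @param rates named per-kb occurrence rate per motif (>= 0).
#' @param length promoter length in bp (default 2000).
#' @param motifs named motif patterns (default [default_motifs()]).
#' @param gc background GC content (default 0.38).
#' @param seed RNG seed.
#' @return list(sequences, planted) where planted is an n x motif count
#'   matrix.
#' @export
plant_motifs <- function(n_promoters, rates, length = 2000,
                         motifs = default_motifs(), gc = 0.38, seed = 1) {
  stopifnot(all(rates >= 0), !is.null(names(rates)),
            all(names(rates) %in% names(motifs)))
  motifs <- motifs[names(rates)]
  if (any(nchar(motifs) > length)) stop("motif longer than promoter")
  with_seed(child_seed(seed, "promoters"), {
    batch_dna <- function(n) {
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      big <- paste(sample(names(p), n * length, replace = TRUE, prob = p),
                   collapse = "")
      substring(big, seq(1, n * length, by = length),
                seq(length, n * length, by = length))
    }
    make_clean <- function(n) {
      out <- batch_dna(n)
      for (iter in 1:20) {
        bad <- scan_any_motif(out, motifs)
        if (!any(bad)) break
        out[bad] <- batch_dna(sum(bad))
      }
      out
    }
    plant_one <- function(s, want) {
      occupied <- integer(0)
      for (m in names(motifs)) {
        w <- nchar(motifs[[m]])
        for (r in seq_len(want[[m]])) {
          pos_ok <- setdiff(seq_len(length - w + 1),
                            unlist(lapply(occupied, function(p) (p - 8):(p + 8))))
          if (length(pos_ok) == 0) return(NULL)
          p <- if (length(pos_ok) == 1) pos_ok else sample(pos_ok, 1)
          substr(s, p, p + w - 1) <- motifs[[m]]
          occupied <- c(occupied, p)
        }
      }
      s
    }
    seqs <- make_clean(n_promoters)
    planted <- matrix(0L, n_promoters, length(motifs),
                      dimnames = list(NULL, names(motifs)))
    for (m in names(motifs)) {
      planted[, m] <- as.integer(rpois(n_promoters, rates[[m]] * length / 1000))
    }
    todo <- seq_len(n_promoters)
    for (round in 1:10) {
      for (i in todo) {
        s <- plant_one(seqs[i], planted[i, ])
        if (!is.null(s)) seqs[i] <- s
      }
      # batch-verify: insertion collisions can create or destroy matches
      ss <- Biostrings::DNAStringSet(toupper(seqs[todo]))
      ok <- rep(TRUE, base::length(todo))
      for (m in names(motifs)) {
        ok <- ok & Biostrings::vcountPattern(motifs[[m]], ss, fixed = TRUE) ==
          planted[todo, m]
      }
      redo <- todo[!ok]
      if (base::length(redo) == 0) break
      seqs[redo] <- make_clean(base::length(redo))
      todo <- redo
    }
    list(sequences = seqs, planted = planted)
  })
}

#' Simulate a diel metabolite abundance table (CAM-like vs flat species)
#'
#' Species F follows CAM-like curves for the rhythmic compounds (malate by
#' default, peaking toward the end of the night), species L is flat; all
#' values carry lognormal noise.
#'
#' @param n_accessions accessions per species (default 6).
#' @param compounds compound names; the first is the rhythmic (malate-like)
#'   one.
#' @param malate_amplitude log-scale amplitude of the rhythmic compound in
#'   species F (default log(3)/2, i.e. a 3x peak-to-trough ratio).
#' @param cv lognormal noise coefficient of variation (default 0.2).
#' @param seed RNG seed.
#' @return list(table, params); table has species, accession, timepoint and
#'   compound columns (MTIC-normalized scale).
#' @export
simulate_metabolites <- function(n_accessions = 6,
                                 compounds = c("malate", "citrate", "glucose",
                                               "fructose", "fumarate"),
                                 malate_amplitude = log(3) / 2, cv = 0.2,
                                 seed = 1) {
  tp <- diel_timepoints()
  grid <- expand.grid(accession = seq_len(n_accessions),
                      timepoint = names(tp), species = c("F", "L"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("species", "accession", "timepoint")]
  with_seed(child_seed(seed, "metabolites"), {
    base <- setNames(10^runif(length(compounds), -1, 1), compounds)
    tab <- grid
    for (cmp in compounds) {
      A <- ifelse(grid$species == "F" & cmp == compounds[1], malate_amplitude, 0)
      hours <- tp[grid$timepoint]
      # malate peaks at the end of the night under CAM: phase set so the
      # sine maximum falls near lights-on
      mu <- base[[cmp]] * exp(A * sin(2 * pi * (hours - 19) / 24 + pi / 2))
      sdlog <- sqrt(log(1 + cv^2))
      tab[[cmp]] <- stats::rlnorm(nrow(grid), log(mu) - sdlog^2 / 2, sdlog)
    }
    list(table = tab,
         params = list(base = base, malate_amplitude = malate_amplitude, cv = cv))
  })
}
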