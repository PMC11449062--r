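# End-to-end orchestration: simulate (or load) a paired-species dataset and
# run curation, family-size correction, diel DE, category enrichment,
# motif, TE and landscape statistics in dependency order, writing one TSV
# per stage plus a JSON summary.

write_stage_tsv <- function(df, path, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# camevo %s; seed=%d",
                     as.character(utils::packageVersion("camevo")), seed), con)
  close(con)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a seeded paired-species dataset, then runs every stage in
#' dependency order: coverage-based family-size correction and
#' categorization, diel DE calling on simulated counts, orthogroup-category
#' enrichment of DE orthogroups, circadian motif statistics (DE vs
#' background promoters), TE-insertion tests, and windowed landscape
#' statistics.  Each stage writes a TSV into `out_dir`.
#'
#' @param config synthetic-data configuration overrides (see
#'   [synthetic_config()]).
#' @param seed global seed.
#' @param out_dir output directory (created if needed); NULL to skip writing.
#' @param de_fraction fraction of genes planted as DE (default 0.1).
#' @param stages character vector of stages to run (default all).
#' @return list of per-stage results plus the truth object.
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = NULL,
                         de_fraction = 0.1,
                         stages = c("famsize", "de", "enrichment", "motifs",
                                    "te", "landscape")) {
  data <- generate_genome_pair(config, seed)
  out <- list(truth = data$truth, data = data)
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_stage_tsv(df, file.path(out_dir, paste0(name, ".tsv")), seed)
    }
  }

  og <- data$og
  if ("famsize" %in% stages) {
    cov_F <- simulate_coverage(data$genes_F, data$truth, "F", seed = seed)
    cov_L <- simulate_coverage(data$genes_L, data$truth, "L", seed = seed)
    og <- correct_family_size(og,
                              setNames(cov_F$mean_cov, cov_F$gene_id),
                              setNames(cov_L$mean_cov, cov_L$gene_id))
    og <- categorize_all(og)
    out$og <- og
    emit(og[, c("orthogroup_id", "A", "F_count", "L_count",
                "corrected_F", "corrected_L", "category")], "orthogroups")
  }

  if ("de" %in% stages) {
    gene_ids <- data$genes_F$gene_id
    n_ex <- setNames(vapply(data$genes_F$exons, nrow, 0L), gene_ids)
    n_de <- max(1, round(de_fraction * length(gene_ids)))
    de_truth <- with_seed(child_seed(seed, "de_pick"), {
      data.frame(gene_id = sample(gene_ids, n_de), A_F = 1.5, A_L = 0,
                 stringsAsFactors = FALSE)
    })
    sim <- simulate_diel_counts(gene_ids, n_ex, de_params = de_truth, seed = seed)
    gm <- exon_to_gene_counts(sim$exon_counts)
    fac <- tmm_normalize(gm)
    gm <- cpm_filter(gm, fac)
    de <- timecourse_de(gm, sim$design, factors = tmm_normalize(gm))
    out$de <- de
    out$de_truth <- de_truth
    out$de_design <- sim$design
    emit(de, "de_results")
  }

  if ("enrichment" %in% stages && !is.null(out$og) && !is.null(out$de)) {
    de_genes <- out$de$gene_id[out$de$is_DE]
    de_og <- vapply(seq_len(nrow(og)), function(k) {
      any(og$genes_F[[k]] %in% de_genes)
    }, FALSE)
    out$enrichment <- tryCatch(category_enrichment(og, de_og),
                               error = function(e) NULL)
    if (!is.null(out$enrichment)) emit(out$enrichment, "category_enrichment")
  }

  if ("motifs" %in% stages && !is.null(out$de)) {
    de_set <- out$de$gene_id[out$de$is_DE]
    bg_set <- setdiff(out$de$gene_id, de_set)
    count_set <- function(ids) {
      t(vapply(ids, function(g) {
        i <- match(g, data$genes_F$gene_id)
        up <- extract_upstream(data$genes_F[i, ], data$genome_F)
        count_motifs(up$sequence)
      }, setNames(integer(4), names(default_motifs()))))
    }
    if (length(de_set) >= 2 && length(bg_set) >= 2) {
      cde <- count_set(de_set); cbg <- count_set(bg_set)
      freq_de <- perkb_frequency(colSums(cde), length(de_set))
      freq_bg <- perkb_frequency(colSums(cbg), length(bg_set))
      out$motifs <- data.frame(
        motif = names(freq_de), freq_de = freq_de, freq_bg = freq_bg,
        pct_change = frequency_change(freq_de, freq_bg),
        p = vapply(names(freq_de), function(m) {
          motif_mw_test(cde[, m], cbg[, m], seed = child_seed(seed, "mw"))$p
        }, 0), stringsAsFactors = FALSE)
      emit(out$motifs, "motif_stats")
    }
  }

  if ("te" %in% stages && !is.null(out$de)) {
    slen <- setNames(rep(nchar(data$genome_F[1]), length(data$genome_F)),
                     names(data$genome_F))
    te_counts <- intersect_te(data$genes_F, data$tes_F, slen,
                              region = "span_upstream")
    de_mask <- data$genes_F$gene_id %in% out$de$gene_id[out$de$is_DE]
    out$te <- list(
      counts = te_counts,
      presence = te_presence_test(te_counts$total[de_mask] > 0,
                                  te_counts$total > 0),
      rate = te_rate_test(te_counts$total[de_mask], te_counts$total[!de_mask]))
    emit(te_counts, "te_counts")
  }

  if ("landscape" %in% stages) {
    out$landscape <- window_stats(data$genome_F, data$genes_F, window = 100000)
    emit(out$landscape, "landscape_windows")
  }

  if (!is.null(out_dir)) {
    summary <- list(
      seed = seed,
      n_orthogroups = nrow(og),
      n_genes_F = nrow(data$genes_F),
      n_genes_L = nrow(data$genes_L),
      n_de = if (!is.null(out$de)) sum(out$de$is_DE) else NA)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
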