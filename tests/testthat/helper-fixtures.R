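# Shared small synthetic dataset, generated once per test run.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_genome_pair(
        list(n_orthogroups = 120, n_scaffolds = 3, scaffold_length = 150000),
        seed = 42)
    }
    cache
  }
})

# Minimal hand-built gene table for interval-level tests.
toy_genes <- function() {
  gene_models(
    gene_id = c("g1", "g2", "g3"),
    scaffold_id = c("s1", "s1", "s2"),
    start = c(5000L, 100L, 0L), end = c(8000L, 900L, 300L),
    strand = c("+", "-", "+"),
    exons = list(cbind(c(5000L, 6000L, 7500L), c(5600L, 6900L, 8000L)),
                 cbind(100L, 900L),
                 cbind(0L, 300L)),
    cds_len_aa = c(200L, 60L, 30L),
    has_start_codon = c(TRUE, TRUE, FALSE),
    has_stop_codon = c(TRUE, TRUE, FALSE))
}
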