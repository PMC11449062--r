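# Gene-model curation: ROBUST/NOT-ROBUST classification, propagation of
# NO_ORTHOLOGY flags across orthogroups, organellar/ribosomal exclusion and
# transcription-factor family identification.

DEFAULT_REPEAT_LABELS <- c("transposon", "transposase", "retrotransposon",
                           "viral", "virus", "gag", "pol", "integrase")

#' Classify a gene model as ROBUST or NOT-ROBUST
#'
#' ROBUST iff (i) all exons are expressed, or (ii) both start and stop
#' codons are present and the CDS is at least 50 amino acids long.
#'
#' @param gene one-row `gene_models` entry (or a list with the same fields).
#' @param exon_expressed logical vector aligned to the gene's exons;
#'   "expressed" means a summed raw count above zero by default.
#' @param min_cds_aa CDS length threshold of criterion (ii), default 50.
#' @return "ROBUST" or "NOT-ROBUST".
#' @export
classify_robust <- function(gene, exon_expressed, min_cds_aa = 50) {
  n_ex <- if (is.data.frame(gene)) nrow(gene$exons[[1]]) else nrow(gene$exons)
  if (length(exon_expressed) != n_ex) {
    stop("exon_expressed length (", length(exon_expressed),
         ") does not match exon count (", n_ex, ")")
  }
  crit1 <- all(exon_expressed)
  crit2 <- isTRUE(gene$has_start_codon[[1]]) && isTRUE(gene$has_stop_codon[[1]]) &&
    gene$cds_len_aa[[1]] >= min_cds_aa
  if (crit1 || crit2) "ROBUST" else "NOT-ROBUST"
}

#' Classify all gene models given an exon count matrix
#'
#' @param genes `gene_models` table.
#' @param exon_counts matrix exons x samples; rownames `<gene_id>.exon<k>`
#'   or a parallel `exon_gene` vector naming each row's gene.
#' @param exon_gene optional gene id per exon row.
#' @param min_cds_aa see [classify_robust()].
#' @return character vector of statuses, named by gene id.
#' @export
classify_robust_all <- function(genes, exon_counts, exon_gene = NULL,
                                min_cds_aa = 50) {
  if (is.null(exon_gene)) exon_gene <- sub("\\.exon\\d+$", "", rownames(exon_counts))
  expressed <- rowSums(exon_counts) > 0
  status <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes$gene_id[i]
    ex <- expressed[exon_gene == g]
    classify_robust(genes[i, ], ex, min_cds_aa)
  }, "")
  setNames(status, genes$gene_id)
}

#' Flag repeat-like genes and all their orthologs with NO_ORTHOLOGY
#'
#' Any gene whose functional labels match the repeat vocabulary
#' (transposon/viral by default), together with every gene sharing its
#' orthogroup, is flagged and excluded downstream.  Propagation over whole
#' orthogroups makes the operation idempotent.
#'
#' @param genes `gene_models` table.
#' @param og `orthogroups` table.
#' @param repeat_labels label vocabulary (substring match, case-insensitive).
#' @return character vector of flagged gene ids.
#' @export
flag_no_orthology <- function(genes, og, repeat_labels = DEFAULT_REPEAT_LABELS) {
  pat <- paste(repeat_labels, collapse = "|")
  seed_hit <- vapply(genes$functional_labels, function(l) {
    length(l) > 0 && any(grepl(pat, l, ignore.case = TRUE))
  }, FALSE)
  seed_ids <- genes$gene_id[seed_hit]
  flagged <- seed_ids
  for (k in seq_len(nrow(og))) {
    members <- c(og$genes_A[[k]], og$genes_F[[k]], og$genes_L[[k]])
    if (any(members %in% seed_ids)) flagged <- c(flagged, members)
  }
  sort(unique(flagged))
}

#' Exclude organellar and ribosomal orthogroups
#'
#' Orthogroups containing a plastid/mitochondrial hit or a gene labelled
#' "ribosomal" are removed from the gene-family analyses.
#'
#' @param og `orthogroups` table.
#' @param genes `gene_models` table (for ribosomal labels).
#' @param plastid_hits,mito_hits gene-id vectors (stand-ins for organelle
#'   homology searches, which are outside this package's boundary).
#' @return filtered `orthogroups` table with attribute `n_removed`.
#' @export
exclude_organellar_ribosomal <- function(og, genes, plastid_hits = character(0),
                                         mito_hits = character(0)) {
  ribo <- genes$gene_id[vapply(genes$functional_labels, function(l) {
    length(l) > 0 && any(grepl("ribosomal", l, ignore.case = TRUE))
  }, FALSE)]
  bad <- unique(c(plastid_hits, mito_hits, ribo))
  drop <- vapply(seq_len(nrow(og)), function(k) {
    any(c(og$genes_A[[k]], og$genes_F[[k]], og$genes_L[[k]]) %in% bad)
  }, FALSE)
  out <- og[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Identify transcription-factor orthogroups
#'
#' An orthogroup is a TF family if any member carries a listed InterPro
#' domain characteristic of large TF families, or contains a homolog of a
#' known outgroup TF.  Both per-list sets, their union, and the overlap
#' fraction (domain-identified TFs also found by homology) are returned.
#'
#' @param og `orthogroups` table.
#' @param genes `gene_models` table (domains live in functional labels).
#' @param interpro_tf_domains character vector of domain ids.
#' @param known_tf_homologs character vector of gene ids.
#' @return list: `by_domain`, `by_homolog`, `union` (orthogroup ids) and
#'   `overlap_fraction`.
#' @export
identify_tf_families <- function(og, genes, interpro_tf_domains,
                                 known_tf_homologs) {
  if (length(interpro_tf_domains) == 0 && length(known_tf_homologs) == 0) {
    stop("both the domain list and the homolog list are empty")
  }
  domain_genes <- genes$gene_id[vapply(genes$functional_labels, function(l) {
    any(l %in% interpro_tf_domains)
  }, FALSE)]
  has_member <- function(ids) vapply(seq_len(nrow(og)), function(k) {
    any(c(og$genes_A[[k]], og$genes_F[[k]], og$genes_L[[k]]) %in% ids)
  }, FALSE)
  by_domain <- og$orthogroup_id[has_member(domain_genes)]
  by_homolog <- og$orthogroup_id[has_member(known_tf_homologs)]
  overlap <- if (length(by_domain) > 0) {
    length(intersect(by_domain, by_homolog)) / length(by_domain)
  } else NA_real_
  list(by_domain = by_domain, by_homolog = by_homolog,
       union = sort(unique(c(by_domain, by_homolog))),
       overlap_fraction = overlap)
}
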