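# All coordinates inside the package are 0-based half-open [start, end).
# GFF3 (1-based inclusive) is converted at the read/write boundary; BED is
# written as-is since BED shares the internal convention.

GENE_ALPHABET <- c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")

TE_CLASSES <- c("LTR-Copia", "LTR-Gypsy", "Helitron", "DNA transposon", "other")

#' Construct a gene-model table
#'
#' @param gene_id,scaffold_id character vectors.
#' @param start,end 0-based half-open gene span.
#' @param strand "+" or "-".
#' @param exons list of two-column integer matrices (start, end), 0-based
#'   half-open, non-overlapping and contained in the gene span.
#' @param cds_len_aa CDS length in amino acids.
#' @param has_start_codon,has_stop_codon CDS completeness flags.
#' @param functional_labels list of character vectors (GO ids, descriptions,
#'   domain ids).
#' @param orthogroup_id optional orthogroup membership.
#' @return data.frame of class `gene_models` with list-columns `exons` and
#'   `functional_labels`.
#' @export
gene_models <- function(gene_id, scaffold_id, start, end, strand,
                        exons = NULL, cds_len_aa = 0L,
                        has_start_codon = FALSE, has_stop_codon = FALSE,
                        functional_labels = NULL, orthogroup_id = NA_character_) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene_id")
  if (any(start >= end)) stop("gene with start >= end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(exons)) {
    exons <- lapply(seq_len(n), function(i) cbind(start[i], end[i]))
  }
  if (is.null(functional_labels)) functional_labels <- rep(list(character(0)), n)
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (nrow(ex) > 0) {
      ex <- ex[order(ex[, 1]), , drop = FALSE]
      if (any(ex[, 1] < start[i]) || any(ex[, 2] > end[i])) {
        stop(sprintf("exons of %s fall outside the gene span", gene_id[i]))
      }
      if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])) {
        stop(sprintf("overlapping exons in %s", gene_id[i]))
      }
      exons[[i]] <- ex
    }
  }
  out <- data.frame(gene_id = gene_id, scaffold_id = scaffold_id,
                    start = as.integer(start), end = as.integer(end),
                    strand = strand,
                    cds_len_aa = as.integer(rep_len(cds_len_aa, n)),
                    has_start_codon = rep_len(has_start_codon, n),
                    has_stop_codon = rep_len(has_stop_codon, n),
                    orthogroup_id = rep_len(orthogroup_id, n),
                    stringsAsFactors = FALSE)
  out$exons <- exons
  out$functional_labels <- functional_labels
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Construct a transposable-element feature table
#'
#' @param scaffold_id character vector.
#' @param start,end 0-based half-open interval.
#' @param te_class one of `LTR-Copia`, `LTR-Gypsy`, `Helitron`,
#'   `DNA transposon`, `other`.
#' @param known logical; whether the TE is a curated ("known") annotation.
#' @param te_id optional identifiers.
#' @return data.frame of class `te_features`.
#' @export
te_features <- function(scaffold_id, start, end, te_class, known = TRUE,
                        te_id = NULL) {
  if (!all(te_class %in% TE_CLASSES)) {
    stop("te_class outside the fixed vocabulary: ",
         paste(setdiff(unique(te_class), TE_CLASSES), collapse = ", "))
  }
  if (any(start >= end)) stop("TE with start >= end")
  n <- length(scaffold_id)
  if (is.null(te_id)) te_id <- sprintf("TE%06d", seq_len(n))
  out <- data.frame(te_id = te_id, scaffold_id = scaffold_id,
                    start = as.integer(start), end = as.integer(end),
                    te_class = te_class, known = rep_len(known, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("te_features", "data.frame")
  out
}

#' Construct an orthogroup table
#'
#' Per-orthogroup gene lists and counts for the outgroup (A) and the two
#' focal species (F, L).
#'
#' @param orthogroup_id character vector.
#' @param genes_A,genes_F,genes_L lists of gene-id character vectors.
#' @return data.frame of class `orthogroups` with raw counts `A`, `F_count`,
#'   `L_count` and empty `corrected_F`/`corrected_L`/`category` columns.
#' @export
orthogroups <- function(orthogroup_id, genes_A, genes_F, genes_L) {
  if (anyDuplicated(orthogroup_id)) stop("duplicate orthogroup_id")
  out <- data.frame(orthogroup_id = orthogroup_id,
                    A = lengths(genes_A), F_count = lengths(genes_F),
                    L_count = lengths(genes_L),
                    corrected_F = NA_real_, corrected_L = NA_real_,
                    category = NA_character_, stringsAsFactors = FALSE)
  out$genes_A <- genes_A
  out$genes_F <- genes_F
  out$genes_L <- genes_L
  class(out) <- c("orthogroups", "data.frame")
  out
}

#' Read a (possibly soft-masked) genome FASTA
#'
#' Lowercase letters mark repeat-masked positions and are preserved.
#'
#' @param path FASTA file.
#' @return named character vector of scaffold sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate scaffold id in ", path)
  seqs <- as.character(ss)
  names(seqs) <- ids
  bad <- !grepl("^[ACGTNacgtn]*$", seqs)
  if (any(bad)) stop("non-ACGTN characters in scaffold(s): ",
                     paste(ids[bad], collapse = ", "))
  seqs
}

#' Write a genome FASTA preserving soft-mask case
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}

#' Write intervals as BED (0-based half-open, matching internal coordinates)
#' @param intervals data.frame with scaffold_id, start, end and optionally name.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  assert_cols(intervals, c("scaffold_id", "start", "end"), "BED input")
  df <- intervals[, c("scaffold_id", "start", "end")]
  if ("name" %in% names(intervals)) df$name <- intervals$name
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a header-less or headered TSV against a declared schema
#'
#' @param path TSV with a header row.
#' @param schema named character vector column -> type
#'   ("character", "integer", "numeric", "logical").
#' @return data.frame with at least the schema columns, coerced.
#' @export
read_table <- function(path, schema) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#", check.names = FALSE)
  assert_cols(df, names(schema), path)
  for (cn in names(schema)) {
    df[[cn]] <- switch(schema[[cn]],
                       character = as.character(df[[cn]]),
                       integer = as.integer(df[[cn]]),
                       numeric = as.numeric(df[[cn]]),
                       logical = as.logical(df[[cn]]),
                       stop("unknown schema type ", schema[[cn]]))
  }
  df
}

gff3_strand <- function(s) {
  if (!all(s %in% c("+", "-"))) stop("unknown strand value in GFF3")
  s
}

#' Write gene models to GFF3
#'
#' Emits `gene` and `exon` features; internal 0-based half-open coordinates
#' are converted to GFF3 1-based inclusive at this boundary.
#'
#' @param genes a `gene_models` table.
#' @param path output file.
#' @export
write_gff3_genes <- function(genes, path) {
  n_ex <- vapply(genes$exons, nrow, 0L)
  gid <- genes$gene_id
  gene_gr <- GenomicRanges::GRanges(
    genes$scaffold_id,
    IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gene_gr)$source <- "camevo"
  S4Vectors::mcols(gene_gr)$type <- "gene"
  S4Vectors::mcols(gene_gr)$ID <- gid
  S4Vectors::mcols(gene_gr)$cds_len_aa <- as.character(genes$cds_len_aa)
  S4Vectors::mcols(gene_gr)$has_start_codon <- ifelse(genes$has_start_codon, "1", "0")
  S4Vectors::mcols(gene_gr)$has_stop_codon <- ifelse(genes$has_stop_codon, "1", "0")
  labs <- vapply(genes$functional_labels, paste, "", collapse = "|")
  S4Vectors::mcols(gene_gr)$labels <- ifelse(labs == "", NA_character_, labs)
  S4Vectors::mcols(gene_gr)$orthogroup <- genes$orthogroup_id

  ex_all <- do.call(rbind, genes$exons)
  ex_gr <- GenomicRanges::GRanges(
    rep(genes$scaffold_id, n_ex),
    IRanges::IRanges(ex_all[, 1] + 1L, ex_all[, 2]),
    strand = rep(genes$strand, n_ex))
  S4Vectors::mcols(ex_gr)$source <- "camevo"
  S4Vectors::mcols(ex_gr)$type <- "exon"
  parent <- rep(gid, n_ex)
  S4Vectors::mcols(ex_gr)$ID <- paste0(parent, ".exon",
                                       unlist(lapply(n_ex, seq_len)))
  S4Vectors::mcols(ex_gr)$Parent <- parent
  gr <- c(gene_gr, ex_gr)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write TE features to GFF3
#' @param tes a `te_features` table.
#' @param path output file.
#' @export
write_gff3_tes <- function(tes, path) {
  gr <- GenomicRanges::GRanges(
    tes$scaffold_id, IRanges::IRanges(tes$start + 1L, tes$end), strand = "+")
  S4Vectors::mcols(gr)$source <- "camevo"
  S4Vectors::mcols(gr)$type <- "transposable_element"
  S4Vectors::mcols(gr)$ID <- tes$te_id
  S4Vectors::mcols(gr)$te_class <- tes$te_class
  S4Vectors::mcols(gr)$known <- ifelse(tes$known, "1", "0")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models or TE features from GFF3
#'
#' GFF3 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention.  Files containing `transposable_element` features
#' are returned as a `te_features` table; files with `gene`/`exon` features
#' as a `gene_models` table.
#'
#' @param path GFF3 file.
#' @return `gene_models` or `te_features` data.frame.
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  type <- as.character(S4Vectors::mcols(gr)$type)
  if (any(type == "transposable_element")) {
    sel <- type == "transposable_element"
    m <- S4Vectors::mcols(gr)[sel, ]
    return(te_features(
      scaffold_id = as.character(GenomicRanges::seqnames(gr))[sel],
      start = GenomicRanges::start(gr)[sel] - 1L,
      end = GenomicRanges::end(gr)[sel],
      te_class = as.character(m$te_class),
      known = as.character(m$known) == "1",
      te_id = as.character(m$ID)))
  }
  sel_g <- type == "gene"
  sel_e <- type == "exon"
  if (!any(sel_g)) stop("no gene or transposable_element features in ", path)
  strand_g <- as.character(GenomicRanges::strand(gr))[sel_g]
  gff3_strand(strand_g)
  m <- S4Vectors::mcols(gr)[sel_g, ]
  gid <- as.character(m$ID)
  parent <- as.character(S4Vectors::mcols(gr)$Parent[sel_e])
  ex_df <- data.frame(parent = parent,
                      start = GenomicRanges::start(gr)[sel_e] - 1L,
                      end = GenomicRanges::end(gr)[sel_e])
  exl <- lapply(gid, function(g) {
    e <- ex_df[ex_df$parent == g, , drop = FALSE]
    unname(as.matrix(e[order(e$start), c("start", "end")]))
  })
  labs <- if ("labels" %in% names(m)) as.character(m$labels) else
    rep(NA_character_, length(gid))
  labs_l <- lapply(labs, function(x) {
    if (is.na(x) || x == "") character(0) else strsplit(x, "|", fixed = TRUE)[[1]]
  })
  og <- if ("orthogroup" %in% names(m)) as.character(m$orthogroup) else NA_character_
  gene_models(
    gene_id = gid,
    scaffold_id = as.character(GenomicRanges::seqnames(gr))[sel_g],
    start = GenomicRanges::start(gr)[sel_g] - 1L,
    end = GenomicRanges::end(gr)[sel_g],
    strand = strand_g,
    exons = exl,
    cds_len_aa = as.integer(as.character(m$cds_len_aa)),
    has_start_codon = as.character(m$has_start_codon) == "1",
    has_stop_codon = as.character(m$has_stop_codon) == "1",
    functional_labels = labs_l,
    orthogroup_id = og)
}

#' Write an orthogroup table to TSV
#' @param og an `orthogroups` table.
#' @param path output file.
#' @export
write_orthogroups <- function(og, path) {
  df <- data.frame(
    orthogroup_id = og$orthogroup_id,
    genes_A = vapply(og$genes_A, paste, "", collapse = ","),
    genes_F = vapply(og$genes_F, paste, "", collapse = ","),
    genes_L = vapply(og$genes_L, paste, "", collapse = ","),
    A = og$A, F_count = og$F_count, L_count = og$L_count,
    corrected_F = og$corrected_F, corrected_L = og$corrected_L,
    category = og$category, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an orthogroup table from TSV
#'
#' Expects one species column per genome with comma-separated gene ids
#' (outgroup A and focal species F and L).
#'
#' @param path TSV written by [write_orthogroups()] (or equivalent).
#' @return `orthogroups` data.frame.
#' @export
read_orthogroups <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  assert_cols(df, c("orthogroup_id", "genes_A", "genes_F", "genes_L"), path)
  split_genes <- function(x) {
    lapply(as.character(x), function(s) {
      if (is.na(s) || s == "") character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
    })
  }
  og <- orthogroups(df$orthogroup_id, split_genes(df$genes_A),
                    split_genes(df$genes_F), split_genes(df$genes_L))
  if ("corrected_F" %in% names(df)) og$corrected_F <- as.numeric(df$corrected_F)
  if ("corrected_L" %in% names(df)) og$corrected_L <- as.numeric(df$corrected_L)
  if ("category" %in% names(df)) og$category <- as.character(df$category)
  og
}
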