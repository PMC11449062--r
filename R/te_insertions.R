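# TE insertions in gene bodies and upstream regions: strand-aware upstream
# extension (bedtools-slop semantics), interval intersection by at least one
# base, and DE-vs-background presence and rate tests.

#' Strand-aware 5' extension of gene spans (bedtools slop -l N -r 0 -s)
#'
#' Extends each gene's span by `extend` bp on its 5' side only, clipping at
#' scaffold boundaries.
#'
#' @param genes `gene_models` table.
#' @param scaffold_lengths named vector scaffold -> length.
#' @param extend bp to add upstream (default 3000).
#' @return data.frame gene_id, scaffold_id, start, end of extended spans.
#' @export
slop_upstream <- function(genes, scaffold_lengths, extend = 3000) {
  slen <- scaffold_lengths[genes$scaffold_id]
  if (any(is.na(slen))) stop("unknown scaffold length for some genes")
  start <- ifelse(genes$strand == "+", pmax(0, genes$start - extend), genes$start)
  end <- ifelse(genes$strand == "+", genes$end, pmin(slen, genes$end + extend))
  data.frame(gene_id = genes$gene_id, scaffold_id = genes$scaffold_id,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(df$scaffold_id,
                         IRanges::IRanges(df$start + 1L, df$end))
}

gene_intron_intervals <- function(genes) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    if (nrow(ex) < 2) return(NULL)
    data.frame(gene_id = genes$gene_id[i], scaffold_id = genes$scaffold_id[i],
               start = ex[-nrow(ex), 2], end = ex[-1, 1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[out$start < out$end, , drop = FALSE]
}

#' Count TE insertions overlapping gene regions, per TE class
#'
#' A TE is counted when it overlaps the queried interval by at least one
#' base (half-open intervals: abutting features do not overlap).  Regions:
#' the full gene span (`region = "span"`), introns only (`"introns"`), or
#' the span extended 5' by `upstream` bp (`"span_upstream"`).  A TE is
#' counted once per gene region queried even if it touches several of the
#' gene's introns.
#'
#' @param genes `gene_models` table.
#' @param tes `te_features` table.
#' @param scaffold_lengths named vector (needed for `span_upstream`).
#' @param region which gene region to intersect.
#' @param upstream extension for `span_upstream` (default 3000).
#' @param known_only restrict to curated ("known") TE annotations.
#' @return data.frame gene_id, total, and one column per TE class.
#' @export
intersect_te <- function(genes, tes, scaffold_lengths = NULL,
                         region = c("span", "introns", "span_upstream"),
                         upstream = 3000, known_only = TRUE) {
  region <- match.arg(region)
  if (known_only) tes <- tes[tes$known, , drop = FALSE]
  classes <- setdiff(TE_CLASSES, "other")
  zero <- matrix(0L, nrow(genes), length(classes) + 1,
                 dimnames = list(genes$gene_id, c("total", classes)))
  if (region == "span") {
    iv <- data.frame(gene_id = genes$gene_id, scaffold_id = genes$scaffold_id,
                     start = genes$start, end = genes$end)
  } else if (region == "span_upstream") {
    if (is.null(scaffold_lengths)) stop("scaffold_lengths required for span_upstream")
    iv <- slop_upstream(genes, scaffold_lengths, extend = upstream)
  } else {
    iv <- gene_intron_intervals(genes)
  }
  out <- data.frame(gene_id = genes$gene_id, zero, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (is.null(iv) || nrow(iv) == 0 || nrow(tes) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(iv),
                                      intervals_to_granges(tes))
  if (length(hits) == 0) return(out)
  hg <- iv$gene_id[S4Vectors::queryHits(hits)]
  ht <- S4Vectors::subjectHits(hits)
  # one count per distinct (gene, TE) pair, however many introns it touches
  uniq <- !duplicated(paste(hg, ht))
  hg <- hg[uniq]; ht <- ht[uniq]
  tot <- table(factor(hg, levels = genes$gene_id))
  out$total <- as.integer(tot)
  for (cl in classes) {
    sel <- tes$te_class[ht] == cl
    out[[cl]] <- as.integer(table(factor(hg[sel], levels = genes$gene_id)))
  }
  out
}

#' Chi-square test: proportion of genes with any TE insertion, DE vs all
#'
#' Falls back to Fisher's exact test when an expected cell count drops
#' below 1 (noted in the result).
#'
#' @param presence_de,presence_all logical vectors (gene has >= 1 TE).
#' @return `stat_result`.
#' @export
te_presence_test <- function(presence_de, presence_all) {
  tab <- matrix(c(sum(presence_de), sum(!presence_de),
                  sum(presence_all), sum(!presence_all)), 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    r <- fisher_exact_2x2(tab)
    r$note <- paste0("fallback from chi-square (expected cell < 1); ", r$note)
    return(r)
  }
  chi_square_2x2(tab)
}

#' Mann-Whitney test of per-gene TE insertion rate, DE vs non-DE
#'
#' "Rate" is the raw per-gene count of TE intersections.  Group means and
#' medians are reported alongside the test.
#'
#' @param counts_de,counts_nonde integer vectors of per-gene counts.
#' @return list(test = `stat_result`, summary = data.frame of group
#'   means/medians).
#' @export
te_rate_test <- function(counts_de, counts_nonde) {
  stopifnot(length(counts_de) > 0, length(counts_nonde) > 0)
  r <- mann_whitney(counts_de, counts_nonde)
  list(test = r,
       summary = data.frame(group = c("DE", "non-DE"),
                            mean = c(mean(counts_de), mean(counts_nonde)),
                            median = c(median(counts_de), median(counts_nonde))))
}

#' Flag genes with TE insertion rates above twice the genome-wide average
#'
#' For flagged genes with a one-to-one ortholog, the difference in TE count
#' between the orthologs (this species minus the other) is also reported.
#'
#' @param counts named vector gene_id -> TE count (curated genes).
#' @param genome_mean genome-wide average TE count per curated gene.
#' @param ortholog_map named vector gene_id -> one-to-one ortholog id
#'   (absent names mean no 1:1 ortholog).
#' @param counts_other named vector of TE counts in the other species.
#' @return data.frame gene_id, count, ortholog_id, ortholog_count, delta for
#'   flagged genes (count strictly above 2 x mean).
#' @export
flag_high_te <- function(counts, genome_mean, ortholog_map = NULL,
                         counts_other = NULL) {
  flagged <- names(counts)[counts > 2 * genome_mean]
  orth <- if (is.null(ortholog_map)) rep(NA_character_, length(flagged)) else
    unname(ortholog_map[flagged])
  oc <- if (is.null(counts_other)) rep(NA_real_, length(flagged)) else
    unname(counts_other[orth])
  data.frame(gene_id = flagged, count = unname(counts[flagged]),
             ortholog_id = orth, ortholog_count = oc,
             delta = unname(counts[flagged]) - oc,
             stringsAsFactors = FALSE)
}
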