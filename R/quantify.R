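#' Count reads mapping to a transcript's exons
#'
#' A read counts toward transcript `T` when its interval overlaps at least
#' one exon of `T` by >= 1 nt on `T`'s strand. Distinct reads mapped to
#' the same genomic location are counted multiply (no deduplication); a
#' read overlapping several exons of the same transcript counts once.
#' Antisense reads never count toward expression (they are analysed
#' separately as antisense transcription).
#'
#' @param reads `GRanges` read set (see [mapped_read_set()]).
#' @param exons `GRanges` of the transcript's exons (one transcript).
#' @return integer read count.
#' @export
count_transcript_reads <- function(reads, exons) {
  sum(GenomicRanges::countOverlaps(reads, exons, ignore.strand = FALSE) > 0L)
}

#' Reference-normalized expression
#'
#' The normalized expression of transcript `T` is the ratio of
#' per-nucleotide read densities
#' `ne_T = (c_T / L_T) / (c_ref / L_ref)`,
#' where `c` are exonic read counts and `L` exonic lengths. The long-RNA
#' reference is an abundant, stable beta-actin transcript analog; short
#' RNA uses a SNORD44 analog. The reference transcript itself has
#' `ne = 1` by construction, and `ne = 0` iff `c_T = 0`.
#'
#' @param c_T,c_ref read counts (non-negative).
#' @param L_T,L_ref exonic lengths in nt (positive).
#' @return numeric `ne_T`.
#' @export
normalized_expression <- function(c_T, L_T, c_ref, L_ref) {
  stopifnot(all(L_T > 0), L_ref > 0, all(c_T >= 0))
  if (any(c_ref <= 0)) {
    stop("reference transcript has zero reads; sample unusable for this preparation",
         call. = FALSE)
  }
  (c_T / L_T) / (c_ref / L_ref)
}

#' Per-transcript expression table for one read set
#'
#' Counts reads over every transcript of the requested biotypes and
#' normalizes to the reference transcript's read density.
#'
#' @param reads `GRanges` read set for one sample and preparation.
#' @param ann an [AnnotationSet].
#' @param reference_id transcript id of the normalizer (must itself be
#'   quantified: its biotype need not be in `biotypes`).
#' @param biotypes transcript biotypes to quantify.
#' @return data.frame with `transcript_id`, `gene_id`, `biotype`,
#'   `sample_id`, `prep`, `c_T`, `L_T`, `ne_T`, `log2_ne` (NA when
#'   `c_T = 0`).
#' @export
transcript_expression <- function(reads, ann, reference_id,
                                  biotypes = "protein_coding") {
  stopifnot(methods::is(ann, "AnnotationSet"))
  tx <- ann$transcripts
  if (!reference_id %in% tx$transcript_id) {
    stop("reference transcript '", reference_id, "' absent from annotation",
         call. = FALSE)
  }
  keep <- tx$biotype %in% biotypes | tx$transcript_id == reference_id
  tx <- tx[keep, ]
  ex <- ann$exons[ann$exons$transcript_id %in% tx$transcript_id]

  hits <- GenomicRanges::findOverlaps(reads, ex, ignore.strand = FALSE)
  pair <- unique(data.frame(read = S4Vectors::queryHits(hits),
                            tx = ex$transcript_id[S4Vectors::subjectHits(hits)]))
  counts <- table(factor(pair$tx, levels = tx$transcript_id))
  c_T <- as.integer(counts[tx$transcript_id])

  c_ref <- c_T[tx$transcript_id == reference_id]
  L_ref <- tx$length[tx$transcript_id == reference_id]
  ne <- normalized_expression(c_T, tx$length, c_ref, L_ref)

  data.frame(
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id,
    biotype = tx$biotype,
    sample_id = if (length(reads)) reads$sample_id[1] else NA_character_,
    prep = if (length(reads)) reads$prep[1] else NA_character_,
    c_T = c_T,
    L_T = tx$length,
    ne_T = ne,
    log2_ne = ifelse(c_T > 0L, log2(ne), NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Gene-level expression rollup
#'
#' A gene is assigned the normalized expression of its most abundant
#' isoform. Ties are broken toward the lexicographically smallest
#' transcript id, so the rollup is deterministic.
#'
#' @param expr data.frame from [transcript_expression()] (one sample/prep).
#' @return data.frame with `gene_id`, `ne`, `top_transcript`, ordered by
#'   `gene_id`.
#' @export
gene_expression <- function(expr) {
  stopifnot(nrow(expr) > 0L)
  expr <- expr[order(expr$gene_id, -expr$ne_T, expr$transcript_id), ]
  top <- expr[!duplicated(expr$gene_id), ]
  data.frame(gene_id = top$gene_id, ne = top$ne_T,
             top_transcript = top$transcript_id,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expressed-gene counts across presence thresholds
#'
#' For each log2 threshold `t`, counts genes with `log2(ne) >= t`. Genes
#' with `ne = 0` are never counted (their log-ratio is undefined). Counts
#' are non-decreasing as the threshold decreases; the default floor of
#' -15 log2 units (1/32768 of the reference) is the presence floor used
#' for protein-coding calls.
#'
#' @param gene_ne named numeric vector of gene-level `ne` values.
#' @param log2_thresholds numeric thresholds, any order.
#' @return data.frame `log2_threshold`, `n_genes`, sorted descending.
#' @export
expression_curve <- function(gene_ne,
                             log2_thresholds = seq(0, -15, by = -1)) {
  stopifnot(all(is.finite(log2_thresholds)))
  lt <- sort(log2_thresholds, decreasing = TRUE)
  pos <- gene_ne[gene_ne > 0]
  data.frame(
    log2_threshold = lt,
    n_genes = vapply(lt, function(t) sum(log2(pos) >= t), integer(1))
  )
}
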