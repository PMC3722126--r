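#' Coverage islands in a restricted genomic space
#'
#' A coverage island is a maximal run of consecutive base positions with
#' read depth >= 1. Depth is computed from full read spans; a single
#' uncovered base breaks an island. Only runs of at least `min_span`
#' positions are kept.
#'
#' @param reads `GRanges` of reads, already restricted to one sample,
#'   one preparation and matched to the strand of the space analysed.
#' @param min_span minimum island length in nt.
#' @param within optional `GRanges`; reads are clipped to this space
#'   before depth is computed, so islands never extend outside it.
#' @return unstranded `GRanges` of islands (strand is reattached by the
#'   callers, which work per gene strand).
#' @export
coverage_islands <- function(reads, min_span, within = NULL) {
  g <- GenomicRanges::granges(reads)
  if (!is.null(within)) {
    g <- GenomicRanges::intersect(g, GenomicRanges::granges(within),
                                  ignore.strand = TRUE)
  }
  if (length(g) == 0L) return(GenomicRanges::GRanges())
  cov <- GenomicRanges::coverage(g)
  isl <- methods::as(IRanges::slice(cov, lower = 1L, rangesOnly = TRUE),
                     "GRanges")
  isl[BiocGenerics::width(isl) >= min_span]
}

# shared engine for the long and short detectors
detect_intronic_regions <- function(reads, intronic_space, ref_density,
                                    min_span, min_rel_abundance,
                                    min_read_length = NULL,
                                    region_class = c("long", "short")) {
  region_class <- match.arg(region_class)
  stopifnot(is.data.frame(ref_density),
            all(c("sample_id", "prep", "density") %in% names(ref_density)))
  if (any(ref_density$density <= 0)) {
    stop("reference read density must be positive in every read set",
         call. = FALSE)
  }
  if (!is.null(min_read_length)) {
    reads <- reads[reads$read_length >= min_read_length]
  }
  key <- paste(reads$sample_id, reads$prep)
  accepted <- list()
  for (k in unique(key)) {
    rs <- reads[key == k]
    dens_row <- ref_density[paste(ref_density$sample_id,
                                  ref_density$prep) == k, ]
    if (nrow(dens_row) == 0L) {
      stop("no reference density supplied for read set '", k, "'",
           call. = FALSE)
    }
    dens <- dens_row$density[1]
    for (s in c("+", "-")) {
      space_s <- intronic_space[BiocGenerics::strand(intronic_space) == s]
      rs_s <- rs[BiocGenerics::strand(rs) == s]
      if (length(space_s) == 0L || length(rs_s) == 0L) next
      isl <- coverage_islands(rs_s, min_span, within = space_s)
      if (length(isl) == 0L) next
      BiocGenerics::strand(isl) <- s
      isl$region_count <- GenomicRanges::countOverlaps(isl, rs_s,
                                                       ignore.strand = FALSE)
      isl$rel_abundance <-
        (isl$region_count / BiocGenerics::width(isl)) / dens
      isl <- isl[isl$rel_abundance >= min_rel_abundance]
      if (length(isl) == 0L) next
      isl$sample_id <- rs_s$sample_id[1]
      accepted[[length(accepted) + 1L]] <- isl
    }
  }
  if (length(accepted) == 0L) {
    out <- GenomicRanges::GRanges()
    out$region_class <- character(0); out$span <- integer(0)
    out$rel_abundance <- numeric(0); out$supporting_samples <- character(0)
    return(out)
  }
  all <- do.call(c, accepted)
  # a region is accepted if at least one sample showed evidence for it:
  # union across samples/preparations, merging overlapping islands
  merged <- GenomicRanges::reduce(all, ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(merged, all, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  merged$region_class <- region_class
  merged$span <- BiocGenerics::width(merged)
  merged$rel_abundance <- vapply(seq_along(merged), function(i)
    max(all$rel_abundance[sh[qh == i]]), numeric(1))
  merged$supporting_samples <- vapply(seq_along(merged), function(i)
    paste(sort(unique(all$sample_id[sh[qh == i]])), collapse = ","),
    character(1))
  BiocGenerics::sort(merged, ignore.strand = TRUE)
}

#' Novel long intronic transcripts
#'
#' Scans the long-RNA read sets (total and rRNA-depleted evaluated
#' separately) for coverage islands inside the bona fide intronic space
#' that span at least `min_span` consecutive covered nucleotides and whose
#' per-nucleotide read density reaches `min_rel_abundance` (default
#' 1:1024, i.e. within 10 PCR cycles) of the long reference transcript's
#' density. A region is accepted when at least one read set shows
#' evidence for it; accepted islands overlapping on the same strand are
#' merged across samples and preparations.
#'
#' @param reads `GRanges` of long-prep reads across samples (columns
#'   `sample_id`, `prep`, `read_length`).
#' @param intronic_space stranded `GRanges` from [derive_intronic_space()].
#' @param ref_density data.frame `sample_id`, `prep`, `density`: the
#'   reference transcript's reads-per-nucleotide in each read set
#'   (`c_ref / L_ref`).
#' @param min_span minimum island span, nt.
#' @param min_rel_abundance inclusive density threshold relative to the
#'   reference.
#' @return `GRanges` of novel regions with `region_class`, `span`,
#'   `rel_abundance` (best supporting read set) and `supporting_samples`.
#' @export
detect_long_intronic <- function(reads, intronic_space, ref_density,
                                 min_span = 100L,
                                 min_rel_abundance = 1 / 1024) {
  stopifnot(all(reads$prep %in% c("long_total", "long_depleted")))
  detect_intronic_regions(reads, intronic_space, ref_density,
                          min_span, min_rel_abundance,
                          region_class = "long")
}

#' Novel short intronic transcripts
#'
#' Same island logic as [detect_long_intronic()] for the short-RNA read
#' sets: only reads of at least `min_read_length` (default 30 nt)
#' contribute, islands must span at least `min_span` nt (default 30) and
#' reach `min_rel_abundance` (default 1:64, within 6 PCR cycles) of the
#' short reference (SNORD44 analog) density. The threshold is inclusive.
#'
#' @inheritParams detect_long_intronic
#' @param min_read_length minimum contributing read length, nt.
#' @return `GRanges` as for [detect_long_intronic()].
#' @export
detect_short_intronic <- function(reads, intronic_space, ref_density,
                                  min_read_length = 30L,
                                  min_span = 30L,
                                  min_rel_abundance = 1 / 64) {
  stopifnot(all(reads$prep == "short"))
  detect_intronic_regions(reads, intronic_space, ref_density,
                          min_span, min_rel_abundance,
                          min_read_length = min_read_length,
                          region_class = "short")
}

#' Overlap between long and short novel-region collections
#'
#' Counts long regions that overlap at least one short region by >= 1 nt
#' on the same strand.
#'
#' @param long_set,short_set `GRanges` from the detectors.
#' @return integer count.
#' @export
long_short_overlap <- function(long_set, short_set) {
  sum(GenomicRanges::countOverlaps(long_set, short_set,
                                   ignore.strand = FALSE) > 0L)
}

#' Write novel regions as BED6+
#'
#' Columns: chrom, start, end, region id, best relative abundance,
#' strand, supporting samples, class.
#'
#' @param regions `GRanges` from the detectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_novel_regions <- function(regions, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(regions)),
    start = BiocGenerics::start(regions) - 1L,
    end = BiocGenerics::end(regions),
    region_id = paste0(regions$region_class, "_",
                       seq_len(length(regions))),
    rel_abundance = signif(regions$rel_abundance, 6),
    strand = as.character(BiocGenerics::strand(regions)),
    supporting_samples = regions$supporting_samples,
    class = regions$region_class
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
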