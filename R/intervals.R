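#' Strand-aware interval subtraction
#'
#' Removes from `minuend` every base position covered by a qualifying
#' `subtrahend` interval. Which subtrahend intervals qualify depends on
#' `strand_mode`:
#'
#' * `"same_strand"`: only subtrahend intervals on the same strand as the
#'   minuend interval (unstranded `*` subtrahend intervals qualify for both).
#' * `"both_strands"`: every subtrahend interval qualifies regardless of
#'   strand; minuend strands are preserved on the output.
#' * `"ignore_strand"`: strand is dropped entirely; the result is unstranded.
#'
#' @param minuend,subtrahend `GRanges`.
#' @param strand_mode one of `"same_strand"`, `"both_strands"`,
#'   `"ignore_strand"`.
#' @return A sorted, non-overlapping `GRanges` covering exactly the base
#'   positions of `minuend` not covered by any qualifying subtrahend
#'   interval. Metadata columns are not propagated.
#' @export
subtract_intervals <- function(minuend, subtrahend,
                               strand_mode = c("same_strand", "both_strands",
                                               "ignore_strand")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(methods::is(minuend, "GRanges"), methods::is(subtrahend, "GRanges"))
  if (length(minuend) == 0L) {
    return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(minuend)))
  }
  minuend <- GenomicRanges::granges(minuend)
  subtrahend <- GenomicRanges::granges(subtrahend)
  if (strand_mode == "ignore_strand") {
    BiocGenerics::strand(minuend) <- "*"
    BiocGenerics::strand(subtrahend) <- "*"
  }
  out <- lapply(unique(as.character(BiocGenerics::strand(minuend))), function(s) {
    m <- minuend[BiocGenerics::strand(minuend) == s]
    sub <- switch(strand_mode,
      same_strand = subtrahend[as.character(BiocGenerics::strand(subtrahend)) %in% c(s, "*")],
      both_strands = subtrahend,
      ignore_strand = subtrahend
    )
    r <- GenomicRanges::setdiff(m, sub, ignore.strand = TRUE)
    BiocGenerics::strand(r) <- s
    r
  })
  BiocGenerics::sort(do.call(c, out), ignore.strand = TRUE)
}

#' Total genomic span of a stranded interval set
#'
#' Sum of widths after merging overlapping intervals (per strand).
#'
#' @param x `GRanges`.
#' @param ignore_strand merge across strands before summing.
#' @return integer number of base positions.
#' @export
interval_span <- function(x, ignore_strand = FALSE) {
  sum(BiocGenerics::width(GenomicRanges::reduce(x, ignore.strand = ignore_strand)))
}

# validity check shared by loaders: every range inside its chromosome
assert_within_bounds <- function(gr, chrom_sizes, what = "feature") {
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  unknown <- setdiff(unique(chr), names(chrom_sizes))
  if (length(unknown) > 0L) {
    stop(sprintf("%s on unknown chromosome(s): %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  bad <- BiocGenerics::start(gr) < 1L |
    BiocGenerics::end(gr) > unname(chrom_sizes[chr])
  if (any(bad)) {
    stop(sprintf("%d %s(s) extend outside chromosome bounds (first: %s:%d-%d)",
                 sum(bad), what, chr[which(bad)[1]],
                 BiocGenerics::start(gr)[which(bad)[1]],
                 BiocGenerics::end(gr)[which(bad)[1]]), call. = FALSE)
  }
  invisible(gr)
}

# Seqinfo from a named chromosome-length vector
make_seqinfo <- function(chrom_sizes) {
  GenomeInfoDb::Seqinfo(seqnames = names(chrom_sizes),
                        seqlengths = unname(as.integer(chrom_sizes)))
}
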