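#' Sequencing preparations
#'
#' The three library preparations the pipeline distinguishes: long RNA
#' from total RNA (`long_total`), long RNA after rRNA depletion
#' (`long_depleted`), and short RNA (`short`). Long reads are >= 40 nt,
#' short reads < 40 nt.
#' @export
PREPS <- c("long_total", "long_depleted", "short")

prep_length_ok <- function(width, prep) {
  if (prep == "short") width < 40L else width >= 40L
}

#' Load uniquely-mapped stranded reads from BED6
#'
#' Reads are expected to be uniquely mapped with strandedness preserved;
#' the caller asserts uniqueness (multi-mapper removal happens upstream,
#' at mapping time). Reads violating the preparation's length class
#' (`short` < 40 nt, long preparations >= 40 nt) are rejected and tallied.
#'
#' @param bed_path BED6 file; the strand column is mandatory.
#' @param sample_id sample label.
#' @param prep one of [PREPS].
#' @return `GRanges` with metadata columns `sample_id`, `prep`,
#'   `read_length`; the number of length-rejected reads is available as
#'   `S4Vectors::metadata(x)$n_rejected`.
#' @export
load_reads <- function(bed_path, sample_id, prep = PREPS) {
  prep <- match.arg(prep)
  stopifnot(file.exists(bed_path))
  validate_bed_lines(bed_path)
  gr <- rtracklayer::import(bed_path, format = "bed")
  if (length(gr) == 0L) {
    warning("no reads in ", bed_path)
  }
  mapped_read_set(gr, sample_id, prep)
}

#' Assemble a mapped read set from in-memory intervals
#'
#' Applies the same per-preparation length-class filter as [load_reads()].
#'
#' @param gr `GRanges` of read intervals (strand required).
#' @param sample_id,prep as in [load_reads()].
#' @return `GRanges` with `sample_id`, `prep`, `read_length` columns.
#' @export
mapped_read_set <- function(gr, sample_id, prep = PREPS) {
  prep <- match.arg(prep)
  if (any(as.character(BiocGenerics::strand(gr)) == "*")) {
    stop("reads must be stranded", call. = FALSE)
  }
  ok <- prep_length_ok(BiocGenerics::width(gr), prep)
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) {
    warning(sprintf("%d read(s) rejected: length outside the %s class",
                    n_rejected, prep))
  }
  gr <- gr[ok]
  out <- GenomicRanges::granges(gr)
  out$sample_id <- if (length(out)) sample_id else character(0)
  out$prep <- if (length(out)) prep else character(0)
  out$read_length <- BiocGenerics::width(out)
  S4Vectors::metadata(out)$n_rejected <- n_rejected
  out
}

#' Write a read set as BED6
#'
#' @param reads `GRanges` read set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  g <- GenomicRanges::granges(reads)
  g$name <- paste0("read", seq_along(g))
  g$score <- 0L
  rtracklayer::export(g, path, format = "bed")
  invisible(path)
}
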