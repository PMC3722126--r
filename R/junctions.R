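#' Combinatorial exon-exon junction enumeration
#'
#' For each gene, enumerates every ordered pair of non-overlapping exons
#' (donor before acceptor in transcription order: genomic order on the
#' `+` strand, reversed on `-`). Identical exon coordinates across
#' isoforms are collapsed before pairing; pairs of overlapping exons are
#' skipped, not trimmed. The junction sequence is the last `flank` nt of
#' the donor followed by the first `flank` nt of the acceptor, read
#' 5'-to-3' on the transcript strand (minus-strand sequences are
#' reverse-complemented). Exons shorter than `flank` contribute their
#' full length and the junction is flagged truncated.
#'
#' @param ann an [AnnotationSet].
#' @param genome named `DNAStringSet` (one entry per chromosome).
#' @param flank flank length in nt; `read_length - 1` guarantees any read
#'   crossing the junction by >= 1 nt fits on the junction sequence.
#' @return list with `junctions` (data.frame `junction_id`, `gene_id`,
#'   `donor`, `acceptor`, `truncated`), `sequences` (named
#'   `DNAStringSet`), and `flank`.
#' @export
enumerate_junctions <- function(ann, genome, flank = 49L) {
  stopifnot(methods::is(ann, "AnnotationSet"),
            methods::is(genome, "DNAStringSet"))
  missing_chr <- setdiff(names(ann$chrom_sizes), names(genome))
  if (length(missing_chr) > 0L) {
    stop("genome sequence missing for: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  ex <- ann$exons
  rows <- list(); seqs <- character(0)
  for (g in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == g]
    key <- paste(GenomeInfoDb::seqnames(e), BiocGenerics::start(e),
                 BiocGenerics::end(e), BiocGenerics::strand(e))
    e <- e[!duplicated(key)]
    if (length(e) < 2L) next
    minus <- as.character(BiocGenerics::strand(e))[1] == "-"
    e <- e[order(BiocGenerics::start(e))]
    n <- length(e)
    chr <- as.character(GenomeInfoDb::seqnames(e))[1]
    chrseq <- genome[[chr]]
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        # genomic order: e[i] before e[j]; skip overlapping pairs
        if (BiocGenerics::start(e[j]) <= BiocGenerics::end(e[i])) next
        if (minus) { donor <- e[j]; acceptor <- e[i] } else {
          donor <- e[i]; acceptor <- e[j]
        }
        wd <- min(flank, BiocGenerics::width(donor))
        wa <- min(flank, BiocGenerics::width(acceptor))
        if (minus) {
          # on the minus strand the donor's transcript-final flank lies at
          # its genomic start side, the acceptor's head at its genomic end
          # side; revcomp(acceptor_head ++ donor_tail) reads 5'-3' on the
          # transcript
          don_piece <- Biostrings::subseq(chrseq,
            BiocGenerics::start(donor),
            BiocGenerics::start(donor) + wd - 1L)
          acc_piece <- Biostrings::subseq(chrseq,
            BiocGenerics::end(acceptor) - wa + 1L,
            BiocGenerics::end(acceptor))
          jseq <- as.character(Biostrings::reverseComplement(
            Biostrings::xscat(acc_piece, don_piece)))
        } else {
          don_piece <- Biostrings::subseq(chrseq,
            BiocGenerics::end(donor) - wd + 1L,
            BiocGenerics::end(donor))
          acc_piece <- Biostrings::subseq(chrseq,
            BiocGenerics::start(acceptor),
            BiocGenerics::start(acceptor) + wa - 1L)
          jseq <- as.character(Biostrings::xscat(don_piece, acc_piece))
        }
        did <- sprintf("%s:%d-%d", chr, BiocGenerics::start(donor),
                       BiocGenerics::end(donor))
        aid <- sprintf("%s:%d-%d", chr, BiocGenerics::start(acceptor),
                       BiocGenerics::end(acceptor))
        rows[[length(rows) + 1L]] <- data.frame(
          junction_id = paste0(g, "|", did, "|", aid),
          gene_id = g, donor = did, acceptor = aid,
          truncated = wd < flank || wa < flank,
          stringsAsFactors = FALSE)
        seqs <- c(seqs, jseq)
      }
    }
  }
  if (length(rows) == 0L) {
    return(list(junctions = data.frame(junction_id = character(0),
                                       gene_id = character(0),
                                       donor = character(0),
                                       acceptor = character(0),
                                       truncated = logical(0)),
                sequences = Biostrings::DNAStringSet(), flank = flank))
  }
  jdf <- do.call(rbind, rows)
  sset <- Biostrings::DNAStringSet(seqs)
  names(sset) <- jdf$junction_id
  list(junctions = jdf, sequences = sset, flank = flank)
}

#' Ungapped mapping of reads against a sequence set
#'
#' Aligns each read against every target sequence (both orientations)
#' allowing up to `max_mismatches` substitutions and no indels; `N`
#' positions never match. A read hitting exactly one target location is
#' reported mapped; reads hitting more than one distinct location
#' (whether on the same or different targets) are discarded as
#' multi-mappers; the rest are unmapped.
#'
#' @param orphans named `DNAStringSet` of reads.
#' @param targets named `DNAStringSet` (junction catalog, genome, or any
#'   reference sequence set such as an HLA allele collection).
#' @param max_mismatches maximum substitutions per read.
#' @return data.frame, one row per read: `read_id`, `status`
#'   (`mapped`/`multi`/`unmapped`), `target`, `offset` (1-based on the
#'   target's forward strand), `target_strand`, `mismatches` (NA unless
#'   mapped).
#' @export
map_reads_to_sequences <- function(orphans, targets, max_mismatches = 2L) {
  stopifnot(length(targets) > 0L)
  if (is.null(names(orphans))) names(orphans) <- paste0("read", seq_along(orphans))
  res <- lapply(seq_along(orphans), function(i) {
    pat <- orphans[[i]]
    hits <- list()
    for (orient in c("+", "-")) {
      p <- if (orient == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::vmatchPattern(p, targets,
                                     max.mismatch = max_mismatches,
                                     fixed = TRUE)
      for (t in which(lengths(m) > 0L)) {
        st <- BiocGenerics::start(m[[t]])
        for (s in st) {
          if (s < 1L || s + length(p) - 1L > length(targets[[t]])) next
          nmm <- Biostrings::neditStartingAt(p, targets[[t]], starting.at = s)
          hits[[length(hits) + 1L]] <- list(target = names(targets)[t],
                                            offset = s, strand = orient,
                                            mismatches = nmm)
        }
      }
    }
    if (length(hits) == 0L) {
      return(data.frame(read_id = names(orphans)[i], status = "unmapped",
                        target = NA_character_, offset = NA_integer_,
                        target_strand = NA_character_,
                        mismatches = NA_integer_, stringsAsFactors = FALSE))
    }
    loc <- unique(vapply(hits, function(h)
      paste(h$target, h$offset, h$strand), character(1)))
    if (length(loc) > 1L) {
      return(data.frame(read_id = names(orphans)[i], status = "multi",
                        target = NA_character_, offset = NA_integer_,
                        target_strand = NA_character_,
                        mismatches = NA_integer_, stringsAsFactors = FALSE))
    }
    h <- hits[[1]]
    data.frame(read_id = names(orphans)[i], status = "mapped",
               target = h$target, offset = h$offset,
               target_strand = h$strand, mismatches = h$mismatches,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Lenient re-mapping of orphan reads
#'
#' Re-maps reads that failed default mapping (<= 2 mismatches) with a
#' relaxed substitution allowance (default 6), against the genome. The
#' rescued set is monotonically non-decreasing in `max_mismatches`.
#'
#' @param orphans named `DNAStringSet`.
#' @param genome named `DNAStringSet`.
#' @param max_mismatches relaxed substitution allowance.
#' @return list: `report` (per-read data.frame as in
#'   [map_reads_to_sequences()]), `n_rescued` (uniquely mapped reads),
#'   `fraction_rescued`.
#' @export
lenient_remap <- function(orphans, genome, max_mismatches = 6L) {
  report <- map_reads_to_sequences(orphans, genome, max_mismatches)
  n <- sum(report$status == "mapped")
  list(report = report, n_rescued = n,
       fraction_rescued = if (length(orphans)) n / length(orphans) else 0)
}

#' Read orphan reads from FASTA/FASTQ
#'
#' @param path FASTA or FASTQ file (format inferred from extension).
#' @return named `DNAStringSet`.
#' @export
read_orphans <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}
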