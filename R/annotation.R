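#' Annotation catalog for the pipeline
#'
#' An `AnnotationSet` bundles every genomic feature track the pipeline
#' consumes: protein-coding and non-coding transcript models (exons and
#' UTRs), repeat elements with RepeatMasker-style `class.family` labels,
#' miRNA precursors with optional 5p/3p mature-arm coordinates, and
#' interval tracks for pseudogenes, lincRNAs and rRNA/snoRNA loci.
#'
#' All coordinates are held as `GRanges` (1-based, closed); BED input
#' (0-based, half-open) and GTF input (1-based, inclusive) are converted at
#' the I/O boundary by `rtracklayer`, so a GTF exon `start=101,end=200`
#' and a BED exon `100 200` denote the same 100 bases.
#'
#' @param exons `GRanges` with metadata columns `transcript_id`, `gene_id`,
#'   `biotype`.
#' @param utr5,utr3 `GRanges` with `transcript_id`, `gene_id` (may be empty).
#' @param repeats `GRanges` with a `family` column; records with identical
#'   coordinates but different families are distinct.
#' @param mirnas `GRanges` of precursor spans with a `name` column.
#' @param mirna_mature `GRanges` of mature arms with `name` (precursor
#'   name) and `arm` (`"5p"` or `"3p"`); each arm must lie within its
#'   precursor, on the precursor strand.
#' @param pseudogenes,lincrnas,rrnas_snornas `GRanges` interval tracks.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return An object of class `AnnotationSet`: a list with the validated
#'   tracks plus a `transcripts` data.frame (`transcript_id`, `gene_id`,
#'   `biotype`, `length` = summed exon widths).
#' @export
AnnotationSet <- function(exons,
                          utr5 = GenomicRanges::GRanges(),
                          utr3 = GenomicRanges::GRanges(),
                          repeats = GenomicRanges::GRanges(family = character(0)),
                          mirnas = GenomicRanges::GRanges(name = character(0)),
                          mirna_mature = GenomicRanges::GRanges(name = character(0), arm = character(0)),
                          pseudogenes = GenomicRanges::GRanges(),
                          lincrnas = GenomicRanges::GRanges(),
                          rrnas_snornas = GenomicRanges::GRanges(),
                          chrom_sizes) {
  stopifnot(methods::is(exons, "GRanges"), length(exons) > 0L,
            !is.null(exons$transcript_id), !is.null(exons$gene_id),
            !is.null(exons$biotype))
  chrom_sizes <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  si <- make_seqinfo(chrom_sizes)

  tracks <- list(exons = exons, utr5 = utr5, utr3 = utr3, repeats = repeats,
                 mirnas = mirnas, mirna_mature = mirna_mature,
                 pseudogenes = pseudogenes, lincrnas = lincrnas,
                 rrnas_snornas = rrnas_snornas)
  tracks <- lapply(names(tracks), function(nm) {
    gr <- tracks[[nm]]
    if (length(gr) > 0L) {
      assert_within_bounds(gr, chrom_sizes, what = nm)
      if (any(as.character(BiocGenerics::strand(gr)) == "*")) {
        stop(sprintf("unstranded interval in track '%s'", nm), call. = FALSE)
      }
    }
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqinfo(gr) <- si
    gr
  })
  names(tracks) <- c("exons", "utr5", "utr3", "repeats", "mirnas",
                     "mirna_mature", "pseudogenes", "lincrnas", "rrnas_snornas")

  if (length(tracks$repeats) > 0L && (is.null(tracks$repeats$family) ||
      any(!nzchar(tracks$repeats$family)))) {
    stop("every repeat element needs a non-empty family label", call. = FALSE)
  }
  if (length(tracks$mirna_mature) > 0L) {
    hit <- GenomicRanges::findOverlaps(tracks$mirna_mature, tracks$mirnas,
                                       type = "within")
    ok <- tapply(tracks$mirnas$name[S4Vectors::subjectHits(hit)] ==
                   tracks$mirna_mature$name[S4Vectors::queryHits(hit)],
                 S4Vectors::queryHits(hit), any)
    covered <- seq_along(tracks$mirna_mature) %in%
      as.integer(names(ok))[unlist(ok)]
    if (!all(covered)) {
      stop("mature miRNA arm(s) not contained in their precursor", call. = FALSE)
    }
  }

  ex <- tracks$exons
  # no overlapping exons within a transcript (one vectorized self-overlap)
  self <- GenomicRanges::findOverlaps(ex, drop.self = TRUE,
                                      drop.redundant = TRUE,
                                      ignore.strand = FALSE)
  if (any(ex$transcript_id[S4Vectors::queryHits(self)] ==
            ex$transcript_id[S4Vectors::subjectHits(self)])) {
    stop("overlapping exons within a transcript", call. = FALSE)
  }
  w <- tapply(BiocGenerics::width(ex), ex$transcript_id, sum)
  first <- !duplicated(ex$transcript_id)
  transcripts <- data.frame(
    transcript_id = ex$transcript_id[first],
    gene_id = ex$gene_id[first],
    biotype = ex$biotype[first],
    length = as.integer(w[ex$transcript_id[first]]),
    stringsAsFactors = FALSE
  )
  transcripts <- transcripts[order(transcripts$transcript_id), ]
  rownames(transcripts) <- NULL

  structure(c(tracks, list(chrom_sizes = chrom_sizes, seqinfo = si,
                           transcripts = transcripts)),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:",
      nrow(x$transcripts), "transcripts /",
      length(unique(x$transcripts$gene_id)), "genes;",
      length(x$repeats), "repeats;",
      length(x$mirnas), "miRNA precursors;",
      length(x$pseudogenes), "pseudogenes;",
      length(x$lincrnas), "lincRNAs;",
      length(x$rrnas_snornas), "rRNA/snoRNA loci;",
      length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

# light pre-validation so parse errors can name file and line
validate_gtf_lines <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) {
      stop(sprintf("%s line %d: expected 9 tab-separated fields, got %d",
                   path, i, length(f)), call. = FALSE)
    }
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || e < s || s < 1L) {
      stop(sprintf("%s line %d: invalid coordinates '%s'-'%s'",
                   path, i, f[4], f[5]), call. = FALSE)
    }
    if (!f[7] %in% c("+", "-")) {
      stop(sprintf("%s line %d: strand must be + or -, got '%s'",
                   path, i, f[7]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

validate_bed_lines <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) {
      stop(sprintf("%s line %d: BED6 needs 6 fields (strand column required), got %d",
                   path, i, length(f)), call. = FALSE)
    }
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || e <= s || s < 0L) {
      stop(sprintf("%s line %d: invalid half-open interval '%s'-'%s'",
                   path, i, f[2], f[3]), call. = FALSE)
    }
    if (!f[6] %in% c("+", "-")) {
      stop(sprintf("%s line %d: strand must be + or -, got '%s'",
                   path, i, f[6]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Load an annotation catalog from GTF and BED tracks
#'
#' Reads transcript models from a 9-column GTF (feature types `exon`,
#' `five_prime_utr`/`5UTR`, `three_prime_utr`/`3UTR`; attributes
#' `gene_id`, `transcript_id` and optionally `gene_biotype`) and auxiliary
#' BED6 tracks. The BED name column carries the repeat family, miRNA
#' precursor name (mature-arm track names are `"<precursor>|5p"` /
#' `"<precursor>|3p"`), or locus name.
#'
#' @param gtf_path path to the GTF file.
#' @param chrom_sizes_path two-column whitespace-separated text
#'   (`chrom  length`).
#' @param aux_tracks named list of BED6 paths; recognised names:
#'   `repeats`, `mirnas`, `mirna_mature`, `pseudogenes`, `lincrnas`,
#'   `rrnas_snornas`. Missing entries yield empty tracks.
#' @return An [AnnotationSet].
#' @export
load_annotation <- function(gtf_path, chrom_sizes_path, aux_tracks = list()) {
  stopifnot(file.exists(gtf_path), file.exists(chrom_sizes_path))
  validate_gtf_lines(gtf_path)
  cs <- utils::read.table(chrom_sizes_path, header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  chrom_sizes <- stats::setNames(as.integer(cs$length), cs$chrom)

  gtf <- rtracklayer::import(gtf_path, format = "gtf")
  type <- tolower(as.character(gtf$type))
  pick <- function(types) {
    gr <- gtf[type %in% types]
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      transcript_id = gr$transcript_id,
      gene_id = gr$gene_id,
      biotype = if (!is.null(gr$gene_biotype)) gr$gene_biotype
                else rep("protein_coding", length(gr))
    )
    gr
  }
  exons <- pick("exon")
  if (length(exons) == 0L) stop("no exon features in ", gtf_path, call. = FALSE)
  exons <- BiocGenerics::sort(exons, ignore.strand = TRUE)
  utr5 <- pick(c("five_prime_utr", "5utr"))
  utr3 <- pick(c("three_prime_utr", "3utr"))

  read_bed <- function(path) {
    if (is.null(path)) return(GenomicRanges::GRanges(name = character(0)))
    validate_bed_lines(path)
    rtracklayer::import(path, format = "bed")
  }
  rep_gr <- read_bed(aux_tracks$repeats)
  if (length(rep_gr) > 0L) rep_gr$family <- rep_gr$name
  else rep_gr <- GenomicRanges::GRanges(family = character(0))
  S4Vectors::mcols(rep_gr) <- S4Vectors::mcols(rep_gr)["family"]

  mm <- read_bed(aux_tracks$mirna_mature)
  if (length(mm) > 0L) {
    parts <- strsplit(mm$name, "|", fixed = TRUE)
    mm$name <- vapply(parts, `[`, "", 1L)
    mm$arm <- vapply(parts, `[`, "", 2L)
    if (any(!mm$arm %in% c("5p", "3p"))) {
      stop("mirna_mature names must be '<precursor>|5p' or '<precursor>|3p'",
           call. = FALSE)
    }
  } else {
    mm <- GenomicRanges::GRanges(name = character(0), arm = character(0))
  }

  AnnotationSet(
    exons = exons, utr5 = utr5, utr3 = utr3,
    repeats = rep_gr,
    mirnas = read_bed(aux_tracks$mirnas),
    mirna_mature = mm,
    pseudogenes = read_bed(aux_tracks$pseudogenes),
    lincrnas = read_bed(aux_tracks$lincrnas),
    rrnas_snornas = read_bed(aux_tracks$rrnas_snornas),
    chrom_sizes = chrom_sizes
  )
}

#' Write an annotation catalog back to GTF/BED
#'
#' Inverse of [load_annotation()]: coordinates round-trip exactly.
#'
#' @param ann an [AnnotationSet].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_annotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gtf_path <- file.path(dir, "annotation.gtf")
  feat <- function(gr, type) {
    if (length(gr) == 0L) return(NULL)
    g <- GenomicRanges::granges(gr)
    g$source <- "plateletseq"; g$type <- type
    g$gene_id <- gr$gene_id; g$transcript_id <- gr$transcript_id
    g$gene_biotype <- gr$biotype
    g
  }
  gtf <- c(feat(ann$exons, "exon"),
           feat(ann$utr5, "five_prime_utr"),
           feat(ann$utr3, "three_prime_utr"))
  rtracklayer::export(gtf, gtf_path, format = "gtf")

  paths <- list(gtf = gtf_path)
  bed_out <- function(gr, names, file) {
    if (length(gr) == 0L) return(NULL)
    g <- GenomicRanges::granges(gr)
    g$name <- names
    g$score <- 0L
    p <- file.path(dir, file)
    rtracklayer::export(g, p, format = "bed")
    p
  }
  nm_or <- function(gr) if (!is.null(gr$name)) gr$name else
    paste0("feat", seq_along(gr))
  paths$repeats <- bed_out(ann$repeats, ann$repeats$family, "repeats.bed")
  paths$mirnas <- bed_out(ann$mirnas, ann$mirnas$name, "mirnas.bed")
  paths$mirna_mature <- bed_out(ann$mirna_mature,
                                paste(ann$mirna_mature$name,
                                      ann$mirna_mature$arm, sep = "|"),
                                "mirna_mature.bed")
  paths$pseudogenes <- bed_out(ann$pseudogenes, nm_or(ann$pseudogenes),
                               "pseudogenes.bed")
  paths$lincrnas <- bed_out(ann$lincrnas, nm_or(ann$lincrnas), "lincrnas.bed")
  paths$rrnas_snornas <- bed_out(ann$rrnas_snornas, nm_or(ann$rrnas_snornas),
                                 "rrnas_snornas.bed")
  cs_path <- file.path(dir, "chrom.sizes")
  utils::write.table(data.frame(names(ann$chrom_sizes),
                                unname(ann$chrom_sizes)),
                     cs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$chrom_sizes <- cs_path
  invisible(paths)
}

#' Derive bona fide intronic space
#'
#' For every protein-coding gene, takes the unspliced gene span (minimum
#' exon start to maximum exon end over all isoforms) and subtracts, on the
#' same strand only, all annotated exons of any gene (coding or
#' non-coding), repeat elements, rRNA/snoRNA loci, miRNA precursors and
#' lincRNAs. Subtraction is global: a feature belonging to one gene
#' removes intronic space from any overlapping gene on the same strand.
#' Antisense instances of these categories are deliberately retained.
#'
#' @param ann an [AnnotationSet].
#' @return `GRanges` of intronic intervals carrying each gene's strand,
#'   with a `gene_id` metadata column. Intronless genes contribute nothing.
#' @export
derive_intronic_space <- function(ann) {
  stopifnot(methods::is(ann, "AnnotationSet"))
  pc <- ann$transcripts[ann$transcripts$biotype == "protein_coding", ]
  if (nrow(pc) == 0L) stop("no protein-coding transcripts", call. = FALSE)
  ex <- ann$exons[ann$exons$gene_id %in% pc$gene_id]
  spans <- unlist(range(GenomicRanges::split(GenomicRanges::granges(ex),
                                             ex$gene_id)))
  spans$gene_id <- names(spans)
  names(spans) <- NULL

  subtrahend <- c(GenomicRanges::granges(ann$exons),
                  GenomicRanges::granges(ann$repeats),
                  GenomicRanges::granges(ann$rrnas_snornas),
                  GenomicRanges::granges(ann$mirnas),
                  GenomicRanges::granges(ann$lincrnas))

  # subtract globally per strand, then clip the freed space back to each
  # gene span; position-wise this equals a per-gene subtraction
  free <- subtract_intervals(spans, subtrahend, "same_strand")
  ov <- GenomicRanges::findOverlaps(spans, free, ignore.strand = FALSE)
  pieces <- GenomicRanges::pintersect(
    GenomicRanges::granges(spans)[S4Vectors::queryHits(ov)],
    free[S4Vectors::subjectHits(ov)])
  pieces$hit <- NULL
  pieces$gene_id <- spans$gene_id[S4Vectors::queryHits(ov)]
  BiocGenerics::sort(pieces, ignore.strand = TRUE)
}
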