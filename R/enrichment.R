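#' Sense/antisense enrichment of reads over an annotation category
#'
#' Enrichment is an observed/expected ratio. The expected fraction of
#' signal falling in a category is its genomic span divided by the
#' background span (by default the summed chromosome lengths). Two
#' observed fractions are computed:
#'
#' * span enrichment — category bases covered by >= 1 orientation-
#'   qualifying read, over all bases covered by >= 1 read anywhere
#'   (ignores read multiplicity);
#' * support enrichment — orientation-qualifying reads overlapping the
#'   category, over all reads (weights by read multiplicity).
#'
#' A read qualifies for a feature when its strand matches (sense) or
#' opposes (antisense) the feature's strand and the overlap covers at
#' least `min_overlap_frac` of the read's length (default 50%, which
#' suppresses edge artifacts at feature boundaries).
#'
#' @param reads `GRanges` read set (one sample/preparation).
#' @param category_intervals stranded `GRanges` of the category's loci.
#' @param orientation `"sense"` or `"antisense"`.
#' @param background_span background size in nt (>= category span).
#' @param min_overlap_frac minimum overlap as a fraction of read length.
#' @param category label carried into the result.
#' @param covered_all total bases covered by any read; computed from
#'   `reads` when `NULL` (callers scoring many categories against the
#'   same read set pass it in once).
#' @return one-row data.frame: `category`, `orientation`, `n_reads`,
#'   `covered_bases`, `category_span`, `span_enrichment`,
#'   `support_enrichment`.
#' @export
category_enrichment <- function(reads, category_intervals,
                                orientation = c("sense", "antisense"),
                                background_span,
                                min_overlap_frac = 0.5,
                                category = "category",
                                covered_all = NULL) {
  orientation <- match.arg(orientation)
  cat_span <- interval_span(category_intervals)
  if (cat_span == 0L) {
    stop("category '", category, "' has zero genomic span", call. = FALSE)
  }
  stopifnot(background_span >= cat_span)
  f <- cat_span / background_span

  target <- category_intervals
  if (orientation == "antisense") {
    target <- invert_strand(target)
  }
  ov <- GenomicRanges::findOverlaps(reads, target, ignore.strand = FALSE)
  if (length(ov) > 0L) {
    inter <- GenomicRanges::pintersect(reads[S4Vectors::queryHits(ov)],
                                       target[S4Vectors::subjectHits(ov)])
    frac_ok <- BiocGenerics::width(inter) >=
      min_overlap_frac * BiocGenerics::width(reads[S4Vectors::queryHits(ov)])
    qual_idx <- unique(S4Vectors::queryHits(ov)[frac_ok])
  } else {
    qual_idx <- integer(0)
  }
  qual <- reads[qual_idx]

  n_total <- length(reads)
  if (is.null(covered_all)) {
    covered_all <- interval_span(reads, ignore_strand = TRUE)
  }
  covered_cat <- if (length(qual) > 0L) {
    interval_span(GenomicRanges::intersect(
      GenomicRanges::granges(qual), GenomicRanges::granges(target),
      ignore.strand = TRUE))
  } else 0L

  span_e <- if (covered_all > 0L) (covered_cat / covered_all) / f else 0
  supp_e <- if (n_total > 0L) (length(qual) / n_total) / f else 0

  data.frame(category = category, orientation = orientation,
             n_reads = length(qual), covered_bases = covered_cat,
             category_span = cat_span,
             span_enrichment = span_e, support_enrichment = supp_e,
             stringsAsFactors = FALSE)
}

invert_strand <- function(gr) {
  s <- as.character(BiocGenerics::strand(gr))
  BiocGenerics::strand(gr) <- ifelse(s == "+", "-", ifelse(s == "-", "+", "*"))
  gr
}

#' Antisense enrichment over protein-coding exonic space
#'
#' Computes antisense enrichment of long-RNA reads over three region
#' classes of protein-coding transcripts: 5'UTRs, 3'UTRs, and full
#' exonic space. Each read set (sample x preparation) is evaluated
#' separately; the classes are not disjoint, so a read may contribute to
#' several rows.
#'
#' @param reads `GRanges` long-prep reads, possibly several samples and
#'   preparations (split internally on `sample_id`/`prep`).
#' @param ann an [AnnotationSet].
#' @param background_span background size in nt; defaults to the summed
#'   chromosome lengths.
#' @param orientation orientation to score (default antisense).
#' @param min_overlap_frac see [category_enrichment()].
#' @return data.frame, one row per read set x region class.
#' @export
antisense_exonic_enrichment <- function(reads, ann,
                                        background_span = sum(ann$chrom_sizes),
                                        orientation = "antisense",
                                        min_overlap_frac = 0.5) {
  pc_tx <- ann$transcripts$transcript_id[
    ann$transcripts$biotype == "protein_coding"]
  regions <- list(
    "5'UTR" = ann$utr5[ann$utr5$transcript_id %in% pc_tx],
    "3'UTR" = ann$utr3[ann$utr3$transcript_id %in% pc_tx],
    "exons" = ann$exons[ann$exons$transcript_id %in% pc_tx]
  )
  regions <- lapply(regions, function(g)
    GenomicRanges::reduce(GenomicRanges::granges(g), ignore.strand = FALSE))
  key <- paste(reads$sample_id, reads$prep, sep = "\r")
  out <- lapply(unique(key), function(k) {
    rs <- reads[key == k]
    covered_all <- interval_span(rs, ignore_strand = TRUE)
    rows <- lapply(names(regions), function(nm)
      category_enrichment(rs, regions[[nm]], orientation,
                          background_span, min_overlap_frac, category = nm,
                          covered_all = covered_all))
    df <- do.call(rbind, rows)
    df$sample_id <- rs$sample_id[1]
    df$prep <- rs$prep[1]
    df
  })
  do.call(rbind, out)
}

#' Per-family repeat-element enrichment
#'
#' Computes sense or antisense enrichment separately for every repeat
#' family present in the repeat track. Families with zero genomic span
#' are omitted. The result is sorted by span enrichment, descending; a
#' display cutoff (>= 1.5 by convention in reporting) can be applied by
#' the caller.
#'
#' @param reads `GRanges` read set (one sample/preparation).
#' @param repeats `GRanges` with a `family` column.
#' @param orientation `"sense"` or `"antisense"`.
#' @param background_span background size in nt.
#' @param min_overlap_frac see [category_enrichment()].
#' @return data.frame, one row per family, sorted by `span_enrichment`
#'   descending.
#' @export
repeat_family_enrichment <- function(reads, repeats,
                                     orientation = c("sense", "antisense"),
                                     background_span,
                                     min_overlap_frac = 0.5) {
  orientation <- match.arg(orientation)
  fams <- sort(unique(repeats$family))
  covered_all <- interval_span(reads, ignore_strand = TRUE)
  rows <- lapply(fams, function(fam) {
    gr <- repeats[repeats$family == fam]
    if (interval_span(gr) == 0L) return(NULL)
    category_enrichment(reads, gr, orientation, background_span,
                        min_overlap_frac, category = fam,
                        covered_all = covered_all)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span_enrichment, out$category), ]
  rownames(out) <- NULL
  out
}

# 5' end of a stranded read
five_prime_end <- function(reads) {
  ifelse(as.character(BiocGenerics::strand(reads)) == "+",
         BiocGenerics::start(reads), BiocGenerics::end(reads))
}

#' Antisense-miRNA locus detection
#'
#' Searches the short-RNA read sets for transcripts antisense to known
#' miRNA precursors. Per precursor, antisense reads with miRNA-typical
#' lengths (default 18-25 nt) are clustered by 5'-end proximity (reads
#' whose 5' ends lie within `max_shift` nt of the cluster seed belong to
#' one product). Clusters supported by at least `min_reads` reads are
#' reported; at most the top two clusters per precursor are kept,
#' mirroring a mature miRNA and its star product.
#'
#' @param short_reads `GRanges` short-prep reads (one read set).
#' @param mirnas `GRanges` precursors with a `name` column.
#' @param length_window inclusive read-length window, nt.
#' @param min_reads minimum reads per product.
#' @param max_shift maximum 5'-end shift within a product, nt.
#' @return data.frame, one row per product: `precursor`, `product`,
#'   `chrom`, `start`, `end`, `strand` (the product's strand, opposite
#'   the precursor), `n_reads`, `median_read_length`.
#' @export
detect_antisense_mirnas <- function(short_reads, mirnas,
                                    length_window = c(18L, 25L),
                                    min_reads = 5L, max_shift = 3L) {
  keep <- short_reads$read_length >= length_window[1] &
    short_reads$read_length <= length_window[2]
  reads <- short_reads[keep]
  out <- list()
  for (i in seq_along(mirnas)) {
    pre <- mirnas[i]
    anti <- reads[GenomicRanges::countOverlaps(
      reads, invert_strand(pre), ignore.strand = FALSE) > 0L]
    if (length(anti) < min_reads) next
    clusters <- cluster_by_five_prime(anti, max_shift)
    clusters <- clusters[vapply(clusters, length, integer(1)) >= min_reads]
    if (length(clusters) == 0L) next
    ord <- order(-vapply(clusters, length, integer(1)))
    clusters <- clusters[ord[seq_len(min(2L, length(clusters)))]]
    for (j in seq_along(clusters)) {
      cl <- anti[clusters[[j]]]
      out[[length(out) + 1L]] <- data.frame(
        precursor = pre$name,
        product = j,
        chrom = as.character(GenomeInfoDb::seqnames(cl))[1],
        start = min(BiocGenerics::start(cl)),
        end = max(BiocGenerics::end(cl)),
        strand = as.character(BiocGenerics::strand(cl))[1],
        n_reads = length(cl),
        median_read_length = stats::median(cl$read_length),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(precursor = character(0), product = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_reads = integer(0), median_read_length = numeric(0)))
  }
  do.call(rbind, out)
}

# greedy 5'-end clustering: sorted seeds, a read joins the open cluster
# while its 5' end is within max_shift of the cluster's seed
cluster_by_five_prime <- function(reads, max_shift) {
  p5 <- five_prime_end(reads)
  ord <- order(p5)
  clusters <- list()
  current <- integer(0)
  seed <- NA_integer_
  for (i in ord) {
    if (length(current) == 0L || p5[i] - seed <= max_shift) {
      if (length(current) == 0L) seed <- p5[i]
      current <- c(current, i)
    } else {
      clusters[[length(clusters) + 1L]] <- current
      current <- i
      seed <- p5[i]
    }
  }
  if (length(current) > 0L) clusters[[length(clusters) + 1L]] <- current
  clusters
}

#' Per-arm miRNA quantification
#'
#' The two potential products of a miRNA hairpin (5p and 3p arms) are
#' quantified separately: sense-strand short reads are assigned to the
#' mature arm they overlap most; reads overlapping both arms equally are
#' tallied as ambiguous and assigned to neither. Counts are normalized by
#' the short reference transcript's read count.
#'
#' @param short_reads `GRanges` short-prep reads (one read set).
#' @param mirna_mature `GRanges` mature arms (`name`, `arm` columns).
#' @param ref_count the short reference's read count in this read set.
#' @return data.frame `precursor`, `arm`, `count`,
#'   `norm_expression = count / ref_count`; ambiguous-read tally in
#'   `attr(x, "n_ambiguous")`.
#' @export
mirna_arm_quantification <- function(short_reads, mirna_mature, ref_count) {
  stopifnot(ref_count > 0)
  ov <- GenomicRanges::findOverlaps(short_reads, mirna_mature,
                                    ignore.strand = FALSE)
  n_amb <- 0L
  counts <- integer(length(mirna_mature))
  if (length(ov) > 0L) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    inter <- BiocGenerics::width(GenomicRanges::pintersect(
      short_reads[qh], mirna_mature[sh]))
    # best (largest-overlap) arm per read; a tie means ambiguous
    o <- order(qh, -inter)
    qh <- qh[o]; sh <- sh[o]; inter <- inter[o]
    first <- !duplicated(qh)
    idx <- which(first)
    nxt <- idx + 1L
    tied <- nxt <= length(qh) & qh[nxt] == qh[idx] & inter[nxt] == inter[idx]
    n_amb <- sum(tied)
    counts <- tabulate(sh[idx[!tied]], nbins = length(mirna_mature))
  }
  out <- data.frame(
    precursor = mirna_mature$name,
    arm = mirna_mature$arm,
    count = unname(counts),
    norm_expression = unname(counts) / ref_count,
    stringsAsFactors = FALSE
  )
  attr(out, "n_ambiguous") <- n_amb
  out
}
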