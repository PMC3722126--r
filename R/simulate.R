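#' Simulate a toy genome and annotation catalog
#'
#' Builds a single-chromosome annotation emulating the feature classes
#' the pipeline consumes: multi-exon protein-coding genes with UTRs on
#' both strands (a subset with a second, exon-skipping isoform), a
#' designated abundant long reference transcript (beta-actin analog) and
#' a short reference locus (SNORD44 analog), repeat elements with
#' RepeatMasker-style family labels placed both intergenically and inside
#' introns (sense and antisense), miRNA precursors with 5p/3p mature
#' arms, pseudogenes and lincRNAs. Everything is deterministic given
#' `seed`.
#'
#' @param n_genes number of protein-coding genes (>= 1; gene 1 hosts the
#'   long reference transcript).
#' @param n_repeats,n_mirnas,n_pseudogenes,n_lincrnas feature counts.
#' @param chrom_length chromosome length, nt.
#' @param seed RNG seed.
#' @return list with `ann` (an [AnnotationSet]), `genome` (named
#'   `DNAStringSet`), `long_reference` and `short_reference` transcript
#'   ids.
#' @export
simulate_annotation <- function(n_genes = 300L, n_repeats = 150L,
                                n_mirnas = 30L, n_pseudogenes = 40L,
                                n_lincrnas = 30L, chrom_length = 2e6,
                                seed = 1L) {
  if (n_genes < 1L) {
    stop("n_genes must be >= 1: the long reference transcript is required",
         call. = FALSE)
  }
  set.seed(seed)
  chrom <- "chrT"
  chrom_length <- as.integer(chrom_length)

  # sequential placement with random intergenic gaps
  cursor <- 1000L
  advance <- function(width, gap) {
    start <- cursor + gap
    if (start + width > chrom_length - 1000L) {
      stop(sprintf(paste0("infeasible packing: feature of width %d at ",
                          "position %d exceeds chromosome length %d; ",
                          "reduce feature counts or enlarge the chromosome"),
                   width, start, chrom_length), call. = FALSE)
    }
    cursor <<- start + width
    start
  }

  exon_rows <- list(); utr5_rows <- list(); utr3_rows <- list()
  rep_rows <- list(); mir_rows <- list(); arm_rows <- list()
  pg_rows <- list(); linc_rows <- list(); sno_rows <- list()

  add_exon <- function(tx, gene, s, e, strand, biotype) {
    exon_rows[[length(exon_rows) + 1L]] <<-
      list(start = s, end = e, strand = strand, transcript_id = tx,
                 gene_id = gene, biotype = biotype)
  }

  rep_families <- c("SINE.SINE", "SINE.tRNA", "LINE.L1", "LINE.Dong-R4",
                    "LTR.ERVL?", "LTR.LTR", "DNA.hAT-Blackjack",
                    "DNA.TcMar-Mariner", "tRNA.tRNA", "snRNA.snRNA",
                    "Satellite.acro", "Unknown.Unknown")

  # interleave genes and intergenic feature types along the chromosome;
  # the reference gene and the short reference locus are placed first so
  # they exist even on tiny chromosomes
  n_intergenic_rep <- max(0L, n_repeats - floor(n_genes * 0.3))
  queue <- c("gene_ref", "snord",
             sample(c(rep("gene", n_genes - 1L),
                      rep("repeat", n_intergenic_rep),
                      rep("mirna", n_mirnas),
                      rep("pseudogene", n_pseudogenes),
                      rep("lincrna", n_lincrnas))))

  gene_n <- 0L
  intron_pool <- list()  # introns eligible for intronic repeats

  place_gene <- function(is_ref) {
    gene_n <<- gene_n + 1L
    gid <- if (is_ref) "GENE_REF" else sprintf("GENE%04d", gene_n)
    tid <- if (is_ref) "TXREF_LONG" else sprintf("TX%04d.1", gene_n)
    strand <- if (is_ref) "+" else sample(c("+", "-"), 1L)
    n_ex <- if (is_ref) 3L else sample(2:5, 1L)
    ex_w <- if (is_ref) rep(600L, 3L) else sample(100:300, n_ex, replace = TRUE)
    in_w <- sample(300:900, n_ex - 1L, replace = TRUE)
    gstart <- advance(sum(ex_w) + sum(in_w), sample(400:1500, 1L))
    s <- gstart
    starts <- integer(n_ex); ends <- integer(n_ex)
    for (k in seq_len(n_ex)) {
      starts[k] <- s; ends[k] <- s + ex_w[k] - 1L
      s <- ends[k] + 1L + if (k < n_ex) in_w[k] else 0L
    }
    for (k in seq_len(n_ex)) {
      add_exon(tid, gid, starts[k], ends[k], strand, "protein_coding")
    }
    # UTRs at the transcript ends (strand-aware: on minus-strand genes
    # the 5' end is the genomically last exon)
    if (strand == "+") {
      u5w <- min(60L, ex_w[1] - 10L); u3w <- min(150L, ex_w[n_ex] - 10L)
    } else {
      u5w <- min(60L, ex_w[n_ex] - 10L); u3w <- min(150L, ex_w[1] - 10L)
    }
    if (strand == "+") {
      utr5_rows[[length(utr5_rows) + 1L]] <<- list(
        start = starts[1], end = starts[1] + u5w - 1L, strand = strand,
        transcript_id = tid, gene_id = gid)
      utr3_rows[[length(utr3_rows) + 1L]] <<- list(
        start = ends[n_ex] - u3w + 1L, end = ends[n_ex], strand = strand,
        transcript_id = tid, gene_id = gid)
    } else {
      utr5_rows[[length(utr5_rows) + 1L]] <<- list(
        start = ends[n_ex] - u5w + 1L, end = ends[n_ex], strand = strand,
        transcript_id = tid, gene_id = gid)
      utr3_rows[[length(utr3_rows) + 1L]] <<- list(
        start = starts[1], end = starts[1] + u3w - 1L, strand = strand,
        transcript_id = tid, gene_id = gid)
    }
    # occasional exon-skipping second isoform
    if (!is_ref && n_ex >= 3L && stats::runif(1) < 0.2) {
      skip <- sample(2:(n_ex - 1L), 1L)
      tid2 <- sprintf("TX%04d.2", gene_n)
      for (k in setdiff(seq_len(n_ex), skip)) {
        add_exon(tid2, gid, starts[k], ends[k], strand, "protein_coding")
      }
    }
    for (k in seq_len(n_ex - 1L)) {
      intron_pool[[length(intron_pool) + 1L]] <<- list(
        start = ends[k] + 1L, end = starts[k + 1L] - 1L, strand = strand,
        gene_id = gid)
    }
  }

  mir_n <- 0L; pg_n <- 0L; linc_n <- 0L
  for (item in queue) {
    if (item == "gene_ref") place_gene(TRUE)
    else if (item == "gene") place_gene(FALSE)
    else if (item == "snord") {
      st <- advance(70L, sample(300:800, 1L))
      sno_rows[[length(sno_rows) + 1L]] <- list(
        start = st, end = st + 69L, strand = "+", name = "SNORD_REF")
      add_exon("TXREF_SHORT", "GENE_SNORD", st, st + 69L, "+", "snoRNA")
    } else if (item == "repeat") {
      w <- sample(80:300, 1L)
      st <- advance(w, sample(150:500, 1L))
      rep_rows[[length(rep_rows) + 1L]] <- list(
        start = st, end = st + w - 1L, strand = sample(c("+", "-"), 1L),
        family = sample(rep_families, 1L))
    } else if (item == "mirna") {
      mir_n <- mir_n + 1L
      st <- advance(82L, sample(200:600, 1L))
      strand <- sample(c("+", "-"), 1L)
      nm <- sprintf("mir-%03d", mir_n)
      mir_rows[[length(mir_rows) + 1L]] <- list(
        start = st, end = st + 81L, strand = strand, name = nm)
      # 5p arm near the precursor 5' end, 3p near the 3' end
      if (strand == "+") {
        arm_rows[[length(arm_rows) + 1L]] <- list(
          start = st + 4L, end = st + 25L, strand = strand, name = nm, arm = "5p")
        arm_rows[[length(arm_rows) + 1L]] <- list(
          start = st + 56L, end = st + 77L, strand = strand, name = nm, arm = "3p")
      } else {
        arm_rows[[length(arm_rows) + 1L]] <- list(
          start = st + 56L, end = st + 77L, strand = strand, name = nm, arm = "5p")
        arm_rows[[length(arm_rows) + 1L]] <- list(
          start = st + 4L, end = st + 25L, strand = strand, name = nm, arm = "3p")
      }
    } else if (item == "pseudogene") {
      pg_n <- pg_n + 1L
      w <- sample(400:1200, 1L)
      st <- advance(w, sample(200:600, 1L))
      pg_rows[[length(pg_rows) + 1L]] <- list(
        start = st, end = st + w - 1L, strand = sample(c("+", "-"), 1L),
        name = sprintf("PG%03d", pg_n))
    } else if (item == "lincrna") {
      linc_n <- linc_n + 1L
      w <- sample(800:2500, 1L)
      st <- advance(w, sample(200:600, 1L))
      linc_rows[[length(linc_rows) + 1L]] <- list(
        start = st, end = st + w - 1L, strand = sample(c("+", "-"), 1L),
        name = sprintf("LINC%03d", linc_n))
    }
  }

  # intronic repeats: sense copies are subtracted from intronic space,
  # antisense copies are retained in it
  wide <- Filter(function(d) d$end - d$start + 1L >= 260L, intron_pool)
  n_intronic_rep <- min(length(wide), max(0L, n_repeats - length(rep_rows)))
  if (n_intronic_rep > 0L) {
    for (d in sample(wide, n_intronic_rep)) {
      w <- sample(80:160, 1L)
      st <- sample(seq(d$start + 50L, d$end - 50L - w), 1L)
      same <- stats::runif(1) < 0.5
      rep_rows[[length(rep_rows) + 1L]] <- list(
        start = st, end = st + w - 1L,
        strand = if (same) d$strand else setdiff(c("+", "-"), d$strand),
        family = sample(rep_families, 1L))
    }
  }

  chrom_sizes <- stats::setNames(chrom_length, chrom)
  pluck <- function(rows, field) unlist(lapply(rows, `[[`, field))
  to_gr <- function(rows, extra_cols) {
    if (length(rows) == 0L) {
      mc <- stats::setNames(rep(list(character(0)), length(extra_cols)),
                            extra_cols)
      return(do.call(GenomicRanges::GRanges, c(list(), mc)))
    }
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(pluck(rows, "start"),
                                                  pluck(rows, "end")),
                                 strand = pluck(rows, "strand"))
    for (col in extra_cols) S4Vectors::mcols(gr)[[col]] <- pluck(rows, col)
    gr
  }

  ann <- AnnotationSet(
    exons = to_gr(exon_rows, c("transcript_id", "gene_id", "biotype")),
    utr5 = to_gr(utr5_rows, c("transcript_id", "gene_id")),
    utr3 = to_gr(utr3_rows, c("transcript_id", "gene_id")),
    repeats = to_gr(rep_rows, "family"),
    mirnas = to_gr(mir_rows, "name"),
    mirna_mature = to_gr(arm_rows, c("name", "arm")),
    pseudogenes = to_gr(pg_rows, "name"),
    lincrnas = to_gr(linc_rows, "name"),
    rrnas_snornas = to_gr(sno_rows, "name"),
    chrom_sizes = chrom_sizes
  )

  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
          collapse = ""), chrom))

  list(ann = ann, genome = genome,
       long_reference = "TXREF_LONG", short_reference = "TXREF_SHORT")
}

#' Build the ground-truth manifest for a simulated dataset
#'
#' Assigns every signal source its true relative read density
#' (per-nucleotide rate relative to the corresponding reference
#' transcript), so the pipeline's estimates can be compared against
#' planted values:
#'
#' * protein-coding transcript densities log2-uniform over
#'   `dynamic_range` (default 16 log2 units below the reference, the
#'   dynamic range the study design assumes), with one transcript pinned
#'   at the bottom of the range;
#' * per-transcript rRNA-depletion distortion factors (1 for most genes;
#'   a planted fraction gets factors of magnitude >= 4);
#' * long and short novel intronic regions placed inside the derived
#'   intronic space at densities above the detection thresholds;
#' * antisense signal over 3'UTRs, one repeat family, and a set of miRNA
#'   precursors (one or two miRNA-sized antisense products each);
#' * sense pseudogene transcription; no lincRNA signal (null category);
#' * orphan reads: junction-spanning, edited-genomic, and random.
#'
#' @param sim output of [simulate_annotation()].
#' @param seed RNG seed.
#' @param dynamic_range span of protein-coding log2 densities below the
#'   reference.
#' @param distorted_frac fraction of well-expressed genes given a
#'   depletion distortion factor.
#' @param n_long_intronic,n_short_intronic planted novel-region counts.
#' @param n_antisense_utr3 genes given antisense 3'UTR signal.
#' @param n_antisense_mirna precursors given antisense products.
#' @param antisense_repeat_family repeat family planted with antisense
#'   short reads.
#' @return list of class `TruthManifest`.
#' @export
simulate_truth <- function(sim, seed = 1L, dynamic_range = 16,
                           distorted_frac = 0.10,
                           n_long_intronic = 20L, n_short_intronic = 15L,
                           n_antisense_utr3 = 100L, n_antisense_mirna = 6L,
                           antisense_repeat_family = "SINE.SINE") {
  set.seed(seed + 1L)
  ann <- sim$ann
  tx <- ann$transcripts
  pc <- tx[tx$biotype == "protein_coding", ]
  # densities per transcript; second isoforms get no independent signal
  primary <- pc[grepl("\\.1$", pc$transcript_id) |
                  pc$transcript_id == sim$long_reference, ]
  dens <- 2^stats::runif(nrow(primary), -dynamic_range, -1)
  dens[primary$transcript_id == sim$long_reference] <- 1
  # pin one transcript at the bottom of the dynamic range
  low <- which(primary$transcript_id != sim$long_reference)
  if (length(low) > 0L) dens[low[1]] <- 2^(-dynamic_range)
  transcripts <- data.frame(
    transcript_id = primary$transcript_id, gene_id = primary$gene_id,
    density = dens, distortion = 1, stringsAsFactors = FALSE)

  # distortion is planted on well-expressed genes so that the flagging
  # test operates in its intended regime (hundreds of reads per gene)
  well <- which(transcripts$density >= 2^-5 &
                  transcripts$transcript_id != sim$long_reference)
  n_dist <- round(length(well) * distorted_frac)
  if (n_dist > 0L) {
    pick <- sample(well, n_dist)
    transcripts$distortion[pick] <-
      sample(c(1 / 8, 1 / 4, 4, 8), n_dist, replace = TRUE)
  }

  intronic_space <- derive_intronic_space(ann)

  plant_regions <- function(n, min_w, max_w, log2_dens_range, class) {
    host <- intronic_space[BiocGenerics::width(intronic_space) >= min_w + 20L]
    if (length(host) == 0L || n == 0L) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        class = character(0), density = numeric(0)))
    }
    idx <- sample(seq_along(host), min(n, length(host)))
    rows <- lapply(idx, function(i) {
      h <- host[i]
      w <- sample(min_w:min(max_w, BiocGenerics::width(h) - 10L), 1L)
      st <- BiocGenerics::start(h) +
        sample.int(BiocGenerics::width(h) - w, 1L) - 1L
      data.frame(chrom = as.character(GenomeInfoDb::seqnames(h)),
                 start = st, end = st + w - 1L,
                 strand = as.character(BiocGenerics::strand(h)),
                 class = class,
                 density = 2^sample(log2_dens_range, 1L))
    })
    do.call(rbind, rows)
  }
  # planted densities sit well above the 1:1024 / 1:64 thresholds so
  # islands are densely tiled by reads at the default read budgets
  long_regions <- plant_regions(n_long_intronic, 150L, 400L, -6:-4, "long")
  short_regions <- plant_regions(n_short_intronic, 35L, 70L, -3:-1, "short")

  # antisense 3'UTR signal on a subset of genes
  u3 <- ann$utr3
  idx <- sample(seq_along(u3), min(n_antisense_utr3, length(u3)))
  antisense_utr3 <- data.frame(
    target = u3$transcript_id[idx],
    chrom = as.character(GenomeInfoDb::seqnames(u3[idx])),
    start = BiocGenerics::start(u3[idx]), end = BiocGenerics::end(u3[idx]),
    strand = ifelse(as.character(BiocGenerics::strand(u3[idx])) == "+",
                    "-", "+"),
    density = 2^sample(-8:-5, length(idx), replace = TRUE),
    stringsAsFactors = FALSE)

  # pseudogene sense transcription, dense enough that pseudogene loci
  # score as clearly enriched (the phenomenon the generator emulates)
  pg <- ann$pseudogenes
  pseudogene_truth <- data.frame(
    name = pg$name,
    chrom = as.character(GenomeInfoDb::seqnames(pg)),
    start = BiocGenerics::start(pg), end = BiocGenerics::end(pg),
    strand = as.character(BiocGenerics::strand(pg)),
    density = 2^sample(-8:-4, length(pg), replace = TRUE),
    stringsAsFactors = FALSE)

  # miRNA arm expression (sense) over a wide range, some >= 32x reference
  arms <- ann$mirna_mature
  mirna_arms <- data.frame(
    name = arms$name, arm = arms$arm,
    chrom = as.character(GenomeInfoDb::seqnames(arms)),
    start = BiocGenerics::start(arms), end = BiocGenerics::end(arms),
    strand = as.character(BiocGenerics::strand(arms)),
    density = 2^sample(-2:5, length(arms), replace = TRUE),
    stringsAsFactors = FALSE)

  # antisense miRNA products: one or two per chosen precursor
  pre <- ann$mirnas
  pick <- sample(seq_along(pre), min(n_antisense_mirna, length(pre)))
  prod_rows <- list()
  for (i in pick) {
    p <- pre[i]
    n_prod <- sample(1:2, 1L)
    offs <- if (n_prod == 1L) 10L else c(8L, 52L)
    for (k in seq_len(n_prod)) {
      st <- BiocGenerics::start(p) + offs[k]
      prod_rows[[length(prod_rows) + 1L]] <- data.frame(
        precursor = p$name, product = k,
        chrom = as.character(GenomeInfoDb::seqnames(p)),
        start = st, end = st + 21L,
        strand = ifelse(as.character(BiocGenerics::strand(p)) == "+",
                        "-", "+"),
        density = 2^sample(2:4, 1L), stringsAsFactors = FALSE)
    }
  }
  antisense_mirna <- if (length(prod_rows)) do.call(rbind, prod_rows) else
    data.frame(precursor = character(0), product = integer(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), density = numeric(0))

  structure(list(
    transcripts = transcripts,
    long_regions = long_regions,
    short_regions = short_regions,
    antisense_utr3 = antisense_utr3,
    pseudogenes = pseudogene_truth,
    mirna_arms = mirna_arms,
    antisense_mirna = antisense_mirna,
    antisense_repeat_family = antisense_repeat_family,
    antisense_repeat_density = 2^-2,
    # no diffuse background by default: read sets carry planted signal
    # only, so every reported novel region traces to a manifest entry
    background_short_density = 0,
    intronic_space = intronic_space,
    long_reference = sim$long_reference,
    short_reference = sim$short_reference,
    seed = seed
  ), class = "TruthManifest")
}

# assemble the per-source weight table for one preparation
prep_sources <- function(ann, truth, prep) {
  src <- list()
  add <- function(id, type, chrom, starts, ends, strand, density) {
    src[[length(src) + 1L]] <<- list(
      id = id, type = type, chrom = chrom,
      starts = as.integer(starts), ends = as.integer(ends),
      strand = strand, density = density,
      weight = density * sum(ends - starts + 1))
  }
  if (prep %in% c("long_total", "long_depleted")) {
    ex <- ann$exons
    ex_start <- split(BiocGenerics::start(ex), ex$transcript_id)
    ex_end <- split(BiocGenerics::end(ex), ex$transcript_id)
    ex_strand <- vapply(split(as.character(BiocGenerics::strand(ex)),
                              ex$transcript_id), `[`, "", 1L)
    ex_chrom <- as.character(GenomeInfoDb::seqnames(ex))[1]
    for (r in seq_len(nrow(truth$transcripts))) {
      t <- truth$transcripts[r, ]
      if (t$transcript_id == truth$short_reference) next
      d <- t$density * if (prep == "long_depleted") t$distortion else 1
      tid <- t$transcript_id
      add(tid, "transcript", ex_chrom, ex_start[[tid]], ex_end[[tid]],
          ex_strand[[tid]], d)
    }
    for (r in seq_len(nrow(truth$pseudogenes))) {
      p <- truth$pseudogenes[r, ]
      add(p$name, "pseudogene", p$chrom, p$start, p$end, p$strand, p$density)
    }
    lr <- truth$long_regions
    for (r in seq_len(nrow(lr))) {
      g <- lr[r, ]
      add(sprintf("long_region_%d", r), "intronic", g$chrom, g$start,
          g$end, g$strand, g$density)
    }
    au <- truth$antisense_utr3
    for (r in seq_len(nrow(au))) {
      g <- au[r, ]
      add(sprintf("anti_utr3_%s", g$target), "antisense", g$chrom,
          g$start, g$end, g$strand, g$density)
    }
  } else {
    ex <- ann$exons
    e <- ex[ex$transcript_id == truth$short_reference]
    add(truth$short_reference, "transcript",
        as.character(GenomeInfoDb::seqnames(e))[1],
        BiocGenerics::start(e), BiocGenerics::end(e),
        as.character(BiocGenerics::strand(e))[1], 1)
    ma <- truth$mirna_arms
    for (r in seq_len(nrow(ma))) {
      g <- ma[r, ]
      add(sprintf("%s_%s", g$name, g$arm), "mirna_arm", g$chrom, g$start,
          g$end, g$strand, g$density)
    }
    sr <- truth$short_regions
    for (r in seq_len(nrow(sr))) {
      g <- sr[r, ]
      add(sprintf("short_region_%d", r), "intronic", g$chrom, g$start,
          g$end, g$strand, g$density)
    }
    am <- truth$antisense_mirna
    for (r in seq_len(nrow(am))) {
      g <- am[r, ]
      add(sprintf("anti_%s_p%d", g$precursor, g$product), "anti_mirna",
          g$chrom, g$start, g$end, g$strand, g$density)
    }
    reps <- ann$repeats[ann$repeats$family == truth$antisense_repeat_family]
    for (r in seq_along(reps)) {
      g <- reps[r]
      add(sprintf("anti_repeat_%d", r), "anti_repeat",
          as.character(GenomeInfoDb::seqnames(g)),
          BiocGenerics::start(g), BiocGenerics::end(g),
          ifelse(as.character(BiocGenerics::strand(g)) == "+", "-", "+"),
          truth$antisense_repeat_density)
    }
    # optional uniform background on both strands
    if (truth$background_short_density > 0) {
      for (s in c("+", "-")) {
        add(paste0("background", s), "background", names(ann$chrom_sizes)[1],
            1L, unname(ann$chrom_sizes[1]), s, truth$background_short_density)
      }
    }
  }
  src
}

#' Simulate one read set (one sample, one preparation)
#'
#' Read placements are multinomial over the truth manifest's signal
#' sources with weights `density x span`; within a source, reads fall
#' uniformly (transcript reads choose an exon proportionally to its
#' width and stay inside it, so every emitted read is an ungapped,
#' uniquely-placed genomic interval). The rRNA-depleted preparation
#' multiplies each transcript's weight by its distortion factor. Long
#' preparations draw read lengths uniformly in 40-60 nt, the short
#' preparation in 18-39 nt except for miRNA-arm and antisense-product
#' reads, which get miRNA-typical lengths (20-24 nt) and 5' ends within
#' 1 nt of the product start.
#'
#' @param ann an [AnnotationSet].
#' @param truth a `TruthManifest` from [simulate_truth()].
#' @param sample_id sample label.
#' @param prep one of [PREPS].
#' @param n_reads reads to draw.
#' @param seed RNG seed.
#' @return `GRanges` read set (see [mapped_read_set()]).
#' @export
simulate_reads <- function(ann, truth, sample_id, prep, n_reads, seed) {
  set.seed(seed)
  prep <- match.arg(prep, PREPS)
  src <- prep_sources(ann, truth, prep)
  w <- vapply(src, function(s) s$weight, numeric(1))
  counts <- as.integer(stats::rmultinom(1L, n_reads, w))
  len_range <- if (prep == "short") c(18L, 39L) else c(40L, 60L)

  acc_start <- vector("list", length(src))
  acc_end <- vector("list", length(src))
  acc_strand <- character(length(src))
  for (i in seq_along(src)) {
    n <- counts[i]
    if (n == 0L) next
    s <- src[[i]]
    if (s$type %in% c("mirna_arm", "anti_mirna")) {
      # anchor the read's 5' end within 1 nt of the product/arm 5' end
      len <- sample(20:24, n, replace = TRUE)
      jit <- sample(-1:1, n, replace = TRUE)
      if (s$strand == "+") {
        starts <- s$starts[1] + jit
      } else {
        starts <- s$ends[1] + jit - len + 1L
      }
      ends <- starts + len - 1L
    } else {
      ew <- s$ends - s$starts + 1L
      block <- sample.int(length(ew), n, replace = TRUE, prob = ew)
      len <- pmin(sample(len_range[1]:len_range[2], n, replace = TRUE),
                  ew[block])
      offmax <- ew[block] - len + 1L
      off <- floor(stats::runif(n) * offmax)
      starts <- s$starts[block] + off
      ends <- starts + len - 1L
    }
    acc_start[[i]] <- starts
    acc_end[[i]] <- ends
    acc_strand[i] <- s$strand
  }
  n_per <- lengths(acc_start)
  all <- GenomicRanges::GRanges(
    names(ann$chrom_sizes)[1],
    IRanges::IRanges(unlist(acc_start), unlist(acc_end)),
    strand = rep(acc_strand, n_per))
  all$source_id <- rep(vapply(src, function(s) s$id, character(1)), n_per)
  keep <- BiocGenerics::width(all) >= 18L
  all <- all[keep]
  suppressWarnings(reads <- mapped_read_set(all, sample_id, prep))
  # carry the source label through the length filter for truth checks
  ok <- prep_length_ok(BiocGenerics::width(all), prep)
  reads$source_id <- all$source_id[ok]
  GenomeInfoDb::seqlevels(reads) <- names(ann$chrom_sizes)
  GenomeInfoDb::seqinfo(reads) <- make_seqinfo(ann$chrom_sizes)
  reads
}

#' Simulate orphan reads
#'
#' Draws unmappable read sequences of three origins: junction-spanning
#' reads (sampled from an exon-exon junction catalog, crossing the
#' boundary by >= 1 nt, with 0-2 substitutions), edited genomic reads
#' (3-6 substitutions, so they fail the default 2-mismatch mapping but
#' are rescuable at 6), and random sequences (unmappable at any setting
#' with high probability).
#'
#' @param sim output of [simulate_annotation()].
#' @param catalog junction catalog from [enumerate_junctions()].
#' @param n_junction,n_edited,n_random read counts per origin.
#' @param read_length orphan read length, nt.
#' @param seed RNG seed.
#' @return list: `reads` (named `DNAStringSet`), `truth` (data.frame
#'   `read_id`, `origin`, `source`, `n_edits`).
#' @export
simulate_orphans <- function(sim, catalog, n_junction = 60L, n_edited = 60L,
                             n_random = 30L, read_length = 50L, seed = 1L) {
  set.seed(seed + 2L)
  bases <- c("A", "C", "G", "T")
  flank <- catalog$flank
  genome <- sim$genome[[1]]
  chrom <- names(sim$genome)[1]

  mutate <- function(seq_chr, k) {
    if (k == 0L) return(seq_chr)
    s <- strsplit(seq_chr, "")[[1]]
    pos <- sample(length(s), k)
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    paste(s, collapse = "")
  }

  rows <- list(); seqs <- character(0)
  full <- which(!catalog$junctions$truncated &
                  Biostrings::width(catalog$sequences) == 2L * flank)
  lo <- max(1L, flank - read_length + 2L)
  hi <- min(flank, 2L * flank - read_length + 1L)
  if (n_junction > 0L && hi < lo) {
    stop("read_length ", read_length, " does not fit on junctions of flank ",
         flank, call. = FALSE)
  }
  for (i in seq_len(n_junction)) {
    j <- sample(full, 1L)
    # offset such that the read crosses the junction boundary by >= 1 nt
    # and still fits on the 2*flank junction sequence
    off <- sample(lo:hi, 1L)
    sq <- as.character(Biostrings::subseq(catalog$sequences[[j]], off,
                                          off + read_length - 1L))
    k <- sample(0:2, 1L)
    seqs <- c(seqs, mutate(sq, k))
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = sprintf("orphan_junction_%03d", i), origin = "junction",
      source = catalog$junctions$junction_id[j], n_edits = k)
  }
  for (i in seq_len(n_edited)) {
    st <- sample(length(genome) - read_length, 1L)
    sq <- as.character(Biostrings::subseq(genome, st, st + read_length - 1L))
    k <- sample(3:6, 1L)
    seqs <- c(seqs, mutate(sq, k))
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = sprintf("orphan_edited_%03d", i), origin = "edited",
      source = sprintf("%s:%d", chrom, st), n_edits = k)
  }
  for (i in seq_len(n_random)) {
    seqs <- c(seqs, paste(sample(bases, read_length, replace = TRUE),
                          collapse = ""))
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = sprintf("orphan_random_%03d", i), origin = "random",
      source = NA_character_, n_edits = NA_integer_)
  }
  truth <- do.call(rbind, rows)
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- truth$read_id
  list(reads = reads, truth = truth)
}

#' Simulate a complete study dataset
#'
#' Four samples by three preparations of uniquely-mapped stranded reads
#' plus orphan sequences, with the full ground-truth manifest.
#'
#' @param n_samples samples (default 4).
#' @param reads_per_long_prep,reads_per_short_prep reads per read set.
#' @param seed master seed; every derived seed is a deterministic small
#'   offset of it.
#' @param junction_flank flank used for the orphan-source junction
#'   catalog.
#' @param ... passed to [simulate_annotation()].
#' @return list: `ann`, `genome`, `truth`, `reads` (list
#'   `sample -> prep -> GRanges`), `orphans`, `catalog`, `references`.
#' @export
simulate_platelet_dataset <- function(n_samples = 4L,
                                      reads_per_long_prep = 2e5,
                                      reads_per_short_prep = 1e5,
                                      seed = 1L, junction_flank = 49L, ...) {
  sim <- simulate_annotation(seed = seed, ...)
  truth <- simulate_truth(sim, seed = seed)
  catalog <- enumerate_junctions(sim$ann, sim$genome, flank = junction_flank)
  reads <- list()
  for (s in seq_len(n_samples)) {
    sid <- paste0("sample", s)
    reads[[sid]] <- list()
    for (p in PREPS) {
      n <- if (p == "short") reads_per_short_prep else reads_per_long_prep
      sub_seed <- seed + 1000L * s + 10L * match(p, PREPS)
      reads[[sid]][[p]] <- simulate_reads(sim$ann, truth, sid, p, n, sub_seed)
    }
  }
  orphans <- simulate_orphans(sim, catalog, seed = seed)
  list(ann = sim$ann, genome = sim$genome, truth = truth, reads = reads,
       orphans = orphans, catalog = catalog,
       references = list(long = sim$long_reference,
                         short = sim$short_reference))
}

#' Write a simulated dataset to disk
#'
#' Emits the same dialects the pipeline consumes: GTF + BED6 annotation
#' tracks, chrom.sizes, genome FASTA, per-sample/preparation BED6 read
#' files, orphan FASTQ, and the truth manifest as key-value YAML plus
#' TSV tables.
#'
#' @param dataset output of [simulate_platelet_dataset()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(dataset$ann, file.path(dir, "annotation"))
  Biostrings::writeXStringSet(dataset$genome, file.path(dir, "genome.fa"))
  rd <- file.path(dir, "reads"); dir.create(rd, showWarnings = FALSE)
  for (s in names(dataset$reads)) {
    for (p in names(dataset$reads[[s]])) {
      write_reads_bed(dataset$reads[[s]][[p]],
                      file.path(rd, sprintf("%s_%s.bed", s, p)))
    }
  }
  orphans <- dataset$orphans$reads
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(orphans),
    function(w) paste(rep("I", w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(orphans, file.path(dir, "orphans.fastq"),
                              format = "fastq", qualities = quals)
  md <- file.path(dir, "manifest"); dir.create(md, showWarnings = FALSE)
  yaml::write_yaml(list(seed = dataset$truth$seed,
                        long_reference = dataset$references$long,
                        short_reference = dataset$references$short,
                        antisense_repeat_family =
                          dataset$truth$antisense_repeat_family),
                   file.path(md, "manifest.yaml"))
  for (nm in c("transcripts", "long_regions", "short_regions",
               "antisense_utr3", "pseudogenes", "mirna_arms",
               "antisense_mirna")) {
    utils::write.table(dataset$truth[[nm]],
                       file.path(md, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(dataset$orphans$truth,
                     file.path(md, "orphans.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a simulated dataset back from disk
#'
#' Counterpart of [write_dataset()]: reconstructs the annotation, read
#' sets, orphan reads and truth tables from their on-disk text formats,
#' so every analysis stage can be re-run from persisted intermediates.
#'
#' @param dir directory written by [write_dataset()].
#' @return list with `ann`, `genome`, `reads`, `orphans` (`reads` +
#'   `truth`), `truth` (data.frame tables plus manifest key-values) and
#'   `references`.
#' @export
read_dataset <- function(dir) {
  ad <- file.path(dir, "annotation")
  ann <- load_annotation(
    file.path(ad, "annotation.gtf"), file.path(ad, "chrom.sizes"),
    aux_tracks = list(
      repeats = if (file.exists(file.path(ad, "repeats.bed")))
        file.path(ad, "repeats.bed"),
      mirnas = if (file.exists(file.path(ad, "mirnas.bed")))
        file.path(ad, "mirnas.bed"),
      mirna_mature = if (file.exists(file.path(ad, "mirna_mature.bed")))
        file.path(ad, "mirna_mature.bed"),
      pseudogenes = if (file.exists(file.path(ad, "pseudogenes.bed")))
        file.path(ad, "pseudogenes.bed"),
      lincrnas = if (file.exists(file.path(ad, "lincrnas.bed")))
        file.path(ad, "lincrnas.bed"),
      rrnas_snornas = if (file.exists(file.path(ad, "rrnas_snornas.bed")))
        file.path(ad, "rrnas_snornas.bed")))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  beds <- list.files(file.path(dir, "reads"), pattern = "\\.bed$")
  reads <- list()
  for (b in beds) {
    stem <- sub("\\.bed$", "", b)
    prep <- PREPS[vapply(PREPS, function(p)
      grepl(paste0("_", p, "$"), stem), logical(1))]
    sample_id <- sub(paste0("_", prep, "$"), "", stem)
    reads[[sample_id]][[prep]] <-
      load_reads(file.path(dir, "reads", b), sample_id, prep)
  }
  md <- file.path(dir, "manifest")
  manifest <- yaml::read_yaml(file.path(md, "manifest.yaml"))
  truth <- list(manifest = manifest)
  for (nm in c("transcripts", "long_regions", "short_regions",
               "antisense_utr3", "pseudogenes", "mirna_arms",
               "antisense_mirna", "orphans")) {
    p <- file.path(md, paste0(nm, ".tsv"))
    if (file.exists(p)) {
      truth[[nm]] <- utils::read.table(p, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE,
                                       quote = "")
    }
  }
  orphans <- list(reads = read_orphans(file.path(dir, "orphans.fastq")),
                  truth = truth$orphans)
  list(ann = ann, genome = genome, reads = reads, orphans = orphans,
       truth = truth,
       references = list(long = manifest$long_reference,
                         short = manifest$short_reference))
}
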