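# shorthand GRanges constructor (1-based, closed)
gr <- function(start, end, strand = "+", chrom = "chrT", ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand)
  mc <- list(...)
  for (nm in names(mc)) S4Vectors::mcols(g)[[nm]] <- mc[[nm]]
  g
}

# expand a GRanges to "strand:position" keys for exact base-level checks
pos_keys <- function(g) {
  if (length(g) == 0L) return(character(0))
  unlist(lapply(seq_along(g), function(i) {
    paste0(as.character(BiocGenerics::strand(g))[i], ":",
           seq(BiocGenerics::start(g)[i], BiocGenerics::end(g)[i]))
  }))
}

# brute-force boolean-mask interval subtraction on a toy chromosome
bf_subtract <- function(minuend, subtrahend, strand_mode, chrom_len = 10000L) {
  fill <- function(g, s) {
    mask <- logical(chrom_len)
    sel <- as.character(BiocGenerics::strand(g)) %in% s
    for (i in which(sel)) {
      mask[seq(BiocGenerics::start(g)[i], BiocGenerics::end(g)[i])] <- TRUE
    }
    mask
  }
  out <- character(0)
  strands <- if (strand_mode == "ignore_strand") list(c("+", "-", "*")) else
    list("+", "-")
  for (s in strands) {
    m <- fill(minuend, s)
    sub_s <- switch(strand_mode,
                    same_strand = c(s, "*"),
                    both_strands = c("+", "-", "*"),
                    ignore_strand = c("+", "-", "*"))
    keep <- m & !fill(subtrahend, sub_s)
    lab <- if (strand_mode == "ignore_strand") "*" else s
    if (any(keep)) out <- c(out, paste0(lab, ":", which(keep)))
  }
  sort(out)
}

# brute-force per-read overlap counting (sense strand, >= 1 nt over exons)
bf_count_reads <- function(reads, exons) {
  n <- 0L
  for (i in seq_along(reads)) {
    hit <- FALSE
    for (j in seq_along(exons)) {
      same_strand <- as.character(BiocGenerics::strand(reads))[i] ==
        as.character(BiocGenerics::strand(exons))[j]
      ov <- min(BiocGenerics::end(reads)[i], BiocGenerics::end(exons)[j]) -
        max(BiocGenerics::start(reads)[i], BiocGenerics::start(exons)[j]) + 1L
      if (same_strand && ov >= 1L) { hit <- TRUE; break }
    }
    if (hit) n <- n + 1L
  }
  n
}

# brute-force island caller over an explicit depth vector
bf_islands <- function(depth, min_span) {
  r <- rle(depth >= 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_span
  data.frame(start = starts[keep], end = ends[keep])
}

# depth vector from reads on [1, len]
depth_vector <- function(reads, len) {
  d <- integer(len)
  for (i in seq_along(reads)) {
    idx <- seq(BiocGenerics::start(reads)[i], BiocGenerics::end(reads)[i])
    d[idx] <- d[idx] + 1L
  }
  d
}

# hand-built two-gene annotation for exact-value tests
tiny_annotation <- function() {
  exons <- c(
    gr(101, 200, "+", transcript_id = "tA.1", gene_id = "gA",
       biotype = "protein_coding"),
    gr(901, 1000, "+", transcript_id = "tA.1", gene_id = "gA",
       biotype = "protein_coding"),
    gr(2001, 2500, "-", transcript_id = "tB.1", gene_id = "gB",
       biotype = "protein_coding"),
    gr(3001, 3500, "-", transcript_id = "tB.1", gene_id = "gB",
       biotype = "protein_coding"),
    gr(5001, 5070, "+", transcript_id = "tS", gene_id = "gS",
       biotype = "snoRNA")
  )
  AnnotationSet(
    exons = exons,
    utr5 = gr(101, 140, "+", transcript_id = "tA.1", gene_id = "gA"),
    utr3 = gr(951, 1000, "+", transcript_id = "tA.1", gene_id = "gA"),
    repeats = gr(c(401, 480), c(460, 520), c("+", "-"),
                 family = c("SINE.SINE", "LINE.L1")),
    mirnas = gr(6001, 6082, "+", name = "mir-001"),
    mirna_mature = gr(c(6005, 6057), c(6026, 6078), "+",
                      name = c("mir-001", "mir-001"), arm = c("5p", "3p")),
    pseudogenes = gr(7001, 7600, "+", name = "PG001"),
    lincrnas = gr(8001, 9000, "-", name = "LINC001"),
    rrnas_snornas = gr(5001, 5070, "+", name = "SNORD_REF"),
    chrom_sizes = c(chrT = 10000L)
  )
}

# small simulated dataset shared across tests (memoised per test run)
.small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.small_sim_cache$ds)) {
    .small_sim_cache$ds <- simulate_platelet_dataset(
      n_samples = 2L, reads_per_long_prep = 4e4, reads_per_short_prep = 2e4,
      seed = 42L, n_genes = 80L, n_repeats = 50L, n_mirnas = 12L,
      n_pseudogenes = 12L, n_lincrnas = 8L, chrom_length = 7e5)
  }
  .small_sim_cache$ds
}
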