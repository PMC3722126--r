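# random single-chromosome gene set + genome for junction tests
random_gene_annotation <- function(n_genes, seed, chrom_len = 60000L) {
  set.seed(seed)
  rows <- list()
  cursor <- 100L
  for (g in seq_len(n_genes)) {
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:5, 1)
    gid <- sprintf("g%03d", g)
    for (k in seq_len(n_ex)) {
      w <- sample(60:200, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        start = cursor, end = cursor + w - 1L, strand = strand,
        transcript_id = paste0(gid, ".1"), gene_id = gid,
        biotype = "protein_coding")
      cursor <- cursor + w + sample(50:300, 1)
    }
    cursor <- cursor + 400L
  }
  d <- do.call(rbind, rows)
  exons <- gr(d$start, d$end, d$strand, transcript_id = d$transcript_id,
              gene_id = d$gene_id, biotype = d$biotype)
  ann <- AnnotationSet(exons = exons, chrom_sizes = c(chrT = chrom_len))
  genome <- Biostrings::DNAStringSet(stats::setNames(paste(
    sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
    collapse = ""), "chrT"))
  list(ann = ann, genome = genome)
}

test_that("junction enumeration counts all ordered non-overlapping exon pairs", {
  toy <- random_gene_annotation(1, seed = 1)
  # single gene, n exons (all disjoint): choose(n, 2) junctions
  n_ex <- length(toy$ann$exons)
  cat <- enumerate_junctions(toy$ann, toy$genome, flank = 20L)
  expect_equal(nrow(cat$junctions), choose(n_ex, 2))

  # two genes with 2 and 4 exons: 1 + 6 = 7, matching brute force
  toy2 <- random_gene_annotation(8, seed = 2)
  cat2 <- enumerate_junctions(toy2$ann, toy2$genome, flank = 20L)
  bf <- 0L
  for (g in unique(toy2$ann$exons$gene_id)) {
    e <- toy2$ann$exons[toy2$ann$exons$gene_id == g]
    for (i in seq_along(e)) for (j in seq_along(e)) {
      if (i < j && (BiocGenerics::start(e)[j] > BiocGenerics::end(e)[i] ||
                      BiocGenerics::start(e)[i] > BiocGenerics::end(e)[j])) {
        bf <- bf + 1L
      }
    }
  }
  expect_equal(nrow(cat2$junctions), bf)
  # single-exon genes contribute nothing
  singles <- unique(toy2$ann$exons$gene_id[
    !duplicated(toy2$ann$exons$gene_id) &
      !toy2$ann$exons$gene_id %in%
        toy2$ann$exons$gene_id[duplicated(toy2$ann$exons$gene_id)]])
  expect_false(any(cat2$junctions$gene_id %in% singles))
})

test_that("junction sequences read 5'-3' on the transcript strand", {
  # deterministic two-exon gene on each strand with a known genome
  genome <- Biostrings::DNAStringSet(c(chrT = paste(
    rep(c("ACGT"), 250), collapse = "")))
  exons <- c(gr(11, 30, "+", transcript_id = "p.1", gene_id = "p",
                biotype = "protein_coding"),
             gr(61, 80, "+", transcript_id = "p.1", gene_id = "p",
                biotype = "protein_coding"),
             gr(111, 130, "-", transcript_id = "m.1", gene_id = "m",
                biotype = "protein_coding"),
             gr(161, 180, "-", transcript_id = "m.1", gene_id = "m",
                biotype = "protein_coding"))
  ann <- AnnotationSet(exons = exons, chrom_sizes = c(chrT = 1000L))
  cat <- enumerate_junctions(ann, genome, flank = 5L)
  expect_equal(nrow(cat$junctions), 2L)
  seqs <- as.character(cat$sequences)
  chr <- genome[[1]]
  plus_expected <- paste0(
    as.character(Biostrings::subseq(chr, 26, 30)),
    as.character(Biostrings::subseq(chr, 61, 65)))
  expect_equal(unname(seqs[cat$junctions$gene_id == "p"]), plus_expected)
  # minus strand: donor is the downstream exon (161-180); its transcript-
  # final 5 nt are genomic 161-165; acceptor head is genomic 126-130;
  # the junction is the reverse complement of [acceptor head][donor tail]
  minus_expected <- as.character(Biostrings::reverseComplement(
    Biostrings::xscat(Biostrings::subseq(chr, 126, 130),
                      Biostrings::subseq(chr, 161, 165))))
  expect_equal(unname(seqs[cat$junctions$gene_id == "m"]), minus_expected)
})

test_that("short exons truncate the flank and are flagged", {
  genome <- Biostrings::DNAStringSet(c(chrT = paste(
    rep("ACGT", 100), collapse = "")))
  exons <- c(gr(11, 16, "+", transcript_id = "t.1", gene_id = "g",
                biotype = "protein_coding"),
             gr(51, 90, "+", transcript_id = "t.1", gene_id = "g",
                biotype = "protein_coding"))
  ann <- AnnotationSet(exons = exons, chrom_sizes = c(chrT = 400L))
  cat <- enumerate_junctions(ann, genome, flank = 10L)
  expect_true(cat$junctions$truncated)
  expect_equal(Biostrings::width(cat$sequences), 6L + 10L)
})

test_that("reads map uniquely, multi-mappers are discarded, N never matches", {
  targets <- Biostrings::DNAStringSet(c(
    t1 = "ACGTACGTACGTACGTACGTACGTACGTAC",
    t2 = "TTTTGGGGCCCCAAAATTTTGGGGCCCCAA",
    t3 = "ACGTACGTACGTACGTACGTACGTACGTAC"))  # duplicate of t1
  # exact match to t2 only: mapped with 0 mismatches
  r <- Biostrings::DNAStringSet(c(a = "TTTTGGGGCCCCAAAATTTT"))
  rep1 <- map_reads_to_sequences(r, targets)
  expect_equal(rep1$status, "mapped")
  expect_equal(rep1$mismatches, 0L)
  expect_equal(rep1$target, "t2")
  # matching two identical targets: discarded as a multi-mapper
  r2 <- Biostrings::DNAStringSet(c(b = "ACGTACGTACGTACGTACGT"))
  expect_equal(map_reads_to_sequences(r2, targets)$status, "multi")
  # three mismatches fail at the default limit of 2, pass at 3
  mut <- "TTTTGGGGCCCCAAAATTTT"
  substr(mut, 1, 1) <- "A"; substr(mut, 5, 5) <- "A"; substr(mut, 9, 9) <- "A"
  r3 <- Biostrings::DNAStringSet(c(c = mut))
  expect_equal(map_reads_to_sequences(r3, targets, 2L)$status, "unmapped")
  expect_equal(map_reads_to_sequences(r3, targets, 3L)$status, "mapped")
  expect_equal(map_reads_to_sequences(r3, targets, 3L)$mismatches, 3L)
  # an N position counts against the budget even over a matching base
  rn <- Biostrings::DNAStringSet(c(d = "NTTTGGGGCCCCAAAATTTT"))
  expect_equal(map_reads_to_sequences(rn, targets, 0L)$status, "unmapped")
  expect_equal(map_reads_to_sequences(rn, targets, 1L)$status, "mapped")
  # reverse-complement hits are found
  rc <- Biostrings::DNAStringSet(c(
    e = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("TTTTGGGGCCCCAAAATTTT")))))
  expect_equal(map_reads_to_sequences(rc, targets)$status, "mapped")
})

test_that("lenient rescue is monotone in the mismatch allowance", {
  ds <- small_sim()
  orph <- ds$orphans$reads
  r2 <- map_reads_to_sequences(orph, ds$genome, 2L)
  r6 <- map_reads_to_sequences(orph, ds$genome, 6L)
  mapped2 <- r2$read_id[r2$status == "mapped"]
  mapped6 <- r6$read_id[r6$status == "mapped"]
  expect_true(all(mapped2 %in% mapped6))
  expect_gte(length(mapped6), length(mapped2))
})

test_that("edited orphans are rescued at the planted rate", {
  ds <- small_sim()
  truth <- ds$orphans$truth
  res <- lenient_remap(ds$orphans$reads, ds$genome, 6L)
  rep <- merge(res$report, truth, by = "read_id")
  edited <- rep[rep$origin == "edited", ]
  # every edited read carries 3-6 substitutions: all rescuable at 6
  expect_true(all(edited$status == "mapped"))
  expect_true(all(edited$mismatches == edited$n_edits))
  # and none of them maps under the default 2-mismatch limit
  strict <- map_reads_to_sequences(
    ds$orphans$reads[truth$read_id[truth$origin == "edited"]],
    ds$genome, 2L)
  expect_true(all(strict$status == "unmapped"))
  # random sequences stay orphans even leniently
  rnd <- rep[rep$origin == "random", ]
  expect_true(all(rnd$status == "unmapped"))
  # overall rescue fraction equals the planted rescuable fraction
  expect_equal(res$fraction_rescued,
               mean(rep$status == "mapped"), tolerance = 1e-9)
})

test_that("junction-spanning orphans are recovered against the catalog", {
  ds <- small_sim()
  truth <- ds$orphans$truth
  jr <- truth$read_id[truth$origin == "junction" & truth$n_edits <= 2]
  rep <- map_reads_to_sequences(ds$orphans$reads[jr], ds$catalog$sequences, 2L)
  rep <- merge(rep, truth, by = "read_id")
  ok <- rep$status == "mapped" & rep$target == rep$source
  # every read with a unique source junction is recovered; reads whose
  # sequence happens to fit several junctions are discarded as multi
  expect_true(all(rep$status %in% c("mapped", "multi")))
  expect_gt(mean(ok), 0.8)
  expect_true(all(rep$mismatches[rep$status == "mapped"] <= 2L))
})
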