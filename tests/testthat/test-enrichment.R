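uniform_reads <- function(n, chrom_len, len = 25L, seed = 1,
                          sample_id = "s1", prep = "short") {
  set.seed(seed)
  st <- sample(chrom_len - len, n, replace = TRUE)
  r <- gr(st, st + len - 1L, sample(c("+", "-"), n, TRUE))
  r$sample_id <- sample_id; r$prep <- prep; r$read_length <- len
  r
}

test_that("uniform reads give enrichment ~1; concentrated reads scale as 1/f", {
  chrom_len <- 1e6
  # strand-agnostic category: the clean null where observed/expected is 1
  cat10 <- gr(100001, 200000, "*")  # 10% of the background
  reads <- uniform_reads(1e5, chrom_len)
  res <- category_enrichment(reads, cat10, "sense", chrom_len,
                             category = "tenth")
  # 99% binomial interval around 1: p = f, ratio sd ~ sqrt((1-p)/(n p))
  p <- 0.1
  half <- 2.58 * sqrt((1 - p) / (1e5 * p))
  expect_lt(abs(res$support_enrichment - 1), half)
  expect_lt(abs(res$span_enrichment - 1), 0.05)
  # a stranded category sees only the matching half of uniform reads
  res_s <- category_enrichment(reads, gr(100001, 200000, "+"), "sense",
                               chrom_len, category = "tenth")
  expect_lt(abs(res_s$support_enrichment - 0.5), half)

  # all reads inside a category occupying 10% of the background
  inside <- uniform_reads(5e3, 1e5)
  inside <- GenomicRanges::shift(inside, 100000L)
  BiocGenerics::strand(inside) <- "+"
  res2 <- category_enrichment(inside, gr(100001, 200000, "+"), "sense",
                              chrom_len, category = "tenth")
  expect_equal(res2$support_enrichment, 10)

  # zero qualifying reads
  res3 <- category_enrichment(inside, gr(100001, 200000, "+"), "antisense",
                              chrom_len, category = "tenth")
  expect_equal(res3$support_enrichment, 0)
  expect_equal(res3$span_enrichment, 0)
})

test_that("support enrichment equals a brute-force read classification", {
  set.seed(91)
  chrom_len <- 50000L
  cat <- gr(c(5001, 20001), c(8000, 26000), c("+", "-"))
  reads <- uniform_reads(2000, chrom_len, len = 30L, seed = 92)
  for (ori in c("sense", "antisense")) {
    res <- category_enrichment(reads, cat, ori, chrom_len, category = "x")
    # brute force: count reads overlapping a qualifying-strand feature by
    # >= 50% of their length
    n_q <- 0L
    for (i in seq_along(reads)) {
      rs <- as.character(BiocGenerics::strand(reads))[i]
      for (j in seq_along(cat)) {
        fs <- as.character(BiocGenerics::strand(cat))[j]
        ok_strand <- if (ori == "sense") rs == fs else rs != fs
        ov <- min(BiocGenerics::end(reads)[i], BiocGenerics::end(cat)[j]) -
          max(BiocGenerics::start(reads)[i], BiocGenerics::start(cat)[j]) + 1L
        if (ok_strand && ov >= 15L) { n_q <- n_q + 1L; break }
      }
    }
    f <- sum(BiocGenerics::width(cat)) / chrom_len
    expect_equal(res$support_enrichment, (n_q / 2000) / f, info = ori)
  }
})

test_that("antisense 3'UTR signal ranks above exon-wide antisense signal", {
  ds <- small_sim()
  long_reads <- do.call(c, unlist(lapply(ds$reads, function(x)
    x[c("long_total", "long_depleted")]), use.names = FALSE))
  res <- antisense_exonic_enrichment(long_reads, ds$ann)
  # planted antisense targets 3'UTRs only: in every read set the 3'UTR
  # enrichment exceeds the full-exonic enrichment, and 5'UTR is ~0
  for (k in split(res, paste(res$sample_id, res$prep))) {
    expect_gt(k$span_enrichment[k$category == "3'UTR"],
              k$span_enrichment[k$category == "exons"])
    expect_gt(k$support_enrichment[k$category == "3'UTR"],
              k$support_enrichment[k$category == "exons"])
    expect_equal(k$support_enrichment[k$category == "5'UTR"], 0)
  }
  # sense-only data yields zero antisense enrichment everywhere
  sense_only <- long_reads[!grepl("^anti", long_reads$source_id)]
  res0 <- antisense_exonic_enrichment(sense_only, ds$ann)
  expect_true(all(res0$support_enrichment == 0))
})

test_that("a repeat family planted at 2x uniform density is recovered", {
  set.seed(55)
  chrom_len <- 5e5
  # two families tiling distinct loci
  fam_a <- gr(seq(10001, 90001, by = 10000), seq(10300, 90300, by = 10000),
              "+", family = rep("SINE.SINE", 9))
  fam_b <- gr(seq(210001, 290001, by = 10000),
              seq(210300, 290300, by = 10000), "+",
              family = rep("LINE.L1", 9))
  repeats <- c(fam_a, fam_b)
  # uniform background plus an extra uniform dose over family A (sense),
  # doubling its local density
  bg <- uniform_reads(4e4, chrom_len, len = 25L, seed = 56)
  extra_n <- round(4e4 * sum(BiocGenerics::width(fam_a)) / chrom_len / 2)
  st <- unlist(lapply(seq_along(fam_a), function(i)
    sample(BiocGenerics::start(fam_a)[i]:(BiocGenerics::end(fam_a)[i] - 25L),
           ceiling(extra_n / length(fam_a)), replace = TRUE)))
  extra <- gr(st, st + 24L, "+")
  extra$sample_id <- "s1"; extra$prep <- "short"; extra$read_length <- 25L
  reads <- c(bg, extra)
  res <- repeat_family_enrichment(reads, repeats, "sense", chrom_len)
  ea <- res$support_enrichment[res$category == "SINE.SINE"]
  eb <- res$support_enrichment[res$category == "LINE.L1"]
  # background sense reads hit a family at rate f/2 (strand), planted
  # extra doubles family A; binomial check at 3 sigma
  f <- sum(BiocGenerics::width(fam_a)) / chrom_len
  expect_gt(ea, eb)
  expect_lt(abs(eb - 0.5), 3 * sqrt((1 - f / 2) / (length(reads) * f / 2)) / f * sqrt(f))
  expect_gt(ea, 0.9)  # ~0.5 background + ~0.5 planted
  expect_lt(ea, 1.2)
  # sorted by span enrichment descending
  expect_true(all(diff(res$span_enrichment) <= 0))
})

test_that("lincRNA loci attract no long-read enrichment in the default data", {
  ds <- small_sim()
  long_reads <- do.call(c, unlist(lapply(ds$reads, function(x)
    x[c("long_total", "long_depleted")]), use.names = FALSE))
  linc <- ds$ann$lincrnas
  for (ori in c("sense", "antisense")) {
    res <- category_enrichment(long_reads, linc, ori,
                               sum(ds$ann$chrom_sizes), category = "lincRNA")
    expect_equal(res$support_enrichment, 0, info = ori)
  }
})

test_that("pseudogene enrichment is positive and mirrored across preparations", {
  ds <- small_sim()
  bg <- sum(ds$ann$chrom_sizes)
  vals <- sapply(c("long_total", "long_depleted"), function(p) {
    r <- ds$reads$sample1[[p]]
    category_enrichment(r, ds$ann$pseudogenes, "sense", bg,
                        category = "pseudogene")$support_enrichment
  })
  expect_true(all(vals > 1))
  expect_lt(abs(vals[1] - vals[2]) / vals[1], 0.2)
})

test_that("antisense miRNA products are clustered by 5' end", {
  pre <- gr(6001, 6082, "+", name = "mir-X")
  mk_stack <- function(p5, n, len = 22L) {
    st <- p5 + sample(-1:1, n, replace = TRUE)
    r <- gr(st, st + len - 1L, "-")
    r$sample_id <- "s1"; r$prep <- "short"; r$read_length <- len
    r
  }
  set.seed(7)
  # 20 antisense 22-nt reads at one position -> one locus, one product
  one <- mk_stack(6010, 20)
  res <- detect_antisense_mirnas(one, pre)
  expect_equal(nrow(res), 1L)
  expect_equal(res$n_reads, 20L)
  # two well-separated stacks -> two products; counts match an exhaustive
  # 5'-end grouping oracle
  two <- c(mk_stack(6010, 12), mk_stack(6055, 9))
  res2 <- detect_antisense_mirnas(two, pre)
  expect_equal(nrow(res2), 2L)
  p5 <- ifelse(as.character(BiocGenerics::strand(two)) == "+",
               BiocGenerics::start(two), BiocGenerics::end(two))
  oracle_sizes <- sort(table(cut(p5, breaks = c(0, 6040, Inf))),
                       decreasing = TRUE)
  expect_equal(sort(res2$n_reads, decreasing = TRUE),
               as.integer(oracle_sizes))
  # sense-only reads at the precursor produce nothing
  sense <- mk_stack(6010, 20); BiocGenerics::strand(sense) <- "+"
  expect_equal(nrow(detect_antisense_mirnas(sense, pre)), 0L)
  # below min_reads: nothing
  expect_equal(nrow(detect_antisense_mirnas(mk_stack(6010, 4), pre)), 0L)
  # length window: 30-nt reads are not miRNA-like
  long_reads <- mk_stack(6010, 20, len = 30L)
  expect_equal(nrow(detect_antisense_mirnas(long_reads, pre)), 0L)
})

test_that("planted antisense-miRNA loci are recovered exactly per sample", {
  ds <- small_sim()
  planted <- unique(ds$truth$antisense_mirna$precursor)
  for (s in names(ds$reads)) {
    res <- detect_antisense_mirnas(ds$reads[[s]]$short, ds$ann$mirnas)
    expect_setequal(unique(res$precursor), planted)
    # product multiplicity matches the manifest
    got <- table(res$precursor)
    want <- table(ds$truth$antisense_mirna$precursor)
    expect_equal(as.integer(got[planted]), as.integer(want[planted]))
  }
})

test_that("miRNA arms are quantified separately and normalized to the reference", {
  arms <- gr(c(6005, 6057), c(6026, 6078), "+",
             name = c("mir-X", "mir-X"), arm = c("5p", "3p"))
  mk <- function(st, n, strand = "+") {
    r <- gr(st + seq_len(n) * 0L, st + 21L, strand)
    r$sample_id <- "s"; r$prep <- "short"; r$read_length <- 22L
    rep(r, n)[seq_len(n)]
  }
  # reads only over the 5p arm: 3p count 0
  r5 <- mk(6005, 8)
  q <- mirna_arm_quantification(r5, arms, ref_count = 2)
  expect_equal(q$count[q$arm == "5p"], 8L)
  expect_equal(q$count[q$arm == "3p"], 0L)
  expect_equal(q$norm_expression[q$arm == "5p"], 4)
  # equal reads on both arms: ratio 1
  q2 <- mirna_arm_quantification(c(mk(6005, 6), mk(6057, 6)), arms, 3)
  expect_equal(q2$count[q2$arm == "5p"], q2$count[q2$arm == "3p"])
  # 64x the reference count with equal lengths normalizes to 64
  q3 <- mirna_arm_quantification(mk(6005, 64), arms, 1)
  expect_equal(q3$norm_expression[q3$arm == "5p"], 64)
  # a read straddling both arms equally is ambiguous, assigned to neither
  straddle <- gr(6020, 6054, "+")
  straddle$sample_id <- "s"; straddle$prep <- "short"
  straddle$read_length <- BiocGenerics::width(straddle)
  equal_arms <- gr(c(6001, 6043), c(6031, 6073), "+",
                   name = c("m", "m"), arm = c("5p", "3p"))
  # overlap with both arms: 12 nt each
  q4 <- mirna_arm_quantification(straddle, equal_arms, 1)
  expect_equal(sum(q4$count), 0L)
  expect_equal(attr(q4, "n_ambiguous"), 1L)
  # antisense reads never count toward arm expression
  anti <- mk(6005, 5, strand = "-")
  q5 <- mirna_arm_quantification(anti, arms, 1)
  expect_equal(sum(q5$count), 0L)
})
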