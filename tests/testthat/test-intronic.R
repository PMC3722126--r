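dens_df <- function(sample_id, prep, density) {
  data.frame(sample_id = sample_id, prep = prep, density = density)
}

test_that("coverage islands are maximal depth>=1 runs above the span floor", {
  # 120 consecutively covered bases -> one island of span 120
  reads <- c(gr(1001, 1060), gr(1041, 1120))
  isl <- coverage_islands(reads, 100)
  expect_length(isl, 1L)
  expect_equal(BiocGenerics::width(isl), 120L)
  # 99 covered bases -> nothing
  expect_length(coverage_islands(gr(1, 99), 100), 0L)
  # a 1-nt gap breaks the run: 150 + 40 with a gap -> one island (the 150)
  reads <- c(gr(1, 150), gr(152, 191))
  isl <- coverage_islands(reads, 100)
  expect_length(isl, 1L)
  expect_equal(BiocGenerics::width(isl), 150L)
})

test_that("island caller agrees with a depth-mask oracle on random vectors", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    st <- sample(9500, n, replace = TRUE)
    reads <- gr(st, pmin(st + sample(17:59, n, TRUE), 10000L))
    min_span <- sample(c(30L, 100L), 1)
    isl <- coverage_islands(reads, min_span)
    oracle <- bf_islands(depth_vector(reads, 10000L), min_span)
    expect_equal(BiocGenerics::start(isl), oracle$start)
    expect_equal(BiocGenerics::end(isl), oracle$end)
  }
})

test_that("islands are clipped to the restriction space", {
  reads <- gr(101, 400)
  isl <- coverage_islands(reads, 50, within = gr(201, 300))
  expect_equal(BiocGenerics::start(isl), 201)
  expect_equal(BiocGenerics::end(isl), 300)
})

test_that("long detector applies density threshold and cross-sample union", {
  space <- gr(1001, 2000)
  mk <- function(sample, n, from, to) {
    st <- round(seq(from, to - 50, length.out = n))
    r <- gr(st, st + 49)
    r$sample_id <- sample; r$prep <- "long_total"; r$read_length <- 50L
    r
  }
  # sample1: island at 1101-1400 with 30 reads -> density 0.1 reads/nt
  r1 <- mk("s1", 30, 1101, 1400)
  # sample2: island at 1601-1900, only in sample2
  r2 <- mk("s2", 30, 1601, 1900)
  dens <- rbind(dens_df("s1", "long_total", 1), dens_df("s2", "long_total", 1))
  # reference density 1 read/nt: rel abundance 0.1 >= 1/1024 -> accepted
  res <- detect_long_intronic(c(r1, r2), space, dens)
  expect_length(res, 2L)
  expect_setequal(res$supporting_samples, c("s1", "s2"))
  expect_true(all(res$span >= 100))
  # same islands against a reference 1024x denser than the regions: rejected
  dens_hi <- rbind(dens_df("s1", "long_total", 205),
                   dens_df("s2", "long_total", 205))
  expect_length(detect_long_intronic(c(r1, r2), space, dens_hi), 0L)
  # overlapping islands from two samples merge into one region
  r3 <- mk("s2", 30, 1201, 1500)
  res2 <- detect_long_intronic(c(r1, r3), space, dens)
  expect_length(res2, 1L)
  expect_equal(res2$supporting_samples, "s1,s2")
  expect_equal(BiocGenerics::start(res2), 1101)
  expect_equal(BiocGenerics::end(res2), 1499)  # last read ends at 1499
})

test_that("short detector filters reads < 30 nt and keeps the 1/64 boundary", {
  space <- gr(1001, 2000)
  mk <- function(len, n, from, to, prep = "short") {
    st <- round(seq(from, to - len + 1, length.out = n))
    r <- gr(st, st + len - 1L)
    r$sample_id <- "s1"; r$prep <- prep; r$read_length <- len
    r
  }
  dens <- dens_df("s1", "short", 1)
  # 31-nt reads forming a 40-nt island above threshold
  res <- detect_short_intronic(mk(31L, 16, 1101, 1140), space, dens)
  expect_length(res, 1L)
  expect_equal(res$region_class, "short")
  # 25-nt reads only: filtered out entirely
  expect_length(detect_short_intronic(mk(25L, 16, 1101, 1140), space, dens),
                0L)
  # density exactly 1/64 of the reference is accepted (inclusive threshold)
  # 32-nt island covered by 1 read of 32 nt: density 1/32 vs reference 2
  one <- mk(32L, 1, 1101, 1132)
  res <- detect_short_intronic(one, space, dens_df("s1", "short", 2))
  expect_length(res, 1L)
  expect_equal(res$rel_abundance, 1 / 64)
  # and 1/64 of a barely larger reference is rejected
  expect_length(detect_short_intronic(one, space,
                                      dens_df("s1", "short", 2.01)), 0L)
})

test_that("long/short overlap counts long regions touching any short region", {
  long <- c(gr(100, 300), gr(500, 700), gr(900, 1100))
  short_disjoint <- gr(2000, 2040)
  expect_equal(long_short_overlap(long, short_disjoint), 0L)
  expect_equal(long_short_overlap(gr(100, 300), gr(100, 300)), 1L)
  # one short region overlapping two long regions -> 2 (brute force: the
  # pair list is {(1,s),(2,s)})
  short_two <- gr(250, 550)
  bf <- sum(vapply(seq_along(long), function(i)
    BiocGenerics::start(short_two) <= BiocGenerics::end(long[i]) &&
      BiocGenerics::end(short_two) >= BiocGenerics::start(long[i]),
    logical(1)))
  expect_equal(long_short_overlap(long, short_two), bf)
  expect_equal(bf, 2L)
  # strand-aware: antisense regions never pair
  expect_equal(long_short_overlap(gr(100, 300, "+"), gr(100, 300, "-")), 0L)
})

test_that("planted intronic regions are recovered; sub-threshold ones are not", {
  ds <- small_sim()
  isp <- ds$truth$intronic_space
  all_long <- do.call(c, unlist(lapply(ds$reads, function(x)
    x[c("long_total", "long_depleted")]), use.names = FALSE))
  all_short <- do.call(c, unname(lapply(ds$reads, function(x) x[["short"]])))
  dens_rows <- list()
  for (s in names(ds$reads)) for (p in names(ds$reads[[s]])) {
    r <- ds$reads[[s]][[p]]
    ref <- if (p == "short") ds$references$short else ds$references$long
    ex <- ds$ann$exons[ds$ann$exons$transcript_id == ref]
    dens_rows[[length(dens_rows) + 1L]] <- dens_df(
      s, p, count_transcript_reads(r, ex) / sum(BiocGenerics::width(ex)))
  }
  dens <- do.call(rbind, dens_rows)
  long_set <- detect_long_intronic(all_long, isp, dens[dens$prep != "short", ])
  short_set <- detect_short_intronic(all_short, isp,
                                     dens[dens$prep == "short", ])
  planted_long <- gr(ds$truth$long_regions$start, ds$truth$long_regions$end,
                     ds$truth$long_regions$strand)
  planted_short <- gr(ds$truth$short_regions$start,
                      ds$truth$short_regions$end,
                      ds$truth$short_regions$strand)
  hit_long <- GenomicRanges::countOverlaps(planted_long, long_set,
                                           ignore.strand = FALSE) > 0
  hit_short <- GenomicRanges::countOverlaps(planted_short, short_set,
                                            ignore.strand = FALSE) > 0
  expect_true(all(hit_long))
  expect_gte(mean(hit_short), 0.95)
  # no reported region overlaps any same-strand subtracted feature
  subtracted <- c(GenomicRanges::granges(ds$ann$exons),
                  GenomicRanges::granges(ds$ann$repeats),
                  GenomicRanges::granges(ds$ann$rrnas_snornas),
                  GenomicRanges::granges(ds$ann$mirnas),
                  GenomicRanges::granges(ds$ann$lincrnas))
  expect_length(GenomicRanges::findOverlaps(c(long_set, short_set), subtracted,
                                            ignore.strand = FALSE), 0L)
})

test_that("no regions are called when planted signal sits below half threshold", {
  space <- gr(1001, 3000)
  # reference density 1 read/nt; plant islands at 1/3000 < (1/1024)/2
  st <- round(seq(1101, 1500, length.out = 3))
  r <- gr(st, st + 49)
  r$sample_id <- "s1"; r$prep <- "long_total"; r$read_length <- 50L
  # 3 reads over ~450 nt of covered-ish span: any island is far below
  # half the 1/1024 threshold relative to a unit-density reference
  res <- detect_long_intronic(r, space, dens_df("s1", "long_total", 1))
  expect_length(res, 0L)
})
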