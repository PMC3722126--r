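#!/usr/bin/env Rscript
# Stage 4: novel intronic transcript discovery.
#
# Derives the bona fide intronic space (unspliced gene spans minus all
# same-strand annotated features), then calls coverage islands in it:
# long RNA requires 100 consecutive covered nucleotides at >= 1:1024 of
# the beta-actin analog's density; short RNA requires >= 30 nt reads,
# 30 nt span and >= 1:64 of the SNORD44 analog. Regions accepted in any
# read set are merged across samples.

suppressMessages(library(plateletseq))

ds <- read_dataset("results/data")
cfg <- read_config("results/data/config.yaml")

isp <- derive_intronic_space(ds$ann)
dens_rows <- list()
for (s in names(ds$reads)) for (p in names(ds$reads[[s]])) {
  ref <- if (p == "short") cfg$short_reference else cfg$long_reference
  ex <- ds$ann$exons[ds$ann$exons$transcript_id == ref]
  dens_rows[[length(dens_rows) + 1L]] <- data.frame(
    sample_id = s, prep = p,
    density = count_transcript_reads(ds$reads[[s]][[p]], ex) /
      sum(BiocGenerics::width(ex)))
}
dens <- do.call(rbind, dens_rows)
all_long <- do.call(c, unlist(lapply(ds$reads, function(x)
  x[c("long_total", "long_depleted")]), use.names = FALSE))
all_short <- do.call(c, unname(lapply(ds$reads, function(x) x[["short"]])))

long_set <- detect_long_intronic(
  all_long, isp, dens[dens$prep != "short", ],
  min_span = cfg$long_intronic_min_span,
  min_rel_abundance = cfg$long_intronic_min_rel_abundance)
short_set <- detect_short_intronic(
  all_short, isp, dens[dens$prep == "short", ],
  min_read_length = cfg$short_intronic_min_read_length,
  min_span = cfg$short_intronic_min_span,
  min_rel_abundance = cfg$short_intronic_min_rel_abundance)
write_novel_regions(c(long_set, short_set), "results/novel_intronic.tsv")

message("intronic space: ", length(isp), " intervals, ",
        sum(BiocGenerics::width(isp)), " nt across ",
        length(unique(isp$gene_id)), " genes")
message("novel regions: ", length(long_set), " long, ",
        length(short_set), " short, ",
        long_short_overlap(long_set, short_set), " in common")
tl <- ds$truth$long_regions
planted <- GenomicRanges::GRanges(tl$chrom,
                                  IRanges::IRanges(tl$start, tl$end),
                                  strand = tl$strand)
message("planted long regions recovered: ",
        sum(GenomicRanges::countOverlaps(planted, long_set,
                                         ignore.strand = FALSE) > 0),
        "/", nrow(tl))
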