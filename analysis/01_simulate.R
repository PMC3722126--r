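#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emulates the study design: four donors, each sequenced as long RNA from
# total and rRNA-depleted preparations plus a short RNA preparation, with
# a ground-truth manifest (planted expression densities spanning >= 16
# log2 units, depletion distortion factors, novel intronic regions,
# antisense signal, pseudogene transcription, orphan reads). Everything
# downstream re-reads this dataset from disk, so each stage is re-runnable
# in isolation.

suppressMessages(library(plateletseq))

seed <- 1L
out_dir <- "results/data"

message("simulating 4 samples x 3 preparations (seed ", seed, ") ...")
ds <- simulate_platelet_dataset(
  n_samples = 4L, reads_per_long_prep = 1e5, reads_per_short_prep = 5e4,
  seed = seed)
write_dataset(ds, out_dir)
write_config(platelet_config(seed = seed), file.path(out_dir, "config.yaml"))

n_reads <- sum(vapply(ds$reads, function(x)
  sum(vapply(x, length, integer(1))), integer(1)))
message("wrote ", out_dir, ": ",
        nrow(ds$ann$transcripts), " transcripts, ",
        n_reads, " mapped reads, ",
        length(ds$orphans$reads), " orphan reads, ",
        nrow(ds$catalog$junctions), " junctions in the catalog")
message("planted: ", nrow(ds$truth$long_regions), " long + ",
        nrow(ds$truth$short_regions), " short intronic regions; ",
        sum(ds$truth$transcripts$distortion != 1),
        " depletion-distorted genes; ",
        length(unique(ds$truth$antisense_mirna$precursor)),
        " antisense-miRNA loci")
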