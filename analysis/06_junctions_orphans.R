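#!/usr/bin/env Rscript
# Stage 6: orphan reads, lenient rescue, and exon-exon junctions.
#
# Re-enumerates the per-gene exon-exon junction catalog from the
# annotation and genome, then accounts for the orphan reads: lenient
# re-mapping against the genome (<= 6 substitutions), junction-catalog
# mapping under the default limit (<= 2), multi-mapper discard.

suppressMessages(library(plateletseq))

ds <- read_dataset("results/data")
cfg <- read_config("results/data/config.yaml")

catalog <- enumerate_junctions(ds$ann, ds$genome, flank = 49L)
message("junction catalog: ", nrow(catalog$junctions), " junctions from ",
        length(unique(catalog$junctions$gene_id)), " genes")

orph <- ds$orphans$reads
lenient <- lenient_remap(orph, ds$genome, cfg$max_mismatches_lenient)
jmap <- map_reads_to_sequences(orph, catalog$sequences,
                               cfg$max_mismatches_default)
report <- merge(lenient$report, jmap, by = "read_id",
                suffixes = c("_genome6", "_junction2"))
report <- merge(report, ds$orphans$truth, by = "read_id")
write.table(report, "results/orphan_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("lenient genome rescue: %d/%d orphans (%.1f%%)",
                lenient$n_rescued, length(orph),
                100 * lenient$fraction_rescued))
by_origin <- table(report$origin,
                   report$status_junction2 == "mapped" |
                     report$status_junction2 == "multi")
message("junction-catalog hits by origin:")
print(by_origin)
edited <- subset(report, origin == "edited")
message("edited orphans rescued leniently: ",
        sum(edited$status_genome6 == "mapped"), "/", nrow(edited))
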