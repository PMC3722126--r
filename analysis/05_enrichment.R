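#!/usr/bin/env Rscript
# Stage 5: sense/antisense category enrichment.
#
# Scores antisense transcription over 5'UTRs, 3'UTRs and exons of
# protein-coding genes (long RNA), per-family repeat enrichment in both
# orientations, pseudogene and lincRNA enrichment, antisense-miRNA locus
# detection, and per-arm (5p/3p) miRNA quantification against the short
# reference.

suppressMessages(library(plateletseq))

ds <- read_dataset("results/data")
cfg <- read_config("results/data/config.yaml")
bg <- sum(ds$ann$chrom_sizes)

all_long <- do.call(c, unlist(lapply(ds$reads, function(x)
  x[c("long_total", "long_depleted")]), use.names = FALSE))
anti <- antisense_exonic_enrichment(
  all_long, ds$ann, min_overlap_frac = cfg$antisense_min_overlap_frac)
write.table(anti, "results/antisense_exonic_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rep_rows <- list(); cat_rows <- list(); mirna_rows <- list(); arm_rows <- list()
for (s in names(ds$reads)) {
  for (p in names(ds$reads[[s]])) {
    r <- ds$reads[[s]][[p]]
    for (ori in c("sense", "antisense")) {
      fe <- repeat_family_enrichment(r, ds$ann$repeats, ori, bg,
                                     min_overlap_frac = cfg$antisense_min_overlap_frac)
      if (!is.null(fe) && nrow(fe)) {
        fe$sample_id <- s; fe$prep <- p
        rep_rows[[length(rep_rows) + 1L]] <- fe
      }
    }
    for (track in c("pseudogenes", "lincrnas")) {
      ce <- category_enrichment(r, ds$ann[[track]], "sense", bg,
                                category = track)
      ce$sample_id <- s; ce$prep <- p
      cat_rows[[length(cat_rows) + 1L]] <- ce
    }
  }
  am <- detect_antisense_mirnas(ds$reads[[s]]$short, ds$ann$mirnas,
                                length_window = cfg$mirna_length_window,
                                min_reads = cfg$mirna_min_reads,
                                max_shift = cfg$mirna_max_shift)
  if (nrow(am)) { am$sample_id <- s; mirna_rows[[s]] <- am }
  ref_ex <- ds$ann$exons[ds$ann$exons$transcript_id == cfg$short_reference]
  cref <- count_transcript_reads(ds$reads[[s]]$short, ref_ex)
  ma <- mirna_arm_quantification(ds$reads[[s]]$short, ds$ann$mirna_mature,
                                 cref)
  ma$sample_id <- s
  arm_rows[[s]] <- ma
}
write.table(do.call(rbind, rep_rows), "results/repeat_family_enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, cat_rows), "results/category_enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, mirna_rows), "results/antisense_mirna.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, arm_rows), "results/mirna_arms.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

u3 <- subset(anti, category == "3'UTR")
message("mean antisense 3'UTR span enrichment: ",
        round(mean(u3$span_enrichment), 2))
fam <- ds$truth$manifest$antisense_repeat_family
fe <- do.call(rbind, rep_rows)
fam_short <- subset(fe, category == fam & prep == "short" &
                      sample_id == names(ds$reads)[1])
message("planted family ", fam, " (sample1, short): antisense support ",
        round(fam_short$support_enrichment[2], 1), " vs sense ",
        round(fam_short$support_enrichment[1], 3))
message("antisense-miRNA loci found: ",
        length(unique(do.call(rbind, mirna_rows)$precursor)), " precursors")
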