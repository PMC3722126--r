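#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' the log2 presence floor for protein-coding calls (-15, i.e. 1/32768
#' of the reference), the depletion-impact abundance floor (2^-10) and
#' flagging ratio (1 log2 unit, i.e. 2-fold), the long novel-intronic
#' rules (span 100 nt, abundance 1:1024 of the long reference), the
#' short rules (read length 30 nt, span 30 nt, abundance 1:64 of the
#' short reference), the default and lenient mismatch limits (2 and 6),
#' the miRNA product length window (18-25 nt) and minimum read support
#' (5), the antisense overlap fraction (0.5), and the reference
#' transcript ids.
#'
#' @param long_reference,short_reference normalizer transcript ids.
#' @param presence_floor_log2 log2(ne) floor for presence calls.
#' @param depletion_min_abundance,depletion_min_abs_log2_ratio depletion
#'   module thresholds.
#' @param long_intronic_min_span,long_intronic_min_rel_abundance long
#'   novel-region rules.
#' @param short_intronic_min_read_length,short_intronic_min_span,short_intronic_min_rel_abundance
#'   short novel-region rules.
#' @param max_mismatches_default,max_mismatches_lenient mapping limits.
#' @param mirna_length_window,mirna_min_reads,mirna_max_shift
#'   antisense-miRNA clustering parameters.
#' @param antisense_min_overlap_frac minimum read-overlap fraction for
#'   orientation calls.
#' @param seed RNG seed recorded with every report.
#' @return list of class `platelet_config`.
#' @export
platelet_config <- function(long_reference = "TXREF_LONG",
                            short_reference = "TXREF_SHORT",
                            presence_floor_log2 = -15,
                            depletion_min_abundance = 2^-10,
                            depletion_min_abs_log2_ratio = 1,
                            long_intronic_min_span = 100L,
                            long_intronic_min_rel_abundance = 1 / 1024,
                            short_intronic_min_read_length = 30L,
                            short_intronic_min_span = 30L,
                            short_intronic_min_rel_abundance = 1 / 64,
                            max_mismatches_default = 2L,
                            max_mismatches_lenient = 6L,
                            mirna_length_window = c(18L, 25L),
                            mirna_min_reads = 5L,
                            mirna_max_shift = 3L,
                            antisense_min_overlap_frac = 0.5,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "platelet_config"
  cfg
}

#' Serialize / restore a configuration
#'
#' Configurations round-trip through YAML unchanged.
#'
#' @param config a [platelet_config()].
#' @param path file path.
#' @return `read_config` returns the restored `platelet_config`.
#' @export
write_config <- function(config, path) {
  # full double precision so thresholds like 2^-10 survive the round-trip
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  int_fields <- c("long_intronic_min_span", "short_intronic_min_read_length",
                  "short_intronic_min_span", "max_mismatches_default",
                  "max_mismatches_lenient", "mirna_length_window",
                  "mirna_min_reads", "mirna_max_shift", "seed")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  class(cfg) <- "platelet_config"
  cfg
}

config_hash <- function(config) rlang::hash(unclass(config))

write_report <- function(df, path, config, notes = character(0)) {
  con <- file(path, "w")
  writeLines(c(sprintf("# config_hash: %s", config_hash(config)),
               sprintf("# %s", notes)), con)
  close(con)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE,
                                      append = TRUE))
  invisible(path)
}

# reference read density (c_ref / L_ref) for one read set
reference_density <- function(reads, ann, reference_id) {
  ex <- ann$exons[ann$exons$transcript_id == reference_id]
  if (length(ex) == 0L) {
    stop("reference transcript '", reference_id, "' absent", call. = FALSE)
  }
  c_ref <- count_transcript_reads(reads, ex)
  if (c_ref == 0L) {
    stop("reference transcript has zero reads in this read set", call. = FALSE)
  }
  c_ref / sum(BiocGenerics::width(ex))
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage over all samples and preparations of an
#' in-memory dataset (as produced by [simulate_platelet_dataset()] or
#' assembled from files with [load_annotation()] / [load_reads()] /
#' [read_orphans()]) and writes the report tables to `out_dir`:
#'
#' 1. `mapping_summary.tsv` — read accounting per read set
#' 2. `transcript_expression.tsv` — per-transcript `ne` values
#' 3. `expression_curves.tsv` — expressed-gene counts vs threshold
#' 4. `depletion_impact.tsv` and `depletion_ranges.tsv`
#' 5. `novel_intronic.tsv` — long and short novel regions
#' 6. `antisense_exonic_enrichment.tsv`
#' 7. `repeat_family_enrichment.tsv`
#' 8. `antisense_mirna.tsv` and `mirna_arms.tsv`
#' 9. `orphan_summary.tsv`
#'
#' Every table carries the configuration hash in a header comment; the
#' run is deterministic given the inputs and the config.
#'
#' @param dataset list with `ann`, `reads` (`sample -> prep -> GRanges`),
#'   and optionally `genome`, `orphans` (`list(reads=DNAStringSet)`),
#'   `catalog` (from [enumerate_junctions()]).
#' @param config a [platelet_config()].
#' @param out_dir report directory (created).
#' @return invisibly, a list with every computed table.
#' @export
run_pipeline <- function(dataset, config = platelet_config(), out_dir) {
  stopifnot(methods::is(dataset$ann, "AnnotationSet"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- dataset$ann
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  res <- list()

  res$mapping_summary <- stage("mapping_summary", {
    rows <- list()
    for (s in names(dataset$reads)) for (p in names(dataset$reads[[s]])) {
      r <- dataset$reads[[s]][[p]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, prep = p, n_reads = length(r),
        n_length_rejected = S4Vectors::metadata(r)$n_rejected %||% 0L,
        mean_read_length = round(mean(r$read_length), 2))
    }
    do.call(rbind, rows)
  })
  write_report(res$mapping_summary,
               file.path(out_dir, "mapping_summary.tsv"), config)

  res$expression <- stage("expression", {
    rows <- list()
    for (s in names(dataset$reads)) for (p in names(dataset$reads[[s]])) {
      r <- dataset$reads[[s]][[p]]
      ref <- if (p == "short") config$short_reference else
        config$long_reference
      bt <- if (p == "short") c("snoRNA", "miRNA_precursor") else
        "protein_coding"
      rows[[length(rows) + 1L]] <- transcript_expression(r, ann, ref, bt)
    }
    do.call(rbind, rows)
  })
  write_report(res$expression,
               file.path(out_dir, "transcript_expression.tsv"), config)

  res$curves <- stage("expression_curves", {
    rows <- list()
    expr <- res$expression
    for (s in unique(expr$sample_id)) {
      for (p in setdiff(unique(expr$prep), "short")) {
        e <- expr[expr$sample_id == s & expr$prep == p &
                    expr$biotype == "protein_coding", ]
        if (nrow(e) == 0L) next
        ge <- gene_expression(e)
        cv <- expression_curve(stats::setNames(ge$ne, ge$gene_id),
                               seq(0, config$presence_floor_log2, by = -1))
        cv$sample_id <- s; cv$prep <- p
        rows[[length(rows) + 1L]] <- cv
      }
    }
    do.call(rbind, rows)
  })
  write_report(res$curves, file.path(out_dir, "expression_curves.tsv"),
               config)

  res$depletion <- stage("depletion", {
    per_sample <- list()
    expr <- res$expression
    for (s in unique(expr$sample_id)) {
      et <- expr[expr$sample_id == s & expr$prep == "long_total" &
                   expr$biotype == "protein_coding", ]
      ed <- expr[expr$sample_id == s & expr$prep == "long_depleted" &
                   expr$biotype == "protein_coding", ]
      if (nrow(et) == 0L || nrow(ed) == 0L) next
      gt <- gene_expression(et); gd <- gene_expression(ed)
      per_sample[[s]] <- depletion_impact(
        stats::setNames(gt$ne, gt$gene_id),
        stats::setNames(gd$ne, gd$gene_id),
        min_abundance = config$depletion_min_abundance,
        min_abs_log2_ratio = config$depletion_min_abs_log2_ratio)
    }
    per_sample
  })
  dep_all <- do.call(rbind, lapply(names(res$depletion), function(s) {
    d <- res$depletion[[s]]
    if (nrow(d) == 0L) return(NULL)
    d$sample_id <- s
    d
  }))
  write_report(dep_all, file.path(out_dir, "depletion_impact.tsv"), config)
  res$depletion_ranges <- depletion_range_table(res$depletion)
  write_report(res$depletion_ranges,
               file.path(out_dir, "depletion_ranges.tsv"), config)

  res$novel_intronic <- stage("novel_intronic", {
    intronic_space <- derive_intronic_space(ann)
    long_reads <- list(); short_reads <- list()
    dens_rows <- list()
    for (s in names(dataset$reads)) for (p in names(dataset$reads[[s]])) {
      r <- dataset$reads[[s]][[p]]
      ref <- if (p == "short") config$short_reference else
        config$long_reference
      dens_rows[[length(dens_rows) + 1L]] <- data.frame(
        sample_id = s, prep = p,
        density = reference_density(r, ann, ref))
      if (p == "short") short_reads[[length(short_reads) + 1L]] <- r
      else long_reads[[length(long_reads) + 1L]] <- r
    }
    dens <- do.call(rbind, dens_rows)
    long_set <- detect_long_intronic(
      do.call(c, long_reads), intronic_space,
      dens[dens$prep != "short", ],
      min_span = config$long_intronic_min_span,
      min_rel_abundance = config$long_intronic_min_rel_abundance)
    short_set <- detect_short_intronic(
      do.call(c, short_reads), intronic_space,
      dens[dens$prep == "short", ],
      min_read_length = config$short_intronic_min_read_length,
      min_span = config$short_intronic_min_span,
      min_rel_abundance = config$short_intronic_min_rel_abundance)
    list(long = long_set, short = short_set,
         n_common = long_short_overlap(long_set, short_set))
  })
  write_novel_regions(c(res$novel_intronic$long, res$novel_intronic$short),
                      file.path(out_dir, "novel_intronic.tsv"))

  res$antisense_exonic <- stage("antisense_exonic", {
    long_reads <- do.call(c, unlist(lapply(dataset$reads, function(x)
      x[setdiff(names(x), "short")]), use.names = FALSE))
    antisense_exonic_enrichment(
      long_reads, ann,
      min_overlap_frac = config$antisense_min_overlap_frac)
  })
  enrichment_note <- paste(
    "enrichment = observed/expected with expected fraction =",
    "category_span / background_span (summed chromosome lengths);",
    "span numerator uses covered bases, support numerator uses read counts")
  write_report(res$antisense_exonic,
               file.path(out_dir, "antisense_exonic_enrichment.tsv"), config,
               notes = enrichment_note)

  res$repeat_enrichment <- stage("repeat_enrichment", {
    rows <- list()
    bg <- sum(ann$chrom_sizes)
    for (s in names(dataset$reads)) for (p in names(dataset$reads[[s]])) {
      r <- dataset$reads[[s]][[p]]
      for (ori in c("sense", "antisense")) {
        fe <- repeat_family_enrichment(
          r, ann$repeats, ori, bg,
          min_overlap_frac = config$antisense_min_overlap_frac)
        if (is.null(fe) || nrow(fe) == 0L) next
        fe$sample_id <- s; fe$prep <- p
        rows[[length(rows) + 1L]] <- fe
      }
    }
    do.call(rbind, rows)
  })
  write_report(res$repeat_enrichment,
               file.path(out_dir, "repeat_family_enrichment.tsv"), config,
               notes = enrichment_note)

  res$antisense_mirna <- stage("antisense_mirna", {
    rows <- list()
    for (s in names(dataset$reads)) {
      r <- dataset$reads[[s]][["short"]]
      if (is.null(r)) next
      am <- detect_antisense_mirnas(r, ann$mirnas,
                                    length_window = config$mirna_length_window,
                                    min_reads = config$mirna_min_reads,
                                    max_shift = config$mirna_max_shift)
      if (nrow(am) == 0L) next
      am$sample_id <- s
      rows[[length(rows) + 1L]] <- am
    }
    do.call(rbind, rows)
  })
  write_report(res$antisense_mirna,
               file.path(out_dir, "antisense_mirna.tsv"), config)

  res$mirna_arms <- stage("mirna_arms", {
    rows <- list()
    for (s in names(dataset$reads)) {
      r <- dataset$reads[[s]][["short"]]
      if (is.null(r) || length(ann$mirna_mature) == 0L) next
      ref_ex <- ann$exons[ann$exons$transcript_id == config$short_reference]
      cref <- count_transcript_reads(r, ref_ex)
      ma <- mirna_arm_quantification(r, ann$mirna_mature, cref)
      ma$sample_id <- s
      rows[[length(rows) + 1L]] <- ma
    }
    do.call(rbind, rows)
  })
  write_report(res$mirna_arms, file.path(out_dir, "mirna_arms.tsv"), config)

  res$orphans <- stage("orphans", {
    if (is.null(dataset$orphans) || is.null(dataset$genome)) return(NULL)
    orph <- dataset$orphans$reads
    lenient <- lenient_remap(orph, dataset$genome,
                             config$max_mismatches_lenient)
    jmap <- if (!is.null(dataset$catalog)) {
      map_reads_to_sequences(orph, dataset$catalog$sequences,
                             config$max_mismatches_default)
    } else NULL
    data.frame(
      n_orphans = length(orph),
      n_rescued_lenient = lenient$n_rescued,
      frac_rescued_lenient = round(lenient$fraction_rescued, 4),
      n_mapped_junctions = if (!is.null(jmap))
        sum(jmap$status == "mapped") else NA_integer_,
      n_multi_junctions = if (!is.null(jmap))
        sum(jmap$status == "multi") else NA_integer_)
  })
  if (!is.null(res$orphans)) {
    write_report(res$orphans, file.path(out_dir, "orphan_summary.tsv"),
                 config)
  }

  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
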