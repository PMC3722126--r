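#' Distortion of abundance estimates by rRNA depletion
#'
#' Compares gene-level normalized expression between the total and the
#' rRNA-depleted long-RNA preparations of one sample. A gene is evaluated
#' when its abundance reaches `min_abundance` (default `2^-10` of the
#' reference) in at least one preparation and is non-zero in both; it is
#' flagged as depletion-affected when the absolute log2 ratio of its
#' normalized expression between the preparations is at least
#' `min_abs_log2_ratio` (default 1, i.e. a >= 2-fold change). Genes with
#' zero expression in exactly one preparation cannot be given a finite
#' ratio and are reported separately as dropouts.
#'
#' @param gene_ne_total,gene_ne_depleted named numeric vectors of
#'   gene-level `ne` (same normalization scheme).
#' @param min_abundance abundance floor relative to the reference.
#' @param min_abs_log2_ratio flagging threshold in log2 units.
#' @return data.frame with `gene_id`, `ne_total`, `ne_depleted`,
#'   `log2_ratio = log2(ne_total/ne_depleted)`, `flagged`, `floor_met_in`
#'   (`"total"`, `"depleted"` or `"both"`), sorted by `|log2_ratio|`
#'   descending. Dropout genes (zero in exactly one preparation, floor
#'   met in the other) are attached as `attr(x, "dropouts")`.
#' @export
depletion_impact <- function(gene_ne_total, gene_ne_depleted,
                             min_abundance = 2^-10,
                             min_abs_log2_ratio = 1) {
  genes <- intersect(names(gene_ne_total), names(gene_ne_depleted))
  if (length(genes) == 0L) {
    warning("no genes shared between the two preparations")
    return(structure(data.frame(gene_id = character(0), ne_total = numeric(0),
                                ne_depleted = numeric(0), log2_ratio = numeric(0),
                                flagged = logical(0), floor_met_in = character(0)),
                     dropouts = data.frame()))
  }
  nt <- gene_ne_total[genes]
  nd <- gene_ne_depleted[genes]
  floor_ok <- nt >= min_abundance | nd >= min_abundance

  dropout <- floor_ok & xor(nt == 0, nd == 0)
  dropouts <- data.frame(gene_id = genes[dropout],
                         ne_total = unname(nt[dropout]),
                         ne_depleted = unname(nd[dropout]),
                         stringsAsFactors = FALSE)

  eval_ok <- floor_ok & nt > 0 & nd > 0
  lr <- log2(nt[eval_ok] / nd[eval_ok])
  out <- data.frame(
    gene_id = genes[eval_ok],
    ne_total = unname(nt[eval_ok]),
    ne_depleted = unname(nd[eval_ok]),
    log2_ratio = unname(lr),
    flagged = unname(abs(lr) >= min_abs_log2_ratio),
    floor_met_in = ifelse(nt[eval_ok] >= min_abundance &
                            nd[eval_ok] >= min_abundance, "both",
                          ifelse(nt[eval_ok] >= min_abundance,
                                 "total", "depleted")),
    stringsAsFactors = FALSE
  )
  out <- out[order(-abs(out$log2_ratio), out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "dropouts") <- dropouts
  out
}

#' Per-gene range of depletion log-ratios across samples
#'
#' Summarises depletion impact over several samples in the style of a
#' "range of estimate ratios (log-scale)" table: for each gene, the
#' minimum and maximum log2 ratio observed across samples.
#'
#' @param records named list of [depletion_impact()] data.frames, one per
#'   sample.
#' @param gene_ids optionally restrict to these genes.
#' @return data.frame `gene_id`, `min_log2_ratio`, `max_log2_ratio`,
#'   `n_samples`.
#' @export
depletion_range_table <- function(records, gene_ids = NULL) {
  all <- do.call(rbind, lapply(names(records), function(s) {
    r <- records[[s]]
    if (nrow(r) == 0L) return(NULL)
    data.frame(gene_id = r$gene_id, log2_ratio = r$log2_ratio,
               sample_id = s, stringsAsFactors = FALSE)
  }))
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(gene_id = character(0), min_log2_ratio = numeric(0),
                      max_log2_ratio = numeric(0), n_samples = integer(0)))
  }
  if (!is.null(gene_ids)) all <- all[all$gene_id %in% gene_ids, ]
  sp <- split(all$log2_ratio, all$gene_id)
  data.frame(
    gene_id = names(sp),
    min_log2_ratio = vapply(sp, min, numeric(1)),
    max_log2_ratio = vapply(sp, max, numeric(1)),
    n_samples = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
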