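#' Annotated protein panel (e.g. the peroxisomal proteome)
#'
#' @param members Character vector of protein ids (unique).
#' @param is_pex Logical flag per member marking peroxins (PEX proteins);
#'   recycled if length 1.
#' @param source Free-text provenance tag.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(members, is_pex = FALSE, source = "user") {
  members <- as.character(members)
  if (anyDuplicated(members)) stop("annotation ids must be unique")
  is_pex <- rep_len(as.logical(is_pex), length(members))
  structure(list(members = members,
                 is_pex = stats::setNames(is_pex, members),
                 source = source),
            class = "annotation_set")
}

#' Restrict a differential table to an annotated panel
#'
#' Volcano-style panel view: the annotation members detected in the
#' condition's differential table, with -log10 p alongside the log2FC.
#'
#' @param diff A `differential_table` for one condition.
#' @param annotation An [annotation_set()].
#' @return data.frame: protein, log2fc, p_value, neg_log10_p, is_pex;
#'   attribute `n_detected` logs the detection count.
#' @export
subset_panel <- function(diff, annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  id_col <- if ("protein" %in% names(diff)) "protein" else "gene"
  keep <- diff[[id_col]] %in% annotation$members
  if (!any(keep))
    warning("no annotation member detected in the differential table")
  out <- diff[keep, , drop = FALSE]
  out <- data.frame(protein = out[[id_col]], log2fc = out$log2fc,
                    p_value = out$p_value,
                    neg_log10_p = -log10(out$p_value),
                    is_pex = unname(annotation$is_pex[out[[id_col]]]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_detected") <- nrow(out)
  attr(out, "condition") <- attr(diff, "condition")
  out
}

#' Cumulative PEX log2 fold change per condition
#'
#' Sums the signed log2FC of peroxin (PEX) proteins whose modulation call
#' is significant and transcription-independent for each condition;
#' non-significant changes contribute zero. Ups and downs can cancel in
#' the signed sum; `split_direction = TRUE` returns separate up/down sums
#' instead. `significant_only = FALSE` sums all detected PEX members
#' regardless of the call.
#'
#' @param calls `modulation_calls` pooled over conditions (carries
#'   log2fc).
#' @param annotation An [annotation_set()]; only members with `is_pex` are
#'   summed.
#' @param split_direction Return up/down sums separately.
#' @param significant_only Restrict to transcription-independent
#'   significant calls (default TRUE).
#' @return data.frame: condition, cumulative_log2fc (and up/down columns
#'   when split), n_contributing.
#' @export
cumulative_pex_log2fc <- function(calls, annotation,
                                  split_direction = FALSE,
                                  significant_only = TRUE) {
  stopifnot(inherits(annotation, "annotation_set"))
  pex <- names(annotation$is_pex)[annotation$is_pex]
  sel <- calls[calls$protein %in% pex, , drop = FALSE]
  if (significant_only)
    sel <- sel[sel$direction != "none" & sel$transcription_independent, ,
               drop = FALSE]
  conds <- unique(calls$condition)
  rows <- lapply(conds, function(cd) {
    s <- sel[sel$condition == cd, ]
    r <- data.frame(condition = cd,
                    cumulative_log2fc = sum(s$log2fc),
                    n_contributing = nrow(s))
    if (split_direction) {
      r$up_log2fc <- sum(s$log2fc[s$log2fc > 0])
      r$down_log2fc <- sum(s$log2fc[s$log2fc < 0])
    }
    r
  })
  do.call(rbind, rows)
}

#' Per-PEX regulator counts split by direction
#'
#' For each peroxin, counts the conditions with a significant
#' transcription-independent upregulation and downregulation call —
#' identifying the PEX proteins most commonly modulated across the
#' screen.
#'
#' @inheritParams cumulative_pex_log2fc
#' @return data.frame: protein, n_up, n_down (every PEX member reported,
#'   (0, 0) when never significant).
#' @export
pex_regulator_counts <- function(calls, annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  pex <- names(annotation$is_pex)[annotation$is_pex]
  sig <- calls[calls$protein %in% pex & calls$direction != "none" &
               calls$transcription_independent, , drop = FALSE]
  out <- data.frame(protein = pex,
                    n_up = vapply(pex, function(p)
                      sum(sig$protein == p & sig$direction == "up"), 0L),
                    n_down = vapply(pex, function(p)
                      sum(sig$protein == p & sig$direction == "down"), 0L),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-(out$n_up + out$n_down), out$protein), ]
}
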