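#' Experiment design for a multiplexed knockdown screen
#'
#' Describes a TMT-style screen layout: knockdown conditions (E2 names),
#' replicates per condition, in-set non-targeting controls, and the
#' assignment of conditions to multiplexed sets (batches). The default
#' layout mirrors a 16-plex set: 4 conditions x 3 replicates plus 4
#' controls per set.
#'
#' @param conditions Character vector of condition labels (e.g. E2 names).
#' @param n_proteins Number of proteins quantified.
#' @param batch_of Named character/integer vector mapping each condition to
#'   a batch id. If `NULL`, conditions are chunked 4-per-batch in order.
#' @param reps_per_condition Knockdown replicates per condition (>= 2).
#' @param controls_per_batch Control replicates per batch (>= 2).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(conditions, n_proteins, batch_of = NULL,
                              reps_per_condition = 3L,
                              controls_per_batch = 4L) {
  conditions <- as.character(conditions)
  if (length(conditions) < 1L || anyDuplicated(conditions))
    stop("'conditions' must be a non-empty set of unique labels")
  if (n_proteins < 1L) stop("'n_proteins' must be >= 1")
  if (reps_per_condition < 2L) stop("'reps_per_condition' must be >= 2")
  if (controls_per_batch < 2L) stop("'controls_per_batch' must be >= 2")
  if (is.null(batch_of)) {
    batch_of <- paste0("b", ceiling(seq_along(conditions) / 4))
    names(batch_of) <- conditions
  }
  batch_of <- vapply(batch_of, as.character, character(1))
  if (!setequal(names(batch_of), conditions) ||
      length(batch_of) != length(conditions))
    stop("every condition must map to exactly one batch")
  structure(
    list(conditions = conditions,
         n_proteins = as.integer(n_proteins),
         batch_of = batch_of[conditions],
         reps_per_condition = as.integer(reps_per_condition),
         controls_per_batch = as.integer(controls_per_batch),
         batches = unique(unname(batch_of[conditions]))),
    class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("experiment_design:", length(x$conditions), "conditions in",
      length(x$batches), "batch(es);",
      x$reps_per_condition, "reps/condition,",
      x$controls_per_batch, "controls/batch,",
      x$n_proteins, "proteins\n")
  invisible(x)
}

#' Ground-truth regulation layer for simulated screens
#'
#' Holds the true per-(condition, protein) effect sizes (log2 fold-change
#' units) injected into simulated proteome data, and the fraction of those
#' effects that are mirrored at the mRNA level.
#'
#' @param effects data.frame with columns `condition`, `protein`, `effect`
#'   (finite log2FC).
#' @param mrna_concordance Fraction of protein effects mirrored in mRNA,
#'   in `[0, 1]`.
#' @param design Optional `experiment_design`; if given, every condition in
#'   `effects` must appear in it.
#' @return An object of class `regulation_truth`.
#' @export
regulation_truth <- function(effects, mrna_concordance = 0.2, design = NULL) {
  stopifnot(is.data.frame(effects),
            all(c("condition", "protein", "effect") %in% names(effects)))
  if (nrow(effects) && !all(is.finite(effects$effect)))
    stop("effect sizes must be finite")
  if (mrna_concordance < 0 || mrna_concordance > 1)
    stop("'mrna_concordance' must be in [0, 1]")
  if (!is.null(design) && nrow(effects) &&
      !all(effects$condition %in% design$conditions))
    stop("effects reference conditions absent from the design")
  effects$condition <- as.character(effects$condition)
  effects$protein <- as.character(effects$protein)
  structure(list(effects = effects,
                 mrna_concordance = mrna_concordance),
            class = "regulation_truth")
}

#' Draw a random regulation truth, optionally with shared-target pairs
#'
#' Regulated proteins are sampled per condition. Condition pairs listed in
#' `shared_pairs` draw a fraction `shared_fraction` of their regulated
#' proteins, with identical signed effects, from a common pool — the
#' minimal mechanism producing graded proteome-response similarity between
#' designated pairs.
#'
#' @param design An `experiment_design`.
#' @param n_regulated Regulated proteins per condition.
#' @param effect_size Absolute log2FC of each effect (sign random unless
#'   shared).
#' @param shared_pairs Optional 2-column matrix/data.frame of condition
#'   pairs that share targets.
#' @param shared_fraction Fraction of each sharing condition's targets
#'   drawn from the pair's common pool.
#' @param mrna_concordance Passed to [regulation_truth()].
#' @param seed Integer RNG seed.
#' @return A `regulation_truth`.
#' @export
simulate_regulation_truth <- function(design, n_regulated = 100L,
                                      effect_size = 0.5,
                                      shared_pairs = NULL,
                                      shared_fraction = 0.5,
                                      mrna_concordance = 0.2,
                                      seed = 1L) {
  set.seed(seed)
  prot <- protein_ids(design$n_proteins)
  eff <- list()
  assigned <- stats::setNames(vector("list", length(design$conditions)),
                              design$conditions)
  if (!is.null(shared_pairs)) {
    shared_pairs <- as.matrix(shared_pairs)
    n_shared <- round(shared_fraction * n_regulated)
    for (k in seq_len(nrow(shared_pairs))) {
      pool <- sample(prot, n_shared)
      sgn <- sample(c(-1, 1), n_shared, replace = TRUE)
      for (cond in shared_pairs[k, ]) {
        eff[[length(eff) + 1L]] <- data.frame(
          condition = cond, protein = pool, effect = sgn * effect_size)
        assigned[[cond]] <- c(assigned[[cond]], pool)
      }
    }
  }
  for (cond in design$conditions) {
    n_own <- n_regulated - length(assigned[[cond]])
    if (n_own > 0L) {
      own <- sample(setdiff(prot, assigned[[cond]]), n_own)
      eff[[length(eff) + 1L]] <- data.frame(
        condition = cond, protein = own,
        effect = sample(c(-1, 1), n_own, replace = TRUE) * effect_size)
    }
  }
  effects <- do.call(rbind, eff)
  effects <- effects[!duplicated(effects[c("condition", "protein")]), ]
  regulation_truth(effects, mrna_concordance, design)
}

protein_ids <- function(n) sprintf("P%05d", seq_len(n))
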