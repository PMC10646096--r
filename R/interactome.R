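#' Length-normalise spectral counts
#'
#' Spectral counts scale with protein size, so counts are divided by the
#' protein's residue count ("counts per residue"). Raw counts are kept
#' alongside.
#'
#' @param table A [spectral_count_table()].
#' @return The input `counts` data.frame with a `norm_count` column
#'   (count / length).
#' @export
normalize_spectral_counts <- function(table) {
  stopifnot(inherits(table, "spectral_count_table"))
  counts <- table$counts
  if (!nrow(counts)) {
    counts$norm_count <- numeric(0)
    return(counts)
  }
  len <- table$lengths[counts$prey]
  if (anyNA(len)) stop("missing length for some prey")
  counts$norm_count <- counts$count / unname(len)
  counts
}

#' Interaction enrichment probability (Poisson mid-p score)
#'
#' Scores each prey observed with a bait for enrichment over the control
#' purifications. Counts are length-normalised, then rescaled to the
#' median prey length (and rounded to integer support). The control rate
#' lambda for a prey is the mean rescaled count over all control runs,
#' floored at `pseudo_rate` so that preys absent from controls are still
#' scored against a small background. Each bait replicate with rescaled
#' count x contributes the Poisson mid-p value
#' P(X < x) + 0.5 P(X = x), X ~ Poisson(lambda), and the score is the mean
#' over replicates; it lies in `[0, 1]` and is monotone non-decreasing in
#' every replicate count. A column of externally computed probabilities
#' (e.g. SAINT) can replace this score downstream — [filter_interactions()]
#' only consumes the `score` column.
#'
#' @param table A [spectral_count_table()].
#' @param bait Bait label with >= 1 run.
#' @param pseudo_rate Floor on the control rate, rescaled counts
#'   (default 0.1).
#' @return data.frame per prey: bait, prey, score, mean_norm_count,
#'   max_sc_bait, max_sc_control.
#' @export
enrichment_probability <- function(table, bait, pseudo_rate = 0.1) {
  stopifnot(inherits(table, "spectral_count_table"))
  bait_runs <- table$runs$run[table$runs$bait == bait]
  ctrl_runs <- table$runs$run[table$runs$bait == "CONTROL"]
  if (!length(bait_runs)) stop("bait '", bait, "' has no runs")
  if (!length(ctrl_runs)) stop("no control runs")
  counts <- table$counts
  preys <- unique(c(counts$prey[counts$run %in% c(bait_runs, ctrl_runs)],
                    if (bait %in% names(table$lengths)) bait))
  if (!length(preys))
    return(data.frame(bait = character(), prey = character(),
                      score = numeric(), mean_norm_count = numeric(),
                      max_sc_bait = numeric(), max_sc_control = numeric()))
  med_len <- stats::median(table$lengths[preys])
  cnt <- function(runs) {
    m <- matrix(0, length(preys), length(runs),
                dimnames = list(preys, runs))
    sel <- counts[counts$run %in% runs & counts$prey %in% preys, ]
    if (nrow(sel)) m[cbind(sel$prey, sel$run)] <- sel$count
    m
  }
  bc <- cnt(bait_runs); cc <- cnt(ctrl_runs)
  resc <- function(m) m / table$lengths[preys] * med_len
  x <- round(resc(bc))
  lambda <- pmax(rowMeans(resc(cc)), pseudo_rate)
  midp <- stats::ppois(x - 1, lambda) + 0.5 * stats::dpois(x, lambda)
  data.frame(bait = bait, prey = preys,
             score = rowMeans(midp),
             mean_norm_count = rowMeans(bc / table$lengths[preys]),
             max_sc_bait = apply(bc, 1, max),
             max_sc_control = apply(cc, 1, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score every bait in a spectral-count table
#'
#' @inheritParams enrichment_probability
#' @return Row-bound [enrichment_probability()] tables for all non-control
#'   baits.
#' @export
score_all_baits <- function(table, pseudo_rate = 0.1) {
  baits <- setdiff(unique(table$runs$bait), "CONTROL")
  do.call(rbind, lapply(baits, function(b)
    enrichment_probability(table, b, pseudo_rate)))
}

#' Contaminant detection frequency from control runs
#'
#' CRAPome-style frequency computed from a table's own control
#' purifications: for each prey, the fraction of control runs with a
#' nonzero count. Frequent control detections mark likely contaminants of
#' the affinity-purification process; feed the result to
#' [filter_interactions()] as `crapome`.
#'
#' @param table A [spectral_count_table()].
#' @return Named vector, prey -> frequency in `[0, 1]`.
#' @export
control_detection_freq <- function(table) {
  stopifnot(inherits(table, "spectral_count_table"))
  ctrl_runs <- table$runs$run[table$runs$bait == "CONTROL"]
  sel <- table$counts[table$counts$run %in% ctrl_runs &
                      table$counts$count > 0, ]
  preys <- unique(table$counts$prey)
  freq <- vapply(preys, function(p)
    length(unique(sel$run[sel$prey == p])) / length(ctrl_runs), 0)
  stats::setNames(freq, preys)
}

#' Filter scored interactions
#'
#' Keeps a (bait, prey) pair iff its probability score passes the
#' threshold (inclusive, mirroring a "score >= 0.65" rule), and
#' optionally: its contaminant frequency (fraction of control experiments
#' in a CRAPome-style table detecting the prey) is at most
#' `max_contaminant_freq`, and its maximum bait-run spectral count
#' strictly exceeds the maximum control-run count.
#'
#' @param scores data.frame from [score_all_baits()] (or with an external
#'   probability in `score`).
#' @param threshold Probability threshold in `[0, 1]` (default 0.65).
#' @param crapome Optional named vector, prey -> contaminant frequency in
#'   `[0, 1]`; preys absent from it are treated as frequency 0.
#' @param max_contaminant_freq Maximum tolerated contaminant frequency
#'   (only applied when `crapome` is given).
#' @param require_max_sc_excess If `TRUE`, additionally require
#'   max bait SC > max control SC (strict).
#' @return Edge list data.frame: bait, prey, score (+ contaminant_freq
#'   when `crapome` given), bait self-rows excluded.
#' @export
filter_interactions <- function(scores, threshold = 0.65, crapome = NULL,
                                max_contaminant_freq = 0.5,
                                require_max_sc_excess = FALSE) {
  if (threshold < 0 || threshold > 1) stop("'threshold' must be in [0, 1]")
  keep <- !is.na(scores$score) & scores$score >= threshold
  if (!is.null(crapome)) {
    freq <- crapome[scores$prey]
    freq[is.na(freq)] <- 0
    scores$contaminant_freq <- unname(freq)
    keep <- keep & scores$contaminant_freq <= max_contaminant_freq
  }
  if (require_max_sc_excess)
    keep <- keep & scores$max_sc_bait > scores$max_sc_control
  out <- scores[keep & scores$bait != scores$prey, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check that every bait is enriched in its own pull-down
#'
#' On well-formed data each FLAG-tagged bait is detected and significantly
#' enriched in its own runs; a bait whose self-score fails the threshold
#' indicates a degraded or failed purification. Returns the failures (an
#' empty data.frame means all baits pass).
#'
#' @param scores data.frame from [score_all_baits()].
#' @param bait_protein Optional named vector mapping bait label -> protein
#'   id; default: bait label is its own protein id.
#' @param threshold Probability threshold (default 0.65).
#' @return data.frame of failing baits: bait, self_score (NA when the bait
#'   protein was never scored in its own runs).
#' @export
bait_self_enrichment_check <- function(scores, bait_protein = NULL,
                                       threshold = 0.65) {
  baits <- unique(scores$bait)
  self_id <- if (is.null(bait_protein)) stats::setNames(baits, baits)
             else bait_protein
  rows <- lapply(baits, function(b) {
    hit <- scores[scores$bait == b & scores$prey == self_id[[b]], ]
    s <- if (nrow(hit)) hit$score[1] else NA_real_
    if (is.na(s) || s < threshold)
      data.frame(bait = b, self_score = s)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(bait = character(),
                                      self_score = numeric())
  out
}

#' Assemble the annotated interaction network
#'
#' Builds a node/edge representation of the filtered interactome with a
#' functional role per protein (UBL, E1, E2, E3, DUB, proteasome,
#' autophagy, other). Endpoints missing from the role table default to
#' "other" with a warning.
#'
#' @param edges Filtered edge list (bait, prey, score).
#' @param roles Optional data.frame (protein, role).
#' @return An `annotated_network`: list with `nodes` (id, role), `edges`,
#'   and `graph` (igraph object).
#' @export
build_network <- function(edges, roles = NULL) {
  ids <- unique(c(edges$bait, edges$prey))
  role <- rep("other", length(ids))
  if (!is.null(roles)) {
    idx <- match(ids, roles$protein)
    role[!is.na(idx)] <- roles$role[idx[!is.na(idx)]]
    if (anyNA(idx) && length(ids))
      warning(sum(is.na(idx)), " node(s) missing from the role table; ",
              "assigned role 'other'")
  }
  nodes <- data.frame(id = ids, role = role, stringsAsFactors = FALSE)
  g <- if (nrow(edges))
    igraph::graph_from_data_frame(
      edges[, c("bait", "prey", setdiff(names(edges), c("bait", "prey")))],
      directed = FALSE, vertices = nodes)
  else igraph::make_empty_graph(0, directed = FALSE)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "annotated_network")
}

#' Extract the E2-E2 cross-interaction subnetwork
#'
#' @param network An `annotated_network` from [build_network()].
#' @return Edge list restricted to pairs where both endpoints have role
#'   "E2".
#' @export
e2_cross_interactions <- function(network) {
  e2 <- network$nodes$id[network$nodes$role == "E2"]
  network$edges[network$edges$bait %in% e2 & network$edges$prey %in% e2, ,
                drop = FALSE]
}

#' @export
print.annotated_network <- function(x, ...) {
  cat("annotated_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  print(table(x$nodes$role))
  invisible(x)
}
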