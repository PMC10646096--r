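#' Proteins regulated by at least one knockdown
#'
#' The similarity analysis starts from proteins significantly modulated
#' (at the screen thresholds) by at least one condition.
#'
#' @param calls `modulation_calls` pooled over conditions.
#' @return Character vector of protein ids.
#' @export
select_regulated_union <- function(calls) {
  unique(calls$protein[calls$direction != "none"])
}

#' Squared correlation of two conditions' fold-change profiles
#'
#' Pearson R^2 over the proteins quantified in both conditions (after
#' restriction to `proteins`, if given). R^2 is sign-blind: perfectly
#' anti-correlated profiles also give 1. Comparisons with fewer than 3
#' shared proteins, or with a zero-variance vector, are undefined and
#' return NA.
#'
#' @param fc_a,fc_b Named numeric vectors of log2 fold changes.
#' @param proteins Optional protein id set to restrict the comparison to
#'   (typically the pair's regulated set).
#' @return list(r2, n_pair): `n_pair` is the number of proteins entering
#'   the comparison.
#' @export
pairwise_r2 <- function(fc_a, fc_b, proteins = NULL) {
  shared <- intersect(names(fc_a), names(fc_b))
  if (!is.null(proteins)) shared <- intersect(shared, proteins)
  a <- fc_a[shared]; b <- fc_b[shared]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r2 = NA_real_, n_pair = n))
  list(r2 = stats::cor(a, b)^2, n_pair = n)
}

#' Similarity score: R^2 weighted by comparison size
#'
#' S = R^2 x number of regulated proteins in the pairwise comparison, so
#' that strong correlations over many shared targets outrank equally
#' strong ones over few.
#'
#' @param r2 Squared correlation in `[0, 1]`.
#' @param n_pair Number of regulated proteins in the comparison.
#' @return S = r2 * n_pair.
#' @export
similarity_score <- function(r2, n_pair) {
  if (any(!is.na(r2) & (r2 < 0 | r2 > 1))) stop("'r2' must be in [0, 1]")
  if (any(n_pair < 0, na.rm = TRUE)) stop("'n_pair' must be >= 0")
  r2 * n_pair
}

#' Pairwise proteome-response similarity matrix
#'
#' For every condition pair, computes R^2 of the two log2FC profiles and
#' the similarity score S = R^2 x n over the pair's regulated protein set.
#' The set entering each comparison is controlled by `pair_universe`:
#' `"either"` (default) uses proteins regulated by at least one of the two
#' conditions, `"union"` the proteins regulated by any condition in the
#' screen, `"intersection"` those regulated by both.
#'
#' @param fc Matrix of log2 fold changes, proteins x conditions (e.g.
#'   column-bound [protein_differential()] `log2fc`), or a named list of
#'   vectors.
#' @param calls `modulation_calls` pooled over the same conditions.
#' @param pair_universe Regulated-set rule per pair (see above).
#' @return A `similarity_matrix` (kind `"score"`): list with `labels`,
#'   `r2`, `n_regulated`, `values` (the S matrix), `kind`.
#' @export
proteome_similarity <- function(fc, calls,
                                pair_universe = c("either", "union",
                                                  "intersection")) {
  pair_universe <- match.arg(pair_universe)
  if (is.list(fc) && !is.data.frame(fc)) {
    labels <- names(fc)
    get_fc <- function(cond) fc[[cond]]
  } else {
    labels <- colnames(fc)
    get_fc <- function(cond) stats::setNames(fc[, cond], rownames(fc))
  }
  reg <- lapply(labels, function(cond)
    unique(calls$protein[calls$condition == cond &
                         calls$direction != "none"]))
  names(reg) <- labels
  union_all <- unique(unlist(reg))
  k <- length(labels)
  r2m <- nm <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    set <- switch(pair_universe,
                  either = union(reg[[i]], reg[[j]]),
                  union = union_all,
                  intersection = intersect(reg[[i]], reg[[j]]))
    pr <- pairwise_r2(get_fc(labels[i]), get_fc(labels[j]), set)
    r2m[i, j] <- r2m[j, i] <- pr$r2
    nm[i, j] <- nm[j, i] <- pr$n_pair
  }
  similarity_matrix(similarity_score(r2m, nm), labels, kind = "score",
                    r2 = r2m, n_regulated = nm)
}

#' Construct a similarity matrix object
#'
#' @param values Symmetric numeric matrix (diagonal ignored).
#' @param labels Condition labels.
#' @param kind One of "r2", "score", "zscore".
#' @param r2,n_regulated,group_of Optional companion matrices.
#' @return A `similarity_matrix`.
#' @export
similarity_matrix <- function(values, labels, kind = c("score", "r2",
                                                       "zscore"),
                              r2 = NULL, n_regulated = NULL,
                              group_of = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  off <- values[upper.tri(values)]
  if (!isTRUE(all.equal(values, t(values))))
    stop("similarity matrix must be symmetric")
  if (kind == "r2" && any(off < -1e-12 | off > 1 + 1e-12, na.rm = TRUE))
    stop("r2 values must be in [0, 1]")
  dimnames(values) <- list(labels, labels)
  diag(values) <- NA_real_
  structure(list(values = values, labels = labels, kind = kind,
                 r2 = r2, n_regulated = n_regulated, group_of = group_of),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix (", x$kind, "): ", length(x$labels),
      " conditions\n", sep = "")
  invisible(x)
}

#' Batch-aware z-scores of pairwise similarity values
#'
#' Multiplexed proteomics shares more technical structure within a TMT set
#' than across sets, inflating similarity for intra-set pairs. Each pair
#' is therefore standardised against its own reference group: pairs whose
#' two conditions share a TMT set form one group per set ("intra-batch"),
#' and all remaining pairs pool into a single "extra-batch" group. The
#' z-score is (value - group mean) / group sample SD. Self-comparisons
#' (the diagonal) are excluded from every group. Groups with fewer than
#' two values, or zero SD, give NA.
#'
#' @param sim A `similarity_matrix` (any kind; typically the S matrix).
#' @param batch_of Named vector condition -> batch; `NULL` places every
#'   pair in one pooled group.
#' @return A `similarity_matrix` of kind `"zscore"` whose `group_of` is a
#'   character matrix of group labels; also carries `pairs`, a long
#'   data.frame (a, b, value, group, z).
#' @export
batch_zscores <- function(sim, batch_of = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"))
  labels <- sim$labels
  k <- length(labels)
  grp <- matrix(NA_character_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    grp[i, j] <- if (is.null(batch_of)) "all"
    else if (batch_of[[labels[i]]] == batch_of[[labels[j]]])
      paste0("intra:", batch_of[[labels[i]]])
    else "extra"
  }
  z <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  ut <- which(upper.tri(z), arr.ind = TRUE)
  vals <- sim$values[ut]
  groups <- grp[ut]
  for (g in unique(groups)) {
    idx <- which(groups == g & !is.na(vals))
    if (length(idx) < 2L) next
    m <- mean(vals[idx]); s <- stats::sd(vals[idx])
    if (s == 0) next
    zi <- (vals[idx] - m) / s
    z[ut[idx, , drop = FALSE]] <- zi
    z[ut[idx, c(2, 1), drop = FALSE]] <- zi
  }
  pairs <- data.frame(a = labels[ut[, 1]], b = labels[ut[, 2]],
                      value = vals, group = groups, z = z[ut],
                      stringsAsFactors = FALSE)
  out <- similarity_matrix(z, labels, kind = "zscore", group_of = grp)
  out$pairs <- pairs
  out
}

#' Interactome similarity between two baits
#'
#' Squared Pearson correlation of two baits' prey probability-score
#' vectors over the union of preys scored for either bait; a prey absent
#' from one bait's interactome scores 0 there. With fewer than 3 preys in
#' the union the fit is degenerate (two points always give R^2 = 1) and
#' the result is flagged.
#'
#' @param scores_a,scores_b Named vectors, prey -> probability.
#' @return list(r2, n_prey, degenerate).
#' @export
interactome_r2 <- function(scores_a, scores_b) {
  preys <- union(names(scores_a), names(scores_b))
  a <- stats::setNames(rep(0, length(preys)), preys)
  b <- a
  a[names(scores_a)] <- scores_a
  b[names(scores_b)] <- scores_b
  n <- length(preys)
  if (n < 2L || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r2 = NA_real_, n_prey = n, degenerate = TRUE))
  list(r2 = stats::cor(a, b)^2, n_prey = n, degenerate = n < 3L)
}

#' Pairwise interactome similarity matrix for all baits
#'
#' @param scores data.frame from [score_all_baits()] (bait, prey, score),
#'   usually pre-filtered.
#' @return A `similarity_matrix` of kind `"r2"`.
#' @export
interactome_similarity <- function(scores) {
  baits <- unique(scores$bait)
  vecs <- lapply(baits, function(b) {
    s <- scores[scores$bait == b, ]
    stats::setNames(s$score, s$prey)
  })
  names(vecs) <- baits
  k <- length(baits)
  r2m <- matrix(NA_real_, k, k, dimnames = list(baits, baits))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    r2m[i, j] <- r2m[j, i] <- interactome_r2(vecs[[i]], vecs[[j]])$r2
  }
  similarity_matrix(r2m, baits, kind = "r2")
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment over the amino-acid alphabet (20
#' letters plus X) with unit scoring: match +1, mismatch 0, linear gap -1
#' per position by default. Identity = matches / alignment length x 100
#' (gapped columns count in the length). The alignment itself is computed
#' by Biostrings; the scoring scheme is recorded in the result.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @param match,mismatch,gap Scoring parameters (gap is per-position,
#'   linear).
#' @return list(identity, n_match, alignment_length, scoring).
#' @export
sequence_identity <- function(seq_a, seq_b, match = 1, mismatch = 0,
                              gap = -1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")
  bad <- setdiff(unique(strsplit(paste0(seq_a, seq_b), "")[[1]]), alphabet)
  if (length(bad))
    stop("sequences contain letters outside the amino-acid alphabet: ",
         paste(bad, collapse = ""))
  sm <- matrix(mismatch, length(alphabet), length(alphabet),
               dimnames = list(alphabet, alphabet))
  diag(sm) <- match
  al <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = -gap)
  len <- nchar(as.character(Biostrings::alignedPattern(al)))
  list(identity = 100 * Biostrings::nmatch(al) / len,
       n_match = Biostrings::nmatch(al),
       alignment_length = len,
       scoring = c(match = match, mismatch = mismatch, gap = gap))
}

#' Cross-compare similarity layers
#'
#' Joins per-pair similarity values from the proteome-response layer, the
#' interactome layer, and (optionally) sequence identity into one tidy
#' pair table, and reports Spearman rank correlations between every pair
#' of layers over the pairs where both are defined. A constant layer has
#' no rank ordering and yields NA, not zero.
#'
#' @param ... Two or more named `similarity_matrix` objects or plain
#'   symmetric matrices with identical label sets (e.g.
#'   `proteome = z1, interactome = z2, identity = idm`).
#' @return list(pairs = long data.frame with one column per layer,
#'   correlations = data.frame(layer_a, layer_b, spearman, n)).
#' @export
compare_similarity_layers <- function(...) {
  layers <- list(...)
  if (length(layers) < 2L) stop("need at least two layers")
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("layers must be named")
  mats <- lapply(layers, function(l)
    if (inherits(l, "similarity_matrix")) l$values else as.matrix(l))
  labels <- rownames(mats[[1]])
  for (m in mats)
    if (!setequal(rownames(m), labels)) stop("layers share no label set")
  mats <- lapply(mats, function(m) m[labels, labels])
  ut <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
  pairs <- data.frame(a = labels[ut[, 1]], b = labels[ut[, 2]],
                      stringsAsFactors = FALSE)
  for (nm in names(mats)) pairs[[nm]] <- mats[[nm]][ut]
  if (!nrow(pairs)) stop("no overlapping pairs")
  combos <- utils::combn(names(mats), 2)
  cors <- apply(combos, 2, function(cc) {
    x <- pairs[[cc[1]]]; y <- pairs[[cc[2]]]
    ok <- is.finite(x) & is.finite(y)
    rho <- if (sum(ok) < 3L || stats::sd(x[ok]) == 0 ||
               stats::sd(y[ok]) == 0) NA_real_
           else suppressWarnings(stats::cor(x[ok], y[ok],
                                            method = "spearman"))
    data.frame(layer_a = cc[1], layer_b = cc[2], spearman = rho,
               n = sum(ok))
  })
  list(pairs = pairs, correlations = do.call(rbind, cors))
}
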