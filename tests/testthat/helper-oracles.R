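# Independent brute-force oracles used across the suite. Each one is
# deliberately written from the textbook definition, not by calling the
# package's code path.

# Exact upper-tail hypergeometric probability by direct summation of
# binomial-coefficient ratios over the support.
oracle_hyper_upper <- function(q, m, n_other, k) {
  kk <- q:min(m, k)
  sum(choose(m, kk) * choose(n_other, k - kk)) / choose(m + n_other, k)
}

# Kruskal-Wallis H from the definition (tie-corrected).
oracle_kw_H <- function(v, grp) {
  r <- rank(v)
  n <- length(v)
  H <- (12 / (n * (n + 1))) *
    sum(tapply(r, grp, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(v)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact permutation p for the two-group Kruskal-Wallis statistic by
# enumerating all assignments of ranks to the first group.
oracle_kw_perm_p <- function(v, grp) {
  n1 <- sum(grp == levels(factor(grp))[1])
  obs <- oracle_kw_H(v, grp)
  combos <- utils::combn(length(v), n1)
  stats <- apply(combos, 2, function(idx) {
    g <- rep("b", length(v)); g[idx] <- "a"
    oracle_kw_H(v, g)
  })
  mean(stats >= obs - 1e-12)
}

# Poisson mid-p from the series definition (no ppois/dpois).
oracle_pois_midp <- function(x, lambda) {
  pm <- function(k) exp(-lambda + k * log(lambda) - lgamma(k + 1))
  below <- if (x > 0) sum(vapply(0:(x - 1), pm, 0)) else 0
  below + 0.5 * pm(x)
}

# Needleman-Wunsch optimal global alignment score, linear gap.
oracle_nw_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  D <- matrix(0, m + 1, n + 1)
  D[, 1] <- gap * (0:m); D[1, ] <- gap * (0:n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s <- if (a[i] == b[j]) match else mismatch
    D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + gap,
                           D[i + 1, j] + gap)
  }
  D[m + 1, n + 1]
}

# Per-punctum overlap fraction by exhaustive pixel scan.
oracle_overlap <- function(pmp_map, pts_map) {
  ids <- sort(unique(pmp_map[pmp_map > 0]))
  vapply(ids, function(id) {
    px <- which(pmp_map == id)
    sum(pts_map[px] > 0) / length(px)
  }, 0)
}

# Small helpers to build standard fixtures.
toy_design <- function(n_cond = 4, n_proteins = 200, ...)
  experiment_design(paste0("E2_", letters[seq_len(n_cond)]),
                    n_proteins = n_proteins, ...)

null_truth <- function(concordance = 0)
  regulation_truth(data.frame(condition = character(),
                              protein = character(), effect = numeric()),
                   mrna_concordance = concordance)

# End-to-end similarity-discrimination run: simulate a multi-batch TMT
# screen in which designated condition pairs share half their regulated
# targets with the same sign, score every pair, z-score with batch
# awareness, and report whether sharing pairs out-rank the rest.
run_similarity_design <- function(seed, shared_pairs, n_conditions = 12,
                                  n_batches = 6, n_proteins = 600,
                                  n_regulated = 60, noise_sd = 0.1) {
  conds <- sprintf("E2_%02d", seq_len(n_conditions))
  design <- experiment_design(
    conds, n_proteins,
    batch_of = stats::setNames(
      rep(paste0("b", seq_len(n_batches)),
          each = n_conditions / n_batches), conds))
  truth <- simulate_regulation_truth(
    design, n_regulated = n_regulated, effect_size = 0.5,
    shared_pairs = shared_pairs, shared_fraction = 0.5, seed = seed)
  x <- simulate_tmt_experiment(design, truth, noise_sd = noise_sd,
                               seed = seed + 1)
  fc <- list(); calls <- list()
  for (cond in conds) {
    dt <- protein_differential(x, cond)
    fc[[cond]] <- stats::setNames(dt$log2fc, dt$protein)
    calls[[cond]] <- suppressMessages(
      call_transcription_independent(dt, NULL))
  }
  calls <- do.call(rbind, calls)
  sim <- proteome_similarity(fc, calls)
  z <- batch_zscores(sim, design$batch_of)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  shared_keys <- key(shared_pairs[, 1], shared_pairs[, 2])
  pk <- key(z$pairs$a, z$pairs$b)
  zs <- z$pairs$z
  mean(zs[pk %in% shared_keys], na.rm = TRUE) >
    mean(zs[!pk %in% shared_keys], na.rm = TRUE)
}
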