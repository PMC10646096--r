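#' Simulate a multiplexed TMT proteome screen
#'
#' Generates a proteins x samples matrix of log2 abundances following the
#' screen layout in `design`. Each protein gets a baseline abundance, a
#' batch-specific offset shared by all samples of the same multiplexed set
#' (drawn once per (batch, protein)), the true effect for regulated
#' (condition, protein) pairs, and i.i.d. Gaussian measurement noise.
#' Because abundances live on the log2 scale, the knockdown-minus-control
#' log2 fold change is an arithmetic mean difference, and at `noise_sd = 0`
#' it recovers the true effect exactly.
#'
#' @param design An [experiment_design()].
#' @param truth A [regulation_truth()]; its effects are injected and it is
#'   echoed back unchanged.
#' @param noise_sd Measurement noise SD, log2 units (>= 0).
#' @param batch_sd SD of the per-(batch, protein) offsets, log2 units.
#' @param baseline_mean,baseline_sd Distribution of per-protein baseline
#'   log2 abundance.
#' @param seed Integer RNG seed; identical inputs and seed give
#'   byte-identical output.
#' @return An `abundance_matrix`: list with `values` (proteins x samples
#'   log2 matrix), `sample_meta` (sample, condition, batch, replicate,
#'   is_control), `protein_ids`, and `truth`.
#' @export
simulate_tmt_experiment <- function(design, truth, noise_sd = 0.1,
                                    batch_sd = 0.3, baseline_mean = 10,
                                    baseline_sd = 1, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "regulation_truth"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (nrow(truth$effects) &&
      !all(truth$effects$condition %in% design$conditions))
    stop("truth references conditions absent from the design")
  set.seed(seed)
  prot <- protein_ids(design$n_proteins)
  if (nrow(truth$effects) && !all(truth$effects$protein %in% prot))
    stop("truth references proteins beyond 'n_proteins'")

  meta <- screen_sample_meta(design)
  n_s <- nrow(meta)
  baseline <- stats::rnorm(design$n_proteins, baseline_mean, baseline_sd)
  batch_off <- matrix(stats::rnorm(design$n_proteins * length(design$batches),
                                   0, batch_sd),
                      nrow = design$n_proteins,
                      dimnames = list(prot, design$batches))
  vals <- matrix(baseline, design$n_proteins, n_s,
                 dimnames = list(prot, meta$sample))
  vals <- vals + batch_off[, meta$batch, drop = FALSE]
  if (nrow(truth$effects)) {
    for (i in seq_len(nrow(truth$effects))) {
      cond <- truth$effects$condition[i]
      cols <- which(meta$condition == cond)
      vals[truth$effects$protein[i], cols] <-
        vals[truth$effects$protein[i], cols] + truth$effects$effect[i]
    }
  }
  if (noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                          nrow = nrow(vals))
  abundance_matrix(vals, meta, truth = truth)
}

screen_sample_meta <- function(design) {
  rows <- list()
  for (b in design$batches) {
    for (cond in design$conditions[design$batch_of == b]) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = paste0(cond, "_r", seq_len(design$reps_per_condition)),
        condition = cond, batch = b,
        replicate = seq_len(design$reps_per_condition),
        is_control = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample = paste0("NT_", b, "_r", seq_len(design$controls_per_batch)),
      condition = paste0("NT_", b), batch = b,
      replicate = seq_len(design$controls_per_batch),
      is_control = TRUE)
  }
  do.call(rbind, rows)
}

#' Construct an abundance matrix with sample metadata
#'
#' @param values proteins x samples numeric matrix, log2 scale; column
#'   names must match `sample_meta$sample`.
#' @param sample_meta data.frame with columns sample, condition, batch,
#'   replicate, is_control. Each batch must contain >= 2 control samples.
#' @param truth Optional `regulation_truth` carried along for simulated
#'   data.
#' @return An `abundance_matrix`.
#' @export
abundance_matrix <- function(values, sample_meta, truth = NULL) {
  stopifnot(is.matrix(values),
            all(c("sample", "condition", "batch", "replicate",
                  "is_control") %in% names(sample_meta)))
  if (!identical(colnames(values), as.character(sample_meta$sample)))
    stop("column names of 'values' must equal sample_meta$sample, in order")
  ctrl <- table(sample_meta$batch[sample_meta$is_control])
  all_b <- unique(sample_meta$batch)
  if (!all(all_b %in% names(ctrl)) || any(ctrl < 2))
    stop("each batch must contain >= 2 control samples")
  structure(list(values = values, sample_meta = sample_meta,
                 protein_ids = rownames(values), truth = truth),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix:", nrow(x$values), "proteins x",
      ncol(x$values), "samples;",
      sum(!x$sample_meta$is_control), "knockdown /",
      sum(x$sample_meta$is_control), "control samples\n")
  invisible(x)
}

#' Simulate the RNA-seq counterpart of a proteome truth layer
#'
#' Produces a genes x samples TPM matrix for the same design. Gene ids
#' equal protein ids (identity mapping). For each true protein effect, the
#' gene carries the matching log2 fold change with probability
#' `mrna_concordance` (the truth's concordance), and no programmed change
#' otherwise. Expression noise is multiplicative log-normal with SD
#' `dispersion` (log2 units); columns are rescaled to sum to 1e6.
#'
#' @param truth A [regulation_truth()].
#' @param design An [experiment_design()].
#' @param dispersion Log2-scale SD of multiplicative noise (> 0).
#' @param base_log2_mean,base_log2_sd Distribution of baseline gene
#'   expression on the log2 scale before TPM normalisation.
#' @param seed Integer RNG seed.
#' @return An `expression_matrix`: list with `tpm`, `sample_meta`,
#'   `gene_ids`, and `concordant` (the (condition, gene) pairs that carry
#'   the protein effect).
#' @export
simulate_rnaseq_counterpart <- function(truth, design, dispersion = 0.25,
                                        base_log2_mean = 5, base_log2_sd = 2,
                                        seed = 1L) {
  stopifnot(inherits(truth, "regulation_truth"),
            inherits(design, "experiment_design"))
  if (dispersion <= 0) stop("'dispersion' must be > 0")
  if (length(design$conditions) == 0L) stop("empty design")
  set.seed(seed)
  genes <- protein_ids(design$n_proteins)
  meta <- screen_sample_meta(design)
  base <- stats::rnorm(design$n_proteins, base_log2_mean, base_log2_sd)
  log2e <- matrix(base, design$n_proteins, nrow(meta),
                  dimnames = list(genes, meta$sample))
  conc <- logical(nrow(truth$effects))
  if (nrow(truth$effects)) {
    conc <- stats::runif(nrow(truth$effects)) < truth$mrna_concordance
    for (i in which(conc)) {
      cols <- which(meta$condition == truth$effects$condition[i])
      log2e[truth$effects$protein[i], cols] <-
        log2e[truth$effects$protein[i], cols] + truth$effects$effect[i]
    }
  }
  log2e <- log2e + matrix(stats::rnorm(length(log2e), 0, dispersion),
                          nrow = nrow(log2e))
  tpm <- 2^log2e
  tpm <- sweep(tpm, 2, colSums(tpm) / 1e6, "/")
  structure(list(tpm = tpm, sample_meta = meta, gene_ids = genes,
                 concordant = truth$effects[conc, , drop = FALSE]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$tpm), "genes x", ncol(x$tpm),
      "samples (TPM)\n")
  invisible(x)
}

#' Simulate bait/control IP-MS spectral counts
#'
#' Generates a long-format spectral-count table for a pull-down screen:
#' `n_bait_reps` runs per bait and `n_controls` no-bait control runs.
#' True prey counts are Poisson draws around the edge's mean rate and
#' appear only in that bait's runs; contaminant preys receive Poisson
#' background in every run (bait and control); each bait protein itself
#' receives high counts in its own runs (self-enrichment).
#'
#' @param network_truth data.frame of true edges: `bait`, `prey`,
#'   `rate` (mean spectral count in the bait's runs).
#' @param lengths Named vector of protein lengths (residues) covering every
#'   prey, bait, and contaminant.
#' @param n_bait_reps Runs per bait (default 3).
#' @param n_controls Control runs (default 10).
#' @param contaminants Named vector, prey -> mean count per run in all
#'   runs; `NULL` for none.
#' @param bait_self_rate Mean self count of each bait in its own runs.
#' @param baits Bait labels to simulate runs for; defaults to the baits in
#'   `network_truth`. Supplying extra labels creates baits with no true
#'   edges (contaminant-only pull-downs).
#' @param seed Integer RNG seed.
#' @return A `spectral_count_table`: list with `counts` (run, bait, prey,
#'   count; zero counts omitted), `runs` (run, bait), `lengths`, and
#'   `truth` (the input edge list).
#' @export
simulate_ipms_counts <- function(network_truth, lengths, n_bait_reps = 3L,
                                 n_controls = 10L, contaminants = NULL,
                                 bait_self_rate = 50, baits = NULL,
                                 seed = 1L) {
  stopifnot(is.data.frame(network_truth),
            all(c("bait", "prey", "rate") %in% names(network_truth)))
  if (n_bait_reps < 1L) stop("'n_bait_reps' must be >= 1")
  if (n_controls < 1L) stop("'n_controls' must be >= 1")
  if (is.null(baits)) baits <- unique(network_truth$bait)
  if (!length(baits)) stop("no baits to simulate")
  need <- unique(c(network_truth$prey, network_truth$bait, baits,
                   names(contaminants)))
  miss <- setdiff(need, names(lengths))
  if (length(miss))
    stop("missing length for: ", paste(miss, collapse = ", "))
  if (any(lengths <= 0)) stop("lengths must be positive")
  set.seed(seed)
  runs <- rbind(
    data.frame(run = paste0(rep(baits, each = n_bait_reps), "_r",
                            seq_len(n_bait_reps)),
               bait = rep(baits, each = n_bait_reps)),
    data.frame(run = paste0("ctrl_r", seq_len(n_controls)),
               bait = "CONTROL"))
  rows <- list()
  emit <- function(run, bait, prey, count) {
    keep <- count > 0
    if (any(keep))
      rows[[length(rows) + 1L]] <<- data.frame(
        run = run[keep], bait = bait[keep], prey = prey[keep],
        count = count[keep])
  }
  for (b in baits) {
    brun <- runs$run[runs$bait == b]
    edges <- network_truth[network_truth$bait == b, ]
    for (r in brun) {
      emit(rep(r, nrow(edges)), rep(b, nrow(edges)), edges$prey,
           stats::rpois(nrow(edges), edges$rate))
      emit(r, b, b, stats::rpois(1L, bait_self_rate))
    }
  }
  if (length(contaminants)) {
    for (r in runs$run) {
      emit(rep(r, length(contaminants)),
           rep(runs$bait[runs$run == r], length(contaminants)),
           names(contaminants),
           stats::rpois(length(contaminants), contaminants))
    }
  }
  counts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run = character(), bait = character(),
               prey = character(), count = integer())
  # collapse duplicate (run, prey) rows (contaminant on top of a true edge)
  if (nrow(counts)) {
    key <- paste(counts$run, counts$prey)
    counts <- do.call(rbind, lapply(split(counts, key), function(d)
      data.frame(run = d$run[1], bait = d$bait[1], prey = d$prey[1],
                 count = sum(d$count))))
    rownames(counts) <- NULL
    counts <- counts[order(counts$run, counts$prey), ]
  }
  spectral_count_table(counts, runs, lengths, truth = network_truth)
}

#' Construct a spectral-count table
#'
#' @param counts Long data.frame (run, bait, prey, count); counts are
#'   non-negative integers, zero rows may be omitted.
#' @param runs data.frame (run, bait) covering every run; bait label
#'   `"CONTROL"` marks control purifications (>= 1 required).
#' @param lengths Named vector of protein lengths covering every prey with
#'   a count.
#' @param truth Optional true edge list for simulated tables.
#' @return A `spectral_count_table`.
#' @export
spectral_count_table <- function(counts, runs, lengths, truth = NULL) {
  stopifnot(all(c("run", "bait", "prey", "count") %in% names(counts)),
            all(c("run", "bait") %in% names(runs)))
  if (nrow(counts)) {
    if (any(counts$count < 0) || any(counts$count != round(counts$count)))
      stop("counts must be non-negative integers")
    miss <- setdiff(unique(counts$prey), names(lengths))
    if (length(miss))
      stop("prey without a length entry: ", paste(miss, collapse = ", "))
  }
  if (!any(runs$bait == "CONTROL")) stop("at least one control run required")
  structure(list(counts = counts, runs = runs, lengths = lengths,
                 truth = truth),
            class = "spectral_count_table")
}

#' @export
print.spectral_count_table <- function(x, ...) {
  cat("spectral_count_table:", nrow(x$counts), "count rows,",
      sum(x$runs$bait != "CONTROL"), "bait runs,",
      sum(x$runs$bait == "CONTROL"), "control runs\n")
  invisible(x)
}
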