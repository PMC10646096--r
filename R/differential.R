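#' Per-protein differential abundance for one knockdown condition
#'
#' Compares a condition's samples against the control samples of the same
#' multiplexed set (batch), protein by protein. The log2 fold change is
#' the mean log2 abundance difference (knockdown minus in-batch control);
#' the p-value comes from a two-sided two-sample t-test, pooled-variance
#' (Student) by default. Proteins with fewer than two quantified replicates
#' in either group are reported with missing statistics, not zeros.
#' Zero-variance inputs return p = 1 (totality convention for degenerate
#' simulated data).
#'
#' The t statistics are computed rowwise in vectorised form; `stats::t.test`
#' gives identical results on any single protein.
#'
#' @param x An [abundance_matrix()].
#' @param condition Condition label present in `x$sample_meta`.
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return A `differential_table` data.frame: protein, log2fc, statistic,
#'   p_value, n_case, n_control; attributes `condition` and `test`.
#' @export
protein_differential <- function(x, condition, var_equal = TRUE) {
  stopifnot(inherits(x, "abundance_matrix"))
  meta <- x$sample_meta
  if (!condition %in% meta$condition[!meta$is_control])
    stop("condition '", condition, "' not present")
  batch <- unique(meta$batch[meta$condition == condition])
  case <- x$values[, meta$condition == condition, drop = FALSE]
  ctrl <- x$values[, meta$is_control & meta$batch %in% batch, drop = FALSE]
  res <- rowwise_t(case, ctrl, var_equal)
  if (all(res$n_case < 2) || all(res$n_control < 2))
    stop("fewer than 2 replicates in a comparison group")
  out <- data.frame(protein = rownames(x$values), res,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "condition") <- condition
  attr(out, "test") <- if (var_equal) "t_pooled" else "t_welch"
  class(out) <- c("differential_table", "data.frame")
  out
}

rowwise_t <- function(case, ctrl, var_equal = TRUE) {
  n1 <- rowSums(!is.na(case)); n2 <- rowSums(!is.na(ctrl))
  m1 <- rowMeans(case, na.rm = TRUE); m2 <- rowMeans(ctrl, na.rm = TRUE)
  v1 <- apply(case, 1, stats::var, na.rm = TRUE)
  v2 <- apply(ctrl, 1, stats::var, na.rm = TRUE)
  d <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- d / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- is.finite(d) & !is.na(se) & se == 0
  p[zero_var] <- 1; tstat[zero_var] <- 0
  bad <- n1 < 2 | n2 < 2
  d[bad] <- NA_real_; tstat[bad] <- NA_real_; p[bad] <- NA_real_
  data.frame(log2fc = d, statistic = tstat, p_value = p,
             n_case = n1, n_control = n2)
}

#' Per-gene differential expression for one knockdown condition
#'
#' Non-parametric test on log2(TPM + 1): Kruskal-Wallis H across the
#' condition and in-batch control groups (equivalent to a Wilcoxon
#' rank-sum when only two groups exist), with Dunn's tie-corrected
#' pairwise z for condition versus control. The log2 fold change is the
#' mean log2(TPM + 1) difference. All-tied genes are degenerate and
#' reported with H = 0, p = 1.
#'
#' @param x An `expression_matrix` (see [simulate_rnaseq_counterpart()]).
#' @param condition Condition label.
#' @param p_from Which p-value to report in `p_value`: Dunn's pairwise z
#'   (default) or the Kruskal-Wallis chi-square p. Both are returned as
#'   columns.
#' @return A `differential_table` data.frame: gene, log2fc, statistic (H),
#'   p_value, p_kw, p_dunn, n_case, n_control.
#' @export
rna_differential <- function(x, condition, p_from = c("dunn", "kw")) {
  stopifnot(inherits(x, "expression_matrix"))
  p_from <- match.arg(p_from)
  meta <- x$sample_meta
  if (!condition %in% meta$condition[!meta$is_control])
    stop("condition '", condition, "' not present")
  batch <- unique(meta$batch[meta$condition == condition])
  case_idx <- which(meta$condition == condition)
  ctrl_idx <- which(meta$is_control & meta$batch %in% batch)
  if (length(case_idx) + length(ctrl_idx) < 3L)
    stop("need >= 3 samples in total")
  lg <- log2(x$tpm[, c(case_idx, ctrl_idx), drop = FALSE] + 1)
  grp <- rep(c("case", "ctrl"), c(length(case_idx), length(ctrl_idx)))
  n1 <- length(case_idx); n2 <- length(ctrl_idx)
  res <- t(apply(lg, 1, function(v) kw_dunn_row(v, grp)))
  out <- data.frame(
    gene = rownames(x$tpm),
    log2fc = rowMeans(lg[, grp == "case", drop = FALSE]) -
             rowMeans(lg[, grp == "ctrl", drop = FALSE]),
    statistic = res[, "H"], p_kw = res[, "p_kw"], p_dunn = res[, "p_dunn"],
    n_case = n1, n_control = n2, row.names = NULL)
  out$p_value <- if (p_from == "dunn") out$p_dunn else out$p_kw
  attr(out, "condition") <- condition
  attr(out, "test") <- paste0("kruskal_dunn(", p_from, ")")
  class(out) <- c("differential_table", "data.frame")
  out
}

# Kruskal-Wallis H + Dunn's tie-corrected pairwise z for one gene.
kw_dunn_row <- function(v, grp) {
  if (length(unique(v)) == 1L)                    # all tied: degenerate
    return(c(H = 0, p_kw = 1, p_dunn = 1))
  kw <- stats::kruskal.test(v, factor(grp))
  r <- rank(v)
  n <- length(v)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  n1 <- sum(grp == "case"); n2 <- sum(grp == "ctrl")
  se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n1 + 1 / n2))
  z <- (mean(r[grp == "case"]) - mean(r[grp == "ctrl"])) / se
  p_dunn <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 1
  c(H = unname(kw$statistic), p_kw = kw$p.value, p_dunn = p_dunn)
}

#' Call transcription-independent protein modulation
#'
#' Applies the screen's thresholds to one condition's protein-level
#' differential table: direction `up` iff p < alpha and log2FC > fc,
#' `down` iff p < alpha and log2FC < -fc, else `none`. A call is
#' transcription-independent unless the mapped gene shows a corresponding
#' mRNA change — significant at the same alpha, |log2FC| > fc, and with
#' the same sign as the protein change. Proteins without a gene mapping
#' (or without mRNA data) lack mRNA evidence and keep their
#' transcription-independent flag; their number is reported in a message.
#'
#' @param protein_diff `differential_table` from [protein_differential()].
#' @param rna_diff `differential_table` from [rna_differential()], same
#'   condition; `NULL` for no mRNA evidence at all.
#' @param mapping Optional data.frame (protein, gene); `NULL` means
#'   protein ids equal gene ids.
#' @param alpha Significance threshold (default 0.05).
#' @param fc Absolute log2FC threshold (default 0.2).
#' @return A `modulation_calls` data.frame: protein, condition, direction,
#'   transcription_independent, p_value, log2fc, rna_p, rna_log2fc;
#'   attributes `alpha` and `fc` record the thresholds verbatim.
#' @export
call_transcription_independent <- function(protein_diff, rna_diff = NULL,
                                           mapping = NULL, alpha = 0.05,
                                           fc = 0.2) {
  cond <- attr(protein_diff, "condition")
  if (!is.null(rna_diff) &&
      !identical(cond, attr(rna_diff, "condition")))
    stop("protein and RNA tables come from different conditions")
  gene <- if (is.null(mapping)) protein_diff$protein else
    mapping$gene[match(protein_diff$protein, mapping$protein)]
  p <- protein_diff$p_value; l2 <- protein_diff$log2fc
  direction <- rep("none", nrow(protein_diff))
  direction[!is.na(p) & p < alpha & l2 > fc] <- "up"
  direction[!is.na(p) & p < alpha & l2 < -fc] <- "down"
  rna_p <- rna_l2 <- rep(NA_real_, nrow(protein_diff))
  if (!is.null(rna_diff)) {
    idx <- match(gene, rna_diff$gene)
    rna_p <- rna_diff$p_value[idx]
    rna_l2 <- rna_diff$log2fc[idx]
  }
  corresponding <- !is.na(rna_p) & rna_p < alpha & abs(rna_l2) > fc &
    sign(rna_l2) == sign(l2)
  txn_ind <- direction != "none" & !corresponding
  n_unmapped <- sum(direction != "none" & is.na(rna_p))
  if (n_unmapped > 0)
    message(n_unmapped,
            " significant protein(s) lack mRNA evidence; treated as",
            " transcription-independent")
  out <- data.frame(protein = protein_diff$protein, condition = cond,
                    direction = direction,
                    transcription_independent = txn_ind,
                    p_value = p, log2fc = l2,
                    rna_p = rna_p, rna_log2fc = rna_l2,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "fc") <- fc
  class(out) <- c("modulation_calls", "data.frame")
  out
}

#' Count how many conditions regulate each protein
#'
#' Over modulation calls pooled across conditions, counts the conditions
#' in which each protein has a transcription-independent call (direction
#' not `none`), and bins the counts as 1, 2-4, 5-9, >=10 regulators.
#' Proteins never regulated are excluded.
#'
#' @param calls A `modulation_calls` data.frame covering >= 1 condition
#'   (rbind of per-condition calls).
#' @return data.frame: protein, n_regulators, bin (ordered factor).
#' @export
count_regulators <- function(calls) {
  stopifnot(all(c("protein", "condition", "direction",
                  "transcription_independent") %in% names(calls)))
  hit <- calls[calls$direction != "none" & calls$transcription_independent, ]
  if (!nrow(hit))
    return(data.frame(protein = character(), n_regulators = integer(),
                      bin = factor(character(),
                                   levels = c("1", "2-4", "5-9", ">=10"))))
  tab <- table(hit$protein)
  out <- data.frame(protein = names(tab), n_regulators = as.integer(tab),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$bin <- cut(out$n_regulators, c(0, 1, 4, 9, Inf),
                 labels = c("1", "2-4", "5-9", ">=10"))
  out[order(-out$n_regulators, out$protein), ]
}

#' Gene-set overrepresentation by hypergeometric test
#'
#' For each gene set, tests whether the hit list overlaps the set more
#' than expected by chance within the universe: upper-tail hypergeometric
#' probability of the observed overlap or larger, with
#' Benjamini-Hochberg adjustment across sets. Sets are intersected with
#' the universe before testing.
#'
#' @param hits Character vector of hit ids (subset of `universe`).
#' @param universe Character vector, the tested background.
#' @param gene_sets Named list of character vectors.
#' @return data.frame: set, n_set, n_overlap, fold_enrichment, p_value,
#'   q_value.
#' @export
overrepresentation <- function(hits, universe, gene_sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  N <- length(universe); k <- length(hits)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    m <- length(s)
    q <- length(intersect(s, hits))
    p <- if (m == 0L) 1 else
      stats::phyper(q - 1, m, N - m, k, lower.tail = FALSE)
    fe <- if (m == 0L || k == 0L) NA_real_ else (q / k) / (m / N)
    data.frame(set = nm, n_set = m, n_overlap = q, fold_enrichment = fe,
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out[order(out$p_value), ]
}
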