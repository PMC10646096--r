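make_matrix <- function(case, ctrl, protein = "P1") {
  vals <- matrix(c(case, ctrl), nrow = 1,
                 dimnames = list(protein,
                                 c(paste0("k", seq_along(case)),
                                   paste0("c", seq_along(ctrl)))))
  meta <- data.frame(
    sample = colnames(vals),
    condition = rep(c("E2a", "NT"), c(length(case), length(ctrl))),
    batch = "b1",
    replicate = c(seq_along(case), seq_along(ctrl)),
    is_control = rep(c(FALSE, TRUE), c(length(case), length(ctrl))))
  abundance_matrix(vals, meta)
}

test_that("pooled t-test matches the direct-formula and t.test oracles", {
  x <- make_matrix(c(1.0, 1.2, 1.1), c(0.0, 0.1, -0.1, 0.0))
  dt <- protein_differential(x, "E2a")
  expect_equal(dt$log2fc, mean(c(1.0, 1.2, 1.1)) - mean(c(0, 0.1, -0.1, 0)))
  ref <- stats::t.test(c(1.0, 1.2, 1.1), c(0.0, 0.1, -0.1, 0.0),
                       var.equal = TRUE)
  expect_equal(dt$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(dt$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(dt$n_case, 3)
  expect_equal(dt$n_control, 4)
})

test_that("degenerate and antisymmetric t-test behaviour", {
  # both groups identical constants: log2fc 0, p 1
  x <- make_matrix(c(2, 2, 2), c(2, 2, 2, 2))
  dt <- protein_differential(x, "E2a")
  expect_equal(dt$log2fc, 0)
  expect_equal(dt$p_value, 1)
  # swapping case and control negates log2fc, keeps p
  a <- c(0.6, 0.9, 0.7); b <- c(0.1, 0.0, 0.2, 0.1)
  d1 <- protein_differential(make_matrix(a, b), "E2a")
  vals <- matrix(c(b, a), nrow = 1, dimnames = list("P1", paste0("s", 1:7)))
  meta <- data.frame(sample = paste0("s", 1:7),
                     condition = rep(c("E2a", "NT"), c(4, 3)),
                     batch = "b1", replicate = c(1:4, 1:3),
                     is_control = rep(c(FALSE, TRUE), c(4, 3)))
  d_swap <- protein_differential(abundance_matrix(vals, meta), "E2a")
  expect_equal(d_swap$log2fc, -d1$log2fc)
  expect_equal(d_swap$p_value, d1$p_value, tolerance = 1e-12)
})

test_that("proteins with missing replicates are reported missing, not zero", {
  x <- make_matrix(c(1.0, NA, NA), c(0.0, 0.1, -0.1, 0.0))
  x$values <- rbind(x$values,
                    P2 = c(1.0, 1.1, 0.9, 0.0, 0.1, -0.1, 0.05))
  dt <- protein_differential(x, "E2a")
  expect_true(is.na(dt$log2fc[dt$protein == "P1"]))
  expect_true(is.na(dt$p_value[dt$protein == "P1"]))
  expect_false(is.na(dt$p_value[dt$protein == "P2"]))
})

test_that("Kruskal-Wallis H and p agree with enumeration and rank oracles", {
  tpm_mat <- function(vals1, vals2) {
    tpm <- matrix(2^c(vals1, vals2) - 1, nrow = 1,
                  dimnames = list("G1", paste0("s", seq_along(c(vals1, vals2)))))
    meta <- data.frame(sample = colnames(tpm),
                       condition = rep(c("E2a", "NT"),
                                       c(length(vals1), length(vals2))),
                       batch = "b1",
                       replicate = c(seq_along(vals1), seq_along(vals2)),
                       is_control = rep(c(FALSE, TRUE),
                                        c(length(vals1), length(vals2))))
    structure(list(tpm = tpm, sample_meta = meta, gene_ids = "G1"),
              class = "expression_matrix")
  }
  # identical group values: degenerate, H = 0, p = 1
  rd0 <- rna_differential(tpm_mat(c(3, 3, 3), c(3, 3, 3)), "E2a")
  expect_equal(rd0$statistic, 0)
  expect_equal(rd0$p_value, 1)
  # separated groups: H matches the definition-based oracle; Dunn's p and
  # the reported chi-square p are internally consistent
  x <- tpm_mat(c(1, 2, 3), c(4, 5, 6))
  rd <- rna_differential(x, "E2a", p_from = "kw")
  grp <- rep(c("a", "b"), each = 3)
  expect_equal(rd$statistic, oracle_kw_H(c(1, 2, 3, 4, 5, 6), grp),
               tolerance = 1e-12)
  expect_equal(rd$p_kw,
               stats::kruskal.test(c(1, 2, 3, 4, 5, 6),
                                   factor(grp))$p.value, tolerance = 1e-12)
  # exact permutation p for this configuration: only 2/20 assignments
  # reach the observed H
  expect_equal(oracle_kw_perm_p(c(1, 2, 3, 4, 5, 6), grp), 0.1)
  # rank invariance: a monotone transform leaves p unchanged
  y <- tpm_mat(log2(2^c(1, 2, 3) * 7 + 5), log2(2^c(4, 5, 6) * 7 + 5))
  rd_t <- rna_differential(y, "E2a", p_from = "kw")
  expect_equal(rd_t$p_value, rd$p_value, tolerance = 1e-12)
  expect_equal(rd_t$p_dunn, rd$p_dunn, tolerance = 1e-12)
})

test_that("Dunn z for two groups matches the tie-corrected formula", {
  set.seed(41)
  for (i in 1:20) {
    v <- sample(1:8, 7, replace = TRUE)  # ties likely
    grp <- rep(c("case", "ctrl"), c(3, 4))
    if (length(unique(v)) == 1) next
    got <- ubiscreen:::kw_dunn_row(v, grp)
    r <- rank(v); n <- 7
    ties <- table(v)
    se <- sqrt((n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))) *
                 (1 / 3 + 1 / 4))
    z <- (mean(r[1:3]) - mean(r[4:7])) / se
    expect_equal(got[["p_dunn"]], 2 * pnorm(-abs(z)), tolerance = 1e-12)
  }
})

test_that("transcription-independent calls follow the threshold rules", {
  mk_diff <- function(p, l2, cond = "E2a") {
    out <- data.frame(protein = "P1", log2fc = l2, statistic = 1,
                      p_value = p, n_case = 3, n_control = 4)
    attr(out, "condition") <- cond
    class(out) <- c("differential_table", "data.frame")
    out
  }
  mk_rna <- function(p, l2, cond = "E2a") {
    out <- data.frame(gene = "P1", log2fc = l2, statistic = 1,
                      p_value = p, n_case = 3, n_control = 4)
    attr(out, "condition") <- cond
    class(out) <- c("differential_table", "data.frame")
    out
  }
  # protein up, mRNA flat: transcription-independent up
  c1 <- call_transcription_independent(mk_diff(0.01, 0.3), mk_rna(0.4, 0.3))
  expect_equal(c1$direction, "up")
  expect_true(c1$transcription_independent)
  # protein not significant: none regardless of mRNA
  c2 <- call_transcription_independent(mk_diff(0.2, 0.9),
                                       mk_rna(0.001, 0.9))
  expect_equal(c2$direction, "none")
  expect_false(c2$transcription_independent)
  # protein and mRNA up together: not transcription-independent
  c3 <- call_transcription_independent(mk_diff(0.01, 0.5),
                                       mk_rna(0.001, 0.6))
  expect_equal(c3$direction, "up")
  expect_false(c3$transcription_independent)
  # opposite-sign mRNA change is not "corresponding"
  c4 <- call_transcription_independent(mk_diff(0.01, 0.5),
                                       mk_rna(0.001, -0.6))
  expect_true(c4$transcription_independent)
  # unmapped protein: lacks mRNA evidence, stays independent
  expect_message(
    c5 <- call_transcription_independent(
      mk_diff(0.01, 0.5), mk_rna(0.001, 0.6),
      mapping = data.frame(protein = "other", gene = "G9")),
    "lack mRNA evidence")
  expect_true(c5$transcription_independent)
  # boundary: log2fc exactly at fc is not a call
  c6 <- call_transcription_independent(mk_diff(0.01, 0.2), NULL)
  expect_equal(c6$direction, "none")
  expect_error(
    call_transcription_independent(mk_diff(0.01, 0.5),
                                   mk_rna(0.4, 0.3, cond = "E2b")),
    "different conditions")
})

test_that("threshold monotonicity: stricter thresholds never add calls", {
  set.seed(7)
  n <- 300
  pd <- data.frame(protein = paste0("P", 1:n),
                   log2fc = rnorm(n, 0, 0.4), statistic = 0,
                   p_value = runif(n), n_case = 3, n_control = 4)
  attr(pd, "condition") <- "E2a"
  class(pd) <- c("differential_table", "data.frame")
  base <- call_transcription_independent(pd, NULL, alpha = 0.05, fc = 0.2)
  tighter_a <- call_transcription_independent(pd, NULL, alpha = 0.01,
                                              fc = 0.2)
  tighter_f <- call_transcription_independent(pd, NULL, alpha = 0.05,
                                              fc = 0.4)
  called <- function(cc) cc$protein[cc$direction != "none"]
  expect_true(all(called(tighter_a) %in% called(base)))
  expect_true(all(called(tighter_f) %in% called(base)))
})

test_that("regulator counts bin correctly and drop unregulated proteins", {
  mk_calls <- function(protein, n_cond, dir = "up") {
    do.call(rbind, lapply(seq_len(n_cond), function(i)
      data.frame(protein = protein, condition = paste0("E", i),
                 direction = dir, transcription_independent = TRUE,
                 p_value = 0.01, log2fc = 0.5, rna_p = NA, rna_log2fc = NA)))
  }
  calls <- rbind(mk_calls("P1", 3), mk_calls("P2", 9), mk_calls("P3", 1),
                 mk_calls("P4", 12),
                 data.frame(protein = "P5", condition = "E1",
                            direction = "none",
                            transcription_independent = FALSE,
                            p_value = 0.5, log2fc = 0, rna_p = NA,
                            rna_log2fc = NA))
  cr <- count_regulators(calls)
  expect_equal(as.character(cr$bin[cr$protein == "P1"]), "2-4")
  expect_equal(as.character(cr$bin[cr$protein == "P2"]), "5-9")
  expect_equal(as.character(cr$bin[cr$protein == "P3"]), "1")
  expect_equal(as.character(cr$bin[cr$protein == "P4"]), ">=10")
  expect_false("P5" %in% cr$protein)
})

test_that("hypergeometric overrepresentation matches brute-force summation", {
  set.seed(17)
  universe <- paste0("g", 1:100)
  hits <- sample(universe, 10)
  gs <- list(S1 = sample(universe, 20), S2 = sample(universe, 40))
  res <- overrepresentation(hits, universe, gs)
  for (nm in names(gs)) {
    q <- length(intersect(gs[[nm]], hits))
    expect_equal(res$p_value[res$set == nm],
                 oracle_hyper_upper(q, length(gs[[nm]]), 100 - length(gs[[nm]]), 10),
                 tolerance = 1e-12)
  }
  # universe == hits forces every set's p to 1
  res_all <- overrepresentation(universe, universe, gs)
  expect_true(all(res_all$p_value == 1))
  # disjoint large set: upper-tail p >= 0.5
  gs2 <- list(S = setdiff(universe, hits)[1:60])
  expect_gte(overrepresentation(hits, universe, gs2)$p_value, 0.5)
  # BH q-values are non-decreasing in sorted p
  set.seed(18)
  gs3 <- lapply(1:8, function(i) sample(universe, 25))
  names(gs3) <- paste0("S", 1:8)
  r3 <- overrepresentation(hits, universe, gs3)
  expect_true(all(diff(r3$q_value[order(r3$p_value)]) >= -1e-12))
})
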