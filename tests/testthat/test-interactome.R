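toy_table <- function(counts, lengths, n_controls = 2) {
  baits <- setdiff(unique(counts$bait), "CONTROL")
  runs <- unique(counts[, c("run", "bait")])
  ctrl <- data.frame(run = paste0("ctrl_r", seq_len(n_controls)),
                     bait = "CONTROL")
  runs <- unique(rbind(runs, ctrl))
  spectral_count_table(counts, runs, lengths)
}

test_that("spectral counts are normalised per residue", {
  counts <- data.frame(run = c("b1_r1", "b1_r1"), bait = "B1",
                       prey = c("Y1", "Y2"), count = c(10, 0))
  tab <- toy_table(counts, c(Y1 = 500, Y2 = 300, B1 = 200))
  nc <- normalize_spectral_counts(tab)
  expect_equal(nc$norm_count[nc$prey == "Y1"], 0.02)
  expect_equal(nc$norm_count[nc$prey == "Y2"], 0)
  tab2 <- toy_table(counts, c(Y1 = 1000, Y2 = 600, B1 = 400))
  nc2 <- normalize_spectral_counts(tab2)
  expect_equal(nc2$norm_count, nc$norm_count / 2)
})

test_that("Poisson mid-p enrichment matches the series oracle and its bounds", {
  # prey absent from controls, strong bait counts: score > 0.99
  counts <- data.frame(run = paste0("b1_r", 1:3), bait = "B1", prey = "Y1",
                       count = c(20, 20, 20))
  tab <- toy_table(counts, c(Y1 = 400, B1 = 400))
  sc <- enrichment_probability(tab, "B1")
  y1 <- sc[sc$prey == "Y1", ]
  expect_gt(y1$score, 0.99)
  expect_equal(y1$score, oracle_pois_midp(20, 0.1), tolerance = 1e-12)
  # bait counts all zero: mid-p at zero is at most 0.5
  counts0 <- data.frame(run = "ctrl_r1", bait = "CONTROL", prey = "Y1",
                        count = 3)
  tab0 <- spectral_count_table(
    counts0,
    data.frame(run = c("b1_r1", "ctrl_r1", "ctrl_r2"),
               bait = c("B1", "CONTROL", "CONTROL")),
    c(Y1 = 400, B1 = 400))
  sc0 <- enrichment_probability(tab0, "B1")
  expect_lte(sc0$score[sc0$prey == "Y1"], 0.5)
  expect_equal(sc0$score[sc0$prey == "Y1"], oracle_pois_midp(0, 1.5),
               tolerance = 1e-12)
  # bait counts equal to the control mean: score near 0.5
  counts_eq <- rbind(
    data.frame(run = paste0("b1_r", 1:3), bait = "B1", prey = "Y1",
               count = 8),
    data.frame(run = paste0("ctrl_r", 1:4), bait = "CONTROL", prey = "Y1",
               count = 8))
  tab_eq <- toy_table(counts_eq, c(Y1 = 400, B1 = 400), n_controls = 4)
  sc_eq <- enrichment_probability(tab_eq, "B1")
  expect_lt(abs(sc_eq$score[sc_eq$prey == "Y1"] - 0.5), 0.1)
})

test_that("enrichment score is monotone in bait counts and order-invariant", {
  lens <- c(Y1 = 400, B1 = 400)
  ctrl <- data.frame(run = paste0("ctrl_r", 1:3), bait = "CONTROL",
                     prey = "Y1", count = 2)
  score_for <- function(cts) {
    counts <- rbind(data.frame(run = paste0("b1_r", 1:3), bait = "B1",
                               prey = "Y1", count = cts), ctrl)
    tab <- toy_table(counts, lens, n_controls = 3)
    sc <- enrichment_probability(tab, "B1")
    sc$score[sc$prey == "Y1"]
  }
  s <- vapply(list(c(0, 1, 2), c(1, 1, 2), c(3, 1, 2), c(5, 5, 5),
                   c(9, 5, 5)), score_for, 0)
  expect_true(all(diff(s[c(1, 2, 3)]) >= 0))
  expect_gt(s[5], s[4])
  expect_equal(score_for(c(2, 1, 0)), score_for(c(0, 1, 2)))
})

test_that("interaction filtering applies inclusive threshold and extra rules", {
  scores <- data.frame(bait = "B1", prey = paste0("Y", 1:5),
                       score = c(0.9, 0.7, 0.65, 0.649, 0.1),
                       max_sc_bait = c(10, 10, 2, 10, 10),
                       max_sc_control = c(0, 0, 5, 0, 0))
  kept <- filter_interactions(scores, threshold = 0.65)
  expect_setequal(kept$prey, c("Y1", "Y2", "Y3"))  # 0.65 kept, 0.649 dropped
  expect_equal(nrow(filter_interactions(scores, threshold = 0)), 5)
  # strict max-SC excess drops ties and reversals
  kept_sc <- filter_interactions(scores, threshold = 0.65,
                                 require_max_sc_excess = TRUE)
  expect_setequal(kept_sc$prey, c("Y1", "Y2"))
  # contaminant frequency filter
  kept_cf <- filter_interactions(scores, threshold = 0.65,
                                 crapome = c(Y1 = 0.9, Y2 = 0.1),
                                 max_contaminant_freq = 0.5)
  expect_setequal(kept_cf$prey, c("Y2", "Y3"))
  expect_error(filter_interactions(scores, threshold = 1.2), "\\[0, 1\\]")
  # nesting: a lower threshold keeps a superset
  k1 <- filter_interactions(scores, 0.3)
  k2 <- filter_interactions(scores, 0.8)
  expect_true(all(paste(k2$bait, k2$prey) %in% paste(k1$bait, k1$prey)))
})

test_that("bait self-enrichment check reports exactly the degraded baits", {
  net <- data.frame(bait = rep(paste0("B", 1:5), each = 2),
                    prey = paste0("Y", 1:10), rate = 20)
  lens <- stats::setNames(rep(400, 15), c(paste0("Y", 1:10), paste0("B", 1:5)))
  tab <- simulate_ipms_counts(net, lens, bait_self_rate = 50, seed = 71)
  sc <- score_all_baits(tab)
  expect_equal(nrow(bait_self_enrichment_check(sc)), 0)
  # degrade bait B3: remove its self counts
  tab$counts <- tab$counts[!(tab$counts$bait == "B3" &
                             tab$counts$prey == "B3"), ]
  sc2 <- score_all_baits(tab)
  rep2 <- bait_self_enrichment_check(sc2)
  expect_equal(rep2$bait, "B3")
  expect_lte(rep2$self_score, 0.5)
})

test_that("network assembly annotates roles and extracts E2 cross-interactions", {
  edges <- data.frame(bait = c("B1", "B1", "B2"),
                      prey = c("Y1", "B2", "Y2"),
                      score = c(0.9, 0.8, 0.7))
  roles <- data.frame(protein = c("B1", "B2", "Y1"),
                      role = c("E2", "E2", "E3"))
  expect_warning(nw <- build_network(edges, roles), "other")
  expect_equal(nrow(nw$nodes), 4)
  expect_equal(nrow(nw$edges), 3)
  expect_equal(nw$nodes$role[nw$nodes$id == "Y2"], "other")
  expect_equal(igraph::vcount(nw$graph), 4)
  cross <- e2_cross_interactions(nw)
  expect_equal(nrow(cross), 1)
  expect_equal(cross$prey, "B2")
  empty <- build_network(edges[0, ])
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(igraph::ecount(empty$graph), 0)
})

test_that("contaminant-only tables pass the threshold at a bounded rate", {
  set.seed(91)
  lens <- stats::setNames(rep(400, 21), c(paste0("C", 1:20), "B1"))
  pass <- replicate(20, {
    tab <- simulate_ipms_counts(
      data.frame(bait = character(), prey = character(), rate = numeric()),
      lens, contaminants = stats::setNames(rep(2, 20), paste0("C", 1:20)),
      n_bait_reps = 3, n_controls = 10, baits = "B1",
      seed = sample.int(1e6, 1))
    sc <- enrichment_probability(tab, "B1")
    sc <- sc[sc$prey != "B1", ]
    mean(sc$score >= 0.65)
  })
  expect_lte(mean(pass), 0.35)
})

test_that("end-to-end recovery: strong true edges over weak contaminants", {
  set.seed(101)
  recalls <- fdps <- numeric(10)
  for (i in 1:10) {
    net <- data.frame(bait = rep(paste0("B", 1:4), each = 5),
                      prey = paste0("Y", 1:20), rate = 20)
    lens <- stats::setNames(
      rep(400, 34), c(paste0("Y", 1:20), paste0("B", 1:4), paste0("C", 1:10)))
    tab <- simulate_ipms_counts(
      net, lens,
      contaminants = stats::setNames(rep(2, 10), paste0("C", 1:10)),
      seed = 1000 + i)
    sc <- score_all_baits(tab)
    edges <- filter_interactions(sc, 0.65,
                                 crapome = control_detection_freq(tab),
                                 max_contaminant_freq = 0.5,
                                 require_max_sc_excess = TRUE)
    truth_key <- paste(net$bait, net$prey)
    got_key <- paste(edges$bait, edges$prey)
    recalls[i] <- mean(truth_key %in% got_key)
    fdps[i] <- if (length(got_key)) mean(!got_key %in% truth_key) else 0
  }
  expect_gte(mean(recalls), 0.95)
  expect_lte(mean(fdps), 0.05)
})

test_that("spectral-count tables round-trip through TSV", {
  net <- data.frame(bait = "B1", prey = c("Y1", "Y2"), rate = 15)
  lens <- stats::setNames(c(300, 500, 200), c("Y1", "Y2", "B1"))
  tab <- simulate_ipms_counts(net, lens, seed = 3)
  path <- file.path(withr::local_tempdir(), "counts.tsv")
  write_spectral_counts_tsv(tab, path)
  back <- read_spectral_counts_tsv(path)
  expect_equal(back$counts$count, tab$counts$count)
  expect_equal(back$lengths, tab$lengths)
})
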