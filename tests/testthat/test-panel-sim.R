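test_that("panel simulation is seeded, conservative and leaves the RNG alone", {
  cells <- rbind(
    data.frame(failure_id = "F1", factor = c("S", "O", "D"),
               p1 = 0.2, p2 = 0.2, p3 = 0.2, p4 = 0.2, p5 = 0.2),
    data.frame(failure_id = "F2", factor = c("S", "O", "D"),
               p1 = 0.2, p2 = 0.2, p3 = 0.2, p4 = 0.2, p5 = 0.2))
  cfg <- panel_config(35, cells, seed = 7)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)                         # bit-reproducible
  expect_equal(nrow(p1), 35 * 6)                   # one record per rater per cell
  expect_true(all(table(p1$failure_id, p1$factor) == 35))
  # a different seed changes the draw
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(simulate_panel(cfg2), p1))
  # global RNG state is preserved
  set.seed(1); before <- .Random.seed
  invisible(simulate_panel(cfg))
  expect_identical(.Random.seed, before)
  # degenerate distribution is deterministic regardless of seed
  dg <- panel_config(10, data.frame(failure_id = "F1", factor = "S",
                                    p1 = 0, p2 = 0, p3 = 1, p4 = 0, p5 = 0),
                     seed = 3)
  expect_true(all(simulate_panel(dg)$score == 3L))
})

test_that("panel configuration validates its distributions", {
  bad <- data.frame(failure_id = "F1", factor = "S",
                    p1 = 0.5, p2 = 0.5, p3 = 0.5, p4 = 0, p5 = 0)
  expect_error(panel_config(10, bad), "sum to 1")
  neg <- data.frame(failure_id = "F1", factor = "S",
                    p1 = -0.1, p2 = 0.4, p3 = 0.7, p4 = 0, p5 = 0)
  expect_error(panel_config(10, neg), "non-negative")
  expect_error(panel_config(0, data.frame(failure_id = "F1", factor = "S",
                                          p1 = 1, p2 = 0, p3 = 0, p4 = 0,
                                          p5 = 0)), "positive integer")
})

test_that("count fitting returns the first lexicographic composition that matches", {
  cv <- fit_counts_to_fuzzy_mean(c(0.429, 0.679, 0.900), n = 35)
  # eight compositions fit this 3-dp target; all share component sums
  # (15, 23.75, 31.5), and the lexicographically first is:
  expect_equal(unname(cv), c(0, 0, 14, 17, 4))
  sc <- case_scale()
  agg <- aggregate_mean(lapply(rep(sc$score, cv), fuzzify, scale = sc))
  expect_equal(unname(unclass(agg)), c(15, 23.75, 31.5) / 35)
  # the published example composition (0,3,8,20,4) is mean-equivalent
  alt <- aggregate_mean(lapply(rep(sc$score, c(0, 3, 8, 20, 4)),
                               fuzzify, scale = sc))
  expect_equal(unclass(alt), unclass(agg))
  # boundary: all mass on the top level
  expect_equal(unname(fit_counts_to_fuzzy_mean(c(0.75, 1, 1), n = 12)),
               c(0, 0, 0, 0, 12))
  # infeasible targets: broken TFN ordering, or no matching composition
  expect_null(fit_counts_to_fuzzy_mean(c(0, 1, 0), n = 35))
  expect_null(fit_counts_to_fuzzy_mean(c(0.001, 0.002, 0.003), n = 35))
})

test_that("fitting then aggregating recovers the target within 0.0005 per component", {
  sc <- case_scale()
  targets <- case_fuzzy_means()
  for (i in seq_len(nrow(targets))) {
    cv <- fit_counts_to_fuzzy_mean(unlist(targets[i, c("q", "o", "p")]), n = 35)
    expect_false(is.null(cv))
    agg <- aggregate_mean(lapply(rep(sc$score, cv), fuzzify, scale = sc))
    expect_true(all(abs(unclass(agg) -
                          unlist(targets[i, c("q", "o", "p")])) <= 5e-4 + 1e-12))
  }
  # and on random realizable targets (exact means of random panels)
  set.seed(41)
  for (k in 1:10) {
    scores <- sample(1:5, 20, replace = TRUE)
    target <- aggregate_mean(lapply(scores, fuzzify, scale = sc))
    cv <- fit_counts_to_fuzzy_mean(target, n = 20, tol = 1e-9)
    agg <- aggregate_mean(lapply(rep(sc$score, cv), fuzzify, scale = sc))
    expect_equal(unclass(agg), unclass(target), tolerance = 1e-9)
  }
})

test_that("the reconstructed case panel pushes through to the published FRPNs", {
  scores <- fmea_risk_scores(case_panel_fixture(), case_scale())
  pub <- case_published()
  got <- scores[match(pub$failure_id, scores$failure_id), ]
  expect_equal(round_half_up(got$frpn, 3), pub$frpn, tolerance = 1e-9)
})

test_that("rank stability: unanimity, single-replicate consistency, separation", {
  # unanimous panels: both rankings coincide in every replicate
  cells_u <- rbind(
    data.frame(failure_id = "A", factor = c("S", "O", "D"),
               p1 = 0, p2 = 0, p3 = 0, p4 = 0, p5 = 1),
    data.frame(failure_id = "B", factor = c("S", "O", "D"),
               p1 = 0, p2 = 0, p3 = 1, p4 = 0, p5 = 0))
  rs_u <- rank_stability(panel_config(5, cells_u, seed = 2), replicates = 5)
  expect_equal(rs_u$taus, rep(1, 5))

  # one replicate equals a direct scoring of the same simulated panel
  cells <- rbind(
    data.frame(failure_id = "A", factor = c("S", "O", "D"),
               p1 = 0.1, p2 = 0.2, p3 = 0.3, p4 = 0.2, p5 = 0.2),
    data.frame(failure_id = "B", factor = c("S", "O", "D"),
               p1 = 0.3, p2 = 0.3, p3 = 0.2, p4 = 0.1, p5 = 0.1))
  cfg <- panel_config(12, cells, seed = 9)
  rs1 <- rank_stability(cfg, replicates = 1)
  scores <- fmea_risk_scores(simulate_panel(cfg), case_scale())
  direct <- compare_rankings(
    stats::setNames(scores$rank, scores$failure_id),
    stats::setNames(scores$rank_traditional, scores$failure_id))
  expect_equal(rs1$taus, direct$kendall_tau)

  # well-separated modes: high-mode failure wins rank 1 in >= 95% of replicates
  cells_s <- rbind(
    data.frame(failure_id = "A", factor = c("S", "O", "D"),
               p1 = 0, p2 = 0, p3 = 0.1, p4 = 0.2, p5 = 0.7),
    data.frame(failure_id = "B", factor = c("S", "O", "D"),
               p1 = 0.7, p2 = 0.2, p3 = 0.1, p4 = 0, p5 = 0))
  rs_s <- rank_stability(panel_config(15, cells_s, seed = 42), replicates = 200)
  expect_gte(rs_s$rank_freq["A", "rank1"] / 200, 0.95)
  expect_equal(rowSums(rs_s$rank_freq), c(A = 200, B = 200))
})
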