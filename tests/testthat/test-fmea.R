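test_that("fuzzy factor means aggregate each (failure, factor) cell", {
  sc <- case_scale()
  unanimous <- data.frame(rater_id = sprintf("r%02d", 1:35),
                          failure_id = "F1", factor = "S", score = 5L)
  fm <- compute_fuzzy_factor_means(unanimous, sc)
  expect_equal(unlist(fm[1, c("q", "o", "p")], use.names = FALSE),
               c(0.75, 1, 1))
  panel <- data.frame(rater_id = sprintf("r%02d", 1:35), failure_id = "F1",
                      factor = "S", score = rep(1:5, c(0, 3, 8, 20, 4)))
  fm <- compute_fuzzy_factor_means(panel, sc)
  expect_equal(round_half_up(unlist(fm[1, c("q", "o", "p")], use.names = FALSE), 3),
               c(0.429, 0.679, 0.900))
  # a registered failure with no ratings is a hard error, not an imputation
  reg <- case_register_fixture()
  expect_error(compute_fuzzy_factor_means(panel, sc, register = reg),
               "\\(F1, O\\)")
})

test_that("FRPN is the product of the defuzzified factors and validates inputs", {
  expect_equal(round_half_up(compute_frpn(0.669, 0.657, 0.667), 3), 0.293)
  expect_equal(round_half_up(compute_frpn(0.610, 0.607, 0.633), 3), 0.234)
  expect_equal(compute_frpn(1, 1, 1), 1)
  expect_error(compute_frpn(1.2, 0.5, 0.5), "\\[0, 1\\]")
  # strictly increasing in each factor when the others are positive
  expect_gt(compute_frpn(0.61, 0.5, 0.5), compute_frpn(0.60, 0.5, 0.5))
  expect_gt(compute_frpn(0.5, 0.5, 0.61), compute_frpn(0.5, 0.5, 0.60))
})

test_that("traditional RPN is the product of per-factor raw-score means", {
  panel <- rbind(
    data.frame(rater_id = "r1", failure_id = "F1",
               factor = c("S", "O", "D"), score = c(3L, 4L, 5L)),
    data.frame(rater_id = "r2", failure_id = "F1",
               factor = c("S", "O", "D"), score = c(5L, 4L, 3L)))
  expect_equal(compute_traditional_rpn(panel)$traditional_rpn, 64)
  all5 <- data.frame(rater_id = rep(sprintf("r%d", 1:4), each = 3),
                     failure_id = "F1", factor = c("S", "O", "D"), score = 5L)
  expect_equal(compute_traditional_rpn(all5)$traditional_rpn, 125)
  all1 <- transform(all5, score = 1L)
  expect_equal(compute_traditional_rpn(all1)$traditional_rpn, 1)
})

test_that("ranking is descending, deterministic on ties, and a permutation", {
  frpn <- data.frame(failure_id = paste0("F", 1:6),
                     frpn = c(0.293, 0.228, 0.188, 0.207, 0.173, 0.234))
  ranked <- rank_failures(frpn, "frpn")
  expect_equal(stats::setNames(ranked$rank, ranked$failure_id),
               c(F1 = 1L, F2 = 3L, F3 = 5L, F4 = 4L, F5 = 6L, F6 = 2L))
  one <- rank_failures(data.frame(failure_id = "F9", frpn = 0.5), "frpn")
  expect_equal(one$rank, 1L)
  tie <- rank_failures(data.frame(failure_id = c("B", "A"), frpn = c(0.4, 0.4)),
                       "frpn")
  expect_equal(tie$rank[tie$failure_id == "A"], 1L)
  expect_equal(tie$rank[tie$failure_id == "B"], 2L)
  expect_error(rank_failures(data.frame(failure_id = c("A", "A"),
                                        frpn = c(1, 2)), "frpn"),
               "duplicate")
  # permutation invariant on random score sets
  set.seed(5)
  for (k in 1:20) {
    n <- sample(2:9, 1)
    r <- rank_failures(data.frame(failure_id = sample(LETTERS, n),
                                  frpn = runif(n)), "frpn")
    expect_setequal(r$rank, seq_len(n))
  }
})

test_that("ranking comparison reports rank correlations and disagreeing ids", {
  fz <- c(F1 = 1, F2 = 3, F3 = 5, F4 = 4, F5 = 6, F6 = 2)
  tr <- c(F1 = 1, F2 = 3, F3 = 6, F4 = 4, F5 = 5, F6 = 2)
  cmp <- compare_rankings(fz, tr)
  expect_equal(cmp$kendall_tau, 13 / 15)
  expect_equal(cmp$kendall_tau, oracle_kendall(fz, tr))
  expect_equal(cmp$disagreements, c("F3", "F5"))
  same <- compare_rankings(fz, fz)
  expect_equal(same$kendall_tau, 1)
  expect_equal(same$spearman_rho, 1)
  expect_length(same$disagreements, 0)
  rev3 <- compare_rankings(c(a = 1, b = 2, c = 3), c(a = 3, b = 2, c = 1))
  expect_equal(rev3$kendall_tau, -1)
  expect_error(compare_rankings(fz, fz[-1]), "different failure id sets")
  # agreement with the brute-force oracle on random permutations
  set.seed(31)
  for (k in 1:15) {
    n <- sample(3:8, 1)
    a <- stats::setNames(sample(n), letters[seq_len(n)])
    b <- stats::setNames(sample(n), letters[seq_len(n)])
    expect_equal(compare_rankings(a, b)$kendall_tau, oracle_kendall(a, b))
  }
})

test_that("expert vote percentages reproduce the published tally and sum to 100", {
  counts <- c(traditional_rpn = 3L, fuzzy_rpn = 10L)
  pct <- expert_vote_summary(counts)
  expect_equal(unname(pct["fuzzy_rpn"]), 76.93)
  expect_equal(unname(pct["traditional_rpn"]), 23.07)
  expect_equal(sum(pct), 100)
  expect_equal(attr(pct, "n_experts"), 13L)
  # independent half-up convention
  pct2 <- expert_vote_summary(counts, convention = "half_up")
  expect_equal(unname(pct2["fuzzy_rpn"]), 76.92)
  expect_equal(unname(pct2["traditional_rpn"]), 23.08)
  expect_equal(unname(expert_vote_summary(c(a = 0L, b = 7L))["a"]), 0)
  expect_error(expert_vote_summary(c(a = 0L, b = 0L)), "at least one")
  votes <- read_expert_votes(fmeatriz_extdata("expert_votes.csv"))
  expect_equal(sum(votes), 13L)
  expect_equal(unname(expert_vote_summary(votes)["fuzzy_rpn"]), 76.93)
})

test_that("fuzzy and traditional rankings coincide on comonotone unanimous panels", {
  # per-factor defuzzified level values are strictly increasing in the score,
  # so componentwise-ordered unanimous score triples keep both orderings
  sc <- case_scale()
  level_crisp <- vapply(1:5, function(s) defuzzify(fuzzify(s, sc)), numeric(1))
  expect_true(all(diff(level_crisp) > 0))
  set.seed(17)
  for (k in 1:10) {
    n_fail <- sample(3:5, 1)
    base <- sort(sample(1:5, n_fail, replace = TRUE))
    triples <- cbind(base, base, base)  # componentwise ordered by construction
    panel <- do.call(rbind, lapply(seq_len(n_fail), function(i) {
      data.frame(rater_id = c("r1", "r2"), failure_id = sprintf("G%d", i),
                 factor = rep(c("S", "O", "D"), each = 2),
                 score = rep(triples[i, ], each = 2))
    }))
    scores <- fmea_risk_scores(panel, sc)
    cmp <- compare_rankings(
      stats::setNames(scores$rank, scores$failure_id),
      stats::setNames(scores$rank_traditional, scores$failure_id))
    expect_equal(cmp$kendall_tau, 1)
  }
})

test_that("non-comonotone unanimous panels can invert the two rankings", {
  # the two risk keys are products of different per-factor transforms, so
  # they are not order-equivalent in general: (1,5,5) beats (2,3,4) on the
  # traditional key (25 > 24) but loses on FRPN (121/1728 < 3/32)
  sc <- case_scale()
  panel <- rbind(
    data.frame(rater_id = "r1", failure_id = "A",
               factor = c("S", "O", "D"), score = c(1L, 5L, 5L)),
    data.frame(rater_id = "r1", failure_id = "B",
               factor = c("S", "O", "D"), score = c(2L, 3L, 4L)))
  scores <- fmea_risk_scores(panel, sc)
  expect_equal(scores$rank_traditional[scores$failure_id == "A"], 1L)
  expect_equal(scores$rank[scores$failure_id == "A"], 2L)
})

test_that("the reconstructed case panel reproduces the published worksheet", {
  scores <- fmea_risk_scores(case_panel_fixture(), case_scale(),
                             register = case_register_fixture())
  pub <- case_published()
  got <- scores[match(pub$failure_id, scores$failure_id), ]
  expect_equal(round_half_up(got$s_defuzz, 3), pub$s, tolerance = 1e-9)
  expect_equal(round_half_up(got$o_defuzz, 3), pub$o, tolerance = 1e-9)
  expect_equal(round_half_up(got$d_defuzz, 3), pub$d, tolerance = 1e-9)
  expect_equal(round_half_up(got$frpn, 3), pub$frpn, tolerance = 1e-9)
  expect_equal(got$rank, pub$rank)
  expect_equal(attr(scores, "defuzz_method"), "centroid")
})

test_that("panel validation rejects malformed records", {
  good <- data.frame(rater_id = "r1", failure_id = "F1", factor = "S", score = 3L)
  expect_silent(validate_panel(good))
  expect_error(validate_panel(transform(good, factor = "X")), "unknown factor")
  expect_error(validate_panel(transform(good, score = 0L)), "1\\.\\.5")
  expect_error(validate_panel(rbind(good, good)), "duplicate rating")
})
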