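# shared fixtures for the bundled CMEC case study, built in code

case_scale <- function() default_scale()

case_register_fixture <- function() {
  read_register(fmeatriz_extdata("case_register.json"))
}

# full 18-cell panel reconstructed from the published fuzzy means
case_panel_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_panel_from_means(case_fuzzy_means(), n = 35)
    }
    cache
  }
})

# published per-failure worksheet values (3 dp) for cross-checks
case_published <- function() {
  data.frame(
    failure_id = paste0("F", 1:6),
    s = c(0.669, 0.593, 0.598, 0.598, 0.538, 0.610),
    o = c(0.657, 0.640, 0.560, 0.602, 0.562, 0.607),
    d = c(0.667, 0.600, 0.562, 0.576, 0.571, 0.633),
    frpn = c(0.293, 0.228, 0.188, 0.207, 0.173, 0.234),
    rank = c(1L, 3L, 5L, 4L, 6L, 2L))
}

# brute-force Kendall tau over all pairs (independent oracle)
oracle_kendall <- function(a, b) {
  b <- b[names(a)]
  n <- length(a); conc <- 0; disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(a[[i]] - a[[j]]) * sign(b[[i]] - b[[j]])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / (n * (n - 1) / 2)
}

# random valid blueprint generator for round-trip property tests
random_blueprint <- function(n_actions = 6L) {
  lanes <- c("customer", "front_stage", "back_stage", "support")
  ids <- sprintf("a%02d", seq_len(n_actions))
  lane <- sample(lanes, n_actions, replace = TRUE)
  actions <- lapply(seq_len(n_actions), function(i) {
    # successors only point forward (acyclic) and respect the line of
    # interaction: customer nodes link only to front_stage and vice versa
    later <- which(seq_len(n_actions) > i)
    ok <- later[vapply(later, function(j) {
      l <- c(lane[i], lane[j])
      !("customer" %in% l) || setequal(l, c("customer", "front_stage")) ||
        all(l == "customer")
    }, logical(1))]
    n_succ <- min(length(ok), sample(0:2, 1))
    succ <- if (length(ok)) ids[ok[sample.int(length(ok), n_succ)]] else character(0)
    list(id = ids[i], lane = lane[i], label = paste("action", i),
         successors = as.list(succ))
  })
  n_fp <- sample(0:3, 1)
  fps <- lapply(seq_len(n_fp), function(k) {
    list(failure_id = paste0("F", k), action_id = sample(ids, 1),
         note = paste("note", k))
  })
  fmeatriz:::as_service_blueprint(list(title = "random", scenario = "mild",
                                       actions = actions, failure_points = fps))
}
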