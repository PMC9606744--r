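#' Configuration for a simulated rater panel
#'
#' Describes a synthetic Likert panel: the rater count (the bundled case
#' study emulates panels of 35), one categorical distribution over scores
#' 1..5 per (failure, factor) cell, and the seed driving the single
#' Mersenne-Twister stream used by [simulate_panel()]. All simulation is
#' bit-reproducible under a fixed seed and leaks no global RNG state.
#'
#' @param n_raters integer >= 1
#' @param cells data frame with columns `failure_id`, `factor` and the five
#'   probability columns `p1`..`p5`; each row must sum to 1 within 1e-9
#' @param seed integer seed
#' @return object of class `"panel_config"`
#' @export
#' @examples
#' cfg <- panel_config(10, data.frame(failure_id = "F1", factor = "S",
#'                                    p1 = 0, p2 = 0, p3 = 1, p4 = 0, p5 = 0),
#'                     seed = 1)
panel_config <- function(n_raters = 35L, cells, seed = 1L) {
  pcols <- paste0("p", 1:5)
  if (!is.data.frame(cells) ||
      !all(c("failure_id", "factor", pcols) %in% names(cells))) {
    stop_validation("cells need columns failure_id, factor, p1..p5")
  }
  if (n_raters < 1 || n_raters != as.integer(n_raters)) {
    stop_validation("n_raters must be a positive integer")
  }
  pm <- as.matrix(cells[, pcols])
  if (any(pm < 0) || any(abs(rowSums(pm) - 1) > 1e-9)) {
    stop_validation("each cell's score distribution must be non-negative and sum to 1")
  }
  bad <- setdiff(unique(as.character(cells$factor)), c("S", "O", "D"))
  if (length(bad)) stop_validation("unknown factor label(s): %s",
                                   paste(bad, collapse = ", "))
  structure(list(n_raters = as.integer(n_raters), cells = cells,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Simulate a rating panel
#'
#' Draws one 1..5 score per rater per configured cell from that cell's
#' categorical distribution. Identical configuration (seed included) yields
#' an identical panel; the caller's RNG state is untouched.
#'
#' @param config a [panel_config]
#' @return rating-panel data frame (`rater_id`, `failure_id`, `factor`,
#'   `score`) accepted by [fmea_risk_scores()]
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  n <- config$n_raters
  raters <- sprintf("r%02d", seq_len(n))
  with_local_seed(config$seed, {
    rows <- lapply(seq_len(nrow(config$cells)), function(i) {
      p <- as.numeric(config$cells[i, paste0("p", 1:5)])
      data.frame(rater_id = raters,
                 failure_id = as.character(config$cells$failure_id[i]),
                 factor = as.character(config$cells$factor[i]),
                 score = sample(1:5, n, replace = TRUE, prob = p))
    })
    do.call(rbind, rows)
  })
}

# lexicographic compositions of n into 5 non-negative parts, cached per n
composition_cache <- new.env(parent = emptyenv())
compositions5 <- function(n) {
  key <- as.character(n)
  if (!is.null(composition_cache[[key]])) return(composition_cache[[key]])
  blocks <- vector("list", 0L)
  for (c1 in 0:n) for (c2 in 0:(n - c1)) {
    r <- n - c1 - c2
    c3 <- rep.int(0:r, (r:0) + 1L)
    c4 <- sequence((r:0) + 1L) - 1L
    blocks[[length(blocks) + 1L]] <- cbind(c1, c2, c3, c4, r - c3 - c4)
  }
  m <- do.call(rbind, blocks)
  dimnames(m) <- NULL
  composition_cache[[key]] <- m
  m
}

#' Fit a per-cell count vector to a target fuzzy mean
#'
#' Reverse-engineers a cell: finds non-negative integer counts over the five
#' scale levels, summing to `n`, whose fuzzified component-wise means match
#' the target TFN within `tol` per component. The search enumerates all
#' compositions of `n` into five parts exhaustively (82,251 for n = 35) and
#' returns the first hit in lexicographic order, so the result is
#' deterministic. Published 3-dp means are reproducible at the default
#' tolerance because rounding perturbs each component by at most 0.0005.
#'
#' Several compositions can match one rounded target; all such candidates
#' share the same component sums whenever the tolerance window contains a
#' single attainable sum (the attainable component sums are multiples of
#' 1/(4n)), so downstream means, defuzzified values and risk numbers do not
#' depend on the choice.
#'
#' @param target a [tfn] (or numeric triple) of component means
#' @param n rater count
#' @param scale a [linguistic_scale]
#' @param tol per-component absolute tolerance (default 5e-4)
#' @return integer count vector over scores 1..5 (named by scale label), or
#'   `NULL` if no composition matches (infeasible target)
#' @export
#' @examples
#' fit_counts_to_fuzzy_mean(c(0.75, 1, 1), n = 10)  # all raters at score 5
fit_counts_to_fuzzy_mean <- function(target, n = 35L, scale = default_scale(),
                                     tol = 5e-4) {
  target <- tryCatch(as_tfn(target), error = function(e) NULL)
  if (is.null(target)) return(NULL)  # e.g. violates TFN ordering: infeasible
  comp <- compositions5(as.integer(n))
  qm <- comp %*% scale$q / n
  om <- comp %*% scale$o / n
  pm <- comp %*% scale$p / n
  hit <- which(abs(qm - target[[1]]) <= tol + 1e-12 &
               abs(om - target[[2]]) <= tol + 1e-12 &
               abs(pm - target[[3]]) <= tol + 1e-12)[1]
  if (is.na(hit)) return(NULL)
  stats::setNames(as.integer(comp[hit, ]), scale$label)
}

#' Build a rating panel from a table of target fuzzy means
#'
#' Fits a count vector per (failure, factor) cell with
#' [fit_counts_to_fuzzy_mean()] and expands the counts into rater records
#' (scores assigned in ascending order across rater ids, deterministically).
#' This reconstructs a full panel that is mean-faithful to published summary
#' tables; the bundled case table
#' (`fmeatriz_extdata("case_fuzzy_means.csv")`) carries the 18 cells of the
#' CMEC study.
#'
#' @param targets data frame with columns `failure_id`, `factor`, `q`, `o`,
#'   `p` (one row per cell)
#' @param n rater count per cell
#' @param scale a [linguistic_scale]
#' @param tol per-component fit tolerance
#' @return rating-panel data frame; fitted counts attached as attribute
#'   `"counts"`
#' @export
build_panel_from_means <- function(targets, n = 35L, scale = default_scale(),
                                   tol = 5e-4) {
  req <- c("failure_id", "factor", "q", "o", "p")
  if (!is.data.frame(targets) || !all(req %in% names(targets))) {
    stop_validation("targets need columns %s", paste(req, collapse = ", "))
  }
  raters <- sprintf("r%02d", seq_len(n))
  rows <- list(); counts <- list()
  for (i in seq_len(nrow(targets))) {
    cv <- fit_counts_to_fuzzy_mean(c(targets$q[i], targets$o[i], targets$p[i]),
                                   n = n, scale = scale, tol = tol)
    if (is.null(cv)) {
      stop_validation("no count vector of %d raters fits cell (%s, %s) within %g",
                      n, targets$failure_id[i], targets$factor[i], tol)
    }
    counts[[paste(targets$failure_id[i], targets$factor[i])]] <- cv
    rows[[i]] <- data.frame(rater_id = raters,
                            failure_id = as.character(targets$failure_id[i]),
                            factor = as.character(targets$factor[i]),
                            score = rep(scale$score, cv))
  }
  out <- do.call(rbind, rows)
  attr(out, "counts") <- counts
  out
}

#' Case-study fuzzy-mean targets
#'
#' The 18 published component-wise fuzzy means (6 failure modes x 3 factors,
#' 35 raters) of the bundled CMEC case study.
#'
#' @return data frame with columns `failure_id`, `factor`, `q`, `o`, `p`
#' @export
case_fuzzy_means <- function() {
  utils::read.csv(fmeatriz_extdata("case_fuzzy_means.csv"),
                  stringsAsFactors = FALSE)
}

#' Rank stability of fuzzy vs traditional prioritization under resampling
#'
#' Repeatedly simulates panels from a configuration, scores each both ways
#' (FRPN and traditional crisp RPN), ranks, and tallies: per-failure rank
#' frequencies under the fuzzy ranking, and the Kendall tau between the two
#' rankings per replicate. Replicate r uses seed `config$seed + r - 1`, so
#' the whole analysis is reproducible.
#'
#' @param config a [panel_config]
#' @param replicates number of simulated panels (>= 1)
#' @param scale a [linguistic_scale]
#' @param method defuzzification method for the fuzzy side
#' @return list with `rank_freq` (failures x ranks count matrix, fuzzy
#'   ranking), `taus` (per-replicate Kendall tau), `mean_tau`, `replicates`
#' @export
rank_stability <- function(config, replicates = 100L,
                           scale = default_scale(),
                           method = c("centroid", "trapezoidal_eq4")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "panel_config"))
  if (replicates < 1) stop_validation("replicates must be >= 1")
  fids <- sort(unique(as.character(config$cells$failure_id)))
  rank_freq <- matrix(0L, nrow = length(fids), ncol = length(fids),
                      dimnames = list(fids, paste0("rank", seq_along(fids))))
  taus <- numeric(replicates)
  for (r in seq_len(replicates)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r - 1L
    panel <- simulate_panel(cfg_r)
    scores <- suppressMessages(fmea_risk_scores(panel, scale, method = method))
    fz <- stats::setNames(scores$rank, scores$failure_id)
    tr <- stats::setNames(scores$rank_traditional, scores$failure_id)
    taus[r] <- compare_rankings(fz, tr)$kendall_tau
    for (f in fids) rank_freq[f, fz[[f]]] <- rank_freq[f, fz[[f]]] + 1L
  }
  list(rank_freq = rank_freq, taus = taus, mean_tau = mean(taus),
       replicates = as.integer(replicates))
}
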