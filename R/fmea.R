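#' Validate a rating panel
#'
#' A rating panel is a long-format data frame with one row per
#' (rater, failure mode, factor) holding a 1..5 Likert score. Factors are
#' `"S"` (severity), `"O"` (occurrence) and `"D"` (detectability).
#' Duplicate (rater, failure, factor) records are rejected; missing cells
#' are a hard error downstream rather than being imputed.
#'
#' @param panel data frame with columns `rater_id`, `failure_id`, `factor`,
#'   `score`
#' @param register optional failure register (see [read_register]); when
#'   given, every registered failure must have at least one record for each
#'   of S, O and D
#' @return the panel, invisibly, with `factor` normalised to character
#' @export
validate_panel <- function(panel, register = NULL) {
  req <- c("rater_id", "failure_id", "factor", "score")
  if (!is.data.frame(panel) || !all(req %in% names(panel))) {
    stop_validation("a rating panel needs columns %s", paste(req, collapse = ", "))
  }
  panel$factor <- as.character(panel$factor)
  bad_factor <- setdiff(unique(panel$factor), c("S", "O", "D"))
  if (length(bad_factor)) {
    stop_validation("unknown factor label(s): %s (expected S, O, D)",
                    paste(bad_factor, collapse = ", "))
  }
  if (any(is.na(panel$score)) || any(panel$score != as.integer(panel$score)) ||
      any(panel$score < 1) || any(panel$score > 5)) {
    stop_validation("scores must be integers in 1..5")
  }
  key <- paste(panel$rater_id, panel$failure_id, panel$factor, sep = "\r")
  if (anyDuplicated(key)) {
    d <- panel[duplicated(key), , drop = FALSE][1, ]
    stop_validation("duplicate rating for (rater %s, failure %s, factor %s)",
                    d$rater_id, d$failure_id, d$factor)
  }
  if (!is.null(register)) {
    need <- expand.grid(failure_id = register$id, factor = c("S", "O", "D"),
                        stringsAsFactors = FALSE)
    have <- unique(panel[, c("failure_id", "factor")])
    miss <- need[!paste(need$failure_id, need$factor) %in%
                   paste(have$failure_id, have$factor), , drop = FALSE]
    if (nrow(miss)) {
      stop_validation(
        "panel has no ratings for registered cell(s): %s",
        paste(sprintf("(%s, %s)", miss$failure_id, miss$factor), collapse = ", "))
    }
  }
  invisible(panel)
}

#' Aggregated fuzzy factor means of a rating panel
#'
#' Fuzzifies every record on the linguistic scale and aggregates each
#' (failure, factor) cell to its component-wise fuzzy mean: with `n` raters
#' in a cell the aggregated triple is the mean of the lower bounds, of the
#' modes and of the upper bounds of the raters' TFNs.
#'
#' @inheritParams validate_panel
#' @param scale a [linguistic_scale]
#' @return data frame with one row per (failure, factor): columns
#'   `failure_id`, `factor`, `q`, `o`, `p`, `n_raters`
#' @export
compute_fuzzy_factor_means <- function(panel, scale = default_scale(),
                                       register = NULL) {
  panel <- validate_panel(panel, register)
  m <- fuzzify_matrix(panel$score, scale)
  cell <- interaction(panel$failure_id, panel$factor, drop = TRUE, sep = "\r")
  agg <- t(vapply(split(seq_len(nrow(panel)), cell),
                  function(i) c(rowMeans(m[, i, drop = FALSE]), n = length(i)),
                  numeric(4)))
  keys <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  out <- data.frame(failure_id = keys[, 1], factor = keys[, 2],
                    q = agg[, "q"], o = agg[, "o"], p = agg[, "p"],
                    n_raters = as.integer(agg[, "n"]))
  out <- out[order(out$failure_id, match(out$factor, c("S", "O", "D"))), ]
  rownames(out) <- NULL
  out
}

# crisp value of (q, o, p) triples, vectorised, no notice
defuzz_values <- function(q, o, p, method = c("centroid", "trapezoidal_eq4")) {
  method <- match.arg(method)
  if (method == "centroid") (q + o + p) / 3 else (q + 2 * o + p) / 4
}

#' Fuzzy risk priority number
#'
#' The FRPN of a failure mode is the product of its defuzzified severity,
#' occurrence and detectability values, each in \[0, 1\], so the FRPN is in
#' \[0, 1\] as well. Reported values are conventionally rounded half-up to
#' 3 dp; this function returns full precision.
#'
#' @param s,o,d crisp defuzzified factor values in \[0, 1\] (vectorised)
#' @return numeric FRPN(s)
#' @export
#' @examples
#' compute_frpn(0.669, 0.657, 0.667)  # ~0.293
compute_frpn <- function(s, o, d) {
  v <- c(s, o, d)
  if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
    stop_validation("defuzzified factor values must lie in [0, 1]")
  }
  s * o * d
}

#' Traditional (crisp) risk priority number of a panel
#'
#' Per failure mode, the product of the three per-factor arithmetic means of
#' the raw 1..5 scores — the standard crisp-FMEA panel RPN, in \[1, 125\].
#'
#' @inheritParams compute_fuzzy_factor_means
#' @return data frame with columns `failure_id`, `traditional_rpn`
#' @export
compute_traditional_rpn <- function(panel, register = NULL) {
  panel <- validate_panel(panel, register)
  means <- aggregate(score ~ failure_id + factor, data = panel, FUN = mean)
  rpn <- vapply(split(means, means$failure_id), function(d) {
    if (nrow(d) != 3L) {
      stop_validation("failure %s is missing factor(s): %s", d$failure_id[1],
                      paste(setdiff(c("S", "O", "D"), d$factor), collapse = ", "))
    }
    prod(d$score)
  }, numeric(1))
  data.frame(failure_id = names(rpn), traditional_rpn = unname(rpn))
}

#' Score and rank the failure modes of a rating panel
#'
#' Runs the full risk-scoring stage: fuzzify, aggregate per cell, defuzzify
#' each factor, multiply into the FRPN, compute the traditional crisp RPN
#' alongside, and rank by FRPN (rank 1 = highest risk).
#'
#' @inheritParams compute_fuzzy_factor_means
#' @param method defuzzification method, see [defuzzify()]; choosing
#'   `"trapezoidal_eq4"` emits the method-discrepancy notice once
#' @return data frame of class `"risk_scores"`, one row per failure:
#'   `failure_id`, `s_defuzz`, `o_defuzz`, `d_defuzz`, `frpn`,
#'   `traditional_rpn`, `rank`, `rank_traditional`; full precision, with the
#'   fuzzy factor means attached as attribute `"factor_means"`
#' @export
fmea_risk_scores <- function(panel, scale = default_scale(),
                             method = c("centroid", "trapezoidal_eq4"),
                             register = NULL) {
  method <- match.arg(method)
  if (method == "trapezoidal_eq4") {
    # same notice as defuzzify(), emitted once for the whole worksheet
    message(paste(
      "defuzzification method 'trapezoidal_eq4' ((q + 2o + p)/4) does not",
      "reproduce the bundled case study's published defuzzified values;",
      "'centroid' ((q + o + p)/3) does. Choose deliberately."))
  }
  fm <- compute_fuzzy_factor_means(panel, scale, register)
  fm$defuzz <- defuzz_values(fm$q, fm$o, fm$p, method)
  wide <- stats::reshape(fm[, c("failure_id", "factor", "defuzz")],
                         idvar = "failure_id", timevar = "factor",
                         direction = "wide")
  names(wide) <- sub("^defuzz\\.", "", names(wide))
  if (!all(c("S", "O", "D") %in% names(wide)) || anyNA(wide[c("S", "O", "D")])) {
    miss <- wide$failure_id[rowSums(is.na(wide[intersect(c("S", "O", "D"),
                                                         names(wide))])) > 0]
    stop_validation("failure(s) missing a factor cell: %s",
                    paste(miss, collapse = ", "))
  }
  out <- data.frame(failure_id = wide$failure_id,
                    s_defuzz = wide$S, o_defuzz = wide$O, d_defuzz = wide$D)
  out$frpn <- compute_frpn(out$s_defuzz, out$o_defuzz, out$d_defuzz)
  out <- merge(out, compute_traditional_rpn(panel), by = "failure_id")
  out <- rank_failures(out, key = "frpn")
  names(out)[names(out) == "rank"] <- "rank_frpn"
  out <- rank_failures(out, key = "traditional")
  names(out)[names(out) == "rank"] <- "rank_traditional"
  names(out)[names(out) == "rank_frpn"] <- "rank"
  out <- out[order(out$failure_id), ]
  rownames(out) <- NULL
  attr(out, "factor_means") <- fm[, c("failure_id", "factor", "q", "o", "p",
                                      "n_raters")]
  attr(out, "defuzz_method") <- method
  class(out) <- c("risk_scores", "data.frame")
  out
}

#' Rank failure modes by a risk key
#'
#' Adds a dense `rank` column: rank 1 for the largest key value, descending
#' order, ties broken deterministically by ascending failure id. The ranks
#' always form a permutation of `1..N`.
#'
#' @param scores data frame with a `failure_id` column and the key column
#' @param key `"frpn"` or `"traditional"` (column `traditional_rpn`)
#' @return `scores` with a `rank` column
#' @export
rank_failures <- function(scores, key = c("frpn", "traditional")) {
  key <- match.arg(key)
  col <- if (key == "frpn") "frpn" else "traditional_rpn"
  if (!is.data.frame(scores) || !all(c("failure_id", col) %in% names(scores))) {
    stop_validation("scores need columns 'failure_id' and '%s'", col)
  }
  if (anyDuplicated(scores$failure_id)) {
    stop_validation("duplicate failure id(s): %s",
                    paste(unique(scores$failure_id[duplicated(scores$failure_id)]),
                          collapse = ", "))
  }
  ord <- order(-scores[[col]], scores$failure_id)
  scores$rank <- NA_integer_
  scores$rank[ord] <- seq_len(nrow(scores))
  scores
}

#' Compare two rankings of the same failure modes
#'
#' Rank-correlation report between two rankings (e.g. FRPN-based vs
#' traditional-RPN-based): Kendall tau, Spearman rho, and the ids whose
#' ranks differ.
#'
#' @param a,b named integer vectors of ranks (names = failure ids) or data
#'   frames with `failure_id` and `rank` columns; the id sets must match
#' @return list with elements `kendall_tau`, `spearman_rho`,
#'   `disagreements` (character vector of ids), `n`
#' @export
#' @examples
#' compare_rankings(c(F1 = 1, F2 = 2, F3 = 3), c(F1 = 1, F2 = 3, F3 = 2))
compare_rankings <- function(a, b) {
  as_rank_vec <- function(x) {
    if (is.data.frame(x)) x <- stats::setNames(x$rank, x$failure_id)
    if (is.null(names(x))) stop_validation("rankings must be named by failure id")
    x
  }
  a <- as_rank_vec(a); b <- as_rank_vec(b)
  if (!setequal(names(a), names(b)) || length(a) != length(b)) {
    stop_validation("rankings cover different failure id sets")
  }
  b <- b[names(a)]
  list(
    kendall_tau  = unname(stats::cor(a, b, method = "kendall")),
    spearman_rho = unname(stats::cor(a, b, method = "spearman")),
    disagreements = sort(names(a)[a != b]),
    n = length(a))
}

#' Summarise an expert vote tally as percentages
#'
#' Each expert endorses exactly one option; the tally is summarised as
#' per-option percentages at 2 dp. The default convention truncates each
#' option's share at 2 dp and credits the truncation residue to the winning
#' option, so the column sums to exactly 100 and the winner's share is the
#' complement of the others (10 of 13 gives 76.93 / 23.07). The plain
#' `"half_up"` convention rounds each share independently (76.92 / 23.08).
#'
#' @param counts named non-negative integer vector of votes per option
#' @param convention `"residual_to_winner"` (default) or `"half_up"`
#' @return named numeric vector of percentages (2 dp), with the total vote
#'   count as attribute `"n_experts"`
#' @export
#' @examples
#' expert_vote_summary(c(traditional = 3, fuzzy = 10))
expert_vote_summary <- function(counts,
                                convention = c("residual_to_winner", "half_up")) {
  convention <- match.arg(convention)
  if (length(counts) == 0L || is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop_validation("counts must be a named vector of per-option votes")
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != as.integer(counts))) {
    stop_validation("vote counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total < 1) stop_validation("at least one expert vote is required")
  raw <- 100 * counts / total
  if (convention == "half_up") {
    pct <- round_half_up(raw, 2)
  } else {
    pct <- floor(raw * 100 + 1e-9) / 100
    residue <- round(100 - sum(pct), 10)
    winner <- which.max(counts)  # tie: first option in input order
    pct[winner] <- pct[winner] + residue
  }
  structure(round_half_up(pct, 2), n_experts = total)
}
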