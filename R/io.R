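#' Read and write rating panels as CSV
#'
#' The ratings CSV is long-format UTF-8 with a header and columns
#' `rater_id`, `failure_id`, `factor` (S/O/D), `score` (1..5). Malformed
#' rows are reported with their line number. Write-then-read is lossless.
#'
#' @param path CSV file path
#' @return validated rating-panel data frame
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  req <- c("rater_id", "failure_id", "factor", "score")
  if (!all(req %in% names(df))) {
    stop_validation("ratings file %s lacks column(s): %s", path,
                    paste(setdiff(req, names(df)), collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score) | score != as.integer(score) | score < 1 | score > 5)
  if (length(bad)) {
    stop_validation("ratings file %s line %d: invalid score '%s'",
                    path, bad[1] + 1L, df$score[bad[1]])  # +1 for header
  }
  badf <- which(!df$factor %in% c("S", "O", "D"))
  if (length(badf)) {
    stop_validation("ratings file %s line %d: unknown factor label '%s'",
                    path, badf[1] + 1L, df$factor[badf[1]])
  }
  df$score <- as.integer(score)
  validate_panel(df)
  df[req]
}

#' @rdname read_ratings
#' @param panel rating-panel data frame
#' @export
write_ratings <- function(panel, path) {
  panel <- validate_panel(panel)
  utils::write.csv(panel[, c("rater_id", "failure_id", "factor", "score")],
                   path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an expert vote tally
#'
#' CSV with columns `expert` and `choice` (one endorsed option per expert);
#' returns per-option counts for [expert_vote_summary()].
#'
#' @param path CSV file path
#' @return named integer vector of counts
#' @export
read_expert_votes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("expert", "choice") %in% names(df))) {
    stop_validation("vote file needs columns 'expert' and 'choice'")
  }
  if (anyDuplicated(df$expert)) {
    stop_validation("each expert marks exactly one option; duplicate expert(s): %s",
                    paste(unique(df$expert[duplicated(df$expert)]), collapse = ", "))
  }
  tab <- table(df$choice)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a risk report
#'
#' Emits the scored worksheet as CSV or a Markdown table. Column order
#' follows the worksheet layout: id, situation, causes, the three
#' defuzzified factors, FRPN and rank. Risk values are rounded half-up to
#' 3 dp at this reporting layer only.
#'
#' @param scores a `"risk_scores"` data frame from [fmea_risk_scores()]
#' @param path output file
#' @param format `"csv"` or `"md"`
#' @param register optional failure register supplying situation and cause
#'   text
#' @return `path`, invisibly
#' @export
write_risk_report <- function(scores, path, format = c("csv", "md"),
                              register = NULL) {
  format <- match.arg(format)
  rep <- data.frame(failure_id = scores$failure_id)
  if (!is.null(register)) {
    i <- match(rep$failure_id, register$id)
    rep$situation <- register$situation[i]
    rep$causes <- vapply(i, function(k) {
      if (is.na(k)) "" else paste(register$causes[[k]]$text, collapse = "; ")
    }, character(1))
  }
  rep$s_defuzz <- round_half_up(scores$s_defuzz, 3)
  rep$o_defuzz <- round_half_up(scores$o_defuzz, 3)
  rep$d_defuzz <- round_half_up(scores$d_defuzz, 3)
  rep$frpn <- round_half_up(scores$frpn, 3)
  rep$traditional_rpn <- round_half_up(scores$traditional_rpn, 3)
  rep$rank <- scores$rank
  if (format == "csv") {
    utils::write.csv(rep, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    fmt3 <- function(x) sprintf("%.3f", x)
    hdr <- names(rep)
    lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"))
    for (i in seq_len(nrow(rep))) {
      vals <- vapply(hdr, function(h) {
        v <- rep[[h]][i]
        if (is.numeric(v) && h != "rank") fmt3(v) else as.character(v)
      }, character(1))
      lines <- c(lines, paste0("| ", paste(vals, collapse = " | "), " |"))
    }
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Write a TRIZ suggestion report
#'
#' JSON export carries the full provenance (per-failure causes,
#' determinants, parameters, consulted cells, raw union, screened list);
#' Markdown renders a principle-per-row table with a blank solution column
#' for the analyst to fill.
#'
#' @param suggestions a `"triz_suggestions"` object
#' @param path output file
#' @param format `"json"` or `"md"`
#' @return `path`, invisibly
#' @export
write_suggestion_report <- function(suggestions, path, format = c("json", "md")) {
  format <- match.arg(format)
  stopifnot(inherits(suggestions, "triz_suggestions"))
  if (format == "json") {
    doc <- list(
      failures = lapply(unname(suggestions$failures), function(f) {
        list(failure_id = f$failure_id, causes = as.list(f$causes),
             determinants = lapply(f$determinants, as.list),
             parameters = as.list(f$parameters))
      }),
      improving = as.list(suggestions$improving),
      worsening = as.list(suggestions$worsening),
      cells = lapply(seq_len(nrow(suggestions$cells)), function(i) {
        list(improving = suggestions$cells$improving[i],
             worsening = suggestions$cells$worsening[i],
             principles = as.list(suggestions$cells$principles[[i]]))
      }),
      raw_union = as.list(suggestions$raw_union),
      screened = as.list(suggestions$screened),
      roster = as.list(suggestions$roster %||% integer(0)),
      mode = suggestions$mode)
    writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                             pretty = TRUE)),
               path, useBytes = TRUE)
  } else {
    pn <- triz_principles()
    lines <- c("| Principle | Name | Proposed solution |", "|---|---|---|",
               vapply(suggestions$screened, function(s) {
                 sprintf("| %d | %s |  |", s, pn$name[match(s, pn$index)])
               }, character(1)))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML (or JSON) document naming the input assets and options of a full
#' three-phase run:
#' ```yaml
#' ratings: ratings.csv
#' register: register.json
#' blueprints: [blueprint_mild.json, blueprint_severe.json]
#' scale: scale_likert5.json          # optional, default bundled scale
#' determinants: determinants.yaml
#' matrix: contradiction_matrix.json  # optional, default bundled matrix
#' defuzz_method: centroid
#' worsening: [22, 36]                # optional, falls back to determinants file
#' roster: [1, 4, 21, 25, 27, 10, 28] # optional expert screening
#' top_n: 3                           # failures forwarded to the TRIZ stage
#' out_dir: out/
#' seed: 1
#' ```
#' Relative paths are resolved against the config file's directory;
#' referenced files must exist at load time.
#'
#' @param path config file path
#' @return a validated run-config list
#' @export
read_run_config <- function(path) {
  raw <- read_config_file(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    vapply(p, function(x) {
      if (file.exists(x)) normalizePath(x) else file.path(base, x)
    }, character(1), USE.NAMES = FALSE)
  }
  cfg <- list(
    ratings = resolve(raw$ratings),
    register = resolve(raw$register),
    blueprints = resolve(unlist(raw$blueprints)),
    scale = resolve(raw$scale),
    determinants = resolve(raw$determinants),
    matrix = resolve(raw$matrix),
    defuzz_method = raw$defuzz_method %||% "centroid",
    worsening = if (!is.null(raw$worsening)) as.integer(unlist(raw$worsening)),
    roster = if (!is.null(raw$roster)) as.integer(unlist(raw$roster)),
    top_n = as.integer(raw$top_n %||% 3L),
    out_dir = raw$out_dir %||% ".",
    seed = as.integer(raw$seed %||% 1L),
    timestamp = !isFALSE(raw$timestamp))
  for (field in c("ratings", "register", "determinants")) {
    if (is.null(cfg[[field]])) {
      stop_validation("run config must name a '%s' file", field)
    }
  }
  for (p in c(cfg$ratings, cfg$register, cfg$blueprints, cfg$scale,
              cfg$determinants, cfg$matrix)) {
    if (!file.exists(p)) stop_validation("configured path does not exist: %s", p)
  }
  if (!cfg$defuzz_method %in% c("centroid", "trapezoidal_eq4")) {
    stop_validation("unknown defuzz_method '%s'", cfg$defuzz_method)
  }
  cfg
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the three-phase pipeline
#'
#' Executes, in order: blueprint validation (phase I), Fuzzy-FMEA scoring
#' and FRPN ranking (phase II), and TRIZ principle suggestion for the
#' top-ranked failures (phase III). All reports are written under the
#' configured output directory; the first hard error aborts with a
#' stage-tagged message. Progress is logged to stderr.
#'
#' @param config a run-config list from [read_run_config()] (or an
#'   equivalent list)
#' @return invisibly, the artifact bundle: list with `blueprint_validation`,
#'   `failure_points`, `risk_scores`, `suggestions`, `paths`
#' @export
run_phase_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  register <- stage("inputs", read_register(config$register))
  scale <- stage("inputs", if (is.null(config$scale)) default_scale()
                 else read_scale(config$scale))
  dmap <- stage("inputs", read_determinant_map(config$determinants))
  matrix <- stage("inputs", if (is.null(config$matrix)) {
    default_contradiction_matrix()
  } else read_contradiction_matrix(config$matrix))

  # phase I: blueprint validation
  bps <- list(); bp_reports <- list(); fps <- NULL
  if (length(config$blueprints)) {
    bps <- stage("blueprint", lapply(config$blueprints, read_blueprint))
    bp_reports <- stage("blueprint", lapply(bps, validate_blueprint))
    bad <- which(!vapply(bp_reports, `[[`, logical(1), "ok"))
    if (length(bad)) {
      stop(sprintf("[stage blueprint] blueprint '%s' invalid: %s",
                   bps[[bad[1]]]$title,
                   paste(bp_reports[[bad[1]]]$violations, collapse = "; ")),
           call. = FALSE)
    }
    fps <- stage("blueprint", list_failure_points(bps, register))
    pipeline_log("blueprint", "%d blueprint(s) valid, %d failure point(s)",
                 length(bps), nrow(fps))
    writeLines(as.character(jsonlite::toJSON(
      list(reports = bp_reports,
           failure_points = fps), auto_unbox = TRUE, pretty = TRUE)),
      file.path(config$out_dir, "blueprint_validation.json"), useBytes = TRUE)
  }

  # phase II: fuzzy FMEA scoring and ranking
  panel <- stage("fmea", read_ratings(config$ratings))
  scores <- stage("fmea", suppressMessages(
    fmea_risk_scores(panel, scale, method = config$defuzz_method,
                     register = register)))
  if (config$defuzz_method == "trapezoidal_eq4") {
    pipeline_log("fmea", paste(
      "note: 'trapezoidal_eq4' does not reproduce the bundled case study's",
      "published defuzzified values; 'centroid' does"))
  }
  pipeline_log("fmea", "%d failure(s) scored; top rank: %s", nrow(scores),
               scores$failure_id[scores$rank == 1])
  write_risk_report(scores, file.path(config$out_dir, "risk_report.csv"),
                    "csv", register)
  write_risk_report(scores, file.path(config$out_dir, "risk_report.md"),
                    "md", register)

  # phase III: TRIZ suggestion on the top-ranked failures
  worsening <- config$worsening %||% dmap$worsening
  roster <- config$roster %||% dmap$roster
  top_ids <- scores$failure_id[order(scores$rank)][seq_len(min(config$top_n,
                                                               nrow(scores)))]
  top <- register[match(top_ids, register$id), , drop = FALSE]
  suggestions <- stage("triz",
    suggest_principles(top, dmap, worsening, matrix, roster = roster))
  pipeline_log("triz", "%d raw principle(s), %d screened",
               length(suggestions$raw_union), length(suggestions$screened))
  write_suggestion_report(suggestions,
                          file.path(config$out_dir, "suggestions.json"), "json")
  write_suggestion_report(suggestions,
                          file.path(config$out_dir, "suggestions.md"), "md")

  invisible(list(
    blueprint_validation = bp_reports,
    failure_points = fps,
    risk_scores = scores,
    suggestions = suggestions,
    paths = file.path(config$out_dir,
                      c("blueprint_validation.json", "risk_report.csv",
                        "risk_report.md", "suggestions.json",
                        "suggestions.md"))))
}
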