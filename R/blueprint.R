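#' Service-blueprint data model
#'
#' A service blueprint is a laned, acyclic action graph. Lanes are
#' `customer`, `front_stage` (between the line of interaction and the line
#' of visibility), `back_stage` (beneath the line of visibility) and
#' `support`. Edges crossing the line of interaction must link a customer
#' action with a front-stage action. Failure-point annotations attach FMEA
#' failure ids to actions; the scenario tag (e.g. mild vs severe illness) is
#' stored, never inferred.
#'
#' On disk a blueprint is JSON:
#' `{title, scenario, actions: [{id, lane, label, successors: [ids]}],
#'   failure_points: [{failure_id, action_id, note}]}`.
#'
#' @param path path to a blueprint JSON document
#' @return object of class `"service_blueprint"`: list with `title`,
#'   `scenario`, `actions` (data frame with list-column `successors`),
#'   `failure_points` (data frame)
#' @export
#' @examples
#' bp <- read_blueprint(fmeatriz_extdata("blueprint_mild.json"))
#' validate_blueprint(bp)$ok
read_blueprint <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  as_service_blueprint(raw)
}

as_service_blueprint <- function(raw) {
  actions <- if (length(raw$actions)) {
    data.frame(
      id = vapply(raw$actions, function(a) as.character(a$id), character(1)),
      lane = vapply(raw$actions, function(a) as.character(a$lane), character(1)),
      label = vapply(raw$actions, function(a) as.character(a$label %||% ""),
                     character(1)),
      successors = I(lapply(raw$actions, function(a) {
        as.character(unlist(a$successors) %||% character(0))
      })))
  } else {
    data.frame(id = character(0), lane = character(0), label = character(0),
               successors = I(list()))
  }
  fps <- if (length(raw$failure_points)) {
    data.frame(
      failure_id = vapply(raw$failure_points, function(f) as.character(f$failure_id),
                          character(1)),
      action_id = vapply(raw$failure_points, function(f) as.character(f$action_id),
                         character(1)),
      note = vapply(raw$failure_points, function(f) as.character(f$note %||% ""),
                    character(1)))
  } else {
    data.frame(failure_id = character(0), action_id = character(0),
               note = character(0))
  }
  structure(list(title = as.character(raw$title %||% ""),
                 scenario = as.character(raw$scenario %||% ""),
                 actions = actions, failure_points = fps),
            class = "service_blueprint")
}

blueprint_lanes <- c("customer", "front_stage", "back_stage", "support")

#' Validate a service blueprint
#'
#' Checks referential and structural invariants: unique action ids, known
#' lanes, successors and failure annotations resolving to existing actions,
#' acyclicity, and the line-of-interaction rule (any edge touching the
#' customer lane has its other endpoint in the front stage). Violations are
#' collected in a report, not thrown; an empty blueprint passes with a
#' warning entry.
#'
#' @param bp a `"service_blueprint"`
#' @return list with `ok` (no violations), `violations`, `warnings`
#' @export
validate_blueprint <- function(bp) {
  stopifnot(inherits(bp, "service_blueprint"))
  v <- character(0); w <- character(0)
  a <- bp$actions
  if (nrow(a) == 0L) {
    w <- c(w, "no actions")
  }
  if (anyDuplicated(a$id)) {
    v <- c(v, sprintf("duplicate action id(s): %s",
                      paste(unique(a$id[duplicated(a$id)]), collapse = ", ")))
  }
  bad_lane <- setdiff(unique(a$lane), blueprint_lanes)
  if (length(bad_lane)) {
    v <- c(v, sprintf("unknown lane(s): %s", paste(bad_lane, collapse = ", ")))
  }
  for (i in seq_len(nrow(a))) {
    miss <- setdiff(a$successors[[i]], a$id)
    if (length(miss)) {
      v <- c(v, sprintf("action %s references absent successor(s): %s",
                        a$id[i], paste(miss, collapse = ", ")))
    }
  }
  # line of interaction: customer actions may only connect to front_stage
  for (i in seq_len(nrow(a))) {
    for (s in intersect(a$successors[[i]], a$id)) {
      lanes <- c(a$lane[i], a$lane[match(s, a$id)])
      if ("customer" %in% lanes && !setequal(lanes, c("customer", "front_stage")) &&
          !all(lanes == "customer")) {
        v <- c(v, sprintf(
          "edge %s -> %s crosses the line of interaction outside customer/front_stage",
          a$id[i], s))
      }
    }
  }
  # acyclicity by repeated removal of sink-free nodes (Kahn)
  if (nrow(a) > 0L && !anyDuplicated(a$id) && length(v) == 0L) {
    succ <- lapply(a$successors, intersect, a$id)
    indeg <- stats::setNames(integer(nrow(a)), a$id)
    for (s in unlist(succ)) indeg[s] <- indeg[s] + 1L
    queue <- names(indeg)[indeg == 0L]; seen <- 0L
    while (length(queue)) {
      n <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
      for (s in succ[[match(n, a$id)]]) {
        indeg[s] <- indeg[s] - 1L
        if (indeg[s] == 0L) queue <- c(queue, s)
      }
    }
    if (seen < nrow(a)) v <- c(v, "action graph contains a cycle")
  }
  fp <- bp$failure_points
  miss_act <- setdiff(fp$action_id, a$id)
  if (length(miss_act)) {
    v <- c(v, sprintf("failure annotation(s) reference absent action(s): %s",
                      paste(miss_act, collapse = ", ")))
  }
  list(ok = length(v) == 0L, violations = v, warnings = w)
}

#' List failure points of one or several blueprints
#'
#' Collects the (failure_id, action_id) annotations, de-duplicated by
#' failure id across scenarios (the first scenario carrying a failure wins)
#' and ordered by failure id. Inputs must validate.
#'
#' @param bps a `"service_blueprint"` or a list of them
#' @param register optional failure register; annotated failure ids outside
#'   the register raise an error
#' @return data frame with columns `failure_id`, `action_id`, `scenario`
#' @export
list_failure_points <- function(bps, register = NULL) {
  if (inherits(bps, "service_blueprint")) bps <- list(bps)
  rows <- list()
  for (bp in bps) {
    rep <- validate_blueprint(bp)
    if (!rep$ok) {
      stop_validation("blueprint '%s' fails validation: %s", bp$title,
                      paste(rep$violations, collapse = "; "))
    }
    fp <- bp$failure_points
    if (nrow(fp)) {
      fp$scenario <- bp$scenario
      rows[[length(rows) + 1L]] <- fp[, c("failure_id", "action_id", "scenario")]
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(failure_id = character(0), action_id = character(0),
               scenario = character(0))
  }
  out <- out[!duplicated(out$failure_id), , drop = FALSE]
  out <- out[order(out$failure_id), , drop = FALSE]
  if (!is.null(register)) {
    unknown <- setdiff(out$failure_id, register$id)
    if (length(unknown)) {
      stop_validation("failure point(s) not in register: %s",
                      paste(unknown, collapse = ", "))
    }
  }
  rownames(out) <- NULL
  out
}

#' Export a blueprint as JSON or Graphviz DOT
#'
#' JSON export round-trips losslessly through [read_blueprint()]. DOT export
#' renders each occupied lane as a cluster, with failure-point actions
#' marked by their failure ids.
#'
#' @param bp a validated `"service_blueprint"`
#' @param format `"json"` or `"dot"`
#' @param path optional output file; when omitted the serialized text is
#'   returned
#' @return the serialized document as a character scalar (invisibly when
#'   written to `path`)
#' @export
export_blueprint <- function(bp, format = c("json", "dot"), path = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_validation(
                       "unknown blueprint export format '%s'", format[1]))
  rep <- validate_blueprint(bp)
  if (!rep$ok) {
    stop_validation("refusing to export invalid blueprint: %s",
                    paste(rep$violations, collapse = "; "))
  }
  txt <- if (format == "json") {
    doc <- list(
      title = bp$title, scenario = bp$scenario,
      actions = lapply(seq_len(nrow(bp$actions)), function(i) {
        list(id = bp$actions$id[i], lane = bp$actions$lane[i],
             label = bp$actions$label[i],
             successors = as.list(bp$actions$successors[[i]]))
      }),
      failure_points = lapply(seq_len(nrow(bp$failure_points)), function(i) {
        list(failure_id = bp$failure_points$failure_id[i],
             action_id = bp$failure_points$action_id[i],
             note = bp$failure_points$note[i])
      }))
    jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  } else {
    lines <- c("digraph blueprint {", "  rankdir=LR;")
    for (lane in intersect(blueprint_lanes, unique(bp$actions$lane))) {
      lines <- c(lines, sprintf("  subgraph cluster_%s {", lane),
                 sprintf("    label=\"%s\";", lane))
      for (i in which(bp$actions$lane == lane)) {
        id <- bp$actions$id[i]
        marks <- bp$failure_points$failure_id[bp$failure_points$action_id == id]
        lab <- bp$actions$label[i]
        if (length(marks)) lab <- sprintf("%s\\n[%s]", lab,
                                          paste(marks, collapse = ", "))
        lines <- c(lines, sprintf("    \"%s\" [label=\"%s\"];", id, lab))
      }
      lines <- c(lines, "  }")
    }
    for (i in seq_len(nrow(bp$actions))) {
      for (s in bp$actions$successors[[i]]) {
        lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", bp$actions$id[i], s))
      }
    }
    paste(c(lines, "}"), collapse = "\n")
  }
  txt <- as.character(txt)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
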