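#' TRIZ registries: 39 engineering parameters and 40 inventive principles
#'
#' Classical TRIZ indexes a contradiction by a pair of engineering
#' parameters — the attribute one wants to improve and the attribute that
#' worsens as a side effect — and suggests generic solution patterns
#' (inventive principles) for that pair. `triz_parameters()` returns the
#' canonical 39-parameter registry and `triz_principles()` the canonical
#' 40-principle registry, both as `index`/`name` data frames.
#'
#' @return data frame with columns `index` and `name`
#' @export
#' @examples
#' subset(triz_parameters(), index %in% c(9, 17, 26, 35))
triz_parameters <- function() {
  data.frame(index = 1:39, name = c(
    "Weight of moving object", "Weight of stationary object",
    "Length of moving object", "Length of stationary object",
    "Area of moving object", "Area of stationary object",
    "Volume of moving object", "Volume of stationary object",
    "Speed", "Force", "Stress or pressure", "Shape",
    "Stability of the object's composition", "Strength",
    "Duration of action of moving object",
    "Duration of action of stationary object", "Temperature",
    "Illumination intensity", "Use of energy by moving object",
    "Use of energy by stationary object", "Power",
    "Loss of energy (costs)", "Loss of substance", "Loss of information",
    "Loss of time", "Amount of substance", "Reliability",
    "Measurement accuracy", "Manufacturing precision",
    "Object-affected harmful factors", "Object-generated harmful factors",
    "Ease of manufacture", "Ease of operation", "Ease of repair",
    "Adaptability or versatility", "System complexity",
    "Difficulty of detecting and measuring", "Extent of automation",
    "Productivity"))
}

#' @rdname triz_parameters
#' @export
triz_principles <- function() {
  data.frame(index = 1:40, name = c(
    "Segmentation", "Taking out", "Local quality", "Asymmetry", "Merging",
    "Universality", "Nested doll", "Anti-weight", "Preliminary anti-action",
    "Preliminary action", "Beforehand cushioning", "Equipotentiality",
    "The other way round", "Spheroidality and curvature", "Dynamics",
    "Partial or excessive actions", "Another dimension",
    "Mechanical vibration", "Periodic action", "Continuity of useful action",
    "Rushing through", "Blessing in disguise", "Feedback", "Intermediary",
    "Self-service", "Copying", "Cheap short-living objects",
    "Replacement of mechanical systems", "Pneumatics and hydraulics",
    "Flexible shells and thin films", "Porous materials", "Color changes",
    "Homogeneity", "Discarding and recovering", "Parameter changes",
    "Phase transitions", "Thermal expansion", "Strong oxidants",
    "Inert atmosphere", "Composite materials"))
}

#' Read a contradiction matrix from JSON or CSV
#'
#' The contradiction matrix is a sparse map from an
#' (improving parameter, worsening parameter) pair to an ordered list of
#' inventive-principle indices. On disk it is a list/table of triples:
#' JSON records `{improving, worsening, principles: [ints]}` or CSV columns
#' `improving`, `worsening`, `principles` (space- or comma-separated ints).
#' Diagonal cells and principle indices outside 1..40 are rejected.
#'
#' The bundled asset (`fmeatriz_extdata("contradiction_matrix.json")`)
#' carries the eight cells exercised by the CMEC case study —
#' improving \{9, 17, 26, 35\} crossed with worsening \{22, 36\} — and the
#' loader accepts any larger user-supplied matrix in the same format.
#'
#' @param path file path (`.json` or `.csv`)
#' @return object of class `"contradiction_matrix"`: a named list of integer
#'   vectors keyed `"improving:worsening"`
#' @export
read_contradiction_matrix <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    cells <- lapply(recs, function(r) {
      list(i = as.integer(r$improving), w = as.integer(r$worsening),
           pr = as.integer(unlist(r$principles)))
    })
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    cells <- lapply(seq_len(nrow(df)), function(k) {
      list(i = as.integer(df$improving[k]), w = as.integer(df$worsening[k]),
           pr = as.integer(strsplit(as.character(df$principles[k]),
                                    "[ ,]+")[[1]]))
    })
  } else {
    stop_validation("unsupported matrix format '.%s' (use JSON or CSV)", ext)
  }
  out <- list()
  for (cell in cells) {
    if (is.na(cell$i) || is.na(cell$w) ||
        cell$i < 1 || cell$i > 39 || cell$w < 1 || cell$w > 39) {
      stop_validation("matrix cell indices must lie in 1..39")
    }
    if (cell$i == cell$w) {
      stop_validation("diagonal cell (%d, %d): self-contradiction undefined",
                      cell$i, cell$w)
    }
    if (any(cell$pr < 1) || any(cell$pr > 40)) {
      stop_validation("cell (%d, %d) references principle outside 1..40",
                      cell$i, cell$w)
    }
    out[[paste0(cell$i, ":", cell$w)]] <- cell$pr
  }
  structure(out, class = "contradiction_matrix")
}

#' @rdname read_contradiction_matrix
#' @export
default_contradiction_matrix <- function() {
  read_contradiction_matrix(fmeatriz_extdata("contradiction_matrix.json"))
}

#' Look up a contradiction-matrix cell
#'
#' Returns the ordered principle list stored for the
#' (improving, worsening) pair. An absent cell yields an empty vector with a
#' notice; querying the diagonal is an error, as a parameter cannot both
#' improve and worsen.
#'
#' @param improving,worsening parameter indices in 1..39
#' @param matrix a `"contradiction_matrix"` (default: bundled asset)
#' @return integer vector of principle indices (possibly empty)
#' @export
#' @examples
#' lookup_matrix(9, 22)  # 20, 14, 19, 35
lookup_matrix <- function(improving, worsening,
                          matrix = default_contradiction_matrix()) {
  improving <- as.integer(improving); worsening <- as.integer(worsening)
  if (is.na(improving) || is.na(worsening) ||
      improving < 1 || improving > 39 || worsening < 1 || worsening > 39) {
    stop_validation("parameter indices must lie in 1..39")
  }
  if (improving == worsening) {
    stop_validation("self-contradiction undefined: (%d, %d)", improving, worsening)
  }
  cell <- matrix[[paste0(improving, ":", worsening)]]
  if (is.null(cell)) {
    message(sprintf("contradiction matrix has no cell (%d, %d); returning no principles",
                    improving, worsening))
    return(integer(0))
  }
  cell
}

#' Read a determinant-to-parameter map
#'
#' Service-quality determinants (the named drivers behind failure causes)
#' are mapped to TRIZ improving parameters. The YAML/JSON file holds
#' `determinants:` — a list of `{id, name, parameter}` — and optionally the
#' case defaults `worsening:` (parameter indices) and `roster:`
#' (expert-screened principle indices). The bundled case map carries the
#' five determinants of the CMEC study: 13 (number of nursing staff) -> 26,
#' 5 (service adaptability) -> 35, 18 (service capacity) -> 26,
#' 7 (healthcare workers' attitude) -> 17, 20 (service delivery time) -> 9.
#'
#' @param path file path
#' @return list with `map` (data frame `id`, `name`, `parameter`),
#'   `worsening` (integer vector or NULL), `roster` (integer vector or NULL)
#' @export
read_determinant_map <- function(path) {
  raw <- read_config_file(path)
  dets <- raw$determinants %||% raw
  df <- do.call(rbind, lapply(dets, function(d) {
    data.frame(id = as.integer(d$id), name = as.character(d$name %||% ""),
               parameter = as.integer(d$parameter))
  }))
  if (anyDuplicated(df$id)) stop_validation("duplicate determinant id(s)")
  if (any(df$parameter < 1) || any(df$parameter > 39)) {
    stop_validation("determinant map targets must be parameter indices in 1..39")
  }
  list(map = df,
       worsening = if (!is.null(raw$worsening)) as.integer(unlist(raw$worsening)),
       roster = if (!is.null(raw$roster)) as.integer(unlist(raw$roster)))
}

#' Map a failure mode's causes to improving parameters
#'
#' Follows each cause's determinant tags through the determinant map and
#' returns the de-duplicated, order-preserving list of TRIZ improving
#' parameter indices. Every cause must carry at least one determinant tag
#' and every tag must be present in the map; otherwise the offending cause
#' is named in the error.
#'
#' @param failure one row of a [read_register] register (data frame of one
#'   row, or a list with `id` and `causes`)
#' @param dmap a determinant map as returned by [read_determinant_map] (or
#'   its `map` data frame)
#' @return integer vector of improving parameter indices
#' @export
map_causes_to_parameters <- function(failure, dmap) {
  map <- if (is.data.frame(dmap)) dmap else dmap$map
  causes <- if (is.data.frame(failure$causes[[1]])) failure$causes[[1]] else failure$causes
  id <- if (is.data.frame(failure)) failure$id[[1]] else failure$id
  params <- integer(0)
  for (k in seq_len(nrow(causes))) {
    dets <- causes$determinants[[k]]
    if (length(dets) == 0L) {
      stop_validation("failure %s: cause '%s' carries no determinant tag",
                      id, causes$text[k])
    }
    hit <- match(dets, map$id)
    if (anyNA(hit)) {
      stop_validation("failure %s: cause '%s' tagged with unmapped determinant %s",
                      id, causes$text[k],
                      paste(dets[is.na(hit)], collapse = ", "))
    }
    params <- c(params, map$parameter[hit])
  }
  params[!duplicated(params)]
}

#' Suggest inventive principles for ranked failure modes
#'
#' Phase-III engine: maps each failure's causes to improving parameters,
#' crosses them with the worsening parameters, collects the consulted
#' contradiction-matrix cells, unions their principles in encounter order,
#' and (optionally) intersects the union with an expert screening roster.
#' Screening is always an explicit roster, never an automated relevance
#' score.
#'
#' @param failures rows of a [read_register] register (typically the
#'   top-ranked failures); an empty register yields an empty report
#' @param dmap determinant map (see [read_determinant_map])
#' @param worsening non-empty integer vector of worsening parameter indices
#' @param matrix a `"contradiction_matrix"`
#' @param roster optional integer vector of expert-accepted principle
#'   indices; when supplied the screened list is `raw_union` intersected
#'   with it, otherwise it equals `raw_union`
#' @param mode `"pooled"` (default) queries the union of improving
#'   parameters across all supplied failures, mirroring the case study;
#'   `"per_failure"` records cells failure by failure (the raw union is
#'   identical, provenance is finer)
#' @return object of class `"triz_suggestions"`: list with `failures`
#'   (per-failure provenance: id, causes, determinants, parameters),
#'   `improving`, `worsening`, `cells` (data frame `improving`, `worsening`,
#'   `principles` list-column), `raw_union`, `screened`, `roster`, `mode`
#' @export
suggest_principles <- function(failures, dmap, worsening,
                               matrix = default_contradiction_matrix(),
                               roster = NULL, mode = c("pooled", "per_failure")) {
  mode <- match.arg(mode)
  if (length(worsening) == 0L) {
    stop_validation("the worsening parameter set must be non-empty")
  }
  worsening <- as.integer(worsening)
  n_fail <- if (is.data.frame(failures)) nrow(failures) else length(failures)
  prov <- list(); improving <- integer(0)
  for (i in seq_len(n_fail)) {
    f <- failures[i, , drop = FALSE]
    params <- map_causes_to_parameters(f, dmap)
    map <- if (is.data.frame(dmap)) dmap else dmap$map
    causes <- f$causes[[1]]
    prov[[f$id[[1]]]] <- list(
      failure_id = f$id[[1]],
      causes = causes$text,
      determinants = causes$determinants,
      parameters = params)
    improving <- c(improving, params)
  }
  improving <- improving[!duplicated(improving)]
  cells <- list(); raw_union <- integer(0)
  for (imp in improving) {
    for (wor in worsening) {
      pr <- suppressMessages(lookup_matrix(imp, wor, matrix))
      cells[[length(cells) + 1L]] <- list(improving = imp, worsening = wor,
                                          principles = pr)
      raw_union <- c(raw_union, pr)
    }
  }
  raw_union <- raw_union[!duplicated(raw_union)]
  screened <- if (is.null(roster)) raw_union else {
    intersect(raw_union, as.integer(roster))
  }
  cells_df <- if (length(cells)) {
    data.frame(
      improving = vapply(cells, `[[`, integer(1), "improving"),
      worsening = vapply(cells, `[[`, integer(1), "worsening"),
      principles = I(lapply(cells, `[[`, "principles")))
  } else {
    data.frame(improving = integer(0), worsening = integer(0),
               principles = I(list()))
  }
  structure(list(failures = prov, improving = improving, worsening = worsening,
                 cells = cells_df, raw_union = raw_union, screened = screened,
                 roster = if (!is.null(roster)) as.integer(roster),
                 mode = mode),
            class = "triz_suggestions")
}

#' @export
print.triz_suggestions <- function(x, ...) {
  pn <- triz_principles()
  cat(sprintf("TRIZ suggestion report: %d failure(s), improving {%s} x worsening {%s}\n",
              length(x$failures), paste(x$improving, collapse = ","),
              paste(x$worsening, collapse = ",")))
  cat(sprintf("  raw union (%d): %s\n", length(x$raw_union),
              paste(x$raw_union, collapse = ", ")))
  cat(sprintf("  screened (%d): %s\n", length(x$screened),
              paste(sprintf("%d %s", x$screened,
                            pn$name[match(x$screened, pn$index)]),
                    collapse = "; ")))
  invisible(x)
}

# the eight case-study cells treated as authoritative for validation
case_reference_cells <- function() {
  list("9:22"  = c(20L, 14L, 19L, 35L),
       "9:36"  = c(10L, 28L, 4L, 34L),
       "17:22" = c(21L, 17L, 35L, 38L),
       "17:36" = c(2L, 17L, 16L),
       "26:22" = c(25L, 7L, 8L),
       "26:36" = c(3L, 13L, 10L, 27L),
       "35:22" = c(18L, 15L, 1L),
       "35:36" = c(15L, 29L, 28L, 37L))
}

#' Validate the TRIZ assets
#'
#' Integrity check of the loaded registries and contradiction matrix:
#' exactly 39 parameters and 40 principles with indices 1..39 / 1..40, and
#' the eight authoritative case-study cells present verbatim (order
#' included) in the matrix, overriding any conflicting upstream source.
#' Deviations are reported, not thrown.
#'
#' @param matrix a `"contradiction_matrix"`
#' @param parameters,principles registries as `index`/`name` data frames
#' @param reference named list of authoritative cells
#'   (`"improving:worsening"` -> integer vector); default: the case-study
#'   cells
#' @return list with `ok` (logical) and `deviations` (character vector)
#' @export
validate_matrix_assets <- function(matrix = default_contradiction_matrix(),
                                   parameters = triz_parameters(),
                                   principles = triz_principles(),
                                   reference = case_reference_cells()) {
  dev <- character(0)
  if (nrow(parameters) != 39L || !identical(as.integer(parameters$index), 1:39)) {
    dev <- c(dev, sprintf("parameter registry has %d entries (expected indices 1..39)",
                          nrow(parameters)))
  }
  if (nrow(principles) != 40L || !identical(as.integer(principles$index), 1:40)) {
    dev <- c(dev, sprintf("principle registry has %d entries (expected indices 1..40)",
                          nrow(principles)))
  }
  for (key in names(reference)) {
    got <- matrix[[key]]
    if (is.null(got)) {
      dev <- c(dev, sprintf("matrix cell (%s) is absent", gsub(":", ", ", key)))
    } else if (!identical(as.integer(got), as.integer(reference[[key]]))) {
      dev <- c(dev, sprintf("matrix cell (%s) holds {%s}, expected {%s}",
                            gsub(":", ", ", key),
                            paste(got, collapse = ", "),
                            paste(reference[[key]], collapse = ", ")))
    }
  }
  list(ok = length(dev) == 0L, deviations = dev)
}
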