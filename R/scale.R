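#' Five-level linguistic rating scale
#'
#' A linguistic scale maps the five Likert scores 1..5 to labelled
#' triangular fuzzy numbers. The default scale maps
#' \{NI, LI, I, VI, EI\} (Not / A Little / -- / Very / Extremely Important)
#' to \{(0,0,0.25), (0,0.25,0.5), (0.25,0.5,0.75), (0.5,0.75,1),
#' (0.75,1,1)\}. Per-factor questionnaire wording (severity, occurrence,
#' detectability) is carried as semantic tags.
#'
#' For the detectability factor the orientation is: a higher score means the
#' failure is detected only at or after occurrence (worse); no
#' re-orientation is applied anywhere in the package.
#'
#' @param levels data frame with columns `label`, `score`, `q`, `o`, `p`
#'   (exactly five rows, scores a permutation of 1..5)
#' @param semantics optional named list of per-factor wording,
#'   names among `"S"`, `"O"`, `"D"`, each a character vector of five
#'   descriptions ordered by score
#' @return an object of class `"linguistic_scale"` (a data frame ordered by
#'   score with the semantics as an attribute)
#' @export
#' @examples
#' default_scale()
linguistic_scale <- function(levels, semantics = NULL) {
  req <- c("label", "score", "q", "o", "p")
  if (!is.data.frame(levels) || !all(req %in% names(levels))) {
    stop_validation("scale levels need columns %s", paste(req, collapse = ", "))
  }
  levels <- levels[order(levels$score), req]
  if (nrow(levels) != 5L || !identical(sort(as.integer(levels$score)), 1:5)) {
    stop_validation("a linguistic scale has exactly five levels with scores 1..5")
  }
  for (i in seq_len(5L)) {
    validate_tfn(c(levels$q[i], levels$o[i], levels$p[i]))
  }
  for (comp in c("q", "o", "p")) {
    if (is.unsorted(levels[[comp]])) {
      stop_validation(
        "scale component '%s' must be non-decreasing in the score", comp)
    }
  }
  rownames(levels) <- NULL
  structure(levels, class = c("linguistic_scale", "data.frame"),
            semantics = semantics)
}

#' @rdname linguistic_scale
#' @export
default_scale <- function() {
  read_scale(fmeatriz_extdata("scale_likert5.json"))
}

#' Read a linguistic scale from JSON or YAML
#'
#' The file holds a list of level records `{label, score, q, o, p}`
#' (optionally under a top-level `levels` key, with an optional `semantics`
#' sibling). Invariants are validated on load.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`)
#' @return a [linguistic_scale]
#' @export
read_scale <- function(path) {
  raw <- read_config_file(path)
  lv <- raw$levels %||% raw
  if (is.data.frame(lv)) {
    df <- lv
  } else {
    df <- do.call(rbind, lapply(lv, function(l) {
      data.frame(label = as.character(l$label), score = as.integer(l$score),
                 q = as.numeric(l$q), o = as.numeric(l$o), p = as.numeric(l$p))
    }))
  }
  linguistic_scale(df, semantics = raw$semantics)
}

# shared loader for small JSON/YAML config assets
read_config_file <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop_validation("unsupported config format '.%s' (use JSON or YAML)", ext))
}

#' Fuzzify a Likert score
#'
#' Returns the triangular fuzzy number that the scale attaches to a 1..5
#' score, unmodified.
#'
#' @param score integer score, one of the scale's scores
#' @param scale a [linguistic_scale] (default: the bundled five-level scale)
#' @return a [tfn]
#' @export
#' @examples
#' fuzzify(5)  # (0.75, 1, 1)
fuzzify <- function(score, scale = default_scale()) {
  stopifnot(inherits(scale, "linguistic_scale"))
  if (length(score) != 1L || is.na(score) || score != as.integer(score)) {
    stop_validation("score must be a single integer; got '%s'",
                    paste(score, collapse = ","))
  }
  i <- match(as.integer(score), scale$score)
  if (is.na(i)) {
    stop_validation("score out of scale: %d (scale scores: %s)",
                    as.integer(score), paste(scale$score, collapse = ", "))
  }
  tfn(scale$q[i], scale$o[i], scale$p[i])
}

# vectorised internal fuzzification: scores -> 3 x n matrix of (q, o, p)
fuzzify_matrix <- function(scores, scale) {
  i <- match(as.integer(scores), scale$score)
  if (anyNA(i)) {
    bad <- unique(scores[is.na(i)])
    stop_validation("score out of scale: %s", paste(bad, collapse = ", "))
  }
  rbind(q = scale$q[i], o = scale$o[i], p = scale$p[i])
}
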