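#' Failure-mode register
#'
#' The register is the FMEA worksheet's qualitative half: one record per
#' failure mode with its id (e.g. `F1`), the service failure point, the
#' failure situation, its causes (each optionally tagged with service-quality
#' determinant ids used by the TRIZ mapping stage) and its effects.
#'
#' Two on-disk forms are read:
#' \itemize{
#'   \item JSON: a list of records `{id, point, situation, causes:
#'     [{text, determinants: [ids]}], effects: [text]}`.
#'   \item CSV: columns `id`, `point`, `situation`, `causes`, `effects`;
#'     causes separated by `;`, each optionally tagged as
#'     `"cause text|det1,det2"`; effects separated by `;`.
#' }
#'
#' @param path path to a `.json` or `.csv` register
#' @return data frame of class `"failure_register"` with list-columns
#'   `causes` (each a data frame with `text` and list-column `determinants`)
#'   and `effects`
#' @export
#' @examples
#' reg <- read_register(fmeatriz_extdata("case_register.json"))
#' reg$id
read_register <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  recs <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    lapply(seq_len(nrow(df)), function(i) {
      causes <- lapply(strsplit(df$causes[i], ";", fixed = TRUE)[[1]], function(cc) {
        parts <- strsplit(trimws(cc), "|", fixed = TRUE)[[1]]
        dets <- if (length(parts) > 1L) {
          as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
        } else integer(0)
        list(text = trimws(parts[1]), determinants = dets)
      })
      list(id = df$id[i], point = df$point[i], situation = df$situation[i],
           causes = causes,
           effects = trimws(strsplit(df$effects[i], ";", fixed = TRUE)[[1]]))
    })
  } else {
    stop_validation("unsupported register format '.%s' (use JSON or CSV)", ext)
  }
  as_failure_register(recs)
}

as_failure_register <- function(recs) {
  ids <- vapply(recs, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids)) {
    stop_validation("duplicate failure id(s): %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  causes <- lapply(recs, function(r) {
    if (length(r$causes) == 0L) {
      stop_validation("failure %s has no causes", r$id)
    }
    data.frame(
      text = vapply(r$causes, function(cc) as.character(cc$text), character(1)),
      determinants = I(lapply(r$causes, function(cc) {
        as.integer(cc$determinants %||% integer(0))
      })))
  })
  out <- data.frame(
    id = ids,
    point = vapply(recs, function(r) as.character(r$point %||% ""), character(1)),
    situation = vapply(recs, function(r) as.character(r$situation %||% ""),
                       character(1)))
  out$causes <- causes
  out$effects <- lapply(recs, function(r) as.character(r$effects %||% character(0)))
  class(out) <- c("failure_register", "data.frame")
  out
}
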