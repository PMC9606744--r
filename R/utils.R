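#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero for
#' positive values, the convention used throughout the reported risk tables
#' (3 dp for risk values, 2 dp for percentages). Base `round()` rounds half
#' to even, which disagrees on exact .5 ties.
#'
#' @param x numeric vector (non-negative in all package uses)
#' @param digits integer number of decimal places
#' @return numeric vector rounded half-up
#' @export
#' @examples
#' round_half_up(0.2345, 3)  # 0.235, where round() gives 0.234
round_half_up <- function(x, digits = 3) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  # tiny guard against binary representation of decimal inputs
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulation never leaks global state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Path to a bundled example asset
#'
#' Convenience wrapper around [system.file()] for the plain-text assets
#' shipped under `inst/extdata` (linguistic scale, case-study register,
#' fuzzy-mean tables, determinant map, contradiction matrix, blueprints,
#' expert votes).
#'
#' @param file asset file name; with no argument, lists available assets
#' @return absolute path, or a character vector of asset names
#' @export
#' @examples
#' fmeatriz_extdata()
#' fmeatriz_extdata("scale_likert5.json")
fmeatriz_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "fmeatriz")))
  }
  path <- system.file("extdata", file, package = "fmeatriz")
  if (!nzchar(path)) stop_validation("no bundled asset named '%s'", file)
  path
}
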