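# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package operations
#' never perturb the user's random stream. `seed = NULL` runs the code with the
#' current stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage child seed from one global seed so pipeline stages can be
# re-run independently yet reproducibly. Kept below 2^31 - 1.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(phantom = 11L, render = 23L, defects = 37L, rois = 53L,
               noise = 71L, demo = 97L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(as.character(stage)))
  as.integer((as.double(seed) * 7919 + off) %% 2147483647)
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max || (!allow_zero && x == 0)) {
    rlang::abort(sprintf("`%s` = %g is outside the allowed range [%g, %g].",
                         name, x, min, max))
  }
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
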