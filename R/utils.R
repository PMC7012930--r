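# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so deterministic generators
#' do not disturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Wrap angles in degrees to [0, 360)
#' @noRd
wrap_deg <- function(x) x %% 360

#' Wrap phase in radians to [-pi, pi)
#' @noRd
wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Circular distance between two angles in degrees (result in [0, 180])
#' @noRd
circ_dist_deg <- function(a, b) {
  d <- abs(wrap_deg(a) - wrap_deg(b)) %% 360
  pmin(d, 360 - d)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Index of the sampled direction closest (circularly) to a target angle
#' @noRd
nearest_direction <- function(directions, target) {
  which.min(circ_dist_deg(directions, target))
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  }
  invisible(x)
}
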