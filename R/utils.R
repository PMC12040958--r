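# Internal helpers shared across modules.

#' Signal an error with a package condition class
#'
#' @param msg message
#' @param class condition class suffix, e.g. "degenerate_geometry"
#' @noRd
abort_ecgvae <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("ecgvae_", class), "ecgvae_error")))
}

warn_ecgvae <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("ecgvae_", class), "ecgvae_warning")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so library code never perturbs the
#' session stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Clamp into [lo, hi]; used to absorb rounding before acos().
clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort_ecgvae("cannot normalize a (near-)zero vector", "degenerate_geometry")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

is_num_vec <- function(x, n) is.numeric(x) && length(x) == n && all(is.finite(x))

#' Canonical electrode ordering used throughout the package
#'
#' The 30-vector flattening order of electrode coordinates is fixed as
#' RA, LA, RL, LL, V1..V6; consistent ordering matters for model conditioning.
#' @return character vector of the 10 electrode names
#' @export
electrode_names <- function() c("RA", "LA", "RL", "LL", "V1", "V2", "V3", "V4", "V5", "V6")

#' Canonical 12-lead ordering
#'
#' @return character vector of the 12 lead names
#' @export
lead_names <- function() c("I", "II", "III", "aVR", "aVL", "aVF",
                           "V1", "V2", "V3", "V4", "V5", "V6")
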