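`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded generators do not disturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Draw from a truncated normal by rejection
#'
#' Adequate for the mild truncations used by the cohort generator; errors if
#' the acceptance region is so extreme that rejection stalls.
#' @noRd
rtruncnorm <- function(n, mean, sd, lower, upper) {
  stopifnot(sd > 0, lower < upper)
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    draw <- rnorm(max(n - length(out), 16L) * 2L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
    tries <- tries + 1L
    if (tries > 1000L) {
      stop("truncated-normal rejection sampling failed; bounds [", lower,
           ", ", upper, "] are too far from mean ", mean)
    }
  }
  out[seq_len(n)]
}

#' Gravitational acceleration used for bodyweight conversion (m/s^2)
#' @noRd
GRAVITY <- 9.81

#' Convert force in newtons to bodyweights
#' @param force_n force in N
#' @param mass participant mass in kg
#' @return force in BW units
#' @export
newtons_to_bw <- function(force_n, mass) {
  stopifnot(mass > 0)
  force_n / (mass * GRAVITY)
}
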