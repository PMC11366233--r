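trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2)

#' Agreement metrics for one measured/estimated trace pair
#'
#' Computes the waveform accuracy metrics reported per foot contact:
#' RMSE in bodyweights, relative RMSE (RMSE as a percentage of the
#' measured waveform's range), Pearson correlation, and component-specific
#' peak metrics. For the vertical component: percentage difference in the
#' peak value and in the impulse (trapezoidal area under the
#' 400-point bodyweight-normalized trace), both relative to the measured
#' value. For the anteroposterior component: signed differences
#' (estimated - measured; negative = underestimation) in the peak braking
#' (most negative) and peak propulsive (most positive) values, in both BW
#' and N.
#'
#' @param measured,estimated equal-length traces in bodyweight units (or
#'   newtons with `units = "n"`).
#' @param mass participant mass, kg (used for BW/N conversion).
#' @param component `"grf_v"` or `"grf_ap"`.
#' @param units units of the supplied traces.
#' @return one-row data.frame with `rmse_bw`, `rrmse`, `pearson_r`, and
#'   the component's peak/impulse columns (others `NA`).
#' @export
contact_metrics <- function(measured, estimated, mass,
                            component = c("grf_v", "grf_ap"),
                            units = c("bw", "n")) {
  component <- match.arg(component)
  units <- match.arg(units)
  stopifnot(length(measured) == length(estimated), mass > 0)
  if (units == "n") {
    measured <- measured / (mass * GRAVITY)
    estimated <- estimated / (mass * GRAVITY)
  }
  rng <- max(measured) - min(measured)
  if (rng == 0) stop("measured trace is flat: rRMSE undefined")
  rmse <- sqrt(mean((estimated - measured)^2))
  out <- data.frame(
    rmse_bw = rmse,
    rrmse = 100 * rmse / rng,
    pearson_r = cor(measured, estimated),
    peak_diff_pct = NA_real_, impulse_diff_pct = NA_real_,
    peak_braking_diff_bw = NA_real_, peak_braking_diff_n = NA_real_,
    peak_propulsive_diff_bw = NA_real_, peak_propulsive_diff_n = NA_real_
  )
  if (component == "grf_v") {
    out$peak_diff_pct <- 100 * (max(estimated) - max(measured)) /
      max(measured)
    out$impulse_diff_pct <- 100 * (trapz(estimated) - trapz(measured)) /
      trapz(measured)
  } else {
    db <- min(estimated) - min(measured)
    dp <- max(estimated) - max(measured)
    out$peak_braking_diff_bw <- db
    out$peak_braking_diff_n <- db * mass * GRAVITY
    out$peak_propulsive_diff_bw <- dp
    out$peak_propulsive_diff_n <- dp * mass * GRAVITY
  }
  out
}

#' Bland-Altman agreement summary
#'
#' For paired discrete metrics (e.g., per-contact peak force):
#' differences `d = estimated - measured`, bias = mean(d), limits of
#' agreement = bias +/- 1.96 SD(d), and the least-squares slope of `d`
#' against the measured magnitude — the quantity that exposes
#' regression-toward-the-mean behaviour (a negative slope means
#' high-magnitude contacts are underestimated).
#'
#' @param measured_values,estimated_values equal-length vectors, n >= 3.
#' @return object of class `grf_bland_altman`: list with `bias`,
#'   `loa_low`, `loa_high`, `slope`, `sd`, `n`.
#' @export
#' @examples
#' m <- rnorm(100, 2.5, 0.3)
#' bland_altman(m, m + 0.1)
bland_altman <- function(measured_values, estimated_values) {
  n <- length(measured_values)
  if (n < 3 || length(estimated_values) != n) {
    stop("need at least 3 pairs of equal length")
  }
  d <- estimated_values - measured_values
  s <- sd(d)
  bias <- mean(d)
  slope <- unname(coef(lm(d ~ measured_values))[2])
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, slope = slope,
                 sd = s, n = n),
            class = "grf_bland_altman")
}

#' @export
print.grf_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias=%.4f LoA=[%.4f, %.4f] slope=%.4f (n=%d)\n",
    x$bias, x$loa_low, x$loa_high, x$slope, x$n))
  invisible(x)
}

#' Peak-error profile against touchdown CoP position
#'
#' Bins per-contact peak errors by the anteroposterior centre-of-pressure
#' position at touchdown (the CoP_y of the first sample with nonzero total
#' pressure, normalized by insole length), exposing whether estimation
#' accuracy degrades for forefoot landings.
#'
#' @param contacts list of `grf_contact` objects.
#' @param peak_errors per-contact peak-error values aligned with
#'   `contacts`.
#' @param n_bins number of equal-width bins over the normalized \[0, 1\]
#'   insole axis (>= 2).
#' @return data.frame `bin`, `center`, `n`, `mean`, `sd` for occupied
#'   bins only.
#' @export
cop_error_profile <- function(contacts, peak_errors, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  stopifnot(length(contacts) == length(peak_errors))
  touchdown <- vapply(contacts, function(ct) {
    idx <- which(rowSums(ct$pressure) > 0)[1]
    if (is.na(idx)) return(NA_real_)
    ct$cop_y[idx] / ct$insole_length
  }, 0)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(pmin(pmax(touchdown, 0), 1), breaks, include.lowest = TRUE,
             labels = FALSE)
  keep <- !is.na(bin)
  agg <- split(peak_errors[keep], bin[keep])
  out <- data.frame(
    bin = as.integer(names(agg)),
    center = (breaks[as.integer(names(agg))] +
                breaks[as.integer(names(agg)) + 1L]) / 2,
    n = vapply(agg, length, 0L),
    mean = vapply(agg, mean, 0),
    sd = vapply(agg, sd, 0)
  )
  rownames(out) <- NULL
  out[order(out$bin), ]
}
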