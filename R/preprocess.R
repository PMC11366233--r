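#' Zero-phase low-pass Butterworth filter
#'
#' Designs an order-`order` low-pass Butterworth filter and applies it
#' forward and backward, giving zero phase lag and the squared single-pass
#' magnitude response (so the half-power cutoff attenuates to 0.5 in
#' amplitude). The signal is extended by odd reflection at both ends before
#' filtering to suppress start-up transients on short segments, then the
#' extension is discarded; output length equals input length.
#'
#' @param x uniformly sampled numeric signal.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz; must lie below the Nyquist rate.
#' @param order filter order (default 4).
#' @return the filtered signal, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' x <- sin(2 * pi * 5 * t) + sin(2 * pi * 80 * t)
#' y <- butterworth_lowpass(x, fs = 1000, cutoff = 15)
butterworth_lowpass <- function(x, fs, cutoff, order = 4) {
  stopifnot(fs > 0, order >= 1)
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie in (0, fs/2)")
  }
  n <- length(x)
  padlen <- min(n - 1L, as.integer(ceiling(5 * fs / cutoff)))
  if (n < 3 * (order + 1) || padlen < order) {
    stop("signal too short to filter at this order")
  }
  bf <- signal::butter(order, 2 * cutoff / fs, type = "low")
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(pre, x, post)
  y <- signal::filter(bf$b, bf$a, ext)
  y <- rev(as.numeric(signal::filter(bf$b, bf$a, rev(y))))
  y[(padlen + 1):(padlen + n)]
}

#' Detect ground contacts by force threshold
#'
#' Initial contact is the first sample of each maximal run with
#' `force > threshold` (strictly greater; ties break toward the earlier
#' sample) and toe off the sample after the last; intervals are half-open
#' `[ic, to)` in 0-based sample indices. Runs shorter than
#' `min_duration_s` are discarded as noise.
#'
#' A run that touches the first or last sample of the recording is a
#' contact the device only partially captured (it powered on or off
#' mid-stance); its touchdown time is unknowable, so such runs are dropped
#' when `drop_edges = TRUE`.
#'
#' @param force_v filtered vertical force trace, N.
#' @param fs sampling rate, Hz.
#' @param threshold detection threshold, N (default 40).
#' @param min_duration_s minimum credible contact duration, s.
#' @param drop_edges drop runs truncated by the recording window.
#' @return object of class `grf_contact_events`: data.frame `ic`, `to`
#'   (0-based indices) with attributes `fs`.
#' @export
detect_contacts <- function(force_v, fs, threshold = 40,
                            min_duration_s = 0.08, drop_edges = TRUE) {
  stopifnot(threshold > 0, fs > 0)
  above <- force_v > threshold
  if (!length(above) || !any(above)) {
    return(contact_events(integer(0), integer(0), fs))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= max(round(min_duration_s * fs), 1L)
  if (drop_edges) {
    keep <- keep & starts > 1L & ends < length(above)
  }
  contact_events(starts[keep] - 1L, ends[keep], fs)   # 0-based, half-open
}

#' Construct a contact-events object
#'
#' @param ic,to 0-based initial-contact and toe-off sample indices
#'   (half-open intervals) on one device's sample clock.
#' @param fs that device's sampling rate, Hz.
#' @return class `grf_contact_events` data.frame.
#' @export
contact_events <- function(ic, to, fs) {
  stopifnot(length(ic) == length(to), all(ic < to), fs > 0)
  if (length(ic) > 1) {
    stopifnot(!is.unsorted(ic, strictly = TRUE),
              all(to[-length(to)] <= ic[-1]))
  }
  structure(data.frame(ic = as.integer(ic), to = as.integer(to)),
            fs = fs, class = c("grf_contact_events", "data.frame"))
}

#' Initial-contact times in seconds
#' @param events a `grf_contact_events` object.
#' @return numeric vector of touchdown times on the device clock.
#' @export
ic_times <- function(events) {
  events$ic / attr(events, "fs")
}

#' Quadratic upsampling of a low-rate log
#'
#' Interpolates irregular or low-rate samples onto a uniform high-rate grid
#' with an interpolating quadratic (degree-2) spline, the scheme used to
#' reconstruct 50 Hz stance-only pressure logs at 1,000 Hz. With fewer than
#' three knots a quadratic spline is not defined and the function falls back
#' to linear interpolation with a warning.
#'
#' @param t knot times, s (strictly increasing).
#' @param y values at the knots (vector, or matrix with one row per knot).
#' @param target_fs output sampling rate, Hz.
#' @return list `t` (uniform grid spanning the knot range) and `y`
#'   (interpolated values, matrix if `y` was one).
#' @export
upsample_quadratic <- function(t, y, target_fs = 1000) {
  stopifnot(length(t) >= 2, !is.unsorted(t, strictly = TRUE), target_fs > 0)
  y_mat <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  stopifnot(nrow(y_mat) == length(t))
  t_out <- seq(t[1], t[length(t)], by = 1 / target_fs)
  if (length(t) < 3) {
    warning("fewer than 3 samples: falling back to linear interpolation")
    out <- apply(y_mat, 2, function(col) approx(t, col, xout = t_out)$y)
  } else {
    # interpolating quadratic B-spline: knot vector with simple interior
    # knots at the data-midpoint average positions (not-a-knot style ends)
    degree <- 2L
    interior <- if (length(t) > 3) (t[2:(length(t) - 2)] +
                                      t[3:(length(t) - 1)]) / 2 else numeric(0)
    knots <- c(rep(t[1], degree + 1L), interior,
               rep(t[length(t)], degree + 1L))
    B <- splines::splineDesign(knots, t, ord = degree + 1L)
    Bout <- splines::splineDesign(knots, t_out, ord = degree + 1L)
    coefs <- solve(B, y_mat)
    out <- Bout %*% coefs
  }
  out <- matrix(out, nrow = length(t_out))
  colnames(out) <- colnames(y_mat)
  list(t = t_out, y = if (is.matrix(y)) out else drop(out))
}

#' Normalize a trace to a fixed number of samples
#'
#' Linear interpolation onto `L` points uniformly spanning the first to the
#' last sample; endpoints are preserved exactly. Used to bring every
#' variable-duration foot contact to a common 400-sample length.
#'
#' @param x numeric trace of length >= 2 (or a matrix, column-wise).
#' @param L output length (default 400).
#' @return length-`L` vector (or `L`-row matrix).
#' @export
time_normalize <- function(x, L = 400) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) >= 2)
    return(apply(x, 2, time_normalize, L = L))
  }
  n <- length(x)
  if (n < 2) stop("cannot time-normalize fewer than 2 samples")
  if (n == L) return(x)
  approx(seq_len(n), x, xout = seq(1, n, length.out = L))$y
}
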