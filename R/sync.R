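#' Stride times from contact events
#'
#' Stride time is the interval between consecutive initial contacts of the
#' same foot. Accepts a [contact_events()] object (indices converted via
#' its sampling rate), a data.frame with an `ic` column in seconds, or a
#' numeric vector of IC times.
#'
#' @param events contact events (see Details).
#' @return numeric vector of stride durations, s (length = contacts - 1).
#' @export
#' @examples
#' stride_times(c(0, 0.7, 1.41))  # 0.70, 0.71
stride_times <- function(events) {
  ic <- if (inherits(events, "grf_contact_events")) {
    ic_times(events)
  } else if (is.data.frame(events)) {
    events$ic
  } else {
    as.numeric(events)
  }
  if (length(ic) < 2) stop("need at least 2 contacts to form stride times")
  diff(ic)
}

#' Align two stride-time sequences by exhaustive lag search
#'
#' Devices running on independent clocks record the same physical contacts
#' but number them differently. Because stride-to-stride duration
#' variability acts as a shared fingerprint, the Pearson correlation of the
#' two stride-time vectors is maximal at the true contact offset. The
#' correlation is evaluated at every integer lag in `[-max_lag, max_lag]`
#' with at least `min_overlap` overlapping stride pairs; the best lag is
#' returned and the alignment accepted if `r > threshold`. Ties break
#' toward the smaller `|lag|`. At offset `k`, stride `i` of stream A pairs
#' with stride `i - k` of stream B (positive `k`: B missed A's first `k`
#' contacts).
#'
#' @param strides_a,strides_b stride-time vectors, s.
#' @param max_lag largest contact offset searched.
#' @param min_overlap minimum number of overlapping stride pairs.
#' @param threshold acceptance bound on Pearson r (default 0.85).
#' @return object of class `grf_alignment`: list with `offset`, `r`,
#'   `n_overlap`, `accepted`, and the full `scan` (lag, r, n) table.
#' @export
align_streams <- function(strides_a, strides_b, max_lag = 20,
                          min_overlap = 10, threshold = 0.85) {
  la <- length(strides_a); lb <- length(strides_b)
  if (la < min_overlap || lb < min_overlap) {
    stop("stride vectors shorter than min_overlap")
  }
  lags <- -max_lag:max_lag
  scan <- data.frame(lag = lags, r = NA_real_, n = 0L)
  for (j in seq_along(lags)) {
    k <- lags[j]
    i_lo <- max(1L, 1L + k); i_hi <- min(la, lb + k)
    n_ov <- i_hi - i_lo + 1L
    if (n_ov < min_overlap) next
    a <- strides_a[i_lo:i_hi]
    b <- strides_b[(i_lo - k):(i_hi - k)]
    scan$n[j] <- n_ov
    if (sd(a) == 0 || sd(b) == 0) next   # correlation undefined
    scan$r[j] <- cor(a, b)
  }
  ok <- which(!is.na(scan$r))
  if (!length(ok)) {
    return(structure(list(offset = NA_integer_, r = NA_real_,
                          n_overlap = 0L, accepted = FALSE, scan = scan),
                     class = "grf_alignment"))
  }
  # max r; ties toward smaller |lag|
  best <- ok[order(-scan$r[ok], abs(scan$lag[ok]))][1]
  structure(list(offset = scan$lag[best], r = scan$r[best],
                 n_overlap = scan$n[best],
                 accepted = isTRUE(scan$r[best] > threshold), scan = scan),
            class = "grf_alignment")
}

#' @export
print.grf_alignment <- function(x, ...) {
  cat(sprintf("<grf_alignment> offset=%s r=%.4f n=%d %s\n",
              x$offset, x$r, x$n_overlap,
              if (x$accepted) "accepted" else "REJECTED"))
  invisible(x)
}

#' Synchronize the three device streams at contact level
#'
#' Runs [align_streams()] twice, both anchored on the force stream (the
#' reference clock): force vs pressure, then force vs IMU. The result maps
#' each physical contact to its per-device contact index; contacts not
#' visible on all three devices are dropped. If either alignment fails the
#' acceptance bound the session is flagged unsynchronizable rather than
#' repaired.
#'
#' @param force_events,pressure_events,imu_events contact events per
#'   device: anything [stride_times()] accepts.
#' @param ... passed to [align_streams()] (`max_lag`, `min_overlap`,
#'   `threshold`).
#' @return list with `synchronized` (logical), `map` (data.frame of
#'   1-based per-device contact indices `force`, `pressure`, `imu`) and
#'   `alignments` (the two `grf_alignment` objects).
#' @export
synchronize_session <- function(force_events, pressure_events, imu_events,
                                ...) {
  sf <- stride_times(force_events)
  sp <- stride_times(pressure_events)
  si <- stride_times(imu_events)
  a_fp <- align_streams(sf, sp, ...)
  a_fi <- align_streams(sf, si, ...)
  if (!a_fp$accepted || !a_fi$accepted) {
    return(list(synchronized = FALSE, map = NULL,
                alignments = list(pressure = a_fp, imu = a_fi)))
  }
  n_force <- length(sf) + 1L
  n_press <- length(sp) + 1L
  n_imu <- length(si) + 1L
  i <- seq_len(n_force)
  map <- data.frame(force = i,
                    pressure = i - a_fp$offset,
                    imu = i - a_fi$offset)
  keep <- map$pressure >= 1L & map$pressure <= n_press &
    map$imu >= 1L & map$imu <= n_imu
  list(synchronized = TRUE, map = map[keep, , drop = FALSE],
       alignments = list(pressure = a_fp, imu = a_fi))
}
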