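#' Contact events from the stance-only pressure log
#'
#' The insole only stores samples between initial contact and toe off, so
#' contacts appear in the log as bursts separated by flight gaps. Samples
#' are grouped wherever consecutive timestamps are closer than `gap_s`;
#' each group is one contact.
#'
#' @param pressure_df logged pressure data.frame whose first column `t` is
#'   the window-centre timestamp (s, pressure-device clock).
#' @param gap_s minimum gap identifying a flight phase (s); must exceed the
#'   logging period (20 ms) and stay below the shortest flight time.
#' @return list with `times` (data.frame `ic`, `to` in seconds) and
#'   `groups` (list of row-index vectors, one per contact).
#' @export
pressure_events <- function(pressure_df, gap_s = 0.06) {
  t <- pressure_df$t
  if (!length(t)) {
    return(list(times = data.frame(ic = numeric(0), to = numeric(0)),
                groups = list()))
  }
  grp <- cumsum(c(1, diff(t) > gap_s))
  groups <- split(seq_along(t), grp)
  # Because the log is stance-only, a burst truncated by power-on cannot be
  # told apart from a complete short contact when the truncation is small,
  # yet its first timestamp (the presumed touchdown) would be wrong and
  # would corrupt the stride-time fingerprint. The first burst is therefore
  # always discarded; a trailing burst clearly shorter than the typical
  # contact (device powered off mid-stance) is discarded too.
  if (length(groups) >= 3) {
    span <- vapply(groups, function(i) t[i[length(i)]] - t[i[1]], 0)
    groups <- groups[-1]
    span <- span[-1]
    if (span[length(groups)] < 0.6 * median(span)) {
      groups <- groups[-length(groups)]
    }
  }
  times <- data.frame(
    ic = vapply(groups, function(i) t[i[1]], 0),
    to = vapply(groups, function(i) t[i[length(i)]], 0)
  )
  # a single-window contact still has to < ic + one period; widen to the
  # window edges so intervals have positive length
  times$ic <- times$ic - 0.01
  times$to <- times$to + 0.01
  rownames(times) <- NULL
  list(times = times, groups = unname(groups))
}

#' Contact events from the accelerometer stream
#'
#' Step detection on the vertical accelerometer axis: the stream is
#' low-pass filtered and contacts are the runs where vertical acceleration
#' exceeds `threshold_g` (stance loading lifts the axis well above the
#' -1 g free-fall reading). Event timing is consistent contact to contact,
#' which is all stride-time synchronization needs.
#'
#' @param imu_df IMU data.frame with columns `t` and `az` (g) on a uniform
#'   grid.
#' @param fs IMU sampling rate, Hz.
#' @param cutoff detection filter cutoff, Hz.
#' @param threshold_g detection threshold on filtered `az`, g.
#' @param min_duration_s minimum credible contact duration, s.
#' @return a [contact_events()] object on the IMU sample clock.
#' @export
imu_events <- function(imu_df, fs = 1138, cutoff = 10, threshold_g = -0.5,
                       min_duration_s = 0.08) {
  az <- butterworth_lowpass(imu_df$az, fs, cutoff)
  above <- az > threshold_g
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= max(round(min_duration_s * fs), 1L) &
    starts > 1L & ends < length(above)   # drop contacts cut by power-on/off
  contact_events(starts[keep] - 1L, ends[keep], fs)
}
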