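#' Synthetic 16-channel FSR pressure for one stance phase
#'
#' Distributes each vertical-force sample over the insole sensors with a
#' Gaussian spatial kernel centred on a travelling pressure centroid, then
#' applies the saturating FSR response `raw = a * log(1 + b * F)`. The
#' centroid starts at a footstrike-dependent touchdown position (rearfoot
#' near the heel, forefoot anterior) and travels monotonically toward the
#' forefoot. Kernel weights are normalized per sample, so the per-sample sum
#' of sensor forces equals `grf_v` exactly; the true centroid path is
#' returned for downstream testing.
#'
#' Weights are computed relative to the per-sample maximum, so a vanishing
#' kernel width degenerates cleanly to the nearest sensor taking all force.
#'
#' @param grf_v non-negative vertical GRF trace in N at the force rate.
#' @param profile participant row (uses `footstrike`).
#' @param geometry an [insole_geometry()].
#' @param config a [synth_config()] list.
#' @param noise logical; add raw-output noise of SD `config$fsr_noise_sd`.
#' @return list with `raw` (n x 16 FSR output), `forces` (n x 16 sensor
#'   forces in N), and `centroid` (data.frame `x`, `y` in mm).
#' @export
generate_pressures <- function(grf_v, profile, geometry,
                               config = synth_config(), noise = TRUE) {
  if (any(grf_v < 0)) stop("grf_v must be non-negative")
  validate_geometry(geometry)
  coords <- geometry$sensor_coords
  n_sensors <- nrow(coords)
  n <- length(grf_v)
  t_frac <- seq(0, 1, length.out = n)
  L <- geometry$insole_length

  y0 <- (config$cop_touchdown_base +
           config$cop_touchdown_span * profile$footstrike) * L
  y_end <- config$cop_toeoff_frac * L
  cy <- y0 + (y_end - y0) * t_frac^0.8
  cx <- config$cop_x_amp_mm * sin(pi * t_frac)

  # squared distance from the travelling centroid to each sensor
  d2 <- outer(cx, coords[, 1], "-")^2 + outer(cy, coords[, 2], "-")^2
  sigma2 <- config$kernel_sd_mm^2
  if (sigma2 > 0) {
    logw <- -d2 / (2 * sigma2)
  } else {
    # degenerate kernel: all mass on the nearest sensor(s)
    logw <- ifelse(d2 == apply(d2, 1, min), 0, -Inf)
  }
  logw <- logw - apply(logw, 1, max)   # numerical stabilization
  w <- exp(logw)
  w <- w / rowSums(w)
  forces <- sweep(w, 1, grf_v, "*")

  raw <- config$fsr_a * log1p(config$fsr_b * forces)
  if (noise && config$fsr_noise_sd > 0) {
    raw <- raw + matrix(rnorm(n * n_sensors, 0, config$fsr_noise_sd),
                        n, n_sensors)
    raw <- pmax(raw, 0)
  }
  colnames(raw) <- colnames(forces) <- rownames(coords)
  list(raw = raw, forces = forces,
       centroid = data.frame(x = cx, y = cy))
}

#' Invert the FSR logarithmic response
#'
#' @param raw FSR raw output (vector or matrix).
#' @param config a [synth_config()] (uses `fsr_a`, `fsr_b`).
#' @return force in N.
#' @export
invert_fsr <- function(raw, config = synth_config()) {
  expm1(raw / config$fsr_a) / config$fsr_b
}

#' Emulate stance-only 50 Hz moving-average pressure logging
#'
#' Reproduces the insole's storage-saving scheme: within each ground
#' contact, consecutive non-overlapping 20 ms windows of the native-rate
#' signal are averaged to a single logged sample stamped at the window
#' centre; everything outside the contact intervals is discarded. A contact
#' shorter than one window still yields one partial-window sample.
#'
#' @param pressure n x k matrix (or length-n vector) sampled at `fs`.
#' @param fs native sampling rate in Hz.
#' @param intervals data.frame with `ic`, `to` contact times in seconds on
#'   the same clock (half-open \[ic, to)), sorted and non-overlapping.
#' @param window_s averaging-window length in seconds (default 0.02).
#' @return data.frame with `t` (window-centre time) followed by one column
#'   per input channel; zero rows if no interval contains a full sample.
#' @export
emulate_pressure_logging <- function(pressure, fs, intervals,
                                     window_s = 0.02) {
  if (is.vector(pressure)) pressure <- matrix(pressure, ncol = 1)
  stopifnot(fs > 0, window_s > 0, all(intervals$ic < intervals$to))
  if (nrow(intervals) > 1) {
    if (is.unsorted(intervals$ic, strictly = TRUE) ||
        any(intervals$to[-nrow(intervals)] > intervals$ic[-1])) {
      stop("intervals must be sorted and non-overlapping")
    }
  }
  n <- nrow(pressure)
  win_n <- max(round(window_s * fs), 1L)
  out_t <- numeric(0)
  out_rows <- list()
  for (i in seq_len(nrow(intervals))) {
    i0 <- max(floor(intervals$ic[i] * fs) + 1L, 1L)   # 1-based sample index
    i1 <- min(ceiling(intervals$to[i] * fs), n)       # last sample inside
    if (i1 < i0) next
    starts <- seq(i0, i1, by = win_n)
    for (s in starts) {
      e <- min(s + win_n - 1L, i1)
      block <- pressure[s:e, , drop = FALSE]
      out_rows[[length(out_rows) + 1L]] <- colMeans(block)
      # timestamp at the centre of the actual (possibly partial) window
      out_t <- c(out_t, ((s - 1L) + (e - s) / 2) / fs)
    }
  }
  if (!length(out_rows)) {
    empty <- as.data.frame(matrix(numeric(0), 0, ncol(pressure) + 1))
    names(empty) <- c("t", colnames(pressure) %||%
                        paste0("ch", seq_len(ncol(pressure))))
    return(empty)
  }
  vals <- do.call(rbind, out_rows)
  colnames(vals) <- colnames(pressure) %||% paste0("ch", seq_len(ncol(vals)))
  data.frame(t = out_t, vals, check.names = FALSE)
}
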