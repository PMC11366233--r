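#' Synthetic shoe-mounted accelerometer (and gyroscope) trace
#'
#' Builds a 3-axis acceleration signal from session-level GRF traces on the
#' force-plate clock and resamples it to the IMU rate. The vertical axis is
#' `grf_v / (mass * g) - 1` in g (free fall reads -1 g during flight), the
#' anteroposterior axis `grf_ap / (mass * g)`; both carry a smooth
#' low-frequency segment-dynamics perturbation plus white noise, and all
#' axes are clipped to the accelerometer range. Gyroscope channels are
#' generated for realism but are not used by the estimation pipeline.
#'
#' Consumes the current RNG stream.
#'
#' @param grf_v,grf_ap session-long force traces in N at `config$force_fs`
#'   (zero during flight).
#' @param profile participant row (uses `mass`).
#' @param config a [synth_config()] list.
#' @param noise logical; add white accelerometer noise.
#' @return data.frame `t` (s, force-plate clock), `ax`, `ay`, `az` (g),
#'   `gx`, `gy`, `gz` (deg/s) at `config$imu_fs`.
#' @export
generate_imu <- function(grf_v, grf_ap, profile, config = synth_config(),
                         noise = TRUE) {
  fs <- config$force_fs
  n <- length(grf_v)
  stopifnot(length(grf_ap) == n, n >= 2)
  t_force <- (seq_len(n) - 1L) / fs
  bw <- profile$mass * GRAVITY

  pert <- function(amp) {
    phase <- runif(1, 0, 2 * pi)
    f <- config$imu_perturb_freq_hz * runif(1, 0.8, 1.2)
    amp * sin(2 * pi * f * t_force + phase)
  }
  az <- grf_v / bw - 1 + pert(config$imu_perturb_amp_g)
  ay <- grf_ap / bw + pert(config$imu_perturb_amp_g / 2)
  ax <- pert(config$imu_perturb_amp_g / 2)

  t_imu <- seq(0, t_force[n], by = 1 / config$imu_fs)
  resample <- function(x) approx(t_force, x, xout = t_imu)$y
  acc <- cbind(ax = resample(ax), ay = resample(ay), az = resample(az))
  if (noise && config$imu_noise_sd_g > 0) {
    acc <- acc + matrix(rnorm(length(acc), 0, config$imu_noise_sd_g),
                        nrow(acc), 3)
  }
  clip <- config$accel_clip_g
  acc <- pmin(pmax(acc, -clip), clip)

  gyr <- vapply(1:3, function(i) {
    g <- config$gyro_amp_dps * sin(2 * pi * runif(1, 1, 4) * t_imu +
                                     runif(1, 0, 2 * pi))
    if (noise) g <- g + rnorm(length(t_imu), 0, config$gyro_amp_dps / 20)
    pmin(pmax(g, -config$gyro_clip_dps), config$gyro_clip_dps)
  }, numeric(length(t_imu)))
  colnames(gyr) <- c("gx", "gy", "gz")

  data.frame(t = t_imu, acc, gyr)
}
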