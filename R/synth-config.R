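#' Default parameters of the synthetic running-session generator
#'
#' Returns the full parameter list controlling the synthetic cohort, the GRF
#' forward model, the insole/FSR sensor model, the IMU model, and session
#' timing. Every downstream generator takes such a list so individual values
#' can be overridden without touching code.
#'
#' Cohort distributions are sex-pooled truncated normals spanning the ranges
#' typical of recreational-to-trained distance runners (mass 45-100 kg, easy
#' running speed 7-16 km/h); footstrike terciles default to a
#' rearfoot-dominant mix (54/30/16 percent rear/mid/fore). The GRF model is a
#' two-component stance curve: an active half-period raised-sine peak near
#' 45 percent of stance around 2.5 BW at easy speed, plus an early impact
#' transient whose amplitude vanishes for forefoot strikers. FSR raw output
#' follows a saturating logarithmic response `a*log(1 + b*F)`.
#'
#' @param ... named overrides of any default parameter.
#' @return a named list of class `grf_synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(noise_sd_bw = 0)
#' cfg$mass_mean
synth_config <- function(...) {
  cfg <- list(
    # cohort distributions
    mass_mean = 66, mass_sd = 10, mass_range = c(45, 100),          # kg
    speed_mean = 11, speed_sd = 1.5, speed_range = c(7, 16),        # km/h
    footstrike_probs = c(rear = 0.54, mid = 0.30, fore = 0.16),
    stride_cv_mean = 0.03, stride_cv_sd = 0.01,
    stride_cv_range = c(0.005, 0.1),
    insole_mean = 265, insole_sd = 15, insole_range = c(230, 310),  # mm

    # vertical GRF forward model (BW units unless noted)
    peak_bw = 2.5,              # active peak at easy speed, flat
    peak_speed_slope = 0.08,    # BW per km/h above easy speed
    peak_grad_slope = 0.005,    # BW per % incline
    active_peak_frac = 0.45,    # stance fraction of the active peak
    impact_bw = 0.8,            # transient amplitude for an extreme rearfoot
    impact_width = 0.30,        # transient support, fraction of stance

    # anteroposterior GRF forward model
    ap_amp_bw = 0.25,           # braking/propulsion amplitude at easy speed
    ap_speed_slope = 0.015,     # BW per km/h above easy speed
    ap_grad_gain = 0.02,        # BW of net shift per % incline

    # noise
    noise_sd_bw = 0.05,         # additive GRF noise during stance
    flight_noise_sd_n = 2,      # force-plate noise between contacts, N
    fsr_noise_sd = 0.005,       # FSR raw-output noise
    imu_noise_sd_g = 0.05,      # accelerometer noise, g

    # FSR response and pressure spatial model
    fsr_a = 1, fsr_b = 0.01,    # raw = a*log(1 + b*F), F in N
    kernel_sd_mm = 30,          # Gaussian footprint of the pressure centroid
    cop_touchdown_base = 0.15,  # touchdown CoP_y fraction, extreme rearfoot
    cop_touchdown_span = 0.55,  # added fraction for an extreme forefoot
    cop_toeoff_frac = 0.78,     # CoP_y fraction at toe off
    cop_x_amp_mm = 5,           # mediolateral CoP excursion

    # IMU model
    imu_fs = 1138, accel_clip_g = 30,
    imu_perturb_amp_g = 0.1, imu_perturb_freq_hz = 3,
    gyro_amp_dps = 50, gyro_clip_dps = 4000,

    # session timing
    force_fs = 1000, pressure_log_fs = 50, pressure_window_s = 0.02,
    cadence_base = 78,          # strides/min per foot at 11 km/h
    cadence_speed_slope = 2.2,  # strides/min per km/h
    duty_base = 0.36,           # contact time as a fraction of stride time
    duty_speed_slope = -0.01,   # per km/h
    contact_jitter_cv = 0.015,  # contact-duration jitter relative to mean
    contact_range_s = c(0.12, 0.38),
    lead_in_s = 0.5,            # global time of the first touchdown
    device_offset_max_s = 2,    # per-device recording start delay, uniform
    stage_duration_s = 30
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("unknown synth_config parameters: ",
                          paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, overrides)
  }
  validate_synth_config(cfg)
  structure(cfg, class = "grf_synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(
    cfg$mass_sd > 0, cfg$speed_sd > 0, cfg$stride_cv_sd > 0,
    cfg$insole_sd > 0,
    all(cfg$footstrike_probs >= 0), sum(cfg$footstrike_probs) > 0,
    cfg$noise_sd_bw >= 0, cfg$flight_noise_sd_n >= 0,
    cfg$fsr_a > 0, cfg$fsr_b > 0, cfg$kernel_sd_mm >= 0,
    cfg$force_fs > 0, cfg$imu_fs > 0,
    cfg$stride_cv_range[1] > 0, cfg$stride_cv_range[2] <= 0.1,
    cfg$device_offset_max_s >= 0
  )
  invisible(cfg)
}
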