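#' Treadmill protocol stage list
#'
#' The `"paper"` protocol mirrors a three-gradient treadmill session built
#' around each runner's easy training speed: flat (+1 percent) stages at the
#' easy speed, 10 percent slower, 10 percent faster and a fixed 12 km/h;
#' uphill (+6 percent) at the easy speed and 10 percent slower; downhill
#' (-4 percent) at the easy speed, 10 percent slower and faster. The
#' `"quick"` protocol keeps all three gradients and three distinct speeds in
#' five stages. Stage durations default to `config$stage_duration_s`.
#'
#' @param profile participant row (uses `easy_speed`).
#' @param protocol `"paper"` (9 stages) or `"quick"` (5 stages).
#' @param config a [synth_config()] list.
#' @return data.frame `condition_id`, `speed` (km/h), `gradient` (%),
#'   `duration` (s).
#' @export
protocol_conditions <- function(profile, protocol = c("quick", "paper"),
                                config = synth_config()) {
  protocol <- match.arg(protocol)
  e <- profile$easy_speed
  stages <- switch(protocol,
    paper = data.frame(
      speed = c(e, 0.9 * e, 1.1 * e, 12, e, 0.9 * e, e, 0.9 * e, 1.1 * e),
      gradient = c(1, 1, 1, 1, 6, 6, -4, -4, -4)
    ),
    quick = data.frame(
      speed = c(e, 1.1 * e, 12, e, e),
      gradient = c(1, 1, 1, 6, -4)
    )
  )
  stages$duration <- config$stage_duration_s
  stages$condition_id <- sprintf("C%02d", seq_len(nrow(stages)))
  stages[, c("condition_id", "speed", "gradient", "duration")]
}

#' Generate one synthetic sensor session
#'
#' Simulates one participant running one condition and returns the three
#' raw device streams exactly as the acquisition hardware would deliver
#' them: a continuous 1,000 Hz two-component force stream, a stance-only
#' 50 Hz pressure log (20 ms moving-average windows), and a continuous
#' ~1,138 Hz accelerometer/gyroscope stream. Each device records on its own
#' clock: recording starts at an independent random delay after the session
#' begins, so the devices disagree about which physical contact is their
#' first. All ground truth (contact intervals, clean GRF traces, centroid
#' paths, offsets) is retained in `$truth` for testing.
#'
#' @param profile one row of a [generate_cohort()] cohort.
#' @param condition list or row with `speed`, `gradient`, `duration` and
#'   optionally `condition_id`.
#' @param seed integer; the session is a pure function of its arguments.
#' @param config a [synth_config()] list.
#' @param geometry optional [insole_geometry()]; defaults to the profile's
#'   insole length.
#' @param noise logical master switch for all stochastic sensor noise
#'   (waveform and timing jitter remain).
#' @return object of class `grf_session`; see Details.
#' @export
#' @examples
#' prof <- generate_cohort(1, seed = 4)[1, ]
#' ses <- generate_session(prof, list(speed = 11, gradient = 0, duration = 20),
#'                         seed = 9)
#' nrow(ses$truth$contacts)
generate_session <- function(profile, condition, seed,
                             config = synth_config(), geometry = NULL,
                             noise = TRUE) {
  stopifnot(condition$duration > 0,
            condition$gradient >= -10, condition$gradient <= 10)
  if (is.null(geometry)) geometry <- insole_geometry(profile$insole_length)
  validate_geometry(geometry)
  fs <- config$force_fs

  with_seed(seed, {
    # --- stance/stride timeline -------------------------------------------
    speed <- condition$speed
    stride_base <- 60 / (config$cadence_base +
                           config$cadence_speed_slope * (speed - 11))
    duty <- config$duty_base + config$duty_speed_slope * (speed - 11)
    contact_base <- min(max(stride_base * duty, config$contact_range_s[1]),
                        config$contact_range_s[2])
    ic <- numeric(0); dur <- numeric(0)
    t <- config$lead_in_s
    while (t + contact_base < condition$duration - 0.1) {
      d <- contact_base * (1 + config$contact_jitter_cv * rnorm(1))
      d <- min(max(d, config$contact_range_s[1]), config$contact_range_s[2])
      if (t + d >= condition$duration - 0.05) break
      ic <- c(ic, t); dur <- c(dur, d)
      stride <- stride_base * (1 + profile$stride_cv * rnorm(1))
      stride <- max(stride, d + 0.05)   # stance phases cannot overlap
      t <- t + stride
    }
    n_contacts <- length(ic)
    if (n_contacts == 0) stop("condition too short to fit any foot contact")

    # --- per-contact waveforms --------------------------------------------
    n_f <- round(condition$duration * fs)
    fv <- rnorm(n_f, 0, if (noise) config$flight_noise_sd_n else 0)
    fap <- rnorm(n_f, 0, if (noise) config$flight_noise_sd_n else 0)
    clean_v_stream <- numeric(n_f)
    clean_ap_stream <- numeric(n_f)
    pressure_stream <- matrix(0, n_f, nrow(geometry$sensor_coords))
    colnames(pressure_stream) <- rownames(geometry$sensor_coords)
    clean_v <- clean_ap <- centroid <- vector("list", n_contacts)

    for (k in seq_len(n_contacts)) {
      g <- generate_grf(profile, condition, dur[k], config, noise = noise)
      p <- generate_pressures(g$clean_v, profile, geometry, config,
                              noise = noise)
      i0 <- round(ic[k] * fs) + 1L
      idx <- i0:(i0 + length(g$grf_v) - 1L)
      fv[idx] <- g$grf_v
      fap[idx] <- g$grf_ap
      clean_v_stream[idx] <- g$clean_v
      clean_ap_stream[idx] <- g$clean_ap
      pressure_stream[idx, ] <- p$raw
      clean_v[[k]] <- g$clean_v
      clean_ap[[k]] <- g$clean_ap
      centroid[[k]] <- p$centroid
    }

    truth_contacts <- data.frame(
      contact = seq_len(n_contacts),
      ic = ic, to = ic + dur, duration = dur,
      speed = speed, gradient = condition$gradient
    )

    # --- stance-only 50 Hz logging ----------------------------------------
    logged <- emulate_pressure_logging(pressure_stream, fs, truth_contacts,
                                       window_s = config$pressure_window_s)

    # --- IMU ---------------------------------------------------------------
    imu <- generate_imu(clean_v_stream, clean_ap_stream, profile, config,
                        noise = noise)

    # --- independent device clocks ----------------------------------------
    offs <- c(force = 0,
              pressure = runif(1, 0, config$device_offset_max_s),
              imu = runif(1, 0, config$device_offset_max_s))
    force_df <- data.frame(t = (seq_len(n_f) - 1L) / fs, fv = fv, fap = fap)
    pressure_df <- logged[logged$t >= offs["pressure"], , drop = FALSE]
    pressure_df$t <- pressure_df$t - offs["pressure"]
    imu_df <- imu[imu$t >= offs["imu"], , drop = FALSE]
    imu_df$t <- imu_df$t - offs["imu"]
    rownames(pressure_df) <- rownames(imu_df) <- NULL

    structure(list(
      force = force_df,
      pressure = pressure_df,
      imu = imu_df,
      device_offsets = offs,
      profile = profile,
      condition = list(
        condition_id = condition$condition_id %||% "C01",
        speed = speed, gradient = condition$gradient,
        duration = condition$duration
      ),
      geometry = geometry,
      config = config,
      truth = list(contacts = truth_contacts, clean_v = clean_v,
                   clean_ap = clean_ap, centroid = centroid)
    ), class = "grf_session")
  })
}

#' @export
print.grf_session <- function(x, ...) {
  cat("<grf_session> participant", x$profile$participant_id,
      "condition", x$condition$condition_id,
      sprintf("(%.1f km/h, %+d%%, %gs)", x$condition$speed,
              as.integer(x$condition$gradient), x$condition$duration), "\n")
  cat("  contacts:", nrow(x$truth$contacts),
      "| pressure samples:", nrow(x$pressure),
      "| device offsets (s):",
      paste(sprintf("%s=%.2f", names(x$device_offsets), x$device_offsets),
            collapse = " "), "\n")
  invisible(x)
}

#' Generate all sessions of a protocol for one participant
#'
#' @param profile one cohort row.
#' @param protocol `"quick"` or `"paper"`; see [protocol_conditions()].
#' @param seed integer seed; per-stage seeds are derived from it.
#' @param config a [synth_config()] list.
#' @param noise logical noise switch passed through.
#' @return list of [generate_session()] objects, one per stage.
#' @export
generate_protocol <- function(profile, protocol = c("quick", "paper"), seed,
                              config = synth_config(), noise = TRUE) {
  protocol <- match.arg(protocol)
  stages <- protocol_conditions(profile, protocol, config)
  stage_seeds <- with_seed(seed,
                           sample.int(.Machine$integer.max %/% 2L,
                                      nrow(stages)))
  geometry <- insole_geometry(profile$insole_length)
  lapply(seq_len(nrow(stages)), function(i) {
    generate_session(profile, as.list(stages[i, ]), seed = stage_seeds[i],
                     config = config, geometry = geometry, noise = noise)
  })
}
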