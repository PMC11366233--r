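test_that("cohort generation is seed-reproducible and respects bounds", {
  c1 <- generate_cohort(2, seed = 7)
  c2 <- generate_cohort(2, seed = 7)
  expect_identical(c1, c2)

  big <- generate_cohort(1000, seed = 1)
  expect_true(all(big$mass >= 45 & big$mass <= 100))
  expect_true(all(big$easy_speed >= 7 & big$easy_speed <= 16))
  expect_true(all(big$stride_cv > 0 & big$stride_cv <= 0.1))
  expect_true(all(big$footstrike >= 0 & big$footstrike <= 1))

  # tercile mixture: rearfoot fraction within 5 points of the configured 54%
  rear_frac <- mean(big$footstrike < 1 / 3)
  expect_lt(abs(rear_frac - 0.54), 0.05)
})

test_that("cohort generator rejects invalid distribution parameters", {
  expect_error(synth_config(mass_sd = -1))
  expect_error(generate_cohort(0, seed = 1))
})

test_that("vertical GRF forward model has the expected morphology", {
  prof <- fixture_profile()
  cond_flat <- list(speed = prof$easy_speed, gradient = 0)

  g <- generate_grf(prof, cond_flat, 0.25, noise = FALSE)
  bw <- prof$mass * 9.81
  # endpoints zero, non-negative throughout
  expect_equal(g$grf_v[1], 0)
  expect_equal(g$grf_v[length(g$grf_v)], 0)
  expect_true(all(g$grf_v >= 0))
  # active peak near 2.5 BW at easy speed on the flat
  expect_gt(max(g$grf_v) / bw, 2.0)
  expect_lt(max(g$grf_v) / bw, 3.0)

  # net anteroposterior impulse ~ 0 on the flat (constant treadmill speed)
  expect_lt(abs(mean(g$grf_ap) / bw), 1e-9)

  # uphill shifts balance toward propulsion, downhill toward braking
  up <- generate_grf(prof, list(speed = 11, gradient = 6), 0.25,
                     noise = FALSE)
  down <- generate_grf(prof, list(speed = 11, gradient = -4), 0.25,
                       noise = FALSE)
  expect_gt(mean(up$grf_ap), 0)
  expect_lt(mean(down$grf_ap), 0)

  # speed increases the active peak
  fast <- generate_grf(prof, list(speed = prof$easy_speed + 3, gradient = 0),
                       0.25, noise = FALSE)
  expect_gt(max(fast$grf_v), max(g$grf_v))
})

test_that("forefoot strikers produce no impact transient", {
  prof <- fixture_profile()
  prof$footstrike <- 1.0
  g <- generate_grf(prof, list(speed = 11, gradient = 0), 0.25,
                    noise = FALSE)
  early <- g$grf_v[g$t_frac < 0.30]
  # strictly increasing up to 30% stance: no local maximum
  expect_true(all(diff(early) > 0))

  prof$footstrike <- 0.0
  g2 <- generate_grf(prof, list(speed = 11, gradient = 0), 0.25,
                     noise = FALSE)
  early2 <- g2$grf_v[g2$t_frac < 0.30]
  expect_false(all(diff(early2) > 0))   # rearfoot has an impact peak
})

test_that("GRF generator rejects out-of-range durations", {
  prof <- fixture_profile()
  cond <- list(speed = 11, gradient = 0)
  expect_error(generate_grf(prof, cond, -0.1))
  expect_error(generate_grf(prof, cond, 0.05))
  expect_error(generate_grf(prof, cond, 0.5))
})

test_that("pressure model conserves force and degenerates cleanly", {
  prof <- fixture_profile()
  geom <- insole_geometry(prof$insole_length)
  g <- generate_grf(prof, list(speed = 11, gradient = 0), 0.25,
                    noise = FALSE)

  p <- generate_pressures(g$clean_v, prof, geom, noise = FALSE)
  # conservation: sensor forces sum to the input per sample
  expect_lt(max(abs(rowSums(p$forces) - g$clean_v)) /
              max(g$clean_v), 1e-12)
  # inverse FSR response recovers the sensor forces exactly (noise off)
  expect_equal(invert_fsr(p$raw), p$forces, tolerance = 1e-9)

  # all-zero force -> all-zero raw output
  p0 <- generate_pressures(numeric(100), prof, geom, noise = FALSE)
  expect_true(all(p0$raw == 0))

  # degenerate kernel: all mass on the nearest sensor
  cfg0 <- synth_config(kernel_sd_mm = 0)
  p1 <- generate_pressures(g$clean_v, prof, geom, config = cfg0,
                           noise = FALSE)
  expect_true(all(rowSums(p1$forces > 0) <= 1))

  expect_error(generate_pressures(-g$clean_v, prof, geom))
  expect_error(generate_pressures(g$clean_v, prof,
                                  insole_geometry(260, n_rows = 1,
                                                  n_cols = 1)))
})

test_that("insole CoP of inverse-transformed forces tracks the true centroid", {
  prof <- fixture_profile()
  geom <- insole_geometry(prof$insole_length)
  g <- generate_grf(prof, list(speed = 11, gradient = 0), 0.25,
                    noise = FALSE)
  p <- generate_pressures(g$clean_v, prof, geom, noise = FALSE)
  forces <- invert_fsr(p$raw)
  cop <- cop_trace(forces, geom)
  active <- g$clean_v > 1   # CoP undefined near zero force
  # kernel-induced tolerance: discrete 4x4 grid + Gaussian footprint shift
  # the weighted mean by up to a fraction of the sensor row spacing
  err_y <- abs(cop$y[active] - p$centroid$y[active])
  expect_lt(max(err_y), 0.15 * geom$insole_length)
  expect_lt(mean(err_y), 0.08 * geom$insole_length)
})

test_that("IMU model follows the free-fall convention and clips", {
  prof <- fixture_profile()
  n <- 2000
  grf_v <- numeric(n); grf_ap <- numeric(n)
  grf_v[500:800] <- 2000   # a crude stance block
  imu <- with_seed(5, generate_imu(grf_v, grf_ap, prof, noise = FALSE))
  # flight samples read -1 g up to the smooth perturbation
  flight <- imu$az[imu$t < 0.4]
  expect_lt(max(abs(flight + 1)), 0.11)
  expect_true(all(abs(imu$az) <= 30 & abs(imu$ay) <= 30 &
                    abs(imu$ax) <= 30))

  # linear link: vertical acceleration correlates with grf_v over stance
  g <- generate_grf(prof, list(speed = 11, gradient = 0), 0.3,
                    noise = FALSE)
  imu2 <- with_seed(6, generate_imu(g$clean_v, g$clean_ap, prof,
                                    noise = FALSE))
  v_on_imu <- approx((seq_along(g$clean_v) - 1) / 1000, g$clean_v,
                     xout = imu2$t)$y
  expect_gt(cor(v_on_imu, imu2$az), 0.9)
})

test_that("stance-only logging averages 20 ms windows and drops flight", {
  # constant input over a 100 ms contact -> five samples equal to c
  x <- matrix(3.5, 1000, 2)
  logged <- emulate_pressure_logging(x, 1000,
                                     data.frame(ic = 0.1, to = 0.2))
  expect_equal(nrow(logged), 5)
  expect_true(all(logged[, -1] == 3.5))
  expect_true(all(logged$t >= 0.1 & logged$t < 0.2))

  # linear ramp over a 40 ms contact -> two per-window means
  ramp <- seq(0, 1, length.out = 40)
  x2 <- matrix(0, 1000, 1)
  x2[101:140, 1] <- ramp
  logged2 <- emulate_pressure_logging(x2, 1000,
                                      data.frame(ic = 0.1, to = 0.14))
  expect_equal(nrow(logged2), 2)
  expect_equal(logged2[[2]], c(mean(ramp[1:20]), mean(ramp[21:40])))

  # nothing outside the intervals
  x3 <- matrix(1, 500, 1)
  logged3 <- emulate_pressure_logging(x3, 1000,
                                      data.frame(ic = 0.05, to = 0.15))
  expect_true(all(logged3$t >= 0.05 & logged3$t <= 0.15))

  # an interval shorter than one window still yields one partial sample
  short <- emulate_pressure_logging(x3, 1000,
                                    data.frame(ic = 0.05, to = 0.058))
  expect_equal(nrow(short), 1)

  expect_error(emulate_pressure_logging(
    x3, 1000, data.frame(ic = c(0.1, 0.05), to = c(0.2, 0.09))))
})

test_that("session generation is deterministic and structurally sound", {
  prof <- fixture_profile()
  cond <- list(speed = 11, gradient = 1, duration = 20,
               condition_id = "C01")
  s1 <- generate_session(prof, cond, seed = 31)
  s2 <- generate_session(prof, cond, seed = 31)
  expect_identical(s1, s2)

  tc <- s1$truth$contacts
  # non-overlapping sorted truth intervals
  expect_true(all(diff(tc$ic) > 0))
  expect_true(all(tc$to[-nrow(tc)] <= tc$ic[-1]))

  # pressure samples exist only inside true contact intervals
  # (timestamps shifted back to the global clock)
  tp <- s1$pressure$t + s1$device_offsets["pressure"]
  inside <- vapply(tp, function(t) {
    any(t >= tc$ic - 1e-9 & t <= tc$to + 1e-9)
  }, TRUE)
  expect_true(all(inside))

  # force stream is the reference clock: detected contacts = truth count
  fvf <- butterworth_lowpass(s1$force$fv, 1000, 15)
  ev <- detect_contacts(fvf, 1000)
  expect_equal(nrow(ev), nrow(tc))
  expect_true(all(abs(ic_times(ev) - tc$ic) < 0.010))
})

test_that("device clock offsets desynchronize the first visible contact", {
  prof <- fixture_profile()
  ses <- fixture_session()
  offs <- ses$device_offsets
  tc <- ses$truth$contacts
  expect_equal(unname(offs["force"]), 0)
  # count truth contacts fully inside each device's recording window
  visible <- function(start) sum(tc$ic >= start)
  expect_lt(visible(offs["pressure"]), nrow(tc))
  # so the devices disagree on which contact is their first
  expect_gt(min(which(tc$ic >= offs["pressure"])), 1)
})

test_that("protocols cover three gradients and at least three speeds", {
  prof <- fixture_profile()
  for (proto in c("quick", "paper")) {
    stages <- protocol_conditions(prof, proto)
    expect_equal(length(unique(stages$gradient)), 3)
    expect_gte(length(unique(round(stages$speed, 6))), 3)
  }
  expect_equal(nrow(protocol_conditions(prof, "paper")), 9)
})
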