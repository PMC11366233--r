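test_that("zero-phase Butterworth matches the analytic magnitude response", {
  # DC gain 1: a constant passes unchanged, including at the edges
  y <- butterworth_lowpass(rep(3, 400), fs = 1000, cutoff = 15)
  expect_equal(y, rep(3, 400), tolerance = 1e-4)

  # at the cutoff the forward-backward pass squares the -3 dB response:
  # |H|^2 = 1 / (1 + (f/fc)^(2*order)) = 0.5 exactly
  t <- seq(0, 2, by = 1e-3)
  x <- sin(2 * pi * 15 * t)
  y <- butterworth_lowpass(x, fs = 1000, cutoff = 15)
  amp <- max(abs(y[800:1200]))
  expect_equal(amp, 0.5, tolerance = 0.01)

  # deep in the stopband (fs / 2.5 = 400 Hz): essentially annihilated
  x2 <- sin(2 * pi * 400 * t)
  y2 <- butterworth_lowpass(x2, fs = 1000, cutoff = 15)
  expect_lt(max(abs(y2[800:1200])), 0.01)

  # a slow in-band sinusoid passes nearly untouched
  x3 <- sin(2 * pi * 2 * t)
  y3 <- butterworth_lowpass(x3, fs = 1000, cutoff = 15)
  expect_lt(max(abs(y3 - x3)), 0.01)
})

test_that("filter rejects invalid cutoffs and too-short signals", {
  expect_error(butterworth_lowpass(rnorm(100), fs = 100, cutoff = 50))
  expect_error(butterworth_lowpass(rnorm(100), fs = 100, cutoff = 0))
  expect_error(butterworth_lowpass(rnorm(5), fs = 1000, cutoff = 15))
})

test_that("contact detection matches a brute-force threshold scan", {
  # independent oracle: linear scan over samples
  oracle <- function(x, thr, min_n) {
    runs <- list()
    start <- NA
    for (i in seq_along(x)) {
      if (x[i] > thr && is.na(start)) start <- i
      if ((x[i] <= thr || i == length(x)) && !is.na(start)) {
        end <- if (x[i] <= thr) i - 1 else i
        if (end - start + 1 >= min_n) {
          runs[[length(runs) + 1]] <- c(start - 1L, end)  # 0-based, half-open
        }
        start <- NA
      }
    }
    do.call(rbind, runs)
  }
  with_seed(12, {
    for (case in 1:300) {
      x <- rnorm(200, mean = runif(1, 20, 60), sd = 25)
      got <- detect_contacts(x, fs = 1000, threshold = 40,
                             min_duration_s = 0.005, drop_edges = FALSE)
      want <- oracle(x, 40, 5)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(unname(cbind(got$ic, got$to)), unname(want))
      }
    }
  })
})

test_that("contact detection handles pulses, empty traces and edges", {
  expect_equal(nrow(detect_contacts(numeric(0), 1000)), 0)
  expect_equal(nrow(detect_contacts(rep(0, 1000), 1000)), 0)

  # a 200 ms 100 N square pulse -> exactly one event spanning the pulse
  x <- rep(0, 1000)
  x[301:500] <- 100
  ev <- detect_contacts(x, 1000)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$ic, 300)   # 0-based first sample above threshold
  expect_equal(ev$to, 500)   # half-open end

  # a run touching the stream boundary is a partial contact: dropped
  x2 <- rep(0, 1000); x2[1:200] <- 100; x2[501:700] <- 100
  ev2 <- detect_contacts(x2, 1000)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$ic, 500)

  # detection on the synthetic session recovers the truth schedule
  ses <- fixture_session()
  fvf <- butterworth_lowpass(ses$force$fv, 1000, 15)
  ev3 <- detect_contacts(fvf, 1000)
  tc <- ses$truth$contacts
  expect_equal(nrow(ev3), nrow(tc))
  expect_true(all(abs(ic_times(ev3) - tc$ic) < 0.010))
})

test_that("quadratic upsampling reproduces quadratics exactly", {
  t <- seq(0, 0.3, by = 0.02)   # 50 Hz knots
  up <- upsample_quadratic(t, t^2, target_fs = 1000)
  expect_equal(up$y, up$t^2, tolerance = 1e-10)

  upc <- upsample_quadratic(t, rep(2.5, length(t)), target_fs = 1000)
  expect_equal(upc$y, rep(2.5, length(upc$t)), tolerance = 1e-10)

  # smooth non-polynomial signal: small interpolation error
  y <- sin(2 * pi * 3 * t)
  ups <- upsample_quadratic(t, y, target_fs = 1000)
  expect_lt(max(abs(ups$y - sin(2 * pi * 3 * ups$t))), 0.05)

  # matrix input interpolates column-wise
  m <- cbind(t^2, 3 * t)
  upm <- upsample_quadratic(t, m, target_fs = 1000)
  expect_equal(upm$y[, 1], upm$t^2, tolerance = 1e-10)
  expect_equal(upm$y[, 2], 3 * upm$t, tolerance = 1e-10)

  # two knots: linear fallback with a warning
  expect_warning(up2 <- upsample_quadratic(c(0, 0.02), c(0, 1),
                                           target_fs = 1000))
  expect_equal(up2$y, seq(0, 1, length.out = 21))
  expect_error(upsample_quadratic(0.1, 5))
})

test_that("time normalization hits 400 samples and preserves endpoints", {
  expect_identical(time_normalize(1:400 * 1.0), 1:400 * 1.0)

  expect_equal(time_normalize(rep(7, 123)), rep(7, 400))

  # a linear ramp maps to the line through its endpoints
  x <- seq(2, 5, length.out = 123)
  y <- time_normalize(x)
  expect_equal(y, seq(2, 5, length.out = 400), tolerance = 1e-12)
  expect_identical(y[1], x[1])
  expect_identical(y[400], x[123])

  # endpoint preservation for arbitrary signals
  with_seed(3, {
    for (n in c(17, 150, 361, 1000)) {
      x <- rnorm(n)
      y <- time_normalize(x)
      expect_length(y, 400)
      expect_equal(y[1], x[1])
      expect_equal(y[400], x[n])
    }
  })
  expect_error(time_normalize(5))
})

test_that("CoP is the pressure-weighted sensor average", {
  geom <- insole_geometry(260)

  # single active channel -> that sensor's coordinates
  p <- numeric(16); p[7] <- 4.2
  expect_equal(compute_cop(p, geom),
               c(x = unname(geom$sensor_coords[7, 1]),
                 y = unname(geom$sensor_coords[7, 2])))

  # two equal channels -> midpoint
  p2 <- numeric(16); p2[c(2, 11)] <- 1
  mid <- colMeans(geom$sensor_coords[c(2, 11), ])
  expect_equal(compute_cop(p2, geom), c(x = mid[["x"]], y = mid[["y"]]))

  # random sample vs an independent term-by-term summation oracle
  with_seed(3, {
    p3 <- runif(16)
    sx <- 0; sy <- 0; sw <- 0
    for (i in 1:16) {
      sw <- sw + p3[i]
      sx <- sx + p3[i] * geom$sensor_coords[i, 1]
      sy <- sy + p3[i] * geom$sensor_coords[i, 2]
    }
    expect_equal(compute_cop(p3, geom), c(x = sx / sw, y = sy / sw))
  })

  expect_error(compute_cop(c(-1, rep(1, 15)), geom))
  expect_error(compute_cop(rep(1, 8), geom))
})

test_that("CoP is translation-equivariant", {
  geom <- insole_geometry(260)
  shifted <- geom
  shifted$sensor_coords[, 1] <- shifted$sensor_coords[, 1] + 13
  shifted$sensor_coords[, 2] <- shifted$sensor_coords[, 2] + 5
  shifted$insole_length <- max(shifted$sensor_coords[, 2]) + 13
  with_seed(4, {
    for (i in 1:20) {
      p <- runif(16)
      a <- compute_cop(p, geom)
      b <- compute_cop(p, shifted)
      expect_equal(b - a, c(x = 13, y = 5))
    }
  })
})

test_that("zero-pressure CoP falls back to carry-forward then centroid", {
  geom <- insole_geometry(260)
  pm <- rbind(rep(0, 16),            # nothing yet: centroid
              diag(16)[3, ] * 2,     # sensor 3
              rep(0, 16))            # carry forward
  tr <- cop_trace(pm, geom)
  expect_equal(unlist(tr[1, ]), c(x = mean(geom$sensor_coords[, 1]),
                                  y = mean(geom$sensor_coords[, 2])))
  expect_equal(tr$y[2], unname(geom$sensor_coords[3, 2]))
  expect_equal(tr[3, ], tr[2, ], ignore_attr = TRUE)
})

test_that("segmentation emits 400-sample traces with faithful content", {
  pp <- fixture_processed()
  ses <- fixture_session()
  expect_true(pp$sync$synchronized)
  expect_gt(length(pp$contacts), 10)

  for (ct in pp$contacts) {
    expect_length(ct$force_v, 400)
    expect_length(ct$force_ap, 400)
    expect_length(ct$cop_x, 400)
    expect_length(ct$cop_y, 400)
    expect_equal(dim(ct$pressure), c(400, 16))
    expect_equal(dim(ct$accel), c(400, 3))
    expect_gt(ct$gct, 0)
    expect_lte(ct$gct, 0.4)
  }

  # gct equals the detected contact duration on the force clock
  ev <- pp$events$force
  first <- pp$contacts[[1]]
  jf <- first$contact
  expect_equal(first$gct, (ev$to[jf] - ev$ic[jf]) / 1000)

  # CoP stays on the insole wherever pressure is present
  for (ct in pp$contacts[1:5]) {
    loaded <- rowSums(ct$pressure) > 0
    expect_true(all(ct$cop_y[loaded] >= 0 &
                      ct$cop_y[loaded] <= ct$insole_length))
  }
})

test_that("noise-free segmentation recovers the true peak force", {
  prof <- fixture_profile()
  ses <- generate_session(prof, list(speed = 11, gradient = 1,
                                     duration = 15, condition_id = "C01"),
                          seed = 55, noise = FALSE)
  pp <- suppressMessages(preprocess_session(ses))
  expect_true(pp$sync$synchronized)
  tc <- ses$truth$contacts
  for (ct in pp$contacts[1:5]) {
    truth_peak <- max(ses$truth$clean_v[[ct$contact]])
    expect_lt(abs(max(ct$force_v) - truth_peak) / truth_peak, 0.01)
  }
})
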