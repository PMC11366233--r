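test_that("contact metrics satisfy their closed forms", {
  with_seed(41, {
    m <- 2.5 * sin(pi * seq(0, 1, length.out = 400))
    # perfect estimate
    cm <- contact_metrics(m, m, mass = 70)
    expect_equal(cm$rmse_bw, 0)
    expect_equal(cm$rrmse, 0)
    expect_equal(cm$pearson_r, 1)
    expect_equal(cm$peak_diff_pct, 0)
    expect_equal(cm$impulse_diff_pct, 0)

    # constant offset of 0.1 x range -> rRMSE exactly 10%
    offset <- 0.1 * (max(m) - min(m))
    cm2 <- contact_metrics(m, m + offset, mass = 70)
    expect_equal(cm2$rrmse, 10.0)

    expect_error(contact_metrics(rep(1, 400), rnorm(400), mass = 70),
                 "flat")
  })
})

test_that("metrics equal an independent straight-from-definition oracle", {
  with_seed(5, {
    for (case in 1:250) {
      m <- rnorm(100, mean = 2, sd = 0.6)
      e <- m + rnorm(100, 0, 0.3)
      mass <- runif(1, 50, 90)

      v <- contact_metrics(m, e, mass, component = "grf_v")
      # each formula re-implemented independently
      expect_equal(v$rmse_bw, sqrt(sum((e - m)^2) / length(m)))
      expect_equal(v$rrmse, 100 * sqrt(mean((e - m)^2)) /
                     (max(m) - min(m)))
      expect_equal(v$pearson_r,
                   sum(scale(m) * scale(e)) / (length(m) - 1))
      expect_equal(v$peak_diff_pct, 100 * (max(e) - max(m)) / max(m))
      tz <- function(y) sum(diff(seq_along(y)) * (head(y, -1) +
                                                    tail(y, -1)) / 2)
      expect_equal(v$impulse_diff_pct, 100 * (tz(e) - tz(m)) / tz(m))

      a <- contact_metrics(m - 2, e - 2, mass, component = "grf_ap")
      expect_equal(a$peak_braking_diff_bw, min(e - 2) - min(m - 2))
      expect_equal(a$peak_propulsive_diff_bw, max(e - 2) - max(m - 2))
      expect_equal(a$peak_braking_diff_n,
                   (min(e - 2) - min(m - 2)) * mass * 9.81)
    }
  })
})

test_that("Bland-Altman recovers constructed bias, limits and slope", {
  # exact case
  m <- seq(1, 3, length.out = 50)
  ba0 <- bland_altman(m, m)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  expect_equal(ba0$slope, 0)

  # normal-theory closed form at n = 10,000
  with_seed(11, {
    meas <- runif(10000, 1.5, 3.5)
    d <- rnorm(10000, 0.2, 0.1)
    ba <- bland_altman(meas, meas + d)
    expect_equal(ba$bias, 0.2, tolerance = 0.01)
    expect_equal(ba$loa_low, 0.2 - 1.96 * 0.1, tolerance = 0.01)
    expect_equal(ba$loa_high, 0.2 + 1.96 * 0.1, tolerance = 0.01)
    coverage <- mean(d > ba$loa_low & d < ba$loa_high)
    expect_equal(coverage, 0.95, tolerance = 0.01)
  })

  # an exactly linear magnitude-dependent error has that slope
  meas2 <- seq(1.5, 4, length.out = 200)
  est2 <- meas2 + 0.3 * (meas2 - 2.5)
  ba2 <- bland_altman(meas2, est2)
  expect_equal(ba2$slope, 0.3, tolerance = 1e-10)

  expect_error(bland_altman(1:2, 1:2))
})

test_that("PFI is exactly 1 for a provably ignored channel", {
  # zero the input weights of channel 5 in both LSTM directions: the
  # network output cannot depend on it
  est <- build_model(tiny_config(), n_channels = 6)
  est$params$Wf[, 5] <- 0
  est$params$Wb[, 5] <- 0
  est$trained <- TRUE
  f <- make_features(8, T_len = 30, C = 6, seed = 7)
  attr(f, "channel_names") <- paste0("ch", 1:6)
  y <- predict(est, f) + 0.05
  p <- pfi(est, f, y, channel = 5, n_reps = 20, seed = 3)
  expect_identical(p$pfi, 1.0)
  expect_identical(unique(p$per_rep), 1.0)

  # corrupting a channel the model does use degrades the RMSE
  p2 <- pfi(est, f, y, channel = 2, n_reps = 20, seed = 3)
  expect_gt(p2$pfi, 1.0)

  expect_error(pfi(est, f, y, channel = "nope"))
})

test_that("PFI matches the closed form for a linear toy model", {
  # toy estimator: prediction = w * channel k; under standard-normal
  # replacement the expected squared error adds w^2 * (Var[x_k] + 1)
  toy <- structure(list(trained = TRUE, standardizer_fingerprint = NULL),
                   class = c("toy_linear", "grf_estimator"))
  w <- 0.8; k <- 2
  registerS3method("predict", "toy_linear",
                   function(object, features, ...) {
                     w * features[, , k]
                   },
                   envir = asNamespace("stats"))
  n <- 40; T_len <- 50
  f <- make_features(n, T_len = T_len, C = 3, seed = 13)
  sigma_e <- 0.3
  y <- with_seed(14, w * f[, , k] + matrix(rnorm(n * T_len, 0, sigma_e),
                                           n, T_len))
  p <- pfi(toy, f, y, channel = k, n_reps = 1000, seed = 15)
  x_var <- mean(f[, , k]^2)   # approximately 1 by construction
  expected <- mean(sqrt((x_var + 1) * w^2 + sigma_e^2) /
                     sqrt(mean((w * f[, , k] - y)^2)))
  expect_equal(p$pfi, expected, tolerance = 0.02)
})

test_that("CoP error profile matches a group-by oracle", {
  contacts <- fixture_contacts()
  with_seed(16, {
    errs <- rnorm(length(contacts))
    prof <- cop_error_profile(contacts, errs, n_bins = 5)
    # independent group-by computation
    touchdown <- vapply(contacts, function(ct) {
      i <- which(rowSums(ct$pressure) > 0)[1]
      ct$cop_y[i] / ct$insole_length
    }, 0)
    bins <- cut(touchdown, seq(0, 1, by = 0.2), include.lowest = TRUE,
                labels = FALSE)
    for (b in unique(bins)) {
      row <- prof[prof$bin == b, ]
      expect_equal(row$n, sum(bins == b))
      expect_equal(row$mean, mean(errs[bins == b]))
      expect_equal(row$sd, sd(errs[bins == b]))
    }
    # occupied bins only
    expect_setequal(prof$bin, unique(bins))
  })
  expect_error(cop_error_profile(contacts, rnorm(length(contacts)),
                                 n_bins = 1))

  # constructed monotone relationship shows up in the bin means
  fake_err <- vapply(contacts, function(ct) {
    i <- which(rowSums(ct$pressure) > 0)[1]
    ct$cop_y[i] / ct$insole_length
  }, 0) * 10
  prof2 <- cop_error_profile(contacts, fake_err, n_bins = 4)
  if (nrow(prof2) > 1) expect_true(all(diff(prof2$mean) > 0))
})

test_that("LOSO folds are structurally sound on a 3-participant cohort", {
  contacts <- fixture_cohort_contacts()
  cfg <- tiny_config(n_epochs = 1, batch_size = 16, lstm_hidden = 4,
                     linear2_size = 4, linear3_size = 4)
  rep <- run_loso(contacts, cfg)
  ids <- unique(vapply(contacts, `[[`, "", "participant_id"))
  expect_equal(nrow(rep$per_participant), 3)
  expect_setequal(rep$per_participant$participant_id, ids)
  # every contact was evaluated exactly once, as validation only
  expect_equal(nrow(rep$per_contact), length(contacts))
  expect_true(all(c("rrmse", "rmse_bw", "pearson_r") %in%
                    names(rep$grand)))
  expect_equal(length(rep$failed), 0)

  # duplicated participant id with conflicting anthropometrics: rejected
  bad <- contacts
  bad[[1]]$participant_id <- bad[[length(bad)]]$participant_id
  expect_error(run_loso(bad, cfg), "duplicated")
  expect_error(run_loso(contacts[1:10], cfg), "at least 3")
})
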