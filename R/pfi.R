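#' Permutation feature importance of one input channel
#'
#' Replaces the channel's values across every contact and timestep with
#' i.i.d. standard-normal draws (the inputs are z-scored, so this destroys
#' the channel's information while preserving its marginal scale),
#' recomputes the prediction RMSE, and reports the ratio
#' `permuted RMSE / original RMSE`. Values near 1 mean the model does not
#' rely on the channel; larger values mean it does. The replacement is
#' repeated `n_reps` times to average out the randomness of the
#' substitute sequences; both the mean (headline) and median of the
#' per-repetition ratios are reported.
#'
#' @param estimator a trained `grf_estimator`.
#' @param features standardized `grf_features`.
#' @param targets aligned `n x T` target matrix.
#' @param channel channel name (see [feature_channels()]) or index.
#' @param n_reps repetitions (default 100).
#' @param seed integer seed for the replacement draws.
#' @return object of class `grf_pfi`: list with `channel`, `pfi` (mean
#'   ratio), `pfi_median`, `n_reps`, `per_rep` (the ratio per repetition)
#'   and `original_rmse`.
#' @export
pfi <- function(estimator, features, targets, channel, n_reps = 100,
                seed = 1L) {
  check_standardized(features, estimator)
  channels <- attr(features, "channel_names")
  if (is.character(channel)) {
    ch <- match(channel, channels)
    if (is.na(ch)) stop("unknown channel name: ", channel)
  } else {
    ch <- as.integer(channel)
    stopifnot(ch >= 1, ch <= length(channels))
  }
  stopifnot(estimator$trained, n_reps >= 1)
  rmse <- function(pred) sqrt(mean((pred - targets)^2))
  original <- rmse(predict(estimator, features))
  n <- dim(features)[1]; T_len <- dim(features)[2]
  per_rep <- with_seed(seed, {
    vapply(seq_len(n_reps), function(rep) {
      perturbed <- features
      perturbed[, , ch] <- rnorm(n * T_len)
      rmse(predict(estimator, perturbed)) / original
    }, 0)
  })
  structure(list(channel = channels[ch], pfi = mean(per_rep),
                 pfi_median = median(per_rep), n_reps = n_reps,
                 per_rep = per_rep, original_rmse = original),
            class = "grf_pfi")
}

#' @export
print.grf_pfi <- function(x, ...) {
  cat(sprintf("<pfi> %s: mean %.4f / median %.4f over %d reps\n",
              x$channel, x$pfi, x$pfi_median, x$n_reps))
  invisible(x)
}

#' PFI across all channels
#'
#' @inheritParams pfi
#' @param channels channel names to evaluate (default: all 26).
#' @return data.frame `channel`, `pfi`, `pfi_median`.
#' @export
pfi_table <- function(estimator, features, targets,
                      channels = attr(features, "channel_names"),
                      n_reps = 100, seed = 1L) {
  res <- lapply(seq_along(channels), function(i) {
    p <- pfi(estimator, features, targets, channels[i], n_reps = n_reps,
             seed = seed + i)
    data.frame(channel = p$channel, pfi = p$pfi,
               pfi_median = p$pfi_median)
  })
  do.call(rbind, res)
}
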