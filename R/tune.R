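#' Hyperparameter search space
#'
#' The tuned dimensions and their ranges: learning rate log-uniform in
#' \[1e-5, 1e-1\]; epochs 1-15; batch size, LSTM hidden size and the two
#' linear-layer sizes from {8..128} / {32..512} option sets; both dropout
#' rates uniform in \[0.1, 0.5\]; four candidate activations. Any element
#' can be overridden — including collapsing it to a single value — which
#' is how desk-scale searches shrink the model sizes.
#'
#' @param ... named overrides; continuous dimensions are length-2
#'   `c(lower, upper)` ranges, discrete ones vectors of options.
#' @return named list describing the search space.
#' @export
default_search_space <- function(...) {
  space <- list(
    learning_rate = c(1e-5, 1e-1),        # log-uniform range
    n_epochs = c(1L, 15L),                # integer range
    batch_size = c(8L, 16L, 32L, 64L, 128L),
    lstm_hidden = c(32L, 64L, 128L, 256L, 512L),
    input_dropout = c(0.1, 0.5),
    linear_dropout = c(0.1, 0.5),
    linear2_size = c(32L, 64L, 128L, 256L, 512L),
    linear3_size = c(32L, 64L, 128L, 256L, 512L),
    activation = c("relu", "leaky_relu", "tanh", "sigmoid")
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(space))
  if (length(bad)) stop("unknown search dimensions: ",
                        paste(bad, collapse = ", "))
  modifyList(space, overrides)
}

sample_search_config <- function(space, target, seed) {
  pick <- function(x) if (length(x) == 1) x else sample(x, 1)
  model_config(
    learning_rate = if (length(space$learning_rate) == 2 &&
                          is.numeric(space$learning_rate) &&
                          space$learning_rate[1] < space$learning_rate[2]) {
      exp(runif(1, log(space$learning_rate[1]),
                log(space$learning_rate[2])))
    } else pick(space$learning_rate),
    n_epochs = if (length(space$n_epochs) == 2) {
      sample(space$n_epochs[1]:space$n_epochs[2], 1)
    } else pick(space$n_epochs),
    batch_size = pick(space$batch_size),
    lstm_hidden = pick(space$lstm_hidden),
    input_dropout = if (length(space$input_dropout) == 2) {
      runif(1, space$input_dropout[1], space$input_dropout[2])
    } else pick(space$input_dropout),
    linear_dropout = if (length(space$linear_dropout) == 2) {
      runif(1, space$linear_dropout[1], space$linear_dropout[2])
    } else pick(space$linear_dropout),
    linear2_size = pick(space$linear2_size),
    linear3_size = pick(space$linear3_size),
    activation = pick(space$activation),
    target = target,
    seed = seed
  )
}

#' Grouped k-fold objective for one configuration
#'
#' Splits participants into `k` subject-disjoint groups and evaluates the
#' configuration by the mean validation RMSE across the k group-folds,
#' with per-fold leak-free standardization.
#'
#' @param contacts list of `grf_contact`.
#' @param config a [model_config()].
#' @param k number of participant groups.
#' @param group_seed seed controlling the participant grouping.
#' @return list with `objective` (mean validation RMSE) and `fold_rmse`.
#' @export
evaluate_config <- function(contacts, config, k = 5, group_seed = 1L) {
  ids <- vapply(contacts, `[[`, "", "participant_id")
  participants <- unique(ids)
  if (length(participants) < k) stop("need at least k participants")
  groups <- with_seed(group_seed, {
    split(sample(participants),
          rep_len(seq_len(k), length(participants)))
  })
  fold_rmse <- vapply(seq_len(k), function(fold) {
    val_ids <- groups[[fold]]
    fit <- fit_fold(contacts, which(!ids %in% val_ids),
                    which(ids %in% val_ids), config)
    sqrt(mean((fit$predicted - fit$measured)^2))
  }, 0)
  list(objective = mean(fold_rmse), fold_rmse = fold_rmse)
}

#' Random hyperparameter search with grouped cross-validation
#'
#' Draws `n_trials` configurations from the search space and scores each
#' with [evaluate_config()] (mean validation RMSE over `k`
#' subject-disjoint folds). Random search is used as the search strategy;
#' the trial log allows auditing that the returned configuration is the
#' argmin of the sampled objectives.
#'
#' @param contacts list of `grf_contact` for the tuning subset.
#' @param target `"grf_v"` or `"grf_ap"`.
#' @param space a [default_search_space()] (possibly collapsed).
#' @param n_trials number of sampled configurations (>= 1).
#' @param k participant groups per evaluation.
#' @param seed master seed: controls the trial draws and the grouping.
#' @return list with `best_config`, `best_objective` and `log`
#'   (data.frame of every trial's hyperparameters and objective).
#' @export
tune_hyperparameters <- function(contacts, target = c("grf_v", "grf_ap"),
                                 space = default_search_space(),
                                 n_trials = 25, k = 5, seed = 1L) {
  target <- match.arg(target)
  stopifnot(n_trials >= 1)
  if (!length(space)) stop("empty search space")
  trial_seeds <- with_seed(seed, sample.int(2^30, n_trials))
  trials <- list()
  for (i in seq_len(n_trials)) {
    cfg <- with_seed(trial_seeds[i],
                     sample_search_config(space, target,
                                          seed = trial_seeds[i]))
    ev <- evaluate_config(contacts, cfg, k = k, group_seed = seed)
    trials[[i]] <- data.frame(
      trial = i, objective = ev$objective,
      learning_rate = cfg$learning_rate, n_epochs = cfg$n_epochs,
      batch_size = cfg$batch_size, lstm_hidden = cfg$lstm_hidden,
      input_dropout = cfg$input_dropout,
      linear_dropout = cfg$linear_dropout,
      linear2_size = cfg$linear2_size, linear3_size = cfg$linear3_size,
      activation = cfg$activation, seed = cfg$seed
    )
  }
  log <- do.call(rbind, trials)
  best_row <- which.min(log$objective)
  best_cfg <- with_seed(trial_seeds[best_row],
                        sample_search_config(space, target,
                                             seed = trial_seeds[best_row]))
  list(best_config = best_cfg, best_objective = log$objective[best_row],
       log = log)
}
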