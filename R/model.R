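#' Hyperparameter configuration of the GRF estimator
#'
#' Defaults are the tuned selections for the vertical-force model at full
#' scale (learning rate 5e-4, batch size 8, hidden size 512, dropout
#' 0.2/0.2, linear layers 64/32, ReLU). Reduced hidden and linear sizes are
#' recommended for desk-scale experiments. The anteroposterior selection
#' (learning rate 2e-5, 8 epochs, dropout 0.5/0.4, linear layers 512/512,
#' leaky ReLU) is available via `target = "grf_ap"` presets in
#' [default_search_space()]-driven tuning rather than hard-coded here.
#'
#' @param learning_rate Adam step size (> 0).
#' @param n_epochs training epochs (>= 1).
#' @param batch_size mini-batch size.
#' @param lstm_hidden LSTM hidden size per direction.
#' @param input_dropout dropout rate on the input matrix, in \[0, 1).
#' @param linear_dropout dropout rate after the first two linear
#'   activations, in \[0, 1).
#' @param linear2_size,linear3_size output widths of linear layers 1 and 2
#'   (the layer named by its position in the three-layer head).
#' @param activation one of `"relu"`, `"leaky_relu"`, `"tanh"`,
#'   `"sigmoid"`.
#' @param target `"grf_v"` or `"grf_ap"`.
#' @param seed integer controlling weight initialization, batch shuffling
#'   and dropout masks.
#' @return list of class `grf_model_config`.
#' @export
model_config <- function(learning_rate = 5e-4, n_epochs = 1,
                         batch_size = 8, lstm_hidden = 512,
                         input_dropout = 0.2, linear_dropout = 0.2,
                         linear2_size = 64, linear3_size = 32,
                         activation = c("relu", "leaky_relu", "tanh",
                                        "sigmoid"),
                         target = c("grf_v", "grf_ap"), seed = 1L) {
  activation <- match.arg(activation)
  target <- match.arg(target)
  stopifnot(learning_rate >= 0, n_epochs >= 1, batch_size >= 1,
            lstm_hidden >= 1, linear2_size >= 1, linear3_size >= 1,
            input_dropout >= 0, input_dropout < 1,
            linear_dropout >= 0, linear_dropout < 1)
  structure(list(learning_rate = learning_rate,
                 n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size),
                 lstm_hidden = as.integer(lstm_hidden),
                 input_dropout = input_dropout,
                 linear_dropout = linear_dropout,
                 linear2_size = as.integer(linear2_size),
                 linear3_size = as.integer(linear3_size),
                 activation = activation, target = target,
                 seed = as.integer(seed)),
            class = "grf_model_config")
}

activation_code <- function(activation) {
  match(activation, c("relu", "leaky_relu", "tanh", "sigmoid")) - 1L
}

#' Build an untrained bi-LSTM sequence regressor
#'
#' Architecture: input dropout, a bi-directional LSTM (hidden size `H` per
#' direction; the concatenated per-timestep state has size `2H`), then
#' three linear layers `2H -> linear2_size -> linear3_size -> 1` with the
#' configured activation and dropout after the first two, applied at every
#' timestep. Weights are initialized uniform in `+/- 1/sqrt(fan)` (LSTM:
#' `fan = H`; linear: the layer input width), seeded by `config$seed`.
#'
#' @param config a [model_config()].
#' @param n_channels input channel count (default 26, see
#'   [feature_channels()]).
#' @return object of class `grf_estimator` (untrained).
#' @export
build_model <- function(config, n_channels = length(feature_channels())) {
  stopifnot(inherits(config, "grf_model_config"))
  H <- config$lstm_hidden
  L2 <- config$linear2_size
  L3 <- config$linear3_size
  C <- n_channels
  params <- with_seed(config$seed, {
    u <- function(nr, nc, fan) {
      k <- 1 / sqrt(fan)
      matrix(runif(nr * nc, -k, k), nr, nc)
    }
    uv <- function(n, fan) {
      matrix(runif(n, -1 / sqrt(fan), 1 / sqrt(fan)), n, 1)
    }
    list(Wf = u(4 * H, C, H), Uf = u(4 * H, H, H), bf = uv(4 * H, H),
         Wb = u(4 * H, C, H), Ub = u(4 * H, H, H), bb = uv(4 * H, H),
         W1 = u(L2, 2 * H, 2 * H), b1 = uv(L2, 2 * H),
         W2 = u(L3, L2, L2), b2 = uv(L3, L2),
         W3 = u(1, L3, L3), b3 = uv(1, L3))
  })
  structure(list(params = params, config = config, n_channels = C,
                 trained = FALSE, loss_history = numeric(0),
                 standardizer_fingerprint = NULL),
            class = "grf_estimator")
}

#' Number of trainable parameters of an estimator
#' @param estimator a `grf_estimator`.
#' @return integer parameter count.
#' @export
n_parameters <- function(estimator) {
  sum(vapply(estimator$params, length, 0L))
}

#' @export
print.grf_estimator <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<grf_estimator> target=%s biLSTM(H=%d) -> %d -> %d -> 1 [%s], %s, %d parameters\n",
    cfg$target, cfg$lstm_hidden, cfg$linear2_size, cfg$linear3_size,
    cfg$activation, if (x$trained) "trained" else "untrained",
    n_parameters(x)))
  invisible(x)
}

# features [n x T x C] -> cube layout (n, C, T) expected by the C++ core
features_to_cube <- function(features, rows = NULL) {
  x <- if (is.null(rows)) unclass(features) else
    unclass(features)[rows, , , drop = FALSE]
  aperm(x, c(1, 3, 2))
}

check_standardized <- function(features, estimator = NULL) {
  if (!isTRUE(attr(features, "standardized"))) {
    stop("features must be standardized (see fit_standardizer/",
         "apply_standardizer)")
  }
  if (!is.null(estimator) && !is.null(estimator$standardizer_fingerprint)) {
    fp <- attr(features, "standardizer_fingerprint")
    if (!is.null(fp) && !identical(fp, estimator$standardizer_fingerprint)) {
      warning("features were standardized with different statistics than ",
              "the estimator was trained with")
    }
  }
  invisible(TRUE)
}

#' Train the estimator with Adam on a batch-RMSE objective
#'
#' Mini-batch gradient descent: the contact order is reshuffled every epoch
#' and for each batch the loss `sqrt(mean((pred - target)^2))` over all
#' timesteps jointly is backpropagated through the three linear layers and
#' both LSTM directions. Inverted-dropout masks are redrawn per batch.
#' Training is deterministic given `config$seed`. Targets are expected in
#' bodyweight units (see [build_targets()]); any row-aligned numeric matrix
#' works.
#'
#' @param estimator a [build_model()] result (or a config, from which a
#'   model is built).
#' @param features standardized `grf_features` array.
#' @param targets `n x T` matrix aligned row-wise with `features`.
#' @param verbose print per-epoch mean loss.
#' @return the trained `grf_estimator` with `$loss_history` (one mean loss
#'   per epoch) and per-batch history in `$batch_losses`.
#' @export
train_estimator <- function(estimator, features, targets, verbose = FALSE) {
  if (inherits(estimator, "grf_model_config")) {
    estimator <- build_model(estimator, n_channels = dim(features)[3])
  }
  stopifnot(inherits(estimator, "grf_estimator"))
  check_standardized(features)
  n <- dim(features)[1]
  T_len <- dim(features)[2]
  C <- dim(features)[3]
  stopifnot(nrow(targets) == n, ncol(targets) == T_len,
            C == estimator$n_channels)
  cfg <- estimator$config
  act <- activation_code(cfg$activation)
  params <- estimator$params
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  epoch_loss <- numeric(cfg$n_epochs)
  batch_losses <- list()

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$n_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
        B <- length(idx)
        X <- features_to_cube(features, idx)
        y <- targets[idx, , drop = FALSE]
        in_mask <- if (cfg$input_dropout > 0) {
          array((runif(B * C * T_len) >= cfg$input_dropout) /
                  (1 - cfg$input_dropout), dim = c(B, C, T_len))
        } else {
          array(1, dim = c(B, C, T_len))
        }
        mk <- function(ncol_) {
          if (cfg$linear_dropout > 0) {
            matrix((runif(B * T_len * ncol_) >= cfg$linear_dropout) /
                     (1 - cfg$linear_dropout), B * T_len, ncol_)
          } else {
            matrix(1, B * T_len, ncol_)
          }
        }
        res <- cpp_bilstm_grad(X, y, params, act, in_mask,
                               mk(cfg$linear2_size), mk(cfg$linear3_size))
        if (!is.finite(res$loss)) {
          stop("non-finite training loss at epoch ", epoch, ", batch ", bi,
               "; lower the learning rate")
        }
        losses[bi] <- res$loss
        step <- step + 1L
        for (nm in names(params)) {
          g <- res$grads[[nm]]
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
          m_hat <- adam_m[[nm]] / (1 - beta1^step)
          v_hat <- adam_v[[nm]] / (1 - beta2^step)
          params[[nm]] <- params[[nm]] -
            cfg$learning_rate * m_hat / (sqrt(v_hat) + eps)
        }
      }
      epoch_loss[epoch] <- mean(losses)
      batch_losses[[epoch]] <- losses
      if (verbose) {
        message(sprintf("epoch %d/%d: mean batch RMSE %.5f", epoch,
                        cfg$n_epochs, epoch_loss[epoch]))
      }
    }
  })
  estimator$params <- params
  estimator$trained <- TRUE
  estimator$loss_history <- epoch_loss
  estimator$batch_losses <- batch_losses
  estimator$standardizer_fingerprint <-
    attr(features, "standardizer_fingerprint")
  estimator
}

#' Predict force traces for standardized features
#'
#' Dropout is disabled at inference, so repeated calls are bit-identical.
#'
#' @param object a trained `grf_estimator`.
#' @param features standardized `grf_features` array (must carry the
#'   `standardized` flag; a mismatching standardizer fingerprint warns).
#' @param batch_size inference batch size (memory knob only).
#' @param ... unused.
#' @return `n x T` matrix of predicted force traces (in the units the
#'   targets were trained in, bodyweights by default).
#' @export
predict.grf_estimator <- function(object, features, batch_size = 256, ...) {
  check_standardized(features, object)
  n <- dim(features)[1]
  T_len <- dim(features)[2]
  act <- activation_code(object$config$activation)
  out <- matrix(NA_real_, n, T_len)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- cpp_bilstm_predict(features_to_cube(features, idx),
                                     object$params, act)
  }
  out
}
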