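#' Leave-one-subject-out evaluation
#'
#' For each participant: a standardizer and an estimator are fitted on all
#' other participants' contacts, the held-out participant's contacts are
#' standardized with the training statistics (leak-free) and predicted,
#' and per-contact metrics are aggregated. A failed fold is recorded and
#' the remaining folds continue.
#'
#' @param contacts list of `grf_contact` objects for the whole cohort
#'   (>= 3 participants).
#' @param config a [model_config()]; `config$target` selects the force
#'   component. Per-fold training seeds are derived from `config$seed` so
#'   the whole evaluation is deterministic.
#' @param verbose print per-fold progress.
#' @return object of class `grf_loso_report`: list with
#'   `per_contact` (metrics + ids), `per_participant` (mean and SD of each
#'   metric), `grand` (means of the per-participant means), `failed`
#'   (named list of fold errors) and `config`.
#' @export
run_loso <- function(contacts, config, verbose = FALSE) {
  stopifnot(inherits(config, "grf_model_config"))
  ids <- vapply(contacts, `[[`, "", "participant_id")
  participants <- unique(ids)
  if (length(participants) < 3) stop("LOSO needs at least 3 participants")
  check_unique_profiles(contacts, ids)
  target <- config$target

  per_contact <- list()
  failed <- list()
  for (fold in seq_along(participants)) {
    pid <- participants[fold]
    res <- tryCatch({
      train_idx <- which(ids != pid)
      val_idx <- which(ids == pid)
      fold_cfg <- config
      fold_cfg$seed <- config$seed + fold
      fit <- fit_fold(contacts, train_idx, val_idx, fold_cfg)
      metrics <- do.call(rbind, lapply(seq_along(val_idx), function(i) {
        ct <- contacts[[val_idx[i]]]
        cbind(data.frame(participant_id = pid,
                         condition_id = ct$condition_id,
                         contact = ct$contact),
              contact_metrics(fit$measured[i, ], fit$predicted[i, ],
                              mass = ct$mass, component = target))
      }))
      if (verbose) {
        message(sprintf("fold %d/%d (%s): rRMSE %.2f%%", fold,
                        length(participants), pid, mean(metrics$rrmse)))
      }
      metrics
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[pid]] <- conditionMessage(res)
      if (verbose) message("fold ", pid, " failed: ", failed[[pid]])
    } else {
      per_contact[[pid]] <- res
    }
  }
  per_contact <- do.call(rbind, per_contact)
  rownames(per_contact) <- NULL
  metric_cols <- setdiff(names(per_contact),
                         c("participant_id", "condition_id", "contact"))
  per_participant <- do.call(rbind, lapply(
    split(per_contact, per_contact$participant_id), function(df) {
      means <- vapply(df[metric_cols], mean, 0)
      sds <- vapply(df[metric_cols], sd, 0)
      out <- data.frame(participant_id = df$participant_id[1],
                        n_contacts = nrow(df))
      for (mc in metric_cols) {
        out[[paste0(mc, "_mean")]] <- means[[mc]]
        out[[paste0(mc, "_sd")]] <- sds[[mc]]
      }
      out
    }))
  rownames(per_participant) <- NULL
  grand <- vapply(metric_cols, function(mc) {
    mean(per_participant[[paste0(mc, "_mean")]])
  }, 0)
  structure(list(per_contact = per_contact,
                 per_participant = per_participant,
                 grand = as.list(grand), failed = failed, config = config),
            class = "grf_loso_report")
}

# one train/validate split: leak-free standardization, training, prediction
fit_fold <- function(contacts, train_idx, val_idx, config) {
  f_train <- build_features(contacts[train_idx])
  f_val <- build_features(contacts[val_idx])
  s <- suppressWarnings(fit_standardizer(f_train))
  z_train <- apply_standardizer(s, f_train)
  z_val <- apply_standardizer(s, f_val)
  y_train <- build_targets(contacts[train_idx], config$target)
  y_val <- build_targets(contacts[val_idx], config$target)
  est <- train_estimator(config, z_train, y_train)
  list(estimator = est, standardizer = s,
       predicted = predict(est, z_val), measured = y_val)
}

check_unique_profiles <- function(contacts, ids) {
  key <- vapply(contacts, function(ct) {
    sprintf("%.6f|%.6f", ct$mass, ct$insole_length)
  }, "")
  tab <- unique(data.frame(id = ids, key = key))
  if (anyDuplicated(tab$id)) {
    stop("duplicated participant id with conflicting profiles")
  }
  invisible(TRUE)
}

#' @export
print.grf_loso_report <- function(x, ...) {
  cat("<grf_loso_report>", x$config$target, "-",
      nrow(x$per_participant), "participants,",
      nrow(x$per_contact), "contacts\n")
  cat(sprintf("  grand-mean rRMSE %.2f%% | RMSE %.4f BW | r %.4f\n",
              x$grand$rrmse, x$grand$rmse_bw, x$grand$pearson_r))
  if (length(x$failed)) {
    cat("  failed folds:", paste(names(x$failed), collapse = ", "), "\n")
  }
  invisible(x)
}
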