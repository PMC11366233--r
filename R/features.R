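#' Canonical channel order of the model input matrix
#'
#' Channels 1-16 are the FSR pressure sensors (heel row first), 17-18 the
#' centre-of-pressure coordinates, 19-21 the accelerometer axes
#' (x = mediolateral, y = anteroposterior, z = vertical), and 22-26 the
#' five discrete descriptors broadcast along the time axis.
#'
#' @return character vector of the 26 channel names, in order.
#' @export
feature_channels <- function() {
  c(sprintf("fsr%02d", 1:16), "cop_x", "cop_y",
    "accel_x", "accel_y", "accel_z",
    "gct", "mass", "speed", "gradient", "insole_length")
}

#' Assemble the per-contact feature matrix
#'
#' Stacks processed foot contacts into the `[n_contacts x 400 x 26]` array
#' consumed by the sequence regressor, with the fixed channel order of
#' [feature_channels()]. Discrete scalars (ground contact time, mass,
#' speed, gradient, insole length) are duplicated across the 400 time
#' samples. Row order preserves the input order.
#'
#' @param contacts non-empty list of `grf_contact` objects (see
#'   [segment_contacts()]), all with the same normalized length.
#' @return object of class `grf_features`: a 3-D array with attributes
#'   `channel_names`, `contact_index` (data.frame `participant_id`,
#'   `condition_id`, `contact`) and `standardized = FALSE`.
#' @export
build_features <- function(contacts) {
  if (!length(contacts)) stop("contacts list is empty")
  L <- length(contacts[[1]]$force_v)
  channels <- feature_channels()
  n <- length(contacts)
  values <- array(NA_real_, dim = c(n, L, length(channels)),
                  dimnames = list(NULL, NULL, channels))
  for (i in seq_len(n)) {
    ct <- contacts[[i]]
    if (length(ct$cop_x) != L || nrow(ct$pressure) != L ||
        nrow(ct$accel) != L) {
      stop("contact ", i, " has traces of the wrong length (expected ",
           L, ")")
    }
    values[i, , 1:16] <- ct$pressure
    values[i, , 17] <- ct$cop_x
    values[i, , 18] <- ct$cop_y
    values[i, , 19:21] <- ct$accel
    values[i, , 22] <- ct$gct
    values[i, , 23] <- ct$mass
    values[i, , 24] <- ct$speed
    values[i, , 25] <- ct$gradient
    values[i, , 26] <- ct$insole_length
  }
  structure(values,
            channel_names = channels,
            contact_index = data.frame(
              participant_id = vapply(contacts, `[[`, "", "participant_id"),
              condition_id = vapply(contacts, `[[`, "", "condition_id"),
              contact = vapply(contacts, `[[`, 0, "contact")
            ),
            standardized = FALSE,
            class = "grf_features")
}

#' Target force matrix aligned with a feature matrix
#'
#' @param contacts the same list given to [build_features()].
#' @param target `"grf_v"` or `"grf_ap"`.
#' @param units `"bw"` (force divided by mass * g; default, the scale the
#'   estimator trains in) or `"n"`.
#' @return `n x 400` numeric matrix.
#' @export
build_targets <- function(contacts, target = c("grf_v", "grf_ap"),
                          units = c("bw", "n")) {
  target <- match.arg(target)
  units <- match.arg(units)
  field <- if (target == "grf_v") "force_v" else "force_ap"
  mat <- t(vapply(contacts, function(ct) {
    f <- ct[[field]]
    if (units == "bw") f / (ct$mass * GRAVITY) else f
  }, numeric(length(contacts[[1]][[field]]))))
  mat
}

#' Fit a per-channel z-score standardizer
#'
#' Channel statistics are pooled over contacts and time samples jointly.
#' A zero-variance channel (e.g., a gradient that never changes in a
#' training subset) gets its SD replaced by 1 with a warning, so it maps
#' to all zeros rather than NaN.
#'
#' @param train an unstandardized `grf_features` array with >= 2 contacts.
#' @return object of class `grf_standardizer`: list with `mean`, `sd`
#'   (length-26 named vectors) and `fitted_on` (a fingerprint of the
#'   training array).
#' @export
fit_standardizer <- function(train) {
  stopifnot(inherits(train, "grf_features"), dim(train)[1] >= 2)
  if (isTRUE(attr(train, "standardized"))) {
    stop("refusing to fit a standardizer on already-standardized data")
  }
  channels <- attr(train, "channel_names")
  m <- apply(train, 3, mean)
  s <- apply(train, 3, sd)
  degenerate <- s == 0
  if (any(degenerate)) {
    warning("zero-variance channel(s) ",
            paste(channels[degenerate], collapse = ", "),
            ": SD replaced by 1")
    s[degenerate] <- 1
  }
  names(m) <- names(s) <- channels
  structure(list(mean = m, sd = s,
                 fitted_on = feature_fingerprint(train)),
            class = "grf_standardizer")
}

#' Apply (or invert) a fitted standardizer
#'
#' Transforms every channel with the *training* statistics only, the
#' leak-free protocol for validation data. Applying a standardizer to an
#' already-standardized array is an error (it would double-standardize).
#'
#' @param s a [fit_standardizer()] result.
#' @param data a `grf_features` array with matching channels.
#' @return the standardized array, with `standardized = TRUE`.
#' @export
apply_standardizer <- function(s, data) {
  stopifnot(inherits(s, "grf_standardizer"), inherits(data, "grf_features"))
  if (isTRUE(attr(data, "standardized"))) {
    stop("data is already standardized")
  }
  channels <- attr(data, "channel_names")
  stopifnot(identical(channels, names(s$mean)))
  out <- data
  for (ch in seq_along(channels)) {
    out[, , ch] <- (data[, , ch] - s$mean[ch]) / s$sd[ch]
  }
  attr(out, "standardized") <- TRUE
  attr(out, "standardizer_fingerprint") <- standardizer_fingerprint(s)
  out
}

#' @rdname apply_standardizer
#' @export
invert_standardizer <- function(s, data) {
  stopifnot(inherits(s, "grf_standardizer"), inherits(data, "grf_features"))
  if (!isTRUE(attr(data, "standardized"))) {
    stop("data is not standardized")
  }
  channels <- attr(data, "channel_names")
  out <- data
  for (ch in seq_along(channels)) {
    out[, , ch] <- data[, , ch] * s$sd[ch] + s$mean[ch]
  }
  attr(out, "standardized") <- FALSE
  out
}

feature_fingerprint <- function(x) {
  v <- as.numeric(x)
  sprintf("n%d-sum%.6e-ss%.6e", dim(x)[1], sum(v), sum(v * v))
}

standardizer_fingerprint <- function(s) {
  sprintf("m%.6e-s%.6e", sum(s$mean), sum(s$sd))
}

#' Subset a feature matrix by contact rows
#'
#' Keeps attributes (channel names, contact index, standardized flag)
#' consistent under row subsetting.
#'
#' @param features a `grf_features` array.
#' @param rows integer or logical row index.
#' @return the subset `grf_features` array.
#' @export
subset_features <- function(features, rows) {
  out <- features[rows, , , drop = FALSE]
  attributes(out)$dimnames <- dimnames(features)
  attr(out, "channel_names") <- attr(features, "channel_names")
  attr(out, "contact_index") <-
    attr(features, "contact_index")[rows, , drop = FALSE]
  attr(out, "standardized") <- attr(features, "standardized")
  class(out) <- "grf_features"
  out
}

#' @export
print.grf_features <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<grf_features> [%d x %d x %d]%s\n", d[1], d[2], d[3],
              if (isTRUE(attr(x, "standardized"))) " (standardized)" else ""))
  invisible(x)
}
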