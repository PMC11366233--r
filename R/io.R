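#' Write a raw session to disk
#'
#' One columnar file per device stream (`force`, `pressure`, `imu`:
#' timestamp + channels), a `metadata.json` (participant, condition,
#' device offsets, generator parameters, sensor geometry) and a
#' `truth_contacts` table. `format = "csv"` writes plain CSV;
#' `format = "parquet"` writes the columnar binary dialect via the arrow
#' package.
#'
#' @param session a `grf_session`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"parquet"`.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (format == "parquet" && !requireNamespace("arrow", quietly = TRUE)) {
    stop("the arrow package is required for parquet output")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (format == "csv") {
      write.csv(df, file.path(dir, paste0(name, ".csv")),
                row.names = FALSE)
    } else {
      arrow::write_parquet(df, file.path(dir, paste0(name, ".parquet")))
    }
  }
  wr(session$force, "force")
  wr(session$pressure, "pressure")
  wr(session$imu, "imu")
  wr(session$truth$contacts, "truth_contacts")
  meta <- list(
    profile = as.list(session$profile),
    condition = session$condition,
    device_offsets = as.list(session$device_offsets),
    geometry = list(
      sensor_coords = unname(apply(session$geometry$sensor_coords, 1,
                                   as.list)),
      insole_length = session$geometry$insole_length
    ),
    config = unclass(session$config),
    format = format
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' Restores the device streams and metadata; the waveform-level ground
#' truth (clean traces, centroid paths) is not serialized, so round-tripped
#' sessions carry `truth$contacts` only.
#'
#' @param dir directory written by [write_session()].
#' @return a `grf_session` (without waveform truth).
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  format <- meta$format %||% "csv"
  rd <- function(name) {
    if (format == "csv") {
      read.csv(file.path(dir, paste0(name, ".csv")), check.names = FALSE)
    } else {
      as.data.frame(arrow::read_parquet(file.path(dir,
                                                  paste0(name,
                                                         ".parquet"))))
    }
  }
  raw_coords <- meta$geometry$sensor_coords
  coords <- if (is.data.frame(raw_coords)) {
    cbind(x = raw_coords$x, y = raw_coords$y)
  } else {
    do.call(rbind, lapply(raw_coords, function(p) c(x = p$x, y = p$y)))
  }
  rownames(coords) <- sprintf("fsr%02d", seq_len(nrow(coords)))
  geometry <- structure(list(sensor_coords = coords,
                             insole_length = meta$geometry$insole_length),
                        class = "grf_insole_geometry")
  cfg_fields <- names(synth_config())
  config <- do.call(synth_config,
                    meta$config[intersect(names(meta$config), cfg_fields)])
  structure(list(
    force = rd("force"),
    pressure = rd("pressure"),
    imu = rd("imu"),
    device_offsets = unlist(meta$device_offsets),
    profile = as.data.frame(meta$profile, stringsAsFactors = FALSE),
    condition = meta$condition,
    geometry = geometry,
    config = config,
    truth = list(contacts = rd("truth_contacts"))
  ), class = "grf_session")
}

#' Serialize a feature matrix
#'
#' Long-format values file (contact, sample, channel, value) plus a JSON
#' sidecar holding the channel order, contact index, and standardized
#' flag, so channel names and positions survive round trips.
#'
#' @param features a `grf_features` array.
#' @param path output stem; writes `<path>.csv` (or `.parquet`) and
#'   `<path>.json`.
#' @param format `"csv"` or `"parquet"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  d <- dim(features)
  channels <- attr(features, "channel_names")
  df <- data.frame(
    contact = rep(seq_len(d[1]), times = d[2] * d[3]),
    sample = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    channel = rep(channels, each = d[1] * d[2]),
    value = as.numeric(features)
  )
  if (format == "csv") {
    write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the arrow package is required for parquet output")
    }
    arrow::write_parquet(df, paste0(path, ".parquet"))
  }
  sidecar <- list(
    channel_names = channels,
    dim = d,
    standardized = isTRUE(attr(features, "standardized")),
    contact_index = attr(features, "contact_index"),
    format = format
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path the stem given to [write_features()].
#' @return the restored `grf_features` array.
#' @export
read_features <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  d <- sidecar$dim
  df <- if (sidecar$format == "csv") {
    read.csv(paste0(path, ".csv"))
  } else {
    as.data.frame(arrow::read_parquet(paste0(path, ".parquet")))
  }
  # restore positional order regardless of on-disk row order
  channel_pos <- match(df$channel, sidecar$channel_names)
  ord <- order(channel_pos, df$sample, df$contact)
  values <- array(df$value[ord], dim = d,
                  dimnames = list(NULL, NULL, sidecar$channel_names))
  structure(values,
            channel_names = sidecar$channel_names,
            contact_index = as.data.frame(sidecar$contact_index),
            standardized = sidecar$standardized,
            class = "grf_features")
}
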