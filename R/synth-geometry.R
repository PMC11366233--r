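#' Sensor layout of the synthetic 16-channel pressure insole
#'
#' A 4 x 4 grid in the insole-local frame: y runs anteroposteriorly from 0 at
#' the heel to `insole_length` at the toe, x mediolaterally with 0 at the
#' midline. Rows span 5-95 percent of the insole length; columns sit at
#' +/- 25 and +/- 8.3 mm. Channel k (1..16) is row-major from the heel:
#' channels 1-4 are the heel row, 13-16 the toe row.
#'
#' @param insole_length insole length in mm.
#' @param n_rows,n_cols grid dimensions (defaults 4 x 4; product is the
#'   channel count).
#' @param x_half_width_mm lateral half-width of the grid in mm.
#' @return list of class `grf_insole_geometry` with `sensor_coords` (an
#'   n x 2 matrix of x, y in mm) and `insole_length`.
#' @export
#' @examples
#' geom <- insole_geometry(265)
#' geom$sensor_coords
insole_geometry <- function(insole_length, n_rows = 4, n_cols = 4,
                            x_half_width_mm = 25) {
  stopifnot(insole_length > 0, n_rows >= 1, n_cols >= 1,
            n_rows * n_cols >= 2)
  ys <- seq(0.05, 0.95, length.out = n_rows) * insole_length
  xs <- seq(-x_half_width_mm, x_half_width_mm, length.out = n_cols)
  coords <- cbind(
    x = rep(xs, times = n_rows),
    y = rep(ys, each = n_cols)
  )
  rownames(coords) <- sprintf("fsr%02d", seq_len(nrow(coords)))
  if (anyDuplicated(coords)) stop("sensor coordinates must be distinct")
  structure(list(sensor_coords = coords, insole_length = insole_length),
            class = "grf_insole_geometry")
}

validate_geometry <- function(geometry) {
  stopifnot(inherits(geometry, "grf_insole_geometry") ||
              (is.list(geometry) && !is.null(geometry$sensor_coords)))
  coords <- geometry$sensor_coords
  if (nrow(coords) < 2) stop("geometry must have at least 2 sensors")
  if (any(coords[, 2] < 0 | coords[, 2] > geometry$insole_length)) {
    stop("sensor y coordinates must lie within [0, insole_length]")
  }
  invisible(geometry)
}
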