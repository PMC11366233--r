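#' Centre of pressure from one 16-channel pressure sample
#'
#' Pressure-weighted average of the sensor coordinates:
#' `cop = sum(w_i * coord_i) / sum(w_i)` with the raw channel values as
#' weights. A sample with zero total pressure has no defined CoP; within a
#' contact [cop_trace()] carries the previous valid CoP forward, and if no
#' valid sample has occurred yet it uses the geometric centroid of the
#' sensor layout.
#'
#' @param pressure_sample non-negative vector, one value per sensor.
#' @param geometry an [insole_geometry()] with matching sensor count.
#' @return named numeric `c(x, y)` in mm, `NA` if total pressure is zero.
#' @export
#' @examples
#' geom <- insole_geometry(260)
#' p <- numeric(16); p[7] <- 3
#' compute_cop(p, geom)  # returns sensor 7's coordinates
compute_cop <- function(pressure_sample, geometry) {
  validate_geometry(geometry)
  coords <- geometry$sensor_coords
  if (length(pressure_sample) != nrow(coords)) {
    stop("pressure sample length must match the sensor count")
  }
  if (any(pressure_sample < 0)) stop("negative pressure values")
  s <- sum(pressure_sample)
  if (s == 0) return(c(x = NA_real_, y = NA_real_))
  c(x = sum(pressure_sample * coords[, 1]) / s,
    y = sum(pressure_sample * coords[, 2]) / s)
}

#' Centre-of-pressure trace over a contact
#'
#' Applies [compute_cop()] per sample with the zero-pressure fallback:
#' carry the last valid CoP forward; before any valid sample, use the
#' geometric centroid of the sensors.
#'
#' @param pressure n x sensors matrix of non-negative values.
#' @param geometry an [insole_geometry()].
#' @return data.frame `x`, `y` (mm) with n rows.
#' @export
cop_trace <- function(pressure, geometry) {
  validate_geometry(geometry)
  coords <- geometry$sensor_coords
  if (any(pressure < 0)) stop("negative pressure values")
  s <- rowSums(pressure)
  x <- (pressure %*% coords[, 1]) / s
  y <- (pressure %*% coords[, 2]) / s
  fallback_x <- mean(coords[, 1])
  fallback_y <- mean(coords[, 2])
  for (i in seq_along(s)) {
    if (s[i] == 0) {
      if (i == 1) {
        x[i] <- fallback_x; y[i] <- fallback_y
      } else {
        x[i] <- x[i - 1]; y[i] <- y[i - 1]
      }
    }
  }
  data.frame(x = as.numeric(x), y = as.numeric(y))
}
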