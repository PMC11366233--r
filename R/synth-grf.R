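#' Synthetic ground reaction force waveforms for one stance phase
#'
#' Forward model generating vertical and anteroposterior GRF traces at the
#' force-plate sampling rate. The vertical trace is the sum of an active
#' component — a half-period raised sine warped so its peak falls at
#' `config$active_peak_frac` of stance, with amplitude increasing with
#' running speed — and an impact transient centred at 15 percent of stance
#' whose amplitude scales with `1 - footstrike` (an extreme forefoot striker
#' produces none). The anteroposterior trace is braking-then-propulsion
#' (`-sin(2*pi*t)`), with incline shifting the balance toward propulsion
#' (uphill) or braking (downhill). Both clean curves are zero at touchdown
#' and toe off; optional Gaussian noise is added on top.
#'
#' Consumes the current RNG stream; seed management belongs to the caller.
#'
#' @param profile one row of a [generate_cohort()] data.frame (or an
#'   equivalent list with `mass`, `easy_speed`, `footstrike`).
#' @param condition list or row with `speed` (km/h) and `gradient` (%).
#' @param contact_duration stance duration in seconds, within \[0.1, 0.4\].
#' @param config a [synth_config()] list.
#' @param noise logical; add stance noise of SD `config$noise_sd_bw` BW.
#' @return list with `grf_v`, `grf_ap` (N, possibly noisy), `clean_v`,
#'   `clean_ap` (noise-free), `t_frac` (stance fraction per sample) and
#'   `fs`.
#' @export
#' @examples
#' prof <- generate_cohort(1, seed = 2)[1, ]
#' g <- generate_grf(prof, list(speed = prof$easy_speed, gradient = 0), 0.25,
#'                   noise = FALSE)
#' max(g$grf_v) / (prof$mass * 9.81)
generate_grf <- function(profile, condition, contact_duration,
                         config = synth_config(), noise = TRUE) {
  if (!is.numeric(contact_duration) || contact_duration <= 0) {
    stop("contact_duration must be positive")
  }
  if (contact_duration < 0.1 || contact_duration > 0.4) {
    stop("contact_duration must lie in [0.1, 0.4] s")
  }
  fs <- config$force_fs
  n <- max(round(contact_duration * fs), 3L)
  t_frac <- seq(0, 1, length.out = n)
  bw <- profile$mass * GRAVITY

  # active peak: sin(pi * u) with u = t^k so the maximum sits at
  # active_peak_frac instead of mid-stance
  k <- log(0.5) / log(config$active_peak_frac)
  amp_bw <- config$peak_bw +
    config$peak_speed_slope * (condition$speed - profile$easy_speed) +
    config$peak_grad_slope * condition$gradient
  active <- amp_bw * sin(pi * t_frac^k)

  # impact transient: sin^2 bump over the first impact_width of stance,
  # peaking at half the width; amplitude fades with the footstrike latent
  w <- config$impact_width
  impact_amp <- config$impact_bw * (1 - profile$footstrike)
  impact <- ifelse(t_frac < w, impact_amp * sin(pi * t_frac / w)^2, 0)

  clean_v <- pmax(active + impact, 0) * bw

  ap_amp <- config$ap_amp_bw +
    config$ap_speed_slope * (condition$speed - profile$easy_speed)
  clean_ap <- bw * (-ap_amp * sin(2 * pi * t_frac) +
                      config$ap_grad_gain * condition$gradient *
                        sin(pi * t_frac))

  grf_v <- clean_v
  grf_ap <- clean_ap
  if (noise && config$noise_sd_bw > 0) {
    grf_v <- grf_v + rnorm(n, 0, config$noise_sd_bw * bw)
    grf_ap <- grf_ap + rnorm(n, 0, config$noise_sd_bw * bw)
  }
  list(grf_v = grf_v, grf_ap = grf_ap,
       clean_v = clean_v, clean_ap = clean_ap,
       t_frac = t_frac, fs = fs)
}
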