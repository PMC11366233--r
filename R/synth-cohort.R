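#' Generate a synthetic cohort of runners
#'
#' Draws participant profiles from the truncated-normal distributions in
#' `config`. The footstrike latent is drawn as a tercile mixture: a category
#' (rear/mid/fore) is sampled with `config$footstrike_probs` and the latent is
#' then uniform within that tercile of \[0, 1\], so the expected tercile
#' occupancies equal the configured proportions exactly.
#'
#' @param n_participants number of profiles to generate (>= 1).
#' @param seed integer seed; the cohort is a pure function of
#'   `(n_participants, seed, config)`.
#' @param config a [synth_config()] list.
#' @return a data.frame of class `grf_cohort` with one row per participant:
#'   `participant_id`, `mass` (kg), `easy_speed` (km/h), `insole_length`
#'   (mm), `footstrike` (latent in \[0,1\], 0 = extreme rearfoot),
#'   `stride_cv`, `rng_seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(5, seed = 1)
#' cohort$mass
generate_cohort <- function(n_participants, seed, config = synth_config()) {
  stopifnot(is.numeric(n_participants), n_participants >= 1)
  n <- as.integer(n_participants)
  validate_synth_config(config)
  with_seed(seed, {
    probs <- config$footstrike_probs / sum(config$footstrike_probs)
    tercile <- sample.int(3L, n, replace = TRUE, prob = probs)
    footstrike <- (tercile - 1L) / 3 + runif(n) / 3
    cohort <- data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      mass = rtruncnorm(n, config$mass_mean, config$mass_sd,
                        config$mass_range[1], config$mass_range[2]),
      easy_speed = rtruncnorm(n, config$speed_mean, config$speed_sd,
                              config$speed_range[1], config$speed_range[2]),
      insole_length = rtruncnorm(n, config$insole_mean, config$insole_sd,
                                 config$insole_range[1],
                                 config$insole_range[2]),
      footstrike = footstrike,
      stride_cv = rtruncnorm(n, config$stride_cv_mean, config$stride_cv_sd,
                             config$stride_cv_range[1],
                             config$stride_cv_range[2]),
      rng_seed = sample.int(.Machine$integer.max %/% 2L, n),
      stringsAsFactors = FALSE
    )
    class(cohort) <- c("grf_cohort", "data.frame")
    cohort
  })
}

#' Footstrike label from the latent scalar
#'
#' Terciles of the latent map to the conventional rear/mid/forefoot labels.
#' @param footstrike latent values in \[0, 1\].
#' @return factor with levels rear, mid, fore.
#' @export
footstrike_label <- function(footstrike) {
  stopifnot(all(footstrike >= 0 & footstrike <= 1))
  cut(footstrike, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
      labels = c("rear", "mid", "fore"))
}
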