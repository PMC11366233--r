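#' Segment synchronized contacts into time-normalized FootContact objects
#'
#' For each physical contact present on all three devices: the force
#' components are cut at the force-plate events and zero-phase filtered at
#' `force_cutoff`; the stance-only 50 Hz pressure log is upsampled back to
#' the native rate with a quadratic interpolator (no further filtering) and
#' converted to a centre-of-pressure trace; the accelerometer axes are cut
#' at the IMU events and filtered at `imu_cutoff`. Everything is then
#' time-normalized to `L` samples. Ground contact time is recorded in
#' seconds before normalization. Contacts whose pressure log is too short
#' to interpolate are dropped with a message.
#'
#' @param session a `grf_session` (or any list exposing `force`,
#'   `pressure`, `imu`, `geometry`, `profile`, `condition`).
#' @param events list with elements `force` (a [contact_events()]),
#'   `pressure` (a [pressure_events()] result) and `imu`
#'   (a [contact_events()]).
#' @param map synchronized per-device contact index table from
#'   [synchronize_session()].
#' @param force_cutoff,imu_cutoff per-contact filter cutoffs, Hz.
#' @param L normalized trace length.
#' @return list of `grf_contact` objects; each has 400-sample `force_v`,
#'   `force_ap`, `cop_x`, `cop_y`, an `L x sensors` `pressure` matrix, an
#'   `L x 3` `accel` matrix, and scalars `gct`, `mass`, `speed`,
#'   `gradient`, `insole_length`, `participant_id`, `condition_id`,
#'   `contact`.
#' @export
segment_contacts <- function(session, events, map, force_cutoff = 15,
                             imu_cutoff = 10, L = 400) {
  force_fs <- attr(events$force, "fs")
  imu_fs <- attr(events$imu, "fs")
  geometry <- session$geometry
  out <- list()
  for (row in seq_len(nrow(map))) {
    jf <- map$force[row]; jp <- map$pressure[row]; ji <- map$imu[row]

    # force: half-open [ic, to) on the force-plate clock
    i0 <- events$force$ic[jf] + 1L; i1 <- events$force$to[jf]
    fv <- session$force$fv[i0:i1]
    fap <- session$force$fap[i0:i1]
    gct <- (events$force$to[jf] - events$force$ic[jf]) / force_fs

    # pressure: quadratic upsampling of this contact's logged burst
    rows_p <- events$pressure$groups[[jp]]
    if (length(rows_p) < 2) {
      message("contact ", jf, " dropped: pressure log too short (",
              length(rows_p), " samples)")
      next
    }
    tp <- session$pressure$t[rows_p]
    pm <- as.matrix(session$pressure[rows_p, -1, drop = FALSE])
    up <- upsample_quadratic(tp, pm, target_fs = force_fs)
    press <- pmax(up$y, 0)    # spline overshoot must not break CoP weights
    cop <- cop_trace(press, geometry)

    # accelerometer: [ic, to) on the IMU clock
    a0 <- events$imu$ic[ji] + 1L; a1 <- events$imu$to[ji]
    acc <- vapply(c("ax", "ay", "az"), function(ch) {
      butterworth_lowpass(session$imu[[ch]][a0:a1], imu_fs, imu_cutoff)
    }, numeric(a1 - a0 + 1L))

    contact <- structure(list(
      force_v = time_normalize(butterworth_lowpass(fv, force_fs,
                                                   force_cutoff), L),
      force_ap = time_normalize(butterworth_lowpass(fap, force_fs,
                                                    force_cutoff), L),
      pressure = time_normalize(press, L),
      cop_x = time_normalize(cop$x, L),
      cop_y = time_normalize(cop$y, L),
      accel = time_normalize(acc, L),
      gct = gct,
      mass = session$profile$mass,
      speed = session$condition$speed,
      gradient = session$condition$gradient,
      insole_length = session$geometry$insole_length,
      participant_id = session$profile$participant_id,
      condition_id = session$condition$condition_id,
      contact = jf
    ), class = "grf_contact")
    out[[length(out) + 1L]] <- contact
  }
  out
}

#' Full preprocessing of one raw session
#'
#' Convenience driver running the whole per-session pipeline: zero-phase
#' filter the continuous force stream and detect contacts at the force
#' threshold, group the stance-only pressure log into contacts, detect
#' contacts on the accelerometer, synchronize the three devices by
#' stride-time correlation, and segment every synchronized contact.
#'
#' @param session a `grf_session`.
#' @param threshold force contact-detection threshold, N.
#' @param force_cutoff,imu_cutoff per-contact filter cutoffs, Hz.
#' @param L normalized trace length.
#' @param ... passed to [synchronize_session()].
#' @return list with `contacts` (list of `grf_contact`), `sync` (the
#'   [synchronize_session()] result) and `events`.
#' @export
#' @examples
#' \donttest{
#' prof <- generate_cohort(1, seed = 4)[1, ]
#' ses <- generate_session(prof, list(speed = 11, gradient = 0,
#'                                    duration = 25), seed = 9)
#' pp <- preprocess_session(ses)
#' length(pp$contacts)
#' }
preprocess_session <- function(session, threshold = 40, force_cutoff = 15,
                               imu_cutoff = 10, L = 400, ...) {
  force_fs <- session$config$force_fs %||% 1000
  imu_fs <- session$config$imu_fs %||% 1138
  fv_filt <- butterworth_lowpass(session$force$fv, force_fs, force_cutoff)
  ev_force <- detect_contacts(fv_filt, force_fs, threshold = threshold)
  ev_press <- pressure_events(session$pressure)
  ev_imu <- imu_events(session$imu, fs = imu_fs, cutoff = imu_cutoff)

  sync <- synchronize_session(ev_force, ev_press$times, ev_imu, ...)
  if (!sync$synchronized) {
    warning("session could not be synchronized (alignment rejected)")
    return(list(contacts = list(), sync = sync,
                events = list(force = ev_force, pressure = ev_press,
                              imu = ev_imu)))
  }
  events <- list(force = ev_force,
                 pressure = list(times = ev_press$times,
                                 groups = ev_press$groups),
                 imu = ev_imu)
  contacts <- segment_contacts(session, events, sync$map,
                               force_cutoff = force_cutoff,
                               imu_cutoff = imu_cutoff, L = L)
  list(contacts = contacts, sync = sync, events = events)
}

#' Rear/mid/forefoot label for a processed contact
#'
#' Derived reporting label: the anteroposterior CoP position at touchdown
#' (first sample with nonzero total pressure), normalized by insole length,
#' cut at the tercile boundaries used throughout the package.
#'
#' @param contact a `grf_contact`.
#' @return one of `"rear"`, `"mid"`, `"fore"`.
#' @export
contact_footstrike <- function(contact) {
  idx <- which(rowSums(contact$pressure) > 0)[1]
  if (is.na(idx)) return(NA_character_)
  frac <- contact$cop_y[idx] / contact$insole_length
  as.character(cut(frac, c(-Inf, 0.33, 0.55, Inf),
                   labels = c("rear", "mid", "fore")))
}
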