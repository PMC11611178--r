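#' Acquisition geometry and sampling constants
#'
#' Describes the A-mode acquisition: depth extent, spatial scale per depth
#' sample, frame (pulse-repetition) rate, RF sampling rate, transducer
#' center frequency and the assumed speed of sound in soft tissue. The
#' defaults describe a 1020-sample scanline at 24.65 um per depth sample,
#' 500 frames/s, RF sampled at 31.25 MHz with a 7.8 MHz carrier.
#'
#' Two consistency checks are enforced: the depth scale must equal
#' `sound_speed / (2 * rf_sampling)` (pulse-echo: the pulse travels the
#' depth twice) to within 0.1 um, and the normalized carrier frequency
#' `center_frequency / rf_sampling` must lie in (0, 0.5).
#'
#' @param depth_samples Number of depth samples per A-mode frame.
#' @param depth_scale Tissue depth per sample, micrometres.
#' @param frame_rate Frame (pulse repetition) rate, Hz.
#' @param rf_sampling RF sampling rate, Hz.
#' @param center_frequency Transducer center frequency, Hz.
#' @param sound_speed Assumed speed of sound, m/s.
#' @return An object of class `acq_spec`.
#' @examples
#' spec <- acquisition_spec()
#' spec$depth_scale
#' @export
acquisition_spec <- function(depth_samples = 1020L,
                             depth_scale = 24.65,
                             frame_rate = 500,
                             rf_sampling = 31.25e6,
                             center_frequency = 7.8e6,
                             sound_speed = 1540) {
  stopifnot(depth_samples >= 1, depth_scale > 0, frame_rate > 0,
            rf_sampling > 0, center_frequency > 0, sound_speed > 0)
  implied <- sound_speed / (2 * rf_sampling) * 1e6
  if (abs(implied - depth_scale) > 0.1) {
    stop("depth_scale (", depth_scale, " um) is inconsistent with ",
         "sound_speed / (2 * rf_sampling) = ", round(implied, 3), " um",
         call. = FALSE)
  }
  f0 <- center_frequency / rf_sampling
  if (f0 <= 0 || f0 >= 0.5) {
    stop("normalized carrier frequency center_frequency/rf_sampling = ",
         signif(f0, 4), " must lie in (0, 0.5)", call. = FALSE)
  }
  structure(list(depth_samples = as.integer(depth_samples),
                 depth_scale = depth_scale, frame_rate = frame_rate,
                 rf_sampling = rf_sampling,
                 center_frequency = center_frequency,
                 sound_speed = sound_speed),
            class = "acq_spec")
}

#' @export
print.acq_spec <- function(x, ...) {
  cat("A-mode acquisition spec\n")
  cat("  depth:", x$depth_samples, "samples x", x$depth_scale, "um/sample\n")
  cat("  frame rate:", x$frame_rate, "Hz; RF sampling:", x$rf_sampling / 1e6,
      "MHz; carrier:", x$center_frequency / 1e6, "MHz\n")
  invisible(x)
}

#' Synthetic carotid phantom subject configuration
#'
#' Parameterizes one simulated subject: mean diameter and the three
#' physiological modulations (cardiac pulsatile distension, paced-breathing
#' modulation, a slow hand-grip trend), the lumen position along depth, and
#' the acoustic texture (speckle, quiet-lumen scatter, static high-contrast
#' artifact bands, sensor noise).
#'
#' The diastolic floor must stay positive:
#' `mean_diameter - pulse_amplitude - resp_amplitude > 0`.
#'
#' @param mean_diameter Mean arterial diameter, mm.
#' @param pulse_amplitude Peak cardiac distension amplitude, mm.
#' @param heart_rate Heart rate, beats per minute.
#' @param resp_amplitude Respiratory diameter modulation amplitude, mm.
#' @param resp_rate Paced-breathing rate, cycles per minute.
#' @param trend_amplitude Peak of the slow hand-grip diameter trend, mm
#'   (0 disables the trend).
#' @param lumen_center_baseline Baseline lumen-center depth, samples
#'   (0-based).
#' @param n_sessions Number of repeated measurement sessions per subject.
#'   Each session re-draws the scatterer (speckle) realizations and shifts
#'   all structures by a common depth offset, emulating probe reattachment
#'   and repositioning between sessions; frames are split evenly.
#' @param session_shift_sigma Standard deviation of the common per-session
#'   depth offset, samples.
#' @param center_drift_sigma Standard deviation of the per-frame random-walk
#'   drift of the lumen center, samples.
#' @param wall_pulse_sigma Gaussian width of the wall echo pulse, samples.
#' @param artifact_bands List of static high-contrast artifact bands, each
#'   `c(depth = <samples>, amplitude = <relative, <= 0.8>)`.
#' @param speckle_sigma Tissue speckle reflectivity sd, relative amplitude.
#' @param lumen_echo_sigma Intraluminal scatter reflectivity sd (blood is
#'   nearly anechoic), relative amplitude.
#' @param noise_sigma Additive sensor noise sd, relative amplitude.
#' @param seed Integer seed; every random draw for this subject derives
#'   from it.
#' @return An object of class `phantom_config`.
#' @examples
#' cfg <- phantom_subject_config(seed = 11)
#' cfg$mean_diameter
#' @export
phantom_subject_config <- function(mean_diameter = 7.5,
                                   pulse_amplitude = 0.5,
                                   heart_rate = 60,
                                   resp_amplitude = 0.2,
                                   resp_rate = 7.5,
                                   trend_amplitude = 0,
                                   lumen_center_baseline = 500,
                                   n_sessions = 3L,
                                   session_shift_sigma = 15,
                                   center_drift_sigma = 0.02,
                                   wall_pulse_sigma = 4,
                                   artifact_bands = list(),
                                   speckle_sigma = 0.1,
                                   lumen_echo_sigma = 0.02,
                                   noise_sigma = 0.02,
                                   seed = 1L) {
  if (mean_diameter - pulse_amplitude - resp_amplitude <= 0) {
    stop("invalid phantom config: mean_diameter - pulse_amplitude - ",
         "resp_amplitude must be > 0 (got ",
         mean_diameter - pulse_amplitude - resp_amplitude, " mm)",
         call. = FALSE)
  }
  if (pulse_amplitude < 0) stop("invalid phantom config: pulse_amplitude must be >= 0", call. = FALSE)
  if (resp_amplitude < 0) stop("invalid phantom config: resp_amplitude must be >= 0", call. = FALSE)
  if (trend_amplitude < 0) stop("invalid phantom config: trend_amplitude must be >= 0", call. = FALSE)
  if (heart_rate <= 0 || resp_rate < 0) {
    stop("invalid phantom config: heart_rate must be > 0 and resp_rate >= 0", call. = FALSE)
  }
  for (band in artifact_bands) {
    if (!all(c("depth", "amplitude") %in% names(band))) {
      stop("invalid phantom config: each artifact band needs depth and amplitude", call. = FALSE)
    }
    if (band[["amplitude"]] > 0.8) {
      stop("invalid phantom config: artifact band amplitude must be <= 0.8", call. = FALSE)
    }
  }
  if (n_sessions < 1) stop("invalid phantom config: n_sessions must be >= 1", call. = FALSE)
  structure(list(mean_diameter = mean_diameter,
                 pulse_amplitude = pulse_amplitude, heart_rate = heart_rate,
                 resp_amplitude = resp_amplitude, resp_rate = resp_rate,
                 trend_amplitude = trend_amplitude,
                 lumen_center_baseline = lumen_center_baseline,
                 n_sessions = as.integer(n_sessions),
                 session_shift_sigma = session_shift_sigma,
                 center_drift_sigma = center_drift_sigma,
                 wall_pulse_sigma = wall_pulse_sigma,
                 artifact_bands = artifact_bands,
                 speckle_sigma = speckle_sigma,
                 lumen_echo_sigma = lumen_echo_sigma,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_config")
}
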