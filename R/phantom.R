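#' Ground-truth diameter waveform of a phantom subject
#'
#' Composes the simulated diameter series in millimetres:
#' `D(t) = D0 + A_p * pulse(cardiac phase) + A_r * sin(2 * pi * f_r * t)
#'  + trend(t)`.
#' The cardiac pulse shape is a raised-cosine upstroke over the first 15%
#' of the cycle followed by an exponential decay with time constant 25% of
#' the cycle, normalized to `[0, 1]` — this keeps a sharp systolic foot,
#' the waveform feature post-smoothing must preserve. The hand-grip trend
#' (when `trend_amplitude > 0`) ramps linearly to its peak at mid-record
#' and back to zero, emulating a grip-and-release intervention.
#'
#' @param subject A [phantom_subject_config()].
#' @param n_frames Number of frames to generate.
#' @param spec An [acquisition_spec()]; supplies the frame rate.
#' @return Numeric vector of length `n_frames`, diameter in mm. The series
#'   is a deterministic function of `(subject, n_frames, spec)`.
#' @examples
#' d <- diameter_waveform(phantom_subject_config(), 1000, acquisition_spec())
#' range(d)
#' @export
diameter_waveform <- function(subject, n_frames,
                              spec = acquisition_spec()) {
  stopifnot(inherits(subject, "phantom_config"), n_frames >= 1)
  t <- (seq_len(n_frames) - 1) / spec$frame_rate
  phase <- (t * subject$heart_rate / 60) %% 1
  pulse <- cardiac_pulse_shape(phase)
  f_r <- subject$resp_rate / 60
  d <- subject$mean_diameter +
    subject$pulse_amplitude * pulse +
    subject$resp_amplitude * sin(2 * pi * f_r * t) +
    subject$trend_amplitude * handgrip_trend(t, t[n_frames])
  if (min(d) <= 0) {
    stop("invalid phantom config: diameter waveform reaches ",
         round(min(d), 3), " mm; reduce pulse_amplitude/resp_amplitude ",
         "or raise mean_diameter", call. = FALSE)
  }
  d
}

# raised-cosine upstroke over the first 15% of the cycle, exponential decay
# (tau = 25% of cycle) afterwards; values in [0, 1]
cardiac_pulse_shape <- function(phase) {
  up <- 0.15
  tau <- 0.25
  ifelse(phase < up,
         0.5 * (1 - cos(pi * phase / up)),
         exp(-(phase - up) / tau))
}

# symmetric triangular ramp peaking at mid-record
handgrip_trend <- function(t, t_end) {
  if (t_end <= 0) return(rep(0, length(t)))
  x <- t / t_end
  1 - abs(2 * x - 1)
}

#' Render a synthetic A-mode/M-mode recording with exact ground truth
#'
#' Simulates the RF M-mode stack of one subject with a one-dimensional
#' scatterer model: a per-subject fixed tissue reflectivity train (speckle)
#' outside the vessel, a much weaker intraluminal scatter train inside
#' (blood is nearly anechoic), unit-amplitude wall reflectors at the
#' anterior/posterior wall positions, and static high-contrast artifact
#' bands. The reflectivity is convolved along depth with a Gabor pulse
#' (Gaussian envelope `wall_pulse_sigma` samples wide, carrier at the
#' normalized center frequency), and white sensor noise is added. Wall
#' positions are real-valued; their reflectors are deposited with linear
#' interpolation between neighbouring depth samples. The recording is split
#' into `n_sessions` segments emulating the repeated measurement sessions
#' of the acquisition protocol: each session re-draws the scatterer
#' realizations and shifts all structures by a common random depth offset
#' (probe reattachment/repositioning), which is the texture variability a
#' depth-invariant detector must cope with.
#'
#' @inheritParams diameter_waveform
#' @return A list with components `record` (class `mmode_record`: `samples`
#'   is a `depth_samples x n_frames` RF matrix, plus `spec` and `kind`) and
#'   `annotation` (class `gt_annotation`: a tibble with per-frame `anterior`,
#'   `posterior`, `center`, `diameter`, all in 0-based depth samples).
#' @examples
#' r <- render_recording(phantom_subject_config(seed = 3), 50)
#' dim(r$record$samples)
#' @export
render_recording <- function(subject, n_frames,
                             spec = acquisition_spec()) {
  stopifnot(inherits(subject, "phantom_config"), n_frames >= 1)
  n_depth <- spec$depth_samples
  d_mm <- diameter_waveform(subject, n_frames, spec)
  d_samp <- mm_to_samples(d_mm, spec$depth_scale)

  with_local_seed(subject$seed, {
    ns <- subject$n_sessions
    session_len <- rep(n_frames %/% ns, ns)
    if (n_frames %% ns > 0) {
      session_len[ns] <- session_len[ns] + n_frames %% ns
    }
    session_len <- session_len[session_len > 0]
    shifts <- if (length(session_len) > 1) {
      rnorm(length(session_len), 0, subject$session_shift_sigma)
    } else numeric(length(session_len))

    g <- gabor_kernel(subject$wall_pulse_sigma,
                      spec$center_frequency / spec$rf_sampling)
    pad <- ceiling(3 * subject$wall_pulse_sigma)

    rf <- matrix(0, n_depth, n_frames)
    anterior <- posterior <- numeric(n_frames)
    off <- 0L
    for (s in seq_along(session_len)) {
      nf <- session_len[s]
      idx <- off + seq_len(nf)
      # probe repositioning: fresh scatterer realizations, common depth shift
      center <- subject$lumen_center_baseline + shifts[s] +
        cumsum(rnorm(nf, 0, subject$center_drift_sigma))
      ant <- center - d_samp[idx] / 2
      post <- center + d_samp[idx] / 2
      if (min(ant) < pad || max(post) > n_depth - 1 - pad) {
        stop("invalid phantom config: wall excursion [",
             round(min(ant), 1), ", ", round(max(post), 1),
             "] leaves the usable depth range [", pad, ", ",
             n_depth - 1 - pad, "]", call. = FALSE)
      }
      tissue <- rnorm(n_depth, 0, subject$speckle_sigma)
      lumen <- rnorm(n_depth, 0, subject$lumen_echo_sigma)
      for (band in subject$artifact_bands) {
        # off-artery structures move more than the artery itself when the
        # probe is repositioned (a different tissue cross-section): each
        # session adds an independent offset on top of the common shift
        extra <- if (length(session_len) > 1) {
          rnorm(1, 0, subject$session_shift_sigma)
        } else 0
        i <- as.integer(round(band[["depth"]] + shifts[s] + extra)) + 1L
        if (i >= 1 && i <= n_depth) {
          tissue[i] <- tissue[i] + band[["amplitude"]]
        }
      }
      refl <- matrix(tissue, n_depth, nf)
      for (j in seq_len(nf)) {
        lo <- ceiling(ant[j]) + 1L    # first sample strictly inside lumen
        hi <- floor(post[j]) + 1L
        if (hi >= lo) refl[lo:hi, j] <- lumen[lo:hi]
        refl[, j] <- deposit_impulse(refl[, j], ant[j], 1)
        refl[, j] <- deposit_impulse(refl[, j], post[j], 1)
      }
      block <- cpp_conv1d_same(refl, g)
      if (subject$noise_sigma > 0) {
        block <- block + matrix(rnorm(n_depth * nf, 0, subject$noise_sigma),
                                n_depth, nf)
      }
      rf[, idx] <- block
      anterior[idx] <- ant
      posterior[idx] <- post
      off <- off + nf
    }

    annotation <- tibble::tibble(frame = seq_len(n_frames),
                                 anterior = anterior, posterior = posterior,
                                 center = (anterior + posterior) / 2,
                                 diameter = posterior - anterior)
    class(annotation) <- c("gt_annotation", class(annotation))
    list(record = new_mmode_record(rf, spec, "rf"), annotation = annotation)
  })
}

new_mmode_record <- function(samples, spec, kind = c("rf", "envelope")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(samples), all(is.finite(samples)))
  structure(list(samples = samples, spec = spec, kind = kind),
            class = "mmode_record")
}

#' @export
print.mmode_record <- function(x, ...) {
  cat("M-mode record (", x$kind, "): ", nrow(x$samples), " depth samples x ",
      ncol(x$samples), " frames @ ", x$spec$frame_rate, " Hz\n", sep = "")
  invisible(x)
}

# add `amp` at real-valued 0-based position, split between neighbours
deposit_impulse <- function(x, pos, amp) {
  i0 <- floor(pos)
  frac <- pos - i0
  x[i0 + 1L] <- x[i0 + 1L] + amp * (1 - frac)
  if (frac > 0 && i0 + 2L <= length(x)) x[i0 + 2L] <- x[i0 + 2L] + amp * frac
  x
}

# Gabor pulse: Gaussian envelope, cosine carrier at f0 cycles/sample
gabor_kernel <- function(sigma, f0) {
  half <- ceiling(4 * sigma)
  n <- (-half):half
  exp(-n^2 / (2 * sigma^2)) * cos(2 * pi * f0 * n)
}

# mm <-> depth samples
mm_to_samples <- function(x, depth_scale = 24.65) x * 1000 / depth_scale

#' Generate a reproducible multi-subject phantom cohort
#'
#' Draws one [phantom_subject_config()] per subject (lumen-center baseline
#' uniform in `[350, 650]` samples, 2-4 static artifact bands placed outside
#' the lumen excursion range, per-subject sub-seed) and renders each
#' subject's recording with exact ground truth. All draws derive
#' deterministically from `master_seed`.
#'
#' @param n_subjects Number of subjects (at least 2; leave-one-subject-out
#'   evaluation needs a non-trivial split).
#' @param frames_per_subject Frames to render per subject.
#' @param master_seed Integer master seed.
#' @param spec An [acquisition_spec()].
#' @param config_fn Optional function `(seed, baseline, artifact_bands) ->
#'   phantom_config` to customize per-subject configs; the default uses
#'   [phantom_subject_config()] defaults.
#' @return An object of class `phantom_cohort`: list with `subjects` (each
#'   `rf`, `annotation`, `config`), `spec`, `master_seed`.
#' @examples
#' cohort <- make_cohort(2, 50, master_seed = 7)
#' length(cohort$subjects)
#' @export
make_cohort <- function(n_subjects, frames_per_subject, master_seed,
                        spec = acquisition_spec(), config_fn = NULL) {
  if (n_subjects < 2) {
    stop("n_subjects must be >= 2: leave-one-subject-out evaluation ",
         "requires at least two subjects", call. = FALSE)
  }
  stopifnot(frames_per_subject >= 1)
  draws <- with_local_seed(master_seed, {
    lapply(seq_len(n_subjects), function(k) {
      baseline <- runif(1, 350, 650)
      n_bands <- sample(2:4, 1)
      bands <- lapply(seq_len(n_bands), function(b) {
        lo_side <- runif(1) < 0.5
        depth <- if (lo_side && baseline - 220 > 40) {
          runif(1, 40, baseline - 220)
        } else {
          runif(1, min(baseline + 220, spec$depth_samples - 40),
                spec$depth_samples - 40)
        }
        c(depth = depth, amplitude = runif(1, 0.3, 0.8))
      })
      list(seed = sample.int(.Machine$integer.max, 1),
           baseline = baseline, bands = bands)
    })
  })
  subjects <- lapply(seq_len(n_subjects), function(k) {
    d <- draws[[k]]
    cfg <- if (is.null(config_fn)) {
      phantom_subject_config(lumen_center_baseline = d$baseline,
                             artifact_bands = d$bands, seed = d$seed)
    } else {
      config_fn(d$seed, d$baseline, d$bands)
    }
    r <- render_recording(cfg, frames_per_subject, spec)
    list(rf = r$record, annotation = r$annotation, config = cfg)
  })
  names(subjects) <- paste0("subject_", seq_len(n_subjects))
  structure(list(subjects = subjects, spec = spec,
                 master_seed = as.integer(master_seed)),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  n <- length(x$subjects)
  fr <- ncol(x$subjects[[1]]$rf$samples)
  cat("Phantom cohort:", n, "subjects x", fr, "frames (master seed",
      x$master_seed, ")\n")
  invisible(x)
}
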