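#' Trace smoother configuration
#'
#' Post-smoothing removes the per-frame estimation noise of the
#' feed-forward tracker. The default is a Savitzky-Golay filter of
#' polynomial order 5 and window 31 samples (62 ms at 500 frames/s) —
#' short and high-order enough to preserve the sharp systolic foot of the
#' distension waveform. A plain moving average with the same window is
#' available as the comparator.
#'
#' @param kind `"savitzky_golay"` or `"moving_average"`.
#' @param window Odd window length, samples.
#' @param order Polynomial order (Savitzky-Golay only), strictly less
#'   than `window`.
#' @return An object of class `smoother_config`.
#' @export
smoother_config <- function(kind = c("savitzky_golay", "moving_average"),
                            window = 31L, order = 5L) {
  kind <- match.arg(kind)
  stopifnot(window %% 2 == 1, order < window, order >= 0)
  structure(list(kind = kind, window = as.integer(window),
                 order = as.integer(order)),
            class = "smoother_config")
}

#' Smooth a diameter trace
#'
#' Savitzky-Golay smoothing performs a local least-squares polynomial fit
#' in each window (exactly reproducing any polynomial up to its order);
#' edges are handled by evaluating polynomial fits over the first/last
#' window rather than padding the record with fabricated samples. The
#' moving-average comparator shrinks its window symmetrically at the
#' edges.
#'
#' @param trace A `diameter_trace` or numeric vector.
#' @param cfg A [smoother_config()].
#' @return Same type as the input, smoothed; for a `diameter_trace` the
#'   `smoothed` attribute is set.
#' @examples
#' smooth_trace(sin(1:100 / 5) + rnorm(100, 0, 0.1))[1:3]
#' @export
smooth_trace <- function(trace, cfg = smoother_config()) {
  is_trace <- inherits(trace, "diameter_trace")
  x <- if (is_trace) trace$diameter else trace
  n <- length(x)
  if (n < cfg$window) {
    stop("trace length ", n, " is shorter than the smoother window ",
         cfg$window, call. = FALSE)
  }
  y <- if (cfg$kind == "savitzky_golay") {
    as.numeric(signal::sgolayfilt(x, p = cfg$order, n = cfg$window))
  } else {
    moving_average_shrink(x, cfg$window)
  }
  if (is_trace) {
    trace$diameter <- y
    attr(trace, "smoothed") <- TRUE
    trace
  } else y
}

# centered moving average; window shrinks symmetrically near the edges
moving_average_shrink <- function(x, window) {
  n <- length(x)
  h <- (window - 1) %/% 2
  cs <- cumsum(c(0, x))
  hw <- pmin(h, seq_len(n) - 1, n - seq_len(n))
  lo <- seq_len(n) - hw
  hi <- seq_len(n) + hw
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Agreement and error metrics between a predicted and reference series
#'
#' Computes the full evaluation report: Pearson correlation `r`;
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot` (of the
#' prediction against the reference — not the square of `r`); Lin's
#' concordance correlation coefficient (CCC), which penalizes scale and
#' location shifts that Pearson ignores; MAE, MSE, RMSE; the absolute
#' deviation summarized both ways ("MAD" is used ambiguously in the
#' field): `mad_median = median(|pred - ref|)` and
#' `mad_mean = mean(|pred - ref|)`; the t statistic of the correlation
#' `r * sqrt((n - 2) / (1 - r^2))`; and the skewness and excess kurtosis
#' of the difference distribution (population moments).
#'
#' @param pred,ref Equal-length numeric vectors (`n >= 3`; `ref` must not
#'   be constant).
#' @return A one-row tibble of class `metrics_report`.
#' @examples
#' m <- compute_metrics(c(1, 2, 3, 4.1), c(1, 2, 3, 4))
#' m$pearson_r
#' @export
compute_metrics <- function(pred, ref) {
  if (length(pred) != length(ref)) {
    stop("pred and ref must have equal length", call. = FALSE)
  }
  n <- length(pred)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(ref) == 0) {
    stop("reference series is constant; correlation undefined", call. = FALSE)
  }
  e <- pred - ref
  r <- stats::cor(pred, ref)
  ss_res <- sum(e^2)
  ss_tot <- sum((ref - mean(ref))^2)
  # population (1/n) moments for CCC and the shape statistics
  mx <- mean(pred); my <- mean(ref)
  vx <- mean((pred - mx)^2); vy <- mean((ref - my)^2)
  sxy <- mean((pred - mx) * (ref - my))
  ccc <- 2 * sxy / (vx + vy + (mx - my)^2)
  m2 <- mean((e - mean(e))^2)
  skew <- if (m2 > 0) mean((e - mean(e))^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((e - mean(e))^4) / m2^2 - 3 else 0
  out <- tibble::tibble(
    pearson_r = r,
    r_squared = 1 - ss_res / ss_tot,
    ccc = ccc,
    mae = mean(abs(e)),
    mse = mean(e^2),
    rmse = sqrt(mean(e^2)),
    mad_median = stats::median(abs(e)),
    mad_mean = mean(abs(e)),
    t_value = r * sqrt((n - 2) / (1 - r^2)),
    skewness = skew,
    excess_kurtosis = kurt,
    n = n)
  class(out) <- c("metrics_report", class(out))
  out
}

#' Convert depth samples to millimetres
#'
#' @param x Value(s) in depth samples.
#' @param depth_scale Depth per sample in micrometres (default 24.65).
#' @return `x * depth_scale / 1000`, millimetres.
#' @examples
#' samples_to_mm(304.3018)  # ~7.5 mm
#' @export
samples_to_mm <- function(x, depth_scale = 24.65) {
  stopifnot(depth_scale > 0)
  x * depth_scale / 1000
}

#' Leave-one-subject-out evaluation of the full pipeline
#'
#' For each subject in turn: both networks are trained from scratch on all
#' other subjects' frames, the held-out subject's recording is streamed
#' through the trained pipeline, the predicted trace is smoothed, and the
#' agreement/error metrics against the subject's ground-truth diameter are
#' computed (plus the ROI stage's lumen-center MAE). The summary row is
#' the unweighted arithmetic mean over subjects; per-fold frame counts are
#' recorded so weighted summaries remain computable.
#'
#' @param cohort A `phantom_cohort` (or any list with the same structure).
#' @param roi_cfg,tracker_cfg,smoother Network and smoother
#'   configurations.
#' @param roi_epochs,tracker_epochs Training epochs per stage.
#' @param seed Master seed; per-fold training seeds derive from it.
#' @param verbose Print per-fold progress?
#' @param roi_args,tracker_args Named lists of further arguments for
#'   [train_roi()] and [train_tracker()] (e.g. `batch_size`, `lr`).
#' @return An object of class `loso_result`: `folds` (one metrics row per
#'   held-out subject, plus `lumen_mae` and bookkeeping columns),
#'   `summary` (unweighted mean row), `traces` (per-fold raw/smoothed
#'   predictions with the reference series, for temporal-alignment
#'   checks), `fits` (per-fold trained networks) and provenance (`seed`,
#'   configs).
#' @export
loso_evaluate <- function(cohort, roi_cfg = roi_config(),
                          tracker_cfg = tracker_config(),
                          smoother = smoother_config(),
                          roi_epochs = 10, tracker_epochs = 20,
                          seed = 1L, verbose = FALSE,
                          roi_args = list(), tracker_args = list()) {
  subjects <- cohort$subjects
  ns <- length(subjects)
  if (ns < 2) stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  len <- roi_cfg$input_length

  # envelopes and labels computed once
  envs <- lapply(subjects, function(s) {
    envelope_record(s$rf, decimation = roi_cfg$decimation,
                    normalize = TRUE)$samples
  })
  labels <- lapply(subjects, function(s) response_matrix(s$annotation, len))
  fold_seeds <- derive_seeds(seed, 2L * ns)

  folds <- vector("list", ns)
  fits <- vector("list", ns)
  traces <- vector("list", ns)
  for (k in seq_len(ns)) {
    train_ids <- setdiff(seq_len(ns), k)
    x_tr <- do.call(cbind, envs[train_ids])
    y_tr <- do.call(cbind, labels[train_ids])
    ann_tr <- dplyr::bind_rows(lapply(subjects[train_ids], `[[`, "annotation"))
    if (verbose) message("fold ", k, ": training on ", ncol(x_tr), " frames")

    roi_fit <- tryCatch(
      do.call(train_roi, c(list(x_tr, y_tr, roi_cfg, epochs = roi_epochs,
                                seed = fold_seeds[2 * k - 1]), roi_args)),
      error = function(e) stop("LOSO fold ", k, " failed in ROI training: ",
                               conditionMessage(e), call. = FALSE))
    trk_fit <- tryCatch(
      do.call(train_tracker, c(list(x_tr, ann_tr, tracker_cfg,
                                    epochs = tracker_epochs,
                                    seed = fold_seeds[2 * k]), tracker_args)),
      error = function(e) stop("LOSO fold ", k,
                               " failed in tracker training: ",
                               conditionMessage(e), call. = FALSE))

    env_te <- envs[[k]]
    ann_te <- subjects[[k]]$annotation
    trace <- predict_trace(env_te, roi_fit, trk_fit)
    attr(trace, "frame_rate") <- cohort$spec$frame_rate
    smoothed <- smooth_trace(trace, smoother)
    metrics <- compute_metrics(smoothed$diameter, ann_te$diameter)
    lumen_mae <- mean(abs(trace$roi_center - ann_te$center))
    folds[[k]] <- dplyr::bind_cols(
      tibble::tibble(subject = names(subjects)[k] %||% paste0("subject_", k),
                     n_train_frames = ncol(x_tr),
                     lumen_mae = lumen_mae,
                     mean_ref_diameter = mean(ann_te$diameter)),
      metrics)
    fits[[k]] <- list(roi = roi_fit, tracker = trk_fit)
    traces[[k]] <- tibble::tibble(frame = seq_len(nrow(trace)),
                                  raw = trace$diameter,
                                  smoothed = smoothed$diameter,
                                  reference = ann_te$diameter)
    if (verbose) {
      message(sprintf("fold %d: r=%.4f rmse=%.3f lumen MAE=%.2f", k,
                      metrics$pearson_r, metrics$rmse, lumen_mae))
    }
  }
  folds <- dplyr::bind_rows(folds)
  num_cols <- names(folds)[vapply(folds, is.numeric, logical(1))]
  summary <- folds |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num_cols), mean)) |>
    dplyr::mutate(subject = "mean", .before = 1)
  structure(list(folds = folds, summary = summary, seed = seed,
                 roi_config = roi_cfg, tracker_config = tracker_cfg,
                 smoother = smoother, fits = fits, traces = traces),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat("Leave-one-subject-out evaluation (", nrow(x$folds), " folds)\n",
      sep = "")
  print(x$folds[, c("subject", "pearson_r", "rmse", "mad_median",
                    "lumen_mae")])
  cat("mean r =", round(x$summary$pearson_r, 4), "; mean RMSE =",
      round(x$summary$rmse, 3), "samples\n")
  invisible(x)
}
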