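#' Tidy a metrics report into long form
#'
#' @param x A `metrics_report` from [compute_metrics()].
#' @param ... Unused.
#' @return Tibble with columns `metric` and `value`.
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(metric = names(x),
                 value = as.numeric(as.data.frame(x)[1, ]))
}

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "metrics_report")
  out
}

#' Tidy / summarize a leave-one-subject-out result
#'
#' `tidy()` returns the per-fold table; `glance()` the across-subject
#' unweighted mean row.
#'
#' @param x A `loso_result` from [loso_evaluate()].
#' @param ... Unused.
#' @export
tidy.loso_result <- function(x, ...) x$folds

#' @rdname tidy.loso_result
#' @export
glance.loso_result <- function(x, ...) x$summary

#' Training history of a fitted network
#'
#' `tidy()` returns the per-epoch loss history; `glance()` a one-row
#' summary (final losses, parameter count, seed).
#'
#' @param x An `roi_fit` or `tracker_fit`.
#' @param ... Unused.
#' @export
tidy.roi_fit <- function(x, ...) x$history

#' @rdname tidy.roi_fit
#' @export
tidy.tracker_fit <- function(x, ...) x$history

#' @rdname tidy.roi_fit
#' @export
glance.roi_fit <- function(x, ...) {
  tibble::tibble(n_parameters = n_parameters(x),
                 epochs = nrow(x$history),
                 final_train_loss = tail(x$history$train_loss, 1),
                 final_val_loss = tail(x$history$val_loss, 1),
                 seed = x$seed)
}

#' @rdname tidy.roi_fit
#' @export
glance.tracker_fit <- function(x, ...) glance.roi_fit(x, ...)

#' Plot a diameter trace
#'
#' @param object A `diameter_trace`.
#' @param reference Optional reference diameter series (samples) to
#'   overlay.
#' @param depth_scale Depth per sample, micrometres, for the mm axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diameter_trace <- function(object, reference = NULL,
                                    depth_scale = 24.65, ...) {
  fr <- attr(object, "frame_rate")
  t <- if (is.finite(fr %||% NA_real_)) (object$frame - 1) / fr
  else object$frame
  df <- tibble::tibble(t = t, mm = samples_to_mm(object$diameter,
                                                 depth_scale),
                       series = "predicted")
  if (!is.null(reference)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      t = t, mm = samples_to_mm(reference, depth_scale),
      series = "reference"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mm,
                                   colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = if (is.finite(fr %||% NA_real_)) "time (s)" else "frame",
                  y = "diameter (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an M-mode record as a depth-time image
#'
#' @param object An `mmode_record`.
#' @param max_frames Downsample the time axis to at most this many frames.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mmode_record <- function(object, max_frames = 1000, ...) {
  m <- object$samples
  if (object$kind == "rf") m <- abs(m)
  step <- max(1L, ceiling(ncol(m) / max_frames))
  cols <- seq(1, ncol(m), by = step)
  df <- expand.grid(depth = seq_len(nrow(m)) - 1, frame = cols)
  df$amplitude <- as.vector(m[, cols])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$depth,
                                   fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "frame", y = "depth (samples)",
                  fill = "|amplitude|") +
    ggplot2::theme_minimal()
}

#' Plot the training history of a fitted network
#'
#' @param object An `roi_fit` or `tracker_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @export
autoplot.roi_fit <- function(object, ...) plot_history(object$history)

#' @rdname autoplot.roi_fit
#' @export
autoplot.tracker_fit <- function(object, ...) plot_history(object$history)

plot_history <- function(history) {
  df <- tidyr_longer(history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

# minimal pivot of a history tibble (avoids a tidyr dependency)
tidyr_longer <- function(history) {
  dplyr::bind_rows(
    tibble::tibble(epoch = history$epoch, loss = history$train_loss,
                   split = "train"),
    tibble::tibble(epoch = history$epoch, loss = history$val_loss,
                   split = "validation"))
}

#' @importFrom rlang .data
NULL
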