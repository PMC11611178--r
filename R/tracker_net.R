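#' Diameter tracker configuration
#'
#' The second-stage regression network maps one fixed-width ROI window to a
#' single diameter estimate. Architecture: five same-width, zero-padded 1-D
#' convolutions whose channel counts rise and then fall (no pooling
#' anywhere — depth position information is what the diameter is read
#' from), batch normalization and a rectifier after each convolution, then
#' a flatten and three fully connected layers ending in one bounded output
#' unit. The unit-interval output is scaled by the window width to give
#' the diameter in depth samples.
#'
#' @param input_width ROI window width, samples (match the ROI config's
#'   `window_width`).
#' @param conv_channels Channel counts of the five convolution layers;
#'   must rise then fall.
#' @param conv_kernel Convolution kernel width, samples (odd).
#' @param fc_widths Widths of the three fully connected layers; the last
#'   must be 1.
#' @param dropout Dropout probability on the first two FC layers during
#'   training.
#' @param huber_delta Huber loss transition point, in depth samples.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(input_width = 401L,
                           conv_channels = c(8L, 16L, 32L, 16L, 8L),
                           conv_kernel = 9L,
                           fc_widths = c(300L, 64L, 1L),
                           dropout = 0.2, huber_delta = 1.0) {
  if (length(conv_channels) != 5) {
    stop("tracker architecture contract: exactly 5 convolution layers",
         call. = FALSE)
  }
  if (length(fc_widths) != 3 || fc_widths[3] != 1) {
    stop("tracker architecture contract: exactly 3 FC layers ending in 1 unit",
         call. = FALSE)
  }
  peak <- which.max(conv_channels)
  if (is.unsorted(conv_channels[1:peak]) ||
      is.unsorted(rev(conv_channels[peak:5]))) {
    stop("conv_channels must rise then fall (e.g. 8,16,32,16,8)",
         call. = FALSE)
  }
  stopifnot(conv_kernel %% 2 == 1, dropout >= 0, dropout < 1,
            huber_delta > 0)
  structure(list(input_width = as.integer(input_width),
                 conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel),
                 fc_widths = as.integer(fc_widths),
                 dropout = dropout, huber_delta = huber_delta),
            class = "tracker_config")
}

tracker_init_params <- function(config) {
  k <- config$conv_kernel
  ch <- c(1L, config$conv_channels)
  conv <- lapply(seq_len(5), function(l) {
    fan_in <- k * ch[l]
    list(W = matrix(rnorm(fan_in * ch[l + 1], sd = sqrt(2 / fan_in)),
                    fan_in, ch[l + 1]),
         b = numeric(ch[l + 1]),
         gamma = rep(1, ch[l + 1]),
         beta = numeric(ch[l + 1]))
  })
  flat <- config$input_width * ch[6]
  widths <- c(flat, config$fc_widths)
  fc <- lapply(seq_len(3), function(l) {
    # the output layer starts near zero so the bounded (sigmoid-scaled)
    # head begins at mid-scale with a healthy gradient; a random head can
    # start saturated (sample-independent offset in its pre-activation),
    # which freezes training
    sd <- if (l == 3) 0.01 * sqrt(2 / widths[l]) else sqrt(2 / widths[l])
    list(W = matrix(rnorm(widths[l + 1] * widths[l], sd = sd),
                    widths[l + 1], widths[l]),
         b = numeric(widths[l + 1]))
  })
  list(conv = conv, fc = fc, kernel = as.integer(k))
}

tracker_init_running <- function(config) {
  list(mean = lapply(config$conv_channels, function(c) numeric(c)),
       var = lapply(config$conv_channels, function(c) rep(1, c)))
}

#' @export
n_parameters.tracker_config <- function(object, ...) {
  k <- object$conv_kernel
  ch <- c(1L, object$conv_channels)
  conv <- sum(vapply(seq_len(5), function(l) {
    k * ch[l] * ch[l + 1] + 3L * ch[l + 1]   # W + bias + bn gamma/beta
  }, integer(1)))
  widths <- c(object$input_width * ch[6], object$fc_widths)
  fc <- sum(vapply(seq_len(3), function(l) {
    widths[l] * widths[l + 1] + widths[l + 1]
  }, integer(1)))
  conv + fc
}

#' @export
n_parameters.tracker_fit <- function(object, ...) {
  cnt <- function(p) if (is.list(p)) sum(vapply(p, cnt, numeric(1))) else length(p)
  as.integer(cnt(object$params$conv) + cnt(object$params$fc))
}

#' Huber loss
#'
#' Quadratic for errors up to `delta`, linear beyond: `0.5 * e^2` for
#' `|e| <= delta`, `delta * (|e| - 0.5 * delta)` otherwise, averaged over
#' the batch. Robust to the occasional gross mis-estimate caused by
#' high-amplitude artifacts, which would dominate a squared loss.
#'
#' @param pred,target Numeric vectors, depth samples.
#' @param delta Transition point, depth samples (> 0).
#' @return Mean loss over the batch.
#' @examples
#' huber_loss(3, 0, 1)   # linear branch: 1 * (3 - 0.5)
#' @export
huber_loss <- function(pred, target, delta = 1.0) {
  if (delta <= 0) stop("huber delta must be > 0", call. = FALSE)
  e <- abs(pred - target)
  mean(ifelse(e <= delta, 0.5 * e^2, delta * (e - 0.5 * delta)))
}

#' Forward pass of the diameter tracker (inference mode)
#'
#' Uses the stored global batch-normalization running statistics and no
#' dropout, so the output is a deterministic function of the input.
#'
#' @param roi An `roi_window`, a numeric vector of `input_width` samples,
#'   or a matrix (`input_width` x batch).
#' @param fit A `tracker_fit` (or a list with `params` and `running`).
#' @return Diameter estimate(s) in depth samples, in `(0, input_width)`.
#' @export
tracker_forward <- function(roi, fit) {
  x <- if (inherits(roi, "roi_window")) matrix(roi$values, ncol = 1)
  else if (is.matrix(roi)) roi else matrix(roi, ncol = 1)
  w <- fit$config$input_width %||% nrow(x)
  if (nrow(x) != w) {
    stop("ROI width ", nrow(x), " does not match tracker input width ", w,
         call. = FALSE)
  }
  out <- cpp_tracker_predict(x, fit$params, fit$running)
  if (length(out) == 1) out[[1]] else as.numeric(out)
}

#' Train the diameter tracker
#'
#' Trains on ROI windows extracted around the ground-truth lumen centers
#' with a fresh uniform integer jitter (default +/- 35 samples, sized to
#' cover the ROI detector's localization scatter including its tail on
#' hard subjects) per frame and epoch, so that at inference time the
#' tracker is insensitive to the ROI stage's centering error. The loss is the Huber loss between the
#' predicted and true diameter in sample units; optimization is Adam with
#' L2 weight decay; batch-normalization uses batch statistics during
#' training and global running averages at test time.
#'
#' @param x Envelope matrix (depth x frames, per-frame normalized) or an
#'   envelope `mmode_record`.
#' @param annotation Ground-truth annotation (`gt_annotation` tibble or
#'   data frame with `center` and `diameter` in 0-based depth samples).
#' @param config A [tracker_config()].
#' @param epochs,batch_size,lr,weight_decay Training hyperparameters.
#' @param jitter Maximum window-center jitter, samples.
#' @param val_fraction Fraction of frames held out for validation loss.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param verbose Print per-epoch losses?
#' @return An object of class `tracker_fit`: `params`, `running` (global
#'   batch-norm statistics), `config`, `history`, `seed`.
#' @export
train_tracker <- function(x, annotation, config = tracker_config(),
                          epochs = 20, batch_size = 256, lr = 1e-3,
                          weight_decay = 1e-4, jitter = 35,
                          val_fraction = 0.1, seed = 1L, verbose = FALSE) {
  if (inherits(x, "mmode_record")) x <- x$samples
  stopifnot(is.matrix(x), nrow(annotation) == ncol(x))
  if (ncol(x) == 0) stop("empty training set", call. = FALSE)
  n <- ncol(x)
  w <- config$input_width
  centers <- annotation$center
  targets <- annotation$diameter

  with_local_seed(seed, {
    params <- tracker_init_params(config)
    running <- tracker_init_running(config)
    state <- adam_init(params, skip = "kernel")
    n_val <- max(if (val_fraction > 0 && n >= 5) round(val_fraction * n) else 0, 0)
    perm <- sample.int(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer()
    tr_idx <- setdiff(perm, val_idx)
    val_x <- if (length(val_idx)) {
      clip_roi_batch(x, centers[val_idx], w, cols = val_idx)
    } else NULL
    history <- vector("list", epochs)

    for (ep in seq_len(epochs)) {
      # cosine-annealed learning rate (initial value `lr`, decaying to ~0)
      lr_ep <- lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
      ord <- sample(tr_idx)
      jit <- if (jitter > 0) {
        sample.int(2 * jitter + 1, length(ord), replace = TRUE) - jitter - 1
      } else numeric(length(ord))
      losses <- c()
      for (b in seq(1, length(ord), by = batch_size)) {
        sel <- b:min(b + batch_size - 1, length(ord))
        ii <- ord[sel]
        xb <- clip_roi_batch(x, centers[ii] + jit[sel], w, cols = ii)
        tb <- targets[ii]
        nb <- length(ii)
        d1 <- make_dropout_mask(config$fc_widths[1], nb, config$dropout)
        d2 <- make_dropout_mask(config$fc_widths[2], nb, config$dropout)
        g <- cpp_tracker_grad(xb, tb, params, running, 0.1,
                              config$huber_delta, d1, d2)
        if (!is.finite(g$loss)) {
          stop("tracker training diverged (non-finite loss) at epoch ", ep,
               call. = FALSE)
        }
        running <- g$running
        st <- adam_step(params, g$grads, state, lr = lr_ep,
                        weight_decay = weight_decay, skip = "kernel")
        params <- st$params
        state <- st$state
        losses <- c(losses, g$loss)
      }
      val_loss <- if (!is.null(val_x)) {
        pv <- cpp_tracker_predict(val_x, params, running)
        huber_loss(as.numeric(pv), targets[val_idx], config$huber_delta)
      } else NA_real_
      history[[ep]] <- tibble::tibble(epoch = ep,
                                      train_loss = mean(losses),
                                      val_loss = val_loss)
      if (verbose) {
        message(sprintf("tracker epoch %d: train %.4f val %.4f", ep,
                        mean(losses), val_loss))
      }
    }
    structure(list(params = params, running = running, config = config,
                   history = dplyr::bind_rows(history), seed = seed),
              class = "tracker_fit")
  })
}

make_dropout_mask <- function(rows, cols, p) {
  if (p <= 0) return(matrix(1, rows, cols))
  matrix((runif(rows * cols) >= p) / (1 - p), rows, cols)
}

#' @export
print.tracker_fit <- function(x, ...) {
  cat("Diameter tracker fit:", n_parameters(x), "parameters,",
      nrow(x$history), "epochs, final train Huber loss",
      signif(tail(x$history$train_loss, 1), 4), "\n")
  invisible(x)
}

#' Predict a per-frame diameter trace
#'
#' Streams an M-mode record through the full two-stage pipeline: Hilbert
#' envelope (if the record is RF), ROI detection and clipping per frame,
#' then the tracker's diameter regression. Every frame is processed
#' independently — no state is carried between frames and no look-ahead is
#' used, so the pipeline is streaming-capable and drift-free by
#' construction.
#'
#' @param record An `mmode_record` (RF or envelope) or an envelope matrix.
#' @param roi_fit A fitted `roi_fit`.
#' @param tracker_fit A fitted `tracker_fit`.
#' @param chunk Frames per prediction batch (memory knob, no effect on
#'   results).
#' @return A `diameter_trace`: tibble with `frame`, `roi_center` (samples)
#'   and `diameter` (samples); attributes `frame_rate` and `smoothed`.
#' @export
predict_trace <- function(record, roi_fit, tracker_fit, chunk = 512L) {
  frame_rate <- NA_real_
  if (inherits(record, "mmode_record")) {
    frame_rate <- record$spec$frame_rate
    env <- if (record$kind == "rf") {
      envelope_record(record, decimation = roi_fit$config$decimation,
                      normalize = TRUE)$samples
    } else record$samples
  } else env <- record
  if (nrow(env) != roi_fit$config$input_length %/% roi_fit$config$decimation) {
    stop("frame length ", nrow(env), " does not match ROI config",
         call. = FALSE)
  }
  n <- ncol(env)
  w <- tracker_fit$config$input_width
  centers <- numeric(n)
  diam <- numeric(n)
  for (b in seq(1, n, by = chunk)) {
    ii <- b:min(b + chunk - 1, n)
    cc <- predict(roi_fit, env[, ii, drop = FALSE])
    xb <- clip_roi_batch(env, cc, w, cols = ii)
    centers[ii] <- cc
    diam[ii] <- as.numeric(cpp_tracker_predict(xb, tracker_fit$params,
                                               tracker_fit$running))
  }
  new_diameter_trace(diam, roi_center = centers, frame_rate = frame_rate)
}

new_diameter_trace <- function(diameter, roi_center = NULL,
                               frame_rate = NA_real_, smoothed = FALSE) {
  out <- tibble::tibble(frame = seq_along(diameter),
                        diameter = as.numeric(diameter))
  if (!is.null(roi_center)) out$roi_center <- as.numeric(roi_center)
  attr(out, "frame_rate") <- frame_rate
  attr(out, "smoothed") <- smoothed
  class(out) <- c("diameter_trace", class(out))
  out
}
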