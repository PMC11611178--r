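#' ROI detector configuration
#'
#' The region-of-interest detector is deliberately tiny: one wide 1-D
#' convolution (1 input channel to `channels` channels; the kernel spans
#' the maximum anticipated arterial diameter), a 1-wide convolution
#' combining the channels into a single per-depth map, and a parameterless
#' moving-average pooling layer. None of the layers change the input
#' width (zero padding throughout), so the argmax of the pooled map is
#' directly a depth index. The clipping window applied downstream has the
#' same width as the first-layer kernel.
#'
#' @param input_length Full-resolution frame length, samples.
#' @param kernel_width First-layer kernel width, samples (odd). Default 401
#'   samples (about 9.9 mm) covers the largest plausible carotid diameter
#'   with margin.
#' @param channels First-layer output channels.
#' @param pool_window Moving-average pooling window, samples (odd).
#' @param window_width Width of the clipped ROI window, samples.
#' @param decimation Depth decimation factor of the network input.
#' @return An object of class `roi_config`.
#' @export
roi_config <- function(input_length = 1020L, kernel_width = 401L,
                       channels = 3L, pool_window = 31L,
                       window_width = 401L, decimation = 1L) {
  stopifnot(kernel_width %% 2 == 1, pool_window %% 2 == 1,
            window_width <= input_length, channels >= 1, decimation >= 1,
            input_length %% decimation == 0)
  structure(list(input_length = as.integer(input_length),
                 kernel_width = as.integer(kernel_width),
                 channels = as.integer(channels),
                 pool_window = as.integer(pool_window),
                 window_width = as.integer(window_width),
                 decimation = as.integer(decimation)),
            class = "roi_config")
}

roi_init_params <- function(config) {
  k <- config$kernel_width
  c <- config$channels
  list(W1 = matrix(rnorm(k * c, sd = sqrt(2 / k)), k, c),
       b1 = numeric(c),
       w2 = rnorm(c, sd = sqrt(2 / c)),
       b2 = numeric(1))
}

#' Forward pass of the ROI detector
#'
#' @param env Envelope frame (numeric vector) or depth x frames matrix at
#'   the network's input resolution.
#' @param params ROI parameter list (`W1`, `b1`, `w2`, `b2`), e.g. from a
#'   fitted `roi_fit`.
#' @param config An [roi_config()].
#' @return List with `pre` (output of the last convolution, the map trained
#'   against the response vector) and `pooled` (after moving-average
#'   pooling, the map that is argmax-ed); both have the input's shape.
#' @export
roi_forward <- function(env, params, config = roi_config()) {
  x <- if (is.matrix(env)) env else matrix(env, ncol = 1)
  if (nrow(x) != config$input_length %/% config$decimation) {
    stop("frame length ", nrow(x), " does not match config input length ",
         config$input_length %/% config$decimation, call. = FALSE)
  }
  out <- cpp_roi_forward(x, params$W1, params$b1, params$w2, params$b2,
                         config$pool_window)
  if (!is.matrix(env)) out <- list(pre = out$pre[, 1], pooled = out$pooled[, 1])
  out
}

#' Locate the lumen center from a pooled response map
#'
#' A plain argmax over depth, with ties broken toward the smallest index,
#' mapped back to full resolution when the map was computed on decimated
#' input (block index `i`, 0-based, maps to `i * decimation +
#' decimation / 2`).
#'
#' @param pooled Numeric vector (one map) or matrix (depth x frames).
#' @param decimation Decimation factor of the map.
#' @return Estimated lumen-center depth(s) in full-resolution 0-based
#'   samples.
#' @examples
#' locate_lumen(c(0, 0.2, 0.9, 0.2))
#' @export
locate_lumen <- function(pooled, decimation = 1L) {
  idx <- if (is.matrix(pooled)) {
    max.col(t(pooled), ties.method = "first") - 1L
  } else {
    which.max(pooled) - 1L
  }
  if (decimation > 1) idx * decimation + decimation / 2 else idx
}

#' Clip a fixed-width ROI window around an estimated center
#'
#' The window is centered at `round(center)`; if the centered window would
#' overhang an edge of the frame it is shifted inward so it always lies
#' fully inside (clamped start), guaranteeing a fixed-length input for the
#' tracker without fabricating padded signal.
#'
#' @param env Envelope frame (numeric vector).
#' @param center Estimated lumen center, 0-based depth samples.
#' @param window_width Window width, samples.
#' @return An object of class `roi_window`: list with `values`
#'   (`window_width` samples), `start` (0-based index of the first element
#'   after any clamping) and `center_estimate`.
#' @examples
#' clip_roi(rnorm(1020), 500, 401)$start
#' @export
clip_roi <- function(env, center, window_width) {
  n <- length(env)
  if (window_width > n) {
    stop("window_width ", window_width, " exceeds frame length ", n,
         call. = FALSE)
  }
  start <- roi_window_start(center, window_width, n)
  structure(list(values = env[(start + 1):(start + window_width)],
                 start = start, center_estimate = center),
            class = "roi_window")
}

# 0-based clamped window start
roi_window_start <- function(center, window_width, n) {
  start <- round(center) - (window_width - 1) %/% 2
  pmin(pmax(start, 0), n - window_width)
}

# batch clip: env matrix (depth x frames), centers -> width x frames.
# cols: which frames of env to clip (defaults to all, aligned with centers)
clip_roi_batch <- function(env, centers, window_width, cols = NULL) {
  n <- nrow(env)
  if (is.null(cols)) cols <- seq_along(centers)
  starts <- roi_window_start(centers, window_width, n)
  # linear single-gather indexing
  lin <- outer(seq_len(window_width), (cols - 1) * n + starts, `+`)
  m <- env[lin]
  dim(m) <- c(window_width, length(cols))
  attr(m, "start") <- starts
  m
}

#' Number of trainable parameters
#'
#' @param object A fitted network (`roi_fit`, `tracker_fit`) or a config
#'   (`roi_config`, `tracker_config`).
#' @param ... Unused.
#' @return Integer count of trainable scalars. The moving-average pooling
#'   layer of the ROI detector is parameterless and contributes 0.
#' @examples
#' n_parameters(roi_config())  # 3*401 + 3 + 3 + 1 = 1210
#' @export
n_parameters <- function(object, ...) UseMethod("n_parameters")

#' @export
n_parameters.roi_config <- function(object, ...) {
  object$kernel_width * object$channels + object$channels +
    object$channels + 1L
}

#' @export
n_parameters.roi_fit <- function(object, ...) {
  sum(vapply(object$params, length, integer(1)))
}

#' Train the ROI detector
#'
#' Minimizes the mean squared error between the output of the last
#' convolution layer (before pooling) and the response-vector labels; the
#' parameterless pooling layer is deliberately excluded from the loss path,
#' which gives a crisper localization gradient. Optimization is Adam with
#' L2 weight decay. Each epoch every frame is translated along depth by a
#' fresh uniform shift in `[-augment_shift, augment_shift]` (restricted so
#' the label support stays inside the frame), teaching the detector to find
#' the wall-echo pattern at any depth.
#'
#' @param x Envelope matrix, depth x frames (per-frame normalized), or an
#'   envelope `mmode_record`.
#' @param labels Response-vector matrix, depth x frames (see
#'   [response_vector()]).
#' @param config An [roi_config()].
#' @param epochs,batch_size,lr,weight_decay Training hyperparameters.
#' @param augment_shift Maximum depth-translation augmentation, samples
#'   (0 disables).
#' @param artifact_prob Per-frame probability of injecting a synthetic
#'   high-contrast artifact band (a Gabor-envelope bump at a random depth
#'   outside the label support) during training; teaches the detector to
#'   suppress lone echo bands instead of memorizing the training
#'   subjects' artifact geometry. 0 disables.
#' @param val_fraction Fraction of frames held out for the per-epoch
#'   validation loss.
#' @param seed Integer seed controlling initialization, shuffling and
#'   augmentation; training is deterministic given the seed.
#' @param verbose Print per-epoch losses?
#' @return An object of class `roi_fit`: `params`, `config`, `history`
#'   (tibble with epoch/train_loss/val_loss) and `seed`.
#' @export
train_roi <- function(x, labels, config = roi_config(), epochs = 10,
                      batch_size = 64, lr = 1e-3, weight_decay = 1e-4,
                      augment_shift = 150, artifact_prob = 0.5,
                      val_fraction = 0.1, seed = 1L, verbose = FALSE) {
  if (inherits(x, "mmode_record")) x <- x$samples
  stopifnot(is.matrix(x), is.matrix(labels), all(dim(x) == dim(labels)))
  if (ncol(x) == 0) stop("empty training set", call. = FALSE)
  n <- ncol(x)
  len <- nrow(x)

  # per-frame admissible shift range so the label support stays in-frame
  first_sup <- apply(labels, 2, function(r) which(r > 0)[1])
  last_sup <- apply(labels, 2, function(r) tail(which(r > 0), 1))
  sup_lo <- first_sup - 1
  sup_hi <- len - last_sup
  # artifact bump template: envelope of the wall echo pulse
  bump_half <- 12L
  bump <- exp(-((-bump_half):bump_half)^2 / (2 * 4^2))

  with_local_seed(seed, {
    params <- roi_init_params(config)
    state <- adam_init(params, skip = character())
    n_val <- max(if (val_fraction > 0 && n >= 5) round(val_fraction * n) else 0, 0)
    perm <- sample.int(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer()
    tr_idx <- setdiff(perm, val_idx)
    history <- vector("list", epochs)

    for (ep in seq_len(epochs)) {
      # cosine-annealed learning rate (initial value `lr`, decaying to ~0)
      lr_ep <- lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
      ord <- sample(tr_idx)
      shifts <- if (augment_shift > 0) {
        pmax(pmin(sample.int(2 * augment_shift + 1, length(ord),
                             replace = TRUE) - augment_shift - 1,
                  sup_hi[ord]), -sup_lo[ord])
      } else numeric(length(ord))
      losses <- c()
      for (b in seq(1, length(ord), by = batch_size)) {
        ii <- ord[b:min(b + batch_size - 1, length(ord))]
        ss <- shifts[b:min(b + batch_size - 1, length(ord))]
        xb <- x[, ii, drop = FALSE]
        if (artifact_prob > 0) {
          hit <- runif(length(ii)) < artifact_prob
          amp <- runif(length(ii), 0.3, 0.8)
          pos <- floor(runif(length(ii)) * len)
          for (j in which(hit)) {
            # keep injected bands away from the (shifted) label support
            lo_keep <- first_sup[ii[j]] + ss[j] - 60
            hi_keep <- last_sup[ii[j]] + ss[j] + 60
            if (pos[j] >= lo_keep && pos[j] <= hi_keep) next
            a <- max(1, pos[j] - bump_half)
            b <- min(len, pos[j] + bump_half)
            seg <- (a:b) - pos[j] + bump_half + 1
            xb[a:b, j] <- xb[a:b, j] + amp[j] * bump[seg]
          }
        }
        g <- cpp_roi_grad(xb, labels[, ii, drop = FALSE],
                          params$W1, params$b1, params$w2, params$b2,
                          as.integer(ss))
        if (!is.finite(g$loss)) {
          stop("ROI training diverged (non-finite loss) at epoch ", ep,
               call. = FALSE)
        }
        grads <- list(W1 = g$dW1, b1 = as.numeric(g$db1),
                      w2 = as.numeric(g$dw2), b2 = g$db2)
        st <- adam_step(params, grads, state, lr = lr_ep,
                        weight_decay = weight_decay, skip = character())
        params <- st$params
        state <- st$state
        losses <- c(losses, g$loss)
      }
      val_loss <- if (length(val_idx)) {
        f <- cpp_roi_forward(x[, val_idx, drop = FALSE], params$W1,
                             params$b1, params$w2, params$b2,
                             config$pool_window)
        mean((f$pre - labels[, val_idx, drop = FALSE])^2)
      } else NA_real_
      history[[ep]] <- tibble::tibble(epoch = ep,
                                      train_loss = mean(losses),
                                      val_loss = val_loss)
      if (verbose) {
        message(sprintf("roi epoch %d: train %.5f val %.5f", ep,
                        mean(losses), val_loss))
      }
    }
    structure(list(params = params, config = config,
                   history = dplyr::bind_rows(history), seed = seed),
              class = "roi_fit")
  })
}

#' @export
print.roi_fit <- function(x, ...) {
  cat("ROI detector fit:", n_parameters(x), "parameters,",
      nrow(x$history), "epochs, final train loss",
      signif(tail(x$history$train_loss, 1), 4), "\n")
  invisible(x)
}

#' Predict lumen-center positions with a fitted ROI detector
#'
#' @param object An `roi_fit`.
#' @param newdata Envelope matrix (depth x frames) or envelope
#'   `mmode_record`.
#' @param ... Unused.
#' @return Numeric vector of per-frame lumen-center estimates, 0-based
#'   full-resolution depth samples.
#' @export
predict.roi_fit <- function(object, newdata, ...) {
  env <- if (inherits(newdata, "mmode_record")) newdata$samples else newdata
  if (!is.matrix(env)) env <- matrix(env, ncol = 1)
  out <- cpp_roi_forward(env, object$params$W1, object$params$b1,
                         object$params$w2, object$params$b2,
                         object$config$pool_window)
  locate_lumen(out$pooled, object$config$decimation)
}
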