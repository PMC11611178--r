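#' Hilbert envelope of an RF frame
#'
#' Returns the magnitude of the analytic signal of the input, computed by
#' one-sided spectrum doubling in the frequency domain: the FFT of the frame
#' has its negative frequencies zeroed and positive frequencies doubled, and
#' the inverse transform's modulus is the envelope. For a pure tone
#' `A*cos(2*pi*f*n)` away from the edges the envelope equals `A`; for a
#' Gabor pulse it recovers the Gaussian envelope.
#'
#' @param rf_frame Numeric vector, one RF A-mode frame (length >= 8).
#' @return Nonnegative numeric vector of the same length.
#' @examples
#' n <- 0:199
#' env <- hilbert_envelope(3 * cos(2 * pi * 0.25 * n))
#' round(env[100], 3)
#' @export
hilbert_envelope <- function(rf_frame) {
  if (length(rf_frame) < 8) stop("rf frame must have length >= 8", call. = FALSE)
  if (!all(is.finite(rf_frame))) stop("rf frame contains non-finite values", call. = FALSE)
  Mod(analytic_signal(matrix(rf_frame, ncol = 1)))[, 1]
}

# analytic signal of every column (one-sided spectrum doubling)
analytic_signal <- function(M) {
  n <- nrow(M)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  mvfft(mvfft(M) * h, inverse = TRUE) / n
}

#' Block-maximum depth decimation
#'
#' Reduces the depth resolution of an envelope frame by taking the maximum
#' over consecutive blocks of `factor` samples. The maximum (rather than the
#' mean) is used so that narrow wall-echo peaks survive decimation. Output
#' index `i` (0-based) summarizes input depth interval
#' `[i * factor, (i + 1) * factor)`.
#'
#' @param env Numeric vector (envelope frame) or matrix (depth x frames).
#' @param factor Positive integer that divides the frame length.
#' @return Decimated vector/matrix of length `length(env) / factor`.
#' @examples
#' decimate_depth(c(0, 1, 0, 0, 5, 0, 0, 0), 4)
#' @export
decimate_depth <- function(env, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(env)
  n <- if (is.matrix(env)) nrow(env) else length(env)
  if (n %% factor != 0) {
    divs <- which(n %% seq_len(n) == 0)
    nearest <- divs[which.min(abs(divs - factor))]
    stop("decimation factor ", factor, " does not divide frame length ", n,
         "; nearest valid factor is ", nearest, call. = FALSE)
  }
  nc <- if (is.matrix(env)) ncol(env) else 1L
  dim(env) <- c(factor, n / factor * nc)
  out <- do.call(pmax, lapply(seq_len(factor), function(i) env[i, ]))
  if (nc > 1L) matrix(out, n / factor) else out
}

#' Per-frame maximum normalization
#'
#' Divides an envelope frame by its maximum so the peak amplitude is 1.
#' Phantom (and real) recordings have arbitrary amplitude units and
#' per-subject gain differences; per-frame normalization removes both.
#'
#' @param env Numeric vector (one frame) or matrix (depth x frames,
#'   normalized column-wise).
#' @return Normalized vector/matrix; each frame's maximum is exactly 1.
#' @examples
#' normalize_frame(c(2, 4, 8))
#' @export
normalize_frame <- function(env) {
  if (is.matrix(env)) {
    m <- apply(env, 2, max)
    if (any(m <= 0)) {
      stop("degenerate all-zero frame(s) at index ", which(m <= 0)[1],
           call. = FALSE)
    }
    sweep(env, 2, m, "/")
  } else {
    m <- max(env)
    if (m <= 0) stop("degenerate all-zero frame", call. = FALSE)
    env / m
  }
}

#' Envelope representation of an M-mode record
#'
#' Converts every RF frame of a record to its Hilbert envelope, with
#' optional block-max depth decimation and per-frame max normalization —
#' the representation both neural networks consume.
#'
#' @param record An `mmode_record` (kind `"rf"`) from [render_recording()].
#' @param decimation Integer depth-decimation factor (must divide the depth
#'   length); 1 keeps full resolution.
#' @param normalize Normalize each frame to unit maximum?
#' @return An `mmode_record` with `kind = "envelope"`.
#' @export
envelope_record <- function(record, decimation = 1L, normalize = TRUE) {
  stopifnot(inherits(record, "mmode_record"))
  if (record$kind == "envelope") {
    env <- record$samples
  } else {
    bad <- which(!apply(record$samples, 2, function(x) all(is.finite(x))))
    if (length(bad)) {
      stop("non-finite RF values in frame ", bad[1], call. = FALSE)
    }
    env <- Mod(analytic_signal(record$samples))
  }
  env <- decimate_depth(env, decimation)
  if (normalize) env <- normalize_frame(env)
  new_mmode_record(env, record$spec, "envelope")
}
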