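#' Lumen center from wall positions
#'
#' The lumen center is the midpoint of the hypoechoic region between the
#' two wall echoes: `(anterior + posterior) / 2`, kept real-valued.
#'
#' @param anterior,posterior Wall positions in depth samples (0-based,
#'   real-valued); vectorized.
#' @return Lumen center position(s), depth samples.
#' @examples
#' lumen_center(280, 320)
#' @export
lumen_center <- function(anterior, posterior) {
  if (any(posterior < anterior)) {
    stop("posterior wall must not be above the anterior wall", call. = FALSE)
  }
  (anterior + posterior) / 2
}

#' Cut-off points of the response-vector support
#'
#' The response vector's support ends halfway between the lumen center and
#' each wall: `cut_anterior = (center + anterior) / 2`,
#' `cut_posterior = (center + posterior) / 2`.
#'
#' @param center Lumen center, depth samples.
#' @inheritParams lumen_center
#' @return Named numeric vector (or 2-column matrix when vectorized) with
#'   `anterior` and `posterior` cut-off positions.
#' @examples
#' cutoff_points(300, 280, 320)
#' @export
cutoff_points <- function(center, anterior, posterior) {
  if (any(anterior > center) || any(center > posterior)) {
    stop("wall/center ordering violated: need anterior <= center <= posterior",
         call. = FALSE)
  }
  a <- (center + anterior) / 2
  p <- (center + posterior) / 2
  if (length(center) == 1L) c(anterior = a, posterior = p)
  else cbind(anterior = a, posterior = p)
}

#' Response vector: per-depth training label for the ROI detector
#'
#' For depth indices `i` strictly between the two cut-off points the label
#' is the normalized inverted squared distance to the lumen center,
#' `R_i = 1 - (i - P_C)^2 / (P_C - P_cutoff)^2`, using the cut-off on the
#' same side of the center as `i`; everywhere else the label is exactly 0.
#' The result is a downward-opening quadratic bump in `[0, 1]` peaking at
#' the lumen center, the regression target that lets a convolutional map
#' localize the lumen by a simple argmax instead of an extremely imbalanced
#' per-depth classification.
#'
#' @inheritParams lumen_center
#' @param length Frame length in depth samples.
#' @return Numeric vector of `length` label values in `[0, 1]` (0-based
#'   depth indexing: element `j` is the label of depth index `j - 1`).
#' @examples
#' r <- response_vector(280, 320, 1020)
#' r[301]  # depth index 300 = lumen center
#' @export
response_vector <- function(anterior, posterior, length) {
  if (anterior >= posterior) {
    stop("zero-width lumen: need anterior < posterior", call. = FALSE)
  }
  if (anterior < 0 || posterior > length - 1) {
    stop("wall positions must lie inside [0, length)", call. = FALSE)
  }
  pc <- lumen_center(anterior, posterior)
  cuts <- cutoff_points(pc, anterior, posterior)
  i <- seq_len(length) - 1
  r <- numeric(length)
  inside <- i > cuts[["anterior"]] & i < cuts[["posterior"]]
  denom2 <- ifelse(i < pc,
                   (pc - cuts[["anterior"]])^2,
                   (cuts[["posterior"]] - pc)^2)
  r[inside] <- 1 - (i[inside] - pc)^2 / denom2[inside]
  r
}

#' Response-vector label matrix for an annotated recording
#'
#' Applies [response_vector()] to every annotated frame.
#'
#' @param annotation A `gt_annotation` (or data frame with `anterior` and
#'   `posterior` columns in 0-based depth samples).
#' @param length Frame length in depth samples.
#' @return `length` x `nrow(annotation)` matrix of labels.
#' @export
response_matrix <- function(annotation, length) {
  vapply(seq_len(nrow(annotation)), function(j) {
    response_vector(annotation$anterior[j], annotation$posterior[j], length)
  }, numeric(length))
}

#' Depth-translation augmentation
#'
#' Shifts an envelope frame along depth by an integer number of samples
#' (zero-filling the vacated end) and shifts the wall annotation by the
#' same amount, so the response vector of the shifted annotation equals the
#' shifted response vector. Used during ROI-detector training so the
#' network learns to find the wall-echo pattern at any depth rather than
#' memorizing the cohort's limited range of lumen positions.
#'
#' @param frame Numeric envelope frame.
#' @param annotation One-row slice (list or data frame row) with `anterior`
#'   and `posterior` (and optionally `center`, `diameter`) in depth samples.
#' @param shift Integer shift in samples (positive = deeper).
#' @return List with `frame` (shifted envelope) and `annotation` (shifted
#'   positions).
#' @examples
#' a <- list(anterior = 280, posterior = 320)
#' out <- augment_translate(response_vector(280, 320, 1020), a, 50)
#' out$annotation$anterior
#' @export
augment_translate <- function(frame, annotation, shift) {
  shift <- as.integer(round(shift))
  n <- length(frame)
  ann <- as.list(annotation)
  if (ann$anterior + shift < 0 || ann$posterior + shift > n - 1) {
    stop("shift of ", shift, " samples pushes the walls outside [0, ",
         n - 1, "]", call. = FALSE)
  }
  for (f in intersect(c("anterior", "posterior", "center"), names(ann))) {
    ann[[f]] <- ann[[f]] + shift
  }
  list(frame = shift_zerofill(frame, shift), annotation = ann)
}

# shift vector (or matrix columns) by s samples with zero fill
shift_zerofill <- function(x, s) {
  if (s == 0) return(x)
  if (is.matrix(x)) {
    out <- matrix(0, nrow(x), ncol(x))
    n <- nrow(x)
    if (s > 0) out[(s + 1):n, ] <- x[1:(n - s), , drop = FALSE]
    else out[1:(n + s), ] <- x[(1 - s):n, , drop = FALSE]
    out
  } else {
    n <- length(x)
    out <- numeric(n)
    if (s > 0) out[(s + 1):n] <- x[1:(n - s)]
    else out[1:(n + s)] <- x[(1 - s):n]
    out
  }
}
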