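#' Reference per-subject clinical evaluation metrics
#'
#' Per-subject evaluation results of this pipeline on its original
#' six-subject clinical cohort (units: depth samples at 24.65 um/sample;
#' the response-vector MSE is dimensionless): the ROI detector's
#' response-vector MSE and lumen-center MAE, and the tracker's Huber loss,
#' mean reference diameter, MSE, RMSE and median absolute deviation.
#' Shipped so summary arithmetic (unweighted across-subject averages,
#' sample-to-mm conversions) can be reproduced without the clinical
#' recordings, which are not publicly deposited.
#'
#' @return Tibble with one row per subject.
#' @examples
#' mean(reference_subject_metrics()$roi_mae_lumen_center)
#' @export
reference_subject_metrics <- function() {
  path <- system.file("extdata", "reference_subject_metrics.csv",
                      package = "lumentrack", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}
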