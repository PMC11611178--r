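#' Write / read a phantom cohort dataset
#'
#' The cohort container is serialized as a single RDS file: one entry per
#' subject (`rf` matrix, `annotation` table, `config`), plus the
#' acquisition spec and the master seed as file-level metadata. Writing
#' then reading restores the object bit-for-bit (arrays, attributes and
#' any extra user-added components are preserved).
#'
#' @param dataset A `phantom_cohort`.
#' @param path File path (conventionally `.rds`).
#' @return `write_dataset` returns `path` invisibly; `read_dataset`
#'   returns the validated `phantom_cohort`.
#' @examples
#' f <- tempfile(fileext = ".rds")
#' write_dataset(make_cohort(2, 20, 1), f)
#' cohort <- read_dataset(f)
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "phantom_cohort"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  dataset <- readRDS(path)
  problems <- character()
  if (is.null(dataset$spec)) problems <- c(problems, "spec")
  if (is.null(dataset$subjects) || !length(dataset$subjects)) {
    problems <- c(problems, "subjects")
  } else {
    for (k in seq_along(dataset$subjects)) {
      s <- dataset$subjects[[k]]
      nm <- names(dataset$subjects)[k] %||% paste0("subject_", k)
      if (is.null(s$rf)) problems <- c(problems, paste0(nm, "/rf"))
      if (is.null(s$annotation)) {
        problems <- c(problems, paste0(nm, "/annotation"))
      } else {
        miss <- setdiff(c("anterior", "posterior", "center", "diameter"),
                        names(s$annotation))
        if (length(miss)) {
          problems <- c(problems, paste0(nm, "/annotation/", miss))
        }
      }
    }
  }
  if (length(problems)) {
    stop("dataset schema error; missing: ", paste(problems, collapse = ", "),
         call. = FALSE)
  }
  dataset
}

#' Assemble a complete run configuration
#'
#' Bundles every tunable of a full pipeline run — cohort size, acquisition
#' constants, network and smoother configurations, training
#' hyperparameters and the master seed — into one object that round-trips
#' losslessly through YAML, so a run is fully described by one file.
#'
#' @param n_subjects,frames_per_subject Cohort dimensions.
#' @param seed Master seed; every random draw in the run derives from it.
#' @param spec,roi,tracker,smoother Component configurations.
#' @param roi_epochs,tracker_epochs,roi_batch_size,tracker_batch_size,lr,
#'   weight_decay,augment_shift,jitter Training hyperparameters.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_subjects = 6L, frames_per_subject = 2000L,
                       seed = 7L, spec = acquisition_spec(),
                       roi = roi_config(), tracker = tracker_config(),
                       smoother = smoother_config(),
                       roi_epochs = 10L, tracker_epochs = 20L,
                       roi_batch_size = 64L, tracker_batch_size = 256L,
                       lr = 1e-3, weight_decay = 1e-4,
                       augment_shift = 150L, jitter = 35L) {
  structure(list(n_subjects = as.integer(n_subjects),
                 frames_per_subject = as.integer(frames_per_subject),
                 seed = as.integer(seed), spec = spec, roi = roi,
                 tracker = tracker, smoother = smoother,
                 roi_epochs = as.integer(roi_epochs),
                 tracker_epochs = as.integer(tracker_epochs),
                 roi_batch_size = as.integer(roi_batch_size),
                 tracker_batch_size = as.integer(tracker_batch_size),
                 lr = lr, weight_decay = weight_decay,
                 augment_shift = as.integer(augment_shift),
                 jitter = as.integer(jitter)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- lapply(unclass(config), function(x) {
    if (is.object(x)) c(unclass(x), list(.class = class(x)[1])) else x
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  plain <- yaml::read_yaml(path)
  rebuild <- function(x) {
    if (is.list(x) && !is.null(x$.class)) {
      cls <- x$.class
      x$.class <- NULL
      # artifact bands arrive as lists; restore named numeric vectors
      if (!is.null(x$artifact_bands)) {
        x$artifact_bands <- lapply(x$artifact_bands, unlist)
      }
      fn <- switch(cls, acq_spec = acquisition_spec,
                   phantom_config = phantom_subject_config,
                   roi_config = roi_config,
                   tracker_config = tracker_config,
                   smoother_config = smoother_config,
                   stop("unknown config class in YAML: ", cls, call. = FALSE))
      do.call(fn, x)
    } else x
  }
  args <- lapply(plain, rebuild)
  do.call(run_config, args)
}

#' Run the complete pipeline end to end
#'
#' Simulates (or loads) the cohort, preprocesses it, builds labels, runs
#' the leave-one-subject-out evaluation and writes a reproducible report
#' directory: `metrics.csv` (one row per fold plus the mean row),
#' `config.json` (the resolved configuration), `checkpoints/` (per-fold
#' fitted networks) and `manifest.json` (inputs, their MD5 hashes, seeds
#' and output inventory — enough to replay the run).
#'
#' @param config A [run_config()].
#' @param out_dir Report directory (created if needed).
#' @param data_path Optional existing cohort RDS (from [write_dataset()]);
#'   when `NULL` the cohort is simulated from the config.
#' @param verbose Print stage progress?
#' @return The `loso_result`, invisibly; side effect: the report
#'   directory.
#' @export
run_pipeline <- function(config, out_dir, data_path = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (is.null(data_path)) {
    if (verbose) message("simulating cohort (", config$n_subjects,
                         " subjects x ", config$frames_per_subject,
                         " frames)")
    make_cohort(config$n_subjects, config$frames_per_subject, config$seed,
                spec = config$spec)
  } else {
    read_dataset(data_path)
  }
  result <- loso_evaluate(cohort, roi_cfg = config$roi,
                          tracker_cfg = config$tracker,
                          smoother = config$smoother,
                          roi_epochs = config$roi_epochs,
                          tracker_epochs = config$tracker_epochs,
                          seed = config$seed, verbose = verbose,
                          roi_args = list(batch_size = config$roi_batch_size,
                                          lr = config$lr,
                                          weight_decay = config$weight_decay,
                                          augment_shift = config$augment_shift),
                          tracker_args = list(
                            batch_size = config$tracker_batch_size,
                            lr = config$lr,
                            weight_decay = config$weight_decay,
                            jitter = config$jitter))

  metrics <- dplyr::bind_rows(result$folds, result$summary)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  plain <- lapply(unclass(config), function(x) {
    if (is.object(x)) c(unclass(x), list(.class = class(x)[1])) else x
  })
  jsonlite::write_json(plain, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ckpt_dir <- file.path(out_dir, "checkpoints")
  dir.create(ckpt_dir, showWarnings = FALSE)
  ckpts <- character()
  for (k in seq_along(result$fits)) {
    p <- file.path(ckpt_dir, sprintf("fold_%d.rds", k))
    saveRDS(result$fits[[k]], p)
    ckpts <- c(ckpts, p)
  }
  input_hash <- if (!is.null(data_path)) {
    as.character(tools::md5sum(data_path))
  } else NA_character_
  manifest <- list(seed = config$seed,
                   data_path = data_path %||% "simulated",
                   input_md5 = input_hash,
                   outputs = c("metrics.csv", "config.json",
                               basename(ckpts)),
                   checkpoint_md5 = as.character(tools::md5sum(ckpts)),
                   n_folds = nrow(result$folds))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}
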