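#' Pipeline configuration
#'
#' Bundles every tunable of the counting pipeline: CLAHE parameters, the
#' segmentation backend and its parameters, whether the first (background)
#' mask is skipped before counting, evaluation thresholds, and the seed.
#' Configurations round-trip losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param clahe [clahe_params()].
#' @param backend `"reference"` or `"sam"`.
#' @param backend_params named list passed to the backend (e.g. `min_area`,
#'   `checkpoint`).
#' @param skip_background skip the largest mask (the background candidate)
#'   before counting. Default TRUE.
#' @param aae_threshold acceptable-absolute-error band in cells.
#' @param density_threshold low/high-density stratum boundary in cells.
#' @param seed integer seed recorded with every run.
#' @param log_level `"info"` or `"quiet"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(clahe = clahe_params(), backend = "reference",
                            backend_params = list(),
                            skip_background = TRUE, aae_threshold = 10,
                            density_threshold = 100, seed = 1L,
                            log_level = c("info", "quiet")) {
  stopifnot(inherits(clahe, "clahe_params"))
  backend <- match.arg(backend, c("reference", "sam"))
  log_level <- match.arg(log_level)
  structure(list(clahe = clahe, backend = backend,
                 backend_params = backend_params,
                 skip_background = isTRUE(skip_background),
                 aae_threshold = aae_threshold,
                 density_threshold = density_threshold,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config [pipeline_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$clahe <- unclass(lst$clahe)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_config()] (or hand-authored with
#'   the same keys).
#' @return [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  }
  lst <- yaml::read_yaml(path)
  cl <- do.call(clahe_params, lst$clahe %||% list())
  pipeline_config(clahe = cl,
                  backend = lst$backend %||% "reference",
                  backend_params = lst$backend_params %||% list(),
                  skip_background = lst$skip_background %||% TRUE,
                  aae_threshold = lst$aae_threshold %||% 10,
                  density_threshold = lst$density_threshold %||% 100,
                  seed = lst$seed %||% 1L,
                  log_level = lst$log_level %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full counting pipeline over a directory of images
#'
#' For every PNG/TIFF image in `in_dir`: illumination correction by CLAHE,
#' prompt-free mask extraction with the configured backend, and centroid
#' counting. Writes `counts.csv` (`image_id,count`), one centroid CSV per
#' image under `out_dir/centers/`, one overlay PNG per image under
#' `out_dir/overlays/`, and `run_log.txt` recording the config hash and
#' per-image timings and mask counts before/after the background skip.
#' Never asks for interactive input. Per-image failures are logged and
#' skipped; an error is raised only if every image fails.
#'
#' @param in_dir directory containing at least one readable image.
#' @param out_dir output directory (created if needed).
#' @param config [pipeline_config()].
#' @param overlays write overlay PNGs (default TRUE).
#' @return the counts data frame (`image_id`, `count`), invisibly.
#' @export
run_pipeline <- function(in_dir, out_dir, config = pipeline_config(),
                         overlays = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  files <- list.files(in_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- sort(files)
  if (length(files) == 0L) {
    stop(sprintf("no PNG/TIFF images found in '%s'", in_dir), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  centers_dir <- file.path(out_dir, "centers")
  dir.create(centers_dir, showWarnings = FALSE)
  if (overlays) dir.create(file.path(out_dir, "overlays"), showWarnings = FALSE)

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_lines <- c(sprintf("config_hash: %s", cfg_hash),
                 sprintf("seed: %d", config$seed),
                 sprintf("backend: %s", config$backend))

  ids <- character(0); counts <- integer(0); failures <- 0L
  for (f in files) {
    id <- tools::file_path_sans_ext(basename(f))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      img <- read_image(f)
      eq <- apply_clahe(img, config$clahe)
      ms <- do.call(segment,
                    c(list(image = eq, backend = config$backend),
                      config$backend_params))
      cr <- count_cells(ms, skip_background = config$skip_background)
      write_annotations(cr$centers, file.path(centers_dir, paste0(id, ".csv")))
      if (overlays) {
        write_overlay(img, cr$centers,
                      file.path(out_dir, "overlays", paste0(id, ".png")))
      }
      list(count = cr$n, n_masks = length(ms))
    }, error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failures <- failures + 1L
      log_lines <- c(log_lines, sprintf("image %s: FAILED (%s) [%.2fs]", id,
                                        conditionMessage(res), dt))
    } else {
      ids <- c(ids, id); counts <- c(counts, res$count)
      log_lines <- c(log_lines, sprintf(
        "image %s: %d masks -> %d cells after background skip [%.2fs]", id,
        res$n_masks, res$count, dt))
      if (config$log_level == "info") {
        message(sprintf("%s: %d cells", id, res$count))
      }
    }
  }
  if (length(ids) == 0L) {
    stop("all images failed; see run_log.txt", call. = FALSE)
  }
  counts_df <- data.frame(image_id = ids, count = counts,
                          stringsAsFactors = FALSE)
  utils::write.csv(counts_df, file.path(out_dir, "counts.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(counts_df)
}

#' Evaluate predicted counts against ground truth
#'
#' Joins a predicted-count table and a true-count table on `image_id` and
#' emits the density-stratified MAE/AAE report. Every id must be present
#' in both tables; unmatched ids raise an error naming them.
#'
#' @param pred_csv CSV `image_id,count` of predictions (e.g. the
#'   `counts.csv` from [run_pipeline()]).
#' @param truth_csv CSV of true counts: either `image_id,count` or a
#'   dataset manifest with `image_id,true_count`.
#' @param config [pipeline_config()] supplying the evaluation thresholds.
#' @return report data frame from [stratified_report()].
#' @export
run_eval <- function(pred_csv, truth_csv, config = pipeline_config()) {
  pred <- read_counts(pred_csv)
  truth <- utils::read.csv(truth_csv, stringsAsFactors = FALSE)
  if (!"image_id" %in% names(truth)) {
    stop(sprintf("truth table '%s' must have an image_id column", truth_csv),
         call. = FALSE)
  }
  tc <- if ("true_count" %in% names(truth)) truth$true_count else truth$count
  if (is.null(tc)) {
    stop(sprintf("truth table '%s' must have a count or true_count column",
                 truth_csv), call. = FALSE)
  }
  truth <- data.frame(image_id = as.character(truth$image_id),
                      true_count = as.integer(tc), stringsAsFactors = FALSE)
  missing_truth <- setdiff(pred$image_id, truth$image_id)
  missing_pred <- setdiff(truth$image_id, pred$image_id)
  if (length(missing_truth) || length(missing_pred)) {
    stop(sprintf(
      "unmatched image ids; missing from truth: [%s]; missing from predictions: [%s]",
      paste(missing_truth, collapse = ", "),
      paste(missing_pred, collapse = ", ")), call. = FALSE)
  }
  records <- merge(truth, data.frame(image_id = pred$image_id,
                                     pred_count = pred$count,
                                     stringsAsFactors = FALSE),
                   by = "image_id")
  stratified_report(records, aae_threshold = config$aae_threshold,
                    density_threshold = config$density_threshold)
}
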