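#' Mean absolute error of per-image cell counts
#'
#' `MAE = mean(|C_i - Chat_i|)` over images, where `C_i` is the true and
#' `Chat_i` the predicted count. Lower is better; 0 means every prediction
#' is exact.
#'
#' @param records data frame with columns `true_count` and `pred_count`
#'   (one row per image; an `image_id` column is carried along if present).
#' @return numeric scalar >= 0.
#' @export
mae <- function(records) {
  .check_records(records)
  mean(abs(records$true_count - records$pred_count))
}

#' Acceptable absolute error percentage
#'
#' The percentage of images whose predicted count lies within `threshold`
#' cells of the true count: `100 * mean(|C_i - Chat_i| <= T)`, inclusive at
#' equality. Higher is better; 100 means every image is within tolerance.
#'
#' @param records data frame with columns `true_count` and `pred_count`.
#' @param threshold acceptance band `T` in cells (> 0). Default 10.
#' @return percentage in `[0, 100]`.
#' @export
aae <- function(records, threshold = 10) {
  .check_records(records)
  if (!(threshold > 0)) stop("`threshold` must be positive", call. = FALSE)
  100 * mean(abs(records$true_count - records$pred_count) <= threshold)
}

.check_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("true_count", "pred_count") %in% names(records))) {
    stop("`records` must be a data frame with true_count and pred_count",
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("`records` must contain at least one image", call. = FALSE)
  }
  if (any(records$true_count < 0) || any(records$pred_count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  invisible(records)
}

#' Density-stratified counting-error report
#'
#' Splits the evaluation into low-density (true count <= the density
#' threshold, boundary inclusive) and high-density images and reports MAE
#' and AAE per stratum plus overall. A stratum with no images is absent
#' from the report rather than reported as zero.
#'
#' @param records data frame with columns `true_count` and `pred_count`.
#' @param aae_threshold AAE band `T` in cells. Default 10.
#' @param density_threshold stratum boundary in cells (low stratum is
#'   `true_count <= density_threshold`). Default 100.
#' @return data frame with columns `stratum` (`"low"`, `"high"`,
#'   `"overall"`), `n_images`, `mae`, `aae`. Full precision; round for
#'   display only.
#' @export
stratified_report <- function(records, aae_threshold = 10,
                              density_threshold = 100) {
  .check_records(records)
  if (!(density_threshold > 0)) {
    stop("`density_threshold` must be positive", call. = FALSE)
  }
  low <- records[records$true_count <= density_threshold, , drop = FALSE]
  high <- records[records$true_count > density_threshold, , drop = FALSE]
  row_for <- function(name, sub) {
    if (nrow(sub) == 0L) return(NULL)
    data.frame(stratum = name, n_images = nrow(sub), mae = mae(sub),
               aae = aae(sub, aae_threshold), stringsAsFactors = FALSE)
  }
  out <- rbind(row_for("low", low), row_for("high", high),
               row_for("overall", records))
  rownames(out) <- NULL
  out
}
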