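#' Bounding box of a binary mask
#'
#' Coordinates are 0-based with `x` the column index and `y` the row index.
#' The box is `(x, y, w, h)` where `x = min(x)`, `y = min(y)`,
#' `w = max(x) - x`, `h = max(y) - y` over the mask's nonzero pixels — the
#' max-minus-min convention, so a single-pixel mask has `w = h = 0`.
#'
#' @param mask binary matrix with at least one nonzero pixel.
#' @return named list `(x, y, w, h)` of class `bbox`.
#' @export
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("cannot compute the bounding box of an empty mask", call. = FALSE)
  }
  xs <- idx[, 2L] - 1L  # 0-based column
  ys <- idx[, 1L] - 1L  # 0-based row
  x <- min(xs); y <- min(ys)
  structure(list(x = x, y = y, w = max(xs) - x, h = max(ys) - y),
            class = "bbox")
}

#' Center point of a bounding box
#'
#' `cx = x + w/2`, `cy = y + h/2`, real-valued (no rounding). With the
#' max-minus-min width convention the center sits on the midpoint of the
#' occupied pixel indices.
#'
#' @param bbox box from [mask_bbox()] (or a compatible list).
#' @return named numeric vector `c(cx, cy)`.
#' @export
mask_center <- function(bbox) {
  c(cx = bbox$x + bbox$w / 2, cy = bbox$y + bbox$h / 2)
}

#' Count cells in a mask set
#'
#' Iterates over the instance masks of a segmentation result, skipping the
#' first (background) mask by default, computes each mask's bounding box
#' and center point, and returns the count with the centroids. One mask is
#' one cell; centers are neither deduplicated nor merged. Degenerate empty
#' masks (possible from a misbehaving backend) are skipped with a warning.
#'
#' @param maskset [mask_set()] from [segment()].
#' @param skip_background skip the first (largest) mask. Default TRUE; set
#'   FALSE for backends that emit no background mask.
#' @return object of class `count_result`: list with `n` (cell count),
#'   `centers` (data frame `x`, `y`), and `bboxes` (data frame `x`, `y`,
#'   `w`, `h`).
#' @export
count_cells <- function(maskset, skip_background = TRUE) {
  if (!inherits(maskset, "mask_set")) {
    stop("`maskset` must be a mask_set (see segment())", call. = FALSE)
  }
  masks <- maskset$masks
  if (length(masks) == 0L) {
    stop("mask set is empty; backends always emit at least one mask",
         call. = FALSE)
  }
  if (skip_background) masks <- masks[-1L]
  centers <- matrix(numeric(0), ncol = 2L)
  boxes <- matrix(numeric(0), ncol = 4L)
  for (m in masks) {
    if (!any(m != 0)) {
      warning("skipping an empty mask in count_cells()", call. = FALSE)
      next
    }
    b <- mask_bbox(m)
    centers <- rbind(centers, mask_center(b))
    boxes <- rbind(boxes, c(b$x, b$y, b$w, b$h))
  }
  centers <- as.data.frame(centers)
  names(centers) <- c("x", "y")
  boxes <- as.data.frame(boxes)
  if (nrow(boxes)) names(boxes) <- c("x", "y", "w", "h")
  structure(list(n = nrow(centers), centers = centers, bboxes = boxes),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %d cells\n", x$n))
  invisible(x)
}
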