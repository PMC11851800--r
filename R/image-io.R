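#' Validate an 8-bit grayscale image matrix
#'
#' The package's working representation of an image is a plain integer
#' matrix with values in `[0, 255]`, indexed `[row, col]` (so `nrow` is the
#' image height and `ncol` its width).
#'
#' @param image object to validate.
#' @param arg name used in error messages.
#' @return the image, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(image) < 1L || ncol(image) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg),
         call. = FALSE)
  }
  if (anyNA(image) || any(image < 0) || any(image > 255)) {
    stop(sprintf("`%s` must contain values in [0, 255]", arg), call. = FALSE)
  }
  if (any(image != floor(image))) {
    stop(sprintf("`%s` must contain integer intensities", arg), call. = FALSE)
  }
  invisible(image)
}

# ITU-R 601 luminance weights, applied on the 0..255 scale.
.luma_601 <- c(0.299, 0.587, 0.114)

#' Read an image file as an 8-bit grayscale matrix
#'
#' Reads a PNG or TIFF image (8- or 16-bit, 1 or 3 channels). RGB input is
#' converted to luminance with ITU-R 601 weights; 16-bit input is linearly
#' rescaled to `[0, 255]`. An alpha channel, if present, is discarded.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return integer matrix `[H, W]` with values in `[0, 255]`.
#' @seealso [write_image()], [read_annotations()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop(sprintf(
                     "cannot read '%s' as PNG: %s", path, conditionMessage(e)),
                     call. = FALSE)),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop(sprintf(
                      "cannot read '%s' as TIFF: %s", path, conditionMessage(e)),
                      call. = FALSE)),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext),
         call. = FALSE)
  )
  if (length(arr) == 0L) {
    stop(sprintf("zero-sized image: '%s'", path), call. = FALSE)
  }
  # readPNG/readTIFF return values in [0, 1] regardless of bit depth, so the
  # 16-bit case reduces to the same linear rescale.
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      g <- .luma_601[1L] * arr[, , 1L] + .luma_601[2L] * arr[, , 2L] +
        .luma_601[3L] * arr[, , 3L]
    } else {
      g <- arr[, , 1L]
    }
    g <- matrix(g, dim(arr)[1L], dim(arr)[2L])  # 1x1 input drops dims
  } else {
    g <- arr
  }
  img <- round_half_up(g * 255)
  img[img > 255] <- 255
  img[img < 0] <- 0
  storage.mode(img) <- "integer"
  validate_gray_image(img)
  img
}

#' Write a grayscale matrix as an 8-bit PNG
#'
#' @param image integer matrix in `[0, 255]`.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  validate_gray_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read point annotations (cell centroids) from CSV
#'
#' The annotation dialect is a CSV with header `x,y` and one row per cell
#' centroid; `x` is the 0-based column coordinate and `y` the 0-based row
#' coordinate.
#'
#' @param path path to the CSV file.
#' @return data frame with numeric columns `x` and `y`; zero rows for an
#'   annotation file that contains only the header.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop(sprintf("annotation file '%s' is empty (header 'x,y' expected)", path),
         call. = FALSE)
  }
  header <- tolower(gsub("[[:space:]\"]", "", lines[1L]))
  if (header != "x,y") {
    stop(sprintf("annotation file '%s': missing 'x,y' header (line 1)", path),
         call. = FALSE)
  }
  if (length(lines) == 1L) {
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  parts <- strsplit(lines[-1L], ",", fixed = TRUE)
  bad_shape <- which(lengths(parts) != 2L)
  if (length(bad_shape)) {
    stop(sprintf("annotation file '%s': malformed row at line %d", path,
                 bad_shape[1L] + 1L), call. = FALSE)
  }
  m <- suppressWarnings(
    matrix(as.numeric(trimws(unlist(parts))), ncol = 2L, byrow = TRUE))
  bad <- which(rowSums(is.na(m)) > 0L)
  if (length(bad)) {
    stop(sprintf("annotation file '%s': non-numeric row at line %d", path,
                 bad[1L] + 1L), call. = FALSE)
  }
  data.frame(x = m[, 1L], y = m[, 2L])
}

#' Write point annotations (cell centroids) to CSV
#'
#' @param points data frame with columns `x` and `y` (0-based image
#'   coordinates; `x` = column, `y` = row).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(points, path) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  utils::write.csv(points[, c("x", "y"), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a predicted- or true-count table
#'
#' @param path CSV with columns `image_id,count` (any further columns kept).
#' @return data frame with character `image_id` and integer `count`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("count table not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "count") %in% names(df))) {
    stop(sprintf("count table '%s' must have columns image_id,count", path),
         call. = FALSE)
  }
  df$image_id <- as.character(df$image_id)
  df$count <- as.integer(df$count)
  df
}

# round-half-up, unlike base round()'s round-half-even
round_half_up <- function(x) floor(x + 0.5)
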