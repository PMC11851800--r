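# 3x5 bitmap font for the count badge digits, column-major strings per digit
.digit_font <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "010", "010", "010"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111")
)

# distinct fully-saturated marker colors; golden-angle hue spacing keeps any
# number of markers visually separable and never gray
marker_palette <- function(n) {
  if (n == 0L) return(character(0))
  h <- (0.11 + 0.61803398875 * (seq_len(n) - 1L)) %% 1
  grDevices::hsv(h = h, s = 1, v = 1)
}

#' Render a count overlay and write it as an RGB PNG
#'
#' Draws one distinctly-colored cross marker per centroid over the grayscale
#' image and stamps the total count in a green badge in the top-right
#' corner, then writes the result as an RGB PNG of the same height and
#' width as the input.
#'
#' @param image integer matrix in `[0, 255]`.
#' @param centers data frame with columns `x`, `y` (0-based; `x` = column,
#'   `y` = row), one row per cell centroid. Must lie within the image.
#' @param path output PNG path.
#' @param marker_half_size cross arm length in pixels.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, centers, path, marker_half_size = 2L) {
  validate_gray_image(image)
  stopifnot(is.data.frame(centers), all(c("x", "y") %in% names(centers)))
  H <- nrow(image); W <- ncol(image)
  n <- nrow(centers)
  if (n > 0L && (any(centers$x < 0) || any(centers$x >= W) ||
                 any(centers$y < 0) || any(centers$y >= H))) {
    stop("overlay centers must lie within the image bounds", call. = FALSE)
  }
  rgb <- array(rep(image / 255, 3L), dim = c(H, W, 3L))

  if (n > 0L) {
    cols <- grDevices::col2rgb(marker_palette(n)) / 255
    for (k in seq_len(n)) {
      r0 <- round_half_up(centers$y[k]) + 1L  # 1-based matrix row
      c0 <- round_half_up(centers$x[k]) + 1L
      arm <- -marker_half_size:marker_half_size
      rr <- c(r0 + arm, rep(r0, length(arm)))
      cc <- c(rep(c0, length(arm)), c0 + arm)
      keep <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      rr <- rr[keep]; cc <- cc[keep]
      for (ch in 1:3) rgb[cbind(rr, cc, ch)] <- cols[ch, k]
    }
  }

  rgb <- .stamp_count_badge(rgb, n)
  png::writePNG(rgb, path)
  invisible(path)
}

# green badge with the count in white 3x5 digits (scaled 2x), top-right
.stamp_count_badge <- function(rgb, count) {
  H <- dim(rgb)[1L]; W <- dim(rgb)[2L]
  digits <- strsplit(as.character(count), "")[[1L]]
  s <- 2L                                   # font scale
  gw <- 3L * s; gh <- 5L * s; gap <- s      # glyph metrics
  pad <- s
  bw <- pad * 2L + length(digits) * gw + (length(digits) - 1L) * gap
  bh <- pad * 2L + gh
  if (bw > W || bh > H) return(rgb)         # image too small for a badge
  top <- 1L; left <- W - bw + 1L
  badge_col <- c(0, 0.69, 0)
  for (ch in 1:3) rgb[top:(top + bh - 1L), left:(left + bw - 1L), ch] <- badge_col[ch]
  gx <- left + pad
  for (d in digits) {
    glyph <- .digit_font[[d]]
    for (row in 1:5) {
      bits <- strsplit(glyph[row], "")[[1L]] == "1"
      for (col in 1:3) {
        if (!bits[col]) next
        rr <- (top + pad + (row - 1L) * s):(top + pad + row * s - 1L)
        cc <- (gx + (col - 1L) * s):(gx + col * s - 1L)
        rgb[rr, cc, ] <- 1
      }
    }
    gx <- gx + gw + gap
  }
  rgb
}
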