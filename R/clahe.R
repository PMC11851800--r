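#' CLAHE parameters
#'
#' Parameter bundle for contrast-limited adaptive histogram equalization.
#' The image is divided into non-overlapping square tiles of
#' `tile_size` x `tile_size` pixels; each tile's intensity histogram is
#' clipped at an absolute per-bin ceiling
#' `beta = max(1, clip_limit * n_tile / n_levels)` (the normalized-clip
#' convention: `clip_limit = 1` caps every bin at the count a perfectly
#' uniform tile histogram would have), the clipped excess is redistributed
#' uniformly over all bins, and each tile's cumulative probability
#' distribution `P(f)` is turned into the intensity mapping
#' `p = (p_max - p_min) * P(f) + g_min`. Pixels are remapped by bilinear
#' interpolation between the mappings of the four surrounding tile centers.
#'
#' @param tile_size tile side in pixels (>= 2). Default 8, i.e. 64-pixel
#'   neighborhoods.
#' @param clip_limit dimensionless clip factor in (0, 1]. Default 0.8.
#' @param n_levels number of intensity levels L (>= 2). Default 256.
#' @param p_min,p_max minimum / maximum output pixel value of the mapping.
#' @param g_min minimum grayscale value of the normalized range
#'   (`g_min <= p_min`); the additive offset of the mapping.
#' @return object of class `clahe_params`.
#' @export
clahe_params <- function(tile_size = 8L, clip_limit = 0.8, n_levels = 256L,
                         p_min = 0, p_max = 255, g_min = 0) {
  tile_size <- as.integer(tile_size)
  n_levels <- as.integer(n_levels)
  if (tile_size < 2L) stop("tile_size must be >= 2", call. = FALSE)
  if (!(clip_limit > 0 && clip_limit <= 1)) {
    stop("clip_limit must be in (0, 1]", call. = FALSE)
  }
  if (n_levels < 2L) stop("n_levels must be >= 2", call. = FALSE)
  if (!(p_min < p_max)) stop("p_min must be < p_max", call. = FALSE)
  if (g_min > p_min) stop("g_min must be <= p_min", call. = FALSE)
  structure(list(tile_size = tile_size, clip_limit = clip_limit,
                 n_levels = n_levels, p_min = p_min, p_max = p_max,
                 g_min = g_min),
            class = "clahe_params")
}

# symmetric reflection indices: 1..n extended to length m (edge included),
# folding back and forth for extensions longer than the source
reflect_indices <- function(n, m) {
  idx <- 0:(m - 1L)
  period <- 2L * n
  j <- idx %% period
  j <- ifelse(j >= n, period - 1L - j, j)
  j + 1L
}

#' Partition an image into non-overlapping tiles
#'
#' Reflect-pads the image on the bottom and right to multiples of the tile
#' size, then records the tile grid. The padding is stripped again after
#' remapping, so outputs always match the input dimensions.
#'
#' @param image integer matrix in `[0, 255]`.
#' @param params [clahe_params()].
#' @return list with `padded` (the padded image), `grid_rows`, `grid_cols`
#'   (tile grid dimensions), `pad_rows`, `pad_cols` (padding added), and
#'   `tile_size`.
#' @export
tile_partition <- function(image, params = clahe_params()) {
  validate_gray_image(image)
  t <- params$tile_size
  H <- nrow(image); W <- ncol(image)
  gr <- ceiling(H / t); gc <- ceiling(W / t)
  Hp <- gr * t; Wp <- gc * t
  padded <- image[reflect_indices(H, Hp), reflect_indices(W, Wp), drop = FALSE]
  list(padded = padded, grid_rows = gr, grid_cols = gc,
       pad_rows = Hp - H, pad_cols = Wp - W, tile_size = t)
}

# quantize 8-bit intensities to L levels (identity for L = 256)
quantize_levels <- function(values, n_levels) {
  q <- floor(values * n_levels / 256)
  q[q > n_levels - 1L] <- n_levels - 1L
  q
}

#' Intensity histogram of one tile
#'
#' @param tile numeric matrix of pixel intensities in `[0, 255]`.
#' @param params [clahe_params()].
#' @return list with `counts` (length `n_levels`, summing to the tile pixel
#'   count) and `n_tile` (pixels in the tile), class `clahe_histogram`.
#' @export
tile_histogram <- function(tile, params = clahe_params()) {
  L <- params$n_levels
  q <- quantize_levels(as.vector(tile), L)
  structure(list(counts = tabulate(q + 1L, nbins = L), n_tile = length(q)),
            class = "clahe_histogram")
}

#' Clip a tile histogram and redistribute the excess
#'
#' Each bin is capped at `beta = max(1, clip_limit * n_tile / n_levels)`;
#' the total excess is redistributed uniformly, `excess / n_levels` added
#' to every bin in a single real-valued pass. The histogram sum is
#' preserved exactly.
#'
#' @param hist histogram from [tile_histogram()] (or a compatible list with
#'   `counts` and `n_tile`).
#' @param params [clahe_params()].
#' @return clipped histogram of class `clahe_histogram` (counts may be
#'   fractional after redistribution).
#' @export
clip_histogram <- function(hist, params = clahe_params()) {
  counts <- hist$counts
  L <- params$n_levels
  if (length(counts) != L) {
    stop("histogram length does not match n_levels", call. = FALSE)
  }
  beta <- max(1, params$clip_limit * hist$n_tile / L)
  clipped <- pmin(counts, beta)
  excess <- sum(counts - clipped)
  structure(list(counts = clipped + excess / L, n_tile = hist$n_tile),
            class = "clahe_histogram")
}

#' Build a tile's intensity mapping from its clipped histogram
#'
#' The cumulative probability distribution
#' `P(f) = sum(H[0..f]) / sum(H[0..L-1])` is mapped to output intensities
#' by `lut[f] = (p_max - p_min) * P(f) + g_min`. The mapping is monotone
#' non-decreasing and reaches `p_max` at the top level whenever
#' `g_min == p_min`.
#'
#' @param hist clipped histogram from [clip_histogram()].
#' @param params [clahe_params()].
#' @return list of class `tile_mapping` with `lut`, a numeric vector of
#'   length `n_levels` (real-valued; rounding happens after interpolation).
#' @export
cumulative_mapping <- function(hist, params = clahe_params()) {
  counts <- hist$counts
  total <- sum(counts)
  if (total <= 0) {
    stop("cannot build a mapping from an all-zero histogram", call. = FALSE)
  }
  P <- cumsum(counts) / total
  lut <- (params$p_max - params$p_min) * P + params$g_min
  structure(list(lut = lut), class = "tile_mapping")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Applies CLAHE to an 8-bit grayscale image: per-tile clipped histograms,
#' cumulative-probability intensity mappings, and bilinear remapping
#' between tile centers. Pixels outside the outermost tile centers use the
#' nearest row/column of tile mappings. The interpolated value is rounded
#' half-up to an integer and clamped to `[g_min, p_max]`; the output has
#' exactly the input dimensions for any image size.
#'
#' @param image integer matrix in `[0, 255]`.
#' @param params [clahe_params()].
#' @return integer matrix of the same dimensions as `image`.
#' @examples
#' img <- matrix(rep(c(10L, 200L), each = 128), 16, 16)
#' out <- apply_clahe(img, clahe_params(tile_size = 8, clip_limit = 0.8))
#' dim(out)
#' @export
apply_clahe <- function(image, params = clahe_params()) {
  validate_gray_image(image)
  part <- tile_partition(image, params)
  t <- params$tile_size
  L <- params$n_levels
  P <- part$padded
  gr <- part$grid_rows; gc <- part$grid_cols
  Hp <- nrow(P); Wp <- ncol(P)

  # one lut per tile, tiles indexed column-major: (j - 1) * gr + i
  luts <- matrix(0, gr * gc, L)
  for (j in seq_len(gc)) {
    for (i in seq_len(gr)) {
      tile <- P[((i - 1L) * t + 1L):(i * t), ((j - 1L) * t + 1L):(j * t)]
      h <- clip_histogram(tile_histogram(tile, params), params)
      luts[(j - 1L) * gr + i, ] <- cumulative_mapping(h, params)$lut
    }
  }

  # fractional tile coordinates of every pixel relative to tile centers
  # (0-based pixel r sits at tile position (r - (t-1)/2) / t)
  tr <- ((0:(Hp - 1L)) - (t - 1) / 2) / t
  tc <- ((0:(Wp - 1L)) - (t - 1) / 2) / t
  i0 <- floor(tr); wy <- tr - i0
  j0 <- floor(tc); wx <- tc - j0
  i0c <- pmin(pmax(i0, 0), gr - 1L); i1c <- pmin(i0 + 1, gr - 1L)
  j0c <- pmin(pmax(j0, 0), gc - 1L); j1c <- pmin(j0 + 1, gc - 1L)

  f <- quantize_levels(P, L)                      # Hp x Wp level matrix
  WY <- matrix(wy, Hp, Wp); WX <- matrix(wx, Hp, Wp, byrow = TRUE)
  I0 <- matrix(i0c, Hp, Wp); I1 <- matrix(i1c, Hp, Wp)
  J0 <- matrix(j0c, Hp, Wp, byrow = TRUE); J1 <- matrix(j1c, Hp, Wp, byrow = TRUE)
  fv <- as.vector(f) + 1L

  v00 <- luts[cbind(as.vector(J0 * gr + I0 + 1), fv)]
  v01 <- luts[cbind(as.vector(J1 * gr + I0 + 1), fv)]
  v10 <- luts[cbind(as.vector(J0 * gr + I1 + 1), fv)]
  v11 <- luts[cbind(as.vector(J1 * gr + I1 + 1), fv)]
  wyv <- as.vector(WY); wxv <- as.vector(WX)

  out <- (1 - wyv) * (1 - wxv) * v00 + (1 - wyv) * wxv * v01 +
    wyv * (1 - wxv) * v10 + wyv * wxv * v11
  out <- round_half_up(out)
  out[out < params$g_min] <- params$g_min
  out[out > params$p_max] <- params$p_max
  out <- matrix(out, Hp, Wp)[seq_len(nrow(image)), seq_len(ncol(image)),
                             drop = FALSE]
  storage.mode(out) <- "integer"
  out
}
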