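# Independent per-pixel CLAHE reference. Deliberately naive: for every
# output pixel it re-derives the (up to) four surrounding tiles' clipped
# histograms and cumulative mappings from the padded image and blends them,
# with no shared code or cached state from the package's implementation.
clahe_oracle <- function(image, tile_size = 8, clip_limit = 0.8,
                         n_levels = 256, p_min = 0, p_max = 255, g_min = 0) {
  H <- nrow(image); W <- ncol(image)
  t <- tile_size; L <- n_levels
  gr <- ceiling(H / t); gc <- ceiling(W / t)

  # symmetric reflect padding (edge included), bottom/right
  refl <- function(n, m) {
    i <- (0:(m - 1)) %% (2 * n)
    ifelse(i >= n, 2 * n - 1 - i, i) + 1
  }
  P <- image[refl(H, gr * t), refl(W, gc * t), drop = FALSE]

  lut_of_tile <- function(ti, tj) {
    tile <- P[((ti - 1) * t + 1):(ti * t), ((tj - 1) * t + 1):(tj * t)]
    q <- floor(as.vector(tile) * L / 256)
    q[q > L - 1] <- L - 1
    hist <- tabulate(q + 1, nbins = L)
    beta <- max(1, clip_limit * length(q) / L)
    clipped <- pmin(hist, beta)
    clipped <- clipped + sum(hist - clipped) / L
    (p_max - p_min) * (cumsum(clipped) / sum(clipped)) + g_min
  }

  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      tr <- ((r - 1) - (t - 1) / 2) / t
      tc <- ((cc - 1) - (t - 1) / 2) / t
      i0 <- floor(tr); wy <- tr - i0
      j0 <- floor(tc); wx <- tc - j0
      clampi <- function(i) min(max(i, 0), gr - 1)
      clampj <- function(j) min(max(j, 0), gc - 1)
      f <- floor(P[r, cc] * L / 256)
      if (f > L - 1) f <- L - 1
      v00 <- lut_of_tile(clampi(i0) + 1, clampj(j0) + 1)[f + 1]
      v01 <- lut_of_tile(clampi(i0) + 1, clampj(j0 + 1) + 1)[f + 1]
      v10 <- lut_of_tile(clampi(i0 + 1) + 1, clampj(j0) + 1)[f + 1]
      v11 <- lut_of_tile(clampi(i0 + 1) + 1, clampj(j0 + 1) + 1)[f + 1]
      v <- (1 - wy) * (1 - wx) * v00 + (1 - wy) * wx * v01 +
        wy * (1 - wx) * v10 + wy * wx * v11
      out[r, cc] <- min(max(floor(v + 0.5), g_min), p_max)
    }
  }
  storage.mode(out) <- "integer"
  out
}

# random 8-bit test image
random_image <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# solid axis-aligned rectangle mask in an H x W image, 1-based pixel bounds
rect_mask <- function(H, W, r1, r2, c1, c2) {
  m <- matrix(0L, H, W)
  m[r1:r2, c1:c2] <- 1L
  m
}
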