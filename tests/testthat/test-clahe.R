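test_that("tile_partition pads to tile multiples and records the grid", {
  p <- clahe_params(tile_size = 8)
  part <- tile_partition(random_image(16, 16, seed = 1), p)
  expect_equal(c(part$grid_rows, part$grid_cols), c(2, 2))
  expect_equal(c(part$pad_rows, part$pad_cols), c(0, 0))

  part <- tile_partition(random_image(10, 10, seed = 2), p)
  expect_equal(c(part$grid_rows, part$grid_cols), c(2, 2))
  expect_equal(c(part$pad_rows, part$pad_cols), c(6, 6))
  expect_equal(dim(part$padded), c(16, 16))

  # 3x3 reflect-padded to one 8x8 tile: symmetric fold 1,2,3,3,2,1,1,2
  img3 <- matrix(1:9, 3, 3)
  part <- tile_partition(img3 * 10L, p)
  expect_equal(c(part$grid_rows, part$grid_cols), c(1, 1))
  fold <- c(1, 2, 3, 3, 2, 1, 1, 2)
  expect_equal(part$padded, (img3 * 10L)[fold, fold])
})

test_that("tile_histogram counts levels; sum equals the tile pixel count", {
  p <- clahe_params(tile_size = 8)
  h <- tile_histogram(matrix(7L, 8, 8), p)
  expect_equal(h$counts[8], 64)
  expect_equal(sum(h$counts), 64)

  h <- tile_histogram(matrix(0:63, 8, 8), p)
  expect_equal(h$counts[1:64], rep(1, 64))

  cb <- matrix(0L, 8, 8); cb[(row(cb) + col(cb)) %% 2 == 0] <- 255L
  h <- tile_histogram(cb, p)
  expect_equal(h$counts[1], 32)
  expect_equal(h$counts[256], 32)
})

test_that("clip_histogram caps bins at beta and redistributes excess exactly", {
  p <- clahe_params(tile_size = 4, clip_limit = 0.5, n_levels = 4, p_max = 3)
  h <- structure(list(counts = c(5, 1, 0, 0), n_tile = 16),
                 class = "clahe_histogram")
  out <- clip_histogram(h, p)
  expect_equal(out$counts, c(2.75, 1.75, 0.75, 0.75))

  # a uniform histogram below the clip is unchanged
  p2 <- clahe_params(tile_size = 8, clip_limit = 1, n_levels = 256)
  hu <- structure(list(counts = rep(0.25, 256), n_tile = 64),
                  class = "clahe_histogram")
  expect_equal(clip_histogram(hu, p2)$counts, rep(0.25, 256))

  # sum conservation on random histograms
  set.seed(31)
  for (i in 1:25) {
    counts <- rpois(256, 2)
    hh <- structure(list(counts = counts, n_tile = 64),
                    class = "clahe_histogram")
    cl <- clahe_params(clip_limit = runif(1, 0.05, 1))
    expect_lt(abs(sum(clip_histogram(hh, cl)$counts) - sum(counts)), 1e-9)
  }
})

test_that("cumulative_mapping evaluates the CPD intensity mapping", {
  p <- clahe_params(tile_size = 4, n_levels = 4, p_max = 3)
  h <- structure(list(counts = c(1, 1, 1, 1), n_tile = 4),
                 class = "clahe_histogram")
  expect_equal(cumulative_mapping(h, p)$lut, c(0.75, 1.5, 2.25, 3))

  # all mass at the top level: a step mapping
  h2 <- structure(list(counts = c(0, 0, 0, 8), n_tile = 8),
                  class = "clahe_histogram")
  expect_equal(cumulative_mapping(h2, p)$lut, c(0, 0, 0, 3))

  # top level always maps to p_max; lut monotone for random histograms
  set.seed(7)
  for (i in 1:25) {
    counts <- runif(256, 0, 4)
    hh <- structure(list(counts = counts, n_tile = 64),
                    class = "clahe_histogram")
    lut <- cumulative_mapping(hh, clahe_params())$lut
    expect_equal(lut[256], 255)
    expect_true(all(diff(lut) >= 0))
  }

  expect_error(cumulative_mapping(
    structure(list(counts = rep(0, 256), n_tile = 64),
              class = "clahe_histogram"), clahe_params()), "all-zero")
})

test_that("apply_clahe maps a constant image to a constant image", {
  out <- apply_clahe(matrix(100L, 16, 16), clahe_params())
  expect_equal(length(unique(as.vector(out))), 1)
})

test_that("apply_clahe matches the per-pixel oracle on a two-tone image", {
  img <- matrix(30L, 16, 16)
  img[, 9:16] <- 200L
  p <- clahe_params(tile_size = 8, clip_limit = 1.0)
  expect_identical(apply_clahe(img, p),
                   clahe_oracle(img, tile_size = 8, clip_limit = 1.0))
})

test_that("apply_clahe preserves shape and range at default parameters", {
  for (d in list(c(8, 8), c(10, 13), c(17, 5), c(32, 32), c(3, 3))) {
    img <- random_image(d[1], d[2], seed = d[1] * 100 + d[2])
    out <- apply_clahe(img, clahe_params())
    expect_equal(dim(out), d)
    expect_true(all(out >= 0 & out <= 255))
  }
})

test_that("equalization spreads a low-contrast image's histogram", {
  set.seed(5)
  img <- matrix(as.integer(pmin(pmax(round(rnorm(64 * 64, 60, 5)), 0), 255)),
                64, 64)
  out <- apply_clahe(img, clahe_params())
  expect_gt(diff(range(out)), diff(range(img)))
})
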