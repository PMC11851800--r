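test_that("reference backend finds a bright square on a dark field", {
  img <- matrix(10L, 12, 12)
  img[5:7, 4:6] <- 200L
  ms <- reference_backend(img, min_area = 1)
  expect_s3_class(ms, "mask_set")
  expect_length(ms, 2)
  expect_equal(sum(ms$masks[[2]]), 9)        # the 3x3 square
  expect_equal(sum(ms$masks[[1]]), 144 - 9)  # background first (largest)

  # min_area filters the 9-pixel component away
  ms2 <- reference_backend(img, min_area = 10)
  expect_length(ms2, 1)
  expect_true(all(ms2$masks[[1]]))
})

test_that("a blank image yields a background-only mask set and count 0", {
  ms <- reference_backend(matrix(42L, 9, 9))
  expect_length(ms, 1)
  expect_equal(count_cells(ms)$n, 0)
})

test_that("diagonally touching squares merge under 8-connectivity", {
  img <- matrix(0L, 10, 10)
  img[2:3, 2:3] <- 255L
  img[4:5, 4:5] <- 255L   # touches the first only at a corner
  ms <- reference_backend(img)
  expect_length(ms, 2)    # background + one merged component
  expect_equal(sum(ms$masks[[2]]), 8)
})

test_that("polarity auto-chooses the minority class as foreground", {
  # dark cells on a bright field
  img <- matrix(230L, 20, 20)
  img[3:5, 3:5] <- 40L
  img[12:14, 15:17] <- 40L
  ms <- reference_backend(img)
  expect_length(ms, 3)
  expect_equal(sort(ms$areas[-1]), c(9, 9))
})

test_that("mask sets are sorted area-descending with background first", {
  set.seed(19)
  for (rep in 1:10) {
    img <- matrix(5L, 40, 40)
    n <- sample(2:6, 1)
    r <- 0
    for (k in seq_len(n)) {
      sz <- sample(2:4, 1)
      r1 <- 1 + (k - 1) * 7
      img[r1:(r1 + sz - 1), r1:(r1 + sz - 1)] <- 220L
    }
    ms <- segment(img, "reference")
    expect_true(all(diff(ms$areas) <= 0))
    expect_equal(which.max(ms$areas), 1)
    # partition property: every pixel covered exactly once
    cover <- Reduce(`+`, lapply(ms$masks, `+`, 0))
    expect_true(all(cover == 1))
  }
})

test_that("reference backend recovers generator cells one-to-one on clean renders", {
  pr <- synth_profile("custom", width = 96, height = 96, count_mean = 5,
                      count_sd = 2, noise_sd = 0, illumination_amplitude = 0,
                      radius_range = c(3, 6), min_separation = 14, seed = 23)
  for (i in 1:5) {
    s <- generate_image(pr, i)
    ms <- reference_backend(s$image)
    expect_length(ms, nrow(s$truth) + 1)
    # instance masks match rendered disks pixel-exactly
    fg <- Reduce(`|`, ms$masks[-1])
    expect_identical(fg, s$label_map > 0)
  }
})

test_that("the mask generator adapter honors the prompt-free contract", {
  img <- matrix(50L, 16, 16)
  stub3 <- function(image) {
    list(rect_mask(16, 16, 2, 4, 2, 4),
         rect_mask(16, 16, 7, 8, 7, 10),
         rect_mask(16, 16, 12, 14, 3, 5))
  }
  ms <- sam_backend(img, generator = stub3)
  expect_length(ms, 4)  # 3 instances + synthesized background
  expect_equal(which.max(ms$areas), 1)

  # zero instances: background only, downstream count 0
  ms0 <- sam_backend(img, generator = function(image) list())
  expect_length(ms0, 1)
  expect_equal(count_cells(ms0)$n, 0)

  # overlapping instances are both retained (no dedup)
  stub_overlap <- function(image) {
    list(rect_mask(16, 16, 2, 6, 2, 6), rect_mask(16, 16, 4, 8, 4, 8))
  }
  expect_length(sam_backend(img, generator = stub_overlap), 3)

  # segment() accepts a generator function directly
  expect_length(segment(img, backend = stub3), 4)
})

test_that("the model-weight backend raises a capability error when unavailable", {
  img <- matrix(50L, 8, 8)
  expect_error(sam_backend(img), "checkpoint")
  expect_error(segment(img, "sam", checkpoint = "no/such/weights.pth"),
               "checkpoint")
})
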