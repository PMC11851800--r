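test_that("named profiles carry the documented count statistics", {
  expect_equal(synth_profile("idcia_like")$count_mean, 83)
  expect_equal(synth_profile("idcia_like")$count_sd, 104)
  expect_equal(synth_profile("vgg_like")$count_mean, 174)
  expect_equal(synth_profile("vgg_like")$count_sd, 64)
  expect_equal(synth_profile("adc_like")$count_mean, 165)
  expect_equal(synth_profile("adc_like")$count_sd, 44)
  expect_equal(synth_profile("adc_like")$background_mode, "bright_field")
  # each default separation keeps clean cells disjoint
  for (nm in c("idcia_like", "vgg_like", "adc_like")) {
    p <- synth_profile(nm)
    expect_gte(p$min_separation, 2 * p$radius_range[2] + 2)
  }
})

test_that("draw_count: degenerate sd, floor at 1, and moment recovery", {
  p0 <- synth_profile("custom", count_mean = 12.4, count_sd = 0)
  expect_equal(draw_count(p0, 5), rep(12L, 5))

  # heavy-tailed profile never draws below 1
  p <- synth_profile("idcia_like", seed = 42)
  x <- draw_count(p, 2000)
  expect_true(all(x >= 1))

  # sample mean within 3 standard errors of the profile mean
  expect_lt(abs(mean(x) - 83), 3 * 104 / sqrt(2000))
  v <- draw_count(synth_profile("vgg_like", seed = 42), 2000)
  expect_lt(abs(mean(v) - 174), 3 * 64 / sqrt(2000))
})

test_that("generate_image is deterministic and leaves global RNG untouched", {
  p <- synth_profile("custom", width = 64, height = 64, count_mean = 5,
                     count_sd = 2, seed = 9)
  set.seed(1234)
  before <- .Random.seed
  s1 <- generate_image(p, 3)
  expect_identical(.Random.seed, before)
  s2 <- generate_image(p, 3)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
  # a different index gives a different image
  s3 <- generate_image(p, 4)
  expect_false(identical(s1$image, s3$image))
})

test_that("placed centers honor the minimum separation", {
  p <- synth_profile("custom", width = 256, height = 256, count_mean = 10,
                     count_sd = 0, min_separation = 20, radius_range = c(3, 8),
                     seed = 5)
  s <- generate_image(p, 1)
  expect_equal(nrow(s$truth), 10)
  d <- as.matrix(dist(s$truth))
  diag(d) <- Inf
  expect_true(all(d >= 20))
})

test_that("label map and truth agree with the rendered cells", {
  p <- synth_profile("custom", width = 96, height = 96, count_mean = 6,
                     count_sd = 2, noise_sd = 0, illumination_amplitude = 0,
                     seed = 13)
  s <- generate_image(p, 2)
  expect_equal(max(s$label_map), nrow(s$truth))
  # every truth centroid is inside its own labeled disk
  for (k in seq_len(nrow(s$truth))) {
    expect_equal(s$label_map[s$truth$y[k] + 1, s$truth$x[k] + 1], k)
  }
})

test_that("an over-constrained placement reduces the count with a warning", {
  p <- synth_profile("custom", width = 48, height = 48, count_mean = 200,
                     count_sd = 0, min_separation = 20, radius_range = c(2, 4),
                     seed = 3)
  expect_warning(s <- generate_image(p, 1), "placed")
  expect_lt(nrow(s$truth), 200)
  expect_equal(max(s$label_map), nrow(s$truth))
})

test_that("generate_dataset writes consistent, reproducible files", {
  p <- synth_profile("custom", width = 48, height = 48, count_mean = 4,
                     count_sd = 1, radius_range = c(2, 4),
                     min_separation = 10, seed = 21)
  d1 <- withr::local_tempdir()
  man <- generate_dataset(p, 5, d1)
  expect_equal(nrow(man), 5)
  expect_length(list.files(d1, pattern = "\\.png$"), 5)
  for (i in seq_len(5)) {
    truth <- read_annotations(file.path(d1, paste0(man$image_id[i], ".csv")))
    expect_equal(nrow(truth), man$true_count[i])
  }
  # regeneration is byte-identical
  d2 <- withr::local_tempdir()
  generate_dataset(p, 5, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})
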