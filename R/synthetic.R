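# Run code under a private RNG stream, restoring the caller's RNG state.
# Keeps the generator free of hidden global state.
with_local_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# per-image stream seed from (dataset seed, image index); stays < 2^31
derive_seed <- function(seed, index) {
  ((seed %% 2147483647) * 48271 + index * 12345 + 1) %% 2147483647
}

#' Synthetic fluorescence-image profile
#'
#' A parameter bundle describing one family of synthetic microscopy images.
#' The three named profiles emulate public cell-counting benchmarks at the
#' level of image size, per-image count statistics (mean +/- sd), cell
#' geometry, and background character:
#'
#' * `idcia_like` — 800 x 600, 83 +/- 104 cells, bright cells on a dark,
#'   unevenly illuminated background (immunocytochemistry-like).
#' * `vgg_like` — 256 x 256, 174 +/- 64 cells, small blurred bright blobs
#'   on a dark background (simulated bacterial fluorescence).
#' * `adc_like` — 500 x 500, 165 +/- 44 cells, bright field with cells
#'   delineated by darker boundaries (adipocyte-histology-like).
#'
#' Per-image counts are drawn from a lognormal distribution moment-matched
#' to (`count_mean`, `count_sd`): a normal cannot hold these moments under
#' truncation at 1 when the sd exceeds the mean (as for `idcia_like`).
#'
#' @param name `"idcia_like"`, `"vgg_like"`, `"adc_like"`, or `"custom"`.
#' @param width,height image size in pixels.
#' @param count_mean,count_sd per-image cell count moments.
#' @param radius_range min and max cell radius in pixels.
#' @param cell_peak_intensity range of per-cell peak intensities, `[0,255]`.
#' @param background_mode `"dark_gradient"` (bright cells, dark uneven
#'   background) or `"bright_field"` (bright background, darker cell rims).
#' @param illumination_amplitude peak-to-trough amplitude of the smooth
#'   illumination field, intensity units.
#' @param noise_sd Gaussian pixel noise sd, intensity units.
#' @param min_separation minimum center-to-center distance in pixels.
#'   Named-profile defaults equal `2 * max(radius_range) + 2`, so clean
#'   renders have disjoint cells.
#' @param seed RNG seed for the profile's image streams.
#' @return object of class `synth_profile`.
#' @export
synth_profile <- function(name = c("idcia_like", "vgg_like", "adc_like",
                                   "custom"),
                          width = NULL, height = NULL,
                          count_mean = NULL, count_sd = NULL,
                          radius_range = NULL, cell_peak_intensity = NULL,
                          background_mode = NULL,
                          illumination_amplitude = NULL, noise_sd = NULL,
                          min_separation = NULL, seed = 42L) {
  name <- match.arg(name)
  defaults <- switch(name,
    idcia_like = list(width = 800L, height = 600L, count_mean = 83,
                      count_sd = 104, radius_range = c(3, 8),
                      cell_peak_intensity = c(180, 255),
                      background_mode = "dark_gradient",
                      illumination_amplitude = 40, noise_sd = 8,
                      min_separation = 18),
    vgg_like = list(width = 256L, height = 256L, count_mean = 174,
                    count_sd = 64, radius_range = c(2, 5),
                    cell_peak_intensity = c(180, 255),
                    background_mode = "dark_gradient",
                    illumination_amplitude = 30, noise_sd = 6,
                    min_separation = 12),
    adc_like = list(width = 500L, height = 500L, count_mean = 165,
                    count_sd = 44, radius_range = c(5, 10),
                    cell_peak_intensity = c(180, 230),
                    background_mode = "bright_field",
                    illumination_amplitude = 15, noise_sd = 5,
                    min_separation = 22),
    custom = list(width = 256L, height = 256L, count_mean = 20,
                  count_sd = 5, radius_range = c(3, 8),
                  cell_peak_intensity = c(180, 255),
                  background_mode = "dark_gradient",
                  illumination_amplitude = 40, noise_sd = 8,
                  min_separation = 18)
  )
  p <- defaults
  override <- list(width = width, height = height, count_mean = count_mean,
                   count_sd = count_sd, radius_range = radius_range,
                   cell_peak_intensity = cell_peak_intensity,
                   background_mode = background_mode,
                   illumination_amplitude = illumination_amplitude,
                   noise_sd = noise_sd, min_separation = min_separation)
  for (k in names(override)) if (!is.null(override[[k]])) p[[k]] <- override[[k]]
  p$name <- name
  p$seed <- as.integer(seed)
  p$background_mode <- match.arg(p$background_mode,
                                 c("dark_gradient", "bright_field"))
  if (!(p$count_mean > 0)) stop("count_mean must be > 0", call. = FALSE)
  if (p$count_sd < 0) stop("count_sd must be >= 0", call. = FALSE)
  if (p$radius_range[1L] <= 0 ||
      p$radius_range[2L] >= min(p$width, p$height) / 4) {
    stop("radius_range must lie in (0, min(width, height)/4)", call. = FALSE)
  }
  structure(p, class = "synth_profile")
}

#' @export
print.synth_profile <- function(x, ...) {
  cat(sprintf(
    "<synth_profile '%s'> %dx%d px, %g +/- %g cells, %s background, seed %d\n",
    x$name, x$width, x$height, x$count_mean, x$count_sd, x$background_mode,
    x$seed))
  invisible(x)
}

#' Draw per-image cell counts for a profile
#'
#' Counts are sampled from a lognormal distribution whose mean and sd are
#' moment-matched to the profile (`sdlog^2 = log(1 + sd^2/mean^2)`,
#' `meanlog = log(mean) - sdlog^2 / 2`), rounded to integers and floored
#' at 1. With `count_sd = 0` the draw is deterministic at
#' `round(count_mean)`.
#'
#' @param profile [synth_profile()].
#' @param n number of draws.
#' @param seed RNG seed (defaults to the profile's seed).
#' @return integer vector of length `n`, all values >= 1.
#' @export
draw_count <- function(profile, n = 1L, seed = profile$seed) {
  stopifnot(inherits(profile, "synth_profile"), n >= 1L)
  m <- profile$count_mean
  s <- profile$count_sd
  if (s == 0) {
    return(rep.int(as.integer(round_half_up(m)), n))
  }
  sdlog2 <- log(1 + s^2 / m^2)
  meanlog <- log(m) - sdlog2 / 2
  x <- with_local_rng(seed,
                      stats::rlnorm(n, meanlog = meanlog, sdlog = sqrt(sdlog2)))
  as.integer(pmax(1, round_half_up(x)))
}

# rejection-sample n centers with pairwise distance >= min_sep, inside the
# margin; returns fewer than n (with a warning upstream) when the budget of
# 10 * n attempts runs out
place_centers <- function(n, width, height, margin, min_sep) {
  xs <- numeric(0); ys <- numeric(0)
  budget <- 10L * n
  lo_x <- margin; hi_x <- width - 1 - margin
  lo_y <- margin; hi_y <- height - 1 - margin
  if (hi_x < lo_x || hi_y < lo_y) {
    stop("image too small for the profile's cell radius", call. = FALSE)
  }
  while (length(xs) < n && budget > 0L) {
    budget <- budget - 1L
    cx <- round(stats::runif(1L, lo_x, hi_x))
    cy <- round(stats::runif(1L, lo_y, hi_y))
    if (length(xs) == 0L ||
        all((xs - cx)^2 + (ys - cy)^2 >= min_sep^2)) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  data.frame(x = xs, y = ys)
}

# smooth low-frequency illumination field in [0, amplitude]
illumination_field <- function(width, height, amplitude) {
  if (amplitude <= 0) return(matrix(0, height, width))
  theta <- stats::runif(1L, 0, 2 * pi)
  phase <- stats::runif(1L, 0, 2 * pi)
  xx <- matrix((0:(width - 1)) / max(1, width - 1), height, width, byrow = TRUE)
  yy <- matrix((0:(height - 1)) / max(1, height - 1), height, width)
  u <- cos(theta) * xx + sin(theta) * yy
  amplitude * (0.5 + 0.5 * sin(2 * pi * u + phase))
}

#' Generate one synthetic image with exact ground truth
#'
#' Renders a seeded fluorescence-like image: cell centers are placed by
#' rejection sampling honoring the profile's minimum separation, each cell
#' is a Gaussian-shaded disk whose radius equals the shading's half-width
#' at half-maximum (the rim renders at half the peak intensity, clearly
#' above a clean background), the background is either a dark,
#' smoothly varying illumination field (`dark_gradient`) or a bright field
#' on which cells carry darker rims (`bright_field`), and Gaussian noise is
#' added and clamped to `[0, 255]`. The label map and centroid truth are
#' recorded exactly as rendered.
#'
#' The per-image RNG stream is derived from `(profile$seed, index)`, so any
#' image of a dataset can be regenerated independently and reproducibly.
#' If the requested number of cells cannot be placed within `10 * n`
#' attempts, the image holds fewer cells and the truth records the actual
#' number (with a warning).
#'
#' @param profile [synth_profile()].
#' @param index image index within the dataset (>= 1).
#' @return list of class `synth_sample` with `image` (integer matrix),
#'   `truth` (data frame `x`, `y` of disk centers), `label_map` (integer
#'   matrix, 0 = background, k = cell k), `index`, and `profile_name`.
#' @export
generate_image <- function(profile, index = 1L) {
  stopifnot(inherits(profile, "synth_profile"), index >= 1L)
  W <- profile$width; H <- profile$height
  with_local_rng(derive_seed(profile$seed, index), {
    n_target <- draw_count(profile, 1L,
                           seed = derive_seed(profile$seed, -index))
    r_max <- profile$radius_range[2L]
    centers <- place_centers(n_target, W, H, margin = ceiling(r_max),
                             min_sep = profile$min_separation)
    n <- nrow(centers)
    if (n < n_target) {
      warning(sprintf(
        "placed %d of %d cells at min_separation %.0f (image %d)", n,
        n_target, profile$min_separation, index), call. = FALSE)
    }
    radii <- stats::runif(n, profile$radius_range[1L], profile$radius_range[2L])
    peaks <- stats::runif(n, profile$cell_peak_intensity[1L],
                          profile$cell_peak_intensity[2L])
    illum <- illumination_field(W, H, profile$illumination_amplitude)
    bright <- profile$background_mode == "bright_field"
    img <- if (bright) 235 - illum else 20 + illum
    label_map <- matrix(0L, H, W)

    for (k in seq_len(n)) {
      cx <- centers$x[k]; cy <- centers$y[k]; r <- radii[k]
      ri <- ceiling(r)
      rows <- max(1L, cy + 1L - ri):min(H, cy + 1L + ri)
      cols <- max(1L, cx + 1L - ri):min(W, cx + 1L + ri)
      dy <- (rows - 1L) - cy
      dx <- (cols - 1L) - cx
      d2 <- outer(dy^2, dx^2, `+`)
      inside <- d2 <= r^2
      if (!any(inside)) next
      if (bright) {
        # interior slightly darker than the field, rim distinctly dark
        rim <- inside & d2 > (r - 1.5)^2
        patch <- img[rows, cols, drop = FALSE]
        patch[inside] <- pmin(patch[inside], 215)
        patch[rim] <- peaks[k] / 2
        img[rows, cols] <- patch
      } else {
        # radius = half-width at half-maximum: the rim renders at half the
        # peak, keeping the whole disk well above a clean background
        sigma <- r / sqrt(2 * log(2))
        shade <- peaks[k] * exp(-d2 / (2 * sigma^2))
        patch <- img[rows, cols, drop = FALSE]
        patch[inside] <- patch[inside] + shade[inside]
        img[rows, cols] <- patch
      }
      lab <- label_map[rows, cols, drop = FALSE]
      lab[inside] <- k
      label_map[rows, cols] <- lab
    }

    if (profile$noise_sd > 0) {
      img <- img + stats::rnorm(H * W, sd = profile$noise_sd)
    }
    img <- round_half_up(img)
    img[img < 0] <- 0
    img[img > 255] <- 255
    storage.mode(img) <- "integer"
    structure(list(image = img, truth = centers, label_map = label_map,
                   index = as.integer(index), profile_name = profile$name),
              class = "synth_sample")
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG images, one ground-truth centroid CSV per image
#' (`x,y` dialect), and a manifest CSV
#' (`image_id,true_count,profile,seed`). Regenerating with the same
#' profile and seed reproduces every file byte-identically.
#'
#' @param profile [synth_profile()].
#' @param n_images number of images (>= 1).
#' @param out_dir output directory (created if needed).
#' @return the manifest data frame, invisibly written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(profile, n_images, out_dir) {
  stopifnot(inherits(profile, "synth_profile"), n_images >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }
  ids <- sprintf("%s_%04d", profile$name, seq_len(n_images))
  counts <- integer(n_images)
  for (i in seq_len(n_images)) {
    s <- generate_image(profile, i)
    write_image(s$image, file.path(out_dir, paste0(ids[i], ".png")))
    write_annotations(s$truth, file.path(out_dir, paste0(ids[i], ".csv")))
    counts[i] <- nrow(s$truth)
  }
  manifest <- data.frame(image_id = ids, true_count = counts,
                         profile = profile$name, seed = profile$seed,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
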