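#' Construct a mask set
#'
#' A mask set is the output contract of every segmentation backend: an
#' area-descending list of binary instance masks of the source image's
#' shape, each with at least one foreground pixel. The first mask is the
#' background candidate (the largest region); downstream counting skips it
#' by default.
#'
#' @param masks list of logical matrices, all of identical dimensions.
#' @param backend backend name recorded as provenance.
#' @param sort sort masks by area descending (default TRUE; the contract).
#' @return object of class `mask_set`.
#' @export
mask_set <- function(masks, backend = "unknown", sort = TRUE) {
  if (!is.list(masks) || length(masks) == 0L) {
    stop("a mask set needs at least one mask", call. = FALSE)
  }
  masks <- lapply(masks, function(m) {
    if (!is.matrix(m)) stop("each mask must be a matrix", call. = FALSE)
    m <- m != 0
    m
  })
  d <- dim(masks[[1L]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1L)))) {
    stop("all masks in a mask set must share the image shape", call. = FALSE)
  }
  areas <- vapply(masks, sum, numeric(1L))
  if (any(areas == 0)) {
    stop("masks in a mask set must have at least one nonzero pixel",
         call. = FALSE)
  }
  if (sort) {
    ord <- order(areas, decreasing = TRUE)
    masks <- masks[ord]
    areas <- areas[ord]
  }
  structure(list(masks = masks, areas = areas, backend = backend,
                 dim = d),
            class = "mask_set")
}

#' @export
length.mask_set <- function(x) length(x$masks)

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %d masks (%dx%d, backend '%s'); areas: %s\n",
              length(x$masks), x$dim[1L], x$dim[2L], x$backend,
              paste(utils::head(x$areas, 8L), collapse = ", ")))
  invisible(x)
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected, so labels
# touching diagonally are merged with a union-find pass.
label_components <- function(fg) {
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(as.integer(round(lab)), nrow(fg), ncol(fg))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W]))   # down-left
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(nl), find, integer(1L))
  remap <- match(roots, unique(roots))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Classical reference segmentation backend
#'
#' A self-contained, prompt-free backend honoring the mask-set contract:
#' Otsu thresholding (with polarity chosen automatically so the foreground
#' is the minority class), 8-connected component labeling, a minimum-area
#' filter, and the complement of all components as the background mask.
#' Intended for offline testing and as a classical baseline; it makes no
#' attempt to split touching cells.
#'
#' @param image integer matrix in `[0, 255]`.
#' @param min_area smallest component (in pixels) kept as an instance mask.
#' @return [mask_set()] sorted by area descending, background first.
#' @export
reference_backend <- function(image, min_area = 1L) {
  validate_gray_image(image)
  H <- nrow(image); W <- ncol(image)
  bg_only <- function() {
    mask_set(list(matrix(TRUE, H, W)), backend = "reference", sort = FALSE)
  }
  if (length(unique(as.vector(image))) < 2L) return(bg_only())
  th <- EBImage::otsu(image / 255, range = c(0, 1), levels = 256L)
  fg <- image / 255 > th
  if (sum(fg) > length(fg) / 2) fg <- !fg  # foreground = minority class
  if (!any(fg)) return(bg_only())
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  masks <- lapply(keep, function(k) lab == k)
  union_fg <- if (length(masks)) Reduce(`|`, masks) else matrix(FALSE, H, W)
  background <- !union_fg
  if (any(background)) masks <- c(list(background), masks)
  if (length(masks) == 0L) return(bg_only())
  mask_set(masks, backend = "reference")
}

#' Adapter for a pre-trained automatic mask generator
#'
#' Adapts the output of a promptable foundation segmenter's automatic
#' (prompt-free) mask generator to the package's mask-set contract. The
#' contract deliberately has no prompt input: the generator proposes masks
#' from the image alone, and this adapter only reshapes its output —
#' sorting masks by area descending and appending the complement of their
#' union as a background mask when the generator did not emit one.
#' Overlapping instance masks are retained as-is (no deduplication).
#'
#' The heavyweight model is an optional dependency: without a `generator`
#' function and a valid `checkpoint`, a capability error names what is
#' missing. Supplying `generator` (any function `image -> list of binary
#' matrices`) exercises the adapter contract without model weights.
#'
#' @param image integer matrix in `[0, 255]`.
#' @param checkpoint path to pre-trained model weights (optional if
#'   `generator` is given).
#' @param generator function taking the image and returning a list of
#'   binary instance masks; injected by tests or by an external model
#'   wrapper.
#' @return [mask_set()] sorted by area descending.
#' @export
sam_backend <- function(image, checkpoint = NULL, generator = NULL) {
  validate_gray_image(image)
  H <- nrow(image); W <- ncol(image)
  if (is.null(generator)) {
    if (is.null(checkpoint) || !file.exists(checkpoint)) {
      stop(paste0(
        "the automatic-mask-generator backend needs pre-trained model ",
        "weights: no usable `checkpoint` was supplied and no `generator` ",
        "function was injected"), call. = FALSE)
    }
    stop(paste0(
      "the automatic-mask-generator backend requires the external ",
      "segment-anything runtime (torch), which is not installed; ",
      "inject a `generator` function or install the optional dependency"),
      call. = FALSE)
  }
  masks <- generator(image)
  if (!is.list(masks)) {
    stop("the mask generator must return a list of binary masks",
         call. = FALSE)
  }
  masks <- lapply(masks, function(m) m != 0)
  union_fg <- if (length(masks)) Reduce(`|`, masks) else matrix(FALSE, H, W)
  covers_all <- any(vapply(masks, all, logical(1L)))
  if (!covers_all && any(!union_fg)) {
    masks <- c(masks, list(!union_fg))
  }
  if (length(masks) == 0L) {
    masks <- list(matrix(TRUE, H, W))
  }
  mask_set(masks, backend = "sam")
}

#' Extract instance masks from an image (prompt-free)
#'
#' Front door of the segmentation stage. Dispatches to a named backend (or
#' any user function returning a list of binary masks) and returns the
#' area-descending mask set. No prompts, points or boxes exist in this
#' interface: mask proposal is fully automatic by construction.
#'
#' @param image integer matrix in `[0, 255]`.
#' @param backend `"reference"`, `"sam"`, or a function
#'   `image -> list of binary matrices`.
#' @param ... passed to the backend ([reference_backend()] or
#'   [sam_backend()]).
#' @return [mask_set()].
#' @export
segment <- function(image, backend = "reference", ...) {
  validate_gray_image(image)
  if (is.function(backend)) {
    return(sam_backend(image, generator = backend))
  }
  switch(match.arg(backend, c("reference", "sam")),
         reference = reference_backend(image, ...),
         sam = sam_backend(image, ...))
}
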