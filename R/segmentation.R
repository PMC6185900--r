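#' 8-bit grayscale image
#'
#' Thin wrapper around an integer matrix of intensities in `[0, 255]` with a
#' physical pixel size, the input of the micro-CT style segmentation step.
#'
#' @param pixels numeric/integer matrix, values within `[0, 255]`.
#' @param resolution_um physical pixel size in micrometres (default 6, the
#'   scan resolution the segmentation emulates).
#' @return object of class `gray_image`.
#' @export
gray_image <- function(pixels, resolution_um = 6) {
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  if (anyNA(pixels)) stop("`pixels` must not contain NA", call. = FALSE)
  if (any(pixels < 0 | pixels > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, resolution_um = resolution_um),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px @ %g um/px, range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$resolution_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

## Kapur objective for every cut s in 1..255: sum of Shannon entropies of the
## two histogram classes {0..s-1} and {s..255}. Empty bins contribute zero
## entropy (0 log 0 := 0); cuts leaving an empty class score -Inf.
.kapur_objective <- function(counts) {
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P1 <- cumsum(p)[1:255]           # class mass below cut s = P(0..s-1)
  S1 <- cumsum(plogp)[1:255]
  P2 <- 1 - P1
  S2 <- sum(plogp) - S1
  obj <- ifelse(P1 > 0 & P2 > 0,
                (log(P1) - S1 / P1) + (log(P2) - S2 / P2),
                -Inf)
  obj
}

#' Maximum-entropy (Kapur) threshold of a grayscale image
#'
#' The automated "threshold on the entropy of the histogram": the intensity
#' cut that maximises the sum of Shannon entropies of the two histogram
#' classes it creates (Kapur's criterion). The returned threshold `T` means
#' pixels with intensity `>= T` fall in the upper (solid) class. The search
#' scans all 255 candidate cuts, so it is exactly the brute-force argmax;
#' ties are broken toward the lowest maximising threshold.
#'
#' @param image a [gray_image()] with at least 2 distinct intensities.
#' @return integer threshold in `[1, 255]`.
#' @export
entropy_threshold <- function(image) {
  if (!inherits(image, "gray_image"))
    stop("`image` must be a gray_image", call. = FALSE)
  counts <- tabulate(as.vector(image$pixels) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2)
    stop("degenerate histogram: image has a single intensity", call. = FALSE)
  obj <- .kapur_objective(counts)
  which.max(obj)   # first (lowest) maximiser; cut s => solid is >= s
}

#' Binarise a grayscale image at a threshold
#'
#' Segments the image into solid (cell wall) and background. X-rays are
#' reflected by the solid matrix, so the cell wall appears bright: pixels
#' with intensity at or above the threshold map to 1 (solid), the rest to 0.
#' The solid (wall) fraction is the mean of the mask.
#'
#' @param image a [gray_image()].
#' @param threshold intensity cut in `[0, 255]`; defaults to
#'   [entropy_threshold()] of the image.
#' @return object of class `segmentation_result`: list with `mask` (0/1
#'   integer matrix), `threshold`, `wall_fraction`, `resolution_um`.
#' @export
segment_image <- function(image, threshold = entropy_threshold(image)) {
  if (!inherits(image, "gray_image"))
    stop("`image` must be a gray_image", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 255)
    stop("`threshold` must be a single value in [0, 255]", call. = FALSE)
  mask <- (image$pixels >= threshold) + 0L
  dim(mask) <- dim(image$pixels)
  structure(list(mask = mask, threshold = threshold,
                 wall_fraction = mean(mask),
                 resolution_um = image$resolution_um),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d x %d, threshold %g, wall fraction %.4f\n",
              nrow(x$mask), ncol(x$mask), x$threshold, x$wall_fraction))
  invisible(x)
}

#' Solid-fraction profile along one image axis
#'
#' The per-row (or per-column) fraction of solid pixels, used to quantify
#' how cell-wall breakage progresses from the drying surface toward the
#' sample centre. With `axis = "row"` element i is the solid fraction of row
#' i; row 1 is taken as the surface-most row, so a sample ruptured near the
#' surface shows depressed leading values.
#'
#' @param result a `segmentation_result` from [segment_image()].
#' @param axis `"row"` (default) or `"col"`.
#' @return numeric vector of solid fractions along the chosen axis.
#' @export
wall_fraction_profile <- function(result, axis = c("row", "col")) {
  if (!inherits(result, "segmentation_result"))
    stop("`result` must be a segmentation_result", call. = FALSE)
  axis <- match.arg(axis)
  if (axis == "row") rowMeans(result$mask) else colMeans(result$mask)
}
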