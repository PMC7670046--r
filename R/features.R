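#' Extract an intensity plane from an RGB spectrogram
#'
#' Returns the raw red, green or blue plane, or the luminance plane
#' `Y = 0.299 r + 0.587 g + 0.114 b` (YUV colour encoding). Y is kept as a
#' real value — it is never rounded — and is compared to the integer
#' binarization threshold directly.
#'
#' @param image H x W x 3 array of 8-bit intensities.
#' @param channel one of `"red"`, `"green"`, `"blue"`, `"Y"`.
#' @return H x W numeric matrix.
#' @examples
#' img <- array(c(0, 0, 255), dim = c(1, 1, 3))
#' extractChannel(img, "Y")  # 0.114 * 255 = 29.07
#' @export
extractChannel <- function(image, channel = c("red", "green", "blue", "Y")) {
  channel <- match.arg(channel)
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L))
    stop("'image' must be an H x W x 3 array")
  plane2d <- function(k) {
    p <- as.numeric(image[, , k])
    matrix(p, dim(image)[1], dim(image)[2])
  }
  switch(channel,
    red   = plane2d(1),
    green = plane2d(2),
    blue  = plane2d(3),
    Y     = 0.299 * plane2d(1) + 0.587 * plane2d(2) + 0.114 * plane2d(3))
}

#' Binarize an intensity plane
#'
#' A pixel becomes white (255) when its value is greater than or equal to
#' the threshold, and black (0) otherwise.
#'
#' @param plane H x W numeric matrix.
#' @param threshold integer in `[0, 255]`.
#' @return H x W integer matrix with values in `{0, 255}`.
#' @examples
#' binarize(matrix(c(49, 50, 51), 1), threshold = 50)
#' @export
binarize <- function(plane, threshold) {
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 255)
    stop("'threshold' must be a single value in [0, 255]")
  mask <- matrix(0L, nrow(plane), ncol(plane))
  mask[plane >= threshold] <- 255L
  mask
}

## contiguous near-equal partition of n positions into k strips; when n is
## not divisible by k the earlier strips receive the extra pixel
stripSizes <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

segmentSums <- function(v, sizes) {
  idx <- rep(seq_along(sizes), sizes)
  as.numeric(tapply(v, idx, sum))
}

#' White-pixel counts per time and velocity strip
#'
#' Partitions the mask's columns into `grid[2]` contiguous near-equal
#' vertical (time-axis) strips and its rows into `grid[1]` horizontal
#' (velocity-axis) strips, and counts the white pixels in each. The
#' returned feature vector lists column-strip counts left to right first
#' (items a-d of the default 4x4 grid — roughly one step each), then
#' row-strip counts top to bottom (items e-h — velocity bands from limb
#' swing down to stance). Each of the two groups partitions the image, so
#' each group sums to the total white-pixel count.
#'
#' @param mask H x W matrix in `{0, 255}` (any non-zero value counts as
#'   white).
#' @param grid integer vector `c(rows, cols)`; default `c(4, 4)` yields 8
#'   features.
#' @return Numeric vector of length `grid[2] + grid[1]` of non-negative
#'   counts.
#' @examples
#' gridCounts(matrix(255, 100, 100), c(4, 4))  # eight times 2500
#' @export
gridCounts <- function(mask, grid = c(4L, 4L)) {
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(is.na(grid)) || any(grid < 1L))
    stop("'grid' must be two positive integers (rows, cols)")
  if (nrow(mask) < grid[1] || ncol(mask) < grid[2])
    stop("grid larger than mask")
  white <- mask != 0
  colTotals <- colSums(white)
  rowTotals <- rowSums(white)
  c(segmentSums(colTotals, stripSizes(ncol(mask), grid[2])),
    segmentSums(rowTotals, stripSizes(nrow(mask), grid[1])))
}

## pixel areas of the strips, in feature order (columns first, then rows)
stripAreas <- function(h, w, grid) {
  c(stripSizes(w, grid[2]) * h, stripSizes(h, grid[1]) * w)
}

#' Extract the strip-count feature vector from a spectrogram
#'
#' Composition of [extractChannel()], [binarize()] and [gridCounts()]:
#' channel selection, thresholding to a white/black mask, and white-pixel
#' counting per grid strip. With `normalize = TRUE` (the default) each
#' count is divided by its strip's pixel area, giving white-pixel
#' fractions in `[0, 1]`; raw counts are available with
#' `normalize = FALSE`.
#'
#' @param image H x W x 3 array of 8-bit intensities.
#' @param channel binarization channel, see [extractChannel()].
#' @param threshold binarization threshold in `[0, 255]`.
#' @param grid `c(rows, cols)` strip grid; default 4x4 gives 8 features.
#' @param normalize divide counts by strip areas.
#' @return Numeric feature vector of length `grid[2] + grid[1]`.
#' @examples
#' img <- simulateSpectrogram(gaitParams(), "non-apathy", seed = 1)
#' extractFeatures(img, "red", 150)
#' @export
extractFeatures <- function(image, channel, threshold, grid = c(4L, 4L),
                            normalize = TRUE) {
  plane <- extractChannel(image, channel)
  counts <- gridCounts(binarize(plane, threshold), grid)
  if (normalize)
    counts <- counts / stripAreas(nrow(plane), ncol(plane), as.integer(grid))
  counts
}

#' Default binarization threshold ladder
#'
#' The evaluation protocol slides the binarization threshold from 50 to
#' 220 in steps of 10 (18 values).
#'
#' @return Integer vector `seq(50, 220, by = 10)`.
#' @export
thresholdLadder <- function() seq(50L, 220L, by = 10L)
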