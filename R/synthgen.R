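#' Jet-style colormap
#'
#' Maps intensities in `[0, 1]` to RGB in 0..255 through the classic jet
#' ramp (dark blue background through cyan/yellow to red peaks). Chosen
#' deliberately: real walking micro-Doppler spectrograms are rendered this
#' way, so the background is blue-saturated and the blue channel carries
#' the least class information.
#'
#' @param x numeric vector/matrix of intensities in `[0, 1]`.
#' @return A list with integer components `r`, `g`, `b`, each shaped like
#'   `x`, values in 0..255.
#' @keywords internal
jetColormap <- function(x) {
  clamp01 <- function(v) pmin(pmax(v, 0), 1)
  r <- clamp01(1.5 - abs(4 * x - 3))
  g <- clamp01(1.5 - abs(4 * x - 2))
  b <- clamp01(1.5 - abs(4 * x - 1))
  out <- lapply(list(r = r, g = g, b = b), function(ch) {
    ch <- as.integer(round(ch * 255))
    if (!is.null(dim(x))) dim(ch) <- dim(x)
    ch
  })
  out
}

## Deterministic intensity field of a simulated walk: sinusoidal torso trace
## plus periodic limb-swing bursts. Velocity v = rows above the bottom edge.
## Both terms vanish when their velocity scale is zero (a stationary scatterer
## has no Doppler return), so all-zero parameters give an identically zero
## field.
walkIntensityField <- function(params, height, width) {
  vt  <- params@torsoVelocityMean
  amp <- params@limbBurstAmplitude
  v <- (height - seq_len(height))        # velocity of each image row
  col <- seq_len(width)
  field <- matrix(0, height, width)
  if (vt > 0) {
    sway <- 0.15 * vt
    torsoV <- vt + sway * sin(2 * pi * params@strideFrequency * col / width)
    # Gaussian ridge across rows, centred on the torso velocity
    field <- field + 0.9 * exp(-0.5 * (outer(v, torsoV, "-") / 6)^2)
  }
  vmax <- vt + amp
  if (vmax > 0 && amp > 0) {
    centers <- (seq_len(params@nSteps) - 0.5) * width / params@nSteps
    colw <- rowSums(exp(-0.5 * (outer(col, centers, "-") /
                                  max(params@limbBurstWidth, 1e-8))^2))
    # triangular velocity profile: strongest at the torso line, fading out
    # at the maximum limb velocity
    prof <- 0.8 * pmax(0, 1 - v / vmax)
    field <- field + outer(prof, colw)
  }
  field
}

#' Simulate one walking micro-Doppler spectrogram
#'
#' Renders a synthetic RGB spectrogram image: horizontal axis time,
#' vertical axis Doppler velocity (zero at the bottom), jet colormap.
#' The intensity field is a sinusoidal torso trace plus `nSteps` periodic
#' limb-swing bursts plus additive uniform noise. For `label = "apathy"`
#' the torso velocity and limb-burst amplitude are scaled down by
#' `classEffect`, emulating the slower, flatter gait signature of the
#' apathetic group.
#'
#' @param params a [GaitParams-class] object.
#' @param label `"apathy"` or `"non-apathy"`.
#' @param seed integer RNG seed; identical seeds and parameters give
#'   bit-identical images.
#' @param canvas integer vector `c(height, width)` in pixels.
#' @param classEffect multiplicative factor in `(0, 1]` applied to
#'   `torsoVelocityMean` and `limbBurstAmplitude` when `label` is apathy;
#'   1 makes the two classes indistinguishable.
#' @return An H x W x 3 integer array with values in 0..255.
#' @examples
#' img <- simulateSpectrogram(gaitParams(), "non-apathy", seed = 1)
#' dim(img)
#' @export
simulateSpectrogram <- function(params, label, seed = 1L,
                                canvas = c(256L, 256L), classEffect = 0.7) {
  validObject(params)
  label <- match.arg(label, APATHY_LEVELS)
  canvas <- as.integer(canvas)
  if (length(canvas) != 2L || any(is.na(canvas)) || any(canvas < 1L))
    stop("'canvas' must be two positive integers (height, width)")
  if (classEffect <= 0 || classEffect > 1)
    stop("'classEffect' must lie in (0, 1]")
  if (label == "apathy" && classEffect < 1) {
    params <- gaitParams(
      torsoVelocityMean = params@torsoVelocityMean * classEffect,
      strideFrequency = params@strideFrequency,
      limbBurstAmplitude = params@limbBurstAmplitude * classEffect,
      limbBurstWidth = params@limbBurstWidth,
      noiseLevel = params@noiseLevel,
      nSteps = params@nSteps)
  }
  field <- walkIntensityField(params, canvas[1], canvas[2])
  if (params@noiseLevel > 0) {
    set.seed(as.integer(seed))
    field <- field + params@noiseLevel *
      matrix(stats::runif(canvas[1] * canvas[2]), canvas[1], canvas[2])
  }
  field <- pmin(field, 1)
  ch <- jetColormap(field)
  img <- array(0L, dim = c(canvas[1], canvas[2], 3L))
  img[, , 1] <- ch$r
  img[, , 2] <- ch$g
  img[, , 3] <- ch$b
  img
}

#' Simulate one Apathy Scale questionnaire response
#'
#' Draws a total score from a class-conditional discretized normal
#' distribution — apathy: Normal(22, 3) truncated to `[16, 42]`,
#' non-apathy: Normal(9, 3) truncated to `[0, 15]` — and decomposes it
#' into 14 items by allocating one point at a time to a uniformly chosen
#' item that has not yet reached the per-item maximum of 3. The derived
#' label (total >= 16) therefore always equals `label`.
#'
#' @param label `"apathy"` or `"non-apathy"`.
#' @param seed integer RNG seed.
#' @return Integer vector of 14 item points in 0..3.
#' @examples
#' r <- simulateResponse("apathy", seed = 7)
#' scoreResponse(r) >= 16
#' @export
simulateResponse <- function(label, seed = 1L) {
  label <- match.arg(label, APATHY_LEVELS)
  set.seed(as.integer(seed))
  if (label == "apathy") {
    lo <- 16; hi <- 42; mu <- 22; sd <- 3
  } else {
    lo <- 0; hi <- 15; mu <- 9; sd <- 3
  }
  repeat {
    total <- round(stats::rnorm(1, mu, sd))
    if (total >= lo && total <= hi) break
  }
  # allocate points one at a time among items still below the maximum
  items <- integer(14)
  if (total > 0) {
    for (unit in seq_len(total)) {
      open <- which(items < 3L)
      pick <- open[sample.int(length(open), 1L)]
      items[pick] <- items[pick] + 1L
    }
  }
  items
}

#' Simulate a labelled spectrogram dataset
#'
#' Generates `nApathy + nNonapathy` samples: one spectrogram and one
#' matching questionnaire response per participant. Defaults reproduce the
#' study composition of 178 participants, 56 apathetic and 122
#' non-apathetic. Per-sample seeds are drawn once from `seed`, so the
#' whole set is reproducible bit for bit.
#'
#' @param nApathy,nNonapathy per-class sample counts (non-negative).
#' @param seed integer master seed.
#' @param params a [GaitParams-class]; defaults to [gaitParams()].
#' @param canvas image size `c(height, width)`.
#' @param classEffect class-separation factor, see [simulateSpectrogram()].
#' @return A [SpectrogramSet-class] with `nApathy + nNonapathy` samples.
#' @examples
#' ds <- simulateDataset(3, 5, seed = 1, canvas = c(64, 64))
#' table(apathyLabels(ds))
#' @export
simulateDataset <- function(nApathy = 56L, nNonapathy = 122L, seed = 1L,
                            params = gaitParams(), canvas = c(256L, 256L),
                            classEffect = 0.7) {
  nApathy <- as.integer(nApathy); nNonapathy <- as.integer(nNonapathy)
  if (is.na(nApathy) || is.na(nNonapathy) || nApathy < 0L || nNonapathy < 0L)
    stop("sample counts must be non-negative")
  n <- nApathy + nNonapathy
  labels <- rep(APATHY_LEVELS, c(nApathy, nNonapathy))
  set.seed(as.integer(seed))
  sampleSeeds <- sample.int(.Machine$integer.max, max(n, 1L))
  images <- vector("list", n)
  responses <- matrix(0L, n, 14L)
  for (i in seq_len(n)) {
    images[[i]] <- simulateSpectrogram(params, labels[i],
                                       seed = sampleSeeds[i],
                                       canvas = canvas,
                                       classEffect = classEffect)
    responses[i, ] <- simulateResponse(labels[i], seed = sampleSeeds[i])
  }
  SpectrogramSet(images, labels, responses, seed = seed)
}
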