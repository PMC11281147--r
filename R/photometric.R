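## Photometric operators: pixel-intensity transforms that leave geometry,
## and therefore the box annotations, untouched. All three apply one shared
## mapping to the R, G and B channels: trap images show near-identical
## per-channel color distributions, so channel-wise mappings would add
## nothing but chroma artifacts.

#' Gamma correction
#'
#' Power-law intensity mapping. Each intensity `v` is scaled to `v/255`,
#' mapped through `gain * (v/255)^gamma`, clipped to \[0, 1\], rescaled to
#' 0..255 and rounded (half away from zero). `gamma < 1` brightens,
#' `gamma > 1` darkens; `gamma = 1, gain = 1` is a bit-exact identity.
#'
#' @param img an [AnnotatedImage-class].
#' @param gamma positive exponent.
#' @param gain multiplicative gain applied in the scaled domain (default 1,
#'   the value used throughout dataset enrichment).
#' @return a new `AnnotatedImage` with provenance `"gamma"`; boxes are
#'   copied unchanged.
#' @export
gammaCorrect <- function(img, gamma, gain = 1) {
  .checkImage(img)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a single positive number", call. = FALSE)
  out <- .roundHalfUp(255 * .clip01(gain * (imageArray(img) / 255)^gamma))
  AnnotatedImage(out, boxes = boxes(img), id = imageId(img),
                 provenance = "gamma",
                 meta = list(gamma = gamma, gain = gain,
                             source = imageId(img)))
}

#' Brightness-contrast adjustment
#'
#' Affine intensity mapping `alpha * v + beta` on the 0..255 scale, clipped
#' and rounded. `alpha` is the contrast gain, `beta` the brightness bias;
#' `alpha = 1, beta = 0` is a bit-exact identity.
#'
#' @param img an [AnnotatedImage-class].
#' @param alpha positive contrast gain.
#' @param beta brightness bias in intensity units (0..255 scale).
#' @return a new `AnnotatedImage` with provenance `"brightness_contrast"`.
#' @export
brightnessContrast <- function(img, alpha, beta) {
  .checkImage(img)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a single positive number", call. = FALSE)
  out <- .roundHalfUp(.clip0255(alpha * imageArray(img) + beta))
  AnnotatedImage(out, boxes = boxes(img), id = imageId(img),
                 provenance = "brightness_contrast",
                 meta = list(alpha = alpha, beta = beta,
                             source = imageId(img)))
}

#' Multiplicative Gaussian noise
#'
#' Each pixel is multiplied by a draw from `Normal(mean, sd^2)` — by default
#' mean 1, sd 0.2, the classic speckle parameterization. One draw is made
#' per pixel location and shared across the three channels (`perChannel =
#' FALSE`, modelling sensor/illumination graininess) or drawn independently
#' per channel (`perChannel = TRUE`, chroma noise). Draws come from the
#' current R random stream, so outputs are reproducible under
#' [set.seed()].
#'
#' @param img an [AnnotatedImage-class].
#' @param mean noise mean (default 1).
#' @param sd positive noise standard deviation (default 0.2).
#' @param perChannel draw noise independently per channel (default FALSE).
#' @return a new `AnnotatedImage` with provenance `"noise"`.
#' @export
addGaussianNoise <- function(img, mean = 1, sd = 0.2, perChannel = FALSE) {
  .checkImage(img)
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0)
    stop("sd must be a single positive number", call. = FALSE)
  a <- imageArray(img)
  d <- dim(a)
  n <- if (perChannel) array(rnorm(prod(d), mean, sd), dim = d)
       else array(rep(rnorm(d[1L] * d[2L], mean, sd), 3L), dim = d)
  out <- .roundHalfUp(.clip0255(a * n))
  AnnotatedImage(out, boxes = boxes(img), id = imageId(img),
                 provenance = "noise",
                 meta = list(mean = mean, sd = sd, perChannel = perChannel,
                             source = imageId(img)))
}

#' Sample photometric augmentation parameters
#'
#' Draws one parameter set from the default uniform laws:
#' `gamma ~ U(0.2, 3.0)` (gain fixed at 1), `alpha ~ U(0.5, 2.0)`,
#' `beta ~ U(-50, 50)`. Uses the current R random stream.
#'
#' @return list with elements `gamma`, `gain`, `alpha`, `beta`.
#' @export
samplePhotometricParams <- function() {
  list(gamma = runif(1, 0.2, 3.0), gain = 1,
       alpha = runif(1, 0.5, 2.0), beta = runif(1, -50, 50))
}
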