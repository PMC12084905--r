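# Stochastic augmentation for contrastive pretraining: random area crop
# with resize, color distortion, and random Gaussian blur. Two draws from
# the same patch form a positive pair.

#' Construct an augmentation policy
#'
#' @param crop_scale_range (min, max) fraction of the patch area kept by
#'   the random crop; both in (0, 1].
#' @param color_distortion_strength nonnegative scalar scaling the
#'   brightness/contrast/saturation jitter (+-0.8 x strength) and the hue
#'   shift (+-0.2 x strength), as in standard contrastive recipes.
#' @param blur_sigma_range (min, max) Gaussian-blur standard deviation in
#'   pixels; sigma is drawn uniformly per view.
#' @param output_side side length of the augmented views in pixels.
#' @return a list of class `AugmentationPolicy`.
#' @export
augmentationPolicy <- function(crop_scale_range = c(0.2, 1.0),
                               color_distortion_strength = 0.5,
                               blur_sigma_range = c(0.1, 2.0),
                               output_side = 32L) {
  stopifnot(length(crop_scale_range) == 2L, length(blur_sigma_range) == 2L)
  if (crop_scale_range[2] <= 0)
    stop("degenerate policy: maximum crop scale must be positive")
  if (crop_scale_range[1] <= 0 || crop_scale_range[1] > crop_scale_range[2] ||
      crop_scale_range[2] > 1)
    stop("crop_scale_range must satisfy 0 < min <= max <= 1")
  if (any(blur_sigma_range < 0) || blur_sigma_range[1] > blur_sigma_range[2])
    stop("blur_sigma_range must be nonnegative and ordered")
  if (color_distortion_strength < 0)
    stop("color_distortion_strength must be nonnegative")
  structure(list(crop_scale_range = crop_scale_range,
                 color_distortion_strength = color_distortion_strength,
                 blur_sigma_range = blur_sigma_range,
                 output_side = as.integer(output_side)),
            class = "AugmentationPolicy")
}

.jitter_range <- function(strength, width) {
  c(max(0, 1 - width * strength), 1 + width * strength)
}

# One stochastic augmentation draw from the current RNG stream.
.augmentOnce <- function(patch, policy) {
  d <- dim(patch)
  # random area crop (square), then area-average resize to output_side
  u <- stats::runif(1, policy$crop_scale_range[1], policy$crop_scale_range[2])
  side <- max(1L, as.integer(round(sqrt(u) * min(d[1], d[2]))))
  top <- if (d[1] > side) sample.int(d[1] - side + 1L, 1L) - 1L else 0L
  left <- if (d[2] > side) sample.int(d[2] - side + 1L, 1L) - 1L else 0L
  v <- patch[top + seq_len(side), left + seq_len(side), , drop = FALSE]
  v <- resizeArea(v, policy$output_side, policy$output_side)
  # color distortion: brightness, contrast, saturation, hue
  s <- policy$color_distortion_strength
  if (s > 0) {
    br <- .jitter_range(s, 0.8)
    v <- v * stats::runif(1, br[1], br[2])
    cf <- stats::runif(1, br[1], br[2])
    v <- (v - mean(v)) * cf + mean(v)
    hsv <- .rgb_to_hsv(pmin(pmax(v, 0), 1))
    hsv[, , 2] <- pmin(hsv[, , 2] * stats::runif(1, br[1], br[2]), 1)
    hsv[, , 1] <- (hsv[, , 1] + stats::runif(1, -0.2 * s, 0.2 * s)) %% 1
    v <- .hsv_to_rgb(hsv)
  }
  # random Gaussian blur
  sigma <- stats::runif(1, policy$blur_sigma_range[1],
                        policy$blur_sigma_range[2])
  v <- gaussianBlur(v, sigma)
  pmin(pmax(v, 0), 1)
}

#' Draw an augmented view pair from one patch
#'
#' Produces two independently augmented views of the same patch (a
#' positive pair for the contrastive loss). Bit-reproducible for a given
#' `seed`; with `seed = NULL` the current RNG stream is consumed.
#'
#' @param patch H x W x 3 array in `[0, 1]`.
#' @param policy an [augmentationPolicy()].
#' @param seed optional integer seed for this draw.
#' @return list of two `output_side` x `output_side` x 3 arrays.
#' @export
makeViewPair <- function(patch, policy, seed = NULL) {
  .assert_raster(patch, "patch")
  stopifnot(inherits(policy, "AugmentationPolicy"))
  if (!is.null(seed)) set.seed(seed)
  list(.augmentOnce(patch, policy), .augmentOnce(patch, policy))
}
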