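# Raster helpers shared by the tiler, the augmenter and the toy-slide
# generator. Images are H x W x 3 arrays with values in [0, 1].

.assert_raster <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L ||
      any(dim(img)[1:2] == 0L))
    stop(what, " must be a nonempty H x W x 3 RGB array")
  invisible(img)
}

# 1-D area-average resampling weights: out-pixel j covers the input
# interval [j*n/m, (j+1)*n/m); weight = fractional overlap. Rows sum to 1.
.area_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (j in seq_len(n_out)) {
    a <- (j - 1) * scale
    b <- j * scale
    i0 <- floor(a) + 1
    i1 <- ceiling(b)
    for (i in i0:min(i1, n_in)) {
      lo <- max(a, i - 1)
      hi <- min(b, i)
      if (hi > lo) W[j, i] <- (hi - lo) / scale
    }
  }
  W
}

#' Resize an RGB raster by area averaging
#'
#' Deterministic, anti-aliased resampling: each output pixel is the exact
#' area-weighted mean of the input pixels it covers. Used for residual
#' downscaling to the working magnification and for crop-resize
#' augmentation.
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param out_h,out_w output height and width in pixels.
#' @return out_h x out_w x 3 array.
#' @export
resizeArea <- function(img, out_h, out_w) {
  .assert_raster(img)
  d <- dim(img)
  if (out_h == d[1] && out_w == d[2]) return(img)
  Wr <- .area_weights(d[1], out_h)
  Wc <- .area_weights(d[2], out_w)
  out <- array(0, c(out_h, out_w, 3))
  for (ch in 1:3) out[, , ch] <- Wr %*% img[, , ch] %*% t(Wc)
  out
}

# Banded Gaussian smoothing matrix with edge renormalization (truncation
# at 3 sigma; each row rescaled to sum 1 so borders keep their level).
.gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    pos <- i + (-r:r)
    ok <- pos >= 1L & pos <= n
    B[i, pos[ok]] <- k[ok]
    B[i, ] <- B[i, ] / sum(B[i, ])
  }
  B
}

#' Gaussian-blur an RGB raster
#'
#' Separable Gaussian filter, truncated at three standard deviations with
#' edge renormalization; `sigma = 0` is the identity.
#'
#' @param img H x W x 3 array.
#' @param sigma standard deviation in pixels.
#' @return blurred array of the same shape.
#' @export
gaussianBlur <- function(img, sigma) {
  .assert_raster(img)
  if (sigma <= 0) return(img)
  d <- dim(img)
  Br <- .gauss_band(d[1], sigma)
  Bc <- .gauss_band(d[2], sigma)
  out <- img
  for (ch in 1:3) out[, , ch] <- Br %*% img[, , ch] %*% t(Bc)
  out
}

# RGB [0,1] -> HSV [0,1]^3, vectorized over all pixels.
.rgb_to_hsv <- function(img) {
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  array(c(hsv[1, ], hsv[2, ], hsv[3, ]), d)
}

# HSV [0,1]^3 -> RGB [0,1], vectorized (standard sector formula).
.hsv_to_rgb <- function(hsv) {
  d <- dim(hsv)
  h <- as.vector(hsv[, , 1]) * 6
  s <- as.vector(hsv[, , 2])
  v <- as.vector(hsv[, , 3])
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), d)
}

#' Read a flat image file as a single-level slide
#'
#' Reads PNG (always) or TIFF (when the `tiff` package is available) into
#' a [SlideSource-class] with one level at a declared magnification.
#'
#' @param path image file path.
#' @param slide_id slide identifier; default: file name without extension.
#' @param magnification declared objective-equivalent magnification of the
#'   stored image (default 10).
#' @return a `SlideSource`.
#' @export
readSlideImage <- function(path, slide_id = NULL, magnification = 10) {
  if (is.null(slide_id))
    slide_id <- sub("\\.[A-Za-z]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  new("SlideSource", slideId = slide_id, levels = list(img),
      magnifications = magnification, mpp = NA_real_)
}

#' Construct an in-memory SlideSource
#'
#' @param img H x W x 3 array in `[0, 1]` (level 0), or a list of such
#'   arrays ordered by decreasing resolution.
#' @param slide_id slide identifier.
#' @param magnifications magnification per level.
#' @param mpp microns per pixel at level 0 (optional).
#' @return a `SlideSource`.
#' @export
slideFromArray <- function(img, slide_id, magnifications = 10,
                           mpp = NA_real_) {
  levels <- if (is.list(img)) img else list(img)
  new("SlideSource", slideId = slide_id, levels = levels,
      magnifications = as.numeric(magnifications), mpp = mpp)
}
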