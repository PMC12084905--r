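# Slide tiling: working-level selection, tissue detection and grid
# patching with the minimum-tissue filter.

#' Select the pyramid level used for tiling
#'
#' Picks the level whose magnification is the smallest value at or above
#' the target, together with the residual factor needed to downsample from
#' that level to exactly the target magnification (1 when an exact level
#' exists).
#'
#' @param slide a [SlideSource-class].
#' @param target_mag target objective-equivalent magnification (default 10).
#' @return list with `level` (1-based index) and `factor` (>= 1).
#' @export
selectWorkingLevel <- function(slide, target_mag = 10) {
  stopifnot(is(slide, "SlideSource"))
  mags <- slide@magnifications
  if (length(mags) == 0L || any(is.na(mags)))
    stop("slide '", slide@slideId, "': magnification metadata is missing")
  cand <- which(mags >= target_mag)
  if (length(cand) == 0L)
    stop("slide '", slide@slideId, "': target magnification ", target_mag,
         " exceeds the highest available level (", max(mags), ")")
  lev <- cand[which.min(mags[cand])]
  list(level = lev, factor = mags[lev] / target_mag)
}

#' Fraction of tissue pixels in a patch
#'
#' A pixel counts as tissue when its HSV saturation is at least `sat_min`
#' and its value (brightness) is at most `val_max`: saturated, non-bright
#' pixels are stained tissue, near-white ones are glass background. With
#' `otsu = TRUE` the saturation cut is instead chosen by Otsu thresholding
#' of the patch's saturation histogram.
#'
#' @param patch nonempty H x W x 3 RGB array in `[0, 1]`.
#' @param sat_min minimum saturation for tissue (default 0.07).
#' @param val_max maximum value/brightness for tissue (default 0.95).
#' @param otsu use Otsu's threshold on saturation instead of `sat_min`.
#' @return fraction in `[0, 1]`.
#' @export
tissueFraction <- function(patch, sat_min = 0.07, val_max = 0.95,
                           otsu = FALSE) {
  .assert_raster(patch, "patch")
  hsv <- .rgb_to_hsv(patch)
  s <- hsv[, , 2]
  v <- hsv[, , 3]
  if (otsu) sat_min <- .otsu_threshold(as.vector(s))
  mean(s >= sat_min & v <= val_max)
}

# Otsu's between-class-variance-maximizing threshold on a 256-bin
# histogram of values in [0,1].
.otsu_threshold <- function(x, nbins = 256L) {
  h <- tabulate(pmin(as.integer(x * nbins) + 1L, nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nbins) - 0.5) / nbins)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  (which.max(sigma_b) - 0.5) / nbins
}

#' Tile a slide into grid patches at a working magnification
#'
#' Reads the appropriate pyramid level, applies any residual area-average
#' downscale to reach the target magnification exactly, cuts the image
#' into a non-overlapping grid of `side_px` x `side_px` patches (edge
#' remainders smaller than one patch are dropped), and keeps patches whose
#' tissue fraction is at least `min_tissue`. Patches strictly below the
#' threshold are discarded.
#'
#' @param slide a [SlideSource-class].
#' @param target_mag working magnification (default 10).
#' @param side_px patch side length in pixels at the working magnification
#'   (default 224).
#' @param min_tissue minimum tissue fraction in `[0, 1]` (default 0.15).
#' @param keep_rasters retain patch rasters in the returned [PatchSet-class]
#'   (default TRUE); set FALSE to keep only the manifest.
#' @param sat_min,val_max,otsu tissue-detector parameters, see
#'   [tissueFraction()].
#' @return a `PatchSet`; empty (with a warning) when the slide is smaller
#'   than one patch.
#' @export
tileSlide <- function(slide, target_mag = 10, side_px = 224,
                      min_tissue = 0.15, keep_rasters = TRUE,
                      sat_min = 0.07, val_max = 0.95, otsu = FALSE) {
  stopifnot(is(slide, "SlideSource"), side_px > 0,
            min_tissue >= 0, min_tissue <= 1)
  wl <- selectWorkingLevel(slide, target_mag)
  img <- slide@levels[[wl$level]]
  if (wl$factor != 1) {
    d <- dim(img)
    img <- resizeArea(img, round(d[1] / wl$factor), round(d[2] / wl$factor))
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  n_rows <- h %/% side_px
  n_cols <- w %/% side_px
  empty <- data.frame(slide_id = character(), grid_row = integer(),
                      grid_col = integer(), origin_x = numeric(),
                      origin_y = numeric(), side_px = numeric(),
                      tissue_fraction = numeric())
  if (n_rows == 0L || n_cols == 0L) {
    warning("slide '", slide@slideId, "' is smaller than one patch (",
            side_px, " px); returning no patches")
    return(new("PatchSet", slideId = slide@slideId, manifest = empty,
               patches = list()))
  }
  # level-0 pixels per working-magnification pixel
  scale0 <- slide@magnifications[1] / target_mag
  rows <- integer(); cols <- integer(); fracs <- numeric()
  rasters <- list()
  for (r in seq_len(n_rows) - 1L) {
    for (cc in seq_len(n_cols) - 1L) {
      patch <- img[r * side_px + seq_len(side_px),
                   cc * side_px + seq_len(side_px), , drop = FALSE]
      tf <- tissueFraction(patch, sat_min = sat_min, val_max = val_max,
                           otsu = otsu)
      if (tf >= min_tissue) {
        rows <- c(rows, r); cols <- c(cols, cc); fracs <- c(fracs, tf)
        if (keep_rasters) rasters[[length(rasters) + 1L]] <- patch
      }
    }
  }
  manifest <- data.frame(
    slide_id = rep(slide@slideId, length(rows)),
    grid_row = rows, grid_col = cols,
    origin_x = cols * side_px * scale0,
    origin_y = rows * side_px * scale0,
    side_px = rep(side_px, length(rows)),
    tissue_fraction = fracs
  )
  new("PatchSet", slideId = slide@slideId, manifest = manifest,
      patches = rasters)
}

#' Write / read a patch manifest CSV
#'
#' Columns: slide_id, grid_row, grid_col, origin_x, origin_y, side_px,
#' tissue_fraction. Several slides' manifests may share one file.
#'
#' @param x a `PatchSet` or a manifest data.frame.
#' @param path CSV file path.
#' @return `writePatchManifest` returns `path` invisibly;
#'   `readPatchManifest` returns the manifest data.frame.
#' @export
writePatchManifest <- function(x, path) {
  m <- if (is(x, "PatchSet")) x@manifest else x
  stopifnot(all(.manifest_cols %in% names(m)))
  data.table::fwrite(m[, .manifest_cols], path)
  invisible(path)
}

#' @rdname writePatchManifest
#' @export
readPatchManifest <- function(path) {
  m <- as.data.frame(data.table::fread(path))
  if (!all(.manifest_cols %in% names(m)))
    stop("not a patch manifest: missing columns in ", path)
  m
}
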