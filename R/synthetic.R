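# Synthetic toy slides: bright background, one or more spatially disjoint
# tissue pieces, and class identity encoded as a blob texture planted in a
# subset of patch-sized cells (tumor classes) or absent (no-tumor). Labels
# exist only at slide level; per-cell ground truth is emitted for testing
# and never consumed by training code.

.texture_params <- list(
  "no-tumor" = c(density = 0.02, radius = 1.2),
  "Ia"       = c(density = 0.10, radius = 2.0),
  "Ib"       = c(density = 0.18, radius = 2.5),
  "II"       = c(density = 0.30, radius = 3.0),
  "III"      = c(density = 0.45, radius = 3.5)
)

# colours chosen so the HSV tissue detector classifies exactly the
# planted mask: background saturation stays < 0.07, tissue >= 0.2
.bg_level <- 245 / 255
.bg_noise_sd <- 3 / 255
.tissue_rgb <- c(0.88, 0.62, 0.75)
.blob_rgb <- c(0.45, 0.25, 0.55)

#' Specification of one toy slide
#'
#' @param label base class label: "no-tumor", "Ia", "Ib", "II" or "III".
#' @param image_side image side in pixels (multiple of `patch_side`).
#' @param patch_side patch cell side in pixels (default 32).
#' @param n_pieces number of disjoint tissue pieces (>= 1); pieces are
#'   pairwise at Chebyshev distance >= 2 on the patch grid.
#' @param tumor_patch_fraction fraction of well-covered tissue cells that
#'   carry the class texture; must be 0 for "no-tumor" and > 0 otherwise.
#'   Default 0 / 0.6.
#' @param seed integer seed.
#' @return list of class `ToySlideSpec`.
#' @export
toySlideSpec <- function(label, image_side = 256L, patch_side = 32L,
                         n_pieces = 2L,
                         tumor_patch_fraction = if (label == "no-tumor") 0 else 0.6,
                         seed = 1L) {
  if (!label %in% names(.texture_params))
    stop("unknown label '", label, "'")
  if (image_side %% patch_side != 0)
    stop("image_side must be a multiple of patch_side")
  if (n_pieces < 1) stop("n_pieces must be >= 1")
  if (label == "no-tumor" && tumor_patch_fraction > 0)
    stop("no-tumor slides cannot carry tumor texture")
  if (label != "no-tumor" && tumor_patch_fraction <= 0)
    stop("tumor slides need tumor_patch_fraction > 0")
  structure(list(label = label, image_side = as.integer(image_side),
                 patch_side = as.integer(patch_side),
                 n_pieces = as.integer(n_pieces),
                 tumor_patch_fraction = tumor_patch_fraction,
                 seed = as.integer(seed)),
            class = "ToySlideSpec")
}

# truncated gaussian noise (+-2 sd), keeps pixels inside the colour band
# the tissue detector expects
.tnoise <- function(n, sd) pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)

# paint `n_blobs` filled circles into image channels within [r0,r1]x[c0,c1]
.paint_blobs <- function(img, r0, r1, c0, c1, n_blobs, radius, rgb) {
  if (n_blobs <= 0 || r1 < r0 || c1 < c0) return(img)
  for (b in seq_len(n_blobs)) {
    cy <- stats::runif(1, r0, r1)
    cx <- stats::runif(1, c0, c1)
    rr <- max(r0, floor(cy - radius)):min(r1, ceiling(cy + radius))
    cc <- max(c0, floor(cx - radius)):min(c1, ceiling(cx + radius))
    dy <- (rr - cy)^2
    dx <- (cc - cx)^2
    hit <- outer(dy, dx, "+") <= radius^2
    for (ch in 1:3) {
      plane <- img[rr, cc, ch]
      plane[hit] <- rgb[ch] + .tnoise(sum(hit), 0.02)
      img[rr, cc, ch] <- plane
    }
  }
  img
}

#' Generate one toy slide
#'
#' Renders a bright noisy background, `n_pieces` disjoint rectangular
#' tissue pieces with pixel-jittered boundaries (so boundary cells have
#' partial tissue coverage and the minimum-tissue filter is exercised),
#' sparse small blobs as the baseline tissue texture, and — for tumor
#' classes — the denser class texture planted in a fraction of the
#' well-covered cells. Fully reproducible from the spec's seed.
#'
#' @param spec a [toySlideSpec()].
#' @param slide_id slide identifier (default derived from label and seed).
#' @return list: `slide` ([SlideSource-class] at declared magnification
#'   10), `image`, `tissue_mask` (pixel-level logical), `truth`
#'   (per-cell data.frame: `grid_row`, `grid_col`, `tissue_fraction`,
#'   `is_tumor_texture`), `tumor_patches` (cells carrying the class
#'   texture), `label`, `spec`.
#' @export
generateToySlide <- function(spec, slide_id = NULL) {
  stopifnot(inherits(spec, "ToySlideSpec"))
  if (is.null(slide_id))
    slide_id <- paste0(spec$label, "_s", spec$seed)
  set.seed(spec$seed)
  side <- spec$image_side
  ps <- spec$patch_side
  G <- side %/% ps
  # background
  img <- array(.bg_level + .tnoise(side * side * 3, .bg_noise_sd),
               c(side, side, 3))
  mask <- matrix(FALSE, side, side)
  # piece slots on a stride-3 cell lattice keep pieces >= 2 apart
  slot_origins <- expand.grid(r = seq(0L, G - 2L, by = 3L),
                              c = seq(0L, G - 2L, by = 3L))
  if (spec$n_pieces > nrow(slot_origins))
    stop("n_pieces = ", spec$n_pieces, " does not fit an image of ",
         G, "x", G, " cells (max ", nrow(slot_origins), ")")
  take <- sample.int(nrow(slot_origins), spec$n_pieces)
  pieces <- list()
  for (k in seq_len(spec$n_pieces)) {
    o <- slot_origins[take[k], ]
    # 2x2-cell rectangle; the top/left sides shrink by up to 0.9 cell
    # (so boundary cells can fall under the tissue filter) while the
    # bottom/right sides shrink at most 0.25 cell, guaranteeing the
    # bottom-right cell always keeps >= 0.56 coverage and each piece
    # survives tiling
    shr <- stats::runif(4, 0, c(0.9, 0.25, 0.9, 0.25)) * ps
    r0 <- o$r * ps + 1 + round(shr[1])
    r1 <- (o$r + 2L) * ps - round(shr[2])
    c0 <- o$c * ps + 1 + round(shr[3])
    c1 <- (o$c + 2L) * ps - round(shr[4])
    mask[r0:r1, c0:c1] <- TRUE
    for (ch in 1:3) {
      blk <- img[r0:r1, c0:c1, ch]
      blk[] <- .tissue_rgb[ch] + .tnoise(length(blk), 0.02)
      img[r0:r1, c0:c1, ch] <- blk
    }
    pieces[[k]] <- c(r0, r1, c0, c1)
  }
  # per-cell coverage and texture assignment
  cells <- expand.grid(grid_row = 0:(G - 1L), grid_col = 0:(G - 1L))
  cov <- mapply(function(r, cc) {
    mean(mask[r * ps + seq_len(ps), cc * ps + seq_len(ps)])
  }, cells$grid_row, cells$grid_col)
  eligible <- which(cov >= 0.5)
  tumor_cells <- integer(0)
  if (spec$label != "no-tumor") {
    n_tex <- max(1L, ceiling(spec$tumor_patch_fraction * length(eligible)))
    tumor_cells <- eligible[sample.int(length(eligible),
                                       min(n_tex, length(eligible)))]
  }
  # textures: baseline sparse blobs everywhere on tissue, class texture
  # in the selected cells
  base_tx <- .texture_params[["no-tumor"]]
  class_tx <- .texture_params[[spec$label]]
  occupied <- which(cov > 0)
  for (ci in occupied) {
    r <- cells$grid_row[ci]; cc <- cells$grid_col[ci]
    # texture region: cell intersected with the tissue mask's bounding rows
    rr <- r * ps + seq_len(ps); ccx <- cc * ps + seq_len(ps)
    sub <- mask[rr, ccx]
    if (!any(sub)) next
    rows <- range(which(rowSums(sub) > 0))
    colsx <- range(which(colSums(sub) > 0))
    tx <- if (ci %in% tumor_cells) class_tx else base_tx
    area <- (rows[2] - rows[1] + 1) * (colsx[2] - colsx[1] + 1)
    n_blobs <- round(tx["density"] * area / (pi * tx["radius"]^2))
    if (ci %in% tumor_cells) n_blobs <- max(n_blobs, 3L)
    img <- .paint_blobs(img, rr[1] + rows[1] - 1L, rr[1] + rows[2] - 1L,
                        ccx[1] + colsx[1] - 1L, ccx[1] + colsx[2] - 1L,
                        n_blobs, tx["radius"], .blob_rgb)
  }
  img <- pmin(pmax(img, 0), 1)
  truth <- data.frame(cells,
                      tissue_fraction = cov,
                      is_tumor_texture = seq_len(nrow(cells)) %in% tumor_cells)
  list(slide = slideFromArray(img, slide_id, magnifications = 10),
       image = img, tissue_mask = mask, truth = truth,
       tumor_patches = cells[tumor_cells, , drop = FALSE],
       label = spec$label, spec = spec)
}

# deterministic per-slide seed derived from a master seed (kept < 2^31)
.slide_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 7919 + index * 104729) %% 2147483587)
}

#' Generate a labelled toy cohort
#'
#' @param n_per_class named integer vector, e.g.
#'   `c("no-tumor" = 10, "Ia" = 10)`; names drawn from the base label set.
#' @param image_side,patch_side,n_pieces forwarded to [toySlideSpec()];
#'   `n_pieces` may be a range from which each slide draws uniformly.
#' @param tumor_patch_fraction texture fraction for tumor slides.
#' @param master_seed master seed; each slide is seeded by a hash of the
#'   master seed and the slide index.
#' @return list of class `ToyCohort`: `slides` (list of
#'   [generateToySlide()] results), `manifest` (data.frame `slide_id`,
#'   `base_label`, `n_pieces`, `seed`), `master_seed`.
#' @export
generateCohort <- function(n_per_class, image_side = 256L, patch_side = 32L,
                           n_pieces = c(1L, 3L),
                           tumor_patch_fraction = 0.6, master_seed = 1L) {
  if (length(n_per_class) == 0L) stop("n_per_class is empty")
  if (any(n_per_class < 0)) stop("negative class counts")
  bad <- setdiff(names(n_per_class), names(.texture_params))
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  slides <- list(); rows <- list()
  idx <- 0L
  for (lab in names(n_per_class)) {
    for (j in seq_len(n_per_class[[lab]])) {
      idx <- idx + 1L
      sd_i <- .slide_seed(master_seed, idx)
      set.seed(sd_i)
      np <- if (length(n_pieces) > 1L)
        sample(seq(n_pieces[1], n_pieces[2]), 1L) else n_pieces
      spec <- toySlideSpec(lab, image_side = image_side,
                           patch_side = patch_side, n_pieces = np,
                           tumor_patch_fraction =
                             if (lab == "no-tumor") 0 else tumor_patch_fraction,
                           seed = sd_i)
      id <- sprintf("slide_%03d_%s", idx, lab)
      slides[[idx]] <- generateToySlide(spec, slide_id = id)
      rows[[idx]] <- data.frame(slide_id = id, base_label = lab,
                                n_pieces = np, seed = sd_i)
    }
  }
  structure(list(slides = slides, manifest = do.call(rbind, rows),
                 master_seed = as.integer(master_seed)),
            class = "ToyCohort")
}

#' Generate an excision-like pretraining patch corpus
#'
#' Larger toy slides (more tissue pieces per slide, all five texture
#' classes represented) tiled into a patch corpus drawn from the same
#' texture family as the cohorts, so pretrained features transfer by
#' construction.
#'
#' @param n_slides number of corpus slides (>= 1).
#' @param image_side,patch_side slide geometry (default 384 / 32).
#' @param min_tissue tiling filter threshold (default 0.15).
#' @param seed integer seed.
#' @return list: `patches` (list of patch rasters), `per_slide` (patch
#'   count per slide), `metadata` (texture family shared with the
#'   cohorts).
#' @export
generatePretrainCorpus <- function(n_slides, image_side = 384L,
                                   patch_side = 32L, min_tissue = 0.15,
                                   seed = 1L) {
  stopifnot(n_slides >= 1)
  labs <- names(.texture_params)
  patches <- list(); per_slide <- integer(n_slides)
  for (i in seq_len(n_slides)) {
    sd_i <- .slide_seed(seed, i)
    lab <- labs[(i - 1L) %% length(labs) + 1L]
    spec <- toySlideSpec(lab, image_side = image_side,
                         patch_side = patch_side, n_pieces = 6L,
                         tumor_patch_fraction =
                           if (lab == "no-tumor") 0 else 0.6,
                         seed = sd_i)
    ts <- generateToySlide(spec, slide_id = sprintf("excision_%03d", i))
    ps <- tileSlide(ts$slide, target_mag = 10, side_px = patch_side,
                    min_tissue = min_tissue)
    per_slide[i] <- length(ps@patches)
    patches <- c(patches, ps@patches)
  }
  list(patches = patches, per_slide = per_slide,
       metadata = list(texture_family = names(.texture_params),
                       texture_params = .texture_params,
                       patch_side = patch_side, seed = seed))
}

#' Write a toy cohort to disk (PNG images + CSV manifests)
#'
#' Emits one PNG per slide, the cohort manifest CSV and the per-cell
#' ground-truth CSV (`slide_id`, `grid_row`, `grid_col`, `is_tissue`,
#' `is_tumor_texture`).
#'
#' @param cohort a `ToyCohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ToyCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truths <- list()
  for (i in seq_along(cohort$slides)) {
    s <- cohort$slides[[i]]
    id <- s$slide@slideId
    png::writePNG(s$image, file.path(dir, paste0(id, ".png")))
    tr <- s$truth
    truths[[i]] <- data.frame(slide_id = id, grid_row = tr$grid_row,
                              grid_col = tr$grid_col,
                              is_tissue = tr$tissue_fraction >= 0.15,
                              is_tumor_texture = tr$is_tumor_texture)
  }
  data.table::fwrite(cohort$manifest, file.path(dir, "manifest.csv"))
  data.table::fwrite(do.call(rbind, truths), file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Tile, embed and graph a cohort with a frozen encoder
#'
#' Convenience pipeline: each cohort slide is tiled at the working
#' magnification, its surviving patches embedded with the frozen encoder,
#' the spatial graph built and split into connected components. Slides
#' whose tiling is empty are dropped (with a warning naming them).
#'
#' @param cohort a `ToyCohort` (or any list with `slides` of
#'   [generateToySlide()] results and a `manifest`).
#' @param encoder an [EncoderState-class].
#' @param min_tissue tiling threshold (default 0.15).
#' @return list: `graphs` (per slide, list of [TissueGraph-class]
#'   components), `base_labels` (character), `slide_ids`.
#' @export
cohortGraphs <- function(cohort, encoder, min_tissue = 0.15) {
  graphs <- list(); labels <- character(); ids <- character()
  for (i in seq_along(cohort$slides)) {
    s <- cohort$slides[[i]]
    ps <- tileSlide(s$slide, target_mag = 10,
                    side_px = s$spec$patch_side, min_tissue = min_tissue)
    if (nrow(ps@manifest) == 0L) {
      warning("slide '", s$slide@slideId, "' has no surviving patches")
      next
    }
    emb <- embedPatches(encoder, ps)
    tg <- buildTissueGraph(emb)
    graphs[[length(graphs) + 1L]] <- splitComponents(tg)
    labels <- c(labels, cohort$manifest$base_label[i])
    ids <- c(ids, s$slide@slideId)
  }
  list(graphs = graphs, base_labels = labels, slide_ids = ids)
}
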