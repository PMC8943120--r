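# Slide reading, tissue segmentation and the 256 px / 5x tile grid.
#
# Slides are represented as a small list of image levels (a pyramid, or a
# single plane for plain PNG/TIFF); all tiling happens on a working plane
# resampled to the requested magnification, with 0-based, half-open pixel
# coordinates and row-major tile ordering.

#' Open a slide for tiling
#'
#' Accepts a pyramidal or plain TIFF, a PNG, an in-memory RGB array, or a
#' synthetic [compose_slide()] result. Plain images are treated as a
#' single-level slide whose base level is at `base_magnification`.
#'
#' @param x file path, RGB array `h x w x 3`, or `qc_slide`.
#' @param slide_id identifier recorded in patch references.
#' @param base_magnification magnification of the highest-resolution
#'   level (default 5).
#' @return object of class `qc_wsi` with `levels` (list of RGB arrays,
#'   largest first), `magnifications`, and `slide_id`.
#' @export
read_slide <- function(x, slide_id = NULL, base_magnification = 5) {
  levels <- NULL
  if (inherits(x, "qc_wsi")) return(x)
  if (inherits(x, "qc_slide")) {
    levels <- list(x$image)
    if (is.null(slide_id)) slide_id <- sprintf("synthetic_%d", x$seed)
  } else if (is.character(x)) {
    if (is.null(slide_id)) slide_id <- sub("\\.[^.]+$", "", basename(x))
    if (grepl("\\.png$", x, ignore.case = TRUE)) {
      levels <- list(ensure_rgb(png::readPNG(x)))
    } else if (grepl("\\.tiff?$", x, ignore.case = TRUE)) {
      planes <- tiff::readTIFF(x, all = TRUE)
      if (!is.list(planes)) planes <- list(planes)
      planes <- lapply(planes, ensure_rgb)
      ord <- order(vapply(planes, function(p) prod(dim(p)[1:2]), 0),
                   decreasing = TRUE)
      levels <- planes[ord]
    } else stop("unsupported slide format: ", x, call. = FALSE)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    levels <- list(x)
    if (is.null(slide_id)) slide_id <- "slide"
  } else stop("cannot interpret `x` as a slide", call. = FALSE)
  base_dim <- dim(levels[[1]])[1:2]
  mags <- vapply(levels, function(p) base_magnification * dim(p)[1] / base_dim[1], 0)
  structure(list(levels = levels, magnifications = mags,
                 slide_id = slide_id, base_magnification = base_magnification,
                 cache = new.env(parent = emptyenv())),
            class = "qc_wsi")
}

ensure_rgb <- function(img) {
  if (length(dim(img)) == 2L) {
    out <- array(img, dim = c(dim(img), 3L))
    return(out)
  }
  if (dim(img)[3] >= 3L) return(img[, , 1:3, drop = FALSE])
  array(img[, , 1], dim = c(dim(img)[1:2], 3L))
}

#' @export
print.qc_wsi <- function(x, ...) {
  d <- dim(x$levels[[1]])
  cat(sprintf("<qc_wsi> '%s': %d level(s), base %d x %d px at %gx\n",
              x$slide_id, length(x$levels), d[1], d[2],
              x$base_magnification))
  invisible(x)
}

# Full plane resampled to `magnification`; the level with the nearest
# magnification is read and bilinearly rescaled to the exact target.
slide_plane <- function(slide, magnification = 5) {
  stopifnot(inherits(slide, "qc_wsi"))
  key <- sprintf("plane_%g", magnification)
  if (!is.null(slide$cache[[key]])) return(slide$cache[[key]])
  i <- which.min(abs(slide$magnifications - magnification))
  plane <- slide$levels[[i]]
  scale <- magnification / slide$magnifications[i]
  if (abs(scale - 1) > 1e-9) {
    target <- round(dim(plane)[1:2] * scale)
    img <- EBImage::Image(aperm(plane, c(2, 1, 3)), colormode = "Color")
    plane <- aperm(EBImage::imageData(
      EBImage::resize(img, w = target[1], h = target[2])), c(2, 1, 3))
    plane <- clamp01(plane)
  }
  slide$cache[[key]] <- plane
  plane
}

#' Downsampled thumbnail of a slide
#'
#' @param slide a `qc_wsi` (or anything [read_slide()] accepts).
#' @param max_dim longest side of the thumbnail in pixels.
#' @param magnification working magnification the downsample factor is
#'   expressed against.
#' @return list with `image` (RGB array) and `downsample` (factor
#'   relative to the working magnification).
#' @export
slide_thumbnail <- function(slide, max_dim = 512L, magnification = 5) {
  slide <- read_slide(slide)
  plane_dim <- round(dim(slide$levels[[1]])[1:2] *
                       magnification / slide$base_magnification)
  ds <- max(1, max(plane_dim) / max_dim)
  i <- which.min(abs(slide$magnifications - magnification / ds))
  src <- slide$levels[[i]]
  target <- pmax(1L, round(plane_dim / ds))
  img <- EBImage::Image(aperm(src, c(2, 1, 3)), colormode = "Color")
  thumb <- aperm(EBImage::imageData(
    EBImage::resize(img, w = target[1], h = target[2])), c(2, 1, 3))
  list(image = clamp01(thumb), downsample = plane_dim[1] / target[1])
}

#' Segment tissue from a slide thumbnail
#'
#' Otsu threshold on the HSV saturation channel, followed by small-object
#' removal and hole filling. Stained tissue is saturated against the
#' near-white glass background, so saturation separates the two without
#' depending on stain intensity.
#'
#' @param thumbnail RGB array (e.g. `slide_thumbnail()$image`).
#' @param downsample factor of the thumbnail relative to the working
#'   magnification (stored in the result).
#' @param min_object_frac connected components smaller than this fraction
#'   of the image are removed.
#' @param fill_holes fill enclosed background holes in the mask.
#' @return object of class `tissue_mask`: list with logical `mask` and
#'   `downsample`. An all-background image yields an empty (all-FALSE)
#'   mask.
#' @export
segment_tissue <- function(thumbnail, downsample = 1,
                           min_object_frac = 5e-4, fill_holes = TRUE) {
  if (is.list(thumbnail) && !is.null(thumbnail$image)) {
    if (missing(downsample) && !is.null(thumbnail$downsample))
      downsample <- thumbnail$downsample
    thumbnail <- thumbnail$image
  }
  assert_patch(thumbnail)
  mx <- pmax(thumbnail[, , 1], thumbnail[, , 2], thumbnail[, , 3])
  mn <- pmin(thumbnail[, , 1], thumbnail[, , 2], thumbnail[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  if (max(sat) < 1e-3) {
    mask <- matrix(FALSE, nrow(sat), ncol(sat))
  } else {
    thr <- EBImage::otsu(EBImage::Image(t(sat)), range = c(0, 1))
    mask <- sat > thr
    if (any(mask)) {
      lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
      sizes <- table(as.vector(EBImage::imageData(lab)))
      sizes <- sizes[names(sizes) != "0"]
      keep <- as.integer(names(sizes)[sizes >= min_object_frac * length(mask)])
      mask <- t(matrix(EBImage::imageData(lab) %in% keep, nrow(t(mask)), ncol(t(mask))))
      if (fill_holes && any(mask)) {
        filled <- EBImage::fillHull(EBImage::Image(t(mask)))
        mask <- t(EBImage::imageData(filled)) > 0
      }
    }
  }
  structure(list(mask = mask, downsample = downsample), class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d x %d (downsample %g), %.1f%% tissue\n",
              nrow(x$mask), ncol(x$mask), x$downsample, 100 * mean(x$mask)))
  invisible(x)
}

#' Build the patch grid of a slide
#'
#' Tiles the working plane into full `size` x `size` patches (partial
#' edge tiles are dropped); a tile is kept when its tissue fraction is at
#' least `min_tissue_fraction`. Output is sorted row-major.
#'
#' @param slide a `qc_wsi` (or anything [read_slide()] accepts).
#' @param mask optional [segment_tissue()] result; `NULL` keeps all tiles.
#' @param size tile side in pixels (default 256).
#' @param min_tissue_fraction minimum tissue fraction to keep a tile.
#' @param magnification working magnification (default 5).
#' @return data frame of class `patch_refs` with columns `slide_id`,
#'   `row`, `col` (0-based grid indices), `x0`, `y0` (0-based pixel
#'   origin), `size`, `magnification`, `tissue_fraction`.
#' @export
tile_grid <- function(slide, mask = NULL, size = 256L,
                      min_tissue_fraction = 0.1, magnification = 5) {
  slide <- read_slide(slide)
  plane_dim <- round(dim(slide$levels[[1]])[1:2] *
                       magnification / slide$base_magnification)
  n_rows <- plane_dim[1] %/% size
  n_cols <- plane_dim[2] %/% size
  if (n_rows == 0 || n_cols == 0) {
    refs <- data.frame(slide_id = character(0), row = integer(0),
                       col = integer(0), x0 = integer(0), y0 = integer(0),
                       size = integer(0), magnification = numeric(0),
                       tissue_fraction = numeric(0))
    class(refs) <- c("patch_refs", "data.frame")
    return(refs)
  }
  grid <- expand.grid(col = 0:(n_cols - 1), row = 0:(n_rows - 1))
  grid <- grid[order(grid$row, grid$col), ]
  frac <- rep(1, nrow(grid))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "tissue_mask"))
    m <- mask$mask
    d <- mask$downsample
    frac <- vapply(seq_len(nrow(grid)), function(i) {
      y0 <- grid$row[i] * size; x0 <- grid$col[i] * size
      ys <- max(1, floor(y0 / d) + 1):min(nrow(m), ceiling((y0 + size) / d))
      xs <- max(1, floor(x0 / d) + 1):min(ncol(m), ceiling((x0 + size) / d))
      mean(m[ys, xs])
    }, 0)
  }
  keep <- frac >= min_tissue_fraction
  refs <- data.frame(slide_id = slide$slide_id, row = grid$row[keep],
                     col = grid$col[keep],
                     x0 = grid$col[keep] * size, y0 = grid$row[keep] * size,
                     size = as.integer(size), magnification = magnification,
                     tissue_fraction = frac[keep])
  rownames(refs) <- NULL
  class(refs) <- c("patch_refs", "data.frame")
  refs
}

#' Read one patch from a slide
#'
#' Returns exactly the half-open pixel window `[x0, x0+size) x
#' [y0, y0+size)` of the working plane (the pyramid level nearest the
#' requested magnification, resampled to the exact working scale).
#'
#' @param slide a `qc_wsi`.
#' @param ref one row of a [tile_grid()] result (or a list with `x0`,
#'   `y0`, `size`, `magnification`).
#' @param plane optional pre-computed working plane (internal use).
#' @return RGB array `size x size x 3`.
#' @export
read_patch <- function(slide, ref, plane = NULL) {
  slide <- read_slide(slide)
  if (is.data.frame(ref)) {
    stopifnot(nrow(ref) == 1L)
    ref <- as.list(ref)
  }
  if (is.null(plane)) plane <- slide_plane(slide, ref$magnification)
  if (ref$x0 < 0 || ref$y0 < 0 || ref$x0 + ref$size > dim(plane)[2] ||
      ref$y0 + ref$size > dim(plane)[1])
    stop("patch reference out of slide bounds", call. = FALSE)
  plane[(ref$y0 + 1):(ref$y0 + ref$size),
        (ref$x0 + 1):(ref$x0 + ref$size), , drop = FALSE]
}

#' Read all referenced patches from a slide
#'
#' @param slide a `qc_wsi`.
#' @param refs a [tile_grid()] data frame.
#' @return list of RGB arrays in the row order of `refs`.
#' @export
read_patches <- function(slide, refs) {
  slide <- read_slide(slide)
  if (nrow(refs) == 0) return(list())
  plane <- slide_plane(slide, refs$magnification[1])
  lapply(seq_len(nrow(refs)), function(i)
    read_patch(slide, refs[i, ], plane = plane))
}
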