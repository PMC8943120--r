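# Per-category quality overlays: patch predictions arranged on the tile
# grid, their summary statistics, and rendered heatmaps.

OVERLAY_CATEGORIES <- c("usability", "no_artefact", "staining", "focus",
                        "folding", "other")

#' Assemble patch predictions into per-category quality overlays
#'
#' Places each patch's six predictions at its (row, col) grid cell,
#' clamped to `[0, 1]`; cells without a kept tile are absent (`NA`).
#'
#' @param predictions matrix/data frame with columns `p1`..`p6` (or six
#'   unnamed columns), one row per reference.
#' @param refs [tile_grid()] data frame (columns `row`, `col`).
#' @param dims grid dimensions `c(n_rows, n_cols)`; inferred from `refs`
#'   when `NULL`.
#' @return object of class `quality_overlays`: named list of six
#'   `n_rows x n_cols` matrices.
#' @export
assemble_overlays <- function(predictions, refs, dims = NULL) {
  predictions <- as.matrix(predictions)
  if (ncol(predictions) != 6)
    stop("`predictions` must have six columns", call. = FALSE)
  if (nrow(predictions) != nrow(refs))
    stop("one prediction per patch reference required", call. = FALSE)
  if (anyDuplicated(refs[, c("row", "col")]))
    stop("duplicate patch references", call. = FALSE)
  if (is.null(dims)) dims <- c(max(refs$row) + 1L, max(refs$col) + 1L)
  vals <- clamp01(predictions)
  out <- lapply(1:6, function(k) {
    m <- matrix(NA_real_, dims[1], dims[2])
    m[cbind(refs$row + 1L, refs$col + 1L)] <- vals[, k]
    m
  })
  names(out) <- OVERLAY_CATEGORIES
  structure(out, class = "quality_overlays")
}

#' @export
print.quality_overlays <- function(x, ...) {
  d <- dim(x$usability)
  cat(sprintf("<quality_overlays> %d x %d grid, %d tissue cells\n",
              d[1], d[2], sum(!is.na(x$usability))))
  means <- vapply(unclass(x), function(m) mean(m, na.rm = TRUE), 0)
  print(round(means, 3))
  invisible(x)
}

#' Mean and variance of a quality overlay
#'
#' Statistics are over present (tissue) cells only; the variance is the
#' population variance.
#'
#' @param overlay a single overlay matrix, or a `quality_overlays` list
#'   (then all six are summarised).
#' @return for a matrix: named vector `c(mean, variance)`; for a
#'   `quality_overlays`: named vector of 12 statistics
#'   (`mean_<category>`, `var_<category>`).
#' @export
overlay_stats <- function(overlay) {
  if (inherits(overlay, "quality_overlays")) {
    out <- numeric(0)
    for (nm in names(overlay)) {
      s <- overlay_stats(overlay[[nm]])
      out[paste0("mean_", nm)] <- s[["mean"]]
      out[paste0("var_", nm)] <- s[["variance"]]
    }
    return(out)
  }
  v <- overlay[!is.na(overlay)]
  if (length(v) == 0)
    stop("overlay has no present cells; slide is unscorable", call. = FALSE)
  c(mean = mean(v), variance = mean((v - mean(v))^2))
}

#' Render a quality overlay as a heatmap raster
#'
#' One `block` x `block` pixel square per grid cell, colour-coded by the
#' cell value through `palette`; absent cells are transparent.
#'
#' @param overlay a single overlay matrix.
#' @param palette two or more colours from value 0 to value 1 (default
#'   white to blue; reverse for "higher is worse" readings).
#' @param block pixels per cell.
#' @param file optional PNG path to write.
#' @return RGBA array `(rows*block) x (cols*block) x 4`, invisibly.
#' @export
render_heatmap <- function(overlay, palette = c("white", "blue"),
                           block = 16L, file = NULL) {
  stopifnot(is.matrix(overlay))
  ramp <- grDevices::colorRampPalette(palette)(256)
  cols <- grDevices::col2rgb(ramp) / 255
  idx <- function(v) pmin(255L, pmax(0L, as.integer(round(v * 255)))) + 1L
  nr <- nrow(overlay); nc <- ncol(overlay)
  out <- array(0, dim = c(nr * block, nc * block, 4L))
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    v <- overlay[r, cc]
    ys <- ((r - 1) * block + 1):(r * block)
    xs <- ((cc - 1) * block + 1):(cc * block)
    if (is.na(v)) next
    k <- idx(v)
    out[ys, xs, 1] <- cols[1, k]
    out[ys, xs, 2] <- cols[2, k]
    out[ys, xs, 3] <- cols[3, k]
    out[ys, xs, 4] <- 1
  }
  if (!is.null(file)) png::writePNG(out, file)
  invisible(out)
}
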