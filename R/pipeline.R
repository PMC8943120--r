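# End-to-end slide profiling: tissue mask -> tile grid -> patch
# predictions -> overlays -> (optionally) slide-level scores.

#' Run the full quality-assessment pipeline on one slide
#'
#' Segments tissue on a thumbnail, tiles the working plane into 256 px
#' patches at the working magnification, scores every kept patch with
#' the quality network, assembles the six quality overlays, and -- when
#' slide-level models are supplied -- predicts usability, focus and
#' staining scores with an intervention recommendation.
#'
#' @param slide anything [read_slide()] accepts.
#' @param model a fitted [qnet()].
#' @param slide_models optional [fit_slide_models()] result.
#' @param size patch side in pixels (default 256).
#' @param magnification working magnification (default 5).
#' @param min_tissue_fraction minimum tissue fraction to keep a tile.
#' @param use_mask segment tissue and drop low-tissue tiles (set FALSE
#'   to keep the full grid, e.g. for synthetic slides with known
#'   geometry).
#' @return list of class `slide_profile`: `refs`, `predictions`
#'   (unclamped), `overlays`, `stats` (the 12 overlay statistics),
#'   `scores` (a `slide_scores` row or `NULL`), `mask`.
#' @export
profile_slide <- function(slide, model, slide_models = NULL, size = 256L,
                          magnification = 5, min_tissue_fraction = 0.1,
                          use_mask = TRUE) {
  slide <- read_slide(slide)
  mask <- NULL
  if (use_mask) {
    thumb <- slide_thumbnail(slide, magnification = magnification)
    mask <- segment_tissue(thumb)
  }
  refs <- tile_grid(slide, mask, size = size,
                    min_tissue_fraction = if (use_mask) min_tissue_fraction else 0,
                    magnification = magnification)
  if (nrow(refs) == 0)
    stop("no tiles kept; slide has no usable tissue area", call. = FALSE)
  patches <- read_patches(slide, refs)
  predictions <- predict(model, patches)
  overlays <- assemble_overlays(predictions, refs)
  stats <- overlay_stats(overlays)
  scores <- NULL
  if (!is.null(slide_models))
    scores <- predict(slide_models, as.data.frame(t(stats)),
                      slide_id = slide$slide_id)
  structure(list(slide_id = slide$slide_id, refs = refs,
                 predictions = predictions, overlays = overlays,
                 stats = stats, scores = scores, mask = mask),
            class = "slide_profile")
}

#' @export
print.slide_profile <- function(x, ...) {
  cat(sprintf("<slide_profile> '%s': %d patches\n", x$slide_id, nrow(x$refs)))
  print(x$overlays)
  if (!is.null(x$scores)) print(x$scores)
  invisible(x)
}
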