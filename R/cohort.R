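# Cohort-level summaries and the feature-space overlap diagnostic.

#' Summarise patch- and slide-level quality over a cohort
#'
#' @param predictions per-patch prediction matrix/data frame (`p1`..`p6`;
#'   clamped to `[0, 1]` for the means).
#' @param slide_scores a `slide_scores` data frame (one row per slide),
#'   or `NULL` for patch-level summaries only.
#' @return object of class `cohort_summary`: per-category mean patch
#'   scores, integer-binned (0-10) histograms of slide focus/stain
#'   scores, fraction of usable slides, and counts flagged for
#'   re-scan/re-stain.
#' @export
summarise_cohort <- function(predictions, slide_scores = NULL) {
  predictions <- clamp01(as.matrix(predictions))
  if (nrow(predictions) == 0) stop("empty cohort", call. = FALSE)
  patch_means <- colMeans(predictions)
  names(patch_means) <- OVERLAY_CATEGORIES[seq_along(patch_means)]
  out <- list(patch_means = patch_means, n_patches = nrow(predictions))
  if (!is.null(slide_scores)) {
    bins <- function(v) {
      h <- tabulate(pmin(10L, pmax(0L, as.integer(round(v)))) + 1L, nbins = 11L)
      names(h) <- 0:10
      h
    }
    out$n_slides <- nrow(slide_scores)
    out$fraction_usable <- mean(slide_scores$usable)
    out$focus_hist <- bins(slide_scores$focus_score)
    out$stain_hist <- bins(slide_scores$stain_score)
    out$n_rescan <- sum(slide_scores$intervention %in%
                          c("rescan", "rescan_and_restain"))
    out$n_restain <- sum(slide_scores$intervention %in%
                           c("restain", "rescan_and_restain"))
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d patches\n", x$n_patches))
  cat("mean patch scores:\n")
  print(round(x$patch_means, 3))
  if (!is.null(x$n_slides)) {
    cat(sprintf("%d slides, %.0f%% usable; %d flagged for re-scan, %d for re-stain\n",
                x$n_slides, 100 * x$fraction_usable, x$n_rescan, x$n_restain))
  }
  invisible(x)
}

# Integrated minimum of two densities on a shared grid (both normalised
# to integrate to 1); 1 = identical, 0 = disjoint.
density_overlap <- function(d1, d2, cell_area) {
  z1 <- d1 / (sum(d1) * cell_area)
  z2 <- d2 / (sum(d2) * cell_area)
  sum(pmin(z1, z2)) * cell_area
}

#' Feature-space overlap between patch cohorts
#'
#' Embeds each cohort's patches with the network's penultimate (pooled)
#' layer, projects the union onto its first two principal components,
#' estimates a 2D kernel density per cohort on a shared grid, and
#' reports pairwise overlap as the integrated minimum of the normalised
#' densities (1 = identical feature distributions).
#'
#' @param cohorts named list of patch sets (each a `qc_dataset`, array
#'   or list of patches; at least 3 patches each).
#' @param model a fitted [qnet()].
#' @param grid_n kernel-density grid resolution per axis.
#' @return list with `embedding` (data frame: `cohort`, `PC1`, `PC2`),
#'   `overlap` (symmetric matrix), `bandwidth`, and `pca` (the fitted
#'   projection).
#' @export
embed_and_compare <- function(cohorts, model, grid_n = 64L) {
  if (length(cohorts) < 2 || is.null(names(cohorts)))
    stop("`cohorts` must be a named list of at least two patch sets", call. = FALSE)
  sizes <- vapply(cohorts, function(x) length(as_patch_list(x)), 0L)
  if (any(sizes < 3))
    stop("each cohort needs at least 3 patches", call. = FALSE)
  feats <- lapply(cohorts, function(x) predict(model, x, type = "features"))
  union <- do.call(rbind, feats)
  pca <- prcomp(union, center = TRUE, scale. = FALSE, rank. = 2)
  proj <- predict(pca, union)[, 1:2, drop = FALSE]
  cohort_id <- rep(names(cohorts), times = sizes)
  # shared bandwidth and grid from the union
  bw <- c(MASS::bandwidth.nrd(proj[, 1]), MASS::bandwidth.nrd(proj[, 2]))
  bw[bw <= 0] <- 1e-3
  pad <- bw
  lims <- c(range(proj[, 1]) + c(-1, 1) * pad[1],
            range(proj[, 2]) + c(-1, 1) * pad[2])
  dens <- lapply(names(cohorts), function(nm) {
    p <- proj[cohort_id == nm, , drop = FALSE]
    MASS::kde2d(p[, 1], p[, 2], h = bw, n = grid_n, lims = lims)
  })
  names(dens) <- names(cohorts)
  cell <- diff(dens[[1]]$x[1:2]) * diff(dens[[1]]$y[1:2])
  k <- length(cohorts)
  overlap <- matrix(1, k, k, dimnames = list(names(cohorts), names(cohorts)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    o <- density_overlap(dens[[i]]$z, dens[[j]]$z, cell)
    overlap[i, j] <- o
    overlap[j, i] <- o
  }
  list(embedding = data.frame(cohort = cohort_id, PC1 = proj[, 1],
                              PC2 = proj[, 2]),
       overlap = overlap, bandwidth = bw, pca = pca)
}
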