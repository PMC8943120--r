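# H&E stain separation in optical-density space.
#
# RGB intensities I in (0, 1] relate to stain densities d through the
# Beer-Lambert law: -log10(I) = d %*% M, where the rows of M are the
# absorbance (optical-density) vectors of hematoxylin, eosin and a residual
# channel. Inverting M separates the stains; the same matrix reconstructs
# RGB from densities, so fade/fold artefacts can be simulated directly in
# stain-density space rather than by scaling brightness.

# Canonical H&E(+residual) absorbance matrix (rows normalised to unit norm).
he_absorbance_matrix <- function() {
  m <- rbind(
    hematoxylin = c(0.65, 0.70, 0.29),
    eosin       = c(0.07, 0.99, 0.11),
    residual    = c(0.27, 0.57, 0.78)
  )
  m / sqrt(rowSums(m^2))
}

#' Convert an RGB patch to optical density
#'
#' @param patch numeric array `h x w x 3`, values in `[0, 1]`.
#' @param eps floor applied to intensities before the log so pure black
#'   maps to a large finite density.
#' @return array `h x w x 3` of per-channel optical densities (>= 0).
#' @export
rgb_to_od <- function(patch, eps = 1e-6) {
  assert_patch(patch)
  patch[patch < eps] <- eps
  -log10(patch)
}

#' Convert optical density back to RGB
#'
#' @param od array `h x w x 3` of optical densities.
#' @return RGB array with values clamped to `[0, 1]`.
#' @export
od_to_rgb <- function(od) {
  clamp01(10^(-od))
}

#' Deconvolve an H&E patch into stain-density channels
#'
#' Separates an RGB patch into hematoxylin, eosin and residual density
#' channels by inverting the canonical H&E absorbance matrix in optical
#' density space. Densities are clipped at zero.
#'
#' @param patch numeric array `h x w x 3`, values in `[0, 1]`.
#' @return list with matrices `hematoxylin`, `eosin`, `residual` (each
#'   `h x w`, non-negative) and the `absorbance` matrix used.
#' @examples
#' p <- generate_base_patch(1, 64)
#' d <- stain_deconvolve(p)
#' mean(d$hematoxylin)
#' @export
stain_deconvolve <- function(patch) {
  assert_patch(patch)
  m <- he_absorbance_matrix()
  od <- rgb_to_od(patch)
  dm <- dim(patch)
  flat <- matrix(od, ncol = 3L)            # pixels x 3 (od per channel)
  dens <- flat %*% solve(m)                # pixels x 3 (density per stain)
  dens[dens < 0] <- 0
  list(
    hematoxylin = matrix(dens[, 1], dm[1], dm[2]),
    eosin       = matrix(dens[, 2], dm[1], dm[2]),
    residual    = matrix(dens[, 3], dm[1], dm[2]),
    absorbance  = m
  )
}

#' Reconstruct an RGB patch from stain densities
#'
#' Inverse of [stain_deconvolve()]: maps per-stain density channels back to
#' RGB through the canonical absorbance matrix.
#'
#' @param hematoxylin,eosin,residual density matrices of equal dimension
#'   (residual defaults to zero).
#' @return RGB array `h x w x 3` in `[0, 1]`.
#' @export
stain_reconstruct <- function(hematoxylin, eosin, residual = NULL) {
  if (is.null(residual)) residual <- matrix(0, nrow(hematoxylin), ncol(hematoxylin))
  m <- he_absorbance_matrix()
  dens <- cbind(as.vector(hematoxylin), as.vector(eosin), as.vector(residual))
  od <- dens %*% m
  out <- array(od, dim = c(nrow(hematoxylin), ncol(hematoxylin), 3L))
  od_to_rgb(out)
}
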