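# Hand-crafted focus/contrast/colour feature banks and per-task random
# forest baselines. Two fixed registries are implemented: an "ours" bank
# (modified-Laplacian LAP2, variance of Laplacian, Tenengrad, Gaussian
# difference, per-channel statistics of RGB/HSV/stain-density channels,
# Otsu threshold) and a HistoQC-style bank (Tenengrad, RMS and Michelson
# contrast, grayscale moments, Gaussian/Laplace/Frangi/Gabor filter means,
# LBP histogram, per-channel means). Kernel sizes are fixed: 3x3
# Sobel/Laplacian, Gaussian sigma 3.

sobel_x <- function() matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
laplacian_kernel <- function() matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE)

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  ax <- seq(-radius, radius)
  k <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Tenengrad focus measure
#'
#' Mean squared Sobel gradient magnitude of the grayscale image; decreases
#' monotonically with defocus blur on textured patches.
#'
#' @param patch RGB array `h x w x 3` or grayscale matrix.
#' @return single non-negative number.
#' @export
focus_tenengrad <- function(patch) {
  g <- if (length(dim(patch)) == 3L) to_gray(patch) else patch
  gx <- filter2_replicate(g, sobel_x())
  gy <- filter2_replicate(g, t(sobel_x()))
  mean(gx^2 + gy^2)
}

#' Variance-of-Laplacian focus measure
#' @inheritParams focus_tenengrad
#' @return single non-negative number.
#' @export
focus_var_laplacian <- function(patch) {
  g <- if (length(dim(patch)) == 3L) to_gray(patch) else patch
  lap <- filter2_replicate(g, laplacian_kernel())
  mean((lap - mean(lap))^2)
}

#' Modified-Laplacian (LAP2) focus measure
#'
#' Mean of `|I * Lx| + |I * Ly|` with the 1D second-difference kernels
#' `[-1, 2, -1]` applied along each axis.
#' @inheritParams focus_tenengrad
#' @return single non-negative number.
#' @export
focus_lap2 <- function(patch) {
  g <- if (length(dim(patch)) == 3L) to_gray(patch) else patch
  lx <- filter2_replicate(g, matrix(c(-1, 2, -1), 1, 3))
  ly <- filter2_replicate(g, matrix(c(-1, 2, -1), 3, 1))
  mean(abs(lx) + abs(ly))
}

otsu_threshold <- function(gray) {
  EBImage::otsu(EBImage::Image(t(gray)), range = c(0, 1))
}

hsv_channels <- function(patch) {
  flat <- rbind(as.vector(patch[, , 1]), as.vector(patch[, , 2]),
                as.vector(patch[, , 3]))
  grDevices::rgb2hsv(flat, maxColorValue = 1)
}

# Uniform LBP (P = 8, R = 1): 10-bin normalised histogram. Patterns with
# at most two 0/1 transitions are binned by their number of set bits
# (0..8); all non-uniform patterns share the final bin.
lbp_histogram <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  c0 <- gray[2:(h - 1), 2:(w - 1)]
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                 c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, h - 2, w - 2)
  for (b in seq_along(shifts)) {
    dy <- shifts[[b]][1]; dx <- shifts[[b]][2]
    nb <- gray[(2 + dy):(h - 1 + dy), (2 + dx):(w - 1 + dx)]
    code <- code + as.integer(nb >= c0) * 2L^(b - 1L)
  }
  map <- lbp_uniform_map()
  counts <- tabulate(map[code + 1L] + 1L, nbins = 10L)
  counts / sum(counts)
}

lbp_uniform_map <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    m <- integer(256)
    for (p in 0:255) {
      bits <- as.integer(intToBits(p))[1:8]
      trans <- sum(bits != c(bits[-1], bits[1]))
      m[p + 1] <- if (trans <= 2) sum(bits) else 9L
    }
    cache <<- m
    m
  }
})

# Single-scale Frangi vesselness (sigma = 2) from Gaussian Hessian
# eigenvalues; responds to bright/dark ridge structure.
frangi_mean <- function(gray, sigma = 2, beta = 0.5, c = 0.08) {
  r <- ceiling(3 * sigma)
  ax <- seq(-r, r)
  g1 <- exp(-ax^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  d2 <- g1 * (ax^2 - sigma^2) / sigma^4
  d1 <- -g1 * ax / sigma^2
  hxx <- filter2_replicate(gray, matrix(d2, 1)) |> filter2_replicate(matrix(g1, ncol = 1))
  hyy <- filter2_replicate(gray, matrix(g1, 1)) |> filter2_replicate(matrix(d2, ncol = 1))
  hxy <- filter2_replicate(gray, matrix(d1, 1)) |> filter2_replicate(matrix(d1, ncol = 1))
  tmp <- sqrt((hxx - hyy)^2 + 4 * hxy^2)
  l1 <- (hxx + hyy + tmp) / 2; l2 <- (hxx + hyy - tmp) / 2
  swap <- abs(l1) > abs(l2)
  big <- ifelse(swap, l1, l2); small <- ifelse(swap, l2, l1)
  rb2 <- (small / pmax(abs(big), 1e-12))^2
  s2 <- big^2 + small^2
  v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * c^2)))
  v[abs(big) < 1e-12] <- 0
  mean(v)
}

gabor_kernel <- function(theta, freq, sigma = 3, radius = 7) {
  ax <- seq(-radius, radius)
  xx <- outer(rep(1, length(ax)), ax); yy <- outer(ax, rep(1, length(ax)))
  xr <- xx * cos(theta) + yy * sin(theta)
  env <- exp(-(xx^2 + yy^2) / (2 * sigma^2))
  k <- env * cos(2 * pi * freq * xr)
  k - mean(k)   # zero-DC so flat regions respond 0
}

#' Compute the "ours" hand-crafted feature bank
#'
#' Fixed registry: LAP2 focus measure, variance of Laplacian, Tenengrad,
#' mean absolute difference from a Gaussian-filtered copy (sigma 3,
#' grayscale), mean per-pixel variance across the R/G/B axis, per-channel
#' means of RGB, HSV and deconvolved H&E stain-density channels, and the
#' Otsu threshold of the grayscale image.
#'
#' @param patch RGB array `h x w x 3` in `[0, 1]`.
#' @return named numeric vector (fixed order).
#' @export
features_ours <- function(patch) {
  assert_patch(patch)
  g <- to_gray(patch)
  hsv <- hsv_channels(patch)
  d <- stain_deconvolve(patch)
  gdiff <- mean(abs(g - filter2_replicate(g, gaussian_kernel(3))))
  # per-pixel sample variance across the R/G/B axis, vectorised
  mu <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  rgbvar <- mean(((patch[, , 1] - mu)^2 + (patch[, , 2] - mu)^2 +
                    (patch[, , 3] - mu)^2) / 2)
  c(lap2 = focus_lap2(g), var_laplacian = focus_var_laplacian(g),
    tenengrad = focus_tenengrad(g), gauss_diff = gdiff,
    rgb_axis_var = rgbvar,
    mean_r = mean(patch[, , 1]), mean_g = mean(patch[, , 2]),
    mean_b = mean(patch[, , 3]),
    mean_h = mean(hsv[1, ]), mean_s = mean(hsv[2, ]), mean_v = mean(hsv[3, ]),
    mean_hema = mean(d$hematoxylin), mean_eosin = mean(d$eosin),
    mean_resid = mean(d$residual),
    otsu = otsu_threshold(g))
}

#' Compute the HistoQC-style feature bank
#'
#' Fixed registry: Tenengrad, RMS contrast, Michelson contrast, grayscale
#' mean/median/variance, means of the image filtered with Gaussian,
#' Laplace, Frangi and Gabor (4 orientations x 2 frequencies) filters, a
#' 10-bin uniform LBP histogram, and per-channel means of RGB, HSV and
#' deconvolved H&E stain-density channels.
#'
#' @inheritParams features_ours
#' @return named numeric vector (fixed order).
#' @export
features_histoqc <- function(patch) {
  assert_patch(patch)
  g <- to_gray(patch)
  hsv <- hsv_channels(patch)
  d <- stain_deconvolve(patch)
  gmean <- mean(g)
  rng <- range(g)
  michelson <- if (sum(rng) < 1e-12) 0 else diff(rng) / sum(rng)
  gabors <- numeric(0)
  for (th in c(0, pi / 4, pi / 2, 3 * pi / 4)) for (fr in c(0.1, 0.25)) {
    gabors <- c(gabors, mean(abs(filter2_replicate(g, gabor_kernel(th, fr)))))
  }
  names(gabors) <- paste0("gabor_", rep(c(0, 45, 90, 135), each = 2), "_",
                          rep(c("f10", "f25"), 4))
  lbp <- lbp_histogram(g)
  names(lbp) <- paste0("lbp_", seq_along(lbp) - 1)
  c(tenengrad = focus_tenengrad(g),
    rms_contrast = sd(as.vector(g)),
    michelson = michelson,
    gray_mean = gmean, gray_median = stats::median(g), gray_var = var(as.vector(g)),
    gauss_mean = mean(filter2_replicate(g, gaussian_kernel(3))),
    laplace_mean = mean(abs(filter2_replicate(g, laplacian_kernel()))),
    frangi_mean = frangi_mean(g),
    gabors, lbp,
    mean_r = mean(patch[, , 1]), mean_g = mean(patch[, , 2]),
    mean_b = mean(patch[, , 3]),
    mean_h = mean(hsv[1, ]), mean_s = mean(hsv[2, ]), mean_v = mean(hsv[3, ]),
    mean_hema = mean(d$hematoxylin), mean_eosin = mean(d$eosin),
    mean_resid = mean(d$residual))
}

#' Feature table for a set of patches
#'
#' @param x a `qc_dataset`, a list of patches, or a 4D array
#'   `h x w x 3 x n`.
#' @param bank `"ours"` or `"histoqc"`.
#' @return data frame, one row per patch, named feature columns.
#' @export
feature_table <- function(x, bank = c("ours", "histoqc")) {
  bank <- match.arg(bank)
  fn <- if (bank == "ours") features_ours else features_histoqc
  patches <- as_patch_list(x)
  as.data.frame(do.call(rbind, lapply(patches, fn)))
}

as_patch_list <- function(x) {
  if (inherits(x, "qc_dataset")) x <- x$x
  if (is.array(x) && length(dim(x)) == 4L)
    return(lapply(seq_len(dim(x)[4]), function(i) x[, , , i]))
  if (is.array(x) && length(dim(x)) == 3L) return(list(x))
  if (is.list(x)) return(x)
  stop("cannot interpret `x` as patches", call. = FALSE)
}
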