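# Synthetic H&E patch and slide generator with ground-truth labels.
#
# Every downstream stage (tiling, the patch quality network, feature
# baselines, overlays, slide scoring) is testable against this generator:
# it produces procedurally textured H&E-like patches and injects the
# artefact catalogue seen on scanned slides -- out-of-focus regions, stain
# fading, tissue folds, ink, dirt, bubbles, coverslip edges and diathermy
# scorch -- with known per-patch labels. Everything is a pure function of
# (parameters, seed).

ARTEFACT_KINDS <- c("focus_blur", "stain_fade", "fold", "ink", "dirt",
                    "bubble", "coverslip_edge", "diathermy")
OTHER_KINDS <- c("ink", "dirt", "bubble", "coverslip_edge", "diathermy")

# Blur severity -> Gaussian sigma (pixels at the 256 px working scale).
severity_sigma <- function(severity, size = 256) {
  c(`0` = 0, `0.5` = 2, `1` = 6)[[as.character(severity)]] * size / 256
}

#' Describe one artefact to inject into a patch
#'
#' @param kind one of `"focus_blur"`, `"stain_fade"`, `"fold"`, `"ink"`,
#'   `"dirt"`, `"bubble"`, `"coverslip_edge"`, `"diathermy"`.
#' @param severity 0, 0.5 (slight) or 1 (severe); meaningful for
#'   `focus_blur` and `stain_fade` only (other kinds are present/absent).
#' @param region rectangle `list(shape="rect", x0, y0, x1, y1)` or disc
#'   `list(shape="disc", cx, cy, r)` in 0-based, half-open patch pixel
#'   coordinates; `NULL` means the whole patch.
#' @param seed integer seed controlling the artefact's internal randomness.
#' @return an object of class `artefact_spec`.
#' @export
artefact_spec <- function(kind, severity = 1, region = NULL, seed = 0L) {
  kind <- match.arg(kind, ARTEFACT_KINDS)
  if (!severity %in% c(0, 0.5, 1))
    stop("`severity` must be one of 0, 0.5, 1", call. = FALSE)
  structure(list(kind = kind, severity = severity, region = region,
                 seed = as.integer(seed)),
            class = "artefact_spec")
}

#' @export
print.artefact_spec <- function(x, ...) {
  reg <- if (is.null(x$region)) "full patch" else
    paste0(x$region$shape, " [", paste(round(unlist(x$region[-1]), 1), collapse = ", "), "]")
  cat(sprintf("<artefact_spec> %s (severity %g) on %s, seed %d\n",
              x$kind, x$severity, reg, x$seed))
  invisible(x)
}

# ---- region geometry ------------------------------------------------------

full_region <- function(size) list(shape = "rect", x0 = 0, y0 = 0, x1 = size, y1 = size)

# Region -> polygon vertices (columns x, y) in pixel coordinates.
region_polygon <- function(region, size, n_arc = 64L) {
  if (is.null(region)) region <- full_region(size)
  switch(region$shape,
    rect = cbind(x = c(region$x0, region$x1, region$x1, region$x0),
                 y = c(region$y0, region$y0, region$y1, region$y1)),
    disc = {
      th <- seq(0, 2 * pi, length.out = n_arc + 1L)[-1L]
      cbind(x = region$cx + region$r * cos(th), y = region$cy + region$r * sin(th))
    },
    poly = cbind(x = region$x, y = region$y),
    stop("unknown region shape: ", region$shape, call. = FALSE)
  )
}

# Sutherland-Hodgman clip of a polygon to the square [0, size]^2.
clip_polygon_to_patch <- function(poly, size) {
  edges <- list(c(1, 1, 0), c(1, -1, size), c(2, 1, 0), c(2, -1, size))
  for (k in seq_along(edges)) {
    if (nrow(poly) == 0L) return(poly)
    ax <- edges[[k]][1]; sgn <- edges[[k]][2]; lim <- edges[[k]][3]
    inside <- if (sgn > 0) poly[, ax] >= lim else poly[, ax] <= lim
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(poly)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      p1 <- poly[i, ]; p2 <- poly[j, ]
      in1 <- inside[i]; in2 <- inside[j]
      if (in1) out <- rbind(out, p1)
      if (xor(in1, in2)) {
        t <- (lim - p1[ax]) / (p2[ax] - p1[ax])
        out <- rbind(out, p1 + t * (p2 - p1))
      }
    }
    poly <- out
  }
  poly
}

polygon_area <- function(poly) {
  if (is.null(nrow(poly)) || nrow(poly) < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Fraction of the patch covered by a region (clipped to patch bounds).
region_coverage <- function(region, size) {
  polygon_area(clip_polygon_to_patch(region_polygon(region, size), size)) / size^2
}

# Logical h x w mask of a (rect/disc) region; rows index y, cols index x.
region_mask <- function(region, size) {
  if (is.null(region)) return(matrix(TRUE, size, size))
  m <- matrix(FALSE, size, size)
  if (region$shape == "rect") {
    ys <- seq.int(max(1, floor(region$y0) + 1), min(size, ceiling(region$y1)))
    xs <- seq.int(max(1, floor(region$x0) + 1), min(size, ceiling(region$x1)))
    if (length(ys) && length(xs)) m[ys, xs] <- TRUE
  } else if (region$shape == "disc") {
    yy <- matrix(seq_len(size) - 0.5, size, size)
    xx <- t(yy)
    m <- (xx - region$cx)^2 + (yy - region$cy)^2 <= region$r^2
  } else stop("masks are only defined for rect/disc regions", call. = FALSE)
  m
}

# ---- base tissue texture --------------------------------------------------

# Smooth random field in [0, 1]: coarse uniform grid upsampled bilinearly.
smooth_noise <- function(size, n_cells) {
  coarse <- matrix(runif(n_cells^2), n_cells, n_cells)
  resize_patch(coarse, size)
}

#' Generate an artefact-free synthetic H&E patch
#'
#' Builds hematoxylin and eosin density fields (smooth stroma texture with
#' background gaps, plus elliptical nuclei) and converts them to RGB
#' through the canonical absorbance matrix. The ground-truth label of the
#' result is `(1, 1, 0, 0, 0, 0)` (usable, no artefact).
#'
#' @param seed integer seed; output is a pure function of `(seed, size)`.
#' @param size patch side in pixels (>= 64; default 256, the working size
#'   of the tiling contract).
#' @return RGB array `size x size x 3` in `[0, 1]`.
#' @examples
#' p <- generate_base_patch(1, 128)
#' dim(p)
#' @export
generate_base_patch <- function(seed, size = 256L) {
  if (size < 64) stop("`size` must be at least 64 pixels", call. = FALSE)
  size <- as.integer(size)
  with_local_seed(seed, {
    s <- size / 256
    tissue <- smooth_noise(size, 8) > 0.25
    eos <- (0.20 + 0.50 * smooth_noise(size, 12)) * tissue
    hem <- 0.06 * smooth_noise(size, 12) * tissue
    n_nuc <- max(10L, round(75 * s^2))
    cx <- runif(n_nuc, 1, size); cy <- runif(n_nuc, 1, size)
    a <- runif(n_nuc, 3, 7) * s; b <- runif(n_nuc, 3, 7) * s
    th <- runif(n_nuc, 0, pi); dens <- runif(n_nuc, 0.55, 1.0)
    for (i in seq_len(n_nuc)) {
      r <- max(a[i], b[i])
      ys <- seq.int(max(1, floor(cy[i] - r)), min(size, ceiling(cy[i] + r)))
      xs <- seq.int(max(1, floor(cx[i] - r)), min(size, ceiling(cx[i] + r)))
      if (!length(ys) || !length(xs)) next
      dy <- outer(ys - cy[i], rep(1, length(xs)))
      dx <- outer(rep(1, length(ys)), xs - cx[i])
      u <- dx * cos(th[i]) + dy * sin(th[i])
      v <- -dx * sin(th[i]) + dy * cos(th[i])
      inside <- (u / a[i])^2 + (v / b[i])^2 <= 1
      blk <- hem[ys, xs, drop = FALSE]
      blk[inside] <- pmax(blk[inside], dens[i])
      hem[ys, xs] <- blk
    }
    hem <- hem + rnorm(size^2, 0, 0.015); hem[hem < 0] <- 0
    eos <- eos + rnorm(size^2, 0, 0.015); eos[eos < 0] <- 0
    rgb <- stain_reconstruct(hem, eos)
    sensor <- rnorm(size^2, 0, 0.004)   # luminance sensor noise
    clamp01(rgb + array(sensor, dim = dim(rgb)))
  })
}

# ---- artefact injectors ---------------------------------------------------

#' Inject an artefact into a patch
#'
#' Applies the artefact described by an [artefact_spec()] to an RGB patch.
#' Focus blur uses a severity-indexed Gaussian sigma (slight = 2, severe =
#' 6 at the 256 px working scale); stain fade attenuates the hematoxylin
#' channel and overall contrast in stain-density space; folds composite a
#' translated copy of nearby tissue by optical-density addition (so a fold
#' is locally doubled stain structure, not a mere darkening); the
#' remaining kinds paint opaque or textured obscuring material.
#'
#' @param patch RGB array `h x w x 3` in `[0, 1]`.
#' @param spec an [artefact_spec()].
#' @return RGB array of the same dimension.
#' @export
apply_artefact <- function(patch, spec) {
  assert_patch(patch)
  stopifnot(inherits(spec, "artefact_spec"))
  size <- dim(patch)[1]
  if (dim(patch)[2] != size)
    stop("patches must be square", call. = FALSE)
  region <- spec$region
  if (!is.null(region)) {
    poly <- region_polygon(region, size)
    if (any(poly[, 1] < -1e-9) || any(poly[, 1] > size + 1e-9) ||
        any(poly[, 2] < -1e-9) || any(poly[, 2] > size + 1e-9))
      stop("artefact region exceeds patch bounds", call. = FALSE)
  }
  with_local_seed(spec$seed, switch(spec$kind,
    focus_blur     = inject_blur(patch, spec, size),
    stain_fade     = inject_fade(patch, spec, size),
    fold           = inject_fold(patch, spec, size),
    ink            = inject_ink(patch, spec, size),
    dirt           = inject_dirt(patch, spec, size),
    bubble         = inject_bubble(patch, spec, size),
    coverslip_edge = inject_coverslip(patch, spec, size),
    diathermy      = inject_diathermy(patch, spec, size)
  ))
}

composite_mask <- function(base, layer, mask) {
  out <- base
  for (ch in 1:3) {
    b <- out[, , ch]; l <- layer[, , ch]
    b[mask] <- l[mask]
    out[, , ch] <- b
  }
  out
}

inject_blur <- function(patch, spec, size) {
  sigma <- severity_sigma(spec$severity, size)
  if (sigma == 0) return(patch)
  img <- EBImage::Image(aperm(patch, c(2, 1, 3)), colormode = "Color")
  blurred <- aperm(EBImage::imageData(EBImage::gblur(img, sigma = sigma)), c(2, 1, 3))
  blurred <- clamp01(blurred)
  if (is.null(spec$region)) return(blurred)
  composite_mask(patch, blurred, region_mask(spec$region, size))
}

inject_fade <- function(patch, spec, size) {
  if (spec$severity == 0) return(patch)
  d <- stain_deconvolve(patch)
  hf <- 1 - 0.85 * spec$severity     # hematoxylin: loss of nuclear detail
  ef <- 1 - 0.40 * spec$severity     # eosin: overall contrast loss
  faded <- stain_reconstruct(d$hematoxylin * hf, d$eosin * ef, d$residual)
  if (is.null(spec$region)) return(faded)
  composite_mask(patch, faded, region_mask(spec$region, size))
}

inject_fold <- function(patch, spec, size) {
  region <- if (is.null(spec$region)) full_region(size) else spec$region
  if (region$shape != "rect") stop("fold regions must be rectangles", call. = FALSE)
  od <- rgb_to_od(patch)
  shift_max <- max(8, round(28 * size / 256))
  dx <- sample(c(-1, 1), 1) * sample(seq.int(8, shift_max), 1)
  dy <- sample(c(-1, 1), 1) * sample(seq.int(8, shift_max), 1)
  ys <- seq.int(max(1, floor(region$y0) + 1), min(size, ceiling(region$y1)))
  xs <- seq.int(max(1, floor(region$x0) + 1), min(size, ceiling(region$x1)))
  src_y <- ys + dy; src_x <- xs + dx
  keep_y <- src_y >= 1 & src_y <= size; keep_x <- src_x >= 1 & src_x <= size
  ys <- ys[keep_y]; xs <- xs[keep_x]; src_y <- src_y[keep_y]; src_x <- src_x[keep_x]
  if (length(ys) && length(xs)) {
    src <- od[src_y, src_x, , drop = FALSE]
    od[ys, xs, ] <- od[ys, xs, , drop = FALSE] + src
  }
  out <- od_to_rgb(od)
  mask <- region_mask(region, size)
  composite_mask(patch, out, mask)
}

inject_ink <- function(patch, spec, size) {
  cols <- rbind(c(0.06, 0.09, 0.38), c(0.05, 0.05, 0.06), c(0.05, 0.28, 0.10))
  colr <- cols[sample.int(3, 1), ]
  mask <- region_mask(if (is.null(spec$region)) full_region(size) else spec$region, size)
  out <- patch
  for (ch in 1:3) {
    b <- out[, , ch]
    b[mask] <- clamp01(0.92 * colr[ch] + 0.08 * b[mask] + rnorm(sum(mask), 0, 0.01))
    out[, , ch] <- b
  }
  out
}

inject_dirt <- function(patch, spec, size) {
  mask <- region_mask(if (is.null(spec$region)) full_region(size) else spec$region, size)
  speck <- smooth_noise(size, max(12, round(size / 12))) > 0.55
  m <- mask & speck
  out <- patch
  for (ch in 1:3) { b <- out[, , ch]; b[m] <- b[m] * 0.30; out[, , ch] <- b }
  out
}

inject_bubble <- function(patch, spec, size) {
  region <- spec$region
  if (is.null(region) || region$shape != "disc") {
    r <- size * 0.3
    region <- list(shape = "disc", cx = size / 2, cy = size / 2, r = r)
  }
  yy <- matrix(seq_len(size) - 0.5, size, size); xx <- t(yy)
  d <- sqrt((xx - region$cx)^2 + (yy - region$cy)^2)
  w <- max(2, size * 0.015)
  rim <- abs(d - region$r) < w
  interior <- d < region$r - w
  out <- patch
  for (ch in 1:3) {
    b <- out[, , ch]
    b[rim] <- b[rim] * 0.55
    b[interior] <- clamp01(0.80 * b[interior] + 0.20)
    out[, , ch] <- b
  }
  out
}

inject_coverslip <- function(patch, spec, size) {
  region <- if (is.null(spec$region)) full_region(size) else spec$region
  mask <- region_mask(region, size)
  th <- runif(1, 0, pi)
  n <- c(cos(th), sin(th))
  cx <- runif(1, 0.3, 0.7) * size; cy <- runif(1, 0.3, 0.7) * size
  yy <- matrix(seq_len(size) - 0.5, size, size); xx <- t(yy)
  sd_ <- (xx - cx) * n[1] + (yy - cy) * n[2]
  band <- abs(sd_) < max(3, size * 0.02)
  beyond <- sd_ >= max(3, size * 0.02)
  out <- patch
  for (ch in 1:3) {
    b <- out[, , ch]
    b[band & mask] <- b[band & mask] * 0.45
    b[beyond & mask] <- clamp01(b[beyond & mask] * 0.92 + 0.07)
    out[, , ch] <- b
  }
  out
}

inject_diathermy <- function(patch, spec, size) {
  mask <- region_mask(if (is.null(spec$region)) full_region(size) else spec$region, size)
  tex <- 0.35 + 0.45 * smooth_noise(size, 10)
  brown <- c(0.45, 0.31, 0.22)
  gray <- to_gray(patch)
  out <- patch
  for (ch in 1:3) {
    b <- out[, , ch]
    scorched <- (1 - tex) * (0.5 * b + 0.5 * gray) + tex * brown[ch]
    b[mask] <- clamp01(scorched[mask])
    out[, , ch] <- b
  }
  out
}

# ---- labels ---------------------------------------------------------------

#' Ground-truth quality label for a set of injected artefacts
#'
#' Six-component label: `y1` usability, `y2` no-artefact, `y3` staining
#' severity (0/0.5/1), `y4` focus severity (0/0.5/1), `y5` folding, `y6`
#' other artefacts. Severities take the maximum over specs; a patch is
#' unusable when focus or staining is severe, or when obscuring "other"
#' material covers at least half the patch.
#'
#' @param specs list of [artefact_spec()] objects applied to one patch
#'   (may be empty).
#' @param size patch side in pixels (used for coverage of obscuring
#'   artefacts).
#' @return named numeric vector `c(y1, y2, y3, y4, y5, y6)`.
#' @export
label_for <- function(specs, size = 256L) {
  if (inherits(specs, "artefact_spec")) specs <- list(specs)
  kinds <- vapply(specs, `[[`, "", "kind")
  sev <- vapply(specs, `[[`, 0, "severity")
  y3 <- if (any(kinds == "stain_fade")) max(sev[kinds == "stain_fade"]) else 0
  y4 <- if (any(kinds == "focus_blur")) max(sev[kinds == "focus_blur"]) else 0
  y5 <- as.numeric(any(kinds == "fold"))
  other <- kinds %in% OTHER_KINDS
  y6 <- as.numeric(any(other))
  coverage <- if (any(other))
    min(1, sum(vapply(specs[other], function(s) region_coverage(s$region, size), 0))) else 0
  y2 <- as.numeric(y3 == 0 && y4 == 0 && y5 == 0 && y6 == 0)
  y1 <- as.numeric(!(y4 == 1 || y3 == 1 || (y6 == 1 && coverage >= 0.5)))
  c(y1 = y1, y2 = y2, y3 = y3, y4 = y4, y5 = y5, y6 = y6)
}

label_names <- function() c("y1", "y2", "y3", "y4", "y5", "y6")

# ---- datasets -------------------------------------------------------------

#' Default artefact mix for synthetic datasets
#'
#' Per-kind draw probabilities; the remainder (0.43) yields clean patches.
#' Obscuring kinds draw their region either clearly sub-critical (5-35%
#' coverage) or clearly super-critical (55-90%) so the usability ground
#' truth is unambiguous.
#'
#' @return named numeric vector of probabilities summing to < 1.
#' @export
default_artefact_mix <- function() {
  c(focus_blur_slight = 0.08, focus_blur_severe = 0.12,
    stain_fade_slight = 0.06, stain_fade_severe = 0.08,
    fold = 0.12, ink = 0.05, dirt = 0.05, bubble = 0.04,
    coverslip_edge = 0.04, diathermy = 0.03)
}

# Draw a concrete artefact_spec for a mix component.
draw_spec <- function(component, size, spec_seed) {
  sev <- 1
  kind <- component
  if (grepl("_slight$", component)) { sev <- 0.5; kind <- sub("_slight$", "", component) }
  if (grepl("_severe$", component)) { sev <- 1.0; kind <- sub("_severe$", "", component) }
  region <- NULL
  if (kind == "fold") {
    f <- runif(1, 0.25, 0.5)
    w <- f * size; h <- runif(1, 0.25, 0.5) * size
    x0 <- runif(1, 0, size - w); y0 <- runif(1, 0, size - h)
    region <- list(shape = "rect", x0 = x0, y0 = y0, x1 = x0 + w, y1 = y0 + h)
  } else if (kind %in% OTHER_KINDS) {
    cov <- if (runif(1) < 0.5) runif(1, 0.05, 0.35) else runif(1, 0.55, 0.90)
    if (kind %in% c("ink", "bubble")) {
      # disc fully inside the patch with area = cov * size^2 (capped by fit)
      r <- min(sqrt(cov / pi) * size, size / 2 - 1)
      cx <- runif(1, r, size - r); cy <- runif(1, r, size - r)
      region <- list(shape = "disc", cx = cx, cy = cy, r = r)
      # disc may cap below requested coverage; re-expand as rect if needed
      if (pi * r^2 / size^2 < cov - 0.02) {
        side <- sqrt(cov) * size
        x0 <- runif(1, 0, size - side); y0 <- runif(1, 0, size - side)
        region <- list(shape = "rect", x0 = x0, y0 = y0, x1 = x0 + side, y1 = y0 + side)
      }
    } else {
      ar <- runif(1, 0.6, 1.6)
      w <- min(sqrt(cov * ar) * size, size); h <- min(cov * size^2 / w, size)
      x0 <- runif(1, 0, size - w); y0 <- runif(1, 0, size - h)
      region <- list(shape = "rect", x0 = x0, y0 = y0, x1 = x0 + w, y1 = y0 + h)
    }
  }
  artefact_spec(kind, severity = if (kind %in% c("focus_blur", "stain_fade")) sev else 1,
                region = region, seed = spec_seed)
}

#' Generate a labelled synthetic patch dataset
#'
#' Draws `n` patches: each gets a primary artefact according to `mix`
#' (remaining probability mass yields clean patches) and, with probability
#' 0.15, a second artefact of a different kind. Labels follow
#' [label_for()]. Deterministic per `seed`.
#'
#' @param n number of patches.
#' @param mix named per-kind probabilities (see [default_artefact_mix()]);
#'   must sum to <= 1. Use an empty vector for clean-only data.
#' @param seed integer seed.
#' @param size generation size in pixels (default 256, the working scale).
#' @param out_size side length patches are resized to before storage
#'   (default: `size`); lets large datasets be held in memory at the
#'   network input size.
#' @param dir optional directory; when given, patches are written as PNG
#'   files plus a `manifest.csv` (columns `patch_path`, `y1`..`y6`,
#'   `specs_json`, `seed`).
#' @param second_prob probability of a second, different artefact kind.
#' @return object of class `qc_dataset`: list with `x` (array
#'   `out_size x out_size x 3 x n`), `labels` (data frame `y1`..`y6`),
#'   `specs`, `manifest`, `seed`, `size`, `out_size`.
#' @export
generate_dataset <- function(n, mix = default_artefact_mix(), seed = 1L,
                             size = 256L, out_size = size, dir = NULL,
                             second_prob = 0.15) {
  stopifnot(n >= 1)
  if (length(mix) && (any(mix < 0) || sum(mix) > 1 + 1e-9))
    stop("`mix` probabilities must be non-negative and sum to <= 1", call. = FALSE)
  components <- c(names(mix), "clean")
  probs <- c(unname(mix), 1 - sum(mix))
  with_local_seed(seed, {
    draws <- sample(components, n, replace = TRUE, prob = probs)
    x <- array(0, dim = c(out_size, out_size, 3L, n))
    labels <- matrix(0, n, 6L, dimnames = list(NULL, label_names()))
    all_specs <- vector("list", n)
    for (i in seq_len(n)) {
      patch_seed <- sample.int(.Machine$integer.max - 1L, 1)
      specs <- list()
      if (draws[i] != "clean") {
        specs <- list(draw_spec(draws[i], size, sample.int(1e9L, 1)))
        if (length(mix) > 1 && runif(1) < second_prob) {
          base_kind <- sub("_(slight|severe)$", "", draws[i])
          others <- mix[!startsWith(names(mix), base_kind)]
          if (length(others)) {
            comp2 <- sample(names(others), 1, prob = others / sum(others))
            specs <- c(specs, list(draw_spec(comp2, size, sample.int(1e9L, 1))))
          }
        }
      }
      patch <- generate_base_patch(patch_seed, size)
      for (sp in specs) patch <- apply_artefact(patch, sp)
      if (out_size != size) patch <- resize_patch(patch, out_size)
      x[, , , i] <- patch
      labels[i, ] <- label_for(specs, size)
      all_specs[[i]] <- specs
    }
    labels <- as.data.frame(labels)
    manifest <- data.frame(
      patch_path = sprintf("patch_%05d.png", seq_len(n)),
      labels,
      specs_json = vapply(all_specs, function(sp)
        jsonlite::toJSON(lapply(sp, unclass), auto_unbox = TRUE, digits = 6), ""),
      seed = seed, stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_len(n))
        png::writePNG(x[, , , i], file.path(dir, manifest$patch_path[i]))
      write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    }
    structure(list(x = x, labels = labels, specs = all_specs,
                   manifest = manifest, seed = seed, size = size,
                   out_size = out_size),
              class = "qc_dataset")
  })
}

#' @export
print.qc_dataset <- function(x, ...) {
  cat(sprintf("<qc_dataset> %d patches (%dpx, stored at %dpx), seed %d\n",
              nrow(x$labels), x$size, x$out_size, x$seed))
  cat("label means:\n")
  print(round(colMeans(x$labels), 3))
  invisible(x)
}

# ---- composite slides -----------------------------------------------------

#' Compose a synthetic slide from a grid of artefact specifications
#'
#' Each grid cell becomes one `size` x `size` tile: a base patch with its
#' cell's artefacts applied. Cells set to `NA` stay background (white).
#' Returns the slide image together with the six ground-truth overlays
#' implied by [label_for()] per cell.
#'
#' @param grid a matrix-shaped list (e.g. `matrix(list(), nr, nc)`): each
#'   element a list of [artefact_spec()]s (empty list = clean tile,
#'   scalar `NA` = background).
#' @param seed integer seed.
#' @param size tile side in pixels.
#' @return object of class `qc_slide`: list with `image` (RGB array),
#'   `overlays` (named list of six `nr x nc` matrices with `NA` for
#'   background cells), `tile_size`, `seed`.
#' @export
compose_slide <- function(grid, seed = 1L, size = 256L) {
  if (is.null(dim(grid))) stop("`grid` must have matrix dimensions", call. = FALSE)
  nr <- nrow(grid); nc <- ncol(grid)
  if (nr == 0 || nc == 0) stop("`grid` must be non-empty", call. = FALSE)
  img <- array(1, dim = c(nr * size, nc * size, 3L))
  overlays <- lapply(1:6, function(i) matrix(NA_real_, nr, nc))
  names(overlays) <- c("usability", "no_artefact", "staining", "focus", "folding", "other")
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    cell <- grid[[r, cc]]
    if (length(cell) == 1L && !is.list(cell) && is.na(cell)) next
    if (inherits(cell, "artefact_spec")) cell <- list(cell)
    if (is.null(cell)) cell <- list()
    cell_seed <- (as.integer(seed) + 7919L * ((r - 1L) * nc + cc)) %% .Machine$integer.max
    patch <- generate_base_patch(cell_seed, size)
    for (sp in cell) patch <- apply_artefact(patch, sp)
    ys <- ((r - 1L) * size + 1L):(r * size)
    xs <- ((cc - 1L) * size + 1L):(cc * size)
    img[ys, xs, ] <- patch
    lab <- label_for(cell, size)
    for (i in 1:6) overlays[[i]][r, cc] <- lab[[i]]
  }
  structure(list(image = img, overlays = overlays, tile_size = size, seed = seed),
            class = "qc_slide")
}

#' @export
print.qc_slide <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<qc_slide> %d x %d px (%d x %d tiles of %d px), seed %d\n",
              d[1], d[2], nrow(x$overlays$usability), ncol(x$overlays$usability),
              x$tile_size, x$seed))
  invisible(x)
}

#' Reference slide-level scores implied by ground-truth overlays
#'
#' Emulates the aggregated assessor scores for a synthetic slide: focus
#' and staining scores are `10 * (1 - mean severity)` over tissue cells
#' (0-10 scale, higher is better); the slide is usable when at most 30%
#' of its tissue cells are unusable.
#'
#' @param slide a `qc_slide` (or its `overlays` list).
#' @return named numeric vector `c(usable, focus_score, stain_score)`.
#' @export
reference_slide_scores <- function(slide) {
  ov <- if (inherits(slide, "qc_slide")) slide$overlays else slide
  c(usable = as.numeric(mean(1 - ov$usability, na.rm = TRUE) <= 0.3),
    focus_score = 10 * (1 - mean(ov$focus, na.rm = TRUE)),
    stain_score = 10 * (1 - mean(ov$staining, na.rm = TRUE)))
}
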