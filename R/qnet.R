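# The multi-label patch-quality regressor: training configuration, Huber
# loss, the quality-preserving augmentation policy, stratified splitting,
# the inverse-frequency weighted sampler, and the `qnet` model object
# (a small residual CNN fitted by Adam; see src/qnet.cpp).

#' Training configuration for the patch-quality network
#'
#' @param input_size network input side in pixels; patches are resized
#'   from the 256 px working size to this before the forward pass.
#'   Default 224. Must be divisible by `2 ^ length(widths)` (the total
#'   downsampling of the stem plus stage strides).
#' @param widths channel widths per stage. The default, together with
#'   `blocks = c(2, 2, 2, 2)`, is the 18-layer residual family; smaller
#'   settings give reduced backbones for CPU-scale experiments.
#' @param blocks number of residual blocks per stage.
#' @param batch_size minibatch size (default 100).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs training epochs (default 200).
#' @param huber_delta Huber loss transition point delta (default 1).
#' @param fractions named train/val/test split fractions (must sum to 1).
#' @param bn_momentum batch-norm running-statistics momentum.
#' @param weighted_sampler draw training batches with inverse
#'   label-combination-frequency weights (default TRUE).
#' @param augment expand the training partition with label-preserving
#'   augmented copies before fitting (default TRUE).
#' @param augment_copies augmented variants appended per training patch
#'   when `augment` is TRUE.
#' @return object of class `qnet_config`.
#' @export
qnet_config <- function(input_size = 224L, widths = c(64L, 128L, 256L, 512L),
                        blocks = c(2L, 2L, 2L, 2L), batch_size = 100L,
                        learning_rate = 1e-4, epochs = 200L, huber_delta = 1,
                        fractions = c(train = 0.8, val = 0.1, test = 0.1),
                        bn_momentum = 0.1, weighted_sampler = TRUE,
                        augment = TRUE, augment_copies = 1L) {
  stopifnot(length(widths) == length(blocks), all(widths >= 1), all(blocks >= 1))
  if (huber_delta <= 0) stop("`huber_delta` must be positive", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("split `fractions` must sum to 1", call. = FALSE)
  ds <- 2L^length(widths)
  if (input_size %% ds != 0)
    stop(sprintf("`input_size` must be divisible by %d for %d stages", ds,
                 length(widths)), call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 widths = as.integer(widths), blocks = as.integer(blocks),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 huber_delta = huber_delta, fractions = fractions,
                 bn_momentum = bn_momentum,
                 weighted_sampler = isTRUE(weighted_sampler),
                 augment = isTRUE(augment),
                 augment_copies = as.integer(augment_copies)),
            class = "qnet_config")
}

#' Reduced training configuration for CPU-scale experiments
#'
#' A small backbone (widths 16/32/64, one block per stage) at 64 px
#' input, 5 epochs, no augmentation expansion; batch size, learning rate
#' and Huber delta keep their standard values.
#'
#' @param ... overrides passed on to [qnet_config()].
#' @return object of class `qnet_config`.
#' @export
qnet_config_reduced <- function(...) {
  defaults <- list(input_size = 64L, widths = c(16L, 32L, 64L),
                   blocks = c(1L, 1L, 1L), epochs = 5L, augment = FALSE)
  args <- utils::modifyList(defaults, list(...))
  do.call(qnet_config, args)
}

#' @export
print.qnet_config <- function(x, ...) {
  cat(sprintf("<qnet_config> input %dpx, stages [%s] x [%s] blocks\n",
              x$input_size, paste(x$widths, collapse = ","),
              paste(x$blocks, collapse = ",")))
  cat(sprintf("  batch %d, lr %g, %d epochs, Huber delta %g, split %s\n",
              x$batch_size, x$learning_rate, x$epochs, x$huber_delta,
              paste(x$fractions, collapse = "/")))
  invisible(x)
}

#' Huber loss
#'
#' Piecewise loss, quadratic for residuals within `delta` of the target
#' and linear beyond: `0.5 (x - y)^2` when `|x - y| <= delta`, else
#' `delta |x - y| - 0.5 delta^2`. Reduced by the mean over all elements.
#'
#' @param x predictions (vector/matrix).
#' @param y targets, same shape.
#' @param delta transition point (> 0).
#' @return single non-negative number.
#' @examples
#' huber_loss(0.5, 0)   # quadratic branch: 0.125
#' huber_loss(2, 0)     # linear branch: 1.5
#' @export
huber_loss <- function(x, y, delta = 1) {
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  d <- abs(x - y)
  mean(ifelse(d <= delta, 0.5 * d^2, delta * d - 0.5 * delta^2))
}

# ---- label combination schema --------------------------------------------

default_label_schema <- function() {
  list(y1 = c(0, 1), y2 = c(0, 1), y3 = c(0, 0.5, 1),
       y4 = c(0, 0.5, 1), y5 = c(0, 1), y6 = c(0, 1))
}

#' Enumerate the multi-label target space
#'
#' Cross-product of the per-component label domains (usability and
#' no-artefact binary; staining and focus three-level 0/0.5/1; folding
#' and other binary).
#'
#' @param schema named list of per-component domains.
#' @return data frame with one row per unique combination.
#' @export
enumerate_label_combinations <- function(schema = default_label_schema()) {
  unique(expand.grid(schema, KEEP.OUT.ATTRS = FALSE))
}

#' Number of unique label combinations
#'
#' With the default six-component schema this is `3^2 * 2^4 = 144`.
#'
#' @inheritParams enumerate_label_combinations
#' @return integer count.
#' @export
count_label_combinations <- function(schema = default_label_schema()) {
  nrow(enumerate_label_combinations(schema))
}

# ---- augmentation ---------------------------------------------------------

#' Draw augmentation parameters
#'
#' The permitted, quality-preserving policy: rotation by 0/90/180/270
#' degrees, horizontal and/or vertical flips, a random affine transform
#' with shear in \[-10, 10\] degrees and per-axis translation in
#' \[-5, 5\]% of the patch side, and a hue perturbation in \[-30, 30\]
#' degrees. Blur, contrast, brightness, saturation and noise transforms
#' are structurally absent: they would alter the very quality attributes
#' being learned.
#'
#' @param seed integer seed.
#' @return named list of parameters (`rot_k`, `flip_h`, `flip_v`,
#'   `shear_deg`, `tx_frac`, `ty_frac`, `hue_deg`).
#' @export
draw_augment_params <- function(seed) {
  with_local_seed(seed, list(
    rot_k = sample(0:3, 1),
    flip_h = runif(1) < 0.5,
    flip_v = runif(1) < 0.5,
    shear_deg = runif(1, -10, 10),
    tx_frac = runif(1, -0.05, 0.05),
    ty_frac = runif(1, -0.05, 0.05),
    hue_deg = runif(1, -30, 30)))
}

#' Identity augmentation parameters
#'
#' The no-op draw of the augmentation policy; [augment_apply()] with
#' these parameters returns the input patch unchanged.
#'
#' @return named parameter list.
#' @export
identity_augment_params <- function() {
  list(rot_k = 0L, flip_h = FALSE, flip_v = FALSE, shear_deg = 0,
       tx_frac = 0, ty_frac = 0, hue_deg = 0)
}

# 2x2 linear part + translation of the augmentation, acting on patch
# coordinates about the centre: p' = A (p - c) + c + t.
augment_affine <- function(params, size) {
  s <- tan(params$shear_deg * pi / 180)
  A <- matrix(c(1, 0, s, 1), 2, 2)           # x-shear
  if (params$flip_h) A <- matrix(c(-1, 0, 0, 1), 2, 2) %*% A
  if (params$flip_v) A <- matrix(c(1, 0, 0, -1), 2, 2) %*% A
  th <- params$rot_k * pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A <- R %*% A
  list(A = A, t = c(params$tx_frac, params$ty_frac) * size, c = size / 2)
}

# Bilinear warp of a patch under the augmentation affine; out-of-range
# samples read as white background.
warp_patch <- function(patch, params) {
  size <- dim(patch)[1]
  aff <- augment_affine(params, size)
  Ainv <- solve(aff$A)
  # output pixel centres
  xs <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)  # x varies by col
  ys <- matrix(rep(seq_len(size) - 0.5, times = size), size, size) # y varies by row
  dx <- xs - aff$c - aff$t[1]
  dy <- ys - aff$c - aff$t[2]
  sx <- Ainv[1, 1] * dx + Ainv[1, 2] * dy + aff$c
  sy <- Ainv[2, 1] * dx + Ainv[2, 2] * dy + aff$c
  # bilinear sample at (sx, sy); pixel (row i, col j) has centre
  # (x = j - 0.5, y = i - 0.5)
  fx <- sx - 0.5; fy <- sy - 0.5
  x0 <- floor(fx); y0 <- floor(fy)
  wx <- fx - x0; wy <- fy - y0
  out <- array(1, dim = dim(patch))
  idx <- function(yy, xx) {
    ok <- yy >= 0 & yy <= size - 1 & xx >= 0 & xx <= size - 1
    list(ok = ok,
         lin = pmin(pmax(yy, 0), size - 1) + 1 + size * pmin(pmax(xx, 0), size - 1))
  }
  i00 <- idx(y0, x0); i01 <- idx(y0, x0 + 1)
  i10 <- idx(y0 + 1, x0); i11 <- idx(y0 + 1, x0 + 1)
  for (ch in 1:3) {
    pc <- patch[, , ch]
    v00 <- ifelse(i00$ok, pc[i00$lin], 1)
    v01 <- ifelse(i01$ok, pc[i01$lin], 1)
    v10 <- ifelse(i10$ok, pc[i10$lin], 1)
    v11 <- ifelse(i11$ok, pc[i11$lin], 1)
    out[, , ch] <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
      wy * ((1 - wx) * v10 + wx * v11)
  }
  clamp01(out)
}

# Vectorised HSV -> RGB (h, s, v matrices in [0, 1]).
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

shift_hue <- function(patch, hue_deg) {
  if (hue_deg == 0) return(patch)
  dm <- dim(patch)
  flat <- rbind(as.vector(patch[, , 1]), as.vector(patch[, , 2]),
                as.vector(patch[, , 3]))
  hsv <- grDevices::rgb2hsv(flat, maxColorValue = 1)
  res <- hsv_to_rgb(hsv[1, ] + hue_deg / 360, hsv[2, ], hsv[3, ])
  out <- array(0, dim = dm)
  out[, , 1] <- res$r; out[, , 2] <- res$g; out[, , 3] <- res$b
  clamp01(out)
}

#' Apply augmentation parameters to a patch
#'
#' @param patch RGB array `h x w x 3`.
#' @param params parameter list from [draw_augment_params()] (or
#'   [identity_augment_params()]).
#' @return augmented patch of the same dimension.
#' @export
augment_apply <- function(patch, params) {
  assert_patch(patch)
  geom <- params[c("rot_k", "flip_h", "flip_v", "shear_deg", "tx_frac", "ty_frac")]
  is_identity <- params$rot_k == 0 && !params$flip_h && !params$flip_v &&
    params$shear_deg == 0 && params$tx_frac == 0 && params$ty_frac == 0
  out <- if (is_identity) patch else warp_patch(patch, params)
  shift_hue(out, params$hue_deg)
}

#' Transform artefact geometry under augmentation parameters
#'
#' Maps each spec's region polygon through the same affine as the image,
#' so ground-truth labels can be recomputed from the transformed geometry
#' (regions become `shape = "poly"`).
#'
#' @param specs list of [artefact_spec()]s.
#' @param params augmentation parameters.
#' @param size patch side in pixels.
#' @return list of specs with transformed regions.
#' @export
transform_specs <- function(specs, params, size) {
  aff <- augment_affine(params, size)
  lapply(specs, function(sp) {
    poly <- region_polygon(sp$region, size)
    rel <- sweep(poly, 2, c(aff$c, aff$c))
    new <- t(aff$A %*% t(rel)) + matrix(c(aff$c + aff$t[1], aff$c + aff$t[2]),
                                        nrow(poly), 2, byrow = TRUE)
    sp$region <- list(shape = "poly", x = new[, 1], y = new[, 2])
    sp
  })
}

#' Randomly augment a labelled patch
#'
#' Draws parameters from the permitted policy, applies them to the patch
#' and returns the label unchanged (every permitted transform preserves
#' the quality label).
#'
#' @param patch RGB array.
#' @param label the patch's quality label (returned as-is).
#' @param seed integer seed for the parameter draw.
#' @param specs optional artefact specs; when given, their transformed
#'   geometry is returned for label-consistency checks.
#' @return list with `patch`, `label`, `params` and (optionally) `specs`.
#' @export
augment <- function(patch, label, seed, specs = NULL) {
  params <- draw_augment_params(seed)
  out <- list(patch = augment_apply(patch, params), label = label,
              params = params)
  if (!is.null(specs))
    out$specs <- transform_specs(specs, params, dim(patch)[1])
  out
}

# ---- splitting and sampling ----------------------------------------------

label_keys <- function(labels) {
  apply(as.matrix(labels), 1, paste, collapse = "|")
}

#' Stratified train/val/test split on unique label combinations
#'
#' Partitions items so that each unique multi-label combination is
#' represented in each partition in proportion to `fractions` (up to
#' integer rounding, largest-remainder allocation). Combinations with
#' fewer members than partitions go entirely to the training set.
#'
#' @param labels data frame or matrix of labels (one row per item).
#' @param fractions named fractions (train/val/test) summing to 1.
#' @param seed integer seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(labels, fractions = c(train = 0.8, val = 0.1, test = 0.1),
                             seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must sum to 1", call. = FALSE)
  if (is.null(names(fractions)))
    stop("`fractions` must be named", call. = FALSE)
  keys <- label_keys(labels)
  parts <- setNames(rep(list(integer(0)), length(fractions)), names(fractions))
  with_local_seed(seed, {
    for (k in unique(keys)) {
      idx <- which(keys == k)
      n <- length(idx)
      if (n < length(fractions)) {
        # too few members to spread over the partitions: all to the first
        parts[[1]] <- c(parts[[1]], idx)
        next
      }
      idx <- idx[sample.int(n)]
      target <- fractions * n
      counts <- floor(target)
      rem <- n - sum(counts)
      if (rem > 0) {
        extra <- order(target - counts, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1
      }
      stops <- cumsum(counts)
      starts <- c(1, head(stops, -1) + 1)
      for (p in seq_along(fractions)) {
        nm <- names(fractions)[p]
        if (counts[p] > 0)
          parts[[nm]] <- c(parts[[nm]], idx[starts[p]:stops[p]])
      }
    }
  })
  lapply(parts, sort)
}

#' Inverse-frequency sampling weights for label imbalance
#'
#' Weight of an item is proportional to `1 / frequency` of its unique
#' label combination, so long-run per-combination sampling frequencies
#' approach uniform.
#'
#' @param labels data frame or matrix of labels (one row per item).
#' @return numeric weight vector (mean 1).
#' @export
make_weighted_sampler <- function(labels) {
  keys <- label_keys(labels)
  if (length(keys) == 0) stop("empty training set", call. = FALSE)
  freq <- table(keys)
  w <- 1 / as.numeric(freq[keys])
  w / mean(w)
}

# ---- parameter initialisation --------------------------------------------

init_convbn <- function(cout, cin, ksize) {
  fan_in <- cin * ksize^2
  list(W = matrix(rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in),
       gamma = rep(1, cout), beta = rep(0, cout),
       rmean = rep(0, cout), rvar = rep(1, cout))
}

# Canonical parameter walk; must match build_net() in src/qnet.cpp.
init_qnet_params <- function(widths, blocks, seed) {
  with_local_seed(seed, {
    par <- list()
    push <- function(l) for (m in l) par[[length(par) + 1]] <<- m
    push(init_convbn(widths[1], 3L, 3L))
    cin <- widths[1]
    for (s in seq_along(widths)) {
      for (b in seq_len(blocks[s])) {
        stride <- if (s > 1 && b == 1) 2L else 1L
        push(init_convbn(widths[s], cin, 3L))
        push(init_convbn(widths[s], widths[s], 3L))
        if (stride != 1 || cin != widths[s])
          push(init_convbn(widths[s], cin, 1L))
        cin <- widths[s]
      }
    }
    # batch-normed embedding + zero-initialised output head: predictions
    # start at the origin and every output movement is learned signal on
    # standardised features, which keeps short training budgets
    # rank-informative instead of dominated by random projections
    wS <- widths[length(widths)]
    par[[length(par) + 1]] <- rep(1, wS)   # head BN gamma
    par[[length(par) + 1]] <- rep(0, wS)   # head BN beta
    par[[length(par) + 1]] <- rep(0, wS)   # head BN running mean
    par[[length(par) + 1]] <- rep(1, wS)   # head BN running var
    par[[length(par) + 1]] <- matrix(0, 6, wS)
    par[[length(par) + 1]] <- rep(0, 6)
    par
  })
}

# Patches (list/array/qc_dataset) -> d x n column matrix at `input_size`.
patches_to_matrix <- function(x, input_size) {
  patches <- as_patch_list(x)
  n <- length(patches)
  X <- matrix(0, 3 * input_size^2, n)
  for (i in seq_len(n)) {
    p <- patches[[i]]
    if (dim(p)[1] != input_size) p <- resize_patch(p, input_size)
    X[, i] <- as.vector(p)
  }
  X
}

labels_to_matrix <- function(labels) {
  t(as.matrix(labels))   # 6 x n
}

# ---- fitting --------------------------------------------------------------

#' Fit the multi-label patch-quality network
#'
#' Trains a residual convolutional network with six linear outputs
#' (usability, no-artefact, staining, focus, folding, other) by Huber
#' regression with Adam, using a stratified train/val/test split on
#' unique label combinations and (by default) an inverse-frequency
#' weighted batch sampler. The returned checkpoint is the epoch with
#' minimum validation loss. Fully deterministic given `seed`.
#'
#' @param x patches: a `qc_dataset`, a 4D array `h x w x 3 x n`, or a
#'   list of patches.
#' @param labels data frame with columns `y1`..`y6` (taken from `x` when
#'   it is a `qc_dataset`).
#' @param config a [qnet_config()].
#' @param seed integer seed controlling initialisation, splitting,
#'   sampling and augmentation.
#' @return object of class `qnet` with elements `params`, `config`,
#'   `history` (per-epoch train/val loss, epoch 0 = before training),
#'   `best_epoch`, `split` (index vectors into the input data), `seed`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(200, seed = 1, out_size = 64)
#' fit <- qnet(ds, config = qnet_config_reduced(epochs = 1), seed = 1)
#' print(fit)
#' }
#' @export
qnet <- function(x, labels = NULL, config = qnet_config(), seed = 1L) {
  stopifnot(inherits(config, "qnet_config"))
  if (is.null(labels)) {
    if (!inherits(x, "qc_dataset"))
      stop("`labels` must be supplied unless `x` is a qc_dataset", call. = FALSE)
    labels <- x$labels
  }
  labels <- as.data.frame(labels)
  patches <- as_patch_list(x)
  if (length(patches) != nrow(labels))
    stop("number of patches and label rows differ", call. = FALSE)

  split <- stratified_split(labels, config$fractions, seed = seed)
  if (length(split$train) == 0 || length(split$val) == 0)
    stop("train and validation partitions must be non-empty", call. = FALSE)

  train_patches <- patches[split$train]
  train_labels <- labels[split$train, , drop = FALSE]
  if (config$augment && config$augment_copies > 0) {
    aug <- with_local_seed(seed + 1L, {
      seeds <- sample.int(.Machine$integer.max - 1L,
                          length(train_patches) * config$augment_copies)
      lapply(seq_along(seeds), function(j) {
        i <- ((j - 1L) %% length(train_patches)) + 1L
        augment_apply(train_patches[[i]], draw_augment_params(seeds[j]))
      })
    })
    rep_idx <- rep(seq_len(nrow(train_labels)), config$augment_copies)
    train_patches <- c(train_patches, aug)
    train_labels <- rbind(train_labels, train_labels[rep_idx, , drop = FALSE])
  }

  Xtr <- patches_to_matrix(train_patches, config$input_size)
  Ytr <- labels_to_matrix(train_labels)
  Xval <- patches_to_matrix(patches[split$val], config$input_size)
  Yval <- labels_to_matrix(labels[split$val, , drop = FALSE])

  n_tr <- ncol(Xtr)
  order_mat <- with_local_seed(seed + 2L, {
    if (config$weighted_sampler) {
      w <- make_weighted_sampler(train_labels)
      t(vapply(seq_len(config$epochs),
               function(e) sample.int(n_tr, n_tr, replace = TRUE, prob = w),
               integer(n_tr)))
    } else {
      t(vapply(seq_len(config$epochs),
               function(e) sample.int(n_tr), integer(n_tr)))
    }
  })
  storage.mode(order_mat) <- "integer"

  par0 <- init_qnet_params(config$widths, config$blocks, seed)
  res <- .qnet_train_cpp(Xtr, Ytr, Xval, Yval, config$widths, config$blocks,
                         config$input_size, par0, order_mat,
                         config$batch_size, config$learning_rate,
                         config$huber_delta, config$bn_momentum)
  history <- data.frame(epoch = 0:config$epochs,
                        train_loss = c(NA_real_, res$train_loss),
                        val_loss = res$val_loss)
  structure(list(params = res$params, config = config, history = history,
                 best_epoch = res$best_epoch, split = split, seed = seed,
                 labels = label_names()),
            class = "qnet")
}

#' Build an untrained patch-quality network
#'
#' Initialises the residual architecture described by `config` without
#' training (He-normal convolution weights, unit batch-norm scale). The
#' result supports [predict.qnet()] directly; useful for architecture
#' checks.
#'
#' @inheritParams qnet
#' @return object of class `qnet` (untrained; `best_epoch = 0`).
#' @export
qnet_build <- function(config = qnet_config(), seed = 1L) {
  stopifnot(inherits(config, "qnet_config"))
  structure(list(params = init_qnet_params(config$widths, config$blocks, seed),
                 config = config,
                 history = data.frame(epoch = integer(0),
                                      train_loss = numeric(0),
                                      val_loss = numeric(0)),
                 best_epoch = 0L, split = NULL, seed = seed,
                 labels = label_names()),
            class = "qnet")
}

#' Predict patch quality scores
#'
#' Patches are resized to the network input size before the forward
#' pass; outputs are the six linear activations (`p1`..`p6`). Values are
#' unbounded by design; clamping to `[0, 1]` happens at overlay assembly
#' (see [assemble_overlays()]) or on request via `clamp = TRUE`.
#'
#' @param object a fitted [qnet()].
#' @param newdata patches (`qc_dataset`, 4D array, single patch or list).
#' @param type `"response"` for the six outputs, `"features"` for the
#'   penultimate (pooled) layer embedding.
#' @param clamp clamp responses to `[0, 1]`.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return numeric matrix, one row per patch (`p1`..`p6` or embedding
#'   dimensions).
#' @export
predict.qnet <- function(object, newdata, type = c("response", "features"),
                         clamp = FALSE, batch_size = 100L, ...) {
  type <- match.arg(type)
  X <- patches_to_matrix(newdata, object$config$input_size)
  out <- .qnet_forward_cpp(X, object$config$widths, object$config$blocks,
                           object$config$input_size, object$params,
                           as.integer(batch_size), type == "features")
  out <- t(out)
  colnames(out) <- if (type == "response") paste0("p", 1:6)
    else paste0("f", seq_len(ncol(out)))
  if (type == "response" && clamp) out <- clamp01(out)
  out
}

#' @export
print.qnet <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<qnet> residual CNN, stages [%s] x [%s], input %dpx, %d parameters\n",
              paste(cfg$widths, collapse = ","),
              paste(cfg$blocks, collapse = ","), cfg$input_size, n_par))
  if (nrow(x$history) > 0 && x$best_epoch > 0) {
    best <- x$history$val_loss[x$history$epoch == x$best_epoch]
    cat(sprintf("  trained %d epochs; best epoch %d (val Huber loss %.4f)\n",
                max(x$history$epoch), x$best_epoch, best))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.qnet <- function(object, ...) {
  out <- list(config = object$config, history = object$history,
              best_epoch = object$best_epoch,
              n_parameters = sum(vapply(object$params, length, 0L)),
              split_sizes = vapply(object$split, length, 0L))
  class(out) <- "summary.qnet"
  out
}

#' @export
print.summary.qnet <- function(x, ...) {
  print(x$config)
  cat(sprintf("parameters: %d\n", x$n_parameters))
  if (!is.null(x$split_sizes))
    cat(sprintf("split sizes: train %d / val %d / test %d\n",
                x$split_sizes[["train"]], x$split_sizes[["val"]],
                x$split_sizes[["test"]]))
  if (nrow(x$history)) {
    cat(sprintf("best epoch %d; final val loss %.4f\n", x$best_epoch,
                x$history$val_loss[nrow(x$history)]))
  }
  invisible(x)
}

#' @export
plot.qnet <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("no training history to plot", call. = FALSE)
  rng <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  plot(h$epoch, h$val_loss, type = "l", col = "firebrick", ylim = rng,
       xlab = "epoch", ylab = "Huber loss", ...)
  lines(h$epoch[!is.na(h$train_loss)], h$train_loss[!is.na(h$train_loss)],
        col = "steelblue")
  graphics::abline(v = x$best_epoch, lty = 3)
  legend("topright", legend = c("validation", "train"), lty = 1,
         col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
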