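# Loss, schema, augmentation policy, splitting, sampler and the network.

test_that("huber_loss matches its closed form on both branches", {
  expect_equal(huber_loss(1, 1), 0)
  expect_equal(huber_loss(0.5, 0), 0.125)
  expect_equal(huber_loss(2, 0), 1.5)
  expect_equal(huber_loss(-2, 0), 1.5)
  # mean reduction over elements
  expect_equal(huber_loss(c(0.5, 2), c(0, 0)), (0.125 + 1.5) / 2)
  # delta scales the transition: |d| = 2, delta = 2 is still quadratic
  expect_equal(huber_loss(2, 0, delta = 2), 2)
  expect_error(huber_loss(1, 0, delta = 0), "positive")
})

test_that("the label schema enumerates 144 unique combinations", {
  expect_equal(count_label_combinations(), 144)
  combos <- enumerate_label_combinations()
  expect_equal(nrow(combos), nrow(unique(combos)))
  binary_only <- lapply(1:6, function(i) c(0, 1))
  names(binary_only) <- paste0("y", 1:6)
  expect_equal(count_label_combinations(binary_only), 64)
})

test_that("augmentation draws only permitted transforms", {
  draws <- lapply(1:200, draw_augment_params)
  expect_true(all(vapply(draws, `[[`, 0, "rot_k") %in% 0:3))
  expect_true(all(abs(vapply(draws, `[[`, 0, "shear_deg")) <= 10))
  expect_true(all(abs(vapply(draws, `[[`, 0, "tx_frac")) <= 0.05))
  expect_true(all(abs(vapply(draws, `[[`, 0, "ty_frac")) <= 0.05))
  expect_true(all(abs(vapply(draws, `[[`, 0, "hue_deg")) <= 30))
  expect_setequal(names(draws[[1]]),
                  c("rot_k", "flip_h", "flip_v", "shear_deg", "tx_frac",
                    "ty_frac", "hue_deg"))
})

test_that("identity augmentation returns the patch unchanged", {
  p <- base_patch(0, 128)
  expect_identical(augment_apply(p, identity_augment_params()), p)
})

test_that("90-degree rotations preserve gradient energy", {
  p <- base_patch(1, 128)
  pars <- identity_augment_params()
  pars$rot_k <- 1L
  rotated <- augment_apply(p, pars)
  expect_equal(focus_tenengrad(rotated), focus_tenengrad(p), tolerance = 0.01)
})

test_that("augmentation preserves ground-truth labels under recomputed geometry", {
  size <- 128
  specs_cases <- list(
    list(),
    list(artefact_spec("focus_blur", 1)),
    list(artefact_spec("ink", region = rect_region(0, 0, 100, 100), seed = 1)),
    list(artefact_spec("ink", region = rect_region(4, 4, 124, 124), seed = 1)),
    list(artefact_spec("stain_fade", 0.5),
         artefact_spec("fold", region = rect_region(20, 20, 80, 80), seed = 2)))
  p <- base_patch(3, size)
  for (specs in specs_cases) {
    stored <- label_for(specs, size)
    for (s in 1:40) {
      out <- augment(p, stored, seed = s, specs = specs)
      recomputed <- label_for(out$specs, size)
      expect_identical(recomputed, stored)
    }
  }
})

test_that("stratified_split respects fractions, determinism and rare combos", {
  labs <- data.frame(y = rep(1, 10))
  sp <- stratified_split(labs, seed = 1)
  expect_equal(lengths(sp)[c("train", "val", "test")],
               c(train = 8L, val = 1L, test = 1L))
  # two combinations of 100: each partition keeps the 50/50 mix (+-1)
  labs2 <- data.frame(y = rep(c(0, 1), each = 100))
  sp2 <- stratified_split(labs2, seed = 2)
  expect_true(all(abs(vapply(sp2, function(i) sum(labs2$y[i] == 0) -
                               sum(labs2$y[i] == 1), 0)) <= 1))
  # partitions are disjoint and exhaustive
  expect_equal(sort(unname(unlist(sp2))), 1:200)
  expect_identical(stratified_split(labs2, seed = 2), sp2)
  expect_false(identical(stratified_split(labs2, seed = 3), sp2))
  # a singleton combination goes entirely to train
  labs3 <- data.frame(y = c(rep(0, 30), 9))
  sp3 <- stratified_split(labs3, seed = 1)
  expect_true(31 %in% sp3$train)
})

test_that("the weighted sampler equalises combination draw rates", {
  labs <- data.frame(y = rep(c(0, 1), times = c(90, 10)))
  w <- make_weighted_sampler(labs)
  expect_true(all(w > 0))
  expect_equal(unique(w[labs$y == 1]) / unique(w[labs$y == 0]), 9)
  set.seed(4)
  draws <- sample(labs$y, 1e4, replace = TRUE, prob = w)
  expect_lt(abs(mean(draws) - 0.5), 0.05)
  # single combination: uniform weights
  expect_equal(make_weighted_sampler(data.frame(y = rep(1, 5))), rep(1, 5))
})

test_that("the network forward pass has the right shape and is deterministic", {
  cfg <- qnet_config_reduced()
  net1 <- qnet_build(cfg, seed = 7)
  net2 <- qnet_build(cfg, seed = 7)
  set.seed(1)
  batch <- array(runif(64 * 64 * 3 * 4), dim = c(64, 64, 3, 4))
  p1 <- predict(net1, batch)
  expect_equal(dim(p1), c(4L, 6L))
  expect_true(all(is.finite(p1)))
  expect_identical(p1, predict(net2, batch))
  expect_identical(p1, predict(net1, batch))
  # batching is invisible to the caller
  expect_equal(predict(net1, batch, batch_size = 2), p1, tolerance = 1e-12)
  # 256 px patches are resized to the input size before the forward pass
  big <- array(runif(256 * 256 * 3 * 2), dim = c(256, 256, 3, 2))
  expect_equal(dim(predict(net1, big)), c(2L, 6L))
})

test_that("config validation enforces the architecture contract", {
  expect_error(qnet_config(input_size = 100), "divisible")
  expect_error(qnet_config(huber_delta = 0), "positive")
  expect_error(qnet_config(fractions = c(train = 0.5, val = 0.2, test = 0.2)),
               "sum to 1")
})

test_that("the backward pass matches finite-difference gradients", {
  widths <- c(4L, 6L); blocks <- c(1L, 1L); in_size <- 8L
  par0 <- slideqc:::init_qnet_params(widths, blocks, 3)
  # perturb the zero head so its gradient check is non-trivial
  par0[[length(par0) - 1]][] <- rnorm(length(par0[[length(par0) - 1]]), 0, 0.1)
  set.seed(42)
  X <- matrix(runif(3 * 64 * 5), 3 * 64, 5)
  Y <- matrix(runif(6 * 5), 6, 5)
  lg <- slideqc:::.qnet_lossgrad_cpp(X, Y, widths, blocks, in_size, par0, 1)
  for (ti in c(1, 6, 11, length(par0) - 1)) {
    g <- as.vector(lg$grads[[ti]])
    for (k in sample(length(par0[[ti]]), 2)) {
      eps <- 1e-6
      pp <- par0; pp[[ti]][k] <- pp[[ti]][k] + eps
      pm <- par0; pm[[ti]][k] <- pm[[ti]][k] - eps
      fd <- (slideqc:::.qnet_lossgrad_cpp(X, Y, widths, blocks, in_size, pp, 1)$loss -
             slideqc:::.qnet_lossgrad_cpp(X, Y, widths, blocks, in_size, pm, 1)$loss) /
        (2 * eps)
      expect_equal(g[k], fd, tolerance = 1e-4)
    }
  }
})

test_that("training runs, logs finite losses and returns the best epoch", {
  fit <- tiny_fit()
  h <- fit$history
  expect_equal(h$epoch, 0:2)
  expect_true(all(is.finite(h$val_loss)))
  expect_true(all(is.finite(h$train_loss[-1])))
  expect_equal(h$val_loss[h$epoch == fit$best_epoch],
               min(h$val_loss[-1]))
  expect_s3_class(fit, "qnet")
  expect_output(print(fit), "residual CNN")
  # inference determinism on the trained model
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  expect_identical(predict(fit, x), predict(fit, x))
})

test_that("a short training run reduces validation loss on a separable task", {
  ds <- generate_dataset(200, mix = c(focus_blur_severe = 0.5), seed = 31,
                         out_size = 64, second_prob = 0)
  fit <- qnet(ds, config = qnet_config_reduced(epochs = 3,
                                               learning_rate = 1e-3), seed = 2)
  expect_lt(min(fit$history$val_loss[-1]), fit$history$val_loss[1])
})
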