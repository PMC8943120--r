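# Stain deconvolution and the two hand-crafted feature banks.

test_that("stain deconvolution: white is zero density and fades register", {
  white <- array(1, dim = c(32, 32, 3))
  d <- stain_deconvolve(white)
  expect_equal(max(d$hematoxylin), 0)
  expect_equal(max(d$eosin), 0)
  p <- base_patch(0)
  faded <- apply_artefact(p, artefact_spec("stain_fade", 1))
  expect_lt(mean(stain_deconvolve(faded)$hematoxylin),
            mean(stain_deconvolve(p)$hematoxylin))
})

test_that("deconvolution round-trips in-gamut patches", {
  p <- base_patch(1, 128)
  d <- stain_deconvolve(p)
  rec <- stain_reconstruct(d$hematoxylin, d$eosin, d$residual)
  expect_lt(mean(abs(rec - p)), 0.02)
})

test_that("flat patches zero the gradient and contrast features", {
  gray <- array(0.5, dim = c(64, 64, 3))
  f <- features_ours(gray)
  expect_equal(unname(f["tenengrad"]), 0)
  expect_equal(unname(f["var_laplacian"]), 0)
  expect_equal(unname(f["lap2"]), 0)
  fh <- features_histoqc(gray)
  expect_equal(unname(fh["rms_contrast"]), 0)
  expect_equal(unname(fh["michelson"]), 0)
  # per-channel means of a flat colour patch equal that colour
  flat <- array(rep(c(0.8, 0.3, 0.5), each = 64 * 64), dim = c(64, 64, 3))
  fo <- features_ours(flat)
  expect_equal(unname(fo[c("mean_r", "mean_g", "mean_b")]), c(0.8, 0.3, 0.5))
})

test_that("Michelson contrast of a black/white checkerboard is 1", {
  checker <- outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  patch <- array(rep(checker, 3), dim = c(32, 32, 3))
  expect_equal(unname(features_histoqc(patch)["michelson"]), 1)
})

test_that("LBP histogram is a normalised distribution", {
  f <- features_histoqc(base_patch(0, 128))
  lbp <- f[grep("^lbp_", names(f))]
  expect_length(lbp, 10)
  expect_equal(sum(lbp), 1)
  expect_true(all(lbp >= 0))
})

test_that("focus measures decrease monotonically with blur", {
  for (seed in c(0, 1)) {
    p <- base_patch(seed)
    p2 <- apply_artefact(p, artefact_spec("focus_blur", 0.5))  # sigma 2
    p6 <- apply_artefact(p, artefact_spec("focus_blur", 1))    # sigma 6
    for (f in list(focus_tenengrad, focus_var_laplacian, focus_lap2)) {
      v <- c(f(p), f(p2), f(p6))
      expect_true(all(diff(v) < 0))
    }
  }
})

test_that("focus and contrast features are invariant to rotations/flips", {
  p <- base_patch(2, 128)
  variants <- list(
    aperm(p, c(2, 1, 3)),                 # transpose
    p[128:1, , , drop = FALSE],           # vertical flip
    p[, 128:1, , drop = FALSE],           # horizontal flip
    aperm(p, c(2, 1, 3))[128:1, , , drop = FALSE])  # 90 degree rotation
  keys <- c("tenengrad", "var_laplacian", "lap2", "gauss_diff")
  f0 <- features_ours(p)[keys]
  for (v in variants) {
    fv <- features_ours(v)[keys]
    expect_equal(unname(fv), unname(f0), tolerance = 0.01)
  }
})

test_that("feature extraction is pure and tables are well-formed", {
  p <- base_patch(0, 128)
  expect_identical(features_ours(p), features_ours(p))
  tab <- feature_table(list(p, base_patch(1, 128)), "histoqc")
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(as.matrix(tab))))
})

test_that("compare_banks reports one AUC table over identical splits", {
  ds <- small_dataset()
  fit <- tiny_fit()
  idx_tr <- 1:40; idx_te <- 41:60
  train <- list(patches = lapply(idx_tr, function(i) ds$x[, , , i]),
                labels = ds$labels[idx_tr, ])
  test <- list(patches = lapply(idx_te, function(i) ds$x[, , , i]),
               labels = ds$labels[idx_te, ])
  tasks <- list(usability = function(l) l$y1 == 1,
                focus_any = function(l) l$y4 > 0)
  tab <- compare_banks(fit, train, test, tasks = tasks, seed = 3)
  expect_equal(tab$task, names(tasks))
  cells <- unlist(tab[, -1])
  expect_true(all(is.na(cells) | (cells >= 0 & cells <= 1)))
  tab2 <- compare_banks(fit, train, test, tasks = tasks, seed = 3)
  expect_identical(tab, tab2)
})

test_that("random forests separate a separable task and not a shuffled one", {
  ds <- small_dataset()
  feats <- feature_table(ds, "ours")
  fit <- suppressWarnings(train_rf_per_task(
    feats, ds$labels, tasks = list(focus_any = function(l) l$y4 > 0), seed = 1))
  expect_s3_class(fit, "rf_bank")
  pr <- predict(fit, feats, "focus_any")
  expect_gte(roc_auc(ds$labels$y4 > 0, pr), 0.95)   # training-set separability
  # permutation null: shuffled labels give chance-level held-out AUC
  set.seed(2)
  half <- 1:30
  shuffled <- ds$labels
  shuffled$y4 <- sample(shuffled$y4)
  fit0 <- suppressWarnings(train_rf_per_task(
    feats[half, ], shuffled[half, ],
    tasks = list(focus_any = function(l) l$y4 > 0), seed = 1))
  if (!is.null(fit0$fits$focus_any)) {
    auc0 <- roc_auc(shuffled$y4[-half] > 0, predict(fit0, feats[-half, ], "focus_any"))
    expect_lt(abs(auc0 - 0.5), 0.35)
  }
  # determinism under a fixed seed
  fit2 <- suppressWarnings(train_rf_per_task(
    feats, ds$labels, tasks = list(focus_any = function(l) l$y4 > 0), seed = 1))
  expect_equal(predict(fit2, feats, "focus_any"), pr)
  # single-class tasks are skipped with a warning
  expect_warning(
    train_rf_per_task(feats, ds$labels,
                      tasks = list(constant = function(l) rep(TRUE, nrow(l)))),
    "single class")
})
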