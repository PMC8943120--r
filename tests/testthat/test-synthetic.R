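# Synthetic H&E generator: determinism, artefact physics, label rules.

test_that("base patches are deterministic per seed and seed-sensitive", {
  p1 <- generate_base_patch(0, 128)
  p2 <- generate_base_patch(0, 128)
  p3 <- generate_base_patch(1, 128)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(generate_base_patch(0, 32), "at least 64")
})

test_that("base patches are sharp: blurring lowers the Tenengrad measure", {
  p <- base_patch(0)
  blurred <- apply_artefact(p, artefact_spec("focus_blur", 1))
  expect_gt(focus_tenengrad(p), focus_tenengrad(blurred))
})

test_that("zero-severity blur is the identity and severity orders Tenengrad", {
  p <- base_patch(0)
  expect_identical(apply_artefact(p, artefact_spec("focus_blur", 0)), p)
  t_none <- focus_tenengrad(p)
  t_slight <- focus_tenengrad(apply_artefact(p, artefact_spec("focus_blur", 0.5)))
  t_severe <- focus_tenengrad(apply_artefact(p, artefact_spec("focus_blur", 1)))
  expect_gt(t_none, t_slight)
  expect_gt(t_slight, t_severe)
})

test_that("severe stain fade reduces RGB variance and hematoxylin density", {
  p <- base_patch(0)
  faded <- apply_artefact(p, artefact_spec("stain_fade", 1))
  for (ch in 1:3)
    expect_lt(var(as.vector(faded[, , ch])), var(as.vector(p[, , ch])))
  expect_lt(mean(stain_deconvolve(faded)$hematoxylin),
            mean(stain_deconvolve(p)$hematoxylin))
})

test_that("folds add optical density and are not a global darkening", {
  p <- base_patch(2)
  reg <- rect_region(60, 60, 190, 190)
  fold <- apply_artefact(p, artefact_spec("fold", region = reg, seed = 3))
  m <- slideqc:::region_mask(reg, 256)
  od_tot <- function(x) x[, , 1] + x[, , 2] + x[, , 3]
  odf <- od_tot(rgb_to_od(fold))
  expect_gt(mean(odf[m]), mean(odf[!m]))
  # best global optical-density gain cannot reproduce the fold: the
  # residual after fitting fold ~ gain * original stays substantial
  odp <- od_tot(rgb_to_od(p))
  gain <- sum(odf[m] * odp[m]) / sum(odp[m]^2)
  resid <- odf[m] - gain * odp[m]
  expect_gt(sqrt(mean(resid^2)) / mean(odf[m]), 0.1)
})

test_that("artefact injection is deterministic and validates inputs", {
  p <- base_patch(0)
  s <- artefact_spec("dirt", region = rect_region(10, 10, 120, 120), seed = 42)
  expect_identical(apply_artefact(p, s), apply_artefact(p, s))
  expect_error(artefact_spec("vignetting"), "arg")
  expect_error(artefact_spec("focus_blur", severity = 0.3), "severity")
  expect_error(
    apply_artefact(p, artefact_spec("ink", region = rect_region(0, 0, 300, 300))),
    "bounds")
})

test_that("label_for applies the severity/coverage rule table", {
  expect_equal(unname(label_for(list())), c(1, 1, 0, 0, 0, 0))
  expect_equal(unname(label_for(list(artefact_spec("focus_blur", 1)))),
               c(0, 0, 0, 1, 0, 0))
  expect_equal(unname(label_for(list(artefact_spec("focus_blur", 0.5)))),
               c(1, 0, 0, 0.5, 0, 0))
  expect_equal(unname(label_for(list(artefact_spec("stain_fade", 0.5),
                                     artefact_spec("fold", region = rect_region(0, 0, 80, 80))))),
               c(1, 0, 0.5, 0, 1, 0))
  # obscuring coverage >= 50% makes the patch unusable
  big <- artefact_spec("ink", region = rect_region(0, 0, 200, 200))
  small <- artefact_spec("ink", region = rect_region(0, 0, 100, 100))
  expect_equal(unname(label_for(list(big)))[1], 0)
  expect_equal(unname(label_for(list(small)))[1], 1)
  # disc region coverage uses its clipped polygon area
  disc <- artefact_spec("bubble",
                        region = list(shape = "disc", cx = 128, cy = 128, r = 120))
  expect_equal(unname(label_for(list(disc)))[6], 1)
})

test_that("generated datasets are reproducible and label-consistent", {
  ds1 <- small_dataset()
  ds2 <- generate_dataset(60, seed = 5, out_size = 64)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(ds1$x, ds2$x)
  for (i in seq_len(nrow(ds1$labels))) {
    expect_equal(unname(unlist(ds1$labels[i, ])),
                 unname(label_for(ds1$specs[[i]], ds1$size)))
  }
  # QualityLabel invariant: y2 = 1 iff all artefact components are zero
  with(ds1$labels, expect_equal(y2 == 1, y3 == 0 & y4 == 0 & y5 == 0 & y6 == 0))
})

test_that("clean-only mixes give clean labels; mixes must be valid", {
  ds <- generate_dataset(25, mix = numeric(0), seed = 7, size = 64)
  expect_true(all(ds$labels$y1 == 1 & ds$labels$y2 == 1))
  expect_error(generate_dataset(5, mix = c(fold = 0.9, ink = 0.2)), "sum")
})

test_that("dataset label frequencies track the requested mix", {
  mix <- c(focus_blur_severe = 0.3, fold = 0.2)
  ds <- generate_dataset(400, mix = mix, seed = 21, size = 64,
                         second_prob = 0)
  expect_lt(abs(mean(ds$labels$y4 == 1) - 0.3), 0.05)
  expect_lt(abs(mean(ds$labels$y5 == 1) - 0.2), 0.05)
})

test_that("composed slides carry ground-truth overlays per cell", {
  grid <- matrix(list(), 2, 2)
  grid[[1, 1]] <- list(); grid[[1, 2]] <- list()
  grid[[2, 1]] <- list(); grid[[2, 2]] <- list()
  sl <- compose_slide(grid, seed = 3, size = 64)
  expect_equal(sl$overlays$usability, matrix(1, 2, 2))
  grid[[2, 2]] <- list(artefact_spec("focus_blur", 1))
  sl2 <- compose_slide(grid, seed = 3, size = 64)
  expect_equal(mean(sl2$overlays$usability), 0.75)
  expect_equal(sl2$overlays$focus[2, 2], 1)
  # background cells are absent from the overlays
  grid[[1, 1]] <- NA
  sl3 <- compose_slide(grid, seed = 3, size = 64)
  expect_true(is.na(sl3$overlays$usability[1, 1]))
  # untouched cells are identical between compositions with equal seed
  expect_identical(sl$image[1:64, 65:128, ], sl2$image[1:64, 65:128, ])
})

test_that("slide reference scores reflect overlay severity", {
  grid <- matrix(list(), 2, 2)
  for (i in 1:4) grid[[i]] <- list()
  clean <- reference_slide_scores(compose_slide(grid, seed = 1, size = 64))
  expect_equal(unname(clean), c(1, 10, 10))
  for (i in 1:4) grid[[i]] <- list(artefact_spec("focus_blur", 1))
  bad <- reference_slide_scores(compose_slide(grid, seed = 1, size = 64))
  expect_equal(unname(bad[c("usable", "focus_score")]), c(0, 0))
})
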