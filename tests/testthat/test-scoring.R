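# Assessor aggregation, slide-level OLS models, binarisation and
# intervention recommendations.

test_that("assessor aggregation is AND for usability, mean for scores", {
  panel <- data.frame(usability = c(1, 1, 0), focus = c(6, 7, 8),
                      stain = c(9, 8, 7))
  agg <- aggregate_assessors(panel)
  expect_equal(unname(agg), c(0, 7, 8))
  panel$usability <- c(1, 1, 1)
  expect_equal(unname(aggregate_assessors(panel)["usable"]), 1)
  # AND equals the minimum over votes and is order-invariant
  for (votes in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1))) {
    for (perm in list(1:3, 3:1, c(2, 3, 1))) {
      p <- data.frame(usability = votes[perm], focus = 5, stain = 5)
      expect_equal(unname(aggregate_assessors(p)["usable"]), min(votes))
    }
  }
  expect_error(aggregate_assessors(data.frame(usability = 2, focus = 5,
                                              stain = 5)), "0/1")
  expect_error(aggregate_assessors(data.frame(usability = 1, focus = 11,
                                              stain = 5)), "\\[0, 10\\]")
})

test_that("binarise_quality fails exactly the scores at or below 4", {
  expect_equal(binarise_quality(c(0, 4, 4.5, 5, 7, 10)),
               c("fail", "fail", "pass", "pass", "pass", "pass"))
  expect_error(binarise_quality(11), "\\[0, 10\\]")
  expect_error(binarise_quality(-1), "\\[0, 10\\]")
})

test_that("intervention rules follow the fail/burden logic", {
  expect_equal(recommend_intervention(1, 3, 8, other_burden = 0.05), "rescan")
  expect_equal(recommend_intervention(1, 8, 3, other_burden = 0.05), "restain")
  expect_equal(recommend_intervention(1, 3, 3, other_burden = 0.05),
               "rescan_and_restain")
  # heavy obscuring burden suppresses re-scanning
  expect_equal(recommend_intervention(1, 3, 8, other_burden = 0.6),
               "manual_review")
  expect_equal(recommend_intervention(1, 3, 3, other_burden = 0.6), "restain")
  expect_equal(recommend_intervention(0, 8, 8), "manual_review")
  expect_equal(recommend_intervention(1, 8, 8), "none")
})

synthetic_slide_stats <- function(n, seed, noise = 0) {
  # overlay statistics with a known linear map to the reference scores
  with_local_seed <- slideqc:::with_local_seed
  with_local_seed(seed, {
    stats <- data.frame(mean_usability = runif(n, 0.2, 1),
                        var_usability = runif(n, 0, 0.1),
                        mean_focus = runif(n, 0, 0.8),
                        var_focus = runif(n, 0, 0.1),
                        mean_staining = runif(n, 0, 0.6),
                        var_staining = runif(n, 0, 0.1),
                        mean_other = runif(n, 0, 0.4))
    scores <- data.frame(
      usable = as.integer(stats$mean_usability >= 0.6),
      focus_score = 10 * (1 - stats$mean_focus) + rnorm(n, 0, noise),
      stain_score = 10 * (1 - stats$mean_staining) + rnorm(n, 0, noise))
    scores$focus_score <- pmin(pmax(scores$focus_score, 0), 10)
    scores$stain_score <- pmin(pmax(scores$stain_score, 0), 10)
    list(stats = stats, scores = scores)
  })
}

test_that("noiseless OLS recovers the exact linear slide model", {
  d <- synthetic_slide_stats(60, seed = 1, noise = 0)
  fit <- fit_slide_models(d$stats, d$scores, seed = 1)
  cf <- coef(fit$models$focus)
  expect_equal(unname(cf["(Intercept)"]), 10, tolerance = 1e-6)
  expect_equal(unname(cf["mean_focus"]), -10, tolerance = 1e-6)
  others <- setdiff(names(cf), c("(Intercept)", "mean_focus"))
  expect_true(all(abs(cf[others]) < 1e-6))
  pred <- predict(fit, d$stats)
  expect_equal(pred$focus_score, d$scores$focus_score, tolerance = 1e-6)
  # determinism of the fit under an equal seed
  fit2 <- fit_slide_models(d$stats, d$scores, seed = 1)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$split, fit2$split)
})

test_that("noisy OLS recovers coefficients within three standard errors", {
  d <- synthetic_slide_stats(200, seed = 7, noise = 0.5)
  fit <- fit_slide_models(d$stats, d$scores, seed = 2)
  sm <- summary(fit$models$focus)$coefficients
  est <- sm["mean_focus", "Estimate"]; se <- sm["mean_focus", "Std. Error"]
  expect_lt(abs(est - (-10)), 3 * se)
  est0 <- sm["(Intercept)", "Estimate"]; se0 <- sm["(Intercept)", "Std. Error"]
  expect_lt(abs(est0 - 10), 3 * se0)
})

test_that("slide predictions are clipped, binarised and flagged", {
  d <- synthetic_slide_stats(40, seed = 3, noise = 0)
  fit <- fit_slide_models(d$stats, d$scores, seed = 1)
  extreme <- d$stats[1:2, ]
  extreme$mean_focus <- c(-0.5, 1.5)     # push raw predictions out of range
  pred <- predict(fit, extreme)
  expect_true(all(pred$focus_score >= 0 & pred$focus_score <= 10))
  expect_true(all(pred$usability_prob >= 0 & pred$usability_prob <= 1))
  expect_true(all(pred$usable %in% c(0, 1)))
  expect_true(all(pred$intervention %in%
                    c("none", "rescan", "restain", "rescan_and_restain",
                      "manual_review")))
  expect_error(predict(fit, d$stats[, 1:3]), "missing overlay statistic")
})

test_that("predicted focus score is monotone in the focus-overlay mean", {
  d <- synthetic_slide_stats(60, seed = 5, noise = 0)
  fit <- fit_slide_models(d$stats, d$scores, seed = 1)
  base <- d$stats[1, ]
  hi <- base; hi$mean_focus <- base$mean_focus + 0.2
  cf <- coef(fit$models$focus)["mean_focus"]
  p0 <- predict(fit, base)$focus_score
  p1 <- predict(fit, hi)$focus_score
  if (cf > 0) expect_gte(p1, p0) else expect_lte(p1, p0)
})

test_that("degenerate designs are handled explicitly", {
  d <- synthetic_slide_stats(30, seed = 9, noise = 0)
  d$stats$var_other <- 0.2   # constant column
  expect_warning(fit_slide_models(d$stats, d$scores, seed = 1),
                 "constant feature")
  expect_error(fit_slide_models(d$stats[1:5, ], d$scores[1:5, ]),
               "at least 10")
  ud <- d$scores; ud$usable <- 1
  expect_error(fit_slide_models(d$stats, ud), "both usable and unusable")
})
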