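# Slide-level scoring: assessor aggregation, three linear models mapping
# overlay statistics to usability/focus/staining scores, the 0-10
# pass/fail rule and intervention recommendations.

#' Aggregate a panel of assessor scores into a reference slide score
#'
#' Usability is combined with a logical AND (a slide is usable only if
#' every assessor considered it usable); focus and staining scores (0-10)
#' are averaged.
#'
#' @param panel data frame with one row per assessor and columns
#'   `usability` (0/1), `focus` and `stain` (0-10).
#' @return named numeric vector `c(usable, focus_score, stain_score)`.
#' @examples
#' aggregate_assessors(data.frame(usability = c(1, 1, 0),
#'                                focus = c(6, 7, 8),
#'                                stain = c(9, 8, 7)))
#' @export
aggregate_assessors <- function(panel) {
  panel <- as.data.frame(panel)
  stopifnot(nrow(panel) >= 1,
            all(c("usability", "focus", "stain") %in% names(panel)))
  if (!all(panel$usability %in% c(0, 1)))
    stop("assessor usability votes must be 0/1", call. = FALSE)
  if (any(panel$focus < 0 | panel$focus > 10 |
          panel$stain < 0 | panel$stain > 10))
    stop("focus/stain scores must lie in [0, 10]", call. = FALSE)
  c(usable = as.numeric(all(panel$usability == 1)),
    focus_score = mean(panel$focus),
    stain_score = mean(panel$stain))
}

#' Pass/fail binarisation of a 0-10 quality score
#'
#' Scores of 4 or less fail; 5-6 pass, 7-8 good, 9-10 excellent (all
#' "pass" at this binary level).
#'
#' @param score numeric in `[0, 10]` (vectorised).
#' @return character vector `"pass"`/`"fail"`.
#' @export
binarise_quality <- function(score) {
  if (any(score < 0 | score > 10))
    stop("quality scores must lie in [0, 10]", call. = FALSE)
  ifelse(score <= 4, "fail", "pass")
}

#' Recommend a quality intervention for a slide
#'
#' Re-scanning is recommended for a focus failure, but suppressed when
#' the slide carries a heavy burden of "other" artefacts (ink, dirt,
#' glue): re-scanning cannot remove physical material, so those slides
#' go to manual review instead. Re-staining is recommended for a
#' staining failure. An unusable slide without a specific failing score
#' also goes to manual review.
#'
#' @param usable 0/1 predicted slide usability.
#' @param focus_score,stain_score predicted 0-10 scores.
#' @param other_burden mean of the "other"-artefact overlay.
#' @param burden_cut suppression threshold for re-scanning (default 0.3).
#' @return one of `"none"`, `"rescan"`, `"restain"`,
#'   `"rescan_and_restain"`, `"manual_review"`.
#' @export
recommend_intervention <- function(usable, focus_score, stain_score,
                                   other_burden = 0, burden_cut = 0.3) {
  focus_fail <- binarise_quality(focus_score) == "fail"
  stain_fail <- binarise_quality(stain_score) == "fail"
  rescan <- focus_fail && other_burden < burden_cut
  restain <- stain_fail
  if (rescan && restain) return("rescan_and_restain")
  if (rescan) return("rescan")
  if (restain) return("restain")
  if (focus_fail) return("manual_review")  # rescan suppressed by burden
  if (usable == 0) return("manual_review") # unusable with no failing score
  "none"
}

# Stratification key for the slide split: usability crossed with
# quartile-binned focus reference scores.
slide_strata <- function(scores) {
  qs <- quantile(scores$focus_score, probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
  bin <- findInterval(scores$focus_score, unique(qs))
  paste(scores$usable, bin, sep = "_")
}

#' Fit slide-level quality models from overlay statistics
#'
#' Three ordinary-least-squares regressions predict reference usability
#' (0/1), focus and staining scores (0-10) from the mean and variance of
#' the quality overlays. Slides are split 60/40 train/test, stratified on
#' usability crossed with quartile-binned focus scores. Constant features
#' are dropped with a warning.
#'
#' @param stats data frame / matrix of overlay statistics, one row per
#'   slide (default feature set: `overlay_stats()` of all six overlays).
#' @param scores data frame with reference `usable`, `focus_score`,
#'   `stain_score` per slide.
#' @param fractions named train/test fractions summing to 1.
#' @param seed integer seed for the stratified split.
#' @param usability_cut threshold on the predicted usability score
#'   (default 0.5).
#' @param burden_cut re-scan suppression threshold on the mean "other"
#'   overlay.
#' @return object of class `slide_quality_models`: `models` (three `lm`
#'   fits), `features`, `split` (train/test indices), `usability_cut`,
#'   `burden_cut`, `seed`.
#' @export
fit_slide_models <- function(stats, scores,
                             fractions = c(train = 0.6, test = 0.4),
                             seed = 1L, usability_cut = 0.5,
                             burden_cut = 0.3) {
  stats <- as.data.frame(stats)
  scores <- as.data.frame(scores)
  stopifnot(nrow(stats) == nrow(scores))
  if (nrow(stats) < 10)
    stop("at least 10 slides are required", call. = FALSE)
  if (length(unique(scores$usable)) < 2)
    stop("both usable and unusable slides are required", call. = FALSE)
  keep <- vapply(stats, function(col) var(col) > 1e-12, TRUE)
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(names(stats)[!keep], collapse = ", "), call. = FALSE)
    stats <- stats[, keep, drop = FALSE]
  }
  strata <- data.frame(key = slide_strata(scores))
  split <- stratified_split(strata, fractions, seed = seed)
  tr <- split$train
  dat <- cbind(stats, scores)
  fml <- function(target)
    stats::as.formula(paste(target, "~",
                            paste(sprintf("`%s`", names(stats)), collapse = " + ")))
  models <- list(
    usability = lm(fml("usable"), data = dat[tr, , drop = FALSE]),
    focus = lm(fml("focus_score"), data = dat[tr, , drop = FALSE]),
    staining = lm(fml("stain_score"), data = dat[tr, , drop = FALSE]))
  structure(list(models = models, features = names(stats), split = split,
                 usability_cut = usability_cut, burden_cut = burden_cut,
                 seed = seed),
            class = "slide_quality_models")
}

#' @export
print.slide_quality_models <- function(x, ...) {
  cat(sprintf("<slide_quality_models> OLS on %d overlay statistics (%d train / %d test slides)\n",
              length(x$features), length(x$split$train), length(x$split$test)))
  r2 <- vapply(x$models, function(m) summary(m)$r.squared, 0)
  cat(sprintf("  train R^2: usability %.3f, focus %.3f, staining %.3f\n",
              r2[["usability"]], r2[["focus"]], r2[["staining"]]))
  invisible(x)
}

#' @export
coef.slide_quality_models <- function(object, ...) {
  sapply(object$models, coef)
}

#' Predict slide-level quality scores
#'
#' Raw linear predictions are clipped to their ranges (usability to
#' `[0, 1]`, focus/staining to `[0, 10]`), usability is binarised at the
#' configured cut, and an intervention is recommended per slide.
#'
#' @param object a [fit_slide_models()] result.
#' @param stats overlay-statistics data frame, one row per slide; must
#'   contain the fitted feature columns (missing ones are an error).
#' @param slide_id optional identifiers for the output.
#' @param ... unused.
#' @return data frame of class `slide_scores`: `slide_id`,
#'   `usability_prob`, `usable`, `focus_score`, `stain_score`,
#'   `intervention`.
#' @export
predict.slide_quality_models <- function(object, stats, slide_id = NULL, ...) {
  stats <- as.data.frame(stats)
  missing_feats <- setdiff(object$features, names(stats))
  if (length(missing_feats))
    stop("missing overlay statistic(s): ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  up <- pmin(pmax(predict(object$models$usability, stats), 0), 1)
  fs <- pmin(pmax(predict(object$models$focus, stats), 0), 10)
  ss <- pmin(pmax(predict(object$models$staining, stats), 0), 10)
  usable <- as.integer(up >= object$usability_cut)
  burden <- if ("mean_other" %in% names(stats)) stats$mean_other else
    rep(0, nrow(stats))
  intervention <- vapply(seq_len(nrow(stats)), function(i)
    recommend_intervention(usable[i], fs[i], ss[i], burden[i],
                           object$burden_cut), "")
  out <- data.frame(
    slide_id = if (is.null(slide_id)) seq_len(nrow(stats)) else slide_id,
    usability_prob = up, usable = usable, focus_score = fs,
    stain_score = ss, intervention = intervention)
  rownames(out) <- NULL
  class(out) <- c("slide_scores", "data.frame")
  out
}
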