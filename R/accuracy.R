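#' Confidence interval for a binomial proportion
#'
#' Wilson score interval (default) via [stats::prop.test()] without
#' continuity correction, or exact Clopper-Pearson via
#' [stats::binom.test()].
#'
#' @param k Number of successes (vectorised).
#' @param n Number of trials.
#' @param level Confidence level, default 0.95.
#' @param method `"wilson"` or `"clopper_pearson"`.
#' @return A tibble with columns `estimate`, `lower`, `upper`, `level`.
#' @export
proportion_ci <- function(k, n, level = 0.95,
                          method = c("wilson", "clopper_pearson")) {
  method <- match.arg(method)
  if (any(n <= 0)) abort("n must be positive")
  if (any(k < 0 | k > n)) abort("k must lie in [0, n]")
  ci <- purrr::map2(k, n, function(ki, ni) {
    if (method == "wilson") {
      stats::prop.test(ki, ni, conf.level = level, correct = FALSE)$conf.int
    } else {
      stats::binom.test(ki, ni, conf.level = level)$conf.int
    }
  })
  tibble(estimate = k / n,
         lower = vapply(ci, `[`, 0, 1),
         upper = vapply(ci, `[`, 0, 2),
         level = level)
}

#' Likelihood-ratio confidence intervals (Simel log method)
#'
#' The log likelihood ratio is treated as approximately normal with
#' `se(ln LR+) = sqrt((1 - sens)/tp + spec/fp)` and
#' `se(ln LR-) = sqrt(sens/fn + (1 - spec)/tn)`. Studies with a zero cell
#' get 0.5 added to all four cells and are flagged.
#'
#' @param counts Data frame with columns `tp`, `fp`, `fn`, `tn`.
#' @param level Confidence level.
#' @return A tibble with `lr_pos`, `lr_pos_lower`, `lr_pos_upper`,
#'   `lr_neg`, `lr_neg_lower`, `lr_neg_upper`, `corrected`.
#' @export
lr_ci <- function(counts, level = 0.95) {
  counts <- as_tibble(counts)
  z <- qnorm(1 - (1 - level) / 2)
  corrected <- with(counts, tp == 0 | fp == 0 | fn == 0 | tn == 0)
  add <- ifelse(corrected, 0.5, 0)
  tp <- counts$tp + add; fp <- counts$fp + add
  fn <- counts$fn + add; tn <- counts$tn + add
  sens <- tp / (tp + fn); spec <- tn / (fp + tn)
  lrp <- sens / (1 - spec); lrn <- (1 - sens) / spec
  se_p <- sqrt((1 - sens) / tp + spec / fp)
  se_n <- sqrt(sens / fn + (1 - spec) / tn)
  tibble(lr_pos = lrp,
         lr_pos_lower = exp(log(lrp) - z * se_p),
         lr_pos_upper = exp(log(lrp) + z * se_p),
         lr_neg = lrn,
         lr_neg_lower = exp(log(lrn) - z * se_n),
         lr_neg_upper = exp(log(lrn) + z * se_n),
         corrected = corrected)
}

#' Diagnostic-accuracy indices from 2x2 confusion tables
#'
#' Computes, per row, sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`,
#' positive predictive value `tp/(tp+fp)`, detection rate
#' `1000*tp/total`, likelihood ratios `sens/(1-spec)` and
#' `(1-sens)/spec`, and the single-test AUC `(sens+spec)/2` (the
#' trapezoidal area through (0,0), (1-spec, sens) and (1,1)).
#' Proportion-type indices carry Wilson (or Clopper-Pearson) intervals;
#' likelihood ratios carry Simel log-method intervals; the AUC carries a
#' Wald interval from the binomial variances of its two components.
#'
#' @param counts Data frame with columns `tp`, `fp`, `fn`, `tn` (one row
#'   per strategy/cohort); a `strategy` column, if present, is carried
#'   through.
#' @param level Confidence level, default 0.95.
#' @param ci_method CI method for proportions, `"wilson"` (default) or
#'   `"clopper_pearson"`.
#' @return A tibble with point estimates and `*_lower` / `*_upper` bounds
#'   for each index, plus `positives` and `total`. `lr_pos` is `Inf` with
#'   `lr_infinite = TRUE` when the false-positive rate is zero.
#' @examples
#' accuracy_summary(confusion_table(tp = 90, fp = 10, fn = 10, tn = 890))
#' @export
accuracy_summary <- function(counts, level = 0.95,
                             ci_method = c("wilson", "clopper_pearson")) {
  ci_method <- match.arg(ci_method)
  counts <- as_tibble(counts)
  need <- setdiff(c("tp", "fp", "fn", "tn"), names(counts))
  if (length(need) > 0) {
    abort(paste0("missing count column(s): ", paste(need, collapse = ", ")))
  }
  if (any(counts$tp + counts$fn == 0)) abort("zero case margin (tp + fn = 0)")
  if (any(counts$fp + counts$tn == 0)) abort("zero non-case margin (fp + tn = 0)")

  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  sens_ci <- proportion_ci(tp, tp + fn, level, ci_method)
  spec_ci <- proportion_ci(tn, fp + tn, level, ci_method)
  ppv_ci <- proportion_ci(tp, tp + fp, level, ci_method)
  dr_ci <- proportion_ci(tp, total, level, ci_method)
  lr <- lr_ci(counts, level)

  sens <- sens_ci$estimate; spec <- spec_ci$estimate
  lr_pos_point <- ifelse(spec < 1, sens / (1 - spec), Inf)
  lr_neg_point <- (1 - sens) / spec
  auc <- (sens + spec) / 2
  z <- qnorm(1 - (1 - level) / 2)
  auc_se <- sqrt(sens * (1 - sens) / (tp + fn) +
                 spec * (1 - spec) / (fp + tn)) / 2

  out <- tibble(
    positives = tp + fp, total = total,
    sensitivity = sens,
    sensitivity_lower = sens_ci$lower, sensitivity_upper = sens_ci$upper,
    specificity = spec,
    specificity_lower = spec_ci$lower, specificity_upper = spec_ci$upper,
    ppv = ppv_ci$estimate,
    ppv_lower = ppv_ci$lower, ppv_upper = ppv_ci$upper,
    detection_rate = 1000 * dr_ci$estimate,
    detection_rate_lower = 1000 * dr_ci$lower,
    detection_rate_upper = 1000 * dr_ci$upper,
    lr_pos = lr_pos_point,
    lr_pos_lower = ifelse(is.finite(lr_pos_point), lr$lr_pos_lower, NA_real_),
    lr_pos_upper = ifelse(is.finite(lr_pos_point), lr$lr_pos_upper, NA_real_),
    lr_neg = lr_neg_point,
    lr_neg_lower = lr$lr_neg_lower, lr_neg_upper = lr$lr_neg_upper,
    auc = auc,
    auc_lower = pmax(0, auc - z * auc_se),
    auc_upper = pmin(1, auc + z * auc_se),
    lr_infinite = !is.finite(lr_pos_point),
    level = level
  )
  if ("strategy" %in% names(counts)) {
    out <- dplyr::bind_cols(counts["strategy"], out)
  }
  out
}

#' Format an accuracy summary the way screening reports print it
#'
#' Returns a character table with the layout of the programme's published
#' accuracy table: positives with percentage, then each index as
#' "estimate (lower, upper)" rounded half-up to 2 decimals (PPV as a
#' percentage).
#'
#' @param acc Output of [accuracy_summary()].
#' @return A tibble of formatted strings.
#' @export
format_accuracy <- function(acc) {
  fmt <- function(e, l, u, d = 2) {
    sprintf("%.*f (%.*f, %.*f)", d, round_half_up(e, d), d,
            round_half_up(l, d), d, round_half_up(u, d))
  }
  out <- tibble(
    positives = sprintf("%d (%.1f)", acc$positives,
                        round_half_up(100 * acc$positives / acc$total, 1)),
    sensitivity = fmt(acc$sensitivity, acc$sensitivity_lower, acc$sensitivity_upper),
    specificity = fmt(acc$specificity, acc$specificity_lower, acc$specificity_upper),
    lr_pos = fmt(acc$lr_pos, acc$lr_pos_lower, acc$lr_pos_upper),
    lr_neg = fmt(acc$lr_neg, acc$lr_neg_lower, acc$lr_neg_upper),
    detection_rate = fmt(acc$detection_rate, acc$detection_rate_lower,
                         acc$detection_rate_upper),
    ppv_pct = fmt(100 * acc$ppv, 100 * acc$ppv_lower, 100 * acc$ppv_upper)
  )
  if ("strategy" %in% names(acc)) out <- dplyr::bind_cols(acc["strategy"], out)
  out
}
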