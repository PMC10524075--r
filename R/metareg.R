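#' Bivariate meta-regression on a categorical covariate
#'
#' Refits the bivariate normal model with cell-means indicators for a
#' categorical study-level covariate on both pooled means, and asks (a)
#' whether the covariate explains heterogeneity in either outcome and
#' (b) how much of the between-study variance it removes.
#'
#' All fits use the full-likelihood normal model (`method = "ml"` of
#' [fit_bivariate()]) so likelihood ratios are comparable across
#' fixed-effect structures: the per-outcome p-values compare a model with
#' the covariate on that outcome's mean only against the covariate-free
#' fit (chi-squared with `k - 1` degrees of freedom for `k` categories).
#' Heterogeneity explained per outcome is the relative reduction in
#' `tau2` between the covariate-free fit and the fit with the covariate
#' on both means, clipped to `[0, 1]`.
#'
#' @param studies Data frame with `tp`, `fp`, `fn`, `tn` and the
#'   covariate column.
#' @param covariate Name of the covariate column (character).
#' @param correction Continuity correction passed to the fits.
#' @return A `meta_regression` object: `coefficients` (per-category
#'   pooled logits for both outcomes), `p_values` (named: `sensitivity`,
#'   `specificity`), `het_explained` (same names), the three fitted
#'   models, and the categories dropped as singletons (with a warning).
#' @export
meta_regression <- function(studies, covariate, correction = 0.5) {
  studies <- as_tibble(studies)
  if (!is.character(covariate) || length(covariate) != 1) {
    abort("covariate must be a single column name")
  }
  if (!covariate %in% names(studies)) {
    abort(paste0("covariate column not found: ", covariate))
  }
  cov_vals <- as.character(studies[[covariate]])
  if (anyNA(cov_vals)) abort("covariate must be present for all studies")
  tab <- table(cov_vals)
  singletons <- names(tab)[tab < 2]
  if (length(singletons) > 0) {
    warn(paste0("dropping singleton categor",
                if (length(singletons) > 1) "ies: " else "y: ",
                paste(singletons, collapse = ", ")))
    keep <- !cov_vals %in% singletons
    studies <- studies[keep, , drop = FALSE]
    cov_vals <- cov_vals[keep]
  }
  cats <- sort(unique(cov_vals))
  if (length(cats) < 2) {
    abort("covariate needs at least 2 categories with at least 2 studies each")
  }
  X <- stats::model.matrix(~ 0 + factor(cov_vals, levels = cats))
  colnames(X) <- cats

  fit0 <- fit_bivariate_impl(studies, NULL, NULL, method = "ml",
                             correction = correction)
  fit_s <- fit_bivariate_impl(studies, X, NULL, method = "ml",
                              correction = correction)
  fit_e <- fit_bivariate_impl(studies, NULL, X, method = "ml",
                              correction = correction)
  fit_se <- fit_bivariate_impl(studies, X, X, method = "ml",
                               correction = correction)

  df <- length(cats) - 1
  p_sens <- pchisq(2 * (fit_s$loglik - fit0$loglik), df, lower.tail = FALSE)
  p_spec <- pchisq(2 * (fit_e$loglik - fit0$loglik), df, lower.tail = FALSE)
  het_exp <- function(t0, t1) {
    if (t0 <= 0) return(0)
    min(1, max(0, (t0 - t1) / t0))
  }
  het <- c(sensitivity = het_exp(fit0$tau2["sens"], fit_se$tau2["sens"]),
           specificity = het_exp(fit0$tau2["spec"], fit_se$tau2["spec"]))

  coefs <- tibble(
    category = cats,
    logit_sens = unname(fit_se$beta[seq_along(cats)]),
    logit_spec = unname(fit_se$beta[length(cats) + seq_along(cats)]),
    n_studies = as.integer(tab[cats])
  ) |>
    dplyr::mutate(sensitivity = plogis(.data$logit_sens),
                  specificity = plogis(.data$logit_spec))

  structure(list(covariate = covariate,
                 coefficients = coefs,
                 p_values = c(sensitivity = unname(p_sens),
                              specificity = unname(p_spec)),
                 het_explained = unname(het) |>
                   setNames(c("sensitivity", "specificity")),
                 fit_null = fit0, fit_covariate = fit_se,
                 dropped = singletons),
            class = "meta_regression")
}

#' @export
print.meta_regression <- function(x, ...) {
  cat("Bivariate meta-regression on '", x$covariate, "'\n", sep = "")
  print(x$coefficients)
  cat(sprintf("  LRT p (sensitivity): %.4g   LRT p (specificity): %.4g\n",
              x$p_values["sensitivity"], x$p_values["specificity"]))
  cat(sprintf("  heterogeneity explained: sens %.1f%%, spec %.1f%%\n",
              100 * x$het_explained["sensitivity"],
              100 * x$het_explained["specificity"]))
  invisible(x)
}

#' Deeks' funnel-plot asymmetry test for small-study effects
#'
#' Regresses each study's log diagnostic odds ratio on the inverse square
#' root of its effective sample size `ESS = 4 * n1 * n2 / (n1 + n2)`
#' (with `n1 = tp + fn` cases and `n2 = fp + tn` non-cases), weighting by
#' ESS. Under no small-study effect the slope is zero; the p-value is the
#' two-sided t-test on the slope. Studies with a zero cell get the 0.5
#' correction before the log DOR is formed.
#'
#' @param studies Data frame with `tp`, `fp`, `fn`, `tn` (and optionally
#'   `study_id`); at least 3 studies.
#' @param correction Continuity correction for zero cells.
#' @return A `deeks_test` object with `slope`, `intercept`, `p_value`,
#'   and per-study `data` (`lndor`, `ess`, `inv_sqrt_ess`).
#' @export
deeks_test <- function(studies, correction = 0.5) {
  dat <- prep_studies(studies, correction)
  if (nrow(dat) < 3) abort("Deeks' test needs at least 3 studies")
  add <- ifelse(dat$corrected, correction, 0)
  tp <- dat$tp + add; fp <- dat$fp + add
  fn <- dat$fn + add; tn <- dat$tn + add
  lndor <- log(tp * tn / (fp * fn))
  n1 <- tp + fn; n2 <- fp + tn
  ess <- 4 * n1 * n2 / (n1 + n2)
  x <- 1 / sqrt(ess)
  if (sd(x) < 1e-12) {
    # all studies share one effective size: the funnel has no width, the
    # regression is exactly flat and asymmetry is untestable
    return(structure(list(slope = 0,
                          intercept = sum(ess * lndor) / sum(ess),
                          p_value = NA_real_,
                          data = tibble(study_id = dat$study_id,
                                        lndor = lndor, ess = ess,
                                        inv_sqrt_ess = x),
                          model = NULL),
                     class = "deeks_test"))
  }
  mod <- lm(lndor ~ x, weights = ess)
  sm <- summary(mod)$coefficients
  structure(list(slope = unname(coef(mod)[2]),
                 intercept = unname(coef(mod)[1]),
                 p_value = unname(sm[2, 4]),
                 data = tibble(study_id = dat$study_id, lndor = lndor,
                               ess = ess, inv_sqrt_ess = x),
                 model = mod),
            class = "deeks_test")
}

#' @export
print.deeks_test <- function(x, ...) {
  cat(sprintf("Deeks' funnel-plot asymmetry test (%d studies)\n",
              nrow(x$data)))
  cat(sprintf("  slope %.3f, intercept %.3f, p = %.4g\n",
              x$slope, x$intercept, x$p_value))
  invisible(x)
}

#' Posttest probability from pretest probability and a likelihood ratio
#'
#' Bayes' theorem in odds form (the arithmetic behind the Fagan
#' nomogram): posttest odds = pretest odds x LR.
#'
#' @param pretest Pretest probability, strictly inside (0, 1)
#'   (vectorised).
#' @param lr Positive likelihood ratio of the observed test result
#'   (LR+ for a positive result, LR- for a negative one).
#' @return A `fagan_result` tibble with `pretest`, `lr`, `posttest`.
#' @examples
#' fagan_posttest(0.01, (1 - 0.76) / 0.59)
#' @export
fagan_posttest <- function(pretest, lr) {
  if (any(pretest <= 0 | pretest >= 1)) {
    abort("pretest probability must lie strictly inside (0, 1)")
  }
  if (any(lr <= 0)) abort("likelihood ratio must be positive")
  odds <- pretest / (1 - pretest) * lr
  out <- tibble(pretest = pretest, lr = lr, posttest = odds / (1 + odds))
  class(out) <- c("fagan_result", class(out))
  out
}
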