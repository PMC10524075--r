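#' Tidy a bivariate random-effects fit
#'
#' @param x A `bivariate_fit`.
#' @param ... Unused.
#' @return One row per parameter (`mu_sens`, `mu_spec`, `tau_sens`,
#'   `tau_spec`, `rho`) with `estimate` and `std.error` where available.
#' @method tidy bivariate_fit
#' @export
tidy.bivariate_fit <- function(x, ...) {
  if (!is.null(x$mu)) {
    mu_se <- sqrt(diag(x$beta_vcov[1:2, 1:2, drop = FALSE]))
    tibble(term = c("mu_sens", "mu_spec", "tau_sens", "tau_spec", "rho"),
           estimate = c(unname(x$mu), unname(x$tau), x$rho),
           std.error = c(mu_se, unname(x$vpar_se)))
  } else {
    tibble(term = names(x$beta), estimate = unname(x$beta),
           std.error = sqrt(diag(x$beta_vcov)))
  }
}

#' @rdname tidy.bivariate_fit
#' @return For `glance()`: a one-row model summary.
#' @method glance bivariate_fit
#' @export
glance.bivariate_fit <- function(x, ...) {
  tibble(n_studies = x$n_studies,
         pooled_sens = if (is.null(x$mu)) NA_real_ else plogis(unname(x$mu["sens"])),
         pooled_spec = if (is.null(x$mu)) NA_real_ else plogis(unname(x$mu["spec"])),
         tau2_sens = unname(x$tau2["sens"]),
         tau2_spec = unname(x$tau2["spec"]),
         rho = x$rho,
         logLik = x$loglik,
         method = x$method,
         converged = x$converged)
}

#' Tidy a bivariate meta-regression
#'
#' @param x A `meta_regression` object.
#' @param ... Unused.
#' @return `tidy()`: per-category pooled logits and back-transformed
#'   accuracies. `glance()`: the per-outcome LRT p-values and the share
#'   of between-study variance the covariate removes.
#' @method tidy meta_regression
#' @export
tidy.meta_regression <- function(x, ...) x$coefficients

#' @rdname tidy.meta_regression
#' @method glance meta_regression
#' @export
glance.meta_regression <- function(x, ...) {
  tibble(covariate = x$covariate,
         n_studies = x$fit_null$n_studies,
         p_sensitivity = unname(x$p_values["sensitivity"]),
         p_specificity = unname(x$p_values["specificity"]),
         het_explained_sens = unname(x$het_explained["sensitivity"]),
         het_explained_spec = unname(x$het_explained["specificity"]))
}

#' Tidy Deeks' asymmetry test
#'
#' @param x A `deeks_test` object.
#' @param ... Unused.
#' @return `tidy()`: the per-study funnel coordinates. `glance()`: slope,
#'   intercept and p-value.
#' @method tidy deeks_test
#' @export
tidy.deeks_test <- function(x, ...) x$data

#' @rdname tidy.deeks_test
#' @method glance deeks_test
#' @export
glance.deeks_test <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, p_value = x$p_value,
         n_studies = nrow(x$data))
}
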