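#' Summary ROC curve from a bivariate fit
#'
#' Maps the bivariate parameters to the Rutter-Gatsonis HSROC curve
#' (Harbord reparameterisation). Writing `x` for logit false-positive
#' rate and `y` for logit sensitivity, the summary line is
#' `y = mu_sens + (tau_sens / tau_spec) * (x + mu_spec)`: a straight line
#' in logit-logit space through the summary point with slope equal to the
#' ratio of the between-study standard deviations (the shape parameter
#' `beta = log(tau_spec^2 / tau_sens^2) / 2` of the HSROC model). The
#' curve is evaluated on a uniform false-positive-rate grid and the AUC
#' obtained by trapezoidal integration over the full (0, 1) range.
#'
#' @param fit A `bivariate_fit` (intercept-only).
#' @param grid_size Number of grid points over (0, 1); default 1001.
#' @return An `sroc` object: list with `curve` (tibble of `fpr`,
#'   `sensitivity`), `auc`, `summary_point`, and `degenerate` (`TRUE`
#'   when both between-study variances are zero, in which case only the
#'   summary point is returned and `auc` is `NA`).
#' @export
sroc_curve <- function(fit, grid_size = 1001) {
  stopifnot(inherits(fit, "bivariate_fit"))
  if (is.null(fit$mu)) abort("sroc_curve needs an intercept-only fit")
  if (grid_size < 3) abort("grid_size must be at least 3")
  mu_s <- unname(fit$mu["sens"]); mu_e <- unname(fit$mu["spec"])
  summary_point <- tibble(fpr = plogis(-mu_e), sensitivity = plogis(mu_s))
  if (fit$tau2["sens"] + fit$tau2["spec"] <= 1e-10) {
    warn("both between-study variances are zero; sROC degenerates to the summary point")
    return(structure(list(curve = summary_point, auc = NA_real_,
                          summary_point = summary_point, degenerate = TRUE),
                     class = "sroc"))
  }
  slope <- max(fit$tau["sens"], 1e-8) / max(fit$tau["spec"], 1e-8)
  fpr <- seq(0, 1, length.out = grid_size)
  x <- qlogis(fpr[-c(1, grid_size)])
  sens_mid <- plogis(mu_s + slope * (x + mu_e))
  # logit-scale limits: slope > 0 drives the curve to (0,0) and (1,1)
  sens <- c(0, sens_mid, 1)
  auc <- pracma::trapz(fpr, sens)
  structure(list(curve = tibble(fpr = fpr, sensitivity = sens),
                 auc = auc, summary_point = summary_point,
                 degenerate = FALSE),
            class = "sroc")
}

#' @export
print.sroc <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate sROC (summary point only)\n")
  } else {
    cat(sprintf("sROC curve on %d grid points, AUC = %.4f\n",
                nrow(x$curve), x$auc))
  }
  cat(sprintf("  summary point: FPR %.3f, sensitivity %.3f\n",
              x$summary_point$fpr, x$summary_point$sensitivity))
  invisible(x)
}

#' @method tidy sroc
#' @export
tidy.sroc <- function(x, ...) x$curve
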