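#' Cochran's Q and the I-squared heterogeneity statistic
#'
#' Fixed-effect (inverse-variance) Q across study-level estimates, with
#' `I2 = max(0, (Q - df) / Q)`.
#'
#' @param data Data frame of study-level results.
#' @param estimate,variance Columns of `data` holding the per-study
#'   estimates and their (positive) variances.
#' @return A one-row tibble with `q`, `df`, `i2`.
#' @export
heterogeneity <- function(data, estimate, variance) {
  data <- as_tibble(data)
  y <- dplyr::pull(data, {{ estimate }})
  v <- dplyr::pull(data, {{ variance }})
  if (length(y) < 2) abort("at least 2 studies are required")
  if (any(v <= 0)) abort("variances must be positive")
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  df <- length(y) - 1
  tibble(q = q, df = df, i2 = if (q > 0) max(0, (q - df) / q) else 0)
}

#' Random-effects pooling of proportions on the logit scale
#'
#' Pools per-study event proportions with a DerSimonian-Laird
#' between-study variance on the logit scale (the `metaprop`-style
#' estimator): studies with zero or all events get the 0.5/1 continuity
#' correction, the fixed-effect Q on logit proportions yields the DL
#' `tau2` and `I2`, and the random-effects mean is back-transformed with
#' a Wald interval. A single study reduces to its Wilson interval.
#'
#' @param data Data frame with one row per study.
#' @param events,denoms Columns holding event counts and denominators.
#' @param scale `"proportion"` (default) or `"per_1000"`.
#' @param level Confidence level.
#' @return A one-row tibble: `estimate`, `conf_low`, `conf_high`, `tau2`,
#'   `i2`, `q`, `df`, `n_studies`, `scale`, `all_zero`.
#' @export
pool_proportion <- function(data, events, denoms,
                            scale = c("proportion", "per_1000"),
                            level = 0.95) {
  scale <- match.arg(scale)
  data <- as_tibble(data)
  k <- dplyr::pull(data, {{ events }})
  n <- dplyr::pull(data, {{ denoms }})
  if (length(k) != length(n)) abort("events and denoms must have equal length")
  if (any(n <= 0)) abort("denominators must be positive")
  if (any(k < 0 | k > n)) abort("events must lie in [0, denominator]")
  mult <- if (scale == "per_1000") 1000 else 1
  ns <- length(k)

  if (all(k == 0)) {
    upper <- stats::binom.test(0, sum(n), conf.level = level)$conf.int[2]
    return(tibble(estimate = 0, conf_low = 0, conf_high = mult * upper,
                  tau2 = 0, i2 = 0, q = 0, df = ns - 1, n_studies = ns,
                  scale = scale, all_zero = TRUE))
  }
  if (ns == 1) {
    ci <- proportion_ci(k, n, level, "wilson")
    return(tibble(estimate = mult * ci$estimate,
                  conf_low = mult * ci$lower, conf_high = mult * ci$upper,
                  tau2 = 0, i2 = 0, q = 0, df = 0, n_studies = 1,
                  scale = scale, all_zero = FALSE))
  }

  corr <- k == 0 | k == n
  kc <- k + ifelse(corr, 0.5, 0)
  nc <- n + ifelse(corr, 1, 0)
  y <- qlogis(kc / nc)
  v <- 1 / kc + 1 / (nc - kc)
  w <- 1 / v
  ybar_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar_fe)^2)
  df <- ns - 1
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - df) / c_dl)
  wr <- 1 / (v + tau2)
  est <- sum(wr * y) / sum(wr)
  se <- sqrt(1 / sum(wr))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(estimate = mult * plogis(est),
         conf_low = mult * plogis(est - z * se),
         conf_high = mult * plogis(est + z * se),
         tau2 = tau2,
         i2 = if (q > 0) max(0, (q - df) / q) else 0,
         q = q, df = df, n_studies = ns, scale = scale, all_zero = FALSE)
}
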