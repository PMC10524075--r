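test_that("identical studies pool to their common accuracy with no heterogeneity", {
  st <- confusion_table(tp = rep(76, 20), fp = rep(7, 20),
                        fn = rep(24, 20), tn = rep(93, 20))
  fit <- fit_bivariate(st)
  expect_equal(unname(plogis(fit$mu["sens"])), 0.76, tolerance = 0.005)
  expect_equal(unname(plogis(fit$mu["spec"])), 0.93, tolerance = 0.005)
  expect_lt(fit$tau2["sens"], 1e-4)
  expect_lt(fit$tau2["spec"], 1e-4)
})

test_that("with variances fixed at zero the fit is inverse-variance pooling", {
  st <- confusion_table(tp = c(40, 55, 102), fp = c(7, 12, 30),
                        fn = c(10, 20, 41), tn = c(80, 150, 260))
  fit <- fit_bivariate(st, fixed_tau = c(0, 0), fixed_rho = 0)
  d <- fitriage:::prep_studies(st)
  expect_equal(unname(fit$mu["sens"]), sum(d$y1 / d$v1) / sum(1 / d$v1),
               tolerance = 1e-6)
  expect_equal(unname(fit$mu["spec"]), sum(d$y2 / d$v2) / sum(1 / d$v2),
               tolerance = 1e-6)
  expect_equal(fit$tau2, c(sens = 0, spec = 0))
  expect_error(fit_bivariate(st[1, ]), "at least 2")
})

test_that("REML fit agrees with an independent multivariate meta-analysis fit", {
  skip_if_not_installed("metafor")
  st <- simulate_study_set(meta_params(n_studies = 60, seed = 7))
  fit <- fit_bivariate(st)
  d <- fitriage:::prep_studies(st)
  long <- data.frame(study = rep(d$study_id, each = 2),
                     outcome = rep(c("sens", "spec"), nrow(d)),
                     yi = as.vector(rbind(d$y1, d$y2)),
                     vi = as.vector(rbind(d$v1, d$v2)))
  mf <- metafor::rma.mv(yi, vi, mods = ~ 0 + outcome,
                        random = ~ outcome | study, struct = "UN",
                        data = long, method = "REML")
  expect_equal(unname(fit$mu), as.numeric(coef(mf)), tolerance = 1e-4)
  expect_equal(unname(fit$tau2), as.numeric(mf$tau2), tolerance = 1e-4)
  expect_equal(fit$rho, as.numeric(mf$rho), tolerance = 1e-3)
})

test_that("parameters are recovered from a simulated study collection", {
  truth <- c(qlogis(0.76), qlogis(0.92), 0.4, 0.5, -0.3)
  st <- simulate_study_set(meta_params(n_studies = 120,
                                       size_range = c(1000, 4000),
                                       seed = 19))
  fit <- fit_bivariate(st)
  td <- tidy(fit)
  expect_true(all(is.finite(td$std.error)))
  expect_true(all(abs(td$estimate - truth) <= 2.5 * td$std.error))
  expect_true(fit$converged)
})

test_that("exact-binomial likelihood agrees with the normal approximation on large studies", {
  st <- simulate_study_set(meta_params(n_studies = 25, tau_sens = 0.3,
                                       tau_spec = 0.3, rho = -0.2,
                                       size_range = c(5000, 20000),
                                       prevalence_range = c(0.01, 0.05),
                                       seed = 23))
  fit_n <- fit_bivariate(st, method = "reml")
  fit_b <- fit_bivariate(st, method = "ml_binomial")
  expect_equal(unname(fit_b$mu), unname(fit_n$mu), tolerance = 0.05)
  expect_equal(fit_b$rho, fit_n$rho, tolerance = 0.25)
  expect_error(fit_bivariate(st, method = "ml_binomial", gh_nodes = 5),
               "at least 21")
})

test_that("pooled summaries satisfy the likelihood-ratio identities", {
  st <- simulate_study_set(meta_params(n_studies = 40, seed = 31))
  fit <- fit_bivariate(st)
  sm <- summarize_bivariate(fit)
  est <- setNames(sm$estimate, sm$statistic)
  expect_equal(unname(est["lr_pos"]),
               unname(est["sensitivity"] / (1 - est["specificity"])),
               tolerance = 1e-12)
  expect_equal(unname(est["lr_neg"]),
               unname((1 - est["sensitivity"]) / est["specificity"]),
               tolerance = 1e-12)
  expect_true(all(sm$conf_low <= sm$estimate & sm$estimate <= sm$conf_high))
  # bootstrap cross-check stays close to the delta intervals
  smb <- summarize_bivariate(fit, ci = "bootstrap", boot_draws = 5000,
                             seed = 1)
  expect_equal(smb$conf_low, sm$conf_low, tolerance = 0.06)
  expect_equal(smb$conf_high, sm$conf_high, tolerance = 0.06)
  # spec spot value: mu = (logit 0.76, logit 0.59) gives LR- near 0.407
  fit2 <- fit
  fit2$mu <- c(sens = qlogis(0.76), spec = qlogis(0.59))
  sm2 <- summarize_bivariate(fit2)
  expect_equal(unname(sm2$estimate[sm2$statistic == "lr_neg"]), (1 - 0.76) / 0.59,
               tolerance = 1e-9)
})

test_that("sROC curve matches a quadrature oracle and degenerates cleanly", {
  st <- simulate_study_set(meta_params(n_studies = 50, seed = 13))
  fit <- fit_bivariate(st)
  sr <- sroc_curve(fit, grid_size = 2001)
  # oracle: numerical integration of the logit-linear curve
  slope <- fit$tau["sens"] / fit$tau["spec"]
  a <- unname(fit$mu["sens"] + slope * fit$mu["spec"])
  oracle <- stats::integrate(function(f) plogis(a + slope * qlogis(f)),
                             0, 1, rel.tol = 1e-9)$value
  expect_equal(sr$auc, oracle, tolerance = 1e-4)
  # grid-size stability beyond 1000 points
  expect_equal(sroc_curve(fit, grid_size = 1001)$auc,
               sroc_curve(fit, grid_size = 5001)$auc, tolerance = 1e-4)
  expect_true(all(diff(sr$curve$sensitivity) >= 0))
  # symmetric fit: curve symmetric about the anti-diagonal
  fs <- fit
  fs$mu <- c(sens = 1.2, spec = 1.2)
  fs$tau <- c(sens = 0.4, spec = 0.4); fs$tau2 <- fs$tau^2
  ss <- sroc_curve(fs, grid_size = 101)
  f1 <- 0.15
  s1 <- plogis(2 * 1.2 + qlogis(f1))
  expect_equal(plogis(2 * 1.2 + qlogis(1 - s1)), 1 - f1, tolerance = 1e-9)
  # chance-level fit gives the diagonal
  fu <- fit
  fu$mu <- c(sens = 0.7, spec = -0.7)  # sens + spec = 1
  fu$tau <- c(sens = 0.3, spec = 0.3); fu$tau2 <- fu$tau^2
  expect_equal(sroc_curve(fu, grid_size = 4001)$auc, 0.5, tolerance = 1e-3)
  # both variances zero: summary point only
  fd <- fit
  fd$tau <- c(sens = 0, spec = 0); fd$tau2 <- fd$tau^2
  expect_warning(sd0 <- sroc_curve(fd), "degenerates")
  expect_true(sd0$degenerate)
  expect_true(is.na(sd0$auc))
})

test_that("full-stack recovery at the pooled operating point of the review", {
  # 103 studies around sens 0.73 / spec 0.92, as the overall pooled row
  st <- simulate_study_set(meta_params(n_studies = 103,
                                       mu_sens = qlogis(0.73),
                                       mu_spec = qlogis(0.92),
                                       tau_sens = 0.35, tau_spec = 0.45,
                                       rho = -0.3, seed = 103))
  sm <- summarize_bivariate(fit_bivariate(st))
  sens <- sm[sm$statistic == "sensitivity", ]
  spec <- sm[sm$statistic == "specificity", ]
  expect_true(sens$conf_low <= 0.73 && 0.73 <= sens$conf_high)
  expect_true(spec$conf_low <= 0.92 && 0.92 <= spec$conf_high)
})
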