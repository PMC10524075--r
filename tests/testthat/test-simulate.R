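test_that("cohort generation is deterministic and respects trivial limits", {
  p <- cohort_params(n_subjects = 2000, seed = 11)
  expect_identical(simulate_cohort(p), simulate_cohort(p))
  # different seed, different cohort
  p2 <- cohort_params(n_subjects = 2000, seed = 12)
  expect_false(identical(simulate_cohort(p), simulate_cohort(p2)))
  # zero prevalence: nobody is ever diagnosed
  none <- simulate_cohort(cohort_params(n_subjects = 2000, prevalence = 0,
                                        seed = 1))
  expect_true(all(is.na(none$days_to_diagnosis)))
  expect_false(any(none$is_case))
  expect_error(cohort_params(prevalence = 1.5))
  expect_error(cohort_params(ra_item_rates = rep(0.1, 5)))
  expect_error(cohort_params(lag_weights_adherent = c(0.5, 0.2, 0.2)))
})

test_that("simulated margins converge to the generating rates", {
  n <- 2e5
  pars <- cohort_params(n_subjects = n, seed = 101)
  coh <- simulate_cohort(pars)
  mcse <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(coh$is_case) - pars$prevalence),
            3 * mcse(pars$prevalence))
  for (j in 1:9) {
    item <- ra_items()[j]
    rate <- pars$ra_item_rates[j]
    # non-cases carry the base rates (cases are a negligible fraction)
    expect_lt(abs(mean(coh[[item]][!coh$is_case]) - rate),
              4 * mcse(rate), label = item)
  }
  # per-specimen FIT sensitivity among cases
  cases <- coh[coh$is_case, ]
  se_sens <- sqrt(0.57 * 0.43 / nrow(cases))
  expect_lt(abs(mean(cases$fit1) - 0.57), 3 * se_sens)
  # 2-specimen union sensitivity: closed form with latent sharing
  s <- pars$fit_sens_per_specimen; cc <- pars$specimen_correlation
  union_sens <- cc * s + (1 - cc) * (1 - (1 - s)^2)
  expect_lt(abs(mean(cases$fit1 | cases$fit2) - union_sens),
            3 * sqrt(union_sens * (1 - union_sens) / nrow(cases)))
})

test_that("diagnosis lags land in the bands the classification expects", {
  coh <- simulate_cohort(cohort_params(n_subjects = 3e5, seed = 21))
  pos <- combine_tests("parallel_ra_fit2", coh$ra_positive, coh$fit1, coh$fit2)
  cls <- classify_outcome(pos, coh$days_to_diagnosis)
  cases_pos <- coh$is_case & pos
  # share of positive cases classed missed converges to 1 - adherence
  missed_share <- sum(cls == "missed") / sum(cases_pos)
  expect_lt(abs(missed_share - 0.4),
            3 * sqrt(0.4 * 0.6 / sum(cases_pos)))
  # screen-negative cases are interval or (late) non-case, never missed
  expect_identical(sum(cls == "missed" & !pos), 0L)
})

test_that("study-set generation is deterministic and honours tau = 0", {
  p <- meta_params(n_studies = 25, seed = 4)
  expect_identical(simulate_study_set(p), simulate_study_set(p))
  fixed <- simulate_study_set(meta_params(n_studies = 200, tau_sens = 0,
                                          tau_spec = 0, rho = 0, seed = 6))
  expect_equal(unique(fixed$true_sens), 0.76, tolerance = 1e-9)
  fit <- fit_bivariate(fixed)
  expect_lt(abs(plogis(fit$mu["sens"]) - 0.76), 0.02)
  expect_lt(fit$tau2["sens"], 0.01)
  # single study: usable by the accuracy layer, rejected by the pooling
  single <- simulate_study_set(meta_params(n_studies = 1, seed = 8))
  expect_identical(nrow(accuracy_summary(single)), 1L)
  expect_error(fit_bivariate(single), "at least 2")
  expect_error(meta_params(rho = 1.5))
  expect_error(meta_params(size_range = c(2, 5)))
})
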