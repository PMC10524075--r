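#' Parameters for a synthetic triage-screening cohort
#'
#' The generator emulates the data-generating setting of a large
#' population-based triage programme: roughly 1 cancer case per 400
#' screening episodes, a questionnaire rule positive in about 10% of
#' participants, a per-specimen FIT with moderate sensitivity and high
#' specificity, positively correlated results across the two stool
#' specimens (a bleeding lesion tends to shed in both), enriched
#' questionnaire items among cases, and a diagnosis-lag structure in
#' which screen-positive adherent cases are confirmed quickly
#' (screen-detected), screen-positive non-adherent cases surface later
#' through registry linkage (missed), and screen-negative cases present
#' clinically within the year (interval).
#'
#' @param n_subjects Number of screening episodes.
#' @param prevalence Probability an episode belongs to a cancer case.
#'   Default 0.0025.
#' @param ra_item_rates Nine marginal item probabilities (order of
#'   [ra_items()]); defaults give ~11% rule positivity in non-cases.
#' @param fit_sens_per_specimen,fit_spec_per_specimen Per-specimen FIT
#'   sensitivity and specificity. Defaults 0.57 and 0.91.
#' @param specimen_correlation Probability the two specimens share a
#'   single latent draw rather than being independent. Default 0.47,
#'   which makes the 2-specimen union sensitivity about 0.70.
#' @param ra_case_enrichment Odds multiplier applied to every item rate
#'   among cases. Default 1.8 (questionnaire sensitivity ~0.22).
#' @param adherence_to_colonoscopy Probability a screen-positive case
#'   completes colonoscopy promptly. Default 0.6.
#' @param lag_weights_adherent,lag_weights_nonadherent,lag_weights_negative
#'   Mixture weights over the diagnosis-lag bands (<=90 days, 91-365
#'   days, >365 days) for screen-positive adherent cases, screen-positive
#'   non-adherent cases, and screen-negative cases. Each must sum to 1.
#' @param seed Integer seed; every draw is reproducible given it.
#' @return A validated `cohort_params` object.
#' @export
cohort_params <- function(n_subjects = 1e5,
                          prevalence = 0.0025,
                          ra_item_rates = c(0.010, 0.015, 0.020,
                                            rep(0.075, 6)),
                          fit_sens_per_specimen = 0.57,
                          fit_spec_per_specimen = 0.91,
                          specimen_correlation = 0.47,
                          ra_case_enrichment = 1.8,
                          adherence_to_colonoscopy = 0.6,
                          lag_weights_adherent = c(1, 0, 0),
                          lag_weights_nonadherent = c(0, 1, 0),
                          lag_weights_negative = c(0.25, 0.75, 0),
                          seed = 1) {
  probs <- c(prevalence, ra_item_rates, fit_sens_per_specimen,
             fit_spec_per_specimen, specimen_correlation,
             adherence_to_colonoscopy)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (length(ra_item_rates) != 9) abort("ra_item_rates must have length 9")
  for (w in list(lag_weights_adherent, lag_weights_nonadherent,
                 lag_weights_negative)) {
    if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      abort("lag weights must be 3 nonnegative numbers summing to 1")
    }
  }
  if (ra_case_enrichment <= 0) abort("ra_case_enrichment must be positive")
  if (n_subjects < 1) abort("n_subjects must be at least 1")
  structure(list(n_subjects = n_subjects, prevalence = prevalence,
                 ra_item_rates = ra_item_rates,
                 fit_sens_per_specimen = fit_sens_per_specimen,
                 fit_spec_per_specimen = fit_spec_per_specimen,
                 specimen_correlation = specimen_correlation,
                 ra_case_enrichment = ra_case_enrichment,
                 adherence_to_colonoscopy = adherence_to_colonoscopy,
                 lag_weights_adherent = lag_weights_adherent,
                 lag_weights_nonadherent = lag_weights_nonadherent,
                 lag_weights_negative = lag_weights_negative,
                 seed = seed),
            class = "cohort_params")
}

# one latent-sharing draw of the two specimen results: with probability
# `corr` both specimens copy a single Bernoulli(p); otherwise independent
draw_specimens <- function(n, p, corr) {
  shared <- runif(n) < corr
  common <- runif(n) < p
  s1 <- ifelse(shared, common, runif(n) < p)
  s2 <- ifelse(shared, common, runif(n) < p)
  cbind(s1, s2)
}

#' Simulate a triage-screening cohort
#'
#' Draws one screening episode per subject under [cohort_params()]:
#' case status, the nine questionnaire items (item odds multiplied by
#' `ra_case_enrichment` among cases, so the decision rule is exercised
#' end to end rather than positivity being drawn directly), two
#' correlated FIT specimens, and a days-to-diagnosis value for cases
#' whose band depends on the programme's own parallel RA + 2-specimen
#' FIT result and colonoscopy adherence.
#'
#' @param params A [cohort_params()] object.
#' @return A tibble of episodes: `subject_id`, `wave_index`, the nine
#'   item columns, `ra_positive`, `fit1`, `fit2`, `days_to_diagnosis`
#'   (`NA` for subjects never diagnosed), and `is_case`.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed_(params$seed, {
    n <- as.integer(params$n_subjects)
    case <- runif(n) < params$prevalence

    rates <- matrix(params$ra_item_rates, n, 9, byrow = TRUE)
    odds <- rates / (1 - rates) *
      ifelse(case, params$ra_case_enrichment, 1)
    p_item <- odds / (1 + odds)
    items <- matrix(runif(n * 9), n, 9) < p_item
    colnames(items) <- ra_items()

    p_fit <- ifelse(case, params$fit_sens_per_specimen,
                    1 - params$fit_spec_per_specimen)
    fits <- draw_specimens(n, p_fit, params$specimen_correlation)

    episodes <- as_tibble(as.data.frame(items))
    episodes <- dplyr::bind_cols(
      tibble(subject_id = sprintf("S%07d", seq_len(n)), wave_index = 1L),
      episodes)
    episodes$fit1 <- unname(fits[, 1])
    episodes$fit2 <- unname(fits[, 2])
    episodes <- assess_risk(episodes)

    positive <- combine_tests("parallel_ra_fit2", episodes$ra_positive,
                              episodes$fit1, episodes$fit2)
    days <- rep(NA_integer_, n)
    idx <- which(case)
    if (length(idx) > 0) {
      adherent <- runif(length(idx)) < params$adherence_to_colonoscopy
      wmat <- rbind(params$lag_weights_negative,
                    params$lag_weights_nonadherent,
                    params$lag_weights_adherent)
      grp <- ifelse(!positive[idx], 1L, ifelse(adherent, 3L, 2L))
      u <- runif(length(idx))
      cum1 <- wmat[grp, 1]; cum2 <- cum1 + wmat[grp, 2]
      band <- ifelse(u < cum1, 1L, ifelse(u < cum2, 2L, 3L))
      lo <- c(1L, 91L, 366L)[band]
      hi <- c(90L, 365L, 730L)[band]
      days[idx] <- lo + as.integer(floor(runif(length(idx)) * (hi - lo + 1L)))
    }
    episodes$days_to_diagnosis <- days
    episodes$is_case <- case
    episodes
  })
}

#' Parameters for a synthetic collection of accuracy studies
#'
#' Study-level data follow the bivariate logit-normal model the pooling
#' stage assumes: each study's (logit sensitivity, logit specificity) is
#' drawn from a bivariate normal, study size is log-uniform, prevalence
#' uniform, and the four cells binomial.
#'
#' @param n_studies Number of studies.
#' @param mu_sens,mu_spec Means on the logit scale. Defaults
#'   `qlogis(0.76)`, `qlogis(0.92)`.
#' @param tau_sens,tau_spec Between-study standard deviations (logit
#'   scale), nonnegative. Defaults 0.4 and 0.5.
#' @param rho Between-study correlation in `[-1, 1]`. Default -0.3.
#' @param size_range Bounds of the log-uniform study-size distribution
#'   (each study >= 10). Default `c(1000, 50000)`.
#' @param prevalence_range Bounds of the uniform study prevalence.
#'   Default `c(0.002, 0.02)`.
#' @param covariate Optional planted covariate: a list with `name`,
#'   `levels` (character), and per-level logit shifts `sens_shift` and
#'   `spec_shift`; levels are assigned to studies in rotation.
#' @param seed Integer seed.
#' @return A validated `meta_params` object.
#' @export
meta_params <- function(n_studies = 50,
                        mu_sens = qlogis(0.76), mu_spec = qlogis(0.92),
                        tau_sens = 0.4, tau_spec = 0.5, rho = -0.3,
                        size_range = c(1000, 50000),
                        prevalence_range = c(0.002, 0.02),
                        covariate = NULL, seed = 1) {
  if (n_studies < 1) abort("n_studies must be at least 1")
  if (tau_sens < 0 || tau_spec < 0) abort("tau values must be nonnegative")
  if (abs(rho) > 1) abort("rho must lie in [-1, 1]")
  if (any(size_range < 10) || size_range[1] > size_range[2]) {
    abort("size_range must be increasing with minimum at least 10")
  }
  if (any(prevalence_range <= 0) || any(prevalence_range >= 1) ||
      prevalence_range[1] > prevalence_range[2]) {
    abort("prevalence_range must be increasing and inside (0, 1)")
  }
  if (!is.null(covariate)) {
    need <- c("name", "levels", "sens_shift", "spec_shift")
    if (!all(need %in% names(covariate)) ||
        length(covariate$levels) != length(covariate$sens_shift) ||
        length(covariate$levels) != length(covariate$spec_shift)) {
      abort("covariate needs name, levels, sens_shift, spec_shift of equal length")
    }
  }
  structure(list(n_studies = n_studies, mu_sens = mu_sens,
                 mu_spec = mu_spec, tau_sens = tau_sens,
                 tau_spec = tau_spec, rho = rho, size_range = size_range,
                 prevalence_range = prevalence_range,
                 covariate = covariate, seed = seed),
            class = "meta_params")
}

#' Simulate a collection of diagnostic-accuracy studies
#'
#' @param params A [meta_params()] object.
#' @return A tibble with `study_id`, `tp`, `fp`, `fn`, `tn`, `n`,
#'   `prevalence`, the latent `true_sens` / `true_spec`, and the planted
#'   covariate column if requested.
#' @export
simulate_study_set <- function(params = meta_params()) {
  stopifnot(inherits(params, "meta_params"))
  with_seed_(params$seed, {
    k <- as.integer(params$n_studies)
    Sigma <- matrix(c(params$tau_sens^2,
                      params$rho * params$tau_sens * params$tau_spec,
                      params$rho * params$tau_sens * params$tau_spec,
                      params$tau_spec^2), 2)
    re <- if (params$tau_sens + params$tau_spec > 0) {
      MASS::mvrnorm(k, c(0, 0), Sigma)
    } else {
      matrix(0, k, 2)
    }
    if (k == 1) re <- matrix(re, 1)
    eta_s <- params$mu_sens + re[, 1]
    eta_e <- params$mu_spec + re[, 2]
    cov_col <- NULL
    if (!is.null(params$covariate)) {
      lev <- params$covariate$levels
      li <- rep_len(seq_along(lev), k)
      eta_s <- eta_s + params$covariate$sens_shift[li]
      eta_e <- eta_e + params$covariate$spec_shift[li]
      cov_col <- lev[li]
    }
    size <- round(exp(runif(k, log(params$size_range[1]),
                            log(params$size_range[2]))))
    prev <- runif(k, params$prevalence_range[1], params$prevalence_range[2])
    n_case <- rbinom(k, size, prev)
    tp <- rbinom(k, n_case, plogis(eta_s))
    tn <- rbinom(k, size - n_case, plogis(eta_e))
    out <- tibble(study_id = sprintf("study_%03d", seq_len(k)),
                  tp = tp, fp = size - n_case - tn,
                  fn = n_case - tp, tn = tn,
                  n = size, prevalence = prev,
                  true_sens = plogis(eta_s), true_spec = plogis(eta_e))
    if (!is.null(cov_col)) out[[params$covariate$name]] <- cov_col
    out
  })
}
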