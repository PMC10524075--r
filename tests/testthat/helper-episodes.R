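# shared fixture builders; everything is generated in code

# a blank profile table with all nine items FALSE
blank_profiles <- function(n = 1) {
  tibble::as_tibble(setNames(as.data.frame(matrix(FALSE, n, 9)), ra_items()))
}

# all 512 item-response combinations
all_profiles <- function() {
  g <- do.call(expand.grid, rep(list(c(FALSE, TRUE)), 9))
  names(g) <- ra_items()
  tibble::as_tibble(g)
}

# a random episode table with ra_positive given directly
random_episodes <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      subject_id = sprintf("R%05d", seq_len(n)),
      wave_index = 1L,
      ra_positive = runif(n) < 0.3,
      fit1 = runif(n) < 0.2,
      fit2 = runif(n) < 0.2,
      days_to_diagnosis = ifelse(runif(n) < 0.05,
                                 sample(0:730, n, replace = TRUE),
                                 NA_integer_)
    )
  })
}

# the six-episode toy cohort: one screen-detected, one missed, one
# interval case, plus two false positives and one true negative under
# the parallel RA + 2-specimen FIT rule
toy_cohort <- function() {
  tibble::tibble(
    subject_id = paste0("T", 1:6),
    wave_index = 1L,
    ra_positive = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    fit1 = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    fit2 = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    days_to_diagnosis = c(60L, 200L, 300L, NA, NA, NA)
  )
}

# independent Wilson score interval, written from the closed form
wilson_oracle <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(centre - half, centre + half) / (1 + z^2 / n)
}
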