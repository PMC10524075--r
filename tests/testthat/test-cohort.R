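test_that("risk rule matches brute-force evaluation on all 512 profiles", {
  profiles <- all_profiles()
  got <- assess_risk(profiles)$ra_positive
  # independent re-evaluation: walk item names one by one
  want <- vapply(seq_len(nrow(profiles)), function(i) {
    majors <- sum(vapply(ra_major_items(), function(cl) profiles[[cl]][i], NA))
    minors <- sum(vapply(ra_minor_items(), function(cl) profiles[[cl]][i], NA))
    majors >= 1 || minors >= 2
  }, NA)
  expect_identical(got, want)
  # the spec'd spot checks
  p <- blank_profiles(4)
  p$major_polyp_history[2] <- TRUE
  p$minor_constipation[3] <- TRUE; p$minor_diarrhea[3] <- TRUE
  p$minor_constipation[4] <- TRUE
  expect_identical(assess_risk(p)$ra_positive, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("assess_risk validates its input columns", {
  p <- blank_profiles(2)
  expect_error(assess_risk(p[-1]), "missing risk-assessment item")
  p$minor_diarrhea <- c(2, 3)
  expect_error(assess_risk(p), "non-binary")
})

test_that("strategy combination matches full truth-table enumeration", {
  tt <- expand.grid(ra = c(FALSE, TRUE), fit1 = c(FALSE, TRUE),
                    fit2 = c(FALSE, TRUE))
  oracle <- list(
    ra_only          = function(r, f1, f2) r,
    fit1_only        = function(r, f1, f2) f1,
    fit2_only        = function(r, f1, f2) f1 | f2,
    parallel_ra_fit1 = function(r, f1, f2) r | f1,
    serial_ra_fit1   = function(r, f1, f2) r & f1,
    parallel_ra_fit2 = function(r, f1, f2) r | f1 | f2,
    serial_ra_fit2   = function(r, f1, f2) r & (f1 | f2)
  )
  for (s in strategies()) {
    expect_identical(combine_tests(s, tt$ra, tt$fit1, tt$fit2),
                     oracle[[s]](tt$ra, tt$fit1, tt$fit2), info = s)
  }
  # all-negative inputs are negative under every strategy
  for (s in strategies()) {
    expect_false(combine_tests(s, FALSE, FALSE, FALSE))
  }
  # the stricter serial reading requires both specimens
  expect_false(combine_tests("serial_ra_fit2", TRUE, TRUE, FALSE,
                             serial_both_specimens = TRUE))
  expect_true(combine_tests("serial_ra_fit2", TRUE, TRUE, FALSE))
  expect_error(combine_tests("bogus", TRUE, TRUE, TRUE))
})

test_that("outcome classification partitions every (result, lag) pair", {
  w <- outcome_windows()
  expect_identical(
    as.character(classify_outcome(c(TRUE, TRUE, FALSE, FALSE),
                                  c(60, 200, 300, NA), w)),
    c("screen_detected", "missed", "interval", "non_case"))
  # exhaustive grid: one and only one class each
  grid <- expand.grid(pos = c(TRUE, FALSE),
                      days = c(NA, 0, 45, 90, 91, 200, 365, 366, 1000))
  cls <- classify_outcome(grid$pos, grid$days, w)
  expect_false(anyNA(cls))
  expect_true(all(cls %in% outcome_classes()))
  # window edges: day 90 is screen-detected, day 365 still a case
  expect_identical(as.character(classify_outcome(TRUE, 90, w)), "screen_detected")
  expect_identical(as.character(classify_outcome(TRUE, 365, w)), "missed")
  expect_identical(as.character(classify_outcome(TRUE, 366, w)), "non_case")
  # a negative episode diagnosed early is interval (no lower bound)
  expect_identical(as.character(classify_outcome(FALSE, 10, w)), "interval")
  expect_error(classify_outcome(TRUE, -1, w), "nonnegative")
  expect_error(outcome_windows(90, 90))
  expect_error(outcome_windows(0, 365))
})

test_that("tabulation counts the toy cohort as constructed", {
  ct <- tabulate_strategies(toy_cohort(), "parallel_ra_fit2")
  expect_identical(ct$tp, 2L)
  expect_identical(ct$fn, 1L)
  expect_identical(ct$fp + ct$tn, 3L)
  expect_error(tabulate_strategies(toy_cohort()[0, ]), "nonempty")
})

test_that("strategy set-inclusion relations hold on random cohorts", {
  for (seed in 1:3) {
    ep <- random_episodes(500, seed)
    pos <- lapply(setNames(nm = strategies()), function(s)
      combine_tests(s, ep$ra_positive, ep$fit1, ep$fit2))
    # serial is contained in both its components
    expect_true(all(!pos$serial_ra_fit1 | (pos$ra_only & pos$fit1_only)))
    expect_true(all(!pos$serial_ra_fit2 | (pos$ra_only & pos$fit2_only)))
    # the widest parallel strategy contains every other one
    for (s in setdiff(strategies(), "parallel_ra_fit2")) {
      expect_true(all(!pos[[s]] | pos$parallel_ra_fit2), info = s)
    }
    # totals are invariant across strategies
    ct <- tabulate_strategies(ep)
    expect_identical(unique(ct$tp + ct$fp + ct$fn + ct$tn), nrow(ep))
  }
})

test_that("tabulation accepts item columns and derives the rule itself", {
  ep <- blank_profiles(4)
  ep$major_cancer_history[1] <- TRUE
  ep <- dplyr::mutate(ep, subject_id = paste0("I", 1:4), wave_index = 1L,
                      fit1 = FALSE, fit2 = FALSE,
                      days_to_diagnosis = c(30L, NA, NA, NA))
  ct <- tabulate_strategies(ep, "ra_only")
  expect_identical(ct$tp, 1L)
  expect_identical(ct$tn, 3L)
})
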