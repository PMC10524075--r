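test_that("accuracy indices reproduce the programme's first-round table", {
  # parallel RA + 2-specimen FIT, first-time participants
  acc <- accuracy_summary(confusion_table(tp = 3780, fp = 419815,
                                          fn = 1047, tn = 1476718))
  expect_equal(acc$sensitivity, 3780 / 4827, tolerance = 1e-12)
  expect_equal(round(acc$sensitivity, 2), 0.78)
  expect_equal(round(acc$specificity, 2), 0.78)
  expect_equal(round(acc$ppv, 4), 0.0089)
  expect_equal(round(acc$detection_rate, 2), 1.99)
  expect_equal(round(acc$lr_pos, 2), 3.54)
  # RA only
  acc2 <- accuracy_summary(confusion_table(tp = 1044, fp = 196800,
                                           fn = 3783, tn = 1699733))
  expect_equal(round(acc2$sensitivity, 2), 0.22)
  expect_equal(round(acc2$lr_pos, 2), 2.08)
})

test_that("degenerate tables behave: perfect and uninformative tests", {
  perfect <- accuracy_summary(confusion_table(tp = 25, fp = 0, fn = 0, tn = 75))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$auc, 1)
  expect_true(perfect$lr_infinite)
  flat <- accuracy_summary(confusion_table(tp = 50, fp = 50, fn = 50, tn = 50))
  expect_equal(flat$lr_pos, 1)
  expect_equal(flat$auc, 0.5)
  expect_error(accuracy_summary(confusion_table(tp = 0, fp = 5, fn = 0, tn = 5)),
               "case margin")
})

test_that("Wilson intervals agree with an independent closed form", {
  cases <- list(c(3780, 4827), c(50, 100), c(1, 30), c(0, 10))
  for (kn in cases) {
    got <- proportion_ci(kn[1], kn[2], 0.95, "wilson")
    want <- wilson_oracle(kn[1], kn[2], 0.95)
    expect_equal(c(got$lower, got$upper), pmax(0, pmin(1, want)),
                 tolerance = 1e-9)
  }
  # spec spot value: parallel-test sensitivity interval
  ci <- proportion_ci(3780, 4827)
  expect_equal(round(c(ci$lower, ci$upper), 2), c(0.77, 0.79))
  # boundary and symmetry
  expect_equal(proportion_ci(0, 20)$lower, 0)
  mid <- proportion_ci(50, 100)
  expect_equal(mid$upper - 0.5, 0.5 - mid$lower, tolerance = 1e-12)
  # Clopper-Pearson is the exact binomial interval
  cp <- proportion_ci(7, 20, method = "clopper_pearson")
  bt <- stats::binom.test(7, 20)$conf.int
  expect_equal(c(cp$lower, cp$upper), as.numeric(bt))
  expect_error(proportion_ci(1, 0))
})

test_that("LR intervals follow the stated closed form", {
  ct <- confusion_table(tp = 40, fp = 10, fn = 20, tn = 120)
  got <- lr_ci(ct)
  sens <- 40 / 60; spec <- 120 / 130
  se_p <- sqrt((1 - sens) / 40 + spec / 10)
  se_n <- sqrt(sens / 20 + (1 - spec) / 120)
  z <- qnorm(0.975)
  expect_equal(got$lr_pos, sens / (1 - spec))
  expect_equal(got$lr_pos_lower, exp(log(sens / (1 - spec)) - z * se_p))
  expect_equal(got$lr_pos_upper, exp(log(sens / (1 - spec)) + z * se_p))
  expect_equal(got$lr_neg_lower, exp(log((1 - sens) / spec) - z * se_n))
  expect_false(got$corrected)
  # uninformative test: interval contains 1
  unif <- lr_ci(confusion_table(tp = 30, fp = 30, fn = 30, tn = 30))
  expect_true(unif$lr_pos_lower < 1 && 1 < unif$lr_pos_upper)
  # zero cell: corrected and flagged
  zc <- lr_ci(confusion_table(tp = 10, fp = 0, fn = 5, tn = 50))
  expect_true(zc$corrected)
  expect_true(is.finite(zc$lr_pos))
})

test_that("estimates are scale invariant and identities hold", {
  base <- confusion_table(tp = 30, fp = 70, fn = 12, tn = 400)
  for (m in c(1, 10, 100)) {
    acc <- accuracy_summary(dplyr::mutate(base, dplyr::across(
      dplyr::everything(), ~ .x * m)))
    ref <- accuracy_summary(base)
    expect_equal(acc$sensitivity, ref$sensitivity)
    expect_equal(acc$lr_pos, ref$lr_pos)
    expect_equal(acc$auc, ref$auc)
    # LR identities at full precision
    expect_equal(acc$lr_pos * (1 - acc$specificity), acc$sensitivity,
                 tolerance = 1e-12)
    expect_equal(acc$lr_neg * acc$specificity, 1 - acc$sensitivity,
                 tolerance = 1e-12)
    # detection rate identity
    expect_equal(acc$detection_rate,
                 1000 * acc$ppv * acc$positives / acc$total,
                 tolerance = 1e-9)
  }
  # CI widths shrink monotonically as counts grow
  w <- sapply(c(1, 10, 100), function(m) {
    a <- accuracy_summary(dplyr::mutate(base, dplyr::across(
      dplyr::everything(), ~ .x * m)))
    a$sensitivity_upper - a$sensitivity_lower
  })
  expect_true(all(diff(w) < 0))
})

test_that("formatted output rounds half-up like the published tables", {
  acc <- accuracy_summary(shanghai_confusion("first_time", "parallel_ra_fit2"))
  line <- format_accuracy(acc)
  expect_match(line$sensitivity, "^0\\.78 \\(0\\.77, 0\\.79\\)$")
  expect_match(line$lr_pos, "^3\\.54")
  expect_match(line$ppv_pct, "^0\\.89")
})
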