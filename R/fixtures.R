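## Packaged aggregate counts from the Shanghai screening programme's
## published tables, and the arithmetic that turns them into per-strategy
## confusion tables.

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "fitriage")
  if (path == "") path <- file.path("inst", "extdata", name)  # pre-install
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Published aggregate counts of the Shanghai screening programme
#'
#' `shanghai_table1()` returns the case counts by initial-test result
#' pattern: one `all` row per cohort (`first_time`: 1,901,360 first-round
#' tests; `multi_time`: 1,143,748 subsequent tests) plus the breakdown by
#' RA-only / FIT-only / both-positive / both-negative patterns, each with
#' screen-detected, missed and interval case counts. Note one internal
#' inconsistency of the source: the multi-time breakdown rows sum to 2214
#' positive cases while the `all` row implies 1342 + 902 = 2244; both are
#' shipped unaltered. `shanghai_table2()` returns the published accuracy
#' indices per strategy and cohort; `shanghai_table3()` the pooled
#' meta-analytic estimates with their stratification scheme (the
#' `cutoff_band` strata split qualitative/quantitative FIT thresholds at
#' 20 ug Hb/g feces).
#'
#' @param cohort Optional filter, `"first_time"` or `"multi_time"`.
#' @return A tibble of counts (or published estimates).
#' @export
shanghai_table1 <- function(cohort = NULL) {
  t1 <- read_fixture("shanghai_table1.csv")
  if (!is.null(cohort)) {
    cohort <- match.arg(cohort, c("first_time", "multi_time"))
    t1 <- dplyr::filter(t1, .data$cohort == !!cohort)
  }
  t1
}

#' @rdname shanghai_table1
#' @export
shanghai_table2 <- function(cohort = NULL) {
  t2 <- read_fixture("shanghai_table2.csv")
  if (!is.null(cohort)) {
    cohort <- match.arg(cohort, c("first_time", "multi_time"))
    t2 <- dplyr::filter(t2, .data$cohort == !!cohort)
  }
  t2
}

#' @rdname shanghai_table1
#' @export
shanghai_table3 <- function() read_fixture("shanghai_table3.csv")

#' Confusion tables reconstructed from the published aggregate counts
#'
#' Four of the seven strategies are derivable from the result-pattern
#' margins: RA only (positives = RA-only + both-positive patterns),
#' 2-specimen FIT only, their parallel combination, and their serial
#' combination. True positives are the screen-detected plus missed cases
#' among the strategy's positives, false negatives the remaining cases,
#' and the rest splits into false positives and true negatives.
#'
#' The parallel strategy uses the aggregate `all` row. The other three
#' need the pattern breakdown; in the multi-time cohort that breakdown is
#' internally inconsistent with the aggregate row (2214 vs 2244 positive
#' cases), so breakdown-derived tables there use the breakdown's own
#' case total.
#'
#' @param cohort `"first_time"` (default) or `"multi_time"`.
#' @param strategy Strategies to reconstruct; default the four derivable
#'   ones.
#' @return A confusion-table tibble (`strategy`, `tp`, `fp`, `fn`, `tn`).
#' @examples
#' shanghai_confusion() |> accuracy_summary()
#' @export
shanghai_confusion <- function(cohort = c("first_time", "multi_time"),
                               strategy = c("parallel_ra_fit2", "ra_only",
                                            "fit2_only", "serial_ra_fit2")) {
  cohort <- match.arg(cohort)
  strategy <- vapply(strategy, match.arg, "",
                     choices = c("parallel_ra_fit2", "ra_only",
                                 "fit2_only", "serial_ra_fit2"))
  t1 <- shanghai_table1(cohort)
  g <- function(row, col) {
    v <- t1[[col]][t1$row == row]
    if (length(v) != 1 || is.na(v)) abort("fixture row/column missing")
    v
  }
  n_total <- g("all", "tests")
  p_all <- g("all", "positives")
  interval <- g("all", "interval")
  cases_row <- function(row) g(row, "screen_detected") + g(row, "missed")
  c_ra <- cases_row("ra_positive_only")
  c_fit <- cases_row("fit_positive_only")
  c_both <- cases_row("both_positive")
  agg_tp <- g("all", "screen_detected") + g("all", "missed")

  one <- function(s) {
    if (s == "parallel_ra_fit2") {
      tp <- agg_tp; pos <- p_all; cases <- agg_tp + interval
    } else if (s == "ra_only") {
      tp <- c_ra + c_both
      pos <- g("ra_positive_only", "positives") + g("both_positive", "positives")
      cases <- c_ra + c_fit + c_both + interval
    } else if (s == "fit2_only") {
      tp <- c_fit + c_both
      pos <- g("fit_positive_only", "positives") + g("both_positive", "positives")
      cases <- c_ra + c_fit + c_both + interval
    } else {
      tp <- c_both
      pos <- g("both_positive", "positives")
      cases <- c_ra + c_fit + c_both + interval
    }
    fn <- cases - tp
    confusion_table(tp = tp, fp = pos - tp, fn = fn,
                    tn = n_total - pos - fn, strategy = s)
  }
  purrr::map_dfr(unname(strategy), one)
}
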