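#' Risk-assessment questionnaire items
#'
#' The triage questionnaire asks nine yes/no questions. Three are "major"
#' items, any one of which flags a participant as high risk: a personal
#' history of any cancer, a history of colorectal polyps, and colorectal
#' cancer in a first-degree relative. Six are "minor" items, any two of
#' which together flag high risk: chronic constipation, chronic diarrhea,
#' mucus or bloody stool, a serious adverse life event, chronic
#' appendicitis or appendectomy, and chronic cholecystitis or
#' cholecystectomy.
#'
#' @return A character vector of canonical column names (3 major then 6
#'   minor items).
#' @export
ra_items <- function() c(ra_major_items(), ra_minor_items())

#' @rdname ra_items
#' @export
ra_major_items <- function() {
  c("major_cancer_history", "major_polyp_history", "major_family_crc")
}

#' @rdname ra_items
#' @export
ra_minor_items <- function() {
  c("minor_constipation", "minor_diarrhea", "minor_mucus_bloody_stool",
    "minor_life_event", "minor_appendix", "minor_gallbladder")
}

# coerce a 0/1, logical or "true"/"false" column to logical, or NULL if it
# contains anything else
as_binary <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (all(x %in% c(0, 1) | is.na(x))) return(x == 1)
    return(NULL)
  }
  if (is.character(x)) {
    lx <- tolower(trimws(x))
    ok <- lx %in% c("0", "1", "true", "false") | is.na(x)
    if (all(ok)) return(lx %in% c("1", "true") & !is.na(x) | ifelse(is.na(x), NA, FALSE))
    return(NULL)
  }
  NULL
}

#' Apply the high-risk decision rule to questionnaire responses
#'
#' A participant is classified high risk when any major item is positive,
#' or when at least two of the six minor items are positive.
#'
#' @param data A data frame with one row per participant containing the
#'   nine item columns named as in [ra_items()] (logical or 0/1).
#' @return The input as a tibble with an added logical column
#'   `ra_positive`.
#' @examples
#' profiles <- tibble::as_tibble(setNames(
#'   as.data.frame(matrix(FALSE, 2, 9)), ra_items()))
#' profiles$major_polyp_history[1] <- TRUE
#' assess_risk(profiles)$ra_positive
#' @export
assess_risk <- function(data) {
  data <- as_tibble(data)
  missing_cols <- setdiff(ra_items(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing risk-assessment item column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  items <- lapply(data[ra_items()], as_binary)
  bad <- names(items)[vapply(items, is.null, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-binary values in item column(s): ",
                 paste(bad, collapse = ", ")))
  }
  major <- do.call(cbind, items[ra_major_items()])
  minor <- do.call(cbind, items[ra_minor_items()])
  data$ra_positive <- rowSums(major) > 0 | rowSums(minor) >= 2
  data
}

#' Initial-test combination strategies
#'
#' The seven initial-test strategies compared by the screening programme:
#' risk assessment (RA) alone, the first FIT specimen alone, the
#' 2-specimen FIT (positive if either specimen is positive), and the
#' parallel (either positive) and serial (both positive) combinations of
#' RA with one or two FIT specimens.
#'
#' @return Character vector of the seven strategy names.
#' @export
strategies <- function() {
  c("ra_only", "fit1_only", "fit2_only",
    "parallel_ra_fit1", "serial_ra_fit1",
    "parallel_ra_fit2", "serial_ra_fit2")
}

#' Combine risk-assessment and FIT results under a strategy
#'
#' Vectorised positivity rule for one strategy. The 2-specimen FIT is
#' positive when either specimen is positive; under the default reading
#' the serial RA + 2-specimen FIT strategy therefore requires RA positive
#' and at least one positive specimen. Set `serial_both_specimens = TRUE`
#' to require both specimens instead (a stricter reading of "both FIT
#' positive").
#'
#' @param strategy One of [strategies()].
#' @param ra,fit1,fit2 Logical vectors (recycled to a common length).
#' @param serial_both_specimens Logical; see Description. Default `FALSE`.
#' @return Logical vector of combined test positivity.
#' @examples
#' combine_tests("parallel_ra_fit2", ra = TRUE, fit1 = FALSE, fit2 = FALSE)
#' combine_tests("serial_ra_fit2", ra = TRUE, fit1 = FALSE, fit2 = FALSE)
#' @export
combine_tests <- function(strategy, ra, fit1, fit2,
                          serial_both_specimens = FALSE) {
  strategy <- match.arg(strategy, strategies())
  n <- max(length(ra), length(fit1), length(fit2))
  ra <- rep_len(ra, n); fit1 <- rep_len(fit1, n); fit2 <- rep_len(fit2, n)
  fit_any <- fit1 | fit2
  fit_serial <- if (serial_both_specimens) fit1 & fit2 else fit_any
  switch(strategy,
    ra_only          = ra,
    fit1_only        = fit1,
    fit2_only        = fit_any,
    parallel_ra_fit1 = ra | fit1,
    serial_ra_fit1   = ra & fit1,
    parallel_ra_fit2 = ra | fit_any,
    serial_ra_fit2   = ra & fit_serial
  )
}

#' Outcome-classification windows
#'
#' A cancer diagnosed within `screen_detected_days` of a positive screen is
#' screen detected; a diagnosis in a screen-positive subject after that but
#' within `case_horizon_days` is a missed cancer; a diagnosis in a
#' screen-negative subject within `case_horizon_days` is an interval
#' cancer. Diagnoses beyond the horizon (or no diagnosis) are non-cases.
#'
#' @param screen_detected_days Positive integer, default 90.
#' @param case_horizon_days Positive integer, default 365; must exceed
#'   `screen_detected_days`.
#' @return An `outcome_windows` object.
#' @export
outcome_windows <- function(screen_detected_days = 90,
                            case_horizon_days = 365) {
  if (!is.numeric(screen_detected_days) || length(screen_detected_days) != 1 ||
      screen_detected_days <= 0) {
    abort("screen_detected_days must be a positive number")
  }
  if (!is.numeric(case_horizon_days) || length(case_horizon_days) != 1 ||
      case_horizon_days <= screen_detected_days) {
    abort("case_horizon_days must exceed screen_detected_days")
  }
  structure(list(screen_detected_days = screen_detected_days,
                 case_horizon_days = case_horizon_days),
            class = "outcome_windows")
}

#' Outcome classes
#' @return Character vector of the four outcome classes, in level order.
#' @export
outcome_classes <- function() {
  c("screen_detected", "missed", "interval", "non_case")
}

#' Classify a screening episode by initial-test result and diagnosis lag
#'
#' @param positive Logical vector: combined initial-test result.
#' @param days_to_diagnosis Integer vector of days from screening to
#'   cancer diagnosis; `NA` means no diagnosis within follow-up.
#' @param windows An [outcome_windows()] object.
#' @return A factor with levels [outcome_classes()]. A screen-negative
#'   episode diagnosed at any time up to the case horizon (including
#'   within the screen-detected window) is an interval case: the interval
#'   definition has no lower bound.
#' @examples
#' classify_outcome(c(TRUE, TRUE, FALSE, FALSE), c(60, 200, 300, NA))
#' @export
classify_outcome <- function(positive, days_to_diagnosis,
                             windows = outcome_windows()) {
  stopifnot(inherits(windows, "outcome_windows"))
  if (any(days_to_diagnosis < 0, na.rm = TRUE)) {
    abort("days_to_diagnosis must be nonnegative")
  }
  n <- max(length(positive), length(days_to_diagnosis))
  positive <- rep_len(positive, n)
  days <- rep_len(days_to_diagnosis, n)
  cls <- rep("non_case", n)
  in_horizon <- !is.na(days) & days <= windows$case_horizon_days
  cls[in_horizon & positive & days <= windows$screen_detected_days] <- "screen_detected"
  cls[in_horizon & positive & days > windows$screen_detected_days] <- "missed"
  cls[in_horizon & !positive] <- "interval"
  factor(cls, levels = outcome_classes())
}

# ensure an episodes table carries ra_positive / fit1 / fit2 / days columns
prepare_episodes <- function(episodes) {
  episodes <- as_tibble(episodes)
  if (nrow(episodes) == 0) abort("episodes must be a nonempty data frame")
  if (!"ra_positive" %in% names(episodes)) {
    if (all(ra_items() %in% names(episodes))) {
      episodes <- assess_risk(episodes)
    } else {
      abort("episodes need either an ra_positive column or the nine item columns")
    }
  }
  for (col in c("ra_positive", "fit1", "fit2")) {
    if (!col %in% names(episodes)) abort(paste0("missing column: ", col))
    v <- as_binary(episodes[[col]])
    if (is.null(v)) abort(paste0("column ", col, " is not 0/1 or logical"))
    if (anyNA(v)) abort(paste0("column ", col, " contains missing values"))
    episodes[[col]] <- v
  }
  if (!"days_to_diagnosis" %in% names(episodes)) {
    abort("missing column: days_to_diagnosis")
  }
  episodes
}

#' Tabulate a screening cohort into 2x2 confusion tables
#'
#' For each requested strategy, episodes are scored positive or negative
#' by [combine_tests()], classified by [classify_outcome()], and counted:
#' true positives are screen-detected or missed cases (positive cases),
#' false negatives are interval cases, and non-cases split into false
#' positives and true negatives. The total always equals the number of
#' episodes, whatever the strategy.
#'
#' @param episodes Data frame with one row per screening episode: either
#'   an `ra_positive` column or the nine questionnaire item columns, plus
#'   `fit1`, `fit2` (logical or 0/1) and `days_to_diagnosis` (`NA` for no
#'   diagnosis).
#' @param strategy Character vector of strategies (default: all seven).
#' @param windows An [outcome_windows()] object.
#' @inheritParams combine_tests
#' @return A tibble with columns `strategy`, `tp`, `fp`, `fn`, `tn`.
#' @export
tabulate_strategies <- function(episodes, strategy = strategies(),
                                windows = outcome_windows(),
                                serial_both_specimens = FALSE) {
  episodes <- prepare_episodes(episodes)
  strategy <- vapply(strategy, match.arg, "", choices = strategies())
  purrr::map_dfr(unname(strategy), function(s) {
    pos <- combine_tests(s, episodes$ra_positive, episodes$fit1,
                         episodes$fit2, serial_both_specimens)
    cls <- classify_outcome(pos, episodes$days_to_diagnosis, windows)
    case <- cls != "non_case"
    tibble(strategy = s,
           tp = sum(pos & case), fp = sum(pos & !case),
           fn = sum(!pos & case), tn = sum(!pos & !case))
  })
}

#' Construct a confusion-table tibble
#'
#' @param tp,fp,fn,tn Nonnegative counts (vectors are allowed and aligned).
#' @param strategy Optional label column.
#' @return A tibble with columns (`strategy`,) `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_table <- function(tp, fp, fn, tn, strategy = NULL) {
  counts <- tibble(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(unlist(counts) < 0) || anyNA(unlist(counts))) {
    abort("confusion-table counts must be nonnegative and complete")
  }
  if (!is.null(strategy)) counts <- tibble(strategy = strategy, counts)
  counts
}
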