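## Delimited-text readers/writers. Comma or tab is chosen by file
## extension (.csv -> comma, anything else -> tab).

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

# read all columns as character and refuse ragged rows outright
read_delim_strict <- function(path) {
  x <- suppressWarnings(
    readr::read_delim(path, delim = delim_for(path),
                      col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE))
  pr <- readr::problems(x)
  if (nrow(pr) > 0) {
    abort(paste0("malformed row(s) at line(s) ",
                 paste(head(sort(unique(pr$row)), 5), collapse = ", ")))
  }
  x
}

cohort_columns <- function() {
  c("subject_id", "wave_index", ra_items(), "fit1", "fit2",
    "days_to_diagnosis")
}

#' Read a screening-cohort file
#'
#' One row per screening episode. Required columns: `subject_id`,
#' `wave_index`, the nine questionnaire items of [ra_items()], `fit1`,
#' `fit2` (each 0/1 or true/false), and `days_to_diagnosis` (blank for no
#' diagnosis within follow-up — never coded as zero). Malformed rows are
#' reported with their line numbers.
#'
#' @param path Path to a comma- (`.csv`) or tab-delimited file with a
#'   header row.
#' @return A tibble of typed episodes with logical test columns and an
#'   added `ra_positive` column.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- read_delim_strict(path)
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  line_of <- function(i) i + 1L  # header occupies line 1

  bin_cols <- c(ra_items(), "fit1", "fit2")
  for (col in bin_cols) {
    v <- as_binary(raw[[col]])
    bad <- if (is.null(v)) which(!tolower(trimws(raw[[col]])) %in%
                                   c("0", "1", "true", "false")) else which(is.na(v))
    if (length(bad) > 0) {
      abort(paste0("malformed values in column '", col, "' at line(s) ",
                   paste(line_of(head(bad, 5)), collapse = ", ")))
    }
    raw[[col]] <- v
  }
  wv <- suppressWarnings(as.integer(raw$wave_index))
  bad <- which(is.na(wv) | wv < 1)
  if (length(bad) > 0) {
    abort(paste0("malformed wave_index at line(s) ",
                 paste(line_of(head(bad, 5)), collapse = ", ")))
  }
  raw$wave_index <- wv
  dd <- trimws(raw$days_to_diagnosis)
  dd[dd == ""] <- NA
  ddn <- suppressWarnings(as.numeric(dd))
  bad <- which(!is.na(dd) & (is.na(ddn) | ddn < 0))
  if (length(bad) > 0) {
    abort(paste0("malformed days_to_diagnosis at line(s) ",
                 paste(line_of(head(bad, 5)), collapse = ", ")))
  }
  raw$days_to_diagnosis <- as.integer(ddn)
  assess_risk(raw)
}

#' Write a screening cohort to delimited text
#'
#' @param episodes Episode tibble (e.g. from [simulate_cohort()]).
#' @param path Output path; `.csv` writes comma-delimited, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(episodes, path) {
  episodes <- as_tibble(episodes)
  keep <- intersect(cohort_columns(), names(episodes))
  out <- episodes[keep]
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.logical), as.integer))
  if (delim_for(path) == ",") readr::write_csv(out, path, na = "")
  else readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a study-level 2x2 table for meta-analysis
#'
#' Required columns: `study_id`, `tp`, `fp`, `fn`, `tn`. Any further
#' columns are kept as character covariates. Zero cells load unaltered
#' (continuity correction is a fitting-time concern); negative counts and
#' duplicate study ids are rejected.
#'
#' @param path Path to a delimited file with a header.
#' @return A tibble of study records.
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- read_delim_strict(path)
  need <- setdiff(c("study_id", "tp", "fp", "fn", "tn"), names(raw))
  if (length(need) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(need, collapse = ", ")))
  }
  for (col in c("tp", "fp", "fn", "tn")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) abort(paste0("non-numeric counts in column '", col, "'"))
    if (any(v < 0)) abort(paste0("negative counts in column '", col, "'"))
    raw[[col]] <- v
  }
  if (anyDuplicated(raw$study_id)) {
    abort(paste0("duplicate study_id: ",
                 paste(unique(raw$study_id[duplicated(raw$study_id)]),
                       collapse = ", ")))
  }
  raw
}

#' @rdname read_studies
#' @param studies Study tibble to write.
#' @export
write_studies <- function(studies, path) {
  if (delim_for(path) == ",") readr::write_csv(studies, path, na = "")
  else readr::write_tsv(studies, path, na = "")
  invisible(path)
}

#' Serialise a results table
#'
#' Writes a results tibble (accuracy summary, pooled summary, ...)
#' deterministically: JSON with sorted keys at full precision, or TSV
#' with numeric columns rounded half-up. Two runs on the same input are
#' byte-identical.
#'
#' @param results A data frame of results.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @param digits Decimal places for the TSV rendering (default 4).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "tsv"),
                         digits = 4) {
  format <- match.arg(format)
  results <- as_tibble(results)
  if (format == "json") {
    results <- results[sort(names(results))]
    jsonlite::write_json(results, path, dataframe = "columns", digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    out <- dplyr::mutate(results,
                         dplyr::across(dplyr::where(is.numeric),
                                       ~ round_half_up(.x, digits)))
    readr::write_tsv(out, path, na = "")
  }
  invisible(path)
}
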