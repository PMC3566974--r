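#' Construct a patient dataset
#'
#' Bundles one study population (one row per child) with its schema and
#' provenance metadata. Variable columns must be a subset of the schema; the
#' serious-infection composite is recomputed from the component diagnoses and
#' any conflicting supplied column is a hard error, because the outcome is a
#' strict composite (sepsis including bacteremia, meningitis, pneumonia,
#' osteomyelitis, cellulitis, complicated UTI).
#'
#' @param records A data frame with columns `record_id`, `age_months`, any
#'   subset of schema variables, the component outcome columns
#'   ([outcome_components()], 0/1) and optionally `serious_infection`.
#' @param name Dataset label.
#' @param setting One of `"GP"`, `"ED"`, `"PAU"`, `"mixed"`.
#' @param country ISO country code.
#' @param schema A `cpr_schema`; defaults to [default_schema()].
#' @return An object of class `patient_dataset`.
#' @export
patient_dataset <- function(records, name, setting = c("GP", "ED", "PAU", "mixed"),
                            country = "XX", schema = default_schema()) {
  setting <- match.arg(setting)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) stop("dataset must contain at least one record", call. = FALSE)
  req <- c("record_id", "age_months")
  miss <- setdiff(c(req, outcome_components()), names(records))
  if (length(miss)) stop("records lack required columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(is.na(records$age_months)) || any(records$age_months < 0))
    stop("age_months must be non-negative and non-missing", call. = FALSE)
  known <- c(req, names(schema), outcome_components(), "serious_infection", "age_years")
  unknown <- setdiff(names(records), known)
  if (length(unknown))
    stop("unknown column(s) not in schema: ", paste(unknown, collapse = ", "), call. = FALSE)
  check_ranges(records, schema)
  comp <- as.matrix(records[outcome_components()])
  if (any(is.na(comp)) || !all(comp %in% c(0, 1)))
    stop("component outcomes must be coded 0/1 without missing values", call. = FALSE)
  composite <- as.integer(rowSums(comp) > 0)
  if ("serious_infection" %in% names(records)) {
    bad <- which(as.integer(records$serious_infection) != composite)
    if (length(bad))
      stop("serious_infection column conflicts with component diagnoses at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  records$serious_infection <- composite
  records$age_years <- NULL
  structure(list(name = name, setting = setting, country = country,
                 schema = schema, records = records),
            class = "patient_dataset")
}

#' @keywords internal
check_ranges <- function(records, schema) {
  for (v in intersect(names(schema), names(records))) {
    sp <- schema[[v]]
    x <- records[[v]]
    ok <- switch(sp$kind,
                 binary = is.na(x) | x %in% c(0, 1),
                 ordinal = is.na(x) | x %in% sp$allowed_values,
                 numeric = is.na(x) | (x >= sp$range[1] & x <= sp$range[2]))
    if (!all(ok))
      stop("value out of range for '", v, "' at row ", which(!ok)[1], call. = FALSE)
  }
  invisible(records)
}

#' Number of records in a dataset
#' @param ds A `patient_dataset`.
#' @return Integer count.
#' @export
n_records <- function(ds) nrow(ds$records)

#' Schema variables recorded as columns in a dataset
#'
#' A variable counts as recorded when it is present as a column, regardless of
#' record-level missing cells. Dataset-eligibility checks and dataset-level
#' rule reduction are based on this set.
#'
#' @param ds A `patient_dataset`.
#' @return Character vector of canonical names.
#' @export
recorded_variables <- function(ds) intersect(names(ds$schema), names(ds$records))

#' Read a patient dataset from CSV
#'
#' CSV dialect: UTF-8, comma-separated, missing cells empty or `NA`, binary
#' variables coded 0/1. Ages are stored canonically in months; a column named
#' `age_years` (or a renamed column declared as years via `age_unit`) is
#' converted on read. When both `age_months` and `age_years` are present,
#' `age_months` wins.
#'
#' @param path CSV file path.
#' @param schema A `cpr_schema`.
#' @param rename Optional named character vector mapping file column names to
#'   canonical names, e.g. `c(temp = "temperature")`.
#' @param age_unit Unit of a plain `age` column after renaming: `"months"` or
#'   `"years"`.
#' @param name,setting,country Dataset metadata.
#' @return A `patient_dataset`.
#' @export
read_dataset <- function(path, schema = default_schema(), rename = NULL,
                         age_unit = c("months", "years"),
                         name = basename(path), setting = "mixed", country = "XX") {
  age_unit <- match.arg(age_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                                         progress = FALSE, na = c("", "NA")))
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
  if (!is.null(rename)) {
    hit <- intersect(names(rename), names(df))
    names(df)[match(hit, names(df))] <- unname(rename[hit])
  }
  if (!"age_months" %in% names(df)) {
    if ("age_years" %in% names(df)) {
      df$age_months <- df$age_years * 12
    } else if ("age" %in% names(df)) {
      df$age_months <- if (age_unit == "years") df$age * 12 else df$age
    } else stop("no age column (age_months / age_years / age) found", call. = FALSE)
  }
  df$age_years <- NULL
  df$age <- NULL
  if (!"record_id" %in% names(df)) df$record_id <- sprintf("r%05d", seq_len(nrow(df)))
  df$record_id <- as.character(df$record_id)
  patient_dataset(df, name = name, setting = setting, country = country, schema = schema)
}

#' Write a patient dataset to CSV
#'
#' Emits age in both months (canonical) and years; missing cells are written
#' as empty strings. A round trip through [read_dataset()] reproduces the
#' records, missingness pattern and outcomes exactly.
#'
#' @param ds A `patient_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  df <- ds$records
  df$age_years <- df$age_months / 12
  front <- c("record_id", "age_months", "age_years")
  df <- df[c(front, setdiff(names(df), front))]
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Summarize a patient dataset
#'
#' @param ds A `patient_dataset`.
#' @param level Confidence level for the prevalence interval (Wald, matching
#'   the reporting convention for dataset prevalences).
#' @return An object of class `dataset_summary`: n, case count, prevalence
#'   with Wald CI, age mean/range in years, and per-recorded-variable
#'   missingness fractions.
#' @export
summarize_dataset <- function(ds, level = 0.95) {
  rec <- ds$records
  n <- nrow(rec)
  cases <- sum(rec$serious_infection)
  vars <- recorded_variables(ds)
  missingness <- vapply(vars, function(v) mean(is.na(rec[[v]])), numeric(1))
  structure(list(
    name = ds$name, n = n, cases = cases,
    prevalence = wald_ci(cases, n, level = level),
    age_mean = mean(rec$age_months) / 12,
    age_range = range(rec$age_months) / 12,
    missingness = missingness
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  p <- x$prevalence
  cat(sprintf("Dataset %s: n = %d, cases = %d\n", x$name, x$n, x$cases))
  cat(sprintf("  prevalence %.1f%% (95%% CI %.1f to %.1f)\n",
              100 * p$point, 100 * p$ci_low, 100 * p$ci_high))
  cat(sprintf("  age mean %.1f y (range %.1f to %.1f)\n",
              x$age_mean, x$age_range[1], x$age_range[2]))
  mm <- x$missingness[x$missingness > 0]
  if (length(mm))
    cat("  missingness:", paste(sprintf("%s %.0f%%", names(mm), 100 * mm), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat(sprintf("<patient_dataset> %s (%s, %s): %d records, %d recorded variables\n",
              x$name, x$setting, x$country, nrow(x$records), length(recorded_variables(x))))
  invisible(x)
}
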