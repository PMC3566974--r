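#' Dataset-eligibility policy
#'
#' A dataset is not used to validate a rule when too many of the rule's
#' required variables are unrecorded (neither the variable nor any proxy
#' exists as a column): one-third or more for the fever guidelines (NICE,
#' NHG), one or more for the pneumonia and meningitis rules, and two or more
#' for the Yale scale and the five-stage decision tree.
#'
#' @param max_missing Named integer vector: the maximum tolerated number of
#'   unrecorded required variables per CPR.
#' @param guideline_frac Ineligibility threshold for guidelines, as a
#'   fraction of the configured feature count; ties (exactly one-third)
#'   count as ineligible.
#' @param guidelines Rule ids treated as guidelines.
#' @return List of class `eligibility_policy`.
#' @export
eligibility_policy <- function(max_missing = c(FSDT = 1, PNEUMONIA = 0,
                                               MENINGITIS = 0, YOS = 1),
                               guideline_frac = 1 / 3,
                               guidelines = c("NICE", "NHG")) {
  stopifnot(all(max_missing >= 0), guideline_frac > 0)
  structure(list(max_missing = max_missing, guideline_frac = guideline_frac,
                 guidelines = guidelines),
            class = "eligibility_policy")
}

#' Check whether a dataset may validate a rule
#'
#' A required variable counts as unrecorded when neither it nor any of its
#' proxies is a dataset column; record-level missing cells do not enter this
#' check. The five-stage decision tree's temperature item counts through the
#' temperature column and its age item is always available.
#'
#' @param ds A `patient_dataset`.
#' @param rule A `rule_definition`.
#' @param policy An [eligibility_policy()].
#' @param proxies A `proxy_map`.
#' @param feature_config NICE feature configuration (the guideline's required
#'   variables are its configured features).
#' @return List with `eligible` (logical), `missing_variables` (character)
#'   and `reason` (character, `NA` when eligible).
#' @export
check_eligibility <- function(ds, rule, policy = eligibility_policy(),
                              proxies = default_proxies(),
                              feature_config = default_nice_features()) {
  recorded <- recorded_variables(ds)
  vars <- if (rule$logic == "traffic_light")
    unlist(feature_config, use.names = FALSE) else rule$required_variables
  unrec <- vars[vapply(vars, function(v) {
    chain <- c(v, proxies[[v]] %||% character())
    !any(chain %in% recorded)
  }, logical(1))]
  if (rule$rule_id %in% policy$guidelines || rule$logic == "traffic_light") {
    ok <- length(unrec) / length(vars) < policy$guideline_frac
    reason <- sprintf("%d of %d guideline variables unrecorded (threshold: one-third or more)",
                      length(unrec), length(vars))
  } else {
    tol <- policy$max_missing[rule$rule_id]
    if (is.na(tol)) tol <- 0
    ok <- length(unrec) <= tol
    reason <- sprintf("%d required variable(s) unrecorded (tolerated: %d)",
                      length(unrec), tol)
  }
  list(eligible = ok, missing_variables = unrec,
       reason = if (ok) NA_character_ else reason)
}

#' Default derivation map
#'
#' Datasets used to derive a rule are not used to validate the same rule: the
#' five-stage decision tree and the pneumonia rule were both derived in the
#' Belgian primary-care cohort (the `vandenbruel` preset profile).
#'
#' @return Named list mapping rule id to derivation dataset name.
#' @export
default_derivation_map <- function() {
  list(FSDT = "vandenbruel", PNEUMONIA = "vandenbruel")
}

#' Run the full multi-dataset validation grid
#'
#' For every (dataset, rule) pair - with one row per cutoff for the Yale
#' scale - checks eligibility and the derivation exclusion, applies the rule
#' under the missing-data policy, builds the complete-case contingency table
#' against the rule's target condition, and attaches the accuracy profile,
#' prevalence stratum, dumbbell point and rule-out assessment. Ineligible or
#' excluded pairs carry the reason instead.
#'
#' @param datasets List of `patient_dataset` objects.
#' @param rules Named list of `rule_definition`s (default [default_rules()]).
#' @param proxies A `proxy_map`.
#' @param policy An [eligibility_policy()].
#' @param missing_policy Record-level policy passed to [apply_rule()].
#' @param yos_cutoffs Cutoffs evaluated for sum-score rules.
#' @param feature_config NICE feature configuration.
#' @param derivation Named list mapping rule id to the name of its derivation
#'   dataset (excluded from validating that rule).
#' @param level Confidence level.
#' @return Object of class `validation_report`: a `results` tibble (one row
#'   per dataset x rule x cutoff with list-columns `profile` and `dumbbell`),
#'   dataset summaries, and run metadata including a config hash.
#' @export
run_validation <- function(datasets, rules = default_rules(),
                           proxies = default_proxies(),
                           policy = eligibility_policy(),
                           missing_policy = "complete_case",
                           yos_cutoffs = c(8, 10),
                           feature_config = default_nice_features(),
                           derivation = default_derivation_map(),
                           level = 0.95) {
  stopifnot(length(datasets) > 0)
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, `[[`, character(1), "name")
  rows <- list()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    for (rule in rules) {
      cutoffs <- if (rule$logic == "sum_score") yos_cutoffs else NA
      for (cut in cutoffs) {
        rows[[length(rows) + 1L]] <-
          validate_cell(ds, rule, cut, proxies, policy, missing_policy,
                        feature_config, derivation, level)
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  if (!any(results$status == "evaluated"))
    stop("no eligible (dataset, rule) pair", call. = FALSE)
  config <- list(missing_policy = missing_policy, yos_cutoffs = yos_cutoffs,
                 feature_config = feature_config,
                 derivation = derivation, level = level,
                 policy = unclass(policy),
                 datasets = names(datasets),
                 rules = names(rules), version = "1")
  structure(list(results = results,
                 summaries = lapply(datasets, summarize_dataset, level = level),
                 config = config,
                 config_hash = rlang::hash(config),
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "validation_report")
}

#' @keywords internal
validate_cell <- function(ds, rule, cut, proxies, policy, missing_policy,
                          feature_config, derivation, level) {
  base <- tibble::tibble(dataset = ds$name, rule_id = rule$rule_id,
                         cutoff = cut, status = NA_character_,
                         reason = NA_character_, stratum = NA_character_,
                         evaluable_n = NA_integer_, not_evaluable_n = NA_integer_,
                         rule_out = NA,
                         profile = list(NULL), dumbbell = list(NULL))
  deriv <- derivation[[rule$rule_id]]
  if (!is.null(deriv) && identical(deriv, ds$name)) {
    base$status <- "excluded"
    base$reason <- "derivation dataset: not used to validate its own rule"
    return(base)
  }
  el <- check_eligibility(ds, rule, policy, proxies, feature_config)
  if (!el$eligible) {
    base$status <- "ineligible"
    base$reason <- paste0(el$reason, " [", paste(el$missing_variables, collapse = ", "), "]")
    return(base)
  }
  res <- apply_rule(ds, rule, proxies, missing_policy,
                    cutoff = if (!is.na(cut)) cut, feature_config = feature_config,
                    eligibility = policy, check_eligible = FALSE)
  keep <- res$classification != "not_evaluable"
  truth <- ds$records[[rule$target_condition]][keep] == 1
  if (sum(keep) == 0L || !any(truth) || all(truth)) {
    base$status <- "degenerate"
    base$reason <- "no evaluable records in one disease class"
    base$evaluable_n <- sum(keep)
    base$not_evaluable_n <- sum(!keep)
    return(base)
  }
  tab <- build_contingency(truth, res$classification[keep])
  auc <- if (rule$logic == "sum_score") auc_rank(res$score[keep], truth)
  prof <- accuracy_profile(tab, level = level, auc = auc, total_n = nrow(res))
  prof$stratum <- assign_stratum(prof$prevalence$point)
  base$status <- "evaluated"
  base$stratum <- prof$stratum
  base$evaluable_n <- sum(keep)
  base$not_evaluable_n <- sum(!keep)
  base$rule_out <- rule_out_assessment(prof)$rule_out
  base$profile <- list(prof)
  base$dumbbell <- list(dumbbell_point(prof))
  base
}

#' Flatten a validation report into a results table
#'
#' One row per evaluated (dataset, rule, cutoff) cell with the columns of a
#' published accuracy table: cases/N, percentage testing positive (evaluable
#' denominator), sensitivity and specificity with exact CIs, likelihood
#' ratios with log-method CIs, and the pre/post-test probabilities.
#'
#' @param report A `validation_report`.
#' @return A tibble.
#' @export
report_to_table <- function(report) {
  rows <- lapply(seq_len(nrow(report$results)), function(i) {
    r <- report$results[i, ]
    out <- tibble::tibble(dataset = r$dataset, rule_id = r$rule_id,
                          cutoff = r$cutoff, status = r$status,
                          stratum = r$stratum, reason = r$reason)
    p <- r$profile[[1]]
    if (is.null(p)) return(out)
    d <- r$dumbbell[[1]]
    dplyr::bind_cols(out, tibble::tibble(
      cases = p$table$n1, n = p$table$n,
      pct_positive = 100 * p$positive_fraction,
      sens = 100 * p$sensitivity$point,
      sens_lo = 100 * p$sensitivity$ci_low, sens_hi = 100 * p$sensitivity$ci_high,
      spec = 100 * p$specificity$point,
      spec_lo = 100 * p$specificity$ci_low, spec_hi = 100 * p$specificity$ci_high,
      lr_pos = p$lr_pos$point, lr_pos_lo = p$lr_pos$ci_low, lr_pos_hi = p$lr_pos$ci_high,
      lr_neg = p$lr_neg$point, lr_neg_lo = p$lr_neg$ci_low, lr_neg_hi = p$lr_neg$ci_high,
      lr_flagged = p$lr_pos$flagged, auc = p$auc,
      pretest = 100 * d$pretest, post_positive = 100 * d$post_positive,
      post_negative = 100 * d$post_negative,
      rule_out = r$rule_out))
  })
  dplyr::bind_rows(rows)
}

#' Serialize a validation report
#'
#' JSON output is deterministic: identical inputs and configuration produce
#' byte-identical files, because volatile metadata (the timestamp) is
#' omitted unless requested.
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @param include_timestamp Include the run timestamp (breaks byte-level
#'   reproducibility across runs).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, include_timestamp = FALSE) {
  payload <- list(config = report$config, config_hash = report$config_hash,
                  results = report_to_table(report))
  if (include_timestamp) payload$timestamp <- report$timestamp
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_tsv <- function(report, path) {
  readr::write_tsv(report_to_table(report), path, na = "")
  invisible(path)
}

#' Do two confidence intervals overlap?
#'
#' Closed-interval comparison; touching bounds count as overlapping.
#'
#' @param a,b `proportion_estimate` or `ratio_estimate` objects (anything
#'   with `ci_low`/`ci_high`).
#' @return Logical.
#' @export
ci_overlap <- function(a, b) a$ci_low <= b$ci_high && b$ci_low <= a$ci_high

#' @keywords internal
comparison_result <- function(profile_a, profile_b, label_a, label_b,
                              suppressed = FALSE, note = NA_character_) {
  overlap <- if (!suppressed) {
    c(sensitivity = ci_overlap(profile_a$sensitivity, profile_b$sensitivity),
      specificity = ci_overlap(profile_a$specificity, profile_b$specificity),
      lr_pos = ci_overlap(profile_a$lr_pos, profile_b$lr_pos),
      lr_neg = ci_overlap(profile_a$lr_neg, profile_b$lr_neg))
  }
  structure(list(profile_a = profile_a, profile_b = profile_b,
                 label_a = label_a, label_b = label_b,
                 overlap = overlap, suppressed = suppressed, note = note),
            class = "comparison_result")
}

#' @keywords internal
profile_from_results <- function(ds, rule, res) {
  keep <- res$classification != "not_evaluable"
  truth <- ds$records[[rule$target_condition]][keep] == 1
  if (sum(keep) == 0L || !any(truth) || all(truth)) return(NULL)
  tab <- build_contingency(truth, res$classification[keep])
  auc <- if (rule$logic == "sum_score") auc_rank(res$score[keep], truth)
  accuracy_profile(tab, auc = auc, total_n = nrow(res))
}

#' Age-subgroup sensitivity analysis
#'
#' Compares the diagnostic characteristics in a rule's target age group (for
#' example 3 to 36 months for the Yale scale, up to 60 months for the NICE
#' guideline) with the entire age range of the dataset, flagging for each
#' metric whether the 95% CIs overlap. Records with missing age cannot occur
#' in a valid dataset (age is mandatory), so the subgroup is a pure window
#' restriction.
#'
#' @param ds A `patient_dataset`.
#' @param rule A `rule_definition`.
#' @param age_window Months, `c(lo, hi)` interpreted as `[lo, hi)`; defaults
#'   to the rule's `intended_age_range`.
#' @param ... Passed to [apply_rule()].
#' @return A `comparison_result` (full range = `profile_a`, subgroup =
#'   `profile_b`). When the subgroup contains no cases the comparison is
#'   suppressed and flagged.
#' @export
age_subgroup_comparison <- function(ds, rule, age_window = rule$intended_age_range, ...) {
  if (is.null(age_window)) stop("no age window given and rule has no intended range", call. = FALSE)
  res_full <- apply_rule(ds, rule, ...)
  prof_full <- profile_from_results(ds, rule, res_full)
  inside <- ds$records$age_months >= age_window[1] & ds$records$age_months < age_window[2]
  sub <- ds
  sub$records <- ds$records[inside, ]
  label_b <- sprintf("ages [%g, %g) months", age_window[1], age_window[2])
  if (nrow(sub$records) == 0L || sum(sub$records[[rule$target_condition]]) == 0L)
    return(comparison_result(prof_full, NULL, "all ages", label_b,
                             suppressed = TRUE, note = "no cases in age subgroup"))
  res_sub <- apply_rule(sub, rule, ...)
  prof_sub <- profile_from_results(sub, rule, res_sub)
  if (is.null(prof_full) || is.null(prof_sub))
    return(comparison_result(prof_full, prof_sub, "all ages", label_b,
                             suppressed = TRUE, note = "degenerate contingency table"))
  comparison_result(prof_full, prof_sub, "all ages", label_b)
}

#' Reduced-rule sensitivity analysis
#'
#' Re-validates a rule after dropping one or more variables (for example the
#' meningitis rule without nuchal rigidity, or the five-item Yale scale) on
#' the same records - those evaluable under both the full and the reduced
#' rule - and flags CI overlap per metric. For any-of rules the reduced
#' sensitivity can never exceed the full-rule sensitivity on the same
#' records.
#'
#' @param ds A `patient_dataset`.
#' @param rule A `rule_definition`.
#' @param dropped_variables Variables to remove.
#' @param min_items Hard floor on the remaining item count.
#' @param ... Passed to [apply_rule()].
#' @return A `comparison_result` (full = `profile_a`, reduced = `profile_b`).
#' @export
reduced_rule_comparison <- function(ds, rule, dropped_variables, min_items = 1, ...) {
  remaining <- setdiff(rule$required_variables, dropped_variables)
  if (length(remaining) < min_items)
    stop("dropping ", paste(dropped_variables, collapse = ", "),
         " leaves fewer than ", min_items, " item(s)", call. = FALSE)
  res_full <- apply_rule(ds, rule, ...)
  res_red <- apply_rule(ds, rule, drop_variables = dropped_variables, ...)
  both <- res_full$classification != "not_evaluable" &
    res_red$classification != "not_evaluable"
  sub <- ds
  sub$records <- ds$records[both, ]
  truth <- sub$records[[rule$target_condition]] == 1
  if (!any(truth) || all(truth))
    return(comparison_result(NULL, NULL, "full rule", "reduced rule",
                             suppressed = TRUE, note = "degenerate contingency table"))
  auc_f <- if (rule$logic == "sum_score") auc_rank(res_full$score[both], truth)
  auc_r <- if (rule$logic == "sum_score") auc_rank(res_red$score[both], truth)
  prof_full <- accuracy_profile(build_contingency(truth, res_full$classification[both]), auc = auc_f)
  prof_red <- accuracy_profile(build_contingency(truth, res_red$classification[both]), auc = auc_r)
  comparison_result(prof_full, prof_red, "full rule",
                    paste("without", paste(dropped_variables, collapse = ", ")))
}

#' Dumbbell plot of pre- and post-test probabilities
#'
#' One panel per prevalence stratum (LP, IP, HP); each row shows, for one
#' (dataset, rule) cell, the probability of the target condition before
#' testing, after a positive result and after a negative result. Cells whose
#' likelihood ratios needed the zero-cell correction are annotated. Output is
#' deterministic given a fixed report.
#'
#' @param report A `validation_report`.
#' @param out_path Output file; device chosen by extension (`.pdf` default,
#'   `.png` where the build supports it).
#' @param width,height Device size in inches.
#' @return `out_path`, invisibly.
#' @export
render_dumbbell <- function(report, out_path, width = 8, height = 6) {
  tab <- report_to_table(report)
  tab <- tab[tab$status == "evaluated", ]
  if (nrow(tab) == 0L) stop("report contains no evaluated cells", call. = FALSE)
  tab$row_label <- paste0(tab$dataset, " - ", tab$rule_id,
                          ifelse(is.na(tab$cutoff), "", paste0(">", tab$cutoff)),
                          ifelse(tab$lr_flagged, " *", ""))
  tab$stratum <- factor(tab$stratum, levels = c("LP", "IP", "HP"))
  long <- dplyr::bind_rows(
    tibble::tibble(row_label = tab$row_label, stratum = tab$stratum,
                   what = "pre-test", prob = tab$pretest),
    tibble::tibble(row_label = tab$row_label, stratum = tab$stratum,
                   what = "post-test +", prob = tab$post_positive),
    tibble::tibble(row_label = tab$row_label, stratum = tab$stratum,
                   what = "post-test -", prob = tab$post_negative))
  long$what <- factor(long$what, levels = c("post-test -", "pre-test", "post-test +"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = prob, y = row_label, color = what)) +
    ggplot2::geom_line(ggplot2::aes(group = row_label), color = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_color_manual(values = c("post-test -" = "#2e7d32",
                                           "pre-test" = "#1565c0",
                                           "post-test +" = "#c62828")) +
    ggplot2::facet_grid(stratum ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "probability of target condition (%)", y = NULL, color = NULL,
                  caption = "* likelihood ratios zero-cell corrected") +
    ggplot2::theme_minimal(base_size = 10)
  ext <- tolower(tools::file_ext(out_path))
  dev <- switch(ext, png = "png", svg = "svg", "pdf")
  ggplot2::ggsave(out_path, p, device = dev, width = width, height = height)
  invisible(out_path)
}

#' @export
print.validation_report <- function(x, ...) {
  tb <- table(x$results$status)
  cat("<validation_report>", nrow(x$results), "cells:",
      paste(names(tb), tb, collapse = ", "), "\n")
  cat("  config hash:", x$config_hash, "\n")
  invisible(x)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$label_a, "vs", x$label_b, "\n")
  if (x$suppressed) {
    cat("  suppressed:", x$note, "\n")
  } else {
    ov <- paste(names(x$overlap), ifelse(x$overlap, "overlap", "DISJOINT"), collapse = "; ")
    cat(" ", ov, "\n")
  }
  invisible(x)
}
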