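#' Define a prediction rule
#'
#' @param rule_id One of `"FSDT"`, `"PNEUMONIA"`, `"MENINGITIS"`, `"YOS"`,
#'   `"NICE"`, `"NHG"` (free identifiers are allowed for user rules).
#' @param target_condition Outcome the rule predicts: `"serious_infection"`,
#'   `"pneumonia"` or `"meningitis"`.
#' @param logic `"any_of"`, `"sum_score"` or `"traffic_light"`.
#' @param required_variables Canonical variable names the rule needs. For the
#'   five-stage decision tree the temperature threshold item and the
#'   15-to-29-months age item are intrinsic and not listed here (age is always
#'   available on a record).
#' @param cutoffs Score thresholds for sum-score rules (positive when score
#'   strictly exceeds the cutoff).
#' @param intended_age_range Target age window in months, `c(lo, hi)`
#'   interpreted as `[lo, hi)`.
#' @param item_weights Per-item weights for sum-score rules (the Yale items
#'   already take values 1/3/5, so weights are 1).
#' @return A list of class `rule_definition`.
#' @export
rule_definition <- function(rule_id, target_condition, logic,
                            required_variables, cutoffs = NULL,
                            intended_age_range = NULL, item_weights = NULL) {
  stopifnot(logic %in% c("any_of", "sum_score", "traffic_light"),
            target_condition %in% c("serious_infection", outcome_components()))
  if (length(required_variables) == 0L)
    stop("required_variables must be non-empty", call. = FALSE)
  if (logic == "sum_score") {
    if (is.null(item_weights)) item_weights <- rep(1, length(required_variables))
    if (length(item_weights) != length(required_variables))
      stop("sum_score rules need a weight for every item", call. = FALSE)
    if (!is.null(cutoffs)) {
      lo <- sum(item_weights * 1); hi <- sum(item_weights * 5)
      if (any(cutoffs < lo | cutoffs > hi))
        stop("cutoffs outside achievable score range [", lo, ", ", hi, "]", call. = FALSE)
    }
  }
  structure(list(rule_id = rule_id, target_condition = target_condition,
                 logic = logic, required_variables = required_variables,
                 cutoffs = cutoffs, intended_age_range = intended_age_range,
                 item_weights = item_weights),
            class = "rule_definition")
}

#' Default rule set: four prediction rules and two guidelines
#'
#' * `FSDT` - five-stage decision tree for any serious infection: positive if
#'   any of clinician instinct that something is wrong, dyspnea, temperature
#'   above 39.5 degC (strict), diarrhea, or age 15 to 29 months.
#' * `PNEUMONIA` - positive if shortness of breath or clinician concern.
#' * `MENINGITIS` - positive if petechiae, nuchal rigidity or coma.
#' * `YOS` - Yale Observation Scale: six observation items scored 1/3/5,
#'   summed (6 to 30); positive when the score strictly exceeds a preselected
#'   cutoff of 8 or 10. Intended for ages 3 to 36 months.
#' * `NICE` - traffic-light system: positive when at least one amber or red
#'   feature is present (see [default_nice_features()]). Intended for
#'   children under 5 years.
#' * `NHG` - Dutch GP alarm symptoms: positive if any of eight findings
#'   (seriously ill impression, reduced consciousness, persistent vomiting,
#'   petechiae, tachypnea/dyspnea, reduced peripheral circulation, pallor,
#'   signs of meningeal irritation).
#'
#' @return Named list of [rule_definition()] objects.
#' @export
default_rules <- function() {
  list(
    FSDT = rule_definition("FSDT", "serious_infection", "any_of",
                           c("clinician_instinct", "dyspnea", "temperature", "diarrhea")),
    PNEUMONIA = rule_definition("PNEUMONIA", "pneumonia", "any_of",
                                c("shortness_of_breath", "clinician_concern")),
    MENINGITIS = rule_definition("MENINGITIS", "meningitis", "any_of",
                                 c("petechiae", "nuchal_rigidity", "coma")),
    YOS = rule_definition("YOS", "serious_infection", "sum_score",
                          c("yos_cry", "yos_reaction_to_parent", "yos_state_variation",
                            "yos_color", "yos_hydration", "yos_social_response"),
                          cutoffs = c(8, 10), intended_age_range = c(3, 36)),
    NICE = rule_definition("NICE", "serious_infection", "traffic_light",
                           unlist(default_nice_features(), use.names = FALSE),
                           intended_age_range = c(0, 60)),
    NHG = rule_definition("NHG", "serious_infection", "any_of",
                          c("seriously_ill_impression", "reduced_consciousness",
                            "persistent_vomiting", "petechiae", "tachypnea",
                            "reduced_peripheral_circulation", "pallor",
                            "meningeal_irritation"))
  )
}

#' Default NICE traffic-light feature configuration
#'
#' A nine-feature reconstruction of the 2007 feverish-illness traffic-light
#' categories (amber = intermediate risk, red = high risk), editable by the
#' user. Test-positive means any amber or red feature present; the result also
#' reports the highest category reached.
#'
#' @return List with character vectors `amber` and `red`.
#' @export
default_nice_features <- function() {
  list(amber = c("pallor", "nasal_flaring", "tachypnea", "reduced_activity",
                 "poor_feeding"),
       red = c("mottled_skin", "reduced_consciousness", "grunting", "petechiae"))
}

#' Proxy map construction and defaults
#'
#' A proxy map lists, per canonical variable, the ordered substitutes used
#' when the variable itself is unrecorded or missing. Resolution is
#' single-step: the original value wins when present; otherwise the first
#' present proxy is used; proxies of proxies are never chased, so mutual
#' proxy pairs (meningeal irritation and nuchal rigidity) are well defined.
#'
#' @param map Named list of character vectors.
#' @param schema Schema used to check that substitutes exist.
#' @return The validated map, class `proxy_map`.
#' @export
proxy_map <- function(map, schema = default_schema()) {
  nms <- names(schema)
  for (v in names(map)) {
    if (!v %in% nms) stop("proxy map key '", v, "' not in schema", call. = FALSE)
    if (v %in% map[[v]]) stop("variable '", v, "' cannot proxy itself", call. = FALSE)
    bad <- setdiff(map[[v]], nms)
    if (length(bad)) stop("proxies of '", v, "' not in schema: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(map, class = "proxy_map")
}

#' @rdname proxy_map
#' @export
default_proxies <- function(schema = default_schema()) {
  m <- lapply(schema, `[[`, "proxy_candidates")
  proxy_map(m[lengths(m) > 0], schema)
}

#' Resolve one variable for one record through its proxy chain
#'
#' @param rec A single patient record: a named list or one-row data frame.
#' @param name Canonical variable name.
#' @param proxies A `proxy_map`.
#' @return List with `value` (the resolved value, `NA` if nothing present) and
#'   `provenance` (`"original"`, `"proxy:<name>"` or `"missing"`).
#' @export
resolve_variable <- function(rec, name, proxies = default_proxies()) {
  get1 <- function(v) if (v %in% names(rec)) rec[[v]][1] else NA
  val <- get1(name)
  if (!is.na(val)) return(list(value = val, provenance = "original"))
  for (p in proxies[[name]]) {
    val <- get1(p)
    if (!is.na(val)) return(list(value = val, provenance = paste0("proxy:", p)))
  }
  list(value = NA, provenance = "missing")
}

# Vectorized resolution of one variable over a records tibble restricted to
# the columns actually recorded in the dataset. Returns value and per-record
# provenance; "unrecorded" when neither variable nor proxy exists as a column.
resolve_column <- function(records, name, proxies, recorded) {
  chain <- c(name, proxies[[name]] %||% character())
  chain <- chain[chain %in% recorded]
  n <- nrow(records)
  if (length(chain) == 0L)
    return(list(value = rep(NA_real_, n), source = rep("unrecorded", n), recorded = FALSE))
  value <- rep(NA_real_, n)
  source <- rep("missing", n)
  for (v in chain) {
    x <- records[[v]]
    take <- is.na(value) & !is.na(x)
    value[take] <- x[take]
    source[take] <- if (v == name) "original" else paste0("proxy:", v)
  }
  list(value = value, source = source, recorded = TRUE)
}

#' @keywords internal
check_policy <- function(missing_policy) {
  if (!missing_policy %in% c("complete_case", "missing_as_absent"))
    stop("missing_policy must be 'complete_case' or 'missing_as_absent'", call. = FALSE)
  missing_policy
}

# Build the logical item matrix for an any_of rule. For FSDT the matrix holds,
# in sequential order: instinct, dyspnea, temperature > 39.5 (strict),
# diarrhea, age 15-29 months ([15, 30) in continuous months). Items whose
# variable is unrecorded dataset-wide are dropped (dataset-level reduction,
# within eligibility tolerance); record-level NA is governed by the
# missing-data policy downstream.
item_matrix <- function(records, rule, proxies, recorded, drop = character()) {
  items <- list(); prov <- list()
  vars <- setdiff(rule$required_variables, drop)
  for (v in vars) {
    r <- resolve_column(records, v, proxies, recorded)
    if (!r$recorded) next
    prov[[v]] <- r$source
    items[[v]] <- if (v == "temperature") r$value > 39.5 else r$value == 1
  }
  if (rule$rule_id == "FSDT") {
    a <- records$age_months
    items[["age_15_to_29mo"]] <- a >= 15 & a < 30
    prov[["age_15_to_29mo"]] <- rep("original", nrow(records))
    order_fsdt <- c("clinician_instinct", "dyspnea", "temperature", "diarrhea",
                    "age_15_to_29mo")
    keep <- intersect(order_fsdt, names(items))
    items <- items[keep]; prov <- prov[keep]
  }
  list(items = items, prov = prov)
}

# Vectorized any_of classification from a logical item matrix.
classify_any_of <- function(items, missing_policy, first_only = FALSE) {
  m <- do.call(cbind, items)
  any_na <- rowSums(is.na(m)) > 0
  m0 <- m; m0[is.na(m0)] <- FALSE
  pos <- rowSums(m0) > 0
  cls <- ifelse(pos, "positive", "negative")
  if (missing_policy == "complete_case") cls[any_na] <- "not_evaluable"
  fired <- character(nrow(m))
  idx <- which(cls == "positive")
  if (length(idx)) {
    nm <- colnames(m)
    fired[idx] <- vapply(idx, function(i) {
      hit <- nm[which(m0[i, ])]
      if (first_only) hit[1] else paste(hit, collapse = ";")
    }, character(1))
  }
  list(classification = cls, fired = fired)
}

#' @keywords internal
as_record_tbl <- function(rec) {
  if (is.data.frame(rec)) tibble::as_tibble(rec) else tibble::as_tibble(as.list(rec))
}

# Single-record wrapper around the vectorized any_of machinery. All rule
# items count as recorded (absent keys are record-level missing).
eval_one <- function(rec, rule, proxies, missing_policy, first_only = FALSE) {
  check_policy(missing_policy)
  rec <- as_record_tbl(rec)
  needed <- unique(c(rule$required_variables,
                     unlist(proxies[rule$required_variables], use.names = FALSE)))
  for (v in setdiff(needed, names(rec))) rec[[v]] <- NA_real_
  if (!"age_months" %in% names(rec)) rec$age_months <- NA_real_
  im <- item_matrix(rec, rule, proxies, recorded = needed)
  cl <- classify_any_of(im$items, missing_policy, first_only = first_only)
  rule_result(cl$classification[1], fired = cl$fired[1],
              provenance = vapply(im$prov, `[[`, character(1), 1))
}

#' @keywords internal
rule_result <- function(classification, fired = "", score = NA_integer_,
                        category = NA_character_, provenance = NULL) {
  structure(list(classification = classification,
                 fired_items = if (nzchar(fired)) strsplit(fired, ";")[[1]] else character(),
                 score = score, category = category, provenance = provenance),
            class = "rule_result")
}

#' Evaluate the five-stage decision tree on one record
#'
#' Positive if any of, in sequential order: clinician instinct that something
#' is wrong, dyspnea, temperature strictly above 39.5 degC, diarrhea, or age
#' 15 to 29 months. The first item that fires is credited; the order never
#' changes the verdict. Under the complete-case policy a record with any
#' required item missing (after proxy resolution) is not evaluable.
#'
#' @param rec Named list or one-row data frame (needs `age_months`).
#' @param proxies A `proxy_map`.
#' @param missing_policy `"complete_case"` (default) or `"missing_as_absent"`.
#' @return A `rule_result`.
#' @export
evaluate_fsdt <- function(rec, proxies = default_proxies(),
                          missing_policy = "complete_case") {
  eval_one(rec, default_rules()$FSDT, proxies, missing_policy, first_only = TRUE)
}

#' Evaluate the pneumonia rule on one record
#'
#' Positive if shortness of breath or clinician concern is present.
#' @inheritParams evaluate_fsdt
#' @return A `rule_result`.
#' @export
evaluate_pneumonia_rule <- function(rec, proxies = default_proxies(),
                                    missing_policy = "complete_case") {
  eval_one(rec, default_rules()$PNEUMONIA, proxies, missing_policy)
}

#' Evaluate the meningitis rule on one record
#'
#' Positive if any of petechiae, nuchal rigidity (proxy: meningeal
#' irritation) or coma (proxy: unconsciousness) is present.
#' @inheritParams evaluate_fsdt
#' @return A `rule_result`.
#' @export
evaluate_meningitis_rule <- function(rec, proxies = default_proxies(),
                                     missing_policy = "complete_case") {
  eval_one(rec, default_rules()$MENINGITIS, proxies, missing_policy)
}

#' Evaluate the NHG alarm symptoms on one record
#'
#' Positive if any of the eight alarm findings is present.
#' @inheritParams evaluate_fsdt
#' @return A `rule_result`.
#' @export
evaluate_nhg <- function(rec, proxies = default_proxies(),
                         missing_policy = "complete_case") {
  eval_one(rec, default_rules()$NHG, proxies, missing_policy)
}

#' Yale Observation Scale sum score for one record
#'
#' Sums the six observation items (quality of cry, reaction to parent
#' stimulation, state variation, color, hydration, response to social
#' overtures), each coded 1 (normal), 3 (moderate impairment) or 5 (severe
#' impairment); the score ranges 6 to 30. Any missing item leaves the score
#' undefined (`NA`), signalling not-evaluable.
#'
#' @param rec Named list or one-row data frame with the `yos_*` items.
#' @return Integer score, or `NA` when an item is missing.
#' @export
yos_score <- function(rec) {
  rec <- as_record_tbl(rec)
  items <- default_rules()$YOS$required_variables
  vals <- vapply(items, function(v) if (v %in% names(rec)) as.numeric(rec[[v]][1]) else NA_real_,
                 numeric(1))
  if (anyNA(vals)) return(NA_integer_)
  as.integer(sum(vals))
}

#' Dichotomize a Yale score at a cutoff
#'
#' Positive when the score strictly exceeds the cutoff (preselected cutoffs
#' 8 and 10); an undefined score yields not-evaluable.
#'
#' @param score Integer score (may be `NA`).
#' @param cutoff Score threshold, 8 or 10 by convention (any value accepted).
#' @return A `rule_result` with the score attached.
#' @export
classify_yos <- function(score, cutoff) {
  stopifnot(length(score) == 1L, length(cutoff) == 1L)
  if (is.na(score)) return(rule_result("not_evaluable", score = NA_integer_))
  rule_result(if (score > cutoff) "positive" else "negative",
              fired = if (score > cutoff) sprintf("score_gt_%d", cutoff) else "",
              score = as.integer(score))
}

#' Evaluate the NICE traffic-light system on one record
#'
#' Positive when at least one amber or red feature is present; the result
#' reports the highest category reached (green/amber/red). A record is not
#' evaluable when more than `max_missing_frac` of the configured features are
#' missing (under the complete-case policy); missing features within that
#' tolerance are treated as absent.
#'
#' @param rec Named list or one-row data frame.
#' @param feature_config List with `amber` and `red` character vectors.
#' @param missing_policy `"complete_case"` or `"missing_as_absent"`.
#' @param max_missing_frac Tolerated fraction of missing configured features
#'   under complete-case (default one-third).
#' @return A `rule_result` with `category` filled in.
#' @export
evaluate_nice <- function(rec, feature_config = default_nice_features(),
                          missing_policy = "complete_case",
                          max_missing_frac = 1 / 3) {
  check_policy(missing_policy)
  rec <- as_record_tbl(rec)
  feats <- unlist(feature_config, use.names = FALSE)
  for (v in setdiff(feats, names(rec))) rec[[v]] <- NA_real_
  res <- nice_eval(rec, feature_config, recorded = feats, missing_policy,
                   max_missing_frac)
  rule_result(res$classification[1], fired = res$fired[1],
              category = res$category[1])
}

# Vectorized NICE evaluation over recorded configured features.
nice_eval <- function(records, feature_config, recorded, missing_policy,
                      max_missing_frac = 1 / 3) {
  amber <- intersect(feature_config$amber, recorded)
  red <- intersect(feature_config$red, recorded)
  feats <- c(amber, red)
  m <- as.matrix(records[feats]) == 1
  nmiss <- rowSums(is.na(m))
  m0 <- m; m0[is.na(m0)] <- FALSE
  any_red <- if (length(red)) rowSums(m0[, red, drop = FALSE]) > 0 else FALSE
  any_amber <- if (length(amber)) rowSums(m0[, amber, drop = FALSE]) > 0 else FALSE
  category <- ifelse(any_red, "red", ifelse(any_amber, "amber", "green"))
  cls <- ifelse(category == "green", "negative", "positive")
  if (missing_policy == "complete_case")
    cls[nmiss / length(feats) > max_missing_frac] <- "not_evaluable"
  fired <- character(nrow(m))
  idx <- which(cls == "positive")
  if (length(idx))
    fired[idx] <- vapply(idx, function(i) paste(feats[m0[i, ]], collapse = ";"),
                         character(1))
  list(classification = cls, category = category, fired = fired, n_missing = nmiss)
}

#' Apply a rule to every record of a dataset
#'
#' Checks dataset eligibility (unless `check_eligible = FALSE`), drops rule
#' variables that are unrecorded dataset-wide (within the eligibility
#' tolerance; e.g. a four-item decision tree in a dataset without a diarrhea
#' column, or the five-item Yale scale), resolves proxies, applies the
#' record-level missing-data policy and returns one verdict per record with
#' full variable provenance.
#'
#' @param ds A `patient_dataset`.
#' @param rule A `rule_definition`.
#' @param proxies A `proxy_map`.
#' @param missing_policy `"complete_case"` (records with a missing recorded
#'   item are excluded as not-evaluable; nothing is imputed) or
#'   `"missing_as_absent"` (missing binary items count as absent; missing
#'   Yale items score 1).
#' @param cutoff Cutoff for sum-score rules (default: first of the rule's
#'   `cutoffs`).
#' @param feature_config NICE feature configuration.
#' @param eligibility An [eligibility_policy()]; set `check_eligible = FALSE`
#'   to skip the check.
#' @param check_eligible Logical.
#' @param drop_variables Extra variables to drop from the rule (reduced-rule
#'   sensitivity analysis).
#' @return A tibble of class `rule_results` with columns `record_id`,
#'   `classification`, `score`, `category`, `fired`; attributes carry the
#'   rule id, cutoff, evaluable count, dropped variables and a provenance
#'   tibble (per record x variable source).
#' @export
apply_rule <- function(ds, rule, proxies = default_proxies(),
                       missing_policy = "complete_case", cutoff = NULL,
                       feature_config = default_nice_features(),
                       eligibility = eligibility_policy(),
                       check_eligible = TRUE, drop_variables = character()) {
  check_policy(missing_policy)
  stopifnot(inherits(ds, "patient_dataset"), inherits(rule, "rule_definition"))
  if (check_eligible) {
    el <- check_eligibility(ds, rule, policy = eligibility, proxies = proxies,
                            feature_config = feature_config)
    if (!el$eligible)
      stop("dataset '", ds$name, "' ineligible for rule ", rule$rule_id, ": ",
           el$reason, call. = FALSE)
  }
  records <- ds$records
  recorded <- recorded_variables(ds)
  n <- nrow(records)
  score <- rep(NA_integer_, n)
  category <- rep(NA_character_, n)
  prov <- NULL
  if (rule$logic == "sum_score") {
    items <- setdiff(intersect(rule$required_variables, recorded), drop_variables)
    if (length(items) == 0L) stop("no scored items recorded", call. = FALSE)
    m <- as.matrix(records[items])
    if (missing_policy == "missing_as_absent") m[is.na(m)] <- 1
    sc <- rowSums(m)
    cut <- cutoff %||% rule$cutoffs[1]
    cls <- ifelse(is.na(sc), "not_evaluable",
                  ifelse(sc > cut, "positive", "negative"))
    score <- as.integer(sc)
    fired <- ifelse(!is.na(sc) & sc > cut, sprintf("score_gt_%d", cut), "")
    dropped <- setdiff(rule$required_variables, items)
    prov_tbl <- NULL
  } else if (rule$logic == "traffic_light") {
    feats <- lapply(feature_config, setdiff, y = drop_variables)
    res <- nice_eval(records, feats, recorded, missing_policy)
    cls <- res$classification; category <- res$category; fired <- res$fired
    cut <- NA
    dropped <- setdiff(unlist(feature_config, use.names = FALSE),
                       c(recorded, drop_variables))
    prov_tbl <- NULL
  } else {
    im <- item_matrix(records, rule, proxies, recorded, drop = drop_variables)
    if (length(im$items) == 0L) stop("no rule items recorded", call. = FALSE)
    res <- classify_any_of(im$items, missing_policy,
                           first_only = rule$rule_id == "FSDT")
    cls <- res$classification; fired <- res$fired
    cut <- NA
    dropped <- setdiff(rule$required_variables, names(im$items))
    prov_tbl <- tibble::as_tibble(im$prov)
    names(prov_tbl) <- paste0("prov_", names(prov_tbl))
    prov_tbl <- dplyr::bind_cols(tibble::tibble(record_id = records$record_id), prov_tbl)
  }
  out <- tibble::tibble(record_id = records$record_id, classification = cls,
                        score = score, category = category, fired = fired)
  structure(out, class = c("rule_results", class(out)),
            rule_id = rule$rule_id, cutoff = cut,
            target_condition = rule$target_condition,
            missing_policy = missing_policy,
            evaluable_n = sum(cls != "not_evaluable"),
            not_evaluable_n = sum(cls == "not_evaluable"),
            dropped_variables = dropped, provenance = prov_tbl)
}

#' Evaluable-record count of a `rule_results` object
#' @param results A `rule_results` tibble from [apply_rule()].
#' @return Integer.
#' @export
evaluable_count <- function(results) attr(results, "evaluable_n")

#' Export per-record rule results as CSV
#'
#' One row per record: record id, rule id, classification, score, fired items
#' and a compact provenance string (`variable=source` pairs).
#'
#' @param results A `rule_results` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rule_results <- function(results, path) {
  prov <- attr(results, "provenance")
  prov_str <- if (!is.null(prov)) {
    vars <- sub("^prov_", "", setdiff(names(prov), "record_id"))
    apply(prov[-1], 1, function(r) paste(vars, r, sep = "=", collapse = ";"))
  } else ""
  out <- tibble::tibble(record_id = results$record_id,
                        rule_id = attr(results, "rule_id"),
                        classification = results$classification,
                        score = results$score, fired_items = results$fired,
                        provenance = prov_str)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Rule definitions and proxy maps as YAML
#'
#' Rules are declared in a plain YAML format so new rules can be added
#' without code changes.
#'
#' @param rules Named list of `rule_definition` objects.
#' @param proxies A `proxy_map`.
#' @param path File path.
#' @return Readers return the parsed objects; writers return `path`.
#' @export
write_rules_yaml <- function(rules, path) {
  out <- lapply(unname(rules), function(r) { x <- unclass(r); x[!vapply(x, is.null, logical(1))] })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_rules_yaml
#' @export
read_rules_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw, function(x)
    rule_definition(x$rule_id, x$target_condition, x$logic,
                    as.character(x$required_variables),
                    cutoffs = if (!is.null(x$cutoffs)) as.numeric(x$cutoffs),
                    intended_age_range = if (!is.null(x$intended_age_range)) as.numeric(x$intended_age_range),
                    item_weights = if (!is.null(x$item_weights)) as.numeric(x$item_weights)))
  names(rules) <- vapply(rules, `[[`, character(1), "rule_id")
  rules
}

#' @rdname write_rules_yaml
#' @export
write_proxies_yaml <- function(proxies, path) {
  yaml::write_yaml(lapply(unclass(proxies), as.list), path)
  invisible(path)
}

#' @rdname write_rules_yaml
#' @param schema Schema used to validate the proxy map on read.
#' @export
read_proxies_yaml <- function(path, schema = default_schema()) {
  proxy_map(lapply(yaml::read_yaml(path), unlist), schema)
}
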