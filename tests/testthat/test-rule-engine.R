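test_that("proxy resolution prefers originals and walks the chain in order", {
  px <- default_proxies()
  r <- resolve_variable(list(dyspnea = NA, respiratory_distress = 1), "dyspnea", px)
  expect_equal(r$value, 1)
  expect_equal(r$provenance, "proxy:respiratory_distress")

  r <- resolve_variable(list(dyspnea = 0, respiratory_distress = 1), "dyspnea", px)
  expect_equal(r$value, 0)
  expect_equal(r$provenance, "original")

  r <- resolve_variable(list(dyspnea = NA, respiratory_distress = NA,
                             chest_flaring = NA), "dyspnea", px)
  expect_true(is.na(r$value))
  expect_equal(r$provenance, "missing")
})

test_that("decision-tree items fire as specified", {
  # temperature strictly above 39.5
  r <- evaluate_fsdt(fsdt_record(temperature = 39.6))
  expect_equal(r$classification, "positive")
  expect_equal(r$fired_items, "temperature")
  expect_equal(evaluate_fsdt(fsdt_record(temperature = 39.5, age_months = 36))$classification,
               "negative")
  # age window 15 to 29 months, inclusive
  r <- evaluate_fsdt(fsdt_record(age_months = 20))
  expect_equal(r$classification, "positive")
  expect_equal(r$fired_items, "age_15_to_29mo")
  expect_equal(evaluate_fsdt(fsdt_record(age_months = 30))$classification, "negative")
  expect_equal(evaluate_fsdt(fsdt_record(age_months = 15))$classification, "positive")
  # sequential attribution credits the first trigger only
  r <- evaluate_fsdt(fsdt_record(clinician_instinct = 1, diarrhea = 1))
  expect_equal(r$fired_items, "clinician_instinct")
})

test_that("decision-tree verdicts equal brute force on the exhaustive truth table", {
  grid <- expand.grid(instinct = 0:1, dysp = 0:1, hot = 0:1, diar = 0:1, agein = 0:1)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rec <- fsdt_record(clinician_instinct = g$instinct, dyspnea = g$dysp,
                       temperature = ifelse(g$hot == 1, 39.8, 37.1),
                       diarrhea = g$diar, age_months = ifelse(g$agein == 1, 20, 48))
    want <- brute_any_of(as.logical(unlist(g)))
    expect_equal(evaluate_fsdt(rec)$classification, want, info = paste(g, collapse = ""))
  }
})

test_that("pneumonia rule follows the missing-data policy truth table", {
  expect_equal(evaluate_pneumonia_rule(list(shortness_of_breath = 1, clinician_concern = 0))$classification,
               "positive")
  expect_equal(evaluate_pneumonia_rule(list(shortness_of_breath = 0, clinician_concern = 0))$classification,
               "negative")
  # exhaustive over {0, 1, NA}^2 against the brute-force evaluator
  vals <- list(0, 1, NA)
  for (a in vals) for (b in vals) for (pol in c("complete_case", "missing_as_absent")) {
    rec <- list(shortness_of_breath = a, clinician_concern = b)
    want <- brute_any_of(c(if (is.na(a)) NA else a == 1,
                           if (is.na(b)) NA else b == 1), pol)
    expect_equal(evaluate_pneumonia_rule(rec, missing_policy = pol)$classification, want,
                 info = sprintf("a=%s b=%s %s", a, b, pol))
  }
})

test_that("meningitis rule accepts proxies and matches brute force", {
  expect_equal(evaluate_meningitis_rule(list(petechiae = 1, nuchal_rigidity = 0, coma = 0))$classification,
               "positive")
  expect_equal(evaluate_meningitis_rule(list(petechiae = 0, nuchal_rigidity = 0, coma = 0))$classification,
               "negative")
  r <- evaluate_meningitis_rule(list(petechiae = 0, nuchal_rigidity = NA,
                                     meningeal_irritation = 1, coma = 0))
  expect_equal(r$classification, "positive")
  expect_equal(unname(r$provenance["nuchal_rigidity"]), "proxy:meningeal_irritation")

  grid <- expand.grid(p = 0:1, nr = 0:1, c = 0:1)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rec <- list(petechiae = g$p, nuchal_rigidity = g$nr, coma = g$c)
    expect_equal(evaluate_meningitis_rule(rec)$classification,
                 brute_any_of(as.logical(unlist(g))))
  }
})

test_that("Yale score sums the six items and is order-invariant", {
  items <- default_rules()$YOS$required_variables
  expect_equal(yos_score(setNames(as.list(rep(1, 6)), items)), 6L)
  expect_equal(yos_score(setNames(as.list(rep(5, 6)), items)), 30L)
  expect_equal(yos_score(setNames(as.list(c(1, 1, 3, 1, 1, 1)), items)), 8L)
  expect_equal(yos_score(setNames(as.list(c(1, 1, 3, 1, 1, 1)), rev(items))), 8L)
  expect_true(is.na(yos_score(setNames(as.list(c(1, 1, 3, 1, 1, NA)), items))))
  # brute-force sum on random item draws
  withr::with_seed(1, {
    for (k in 1:20) {
      v <- sample(c(1, 3, 5), 6, replace = TRUE)
      expect_equal(yos_score(setNames(as.list(v), items)), as.integer(sum(v)))
    }
  })
})

test_that("Yale classification is strictly greater-than and nested across cutoffs", {
  expect_equal(classify_yos(11, 10)$classification, "positive")
  expect_equal(classify_yos(10, 10)$classification, "negative")
  expect_equal(classify_yos(6, 8)$classification, "negative")
  expect_equal(classify_yos(NA, 8)$classification, "not_evaluable")
  # the cutoff-8 positive set contains the cutoff-10 positive set
  for (s in 6:30) {
    if (classify_yos(s, 10)$classification == "positive")
      expect_equal(classify_yos(s, 8)$classification, "positive")
  }
})

test_that("traffic-light evaluation reports the highest category reached", {
  feats <- default_nice_features()
  all_absent <- setNames(as.list(rep(0, 9)), unlist(feats, use.names = FALSE))
  r <- evaluate_nice(all_absent)
  expect_equal(r$classification, "negative")
  expect_equal(r$category, "green")

  amber <- utils::modifyList(all_absent, list(pallor = 1))
  r <- evaluate_nice(amber)
  expect_equal(r$classification, "positive")
  expect_equal(r$category, "amber")

  red <- utils::modifyList(all_absent, list(grunting = 1))
  r <- evaluate_nice(red)
  expect_equal(r$classification, "positive")
  expect_equal(r$category, "red")

  # more than a third of features missing -> not evaluable under complete case
  four_missing <- utils::modifyList(all_absent, list(pallor = NA, grunting = NA,
                                                     tachypnea = NA, petechiae = NA))
  expect_equal(evaluate_nice(four_missing)$classification, "not_evaluable")
  expect_equal(evaluate_nice(four_missing, missing_policy = "missing_as_absent")$classification,
               "negative")
  # within tolerance, missing features count as absent
  two_missing <- utils::modifyList(all_absent, list(pallor = NA, grunting = NA))
  expect_equal(evaluate_nice(two_missing)$classification, "negative")
})

test_that("alarm-symptom rule matches brute force on the exhaustive truth table", {
  items <- default_rules()$NHG$required_variables
  expect_equal(evaluate_nhg(setNames(as.list(c(0, 0, 0, 0, 0, 0, 1, 0)), items))$classification,
               "positive")
  expect_equal(evaluate_nhg(setNames(as.list(rep(0, 8)), items))$classification, "negative")
  rec <- setNames(as.list(rep(0, 8)), items)
  rec$persistent_vomiting <- NA
  expect_equal(evaluate_nhg(rec)$classification, "not_evaluable")
  expect_equal(evaluate_nhg(rec, missing_policy = "missing_as_absent")$classification,
               "negative")

  grid <- expand.grid(rep(list(0:1), 8))
  names(grid) <- items
  for (i in seq_len(nrow(grid))) {
    rec <- as.list(grid[i, ])
    expect_equal(evaluate_nhg(rec)$classification,
                 brute_any_of(unlist(rec) == 1))
  }
})

test_that("any-of rules are monotone and proxies never override originals", {
  withr::with_seed(42, {
    items <- default_rules()$NHG$required_variables
    for (k in 1:25) {
      vals <- sample(0:1, 8, replace = TRUE)
      rec <- setNames(as.list(vals), items)
      base <- evaluate_nhg(rec)$classification
      off <- which(vals == 0)
      if (length(off)) {
        j <- sample(off, 1)
        rec2 <- rec; rec2[[j]] <- 1
        expect_equal(evaluate_nhg(rec2)$classification, "positive")
        if (base == "positive") expect_equal(evaluate_nhg(rec2)$classification, base)
      }
      # an original value always wins over a contradicting proxy
      orig <- sample(0:1, 1)
      r <- resolve_variable(list(dyspnea = orig, respiratory_distress = 1 - orig),
                            "dyspnea")
      expect_equal(r$value, orig)
      expect_equal(r$provenance, "original")
    }
  })
})

test_that("apply_rule counts evaluable records per missing-data policy", {
  ds <- make_tiny_dataset(n = 10, cases = 3)
  ds$records$dyspnea[c(2, 5)] <- NA
  res <- apply_rule(ds, default_rules()$FSDT)
  expect_equal(evaluable_count(res), 8)
  expect_equal(attr(res, "not_evaluable_n"), 2)
  res2 <- apply_rule(ds, default_rules()$FSDT, missing_policy = "missing_as_absent")
  expect_equal(evaluable_count(res2), 10)
  # per-record results export
  path <- withr::local_tempfile(fileext = ".csv")
  write_rule_results(res, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(out), 10)
  expect_true(all(c("record_id", "rule_id", "classification", "provenance") %in% names(out)))
})

test_that("rules and proxy maps survive a YAML round trip", {
  rules <- default_rules()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rules_yaml(rules, path)
  rules2 <- read_rules_yaml(path)
  expect_identical(names(rules2), names(rules))
  expect_identical(rules2$YOS$cutoffs, c(8, 10))
  expect_identical(rules2$FSDT$required_variables, rules$FSDT$required_variables)
})
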