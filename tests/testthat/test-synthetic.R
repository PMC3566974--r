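test_that("preset profiles reproduce the printed dataset sizes and prevalences", {
  want <- list(vandenbruel = c(4102, 33), roukema = c(1750, 216),
               bleeker = c(595, 137), monteny = c(506, 20),
               brent = c(2777, 147), thompson = c(700, 264),
               oostenbrink = c(593, 260))
  for (nm in names(want)) {
    p <- preset_profile(nm)
    expect_equal(c(p$n, p$cases), want[[nm]], info = nm)
    expect_equal(sum(p$components), p$cases, info = nm)
  }
  # printed prevalences at one decimal
  expect_equal(round_half_away(100 * 20 / 506, 1), 4.0)
  expect_equal(round_half_away(100 * 264 / 700, 1), 37.7)
  expect_equal(round_half_away(100 * 260 / 593, 1), 43.8)
  expect_error(preset_profile("nosuch"), "unknown preset")
})

test_that("generated presets have exactly the profile's case count", {
  for (nm in c("monteny", "thompson")) {
    p <- preset_profile(nm)
    ds <- generate(p, seed = 77)
    expect_equal(n_records(ds), p$n)
    expect_equal(sum(ds$records$serious_infection), p$cases)
    comp <- colSums(ds$records[outcome_components()])
    expect_equal(comp[names(p$components)], as.double(p$components),
                 ignore_attr = TRUE)
  }
})

test_that("generation is deterministic in the seed", {
  p <- preset_profile("monteny")
  d1 <- generate(p, seed = 5)
  d2 <- generate(p, seed = 5)
  d3 <- generate(p, seed = 6)
  expect_identical(d1$records, d2$records)
  expect_false(identical(d1$records, d3$records))
})

test_that("generated ages respect the truncated age model", {
  p <- preset_profile("bleeker")
  ds <- generate(p, seed = 4)
  a <- ds$records$age_months
  expect_gte(min(a), p$age_model$min_months - 0.06)  # values rounded to 0.1
  expect_lte(max(a), p$age_model$max_months + 0.06)
  # window mass matches the analytic value at generation scale
  big <- generate(scale_profile(p, 20000), seed = 4)
  q <- mean(big$records$age_months >= 15 & big$records$age_months < 30)
  expect_equal(q, age_window_mass(p$age_model), tolerance = 0.02)
})

test_that("missingness injection hits the requested rates and spares outcomes", {
  p <- scale_profile(preset_profile("monteny"), 1000)
  p$missingness <- numeric()
  ds <- generate(p, seed = 9)
  expect_equal(sum(is.na(as.matrix(ds$records[recorded_variables(ds)]))), 0)

  ds0 <- inject_missingness(ds, c(heart_rate = 0), seed = 1)
  expect_identical(ds0$records, ds$records)
  ds1 <- inject_missingness(ds, c(heart_rate = 1), seed = 1)
  expect_true(all(is.na(ds1$records$heart_rate)))

  ds2 <- inject_missingness(ds, c(heart_rate = 0.48), seed = 2)
  emp <- mean(is.na(ds2$records$heart_rate))
  expect_lt(abs(emp - 0.48), 3 * sqrt(0.48 * 0.52 / 1000))
  expect_false(any(is.na(ds2$records$serious_infection)))
  expect_false(any(is.na(ds2$records$age_months)))

  # MNAR option raises missingness among cases
  ds3 <- inject_missingness(ds, c(heart_rate = 0.3), seed = 3, mnar_odds = 4)
  si <- ds3$records$serious_infection == 1
  expect_gt(mean(is.na(ds3$records$heart_rate[si])),
            mean(is.na(ds3$records$heart_rate[!si])))
})

test_that("any-of calibration inverts and recovers its targets analytically", {
  expect_equal(calibrate_any_of(0.9, 0.5, 1)$p_pos, 0.9)
  expect_equal(calibrate_any_of(0.5, 0.81, 2)$p_neg, 0.1, tolerance = 1e-12)
  cal <- calibrate_any_of(0.9, 0.5, 3)
  expect_equal(cal$p_pos, 1 - 0.1^(1 / 3), tolerance = 1e-12)
  # forward any-of evaluation returns the targets exactly
  expect_equal(1 - (1 - cal$p_pos)^3, 0.9, tolerance = 1e-12)
  expect_equal((1 - cal$p_neg)^3, 0.5, tolerance = 1e-12)
  expect_error(calibrate_any_of(0.9, 0.5, 0))
})

test_that("the pipeline recovers calibration targets on large generated samples", {
  # seed-averaged estimates within 3 exact-binomial SEs (single-replicate
  # size) of the targets; the full 20-seed sweep runs in the acceptance suite
  for (nm in c("monteny", "thompson")) {
    p <- preset_profile(nm)
    est <- vapply(1:5, function(s) {
      r <- recover_calibration(p, seed = 100 + s, n = 10000)
      c(r$sens_hat, r$spec_hat)
    }, numeric(2))
    r1 <- recover_calibration(p, seed = 101, n = 10000)
    expect_lt(abs(mean(est[1, ]) - r1$sens_target), 3 * r1$se_sens)
    expect_lt(abs(mean(est[2, ]) - r1$spec_target), 3 * r1$se_spec)
  }
})

test_that("confidence intervals cover the calibration targets across replicates", {
  p <- scale_profile(preset_profile("monteny"), 2000)
  rule <- default_rules()$FSDT
  hit_sens <- hit_spec <- logical(200)
  for (s in seq_len(200)) {
    ds <- generate(p, seed = 5000 + s)
    res <- apply_rule(ds, rule, check_eligible = FALSE)
    keep <- res$classification != "not_evaluable"
    truth <- ds$records$serious_infection[keep] == 1
    tab <- build_contingency(truth, res$classification[keep])
    se_ci <- clopper_pearson_ci(tab$tp, tab$n1)
    sp_ci <- clopper_pearson_ci(tab$tn, tab$n0)
    hit_sens[s] <- se_ci$ci_low <= p$calibration$sens && p$calibration$sens <= se_ci$ci_high
    hit_spec[s] <- sp_ci$ci_low <= p$calibration$spec && p$calibration$spec <= sp_ci$ci_high
  }
  expect_gte(mean(hit_sens), 0.93)
  expect_gte(mean(hit_spec), 0.93)
})

test_that("profiles survive a YAML round trip", {
  p <- preset_profile("oostenbrink")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_profile_yaml(p, path)
  p2 <- read_profile_yaml(path)
  expect_equal(p2$n, p$n)
  expect_equal(p2$components, p$components)
  expect_equal(p2$calibration$sens, p$calibration$sens)
  expect_equal(p2$age_model, p$age_model, tolerance = 1e-9)
  expect_identical(generate(p2, 3)$records$serious_infection,
                   generate(p, 3)$records$serious_infection)
})

test_that("infeasible profiles are rejected", {
  expect_error(dataset_profile("bad", "GP", "XX", n = 10, cases = 20,
                               components = c(sepsis = 20),
                               age_model = list(meanlog = 3, sdlog = 0.5,
                                                min_months = 1, max_months = 100),
                               recorded = "temperature",
                               calibration = list(rule_id = "FSDT", sens = 0.9, spec = 0.5)))
  expect_error(dataset_profile("bad", "GP", "XX", n = 10, cases = 2,
                               components = c(sepsis = 1),
                               age_model = list(meanlog = 3, sdlog = 0.5,
                                                min_months = 1, max_months = 100),
                               recorded = "temperature",
                               calibration = list(rule_id = "FSDT", sens = 0.9, spec = 0.5)),
               "sum")
})
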