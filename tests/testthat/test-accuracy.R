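test_that("contingency construction counts cells correctly", {
  t <- build_contingency(c(1, 1, 0, 0), c("positive", "negative", "positive", "negative"))
  expect_equal(c(t$tp, t$fn, t$fp, t$tn), c(1, 1, 1, 1))
  t <- build_contingency(c(1, 0, 1), rep("positive", 3))
  expect_equal(c(t$fn, t$tn), c(0, 0))
  expect_error(build_contingency(logical(), character()), "empty")
  expect_error(build_contingency(c(1, 0), c("positive", "not_evaluable")), "not_evaluable")
  # all-diseased input is flagged degenerate
  expect_true(build_contingency(c(1, 1), c("positive", "negative"))$degenerate)
})

test_that("Wald intervals reproduce reported prevalence bounds", {
  pct1 <- function(pe) round_half_away(100 * c(pe$ci_low, pe$ci_high), 1)
  expect_equal(pct1(wald_ci(264, 700)), c(34.1, 41.3))
  expect_equal(pct1(wald_ci(137, 595)), c(19.6, 26.4))
  expect_equal(pct1(wald_ci(20, 506)), c(2.3, 5.7))
  # degenerate boundary clips to [0, 1]
  w0 <- wald_ci(0, 100)
  expect_equal(c(w0$ci_low, w0$ci_high), c(0, 0))
})

test_that("exact binomial intervals match closed forms and printed values", {
  pe <- clopper_pearson_ci(18, 20)
  expect_equal(round_half_away(100 * c(pe$ci_low, pe$ci_high)), c(68, 99))
  pe <- clopper_pearson_ci(3, 3)
  expect_equal(pe$ci_low, 0.025^(1 / 3), tolerance = 1e-10)
  expect_equal(pe$ci_high, 1)
  pe <- clopper_pearson_ci(0, 5)
  expect_equal(pe$ci_low, 0)
  expect_equal(pe$ci_high, 1 - 0.025^(1 / 5), tolerance = 1e-10)
})

test_that("exact binomial intervals equal the tail root-finder for all x <= n <= 30", {
  for (n in 1:30) for (x in 0:n) {
    got <- clopper_pearson_ci(x, n)
    want <- cp_oracle(x, n)
    expect_equal(c(got$ci_low, got$ci_high), want, tolerance = 1e-6,
                 info = sprintf("x=%d n=%d", x, n))
    expect_true(got$ci_low <= got$point && got$point <= got$ci_high)
  }
})

test_that("exact binomial coverage is at least nominal", {
  # exact enumeration over the binomial support (deterministic form)
  for (n in c(10, 25, 40)) for (p in c(0.05, 0.3, 0.5, 0.9)) {
    cov <- sum(vapply(0:n, function(x) {
      ci <- clopper_pearson_ci(x, n)
      stats::dbinom(x, n, p) * (ci$ci_low <= p && p <= ci$ci_high)
    }, numeric(1)))
    expect_gte(cov, 0.95)
  }
  # empirical check at 10,000 replicates
  withr::with_seed(2024, {
    for (p in c(0.1, 0.5, 0.9)) {
      x <- stats::rbinom(10000, 25, p)
      hit <- vapply(x, function(xi) {
        ci <- clopper_pearson_ci(xi, 25)
        ci$ci_low <= p && p <= ci$ci_high
      }, logical(1))
      expect_gte(mean(hit), 0.95)
    }
  })
})

test_that("likelihood ratios reproduce the reconstructed low-prevalence table", {
  t <- two_by_two(tp = 18, fp = 273, fn = 2, tn = 213)
  lr <- likelihood_ratios(t)
  expect_equal(round_half_away(lr$lr_neg$point, 1), 0.2)
  expect_equal(round_half_away(lr$lr_neg$ci_low, 1), 0.1)
  expect_equal(round_half_away(lr$lr_neg$ci_high, 1), 0.9)
  expect_false(lr$lr_neg$flagged)
  # uninformative test: sens = spec = 0.5
  lr <- likelihood_ratios(two_by_two(10, 10, 10, 10))
  expect_equal(lr$lr_pos$point, 1)
  expect_equal(lr$lr_neg$point, 1)
  # perfect test triggers the zero-cell continuity policy
  lr <- likelihood_ratios(two_by_two(tp = 20, fp = 0, fn = 0, tn = 80))
  expect_true(lr$lr_neg$flagged)
  expect_lt(lr$lr_neg$point, 0.05)
})

test_that("accuracy profiles assemble all estimates coherently", {
  t <- two_by_two(tp = 18, fp = 273, fn = 2, tn = 213)
  p <- accuracy_profile(t)
  expect_equal(round_half_away(100 * p$sensitivity$point), 90)
  expect_equal(round_half_away(100 * c(p$sensitivity$ci_low, p$sensitivity$ci_high)),
               c(68, 99))
  expect_equal(p$positive_fraction, (18 + 273) / 506)
  expect_equal(p$stratum, "LP")
  # perfect table
  p1 <- accuracy_profile(two_by_two(5, 0, 0, 5))
  expect_equal(p1$sensitivity$point, 1)
  expect_equal(p1$specificity$point, 1)
  # symmetry: tp = tn, fp = fn implies sens = spec
  ps <- accuracy_profile(two_by_two(30, 7, 7, 30))
  expect_equal(ps$sensitivity$point, ps$specificity$point)
})

test_that("predictive values agree with Bayes on sens/spec/prevalence", {
  withr::with_seed(9, {
    for (k in 1:20) {
      t <- two_by_two(sample(1:50, 1), sample(1:50, 1), sample(1:50, 1), sample(1:50, 1))
      p <- accuracy_profile(t)
      prev <- p$prevalence$point
      sens <- p$sensitivity$point; spec <- p$specificity$point
      ppv_bayes <- sens * prev / (sens * prev + (1 - spec) * (1 - prev))
      npv_bayes <- spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)
      expect_equal(p$ppv$point, ppv_bayes, tolerance = 1e-12)
      expect_equal(p$npv$point, npv_bayes, tolerance = 1e-12)
    }
  })
})

test_that("post-test probabilities follow the odds arithmetic", {
  expect_equal(round(post_test_probability(0.04, 0.228), 4), 0.0094)
  expect_equal(post_test_probability(0.3, 1), 0.3)
  expect_equal(post_test_probability(0.5, 3), 0.75)
  expect_error(post_test_probability(0, 2))
  # ordering whenever lr_pos >= 1 >= lr_neg
  withr::with_seed(4, {
    for (k in 1:20) {
      p <- runif(1, 0.01, 0.99)
      lp <- runif(1, 1, 20); ln <- runif(1, 0, 1)
      expect_gte(post_test_probability(p, lp), p)
      expect_lte(post_test_probability(p, ln), p)
    }
  })
})

test_that("dumbbell points sit around the pre-test probability", {
  p <- accuracy_profile(two_by_two(18, 273, 2, 213))
  d <- dumbbell_point(p)
  expect_lt(d$post_negative, d$pretest)
  expect_gt(d$post_positive, d$pretest)
  # uninformative test leaves all three equal
  pu <- accuracy_profile(two_by_two(10, 10, 10, 10))
  du <- dumbbell_point(pu)
  expect_equal(du$post_positive, du$pretest)
  expect_equal(du$post_negative, du$pretest)
  # lr_neg of zero sends the post-negative probability to zero (no correction)
  expect_equal(post_test_probability(0.3, 0), 0)
})

test_that("rank AUC equals exhaustive pair counting", {
  expect_equal(auc_rank(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc_rank(rep(3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_error(auc_rank(1:3, c(1, 1, 1)), "both classes")
  withr::with_seed(11, {
    for (k in 1:40) {
      n <- sample(3:12, 1)
      scores <- sample(1:5, n, replace = TRUE)  # deliberate ties
      truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      expect_equal(auc_rank(scores, truth), auc_oracle(scores, truth),
                   info = paste(n, k))
    }
  })
})

test_that("prevalence strata split at 5% and 20%", {
  expect_equal(assign_stratum(0.008), "LP")
  expect_equal(assign_stratum(0.123), "IP")
  expect_equal(assign_stratum(0.377), "HP")
  expect_equal(assign_stratum(0.05), "IP")
  expect_equal(assign_stratum(0.20), "IP")
  expect_equal(assign_stratum(0.201), "HP")
})

test_that("rule-out criterion needs sensitivity > 90% and NLR <= 0.2", {
  mk <- function(sens_pt, nlr_pt) {
    p <- accuracy_profile(two_by_two(18, 273, 2, 213))
    p$sensitivity$point <- sens_pt
    p$lr_neg$point <- nlr_pt
    p
  }
  expect_true(rule_out_assessment(mk(0.94, 0.15))$rule_out)
  r <- rule_out_assessment(mk(0.90, 0.15))
  expect_false(r$rule_out)
  expect_match(r$reasons, "sensitivity")
  r <- rule_out_assessment(mk(0.95, 0.3))
  expect_false(r$rule_out)
  expect_match(r$reasons, "likelihood")
})
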