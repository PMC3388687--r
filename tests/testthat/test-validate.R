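test_that("c-index equals brute-force pair counting", {
  expect_equal(c_index(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  expect_equal(c_index(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(c_index(rep(2, 10), rep(0:1, 5)), 0.5)
  set.seed(41)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    score <- sample(0:10, n, replace = TRUE)  # heavy ties on purpose
    outcome <- rbinom(n, 1, 0.3)
    if (length(unique(outcome)) < 2) next
    expect_equal(c_index(score, outcome), brute_c_index(score, outcome))
  }
  expect_error(c_index(1:5, rep(1, 5)), "both outcome classes")
})

test_that("c-index agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  score <- rnorm(300)
  outcome <- rbinom(300, 1, plogis(score))
  auc <- as.numeric(pROC::auc(pROC::roc(outcome, score, quiet = TRUE)))
  expect_equal(c_index(score, outcome), auc, tolerance = 1e-10)
})

test_that("likelihood R-squared statistics follow their formulas", {
  r2 <- logistic_r2(-100, -80, 200)
  expect_equal(r2$r2_generalized, 1 - exp(-0.2), tolerance = 1e-12)
  expect_equal(r2$r2_max_rescaled, (1 - exp(-0.2)) / (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(unlist(logistic_r2(-50, -50, 100)), c(r2_generalized = 0,
                                                     r2_max_rescaled = 0))
  # max-rescaled approaches 1 for a saturated balanced fit
  n <- 100
  ll0 <- n * log(0.5)
  sat <- logistic_r2(ll0, -1e-8, n)
  expect_gt(sat$r2_max_rescaled, 0.999)
  # monotone in the model log-likelihood
  vals <- sapply(seq(-95, -60, by = 5),
                 function(l1) logistic_r2(-100, l1, 150)$r2_max_rescaled)
  expect_true(all(diff(vals) > 0))
  expect_error(logistic_r2(-10, -20, 50), "loglik_model")
  expect_error(logistic_r2(-10, -5, 0), "positive")
})

test_that("Hosmer-Lemeshow keeps ties together and flags miscalibration", {
  set.seed(43)
  p <- runif(2000, 0.05, 0.6)
  y <- rbinom(2000, 1, p / 2)  # predictions systematically doubled
  hl <- hosmer_lemeshow(p, y)
  expect_lt(hl$p, 0.001)
  expect_equal(hl$df, nrow(hl$groups) - 2)
  # heavy ties reduce the group count and the df follows
  p_tied <- rep(c(0.1, 0.2, 0.3, 0.4), each = 100)
  y_tied <- rbinom(400, 1, p_tied)
  hl_tied <- hosmer_lemeshow(p_tied, y_tied, g = 10)
  expect_equal(nrow(hl_tied$groups), 4)
  expect_equal(hl_tied$df, 2)
  expect_error(hosmer_lemeshow(rep(c(0.2, 0.4), 50), rbinom(100, 1, 0.3)),
               "3 risk groups")
  expect_error(hosmer_lemeshow(c(0, runif(99)), rbinom(100, 1, 0.3)),
               "in \\(0, 1\\)")
})

test_that("VIF matches the closed form and flags exact collinearity", {
  set.seed(44)
  n <- 4000
  x1 <- rnorm(n)
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n)
  v <- vif(cbind(a = x1, b = x2))
  r2 <- summary(lm(x2 ~ x1))$r.squared
  expect_equal(unname(v["b"]), 1 / (1 - r2), tolerance = 1e-10)
  expect_equal(unname(v["b"]), 1.5625, tolerance = 0.15)
  orth <- vif(cbind(a = rnorm(100), b = rnorm(100), c = rnorm(100)))
  expect_true(all(orth < 1.2))
  dup <- suppressWarnings(vif(cbind(a = x1, b = x1)))
  expect_true(all(!is.finite(dup)))
})

test_that("VIF agrees with the car implementation on a fitted model", {
  skip_if_not_installed("car")
  co <- simulate_cohort(synthetic_config(n = 1500, seed = 45))
  vars <- c("age", "apache2", "sofa", "n_comorbid", "days_hosp_to_icu", "il6")
  ours <- vif(co[, vars])
  fit <- lm(mort28 ~ age + apache2 + sofa + n_comorbid + days_hosp_to_icu +
              il6, data = co)
  theirs <- car::vif(fit)
  expect_equal(unname(ours[vars]), unname(theirs[vars]), tolerance = 1e-8)
})

test_that("split-half cross-validation is deterministic with balanced halves", {
  co <- simulate_cohort(synthetic_config(n = 598, seed = 46))
  cv1 <- split_half_cv(co, seed = 9)
  cv2 <- split_half_cv(co, seed = 9)
  expect_identical(cv1$idx_a, cv2$idx_a)
  expect_equal(length(cv1$idx_a), 299)
  expect_equal(cv1$n - length(cv1$idx_a), 299)
  for (h in c("A", "B")) {
    r <- cv1$halves[[h]]
    if (is.null(r$error)) {
      expect_true(r$c_out > 0.5 && r$c_out <= 1)
    }
  }
  cv3 <- split_half_cv(co, seed = 10)
  expect_false(identical(cv1$idx_a, cv3$idx_a))
})

test_that("out-of-sample discrimination tracks in-sample on large cohorts", {
  diffs <- sapply(1:10, function(i) {
    co <- simulate_cohort(synthetic_config(n = 5000, seed = 400 + i))
    cv <- split_half_cv(co, seed = i, candidates = nutric_score_variables())
    c(cv$halves$A$c_in - cv$halves$A$c_out,
      cv$halves$B$c_in - cv$halves$B$c_out)
  })
  # the derivation barely overfits: optimism stays near the noise floor of a
  # half-cohort c-index estimate, and no half drifts far out of sample
  expect_lt(mean(diffs), 0.035)
  expect_lt(max(abs(diffs)), 0.07)
})

test_that("comparison models rank as the data generation dictates", {
  co <- simulate_cohort(synthetic_config(n = 3000, seed = 47))
  cmp <- compare_models(co)
  expect_equal(nrow(cmp), 4)
  c_score <- cmp$c_index[cmp$model == "score_single_predictor"]
  c_full <- cmp$c_index[cmp$model == "all_six_variables"]
  # the single-predictor score model keeps pace with the six-variable model
  expect_lt(abs(c_score - c_full), 0.03)
  expect_true(all(cmp$c_index > 0.65))

  set.seed(48)
  null <- data.frame(age = runif(2000, 20, 90), apache2 = runif(2000, 0, 40),
                     sofa = runif(2000, 0, 15), n_comorbid = sample(0:5, 2000, TRUE),
                     days_hosp_to_icu = rlnorm(2000), il6 = rlnorm(2000, 4.7, 1),
                     mort28 = rbinom(2000, 1, 0.25))
  cmp_null <- compare_models(null)
  expect_true(all(abs(cmp_null$c_index - 0.5) < 0.05))

  det <- null
  det$mort28 <- as.integer(det$age > 60)
  cmp_det <- compare_models(det)
  expect_true(all(cmp_det$c_index[cmp_det$model != "score_single_predictor"]
                  > 0.95))
})

test_that("the consolidated validation report is coherent", {
  co <- simulate_cohort(synthetic_config(n = 598, seed = 49))
  val <- suppressWarnings(validate_score(co, seed = 3))
  expect_gte(val$r2_max_rescaled, val$r2_generalized)
  expect_true(val$c_index > 0.5 && val$c_index < 1)
  expect_true(inherits(val$hl, "hl_test"))
  # expected deaths across H-L groups sum to the model's predicted total,
  # which for an ML logistic fit with intercept equals the observed total
  expect_equal(sum(val$hl$groups$expected), sum(val$hl$groups$observed),
               tolerance = 1e-6)
  expect_equal(sum(val$hl$groups$n), val$n)
  expect_true(all(val$calibration$observed >= 0 &
                    val$calibration$observed <= 1))
  expect_output(print(val), "c-index")
})
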