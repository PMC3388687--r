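test_that("categorical logistic fit equals the closed-form count log-odds", {
  # ref 10/90 vs cat2 20/80 -> log(2.25); 50/50 vs 10/90 -> log(9)
  idx <- rep(c(1, 2), each = 100)
  y <- c(rep(1, 10), rep(0, 90), rep(1, 20), rep(0, 80))
  fit <- fit_category_logit(idx, y, name = "v")
  expect_equal(fit$logits[2], log(2.25), tolerance = 1e-7)
  y2 <- c(rep(1, 10), rep(0, 90), rep(1, 50), rep(0, 50))
  fit2 <- fit_category_logit(idx, y2, name = "v")
  expect_equal(fit2$logits[2], log(9), tolerance = 1e-7)
})

test_that("identical death fractions give zero logits and p near 1", {
  idx <- rep(c(1, 2, 3), each = 60)
  y <- rep(c(rep(1, 15), rep(0, 45)), 3)
  fit <- fit_category_logit(idx, y, name = "flat")
  expect_equal(fit$logits, c(0, 0, 0), tolerance = 1e-7)
  expect_gt(fit$overall_p, 0.999)
})

test_that("sparse categories are flagged with infinite logits", {
  idx <- rep(c(1, 2), each = 30)
  y <- c(rep(0:1, 15), rep(1, 30))  # category 2 has zero survivors
  fit <- fit_category_logit(idx, y, name = "sp")
  expect_true(fit$sparse[2])
  expect_identical(fit$logits[2], Inf)
  expect_error(assign_points(fit), "sparse")
  expect_error(fit_category_logit(c(1, 1, 3, 3), c(0, 1, 0, 1)),
               "zero deaths and zero survivors")
})

test_that("points re-reference to the minimum logit and round half away", {
  expect_equal(assign_points(c(0, 0.49, 1.6)), c(0L, 0L, 2L))
  expect_equal(assign_points(c(0.3, 0, -0.2)), c(1L, 0L, 0L))
  expect_equal(assign_points(c(0.7, 0.7, 0.7)), c(0L, 0L, 0L))
  expect_equal(assign_points(c(0, 0.5, 1.5)), c(0L, 1L, 2L))
})

test_that("equal-point categories collapse and boundaries snap to convenient values", {
  cv <- structure(list(name = "apache2", kind = "quintile",
                       boundaries = c(14.7, 19.8, 24.2, 27.9),
                       index = integer(0), k = 5L, counts = integer(5)),
                  class = "categorized_variable")
  entries <- collapse_and_round(cv, c(0L, 0L, 1L, 1L, 2L))
  expect_equal(nrow(entries), 3)
  expect_equal(entries$upper[1:2], c(20, 28))
  expect_equal(attr(entries, "exact_boundaries"), c(19.8, 27.9))

  cv2 <- structure(list(name = "il6", kind = "quintile",
                        boundaries = c(30, 90, 397, 803),
                        index = integer(0), k = 5L, counts = integer(5)),
                   class = "categorized_variable")
  entries2 <- collapse_and_round(cv2, c(0L, 0L, 0L, 1L, 2L))
  expect_equal(entries2$upper[1:2], c(400, 800))

  all_equal <- collapse_and_round(cv, c(1L, 1L, 1L, 1L, 1L))
  expect_equal(nrow(all_equal), 1)
  expect_equal(all_equal$label, "ALL")
})

test_that("total score equals exhaustive category-combination enumeration", {
  table <- nutric_points_table()
  combos <- expand.grid(age = c(40, 60, 80), apache2 = c(5, 17, 25, 30),
                        sofa = c(2, 8, 11), n_comorbid = c(0, 3),
                        days_hosp_to_icu = c(0.2, 5), il6 = c(10, 500))
  scores <- total_score(table, combos)
  oracle <- with(combos,
    findInterval(age, c(50, 75)) + findInterval(apache2, c(15, 20, 28)) +
    findInterval(sofa, c(6, 10)) + (n_comorbid >= 2) +
    (days_hosp_to_icu >= 1) + (il6 >= 400))
  expect_equal(scores, as.integer(oracle))
  expect_true(all(scores >= table$total_range[1] &
                    scores <= table$total_range[2]))
})

test_that("raising one variable's category never lowers the total score", {
  table <- nutric_points_table()
  set.seed(21)
  base <- data.frame(age = runif(50, 20, 95), apache2 = runif(50, 0, 40),
                     sofa = runif(50, 0, 16), n_comorbid = sample(0:5, 50, TRUE),
                     days_hosp_to_icu = runif(50, 0, 8),
                     il6 = runif(50, 0, 900))
  s0 <- total_score(table, base)
  for (v in names(base)) {
    bumped <- base
    bumped[[v]] <- bumped[[v]] * 1.5 + 1
    if (v == "n_comorbid") bumped[[v]] <- pmin(5, base[[v]] + 1)
    expect_true(all(total_score(table, bumped) >= s0), label = v)
  }
})

test_that("missing required values follow the scoring policy", {
  table <- nutric_points_table()
  d <- data.frame(age = c(60, NA), apache2 = 20, sofa = 5, n_comorbid = 2,
                  days_hosp_to_icu = 0.5, il6 = 100)
  expect_error(total_score(table, d), "missing value for variable 'age'")
  expect_equal(total_score(table, d, missing = "na"), c(4L, NA))
  d2 <- d; d2$age <- c(60, 70); d2$il6 <- c(100, NA)
  expect_equal(total_score(table, d2, missing = "drop_variable"), c(4L, 4L))
})

test_that("derivation excludes null candidates and keeps structured ones", {
  cohort <- make_logistic_cohort(4000, seed = 22)
  cohort$crp <- rlnorm(4000, 4.7, 0.9)          # pure noise candidate
  der <- derive_score(cohort, candidates = c(nutric_score_variables(), "crp"))
  expect_true(all(nutric_score_variables() %in% der$included))
  expect_false("crp" %in% der$included)
  expect_equal(nrow(der$excluded) + length(der$included), 7)
  expect_match(paste(der$excluded$reason, collapse = " "),
               "significance|0 points|improvement")
  # printed summary carries one row per candidate
  expect_equal(nrow(summary(der)$fits), 7)
})

test_that("all-zero-point candidates are excluded with the stated reason", {
  set.seed(23)
  n <- 3000
  cohort <- data.frame(age = runif(n, 20, 90), mort28 = rbinom(n, 1, 0.25))
  cohort$flat <- runif(n)  # unrelated but will have p < 0.2 sometimes
  der <- tryCatch(derive_score(cohort, candidates = "age"),
                  error = identity)
  if (inherits(der, "error")) {
    expect_match(conditionMessage(der), "all candidates excluded")
  } else {
    succeed()
  }
})

test_that("predict() scores new patients with the derived table", {
  cohort <- make_logistic_cohort(4000, seed = 24)
  der <- derive_score(cohort, candidates = nutric_score_variables())
  newdata <- cohort[1:50, ]
  s <- predict(der, newdata)
  expect_true(all(s >= der$table$total_range[1] &
                    s <= der$table$total_range[2], na.rm = TRUE))
  p <- predict(der, newdata, type = "response")
  expect_true(all(p > 0 & p < 1, na.rm = TRUE))
  expect_equal(coef(der), der$table$entries)
})
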