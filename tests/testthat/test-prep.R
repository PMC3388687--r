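test_that("quintile binning matches the sort-and-split oracle", {
  cv <- quintile_bin(1:10, name = "x")
  expect_equal(cv$index, rep(1:5, each = 2))
  expect_equal(cv$k, 5)
  expect_error(quintile_bin(rep(3, 20)), "distinct")
  expect_error(quintile_bin(c(1, 2, 3, 4)), "distinct")
})

test_that("quintiles of uniform draws are near-equal in size", {
  set.seed(11)
  cv <- quintile_bin(runif(10000), name = "u")
  expect_true(all(abs(cv$counts - 2000) <= 100))
  expect_equal(sum(cv$counts), 10000)
})

test_that("categorization is total, idempotent, and respects half-open cuts", {
  set.seed(12)
  x <- c(rnorm(500), NA, NA)
  cv <- quintile_bin(x, name = "x")
  expect_equal(sum(cv$counts), 500)
  expect_true(all(is.na(cv$index[is.na(x)])))
  # a value equal to a cut-point goes to the upper category (half-open [a, b)):
  # type-7 quantiles of 0:100 fall exactly on 20/40/60/80
  cv_int <- quintile_bin(c(0:100, NA), name = "grid")
  expect_equal(cv_int$boundaries, c(20, 40, 60, 80))
  expect_equal(cv_int$index[c(20, 40, 60, 80) + 1], 2:5)
  expect_equal(cv_int$index[c(19, 39, 59, 79) + 1], 1:4)
  # re-binning category representatives reproduces the categories
  expect_equal(findInterval(x, cv$boundaries) + 1L,
               ifelse(is.na(x), NA_integer_, cv$index))
})

test_that("BMI dichotomization uses strictly-less-than 20 with missing as other", {
  cv <- dichotomize_bmi(c(19.9, 20.0, 35, NA))
  expect_equal(cv$index, c(2L, 1L, 1L, 1L))
  expect_error(dichotomize_bmi(-1), "bmi")
})

test_that("oral-intake and weight-loss rules and their sensitivity recodings", {
  oral <- dichotomize_oral_intake(c(100, NA, 50))
  expect_equal(oral$index, c(1L, 1L, 2L))
  oral_s <- dichotomize_oral_intake(c(100, NA, 50), sensitivity = TRUE)
  expect_equal(oral_s$index, c(1L, 2L, 2L))
  expect_error(dichotomize_oral_intake(120), "\\[0, 100\\]")

  wl <- dichotomize_weight_loss(c(2.5, 0, NA))
  expect_equal(wl$index, c(2L, 1L, 1L))
  wl_s <- dichotomize_weight_loss(c(2.5, 0, NA), sensitivity = TRUE)
  expect_equal(wl_s$index, c(2L, 1L, 2L))
  expect_error(dichotomize_weight_loss(-0.5), "weight_loss")

  # sensitivity recoding only ever changes missing entries
  set.seed(13)
  pct <- ifelse(runif(200) < 0.5, NA, round(runif(200, 0, 100)))
  a <- dichotomize_oral_intake(pct)$index
  b <- dichotomize_oral_intake(pct, sensitivity = TRUE)$index
  expect_true(all(a[!is.na(pct)] == b[!is.na(pct)]))
})

test_that("group comparison reproduces the closed-form Pearson chi-square", {
  # counts as printed for comorbidity burden by survival status
  tab <- matrix(c(20, 118, 140, 319), nrow = 2,
                dimnames = list(comorbid = c("0-1", "2+"),
                                dead = c("yes", "no")))
  oracle <- {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  x <- rep(rep(c("0-1", "2+"), 2), times = c(20, 118, 140, 319))
  g <- rep(c(1, 1, 0, 0), times = c(20, 118, 140, 319))
  cmp <- compare_groups(factor(x), g)
  expect_equal(cmp$statistic, oracle, tolerance = 1e-10)
  expect_equal(cmp$test, "chi-square")
})

test_that("group comparison detects a large continuous shift and not a null", {
  set.seed(14)
  x <- c(rnorm(100), rnorm(100, mean = 3))
  g <- rep(0:1, each = 100)
  cmp <- compare_groups(x, g)
  expect_equal(cmp$test, "wilcoxon")
  expect_lt(cmp$p, 0.001)
  expect_equal(unname(cmp$summary[, "n"]), c(100, 100))

  same <- compare_groups(c(rnorm(50)), rep(0:1, 25))
  expect_gt(same$p, 0.01)
  expect_error(compare_groups(rnorm(10), rep(1, 10)), "two non-empty groups")
})
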