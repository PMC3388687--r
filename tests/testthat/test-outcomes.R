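test_that("Spearman correlation matches the rank-formula hand computation", {
  expect_equal(spearman_test(1:4, c(1, 3, 2, 4))$rho, 0.8)
  expect_equal(spearman_test(1:10, 1:10)$rho, 1)
  expect_equal(spearman_test(1:10, 10:1)$rho, -1)
  expect_equal(spearman_test(1:10, 1:10)$p, 0)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:2, 1:2), "at least 3")
  # pairwise-complete handling reports the effective n
  x <- c(1:8, NA, 10); y <- c(NA, 2:10)
  expect_equal(spearman_test(x, y)$n, 8)
})

test_that("Spearman rho agrees with the reference implementation under ties", {
  set.seed(51)
  x <- sample(0:10, 200, replace = TRUE)
  y <- x + sample(-3:3, 200, replace = TRUE)
  expect_equal(spearman_test(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("adequacy drops the final partial day unless the stay reaches day 14", {
  co <- data.frame(patient_id = "X", icu_days = 4, energy_prescribed = 2000,
                   mv_start_within_48h = 1, stringsAsFactors = FALSE)
  co$energy_received_daily <- list(c(1000, 1500, 2000, 500))
  adq <- adequacy(co)
  expect_equal(adq$counted_days, 3)
  expect_equal(adq$pct_received, 75)
  expect_true(adq$eligible)

  co14 <- data.frame(patient_id = "Y", icu_days = 14, energy_prescribed = 1000,
                     mv_start_within_48h = 1, stringsAsFactors = FALSE)
  co14$energy_received_daily <- list(rep(800, 14))
  adq14 <- adequacy(co14)
  expect_equal(adq14$counted_days, 14)  # day 14 included
  expect_equal(adq14$pct_received, 80)

  short <- data.frame(patient_id = "Z", icu_days = 2, energy_prescribed = 1500,
                      mv_start_within_48h = 1, stringsAsFactors = FALSE)
  short$energy_received_daily <- list(c(900, 400))
  adq_s <- adequacy(short)
  expect_false(adq_s$eligible)
  expect_match(adq_s$reason, "3 days")

  bad <- co; bad$energy_prescribed <- 0
  expect_error(adequacy(bad), "prescription")
})

test_that("adequacy is invariant to common rescaling of intake and prescription", {
  co <- data.frame(patient_id = "X", icu_days = 6, energy_prescribed = 1800,
                   mv_start_within_48h = 1, stringsAsFactors = FALSE)
  co$energy_received_daily <- list(c(500, 900, 1300, 1500, 1700, 600))
  scaled <- co
  scaled$energy_prescribed <- co$energy_prescribed * 3.7
  scaled$energy_received_daily <- list(co$energy_received_daily[[1]] * 3.7)
  expect_equal(adequacy(co)$pct_received, adequacy(scaled)$pct_received,
               tolerance = 1e-12)
})

test_that("MV-duration regression and its pure-error lack-of-fit test", {
  # exactly linear means with replicates: lack-of-fit F is 0
  score <- rep(0:6, each = 5)
  mv <- 2 + 1.5 * score
  fit <- suppressWarnings(mv_duration_model(score, mv))
  expect_equal(fit$lof_F, 0, tolerance = 1e-10)
  expect_equal(fit$slope, 1.5, tolerance = 1e-10)

  # curvature is detected
  set.seed(52)
  s <- sample(0:9, 400, replace = TRUE)
  y_quad <- 1 + 0.3 * s + 0.35 * s^2 + rnorm(400, sd = 2)
  expect_lt(mv_duration_model(s, y_quad)$lof_p, 0.01)

  # a correctly specified linear model is not flagged
  y_lin <- 1 + 1.2 * s + rnorm(400, sd = 2)
  expect_gt(mv_duration_model(s, y_lin)$lof_p, 0.001)

  expect_warning(mv_duration_model(c(1, 2, 3), c(1, 2, 3.1)), "replicate")
  expect_error(mv_duration_model(rep(1:2, 5), rnorm(10)), "3 distinct")
})

test_that("survivor MV duration rises with the simulated score", {
  co <- simulate_cohort(synthetic_config(n = 2000, seed = 53))
  s <- score_cohort(co)$scores
  surv <- co$mort28 == 0
  fit <- mv_duration_model(s[surv], co$mv_days[surv])
  expect_gt(fit$slope, 0)
  expect_lt(fit$slope_p, 1e-4)
})

test_that("interaction LRT is zero when the product adds nothing and never negative", {
  set.seed(54)
  n <- 500
  a <- runif(n, 20, 110)
  s <- sample(0:10, n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-2 + 0.25 * s))
  res <- interaction_test(a, s, y)
  expect_gte(res$lrt_statistic, 0)
  expect_true(all(res$curves$fit >= 0 & res$curves$fit <= 1))
  expect_true(all(res$curves$lwr <= res$curves$fit &
                    res$curves$fit <= res$curves$upr))
  expect_setequal(unique(res$curves$group), c("low", "high"))
  expect_warning(interaction_test(a[1:25], s[1:25], rep(0:1, c(12, 13))),
                 "smaller than 30")
})

test_that("interaction LRT approximates the Wald chi-square at large n", {
  set.seed(55)
  n <- 20000
  a <- runif(n, 20, 110)
  s <- sample(0:10, n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-2.5 + 0.2 * s + 0.015 * (a - 60) -
                             0.004 * (a - 60) * s))
  res <- interaction_test(a, s, y)
  fit <- glm(y ~ a * s, family = binomial())
  wald <- (coef(fit)[["a:s"]] / sqrt(vcov(fit)["a:s", "a:s"]))^2
  expect_lt(abs(res$lrt_statistic - wald) / wald, 0.10)
})

test_that("the generator's default interaction is detectable at the eligible subset", {
  ps <- sapply(1:80, function(i) {
    co <- simulate_cohort(synthetic_config(n = 598, seed = 5600 + i))
    s <- score_cohort(co)$scores
    adq <- adequacy(co)
    el <- adq$eligible
    interaction_test(adq$pct_received[el], s[el], co$mort28[el])$lrt_p
  })
  expect_lt(median(ps), 0.05)
})
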