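# small deterministic cohort for round-trip and scoring tests
make_small_cohort <- function() {
  data.frame(
    patient_id = c("A1", "B2", "C3"),
    age = c(45, 63.25, 80),
    apache2 = c(10, 21, 30),
    sofa = c(3, 7, 12),
    days_hosp_to_icu = c(0.5, 0.4, 2.125),
    bmi = c(26.5, NA, 19.2),
    n_comorbid = c(1L, 3L, 4L),
    il6 = c(100, NA, 600.5),
    crp = c(50, 120.75, NA),
    pct = c(0.5, 2.25, 20),
    oral_intake_pct = c(100, NA, 40),
    weight_loss_pct = c(0, NA, 2.5),
    mort28 = c(0L, 0L, 1L),
    mv_start_within_48h = c(0L, 1L, 1L),
    mv_days = c(0, 10, 5),
    icu_days = c(1.5, 12.25, 5.75),
    energy_prescribed = c(1800, 2000, 2200),
    stringsAsFactors = FALSE
  )
}

with_energy <- function(cohort) {
  cohort$energy_received_daily <- lapply(seq_len(nrow(cohort)), function(i) {
    ndays <- min(ceiling(cohort$icu_days[i]), 14)
    round(seq(800, 1800, length.out = ndays) + i * 10.5, 3)
  })
  cohort
}

# all-pairs concordance, the brute-force oracle for c_index
brute_c_index <- function(score, outcome) {
  cases <- score[outcome == 1]
  controls <- score[outcome == 0]
  total <- 0
  for (x in cases) {
    total <- total + sum(x > controls) + 0.5 * sum(x == controls)
  }
  total / (length(cases) * length(controls))
}

# closed-form saturated-categorical logits: log(d_k/s_k) - log(d_1/s_1)
count_logits <- function(index, y) {
  k <- max(index)
  sapply(seq_len(k), function(j) {
    d <- sum(y[index == j] == 1); s <- sum(y[index == j] == 0)
    log(d / s)
  }) -> lo
  lo - lo[1]
}

# quick logistic-structured data frame for derivation tests
make_logistic_cohort <- function(n, seed, beta = NULL) {
  set.seed(seed)
  x <- data.frame(
    age = rnorm(n, 64, 16),
    apache2 = round(rgamma(n, 7.5, scale = 2.9)),
    sofa = round(rgamma(n, 7, scale = 1.07)),
    days_hosp_to_icu = rlnorm(n, 0.2, 1.5),
    n_comorbid = sample(0:5, n, replace = TRUE),
    il6 = rlnorm(n, 4.7, 1.4)
  )
  pts <- nutric_score(pmax(18, x$age), x$apache2, x$sofa, x$n_comorbid,
                      x$days_hosp_to_icu, x$il6)
  x$age <- pmax(18, x$age)
  x$mort28 <- rbinom(n, 1, plogis(-4.3 + 0.7 * pts))
  x
}
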