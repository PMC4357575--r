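# Minimal cohort-like frame with constant covariates so the exposure
# coefficient can be checked against closed forms.
flat_table <- function(exposure, y, time = NULL, event = NULL) {
  n <- length(exposure)
  data.frame(
    participant_id = as.character(seq_len(n)),
    age = 70, bmi = 27, smoker = 0, drinks_per_week = "0",
    education = "high school or less", baseline_falls = "0",
    prior_fracture = 0, family_history_fracture = 0,
    fi = exposure, pf_total = exposure,
    fall_year3 = y, death = y,
    fracture_time = if (is.null(time)) 3 else time,
    fracture_event = if (is.null(event)) 0L else event,
    stringsAsFactors = FALSE
  )
}

test_that("a single-exposure logistic fit reproduces the 2x2 cross-product OR", {
  # 2x2 table: exposed 35/65 events, unexposed 20/80
  exposure <- rep(c(1, 0), each = 100)
  y <- c(rep(1, 35), rep(0, 65), rep(1, 20), rep(0, 80))
  fit <- fit_logistic(flat_table(exposure, y), outcome = "falls",
                      exposure = "fi", adjustment = "age")
  or <- exp(coef(fit$fit)[".exposure"])
  expect_equal(unname(or), (35 * 80) / (65 * 20), tolerance = 1e-6)
})

test_that("effects rescale exactly to the reporting increment", {
  scored <- score_cohort(make_cohort(n = 1000, seed = 13))
  fit <- fit_logistic(scored, "falls", "fi", "multivariable")
  e1 <- effect_per_increment(fit, 1)
  e144 <- effect_per_increment(fit, 0.144)
  # exponential rescaling: effect(delta) = effect(1)^delta
  expect_equal(e144$estimate, e1$estimate^0.144)
  expect_equal(e144$ci95, e1$ci95^0.144)
  # closed form from the extracted coefficient
  expect_equal(e144$estimate, exp(e1$beta * 0.144))
  expect_equal(e144$scale, "OR")
  # beta = log 2 at increment 1 gives OR 2 (arithmetic identity on the scale)
  expect_equal(exp(log(2) * 1), 2)
  expect_equal(exp(2.1972 * 0.144), 1.3722, tolerance = 1e-4)
})

test_that("null and nested model relationships hold", {
  scored <- score_cohort(make_cohort(n = 1500, seed = 14))
  multi <- fit_logistic(scored, "falls", "fi", "multivariable")
  agead <- fit_logistic(scored, "falls", "fi", "age")
  expect_gte(as.numeric(logLik(multi$fit)), as.numeric(logLik(agead$fit)))
  # a null exposure in the generator is recovered as OR ~ 1 with covering CI
  cover <- vapply(1:30, function(r) {
    cfg <- generator_config(n = 1000, seed = 3000 + r,
                            outcome = modifyList(generator_config()$outcome,
                                                 list(or_falls = 1.0)))
    sc <- score_cohort(generate_cohort(cfg)$cohort)
    f <- fit_logistic(sc, "falls", "fi", "multivariable")
    b <- coef(f$fit)[".exposure"]
    se <- sqrt(vcov(f$fit)[".exposure", ".exposure"])
    abs(b) <= 1.96 * se
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})

test_that("the Cox fit recovers a two-group exponential hazard ratio of 2", {
  set.seed(15)
  n <- 3000
  grp <- rep(c(0, 1), each = n / 2)
  t_event <- rexp(n, rate = 0.05 * 2^grp)
  event <- as.integer(t_event <= 3)
  time <- pmin(t_event, 3)
  expect_warning(
    fit <- fit_cox(flat_table(grp, 0, time = time, event = event),
                   exposure = "fi", adjustment = "age"),
    "constant covariate")
  expect_equal(unname(exp(coef(fit$fit)[".exposure"])), 2, tolerance = 0.15)
  expect_true(is.finite(fit$aic))
})

test_that("the proportional-hazards check behaves under PH-true data", {
  scored <- score_cohort(make_cohort(n = 2000, seed = 16))
  fit <- fit_cox(scored, "fi", "multivariable")
  z <- schoenfeld_ph_check(fit)
  expect_true("GLOBAL" %in% z$term)
  expect_true(all(z$p >= 0 & z$p <= 1, na.rm = TRUE))
  # the generator is PH-true, so the global test should not reject strongly
  expect_gt(z$p[z$term == "GLOBAL"], 0.001)
})

test_that("group exposures report per-level effects against the reference", {
  scored <- score_cohort(make_cohort(n = 1500, seed = 17))
  fit <- fit_logistic(scored, "falls", "group", "age",
                      group = scored$pf_category)
  ge <- group_effects(fit)
  expect_setequal(ge$level, c("pre-frail", "frail"))
  expect_true(all(ge$lo <= ge$estimate & ge$estimate <= ge$hi))
  # frailer groups carry higher fall risk in the synthetic cohort
  expect_gt(ge$estimate[ge$level == "frail"], 1)
})

test_that("degenerate inputs are rejected with informative errors", {
  tab <- flat_table(runif(150), rep(1, 150))
  expect_error(fit_logistic(tab, "falls", "fi", "age"), "single class")
  tab2 <- flat_table(runif(150), rbinom(150, 1, 0.4))
  tab2$fracture_event <- 0L
  expect_error(fit_cox(tab2, "fi", "age"), "at least 10 fracture events")
})
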