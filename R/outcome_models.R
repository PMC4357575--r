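# Ordinal-to-numeric coding used by the outcome models.  Drinking enters as
# an ordinal integer 0-3 and baseline falls as 0-2 (their survey
# categories); swap to dummy coding by editing model_frame if needed.
drinks_score <- function(x) {
  match(x, c("0", "<7", "7-13", ">=14")) - 1L
}

falls_score <- function(x) {
  match(x, c("0", "1", ">=2")) - 1L
}

education_score <- function(x) {
  as.integer(x == "more than high school")
}

# Numeric covariate frame shared by every outcome model.
model_frame <- function(table) {
  data.frame(
    age = table$age,
    bmi = table$bmi,
    smoker = table$smoker,
    drinks = drinks_score(table$drinks_per_week),
    education = education_score(table$education),
    baseline_falls = falls_score(table$baseline_falls),
    prior_fracture = table$prior_fracture,
    family_history_fracture = table$family_history_fracture
  )
}

#' Adjustment covariates per outcome
#'
#' Multivariable models adjust for age, smoking, drinking, BMI, education
#' and baseline falls for falls; for age, smoking, drinking, baseline
#' fracture, family history of fractures, BMI and education for fractures;
#' and for age, smoking, drinking, BMI and education for death.
#'
#' @param outcome One of `"falls"`, `"fractures"`, `"death"`.
#' @return Character vector of covariate names in the model frame.
#' @export
outcome_covariates <- function(outcome = c("falls", "fractures", "death")) {
  outcome <- match.arg(outcome)
  switch(outcome,
    falls = c("age", "smoker", "drinks", "bmi", "education", "baseline_falls"),
    fractures = c("age", "smoker", "drinks", "prior_fracture",
                  "family_history_fracture", "bmi", "education"),
    death = c("age", "smoker", "drinks", "bmi", "education")
  )
}

exposure_column <- function(table, exposure, group) {
  switch(exposure,
    fi = table$fi,
    pf = table$pf_total,
    group = {
      if (is.null(group)) stop("exposure = 'group' requires a group vector")
      factor(group, ordered = FALSE)
    }
  )
}

check_separation <- function(fit) {
  if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    stop("logistic fit did not converge cleanly (possible separation); ",
         "consider a penalised (ridge) fallback")
  }
}

#' Fit a logistic outcome model
#'
#' Maximum-likelihood logistic regression of a binary outcome (falls in
#' follow-up year 3, or death over follow-up) on a frailty exposure, either
#' age-adjusted or with the full multivariable adjustment set for that
#' outcome.  Rows with missing outcome or covariates are dropped
#' (complete-case).  The in-sample linear predictor is stored for
#' downstream discrimination statistics.
#'
#' @param table Scored cohort data frame.
#' @param outcome `"falls"` or `"death"`.
#' @param exposure `"fi"` (continuous index), `"pf"` (0-5 score) or
#'   `"group"` (categorical, supply `group`).
#' @param adjustment `"multivariable"` (default) or `"age"`.
#' @param group Optional factor of group labels when `exposure = "group"`;
#'   the first level is the reference.
#' @return An object of class `frailty_logistic`: list with the `glm` fit,
#'   the analysis data, linear predictor `lp`, fitted probabilities, and
#'   metadata.
#' @export
fit_logistic <- function(table, outcome = c("falls", "death"),
                         exposure = c("fi", "pf", "group"),
                         adjustment = c("multivariable", "age"),
                         group = NULL) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  adjustment <- match.arg(adjustment)
  y <- switch(outcome, falls = table$fall_year3, death = table$death)
  covs <- if (adjustment == "age") "age" else outcome_covariates(
    if (outcome == "falls") "falls" else "death")
  dat <- cbind(data.frame(.y = y, .exposure = exposure_column(table, exposure, group)),
               model_frame(table)[covs])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$.y)) < 2) stop("outcome '", outcome,
                                       "' has a single class after complete-case filtering")
  n_par <- 1L + length(covs) + if (is.factor(dat$.exposure))
    nlevels(dat$.exposure) - 1L else 1L
  if (nrow(dat) <= 10 * n_par) {
    stop("too few observations (", nrow(dat), ") for ", n_par, " parameters")
  }
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  check_separation(fit)
  structure(list(
    fit = fit, data = dat, outcome = outcome, exposure = exposure,
    adjustment = adjustment, covariates = covs,
    lp = unname(stats::predict(fit, type = "link")),
    prob = unname(stats::fitted(fit)),
    y = dat$.y
  ), class = "frailty_logistic")
}

#' Fit a Cox proportional-hazards model for fractures
#'
#' Partial-likelihood fit (Efron handling of tied event times) of incident
#' fracture over the 3-year follow-up, with administrative censoring at 3
#' years and censoring at death.  Constant covariates are dropped with a
#' warning.  The AIC (2k - 2 log partial likelihood) is reported as the
#' model-fit metric.
#'
#' @inheritParams fit_logistic
#' @return An object of class `frailty_cox`: list with the `coxph` fit,
#'   analysis data, linear predictor (risk score), number of events, and
#'   `aic`.
#' @export
fit_cox <- function(table, exposure = c("fi", "pf", "group"),
                    adjustment = c("multivariable", "age"),
                    group = NULL) {
  exposure <- match.arg(exposure)
  adjustment <- match.arg(adjustment)
  covs <- if (adjustment == "age") "age" else outcome_covariates("fractures")
  dat <- cbind(data.frame(.time = table$fracture_time,
                          .event = table$fracture_event,
                          .exposure = exposure_column(table, exposure, group)),
               model_frame(table)[covs])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (any(dat$.time <= 0)) stop("fracture times must be positive")
  n_events <- sum(dat$.event)
  if (n_events < 10) stop("need at least 10 fracture events, found ", n_events)
  constant <- vapply(covs, function(nm) length(unique(dat[[nm]])) < 2, logical(1))
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(covs[constant], collapse = ", "))
    dat <- dat[, c(".time", ".event", ".exposure", covs[!constant]), drop = FALSE]
  }
  rhs <- setdiff(names(dat), c(".time", ".event"))
  form <- stats::reformulate(sprintf("`%s`", rhs),
                             response = "survival::Surv(.time, .event)")
  fit <- survival::coxph(form, data = dat, ties = "efron")
  structure(list(
    fit = fit, data = dat, outcome = "fractures", exposure = exposure,
    adjustment = adjustment, covariates = covs[!constant],
    lp = unname(stats::predict(fit, type = "lp")),
    n_events = n_events,
    aic = stats::AIC(fit)
  ), class = "frailty_cox")
}

#' Effect estimate per increment of the exposure
#'
#' Rescales the fitted exposure coefficient to the reporting increment:
#' the odds or hazard ratio per `increment` units of the exposure is
#' `exp(beta * increment)` with Wald 95% confidence limits
#' `exp((beta +/- 1.96 se) * increment)`.  Use `increment = 1` for the
#' phenotypic score (per 1 point) and the rounded one-fifth range for the
#' frailty index.
#'
#' @param fit A `frailty_logistic` or `frailty_cox` fit with a continuous
#'   exposure.
#' @param increment Exposure increment on which to report the effect.
#' @return A list with `scale` ("OR" or "HR"), `estimate`, `ci95`
#'   (length-2), `beta`, `se` and `per` (description of the increment).
#' @export
effect_per_increment <- function(fit, increment = 1) {
  stopifnot(inherits(fit, c("frailty_logistic", "frailty_cox")))
  cf <- stats::coef(fit$fit)
  if (!".exposure" %in% names(cf)) {
    stop("no continuous exposure coefficient in this fit")
  }
  beta <- cf[[".exposure"]]
  se <- sqrt(stats::vcov(fit$fit)[".exposure", ".exposure"])
  est <- exp(beta * increment)
  ci <- exp((beta + c(-1, 1) * 1.96 * se) * increment)
  list(scale = if (inherits(fit, "frailty_cox")) "HR" else "OR",
       estimate = est, ci95 = ci, beta = beta, se = se,
       per = paste0("per ", format(increment), " units of ", fit$exposure))
}

#' Per-level effects of a categorical exposure
#'
#' For group exposures (strategy 2/3 trichotomizations or the phenotypic
#' categories) returns the odds/hazard ratio of each non-reference level
#' against the reference with Wald 95% confidence limits.
#'
#' @param fit A `frailty_logistic` or `frailty_cox` fit with
#'   `exposure = "group"`.
#' @return Data frame with `level`, `estimate`, `lo`, `hi`.
#' @export
group_effects <- function(fit) {
  stopifnot(inherits(fit, c("frailty_logistic", "frailty_cox")))
  cf <- stats::coef(fit$fit)
  vc <- stats::vcov(fit$fit)
  idx <- grep("^\\.exposure", names(cf))
  if (!length(idx)) stop("no group exposure terms in this fit")
  lev <- sub("^\\.exposure", "", names(cf)[idx])
  se <- sqrt(diag(vc)[idx])
  data.frame(level = lev,
             estimate = exp(cf[idx]),
             lo = exp(cf[idx] - 1.96 * se),
             hi = exp(cf[idx] + 1.96 * se),
             row.names = NULL)
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Grambsch-Therneau test: correlation of the scaled Schoenfeld residuals
#' with the rank of event time, per covariate and globally.
#'
#' @param fit A `frailty_cox` fit.
#' @return Data frame with `term`, `chisq`, `df`, `p` (last row `GLOBAL`).
#' @export
schoenfeld_ph_check <- function(fit) {
  stopifnot(inherits(fit, "frailty_cox"))
  if (fit$n_events < 3) stop("need at least 3 events for the proportional-hazards check")
  z <- survival::cox.zph(fit$fit, transform = "rank")
  tab <- as.data.frame(z$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL)
}
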