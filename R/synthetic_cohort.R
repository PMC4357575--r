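# Synthetic cohort generator.  A single latent frailty trait Z (standard
# normal plus an age slope) drives the deficit items, the phenotypic
# components and - through the realized frailty index - the outcome risks,
# so that every pipeline stage has fully-known-truth inputs.  Default
# distributional targets (age mix, frailty-index moments, marginal event
# rates) emulate the published cohort this package models.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions: n = 4000 women aged 55+, sampled
#' so two thirds are 65 or older; a latent frailty trait
#' `Z = age_slope * (age - 70)/10 + N(0, sd)`; monotone item loadings
#' chosen so the frailty index has mean about 0.24 and SD about 0.13 and
#' correlates with the phenotypic score at Spearman about 0.6; true
#' per-one-fifth-increment effects OR 1.4 (falls), OR 1.8 (death) and HR
#' 1.25 (fractures); and marginal event rates 0.32 / 0.064 / 0.027 for
#' falls, fractures and death, hit by calibrating the outcome intercepts.
#'
#' @param n Cohort size.
#' @param seed Integer seed; all randomness flows from it.
#' @param age_mix Proportion aged 65 or older (default 2/3).
#' @param trait List: `age_slope`, `sd` of the latent trait.
#' @param deficit List: `loading` of Z on item severities, `noise_sd`,
#'   global intercept `shift` (calibration of the frailty-index mean).
#' @param pf List: `loading`, `noise_sd` for the phenotypic instrument
#'   items.
#' @param outcome List: true per-increment effects `or_falls`, `or_death`,
#'   `hr_fracture`, the reference increment `increment_ref` (one fifth of
#'   the anticipated index range), and covariate log-effect vectors
#'   `falls_effects`, `fracture_effects`, `death_effects`.
#' @param event_rates List of target marginal rates `falls`, `fracture`,
#'   `death`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n = 4000, seed = 1L, age_mix = 2 / 3,
                             trait = list(age_slope = 0.5, sd = 1),
                             deficit = list(loading = 0.55, noise_sd = 0.8,
                                            shift = 0.32),
                             pf = list(loading = 1.0, noise_sd = 0.75),
                             outcome = list(
                               or_falls = 1.4, or_death = 1.8,
                               hr_fracture = 1.25, increment_ref = 0.144,
                               falls_effects = c(age = 0.012, smoker = 0.15,
                                                 drinks = -0.05, bmi = 0.015,
                                                 education = -0.10,
                                                 baseline_falls = 0.55),
                               fracture_effects = c(age = 0.025, smoker = 0.20,
                                                    drinks = 0, prior_fracture = 0.50,
                                                    family_history_fracture = 0.20,
                                                    bmi = -0.01, education = 0),
                               death_effects = c(age = 0.075, smoker = 0.50,
                                                 drinks = 0, bmi = -0.02,
                                                 education = -0.10)),
                             event_rates = list(falls = 0.32, fracture = 0.064,
                                                death = 0.027)) {
  stopifnot(n >= 100, age_mix > 0, age_mix < 1)
  rates <- unlist(event_rates)
  stopifnot(all(rates > 0), all(rates < 1))
  structure(list(n = n, seed = seed, age_mix = age_mix, trait = trait,
                 deficit = deficit, pf = pf, outcome = outcome,
                 event_rates = event_rates),
            class = "generator_config")
}

# Deterministic per-item intercepts: prevalences vary across items so the
# deficit profile is heterogeneous, as in real instruments.
deficit_item_intercepts <- function(codebook) {
  items <- codebook$items
  ids <- names(items)
  a <- numeric(length(ids))
  names(a) <- ids
  dom <- vapply(items, `[[`, character(1), "domain")
  nlev <- vapply(items, function(it) length(it$values), integer(1))
  # polychotomous symptoms (vitality-style, pain) are common complaints
  a[dom == "symptoms_signs" & nlev >= 5] <- -0.65
  a[dom == "symptoms_signs" & nlev == 2] <- -1.45
  com <- ids[dom == "comorbidity"]
  a[com] <- seq(-0.35, -2.45, length.out = length(com))
  adl <- ids[dom == "adl"]
  a[adl] <- seq(-0.15, -2.35, length.out = length(adl))
  a[dom == "healthcare_utilization"] <- -2.6
  a
}

# Map a severity in [0, 1] to the nearest declared level of an item.
nearest_level_index <- function(p, values) {
  mids <- (values[-1] + values[-length(values)]) / 2
  findInterval(p, mids) + 1L
}

truncated_normal <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

calibrate_logistic_intercept <- function(offset, target) {
  f <- function(b0) mean(stats::plogis(b0 + offset)) - target
  sol <- tryCatch(stats::uniroot(f, c(-30, 10), tol = 1e-10),
                  error = function(e) stop("target rate ", target,
                                           " unattainable given the configured coefficients"))
  sol$root
}

calibrate_hazard_intercept <- function(offset, censor_time, target) {
  f <- function(lh0) mean(1 - exp(-exp(lh0 + offset) * censor_time)) - target
  sol <- tryCatch(stats::uniroot(f, c(-30, 5), tol = 1e-10),
                  error = function(e) stop("target rate ", target,
                                           " unattainable given the configured coefficients"))
  sol$root
}

#' Generate a synthetic cohort with known truth
#'
#' Draws a cohort table in the package's schema together with a truth
#' record: ages in two strata, a latent frailty trait, deficit responses
#' through monotone ordered links, phenotypic-instrument responses as noisy
#' monotone transforms of the negative trait, and outcomes from logistic
#' (falls, death) and exponential proportional-hazards (fractures) models
#' whose exposure is the *realized* frailty index computed from the
#' generated deficits - so downstream model fits are correctly specified
#' and parameter recovery is well-posed.  Outcome intercepts are calibrated
#' by root-finding so the expected marginal rates equal the configured
#' targets.  Fracture follow-up is censored administratively at 3 years and
#' at death.
#'
#' @param config A [generator_config()].
#' @param codebook A `deficit_codebook` describing the 34 items.
#' @return A list with `cohort` (data frame in the cohort schema) and
#'   `truth` (latent trait, true event probabilities and hazards, true
#'   coefficients, calibrated intercepts, realized frailty index, and the
#'   config).  Regenerable bit-exactly from the same config.
#' @export
generate_cohort <- function(config = generator_config(),
                            codebook = default_codebook()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  with_seed(config$seed, {
    n_old <- round(n * config$age_mix)
    n_young <- n - n_old
    age <- c(truncated_normal(n_young, 60.0, 2.9, 55, 64.999),
             truncated_normal(n_old, 74.1, 7.1, 65, 97))
    age <- sample(age)  # shuffle strata
    z <- config$trait$age_slope * (age - 70) / 10 +
      stats::rnorm(n, 0, config$trait$sd)

    # --- baseline covariates (marginals emulate the study's Table-1 mix) ---
    bmi <- pmax(15, stats::rnorm(n, 27.7 - 0.8 * 0, 5.3) + 0.9 * z)
    smoker <- stats::rbinom(n, 1, stats::plogis(-2.25 + 0.2 * z))
    drinks_lv <- c("0", "<7", "7-13", ">=14")
    u <- stats::plogis(0.3 * z + stats::rlogis(n))
    drinks <- drinks_lv[1L + findInterval(u, c(0.51, 0.87, 0.98))]
    education <- ifelse(stats::rbinom(n, 1, stats::plogis(0.6 + 0.2 * z)) == 1,
                        "high school or less", "more than high school")
    prior_fracture <- stats::rbinom(n, 1, stats::plogis(-1.35 + 0.25 * z))
    family_history_fracture <- stats::rbinom(n, 1, 0.27)
    bf_lv <- c("0", "1", ">=2")
    u <- stats::plogis(0.9 * z + stats::rlogis(n))
    baseline_falls <- bf_lv[1L + findInterval(u, c(0.62, 0.84))]

    # --- deficit items ---
    a_item <- deficit_item_intercepts(codebook) + config$deficit$shift
    deficits <- lapply(names(codebook$items), function(id) {
      it <- codebook$items[[id]]
      latent <- a_item[[id]] + config$deficit$loading * z +
        stats::rnorm(n, 0, config$deficit$noise_sd)
      it$levels[nearest_level_index(stats::plogis(latent), it$values)]
    })
    names(deficits) <- names(codebook$items)

    # --- phenotypic instrument items (higher Z -> worse responses) ---
    # Each 0-100 component gets its own person-level random effect in
    # addition to per-item noise: per-item noise averages out over the
    # items of a component, so without the shared term the four criteria
    # would be nearly deterministic functions of Z and the frail category
    # would be far larger than observed in practice.
    b_pf <- config$pf$loading
    s_pf <- config$pf$noise_sd
    u_sw <- stats::rnorm(n, 0, s_pf)
    u_vit <- stats::rnorm(n, 0, s_pf)
    sf_off <- seq(1.6, -0.2, length.out = 10)
    sf36 <- lapply(seq_len(10), function(j) {
      latent <- sf_off[j] - b_pf * z + u_sw + stats::rnorm(n, 0, 0.7)
      SF36_PF_LEVELS[nearest_level_index(stats::plogis(latent), c(0, 0.5, 1))]
    })
    names(sf36) <- SF36_PF_COLUMNS
    vit_off <- c(vit_worn_out = 0.55, vit_full_of_life = 0.75,
                 vit_tired = 0.35, vit_energy = 0.65)
    vitality <- lapply(names(VITALITY_COLUMNS), function(nm) {
      latent <- vit_off[[nm]] - b_pf * z + u_vit + stats::rnorm(n, 0, 0.7)
      score_frac <- stats::plogis(latent)  # 1 = best
      k <- nearest_level_index(score_frac, c(0, 0.25, 0.5, 0.75, 1))
      if (VITALITY_COLUMNS[[nm]]) rev(VITALITY_LEVELS)[k] else VITALITY_LEVELS[k]
    })
    names(vitality) <- names(VITALITY_COLUMNS)
    walk20_days <- stats::rbinom(n, 30, stats::plogis(0.4 - 0.55 * z +
                                                        stats::rnorm(n, 0, 0.7)))
    weight_loss <- stats::rbinom(n, 1, stats::plogis(-2.6 + 0.5 * z))

    cohort <- data.frame(
      participant_id = sprintf("P%05d", seq_len(n)),
      age = age, bmi = bmi, smoker = smoker, drinks_per_week = drinks,
      education = education, baseline_falls = baseline_falls,
      prior_fracture = prior_fracture,
      family_history_fracture = family_history_fracture,
      sf36, vitality,
      walk20_days = walk20_days, weight_loss_10lb = weight_loss,
      deficits,
      stringsAsFactors = FALSE, check.names = FALSE
    )

    # --- realized frailty index drives the outcomes ---
    fi <- as.numeric(compute_fi(code_deficit_columns(cohort, codebook)))
    mf <- model_frame(cohort)
    oc <- config$outcome
    beta_fi_falls <- log(oc$or_falls) / oc$increment_ref
    beta_fi_death <- log(oc$or_death) / oc$increment_ref
    beta_fi_frac <- log(oc$hr_fracture) / oc$increment_ref

    lin <- function(effects) {
      as.vector(as.matrix(mf[names(effects)]) %*% effects)
    }
    off_falls <- beta_fi_falls * fi + lin(oc$falls_effects)
    off_death <- beta_fi_death * fi + lin(oc$death_effects)
    off_frac <- beta_fi_frac * fi + lin(oc$fracture_effects)

    b0_falls <- calibrate_logistic_intercept(off_falls, config$event_rates$falls)
    b0_death <- calibrate_logistic_intercept(off_death, config$event_rates$death)
    p_fall <- stats::plogis(b0_falls + off_falls)
    p_death <- stats::plogis(b0_death + off_death)
    cohort$fall_year3 <- stats::rbinom(n, 1, p_fall)
    cohort$death <- stats::rbinom(n, 1, p_death)

    censor <- ifelse(cohort$death == 1, stats::runif(n, 0, 3), 3)
    lh0 <- calibrate_hazard_intercept(off_frac, censor, config$event_rates$fracture)
    hazard <- exp(lh0 + off_frac)
    t_frac <- stats::rexp(n, hazard)
    cohort$fracture_event <- as.integer(t_frac <= censor)
    cohort$fracture_time <- pmin(t_frac, censor)

    truth <- list(
      z = z, fi = fi, p_fall = p_fall, p_death = p_death, hazard = hazard,
      coefficients = list(
        beta_fi_falls = beta_fi_falls, beta_fi_death = beta_fi_death,
        beta_fi_fracture = beta_fi_frac,
        falls_effects = oc$falls_effects,
        death_effects = oc$death_effects,
        fracture_effects = oc$fracture_effects),
      intercepts = list(falls = b0_falls, death = b0_death,
                        fracture_log_hazard = lh0),
      config = config
    )
    list(cohort = cohort, truth = truth)
  })
}

#' Mask cells completely at random
#'
#' Introduces missingness (MCAR) into a column subset, recording the mask,
#' to exercise the missing-data policy.
#'
#' @param table A cohort data frame.
#' @param rate Masking probability per cell, in \[0, 0.5\].
#' @param columns Character vector of columns to mask.
#' @param seed Integer seed.
#' @return The masked table with attribute `"missing_mask"`: a data frame
#'   of (`row`, `column`) pairs that were set to missing.
#' @export
make_missing <- function(table, rate, columns, seed = 1L) {
  stopifnot(rate >= 0, rate <= 0.5, all(columns %in% names(table)))
  mask <- list()
  out <- with_seed(seed, {
    tab <- table
    for (nm in columns) {
      hit <- which(stats::runif(nrow(tab)) < rate)
      if (length(hit)) {
        tab[[nm]][hit] <- NA
        mask[[length(mask) + 1L]] <- data.frame(row = hit, column = nm,
                                                stringsAsFactors = FALSE)
      }
    }
    tab
  })
  attr(out, "missing_mask") <- if (length(mask)) do.call(rbind, mask) else
    data.frame(row = integer(), column = character(), stringsAsFactors = FALSE)
  out
}
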