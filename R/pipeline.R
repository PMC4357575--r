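#' Configuration for a full comparison run
#'
#' @param input Optional path to a cohort CSV; when `NULL` a synthetic
#'   cohort is generated from `generator`.
#' @param generator A [generator_config()] used when `input` is `NULL`.
#' @param strategies Subset of `1:3` to run (all by default).
#' @param outcomes Subset of `c("falls", "fractures", "death")`.
#' @param adjustments Subset of `c("age", "multivariable")`.
#' @param subgroup `"all"`, `"<65"` or `">=65"` age filter.
#' @param seed Integer seed governing imputation and bootstrap resampling.
#' @param n_boot Bootstrap resamples for the concordance contrast.
#' @param out_dir Optional directory for per-stage artifacts (scored cohort
#'   CSV, assignment CSV, report JSON).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = generator_config(),
                            strategies = 1:3,
                            outcomes = c("falls", "fractures", "death"),
                            adjustments = c("age", "multivariable"),
                            subgroup = c("all", "<65", ">=65"),
                            seed = 1L, n_boot = 500, out_dir = NULL) {
  subgroup <- match.arg(subgroup)
  stopifnot(length(strategies) >= 1, all(strategies %in% 1:3),
            length(outcomes) >= 1,
            all(outcomes %in% c("falls", "fractures", "death")),
            all(adjustments %in% c("age", "multivariable")))
  structure(list(input = input, generator = generator,
                 strategies = sort(strategies), outcomes = outcomes,
                 adjustments = adjustments, subgroup = subgroup,
                 seed = seed, n_boot = n_boot, out_dir = out_dir),
            class = "pipeline_config")
}

fit_outcome <- function(table, outcome, exposure, adjustment, group = NULL) {
  if (outcome == "fractures") {
    fit_cox(table, exposure = exposure, adjustment = adjustment, group = group)
  } else {
    fit_logistic(table, outcome = if (outcome == "fractures") "falls" else outcome,
                 exposure = exposure, adjustment = adjustment, group = group)
  }
}

# Discrimination of one pair of fits (PF vs FI) on the same outcome.
compare_discrimination <- function(fit_pf, fit_fi, outcome, n_boot, seed) {
  if (outcome == "fractures") {
    ct <- concordance_contrast(fit_pf$data$.time, fit_pf$data$.event,
                               fit_pf$lp, fit_fi$lp,
                               n_boot = n_boot, seed = seed)
    list(metric = "c_index", pf = ct$c_a, fi = ct$c_b,
         contrast_p = ct$p, delta = ct$delta)
  } else {
    dl <- delong_contrast(fit_pf$lp, fit_fi$lp, fit_pf$y)
    list(metric = "auc", pf = dl$auc_a, fi = dl$auc_b,
         pf_ci = dl$ci95_a, fi_ci = dl$ci95_b,
         contrast_p = dl$p, delta = dl$delta, z = dl$z)
  }
}

#' Run the full frailty-comparison pipeline
#'
#' Orchestrates simulate/read, missing-data handling, scoring of both
#' instruments, strategy assignment, outcome modelling and accuracy
#' comparison, and optionally writes per-stage artifacts.  For each
#' requested outcome and adjustment the continuous-exposure models report
#' effects per increment (1 phenotypic point; the rounded one-fifth index
#' range), and discrimination is contrasted between the instruments with
#' the DeLong test (falls, death) or a paired bootstrap of the concordance
#' index (fractures).  Strategy 2 and 3 group models report per-group
#' odds/hazard ratios against the robust / low-risk reference.
#'
#' @param config A [pipeline_config()].
#' @param codebook A `deficit_codebook`.
#' @return An object of class `frailty_comparison` (nested list; see the
#'   methods vignette for the layout), with the scored cohort attached as
#'   attribute `"cohort"`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         codebook = default_codebook()) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (is.null(config$input)) {
    sim <- generate_cohort(config$generator, codebook)
    cohort <- sim$cohort
    truth <- sim$truth
  } else {
    cohort <- read_cohort(config$input, codebook)
  }
  if (config$subgroup == "<65") cohort <- cohort[cohort$age < 65, , drop = FALSE]
  if (config$subgroup == ">=65") cohort <- cohort[cohort$age >= 65, , drop = FALSE]

  item_cols <- setdiff(names(cohort),
                       c("participant_id", "fall_year3", "fracture_event",
                         "fracture_time", "death"))
  if (anyNA(cohort[item_cols])) {
    cohort <- apply_missing_policy(cohort, missing_policy(), seed = config$seed)
  }
  scored <- score_cohort(cohort, codebook)
  strat <- assign_strategies(scored)

  results <- list()
  for (outcome in config$outcomes) {
    res_o <- list()
    for (adj in config$adjustments) {
      fit_pf <- fit_outcome(scored, outcome, "pf", adj)
      fit_fi <- fit_outcome(scored, outcome, "fi", adj)
      entry <- list(
        effect_pf = effect_per_increment(fit_pf, 1),
        effect_fi = effect_per_increment(fit_fi, strat$increment_rounded),
        discrimination = compare_discrimination(fit_pf, fit_fi, outcome,
                                                config$n_boot, config$seed)
      )
      if (outcome == "fractures") {
        entry$aic <- c(pf = fit_pf$aic, fi = fit_fi$aic)
        entry$ph_check <- list(pf = schoenfeld_ph_check(fit_pf),
                               fi = schoenfeld_ph_check(fit_fi))
      } else {
        entry$calibration <- list(
          pf = hosmer_lemeshow(fit_pf$prob, fit_pf$y),
          fi = hosmer_lemeshow(fit_fi$prob, fit_fi$y))
      }
      # group-exposure models for strategies 2 and 3
      groups <- list()
      if (2 %in% config$strategies) {
        groups$strategy2 <- list(
          pf = group_effects(fit_outcome(scored, outcome, "group", adj,
                                         group = strat$assignments$s2_pf)),
          fi = group_effects(fit_outcome(scored, outcome, "group", adj,
                                         group = strat$assignments$s2_fi)))
      }
      if (3 %in% config$strategies) {
        groups$strategy3 <- list(
          pf = group_effects(fit_outcome(scored, outcome, "group", adj,
                                         group = strat$assignments$s3_pf)),
          fi = group_effects(fit_outcome(scored, outcome, "group", adj,
                                         group = strat$assignments$s3_fi)))
      }
      entry$group_models <- groups
      res_o[[adj]] <- entry
    }
    results[[outcome]] <- res_o
  }

  report <- structure(list(
    n = nrow(scored),
    subgroup = config$subgroup,
    seed = config$seed,
    increment = strat$increment,
    increment_rounded = strat$increment_rounded,
    s1_cutpoints = strat$s1_cutpoints,
    s2_cutpoints = strat$s2_cutpoints,
    risk_cutoffs = unclass(strat$cutoffs),
    group_counts = list(
      s1 = list(pf = as.list(table(strat$assignments$s1_pf)),
                fi = as.list(table(strat$assignments$s1_fi))),
      s2 = list(pf = as.list(table(strat$assignments$s2_pf)),
                fi = as.list(table(strat$assignments$s2_fi))),
      s3 = list(pf = as.list(table(strat$assignments$s3_pf)),
                fi = as.list(table(strat$assignments$s3_fi)))),
    agreement = strat$agreement,
    outcomes = results,
    strategies = config$strategies
  ), class = "frailty_comparison")
  attr(report, "cohort") <- scored
  attr(report, "assignments") <- strat$assignments
  attr(report, "truth") <- truth

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(scored, file.path(config$out_dir, "cohort_scored.csv"))
    utils::write.csv(strat$assignments,
                     file.path(config$out_dir, "assignments.csv"),
                     row.names = FALSE)
    write_report_json(report, file.path(config$out_dir, "report.json"))
  }
  report
}

#' Serialise a comparison report to JSON
#'
#' @param report A `frailty_comparison` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, c("frailty_logistic", "frailty_cox"))) return(NULL)
    if (is.list(x) && !is.data.frame(x)) {
      return(Filter(Negate(is.null), lapply(x, strip)))
    }
    x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = 10, dataframe = "rows")
  invisible(path)
}

#' @export
print.frailty_comparison <- function(x, ...) {
  cat("Frailty instrument comparison (n =", x$n, ")\n")
  cat("  FI increment (one fifth of range):", sprintf("%.3f", x$increment),
      "-> reported", sprintf("%.2f", x$increment_rounded), "\n")
  cat("  Strategy 1 cutpoints:",
      paste(sprintf("%.2f", x$s1_cutpoints), collapse = ", "), "\n")
  cat("  Strategy 2 cutpoints:",
      paste(sprintf("%.3f", x$s2_cutpoints), collapse = ", "), "\n")
  cat("  PF-FI Spearman agreement: ",
      paste(sprintf("%s %.2f", sub("strategy", "s", names(x$agreement)),
                    vapply(x$agreement, `[[`, numeric(1), "rho")),
            collapse = ", "), "\n", sep = "")
  for (outcome in names(x$outcomes)) {
    cat("  ", outcome, ":\n", sep = "")
    for (adj in names(x$outcomes[[outcome]])) {
      e <- x$outcomes[[outcome]][[adj]]
      d <- e$discrimination
      cat(sprintf("    %-13s PF %s %.2f (%.2f-%.2f), FI %s %.2f (%.2f-%.2f); %s PF %.2f vs FI %.2f, p=%.3f\n",
                  paste0(adj, ":"),
                  e$effect_pf$scale, e$effect_pf$estimate,
                  e$effect_pf$ci95[1], e$effect_pf$ci95[2],
                  e$effect_fi$scale, e$effect_fi$estimate,
                  e$effect_fi$ci95[1], e$effect_fi$ci95[2],
                  toupper(d$metric), d$pf, d$fi, d$contrast_p))
    }
  }
  invisible(x)
}
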