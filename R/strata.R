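#' One-fifth increment of the frailty index
#'
#' The comparison scales the frailty-index effect to "per one-fifth of the
#' observed range": the increment is (max - min) / 5.  With an observed
#' range of 0 to 0.72 the increment is 0.144, reported as 0.14 at two
#' decimals by the reporting layer.
#'
#' @param fi Numeric vector of frailty-index values in \[0, 1\].
#' @return The increment (a single real).
#' @export
fi_increment <- function(fi) {
  fi <- fi[!is.na(fi)]
  if (!length(fi)) stop("no non-missing frailty-index values")
  if (any(fi < 0 | fi > 1)) stop("frailty-index values must lie in [0, 1]")
  r <- max(fi) - min(fi)
  if (r <= 0) stop("frailty index is constant: zero range, no increment")
  r / 5
}

#' Strategy 1 cutpoints: successive multiples of the rounded increment
#'
#' @param increment The (rounded) per-one-fifth increment.
#' @return Numeric vector of four cutpoints `increment * 1:4`.
#' @export
strategy1_cutpoints <- function(increment) {
  stopifnot(is.numeric(increment), length(increment) == 1L, increment > 0)
  increment * (1:4)
}

#' Strategy 1: bin the frailty index into levels 0-5
#'
#' Level 0 is reserved for an index of exactly zero (no deficits at all);
#' positive values fall into left-open/right-closed bins
#' `(c[k-1], c[k]]` with `c[k] = k * increment`, and values above the
#' fourth cutpoint are level 5.  This puts the frailty index on the same
#' 0-5 footing as the phenotypic score.
#'
#' @param fi Numeric vector of frailty-index values.
#' @param increment The rounded increment defining the cutpoints (e.g. 0.14).
#' @return Integer vector of levels 0-5.
#' @export
strategy1_bins <- function(fi, increment) {
  cuts <- strategy1_cutpoints(increment)
  lev <- findInterval(fi, cuts, left.open = TRUE) + 1L
  lev[!is.na(fi) & fi == 0] <- 0L
  lev[is.na(fi)] <- NA_integer_
  lev
}

# Locate the crossing of two kernel density estimates between the two group
# means; linear interpolation between grid points.  Multiple crossings:
# take the one nearest the midpoint of the means.  No crossing: fall back
# to the midpoint with a warning.
density_crossing <- function(x_a, x_b, grid_n = 512, bw = "nrd0") {
  m_a <- mean(x_a)
  m_b <- mean(x_b)
  lo <- min(m_a, m_b)
  hi <- max(m_a, m_b)
  d_a <- stats::density(x_a, bw = bw, n = grid_n, from = 0, to = 1)
  d_b <- stats::density(x_b, bw = bw, n = grid_n, from = 0, to = 1)
  g <- d_a$x
  diff <- d_a$y - d_b$y
  inside <- which(g >= lo & g <= hi)
  if (length(inside) < 2) {
    warning("degenerate inter-mean interval; using midpoint of group means")
    return((lo + hi) / 2)
  }
  i <- inside[-length(inside)]
  sign_change <- which(diff[i] * diff[i + 1L] < 0)
  if (!length(sign_change)) {
    warning("no density crossing between group means; using midpoint of group means")
    return((lo + hi) / 2)
  }
  crossings <- vapply(i[sign_change], function(k) {
    g[k] + (g[k + 1L] - g[k]) * diff[k] / (diff[k] - diff[k + 1L])
  }, numeric(1))
  crossings[which.min(abs(crossings - (lo + hi) / 2))]
}

#' Strategy 2: density-overlap trichotomization cutpoints
#'
#' Fits a Gaussian-kernel density (rule-of-thumb bandwidth, 512-point grid
#' over \[0, 1\]) to the frailty index within each phenotypic category and
#' returns two cutpoints: the crossing of the robust and pre-frail
#' densities, and the crossing of the pre-frail and frail densities, each
#' located between the respective group means.  When several crossings lie
#' in the inter-mean interval the one nearest the midpoint of the means is
#' taken; when none does, the midpoint itself is used with a warning.
#'
#' @param fi Numeric vector of frailty-index values.
#' @param pf_category Vector of phenotypic categories
#'   (robust/pre-frail/frail), each with at least 10 members.
#' @param grid_n Density grid size (default 512).
#' @param bw Bandwidth selector passed to [stats::density()]
#'   (default `"nrd0"`, the rule-of-thumb bandwidth).
#' @return Numeric vector `c(cut1, cut2)` with `cut1 < cut2`.
#' @export
strategy2_cutpoints <- function(fi, pf_category, grid_n = 512, bw = "nrd0") {
  keep <- !is.na(fi) & !is.na(pf_category)
  fi <- fi[keep]
  pf_category <- as.character(pf_category)[keep]
  groups <- split(fi, factor(pf_category, levels = PF_CATEGORIES))
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 10)) {
    stop("each phenotypic category needs at least 10 members; counts: ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "))
  }
  cut1 <- density_crossing(groups[["robust"]], groups[["pre-frail"]],
                           grid_n = grid_n, bw = bw)
  cut2 <- density_crossing(groups[["pre-frail"]], groups[["frail"]],
                           grid_n = grid_n, bw = bw)
  sort(c(cut1, cut2))
}

#' Fall-risk cutoffs for strategy 3
#'
#' Defaults to 0.27 (estimated annual probability of falling in the
#' elderly) and 0.50 (annual fall risk given a fall in the past year or
#' gait/balance abnormality).
#'
#' @param low_medium,medium_high Probability cutoffs, `0 < low_medium <
#'   medium_high < 1`.
#' @return An object of class `risk_cutoffs`.
#' @export
risk_cutoffs <- function(low_medium = 0.27, medium_high = 0.50) {
  stopifnot(low_medium > 0, low_medium < medium_high, medium_high < 1)
  structure(list(low_medium = low_medium, medium_high = medium_high),
            class = "risk_cutoffs")
}

RISK_GROUPS <- c("low", "medium", "high")

#' Map predicted fall probabilities to risk groups
#'
#' Intervals are left-closed/right-open: low is p < 0.27, medium is
#' 0.27 <= p < 0.50, high is p >= 0.50 (so a predicted probability of
#' exactly 0.50 is high risk).
#'
#' @param p Numeric vector of predicted probabilities.
#' @param cutoffs A [risk_cutoffs()] object.
#' @return Ordered factor low < medium < high.
#' @export
prob_to_risk_group <- function(p, cutoffs = risk_cutoffs()) {
  stopifnot(inherits(cutoffs, "risk_cutoffs"))
  g <- ifelse(p < cutoffs$low_medium, "low",
              ifelse(p < cutoffs$medium_high, "medium", "high"))
  factor(g, levels = RISK_GROUPS, ordered = TRUE)
}

#' Strategy 3: predicted fall-risk grouping
#'
#' Fits the multivariable logistic model of falls in follow-up year 3 on
#' the frailty index (adjusted for age, smoking, drinking, BMI, education
#' and baseline falls), computes in-sample predicted probabilities for
#' every participant with complete predictors, and assigns low/medium/high
#' risk groups at the cutoffs.
#'
#' @param table A scored cohort data frame (must contain `fi`,
#'   `fall_year3` and the adjustment covariates).
#' @param cutoffs A [risk_cutoffs()] object.
#' @return A list with `group` (ordered factor per participant, `NA` where
#'   predictors are incomplete), `prob` (predicted probabilities), `fit`
#'   (the underlying model) and `cutoffs`.
#' @export
strategy3_groups <- function(table, cutoffs = risk_cutoffs()) {
  fit <- fit_logistic(table, outcome = "falls", exposure = "fi",
                      adjustment = "multivariable")
  mf <- cbind(.exposure = table$fi, model_frame(table))
  prob <- rep(NA_real_, nrow(table))
  ok <- stats::complete.cases(mf[c(".exposure", fit$covariates)])
  prob[ok] <- stats::predict(fit$fit, newdata = mf[ok, , drop = FALSE],
                             type = "response")
  list(group = prob_to_risk_group(prob, cutoffs), prob = prob,
       fit = fit, cutoffs = cutoffs)
}

#' Assign all three comparison strategies
#'
#' Puts the phenotypic score and the frailty index on a common footing:
#' strategy 1 bins the index at successive multiples of the rounded
#' per-one-fifth increment (levels 0-5, against the 0-5 phenotypic score);
#' strategy 2 trichotomizes the index at the density-overlap cutpoints
#' (against robust/pre-frail/frail); strategy 3 groups participants by the
#' predicted probability of falling (against the same three phenotypic
#' categories).  Agreement between the instruments under each strategy is
#' quantified by tie-corrected Spearman correlation.
#'
#' @param table A scored cohort data frame (see [score_cohort()]).
#' @param cutoffs Strategy 3 [risk_cutoffs()].
#' @return An object of class `strategy_assignment`: list with the
#'   per-participant `assignments` data frame (`s1_pf`, `s1_fi`, `s2_pf`,
#'   `s2_fi`, `s3_pf`, `s3_fi`), the `increment` (raw and rounded),
#'   `s1_cutpoints`, `s2_cutpoints`, the strategy 3 `s3_prob` and model,
#'   and per-strategy `agreement` (Spearman results).
#' @export
assign_strategies <- function(table, cutoffs = risk_cutoffs()) {
  stopifnot(all(c("fi", "pf_total", "pf_category") %in% names(table)))
  increment <- fi_increment(table$fi)
  inc_rounded <- round(increment, 2)
  s1_fi <- strategy1_bins(table$fi, inc_rounded)
  s2_cuts <- strategy2_cutpoints(table$fi, table$pf_category)
  s2_fi <- cut(table$fi, breaks = c(-Inf, s2_cuts, Inf),
               labels = PF_CATEGORIES, right = FALSE, ordered_result = TRUE)
  s3 <- strategy3_groups(table, cutoffs)
  assignments <- data.frame(
    s1_pf = table$pf_total,
    s1_fi = s1_fi,
    s2_pf = table$pf_category,
    s2_fi = s2_fi,
    s3_pf = table$pf_category,
    s3_fi = s3$group
  )
  agreement <- list(
    strategy1 = spearman_agreement(assignments$s1_pf, assignments$s1_fi),
    strategy2 = spearman_agreement(as.integer(assignments$s2_pf),
                                   as.integer(assignments$s2_fi)),
    strategy3 = spearman_agreement(as.integer(assignments$s3_pf),
                                   as.integer(assignments$s3_fi))
  )
  structure(list(
    assignments = assignments,
    increment = increment,
    increment_rounded = inc_rounded,
    s1_cutpoints = strategy1_cutpoints(inc_rounded),
    s2_cutpoints = s2_cuts,
    s3_prob = s3$prob,
    s3_fit = s3$fit,
    cutoffs = cutoffs,
    agreement = agreement
  ), class = "strategy_assignment")
}
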