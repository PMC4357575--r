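# Discrimination, calibration and agreement statistics used to compare the
# two frailty instruments.  These are implemented from first principles
# (rank statistics and structural components) so the package does not
# depend on any particular ROC library; pROC and survival::concordance
# serve as independent cross-checks in the test suite.

#' Area under the ROC curve with DeLong variance
#'
#' AUC by the Mann-Whitney rank statistic with midrank tie correction:
#' the probability that a random case outranks a random non-case, ties
#' counting one half.  The variance is estimated from the DeLong structural
#' components (per-case and per-control placement values), which also
#' provide the covariance needed for paired AUC contrasts.
#'
#' @param scores Numeric risk scores (higher = more case-like).
#' @param labels Binary labels (1 = case, 0 = non-case); both classes must
#'   be present.
#' @return List with `auc`, `var`, `se`, `ci95`, class counts `m` (cases)
#'   and `n` (controls), and the placement components `v10`, `v01`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  if (m == 0 || n == 0) stop("both classes must be present to compute an AUC")
  r <- rank(scores)  # midranks
  cases <- labels == 1
  auc <- (sum(r[cases]) - m * (m + 1) / 2) / (m * n)
  # placement values: v10[i] = P_hat(score_control < score_case_i) + ties/2
  v10 <- (r[cases] - rank(scores[cases])) / n
  v01 <- 1 - (r[!cases] - rank(scores[!cases])) / m
  v <- if (m > 1) stats::var(v10) / m else 0
  v <- v + if (n > 1) stats::var(v01) / n else 0
  se <- sqrt(v)
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * se, 0), 1)
  list(auc = auc, var = v, se = se, ci95 = ci, m = m, n = n,
       v10 = v10, v01 = v01)
}

#' Paired DeLong contrast of two correlated AUCs
#'
#' Compares the AUCs of two risk scores evaluated on the *same* subjects
#' (paired design): `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)`
#' with the covariance from the shared DeLong placement components, and a
#' two-sided normal p-value.  Identical score vectors give z = 0, p = 1
#' exactly.
#'
#' @param scores_a,scores_b Numeric score vectors of equal length.
#' @param labels Shared binary labels.
#' @return List with `auc_a`, `auc_b`, `ci95_a`, `ci95_b`, `delta`,
#'   `var_a`, `var_b`, `cov`, `z`, `p`.
#' @export
delong_contrast <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  scores_a <- scores_a[keep]
  scores_b <- scores_b[keep]
  labels <- labels[keep]
  a <- auc_mann_whitney(scores_a, labels)
  b <- auc_mann_whitney(scores_b, labels)
  cv <- 0
  if (a$m > 1) cv <- cv + stats::cov(a$v10, b$v10) / a$m
  if (a$n > 1) cv <- cv + stats::cov(a$v01, b$v01) / a$n
  vd <- a$var + b$var - 2 * cv
  delta <- a$auc - b$auc
  if (vd <= .Machine$double.eps) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = a$auc, auc_b = b$auc, ci95_a = a$ci95, ci95_b = b$ci95,
       delta = delta, var_a = a$var, var_b = b$var, cov = cv, z = z, p = p)
}

#' Harrell's concordance index for censored survival data
#'
#' Counts all usable pairs: a pair is usable when the subject with the
#' shorter follow-up experienced the event (so the ordering of survival is
#' known); pairs tied on event time with both events are not orderable and
#' are excluded.  A higher risk score predicting the shorter event time is
#' concordant; ties in the score count one half.
#'
#' @param times Positive follow-up times.
#' @param events Binary event indicators.
#' @param risk_scores Numeric risk scores (higher = higher predicted risk).
#' @return List with `c_index`, `n_concordant`, `n_discordant`, `n_tied`
#'   and `n_pairs`.
#' @export
harrell_c <- function(times, events, risk_scores) {
  keep <- !is.na(times) & !is.na(events) & !is.na(risk_scores)
  times <- times[keep]
  events <- events[keep]
  risk_scores <- risk_scores[keep]
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  idx <- which(events == 1)
  conc <- disc <- tied <- 0
  for (i in idx) {
    comp <- times > times[i] | (times == times[i] & events == 0)
    if (!any(comp)) next
    s <- risk_scores[comp]
    conc <- conc + sum(risk_scores[i] > s)
    disc <- disc + sum(risk_scores[i] < s)
    tied <- tied + sum(risk_scores[i] == s)
  }
  n_pairs <- conc + disc + tied
  if (n_pairs == 0) stop("no usable pairs under the observed censoring pattern")
  list(c_index = (conc + tied / 2) / n_pairs,
       n_concordant = conc, n_discordant = disc, n_tied = tied,
       n_pairs = n_pairs)
}

#' Paired bootstrap contrast of two concordance indices
#'
#' Resamples subjects with replacement and recomputes the difference in
#' c-index between two risk scores on the same survival data; the
#' two-sided p-value is twice the smaller tail proportion of the bootstrap
#' differences around zero.
#'
#' @inheritParams harrell_c
#' @param scores_a,scores_b Two risk-score vectors on the same subjects.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return List with `c_a`, `c_b`, `delta`, `p`, `boot_se`, `n_boot`.
#' @export
concordance_contrast <- function(times, events, scores_a, scores_b,
                                 n_boot = 1000, seed = 1L) {
  c_a <- harrell_c(times, events, scores_a)$c_index
  c_b <- harrell_c(times, events, scores_b)$c_index
  n <- length(times)
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      da <- tryCatch(harrell_c(times[idx], events[idx], scores_a[idx])$c_index,
                     error = function(e) NA_real_)
      db <- tryCatch(harrell_c(times[idx], events[idx], scores_b[idx])$c_index,
                     error = function(e) NA_real_)
      da - db
    }, numeric(1))
  })
  diffs <- diffs[!is.na(diffs)]
  p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  list(c_a = c_a, c_b = c_b, delta = c_a - c_b, p = p,
       boot_se = stats::sd(diffs), n_boot = length(diffs))
}

#' Hosmer-Lemeshow calibration statistic
#'
#' Groups subjects into deciles of predicted risk and compares observed
#' with expected event counts: the statistic is
#' `sum((O - E)^2 / (E (1 - E / n_g)))` on `n_groups - 2` degrees of
#' freedom against a chi-square reference.  Groups whose expected count
#' makes the denominator vanish are merged with a neighbour with a
#' warning; heavily tied predictions collapse duplicate quantile breaks.
#'
#' @param pred_probs Predicted event probabilities.
#' @param labels Observed binary outcomes.
#' @param n_groups Number of risk groups (default 10).
#' @return List with `statistic`, `df`, `p` and the per-group `table`
#'   (observed, expected, size).
#' @export
hosmer_lemeshow <- function(pred_probs, labels, n_groups = 10) {
  keep <- !is.na(pred_probs) & !is.na(labels)
  pred_probs <- pred_probs[keep]
  labels <- labels[keep]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(labels) < 2 * n_groups) {
    stop("need at least ", 2 * n_groups, " observations for ", n_groups, " groups")
  }
  br <- unique(stats::quantile(pred_probs, probs = seq(0, 1, length.out = n_groups + 1)))
  if (length(br) < 2) {
    grp <- factor(rep(1, length(pred_probs)))
  } else {
    grp <- cut(pred_probs, breaks = br, include.lowest = TRUE)
  }
  O <- tapply(labels, grp, sum)
  E <- tapply(pred_probs, grp, sum)
  ng <- tapply(labels, grp, length)
  denom <- E * (1 - E / ng)
  bad <- which(denom <= .Machine$double.eps)
  while (length(bad) && length(O) > 1) {
    warning("merging a risk group with degenerate expected count into its neighbour")
    k <- bad[1]
    j <- if (k == 1) 2L else k - 1L
    O[j] <- O[j] + O[k]; E[j] <- E[j] + E[k]; ng[j] <- ng[j] + ng[k]
    O <- O[-k]; E <- E[-k]; ng <- ng[-k]
    denom <- E * (1 - E / ng)
    bad <- which(denom <= .Machine$double.eps)
  }
  statistic <- sum((O - E)^2 / denom)
  df <- length(O) - 2L
  p <- if (df >= 1) stats::pchisq(statistic, df, lower.tail = FALSE) else NA_real_
  list(statistic = unname(statistic), df = df, p = p,
       table = data.frame(observed = as.vector(O), expected = as.vector(E),
                          size = as.vector(ng)))
}

#' Tie-corrected Spearman rank agreement
#'
#' Spearman's rho computed as the Pearson correlation of midranks (the
#' tie-corrected formula), with a Fisher-transform 95% confidence interval
#' (standard error `1/sqrt(n - 3)`) and two-sided normal p-value.
#'
#' @param x,y Numeric or ordered vectors of equal length, n >= 10.
#' @return List with `rho`, `ci95`, `p`, `n`.
#' @export
spearman_agreement <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 10) stop("need at least 10 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("Spearman correlation undefined for a constant vector")
  }
  rho <- stats::cor(rank(x), rank(y))
  se <- 1 / sqrt(n - 3)
  zr <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  ci <- tanh(zr + c(-1, 1) * 1.96 * se)
  p <- 2 * stats::pnorm(-abs(zr) / se)
  list(rho = rho, ci95 = ci, p = p, n = n)
}
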