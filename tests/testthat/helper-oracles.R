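# Independent oracles used across test files.

# Trapezoidal area under the empirical ROC curve (ties handled by stepping
# through the distinct thresholds).
trapezoid_auc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1))
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Exhaustive pairwise DeLong components (psi kernel over all case-control
# pairs); feasible only at tiny n.
delong_brute <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = length(x), n = length(y))
}

# Closed-form equal-density point of two Normals, restricted to the
# interval between the means.
normal_intersection <- function(m1, s1, m2, s2) {
  a <- 1 / (2 * s1^2) - 1 / (2 * s2^2)
  b <- m2 / s2^2 - m1 / s1^2
  cc <- m1^2 / (2 * s1^2) - m2^2 / (2 * s2^2) - log(s2 / s1)
  roots <- polyroot(c(cc, b, a))
  roots <- Re(roots[abs(Im(roots)) < 1e-9])
  roots[roots > min(m1, m2) & roots < max(m1, m2)][1]
}

# Normal samples truncated to [0, 1] by rejection.
rtruncnorm01 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0 | x > 1)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < 0 | x > 1)
  }
  x
}

# Absolute-tolerance check (expect_equal tolerances are relative).
expect_within <- function(actual, target, tol) {
  testthat::expect_lte(abs(actual - target), tol,
                       label = sprintf("|%.4f - %.4f|", actual, target))
}

# Small synthetic cohort for schema / scoring tests (the generator draws at
# least 100 rows; smaller fixtures take the leading rows).
make_cohort <- function(n = 120, seed = 1) {
  m <- max(n, 100)
  utils::head(generate_cohort(generator_config(n = m, seed = seed))$cohort, n)
}
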