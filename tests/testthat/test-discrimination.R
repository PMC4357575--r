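test_that("AUC handles separation and ties by the midrank convention", {
  expect_equal(auc_mann_whitney(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  # brute force over the 4 case-control pairs: 2 ties of 0.5, 1 win, 1 loss
  expect_equal(auc_mann_whitney(c(1, 1, 2, 2), c(0, 1, 0, 1))$auc, 0.5)
  expect_error(auc_mann_whitney(1:4, c(0, 0, 0, 0)), "both classes")
})

test_that("rank AUC equals the exhaustive pairwise kernel and pROC agrees", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    res <- auc_mann_whitney(scores, labels)
    br <- delong_brute(scores, labels)
    expect_equal(res$auc, br$auc, tolerance = 1e-12)
    expect_equal(sort(res$v10), sort(br$v10), tolerance = 1e-12)
    expect_equal(sort(res$v01), sort(br$v01), tolerance = 1e-12)
  }
  # independent library cross-check of AUC and DeLong variance
  set.seed(42)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.5)
  res <- auc_mann_whitney(scores, labels)
  roc <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(res$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
  expect_equal(res$var, as.numeric(pROC::var(roc)), tolerance = 1e-10)
})

test_that("the DeLong contrast is antisymmetric and exact for self-comparison", {
  set.seed(43)
  labels <- rbinom(60, 1, 0.5)
  a <- rnorm(60)
  b <- rnorm(60)
  fw <- delong_contrast(a, b, labels)
  bw <- delong_contrast(b, a, labels)
  expect_equal(fw$z, -bw$z)
  expect_equal(fw$p, bw$p)
  self <- delong_contrast(a, a, labels)
  expect_identical(self$p, 1)
  expect_identical(self$z, 0)
  # library cross-check of the paired test
  pt <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE, direction = "<"),
                       pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(fw$p, pt$p.value, tolerance = 1e-10)
})

test_that("Harrell's c matches hand counts, the AUC equivalence and survival::concordance", {
  # all-tied risk scores: every usable pair counts half
  expect_equal(harrell_c(1:5, rep(1, 5), rep(2, 5))$c_index, 0.5)
  # 5-subject worked set with one censored subject, counted by hand:
  # usable pairs (event first): (1,2) (1,3) (1,4) (1,5) (2,4) (2,5) (3,4) (3,5)
  # risk 5 > all later -> conc; subject 3 censored at 2.5 contributes as the
  # later member only
  times <- c(1, 2, 2.5, 3, 4)
  events <- c(1, 1, 0, 1, 1)
  risk <- c(5, 4, 1, 2, 3)
  # hand count: pairs from t=1: (5>4),(5>1),(5>2),(5>3) = 4 conc
  #             from t=2: (4>2),(4>3) and (4 vs 1 censored later) = 3 conc
  #             from t=3: (2<3) = 1 disc -> c = 7/8
  res <- harrell_c(times, events, risk)
  expect_equal(res$n_pairs, 8)
  expect_equal(res$c_index, 7 / 8)
  # no censoring, binary time = inverted event label: c equals the AUC
  set.seed(44)
  y <- rbinom(40, 1, 0.5)
  sc <- rnorm(40)
  expect_equal(harrell_c(2 - y, rep(1, 40), sc)$c_index,
               auc_mann_whitney(sc, y)$auc)
  # invariant to strictly monotone transforms of the risk score
  tm <- rexp(60) ; ev <- rbinom(60, 1, 0.6); rs <- rnorm(60)
  expect_equal(harrell_c(tm, ev, rs)$c_index,
               harrell_c(tm, ev, exp(rs))$c_index)
  # independent library cross-check under censoring
  cc <- survival::concordance(survival::Surv(tm, ev) ~ rs, reverse = TRUE)
  expect_equal(harrell_c(tm, ev, rs)$c_index, unname(cc$concordance),
               tolerance = 1e-12)
})

test_that("the paired bootstrap concordance contrast is seeded and sane", {
  set.seed(45)
  n <- 150
  x <- rnorm(n)
  tm <- rexp(n, exp(0.8 * x)); ev <- as.integer(tm < quantile(tm, 0.7))
  good <- x; bad <- rnorm(n)
  r1 <- concordance_contrast(tm, ev, good, bad, n_boot = 200, seed = 7)
  r2 <- concordance_contrast(tm, ev, good, bad, n_boot = 200, seed = 7)
  expect_identical(r1, r2)
  expect_gt(r1$c_a, r1$c_b)
  expect_lt(r1$p, 0.05)  # informative vs noise predictor should separate
})

test_that("the Hosmer-Lemeshow statistic matches its closed forms", {
  # labels exactly equal to expected counts per decile -> statistic 0
  p <- rep(seq(0.05, 0.5, by = 0.05), each = 20)
  y <- unlist(lapply(seq(0.05, 0.5, by = 0.05), function(pp) {
    rep(c(1, 0), c(round(20 * pp), 20 - round(20 * pp)))
  }))
  res <- hosmer_lemeshow(p, y)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(sum(res$table$expected), sum(p))
  # constant predictions collapse to one group: binomial dispersion form
  p2 <- rep(0.3, 50)
  y2 <- rbinom(50, 1, 0.3)
  res2 <- suppressWarnings(hosmer_lemeshow(p2, y2))
  O <- sum(y2); E <- 50 * 0.3
  expect_equal(res2$statistic, (O - E)^2 / (E * (1 - E / 50)))
  # invariant to observation order
  set.seed(46)
  p3 <- runif(200, 0.05, 0.95); y3 <- rbinom(200, 1, p3)
  perm <- sample(200)
  expect_equal(hosmer_lemeshow(p3, y3)$statistic,
               hosmer_lemeshow(p3[perm], y3[perm])$statistic)
})

test_that("Spearman agreement is tie-corrected with a Fisher interval", {
  x <- 1:12
  expect_equal(spearman_agreement(x, x)$rho, 1)
  expect_equal(spearman_agreement(x, rev(x))$rho, -1)
  # tie-corrected rho equals the base-R Spearman on a tied table
  set.seed(47)
  a <- sample(1:4, 30, replace = TRUE)
  b <- sample(1:3, 30, replace = TRUE)
  res <- spearman_agreement(a, b)
  expect_equal(res$rho, cor(a, b, method = "spearman"))
  expect_true(res$ci95[1] <= res$rho && res$rho <= res$ci95[2])
  expect_equal(res$ci95,
               tanh(atanh(res$rho) + c(-1, 1) * 1.96 / sqrt(30 - 3)))
  expect_error(spearman_agreement(rep(1, 12), 1:12), "constant")
  expect_error(spearman_agreement(1:5, 5:1), "at least 10")
})
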