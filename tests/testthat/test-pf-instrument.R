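test_that("SF-36 physical functioning items score 0/50/100", {
  expect_equal(score_sf36_pf_item("limited a lot"), 0)
  expect_equal(score_sf36_pf_item("limited a little"), 50)
  expect_equal(score_sf36_pf_item("not limited at all"), 100)
  expect_error(score_sf36_pf_item("limited"), "unknown")
})

test_that("vitality items use the published point map with reversal", {
  # negatively worded (worn out / tired)
  expect_equal(score_vitality_item("none of the time"), 100)
  expect_equal(score_vitality_item("a little of the time"), 75)
  expect_equal(score_vitality_item("most of the time"), 25)
  expect_equal(score_vitality_item("all of the time"), 0)
  # "some of the time" = 50 by interpolation, under either wording
  expect_equal(score_vitality_item("some of the time"), 50)
  expect_equal(score_vitality_item("some of the time", reverse = TRUE), 50)
  # positively worded (energy / full of life): map flips
  expect_equal(score_vitality_item("all of the time", reverse = TRUE), 100)
  expect_equal(score_vitality_item("none of the time", reverse = TRUE), 0)
  expect_error(score_vitality_item("often"), "unknown")
})

test_that("quartile cuts use linear interpolation between order statistics", {
  comp <- function(x) data.frame(slowness_weakness = x,
                                 endurance_exhaustion = x,
                                 activity_days = x)
  cuts <- compute_quartile_cuts(comp(c(0, 25, 50, 75, 100)))
  expect_equal(cuts$q1_slowness_weakness, 25)
  # degenerate distribution: all mass at one value
  expect_equal(compute_quartile_cuts(comp(rep(7, 10)))$q1_activity, 7)
  # interpolation on {0, 0, 100, 100}
  expect_equal(compute_quartile_cuts(comp(c(0, 0, 100, 100)))$q1_endurance_exhaustion, 0)
  expect_error(compute_quartile_cuts(comp(c(1, 2, 3))), "at least 4")
})

test_that("points and categories follow the scoring rule", {
  cuts <- structure(list(q1_slowness_weakness = 50, q1_endurance_exhaustion = 50,
                         q1_activity = 10), class = "quartile_cuts")
  comp <- data.frame(
    slowness_weakness = c(40, 50, 60, 40, 60),
    endurance_exhaustion = c(40, 50, 60, 60, 60),
    activity_days = c(5, 10, 20, 20, 20),
    weight_loss = c(1, 1, 0, 0, 0)
  )
  res <- score_pf(comp, cuts)
  # row 1: all four criteria met -> 2+1+1+1 = 5, frail
  expect_equal(res$pf_total[1], 5L)
  expect_equal(as.character(res$pf_category[1]), "frail")
  # row 2: boundary values are inclusive (<= Q1 earns points)
  expect_equal(res$pf_total[2], 5L)
  # row 3: nothing met -> robust
  expect_equal(res$pf_total[3], 0L)
  expect_equal(as.character(res$pf_category[3]), "robust")
  # row 4: slowness/weakness alone = 2 points -> pre-frail
  expect_equal(res$pf_total[4], 2L)
  expect_equal(as.character(res$pf_category[4]), "pre-frail")
  expect_equal(res$pf_total,
               res$pf_points_slowness_weakness + res$pf_points_exhaustion +
                 res$pf_points_activity + res$pf_points_weight_loss)
})

test_that("the category is monotone in the total", {
  cats <- pf_category(0:5)
  expect_equal(as.character(cats),
               c("robust", "pre-frail", "pre-frail", "frail", "frail", "frail"))
  expect_true(all(diff(as.integer(cats)) >= 0))
  expect_error(pf_category(6), "0..5")
})

test_that("everyone above the cuts with no weight loss is robust", {
  cuts <- structure(list(q1_slowness_weakness = 10, q1_endurance_exhaustion = 10,
                         q1_activity = 2), class = "quartile_cuts")
  comp <- data.frame(slowness_weakness = runif(20, 50, 100),
                     endurance_exhaustion = runif(20, 50, 100),
                     activity_days = sample(10:30, 20, replace = TRUE),
                     weight_loss = 0)
  res <- score_pf(comp, cuts)
  expect_true(all(res$pf_total == 0))
  expect_true(all(res$pf_category == "robust"))
})

test_that("component scores require at least half the items", {
  cohort <- make_cohort(n = 12, seed = 9)
  cohort[1, sprintf("sf36_pf_%02d", 1:6)] <- NA   # 6 of 10 missing
  cohort[2, sprintf("sf36_pf_%02d", 1:5)] <- NA   # 5 of 10 missing: still scored
  comp <- pf_components(cohort)
  expect_true(is.na(comp$slowness_weakness[1]))
  expect_false(is.na(comp$slowness_weakness[2]))
  manual <- mean(score_sf36_pf_item(unlist(cohort[2, sprintf("sf36_pf_%02d", 6:10)])))
  expect_equal(comp$slowness_weakness[2], manual)
})
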