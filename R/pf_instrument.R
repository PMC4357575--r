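SF36_PF_LEVELS <- c("limited a lot", "limited a little", "not limited at all")
SF36_PF_POINTS <- c(0, 50, 100)

VITALITY_LEVELS <- c("all of the time", "most of the time", "some of the time",
                     "a little of the time", "none of the time")
# Negatively worded items (worn out, tired): none of the time is best.
# "some of the time" = 50 by linear interpolation between the published
# 75 ("a little") and 25 ("most").
VITALITY_POINTS <- c(0, 25, 50, 75, 100)

SF36_PF_COLUMNS <- sprintf("sf36_pf_%02d", 1:10)
VITALITY_COLUMNS <- c(vit_worn_out = FALSE, vit_full_of_life = TRUE,
                      vit_tired = FALSE, vit_energy = TRUE)  # TRUE = reverse-coded

#' Score one SF-36 physical-functioning item
#'
#' Each of the ten items asks whether an activity (e.g. climbing stairs,
#' walking several blocks) is limited: "limited a lot" scores 0,
#' "limited a little" 50, "not limited at all" 100.
#'
#' @param response Character vector of responses; `NA` passes through.
#' @return Numeric points (0/50/100).
#' @export
score_sf36_pf_item <- function(response) {
  idx <- match(response, SF36_PF_LEVELS)
  bad <- which(!is.na(response) & is.na(idx))
  if (length(bad)) {
    stop("unknown SF-36 physical-functioning level '", response[bad[1]],
         "'; levels are: ", paste(sQuote(SF36_PF_LEVELS), collapse = ", "))
  }
  SF36_PF_POINTS[idx]
}

#' Score one SF-36 vitality item
#'
#' For negatively worded items (felt worn out, felt tired) the points are
#' 100 for "none of the time", 75 "a little", 50 "some", 25 "most", 0 "all
#' of the time".  Positively worded items (had a lot of energy, felt full
#' of life) use the reversed map (`reverse = TRUE`).
#'
#' @param response Character vector of responses; `NA` passes through.
#' @param reverse Flip the point map for positively worded items.
#' @return Numeric points in \{0, 25, 50, 75, 100\}.
#' @export
score_vitality_item <- function(response, reverse = FALSE) {
  idx <- match(response, VITALITY_LEVELS)
  bad <- which(!is.na(response) & is.na(idx))
  if (length(bad)) {
    stop("unknown vitality level '", response[bad[1]],
         "'; levels are: ", paste(sQuote(VITALITY_LEVELS), collapse = ", "))
  }
  pts <- VITALITY_POINTS  # "all of the time" -> 0 on negative wording
  if (reverse) pts <- rev(VITALITY_POINTS)
  pts[idx]
}

# Mean of item points, requiring at least half the items to be answered;
# otherwise the component is missing and is routed to the missing policy.
component_mean <- function(points_matrix) {
  n_items <- ncol(points_matrix)
  answered <- rowSums(!is.na(points_matrix))
  m <- rowMeans(points_matrix, na.rm = TRUE)
  m[answered < n_items / 2] <- NA_real_
  m
}

#' Compute the four phenotypic-frailty component scores
#'
#' Components: slowness/weakness (mean of the 10 SF-36 physical-functioning
#' items, 0-100), endurance/exhaustion (mean of the 4 vitality items,
#' 0-100), physical activity (days walked at least 20 minutes in the past
#' 30 days), and unintentional weight loss of 10 lb or more (binary flag).
#' A 0-100 component is missing when fewer than half its items were
#' answered.
#'
#' @param table Cohort data frame with the instrument columns.
#' @return Data frame with columns `slowness_weakness`, `endurance_exhaustion`,
#'   `activity_days`, `weight_loss`.
#' @export
pf_components <- function(table) {
  miss <- setdiff(c(SF36_PF_COLUMNS, names(VITALITY_COLUMNS),
                    "walk20_days", "weight_loss_10lb"), names(table))
  if (length(miss)) stop("missing instrument columns: ", paste(miss, collapse = ", "))
  sw <- vapply(SF36_PF_COLUMNS, function(nm) score_sf36_pf_item(table[[nm]]),
               numeric(nrow(table)))
  vit <- vapply(names(VITALITY_COLUMNS), function(nm) {
    score_vitality_item(table[[nm]], reverse = VITALITY_COLUMNS[[nm]])
  }, numeric(nrow(table)))
  if (nrow(table) == 1L) {
    sw <- matrix(sw, nrow = 1L)
    vit <- matrix(vit, nrow = 1L)
  }
  data.frame(
    slowness_weakness = component_mean(sw),
    endurance_exhaustion = component_mean(vit),
    activity_days = as.numeric(table$walk20_days),
    weight_loss = as.numeric(table$weight_loss_10lb)
  )
}

#' Empirical lowest-quartile cutoffs for the continuous components
#'
#' Points are awarded for a component score in the lowest quartile of its
#' distribution in the scoring sample.  The 25th percentile uses the linear
#' interpolation between order statistics (R quantile type 7 by default;
#' the variant is exposed so other conventions are reproducible).
#'
#' @param components Data frame from [pf_components()].
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return Named list of class `quartile_cuts` with elements
#'   `q1_slowness_weakness`, `q1_endurance_exhaustion`, `q1_activity`.
#' @export
compute_quartile_cuts <- function(components, type = 7) {
  q1 <- function(x, what) {
    x <- x[!is.na(x)]
    if (length(x) < 4) stop("need at least 4 non-missing values for the ",
                            what, " quartile cut")
    unname(stats::quantile(x, probs = 0.25, type = type))
  }
  structure(list(
    q1_slowness_weakness = q1(components$slowness_weakness, "slowness/weakness"),
    q1_endurance_exhaustion = q1(components$endurance_exhaustion,
                                 "endurance/exhaustion"),
    q1_activity = q1(components$activity_days, "physical-activity")
  ), class = "quartile_cuts")
}

#' Write quartile cuts to a JSON sidecar / read them back
#'
#' Serialising the cuts allows out-of-sample scoring with the cutoffs of a
#' reference sample.
#'
#' @param cuts A `quartile_cuts` object.
#' @param path JSON file path.
#' @return `path` invisibly (write); a `quartile_cuts` object (read).
#' @export
write_quartile_cuts <- function(cuts, path) {
  jsonlite::write_json(unclass(cuts), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_quartile_cuts
#' @export
read_quartile_cuts <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "quartile_cuts")
}

PF_CATEGORIES <- c("robust", "pre-frail", "frail")

#' Aggregate phenotypic frailty score and category
#'
#' Point assignment: slowness/weakness in the lowest quartile earns 2
#' points (it stands in for the two separate slowness and weakness criteria
#' of the original phenotype); endurance/exhaustion and physical activity
#' in their lowest quartiles earn 1 point each; reported unintentional
#' weight loss earns 1 point.  The lowest-quartile boundary is inclusive
#' (score <= Q1) so that ties at the cut score consistently.  Totals of 0
#' are robust, 1-2 pre-frail, 3-5 frail.
#'
#' @param components Data frame from [pf_components()].
#' @param cuts Quartile cuts from [compute_quartile_cuts()], either from the
#'   same sample or supplied externally for out-of-sample scoring.
#' @return Data frame with the four point columns, `pf_total` (0-5) and
#'   `pf_category` (ordered factor robust < pre-frail < frail).
#' @export
score_pf <- function(components, cuts) {
  stopifnot(inherits(cuts, "quartile_cuts"))
  p_sw <- 2L * (components$slowness_weakness <= cuts$q1_slowness_weakness)
  p_ex <- 1L * (components$endurance_exhaustion <= cuts$q1_endurance_exhaustion)
  p_act <- 1L * (components$activity_days <= cuts$q1_activity)
  p_wl <- 1L * (components$weight_loss > 0)
  total <- p_sw + p_ex + p_act + p_wl
  data.frame(
    pf_points_slowness_weakness = p_sw,
    pf_points_exhaustion = p_ex,
    pf_points_activity = p_act,
    pf_points_weight_loss = p_wl,
    pf_total = as.integer(total),
    pf_category = pf_category(total)
  )
}

#' Map a phenotypic frailty total to its category
#'
#' @param total Integer vector of aggregate scores 0-5.
#' @return Ordered factor with levels robust < pre-frail < frail
#'   (0 robust; 1-2 pre-frail; 3-5 frail).
#' @export
pf_category <- function(total) {
  if (any(!is.na(total) & (total < 0 | total > 5))) {
    stop("phenotypic frailty totals must lie in 0..5")
  }
  cat <- ifelse(total == 0, "robust",
                ifelse(total <= 2, "pre-frail", "frail"))
  factor(cat, levels = PF_CATEGORIES, ordered = TRUE)
}

#' Score a cohort table with both frailty instruments
#'
#' Convenience wrapper: computes the phenotypic frailty components, cuts,
#' points and category, codes the deficit items and appends the frailty
#' index.  Missing instrument responses should be resolved first with
#' [apply_missing_policy()].
#'
#' @param table A validated cohort data frame.
#' @param codebook A `deficit_codebook`.
#' @param cuts Optional externally supplied `quartile_cuts`; by default the
#'   cuts are computed on `table` itself.
#' @return The table with appended component, point, `pf_total`,
#'   `pf_category` and `fi` columns; the cuts used are attached as
#'   attribute `"quartile_cuts"`.
#' @export
score_cohort <- function(table, codebook = default_codebook(), cuts = NULL) {
  comp <- pf_components(table)
  if (is.null(cuts)) cuts <- compute_quartile_cuts(comp)
  pf <- score_pf(comp, cuts)
  out <- cbind(table, comp, pf)
  out <- add_fi(out, codebook)
  attr(out, "quartile_cuts") <- cuts
  out
}
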