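#' Compute the deficit-accumulation frailty index
#'
#' The frailty index (FI) of a participant is the sum of her coded deficit
#' values divided by the total number of items considered, giving a number
#' in \[0, 1\]; higher values indicate greater deficit accumulation.  For
#' example, a participant with 5 deficits coded 1, 25 coded 0 and 4 coded
#' 0.25 accumulates 6 points over 34 items, an FI of 6/34 = 0.18 (2 dp).
#'
#' The denominator is fixed at the declared item count even when some items
#' were imputed upstream (`denominator = "fixed"`, the default).  Some FI
#' literatures divide by the number of answered items instead; set
#' `denominator = "answered"` for that convention (missing values are then
#' dropped item-wise).
#'
#' @param values Either a numeric vector of `n_items` coded deficit values
#'   in \[0, 1\] (one participant), or a numeric matrix with `n_items`
#'   columns (one row per participant).
#' @param n_items Expected number of items (default 34).
#' @param denominator `"fixed"` divides by `n_items`; `"answered"` divides
#'   by the per-row count of non-missing values.
#' @return A numeric vector of FI values with attribute `n_items_used`.
#' @examples
#' compute_fi(c(rep(1, 5), rep(0, 25), rep(0.25, 4)))  # 6/34 = 0.1765
#' @export
compute_fi <- function(values, n_items = 34L,
                       denominator = c("fixed", "answered")) {
  denominator <- match.arg(denominator)
  if (is.matrix(values) || is.data.frame(values)) {
    values <- as.matrix(values)
    if (ncol(values) != n_items) {
      stop("expected ", n_items, " deficit columns, found ", ncol(values))
    }
  } else {
    if (length(values) != n_items) {
      stop("expected ", n_items, " deficit values, found ", length(values))
    }
    values <- matrix(as.numeric(values), nrow = 1L)
  }
  if (denominator == "fixed" && anyNA(values)) {
    stop("missing deficit values: resolve missingness upstream ",
         "(see apply_missing_policy) or use denominator = \"answered\"")
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("deficit values must lie in [0, 1]; found range [",
         signif(rng[1], 3), ", ", signif(rng[2], 3), "]")
  }
  used <- switch(denominator,
    fixed = rep(n_items, nrow(values)),
    answered = rowSums(!is.na(values))
  )
  if (any(used == 0)) stop("a row has no answered deficit items")
  fi <- rowSums(values, na.rm = TRUE) / used
  attr(fi, "n_items_used") <- used
  fi
}

#' Append the frailty index to a cohort table
#'
#' Codes the 34 deficit columns through the codebook and appends an `fi`
#' column.  Missing responses must be resolved first (see
#' [apply_missing_policy()]) unless `denominator = "answered"`.
#'
#' @inheritParams code_deficit_columns
#' @inheritParams compute_fi
#' @return The table with an added numeric column `fi`.
#' @export
add_fi <- function(table, codebook = default_codebook(),
                   denominator = c("fixed", "answered")) {
  coded <- code_deficit_columns(table, codebook)
  fi <- compute_fi(coded, n_items = length(codebook$items),
                   denominator = denominator)
  table$fi <- as.numeric(fi)
  table
}
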