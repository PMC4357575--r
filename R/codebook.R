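#' Read a deficit codebook from a YAML file
#'
#' A deficit codebook is a declarative map from each of the 34 health-deficit
#' items to an *ordered* set of response levels and their numeric values in
#' \[0, 1\].  Items are tagged with one of four domains: symptoms and signs
#' (6 items), comorbidity (15), activities of daily living (12), and
#' healthcare utilization (1).  The codebook is data, not code: an
#' alternative item set with the same structure can be dropped in without
#' touching the scoring functions.
#'
#' @param path Path to a YAML codebook file.  The file must contain a
#'   top-level `items` list; each entry has an `id`, a `domain`, and a
#'   `levels` mapping from response label to value.
#' @return An object of class `deficit_codebook`: a list with elements
#'   `items` (named list of per-item descriptors) and `version`.
#' @seealso [default_codebook()], [code_deficit()], [compute_fi()]
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop("codebook file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$items)) stop("codebook file has no 'items' entry: ", path)
  items <- lapply(raw$items, function(it) {
    vals <- unlist(it$levels, use.names = TRUE)
    list(
      id = it$id,
      domain = it$domain,
      levels = names(vals),
      values = as.numeric(unname(vals))
    )
  })
  names(items) <- vapply(items, `[[`, character(1), "id")
  cb <- structure(
    list(items = items, version = raw$version %||% 1L),
    class = "deficit_codebook"
  )
  validate_codebook(cb)
  cb
}

#' Default 34-item deficit codebook
#'
#' Returns the codebook shipped with the package.  It follows the published
#' domain structure (6 symptoms/signs, 15 comorbidities, 12 activities of
#' daily living, 1 healthcare-utilization item) with evenly spaced values
#' for polychotomous items and \{0, 1\} for binary items.  The shipped item
#' wording is a synthetic structural stand-in for the original survey
#' instrument, which is not publicly deposited; a verbatim codebook can be
#' substituted via [read_codebook()].
#'
#' @return A `deficit_codebook` object.
#' @export
default_codebook <- function() {
  path <- system.file("extdata", "deficit_codebook.yaml",
                      package = "frailtycompare", mustWork = TRUE)
  read_codebook(path)
}

#' Validate the structure of a deficit codebook
#'
#' Checks the structural invariants: exactly 34 items; domain counts
#' 6/15/12/1; every level map spans \[0, 1\] (contains both 0 and 1) and is
#' non-decreasing over the declared level order; item ids unique.
#'
#' @param codebook A `deficit_codebook` object.
#' @return The codebook, invisibly, if valid; otherwise an error.
#' @export
validate_codebook <- function(codebook) {
  stopifnot(inherits(codebook, "deficit_codebook"))
  items <- codebook$items
  if (length(items) != 34L) {
    stop("codebook must declare exactly 34 items, found ", length(items))
  }
  ids <- names(items)
  if (anyDuplicated(ids)) stop("duplicate item ids in codebook")
  expected <- c(symptoms_signs = 6L, comorbidity = 15L, adl = 12L,
                healthcare_utilization = 1L)
  domains <- vapply(items, `[[`, character(1), "domain")
  counts <- table(factor(domains, levels = names(expected)))
  bad <- names(expected)[counts != expected]
  if (length(bad)) {
    stop("domain counts must be 6/15/12/1 ",
         "(symptoms_signs/comorbidity/adl/healthcare_utilization); ",
         "mismatch in: ", paste(bad, collapse = ", "))
  }
  for (it in items) {
    v <- it$values
    if (any(v < 0 | v > 1)) stop("item '", it$id, "': values outside [0, 1]")
    if (!any(v == 0) || !any(v == 1)) {
      stop("item '", it$id, "': level values must include both 0 and 1")
    }
    if (is.unsorted(v)) {
      stop("item '", it$id, "': values must be non-decreasing over level order")
    }
    if (anyDuplicated(it$levels)) stop("item '", it$id, "': duplicate levels")
  }
  invisible(codebook)
}

#' Code a deficit response to its numeric value
#'
#' Maps a response label for one codebook item to its value in \[0, 1\].
#' Vectorised over `response`.
#'
#' @param codebook A `deficit_codebook`.
#' @param item_id Item identifier (must be in the codebook).
#' @param response Character vector of response labels; `NA` passes through.
#' @return Numeric vector of deficit values in \[0, 1\] (`NA` where the
#'   response was `NA`).
#' @examples
#' cb <- default_codebook()
#' code_deficit(cb, "feels_full_of_life", "all of the time")   # 0
#' code_deficit(cb, "feels_full_of_life", "none of the time")  # 1
#' @export
code_deficit <- function(codebook, item_id, response) {
  stopifnot(inherits(codebook, "deficit_codebook"))
  it <- codebook$items[[item_id]]
  if (is.null(it)) stop("unknown codebook item: '", item_id, "'")
  idx <- match(response, it$levels)
  bad <- which(!is.na(response) & is.na(idx))
  if (length(bad)) {
    stop("item '", item_id, "': undeclared level '", response[bad[1]],
         "'; declared levels are: ",
         paste(sQuote(it$levels), collapse = ", "))
  }
  it$values[idx]
}

#' Code all deficit columns of a cohort table
#'
#' @param table A cohort data frame containing one column per codebook item.
#' @param codebook A `deficit_codebook`.
#' @return A numeric matrix with one column per item, values in \[0, 1\].
#' @export
code_deficit_columns <- function(table, codebook) {
  stopifnot(inherits(codebook, "deficit_codebook"))
  ids <- names(codebook$items)
  missing_cols <- setdiff(ids, names(table))
  if (length(missing_cols)) {
    stop("cohort table lacks deficit columns: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- vapply(ids, function(id) code_deficit(codebook, id, table[[id]]),
                numeric(nrow(table)))
  if (nrow(table) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, ids))
  out
}
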