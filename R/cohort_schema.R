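#' Load the cohort column manifest
#'
#' The schema is a versioned YAML manifest declaring every non-deficit
#' column of a cohort table: its type (`id`, `numeric`, `integer`,
#' `binary`, `ordinal`) and, for ordinals, the declared response levels.
#' Deficit columns are declared by the codebook instead.
#'
#' @param path Path to a schema YAML file; the default loads the manifest
#'   shipped with the package.
#' @return An object of class `cohort_schema` (list with `columns`,
#'   `version`).
#' @export
cohort_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_schema.yaml",
                        package = "frailtycompare", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  cols <- raw$columns
  names(cols) <- vapply(cols, `[[`, character(1), "name")
  structure(list(columns = cols, version = raw$version %||% 1L),
            class = "cohort_schema")
}

schema_column_names <- function(schema, codebook) {
  c(names(schema$columns), names(codebook$items))
}

# Coerce raw character columns to their schema types (in place).
coerce_schema_types <- function(table, schema) {
  for (col in schema$columns) {
    nm <- col$name
    if (col$type %in% c("numeric", "integer", "binary")) {
      x <- table[[nm]]
      if (is.character(x)) x[x == ""] <- NA
      x <- as.numeric(x)
      if (col$type != "numeric" && all(is.na(x) | x == round(x))) {
        x <- as.integer(x)
      }
      table[[nm]] <- x
    } else {
      x <- as.character(table[[nm]])
      x[x == ""] <- NA
      table[[nm]] <- x
    }
  }
  table
}

#' Validate a cohort table against the schema and codebook
#'
#' Column-level violations (unknown column, undeclared ordinal level,
#' non-binary values) are errors.  Row-level invariant violations (age
#' below 55, fracture time out of range, integer bounds) are collected and
#' returned as a data frame so that callers can report rather than silently
#' drop offending rows.
#'
#' @param table A cohort data frame.
#' @param codebook A `deficit_codebook`.
#' @param schema A `cohort_schema`.
#' @return A data frame of problems with columns `row`, `participant_id`,
#'   `column`, `problem` (zero rows when the table is clean).
#' @export
validate_cohort <- function(table, codebook = default_codebook(),
                            schema = cohort_schema()) {
  expected <- schema_column_names(schema, codebook)
  unknown <- setdiff(names(table), expected)
  if (length(unknown)) {
    stop("unknown column(s) not in schema manifest: ",
         paste(unknown, collapse = ", "))
  }
  absent <- setdiff(expected, names(table))
  if (length(absent)) {
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  }
  ids <- as.character(table$participant_id)

  # ordinal levels (schema)
  for (col in schema$columns) {
    nm <- col$name
    x <- table[[nm]]
    if (col$type == "ordinal") {
      bad <- which(!is.na(x) & !(x %in% col$levels))
      if (length(bad)) {
        stop("column '", nm, "', row ", bad[1], " (participant ",
             ids[bad[1]], "): value '", x[bad[1]],
             "' is not a declared level; levels are: ",
             paste(sQuote(col$levels), collapse = ", "))
      }
    } else if (col$type == "binary") {
      if (!is_binary01(x)) {
        stop("column '", nm, "': binary columns must be coded 0/1")
      }
    }
  }
  # deficit levels (codebook): code_deficit errors on undeclared levels
  for (id in names(codebook$items)) code_deficit(codebook, id, table[[id]])

  problems <- list()
  note <- function(rows, column, msg) {
    if (length(rows)) {
      problems[[length(problems) + 1L]] <<- data.frame(
        row = rows, participant_id = ids[rows], column = column,
        problem = msg, stringsAsFactors = FALSE)
    }
  }
  note(which(!is.na(table$age) & table$age < 55), "age",
       "age below eligibility bound of 55 years")
  note(which(!is.na(table$bmi) & table$bmi <= 0), "bmi", "BMI must be > 0")
  ft <- table$fracture_time
  note(which(!is.na(ft) & (ft <= 0 | ft > 3.05)), "fracture_time",
       "fracture_time must lie in (0, 3] (small tolerance)")
  note(which(is.na(ft) & !is.na(table$fracture_event)), "fracture_time",
       "fracture_time must be present when fracture follow-up is observed")
  wd <- table$walk20_days
  note(which(!is.na(wd) & (wd < 0 | wd > 30 | wd != round(wd))),
       "walk20_days", "must be an integer between 0 and 30")
  if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(), participant_id = character(),
               column = character(), problem = character(),
               stringsAsFactors = FALSE)
}

#' Read a cohort table from CSV
#'
#' Reads a UTF-8 CSV with mandatory header, coerces columns to their schema
#' types (empty string is the missing sentinel), and validates the table.
#' Schema errors (unknown columns, undeclared levels) are always errors.
#' Row-level invariant failures are an error under `strict = TRUE`
#' (listing the offending rows); under `strict = FALSE` the rows are kept
#' and the problem report is attached as attribute `"validation"` with a
#' warning.
#'
#' @param path CSV file path.
#' @param codebook A `deficit_codebook` used to validate deficit columns.
#' @param schema A `cohort_schema`; pass [cohort_schema()] with a custom
#'   path to override the shipped manifest.
#' @param strict Error on row-invariant failures (default `TRUE`).
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path, codebook = default_codebook(),
                        schema = cohort_schema(), strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  table <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  table <- coerce_schema_types(table, schema)
  table$participant_id <- as.character(table$participant_id)
  problems <- validate_cohort(table, codebook, schema)
  if (nrow(problems)) {
    msg <- paste0("row ", problems$row, " (participant ",
                  problems$participant_id, "), ", problems$column, ": ",
                  problems$problem)
    if (strict) {
      stop("cohort validation failed:\n  ",
           paste(utils::head(msg, 10), collapse = "\n  "),
           if (nrow(problems) > 10) "\n  ..." else "")
    }
    warning(nrow(problems), " row-invariant violation(s); see attr(x, 'validation')")
    attr(table, "validation") <- problems
  }
  table
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: numerics are written with full precision so
#' that a write/read round trip reproduces the value matrix exactly;
#' missing values are written as the empty string.
#'
#' @param table A cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  out <- table
  for (nm in names(out)) {
    x <- out[[nm]]
    if (is.numeric(x)) {
      s <- sprintf("%.17g", x)
      s[is.na(x)] <- ""
      out[[nm]] <- s
    } else {
      x <- as.character(x)
      x[is.na(x)] <- ""
      out[[nm]] <- x
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a missing-data policy
#'
#' Variables with a missing fraction below `threshold` are filled
#' deterministically with the within-group median (numeric) or mode
#' (categorical).  Variables at or above the threshold are filled by
#' seeded random draws from the variable's observed within-group empirical
#' distribution - a single-imputation simplification of multiple
#' imputation, adequate here because imputation uncertainty is not
#' propagated into any reported estimate.
#'
#' @param threshold Missing-fraction threshold in (0, 1); default 0.10.
#' @param numeric_fill `"median"` (default) or `"mean"` for numerics below
#'   the threshold.
#' @param group_key Optional column name defining fill groups (e.g. the
#'   phenotypic frailty category once available); `NULL` uses the full
#'   sample as one group.
#' @return An object of class `missing_policy`.
#' @export
missing_policy <- function(threshold = 0.10,
                           numeric_fill = c("median", "mean"),
                           group_key = NULL) {
  numeric_fill <- match.arg(numeric_fill)
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  structure(list(threshold = threshold, numeric_fill = numeric_fill,
                 group_key = group_key),
            class = "missing_policy")
}

#' Apply the missing-data policy to a cohort table
#'
#' Fills missing cells column by column according to the policy.  Observed
#' cells are never altered; every filled cell is recorded in the imputation
#' log (attribute `"imputation_log"`, also retrievable with
#' [imputation_log()]).  The operation is idempotent on its own output.
#'
#' @param table A cohort data frame.
#' @param policy A [missing_policy()].
#' @param seed Integer seed for the stochastic (at/above-threshold) fills.
#' @param columns Columns eligible for imputation; defaults to every column
#'   except the identifier and the outcome columns (`fall_year3`,
#'   `fracture_event`, `fracture_time`, `death`), which are left missing
#'   for complete-case outcome modelling.
#' @return The filled table with attribute `"imputation_log"`: a data frame
#'   with one row per filled cell (`row`, `column`, `method`, `value`).
#' @export
apply_missing_policy <- function(table, policy = missing_policy(), seed = 1L,
                                 columns = NULL) {
  stopifnot(inherits(policy, "missing_policy"))
  if (is.null(columns)) {
    columns <- setdiff(names(table),
                       c("participant_id", "fall_year3", "fracture_event",
                         "fracture_time", "death"))
  }
  key <- policy$group_key
  grp <- if (is.null(key)) rep("all", nrow(table)) else {
    g <- as.character(table[[key]])
    g[is.na(g)] <- ".missing_group"
    g
  }
  log <- list()
  out <- with_seed(seed, {
    tab <- table
    for (nm in columns) {
      x <- tab[[nm]]
      miss <- which(is.na(x))
      if (!length(miss)) next
      frac <- length(miss) / length(x)
      if (frac == 1) stop("column '", nm, "' is 100% missing: nothing to impute from")
      stochastic <- frac >= policy$threshold
      for (g in unique(grp[miss])) {
        rows <- miss[grp[miss] == g]
        obs <- x[!is.na(x) & grp == g]
        if (!length(obs)) obs <- x[!is.na(x)]  # empty group: fall back to full sample
        if (stochastic) {
          fill <- sample(obs, length(rows), replace = TRUE)
          method <- "empirical_draw"
        } else if (is.numeric(x)) {
          fill <- rep(switch(policy$numeric_fill,
                             median = stats::median(obs),
                             mean = mean(obs)), length(rows))
          method <- paste0("group_", policy$numeric_fill)
        } else {
          fill <- rep(stat_mode(obs), length(rows))
          method <- "group_mode"
        }
        x[rows] <- fill
        log[[length(log) + 1L]] <- data.frame(
          row = rows, column = nm, method = method,
          value = as.character(fill), stringsAsFactors = FALSE)
      }
      tab[[nm]] <- x
    }
    tab
  })
  attr(out, "imputation_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(row = integer(), column = character(), method = character(),
               value = character(), stringsAsFactors = FALSE)
  out
}

#' Retrieve the imputation log from a filled table
#' @param table A table returned by [apply_missing_policy()].
#' @return The imputation-log data frame (zero rows if nothing was filled).
#' @export
imputation_log <- function(table) {
  attr(table, "imputation_log") %||%
    data.frame(row = integer(), column = character(), method = character(),
               value = character(), stringsAsFactors = FALSE)
}
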