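#' @title Dataset container for bounded-missingness growth data
#'
#' @description
#' An `mi_dataset` bundles everything one study table carries:
#' \itemize{
#'   \item `values`: data frame of non-temporal variables, one row per
#'     observation, `NA` marking missing cells;
#'   \item `meta`: variable metadata (`name`, `role`, `kind`, `units`,
#'     `temporal`); roles are `predictor`, `response`, `blocking_dummy`,
#'     `categorical_raw`, `auxiliary`;
#'   \item `series`: long-form daily profiles (`observation`, `variable`,
#'     `day`, `value`) for variables flagged `temporal`; day 0 is inoculation;
#'   \item `collection_day`: integer day of biomass harvest per observation.
#' }
#' Temporal variables live only in `series`; their day-of-harvest snapshot and
#' k-day averages are derived downstream (see [build_design()]).
#'
#' @param values Data frame of per-observation values. Must carry an
#'   `observation` id column or row names.
#' @param meta Data frame of variable metadata.
#' @param series Long-form daily data frame, or `NULL` when no variable is
#'   temporal.
#' @param collection_day Integer vector named by observation id.
#' @return An object of class `mi_dataset`.
#' @export
mi_dataset <- function(values, meta, series = NULL, collection_day = NULL) {
  if (!is.null(values$observation)) {
    obs <- as.character(values$observation)
    values <- values[, setdiff(names(values), "observation"), drop = FALSE]
  } else {
    obs <- rownames(values)
  }
  if (is.null(obs) || anyDuplicated(obs)) {
    stop("observations must carry unique ids", call. = FALSE)
  }
  rownames(values) <- obs
  if (nrow(values) < 2) stop("need at least 2 observations", call. = FALSE)

  meta <- validate_meta(meta)
  if (is.null(series)) {
    series <- data.frame(observation = character(), variable = character(),
                         day = integer(), value = numeric())
  }
  series$observation <- as.character(series$observation)
  series$variable <- as.character(series$variable)

  if (is.null(collection_day)) {
    collection_day <- setNames(rep(0L, length(obs)), obs)
  }
  collection_day <- collection_day[obs]
  if (anyNA(collection_day) || any(collection_day < 0)) {
    stop("collection_day must be a non-negative integer per observation",
         call. = FALSE)
  }

  tabular <- meta$name[!meta$temporal & meta$role != "categorical_raw"]
  missing_cols <- setdiff(tabular, names(values))
  if (length(missing_cols)) {
    stop("variables declared in metadata but absent from values: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(values), meta$name)
  if (length(extra)) {
    stop("columns without metadata: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  # numeric storage is double everywhere so round trips are bit-exact
  num <- meta$name[meta$kind %in% c("numeric", "binary")]
  for (v in intersect(num, names(values))) {
    values[[v]] <- as.double(values[[v]])
  }
  bin <- meta$name[meta$kind == "binary" & !meta$temporal]
  for (v in intersect(bin, names(values))) {
    x <- values[[v]]
    bad <- !is.na(x) & !(x %in% c(0, 1))
    if (any(bad)) {
      stop(sprintf("binary column '%s' contains non-{0,1} values (e.g. %s)",
                   v, x[bad][1]), call. = FALSE)
    }
  }
  tvars <- meta$name[meta$temporal]
  bad_series <- setdiff(unique(series$variable), tvars)
  if (length(bad_series)) {
    stop("series rows for non-temporal variables: ",
         paste(bad_series, collapse = ", "), call. = FALSE)
  }

  structure(list(values = values, meta = meta, series = series,
                 obs = obs, collection_day = collection_day),
            class = "mi_dataset")
}

valid_roles <- c("predictor", "response", "blocking_dummy",
                 "categorical_raw", "auxiliary")
valid_kinds <- c("numeric", "binary", "categorical")

# Response names must declare their type: percent of total fatty acids,
# ratio to C16:0, or percent of ash-free dry weight.
response_pattern <- "_(pctFA|ratioC16|pctAFDW)$"

validate_meta <- function(meta) {
  req <- c("name", "role", "kind")
  if (!all(req %in% names(meta))) {
    stop("metadata needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  meta$name <- as.character(meta$name)
  if (anyDuplicated(meta$name)) stop("duplicate variable names", call. = FALSE)
  bad_role <- setdiff(meta$role, valid_roles)
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  bad_kind <- setdiff(meta$kind, valid_kinds)
  if (length(bad_kind)) {
    stop("unknown kind(s): ", paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  if (is.null(meta$units)) meta$units <- ""
  if (is.null(meta$temporal)) meta$temporal <- FALSE
  meta$temporal <- as.logical(meta$temporal)
  bd <- meta$role == "blocking_dummy"
  if (any(bd & meta$kind != "binary")) {
    stop("blocking_dummy variables must be binary", call. = FALSE)
  }
  resp <- meta$name[meta$role == "response"]
  bad_resp <- resp[!grepl(response_pattern, resp)]
  if (length(bad_resp)) {
    stop("response names must end in _pctFA, _ratioC16 or _pctAFDW: ",
         paste(bad_resp, collapse = ", "), call. = FALSE)
  }
  meta
}

#' @export
print.mi_dataset <- function(x, ...) {
  tally <- table(x$meta$role)
  cat(sprintf("mi_dataset: %d observations, %d variables\n",
              length(x$obs), nrow(x$meta)))
  cat("  roles:", paste(sprintf("%s=%d", names(tally), tally), collapse = ", "),
      "\n")
  n_missing <- sum(is.na(x$values)) + sum(is.na(x$series$value))
  cat(sprintf("  missing cells: %d (values + daily series)\n", n_missing))
  invisible(x)
}

#' Construct a validated bounds table
#'
#' Per missing cell, a `[lower, upper]` interval. Cells are keyed by
#' `(observation, variable)` and additionally by `day` for temporal variables
#' (`NA` day for tabular cells).
#'
#' @param df Data frame with columns `observation`, `variable`, `day`,
#'   `lower`, `upper`.
#' @return The validated data frame, classed `bounds_table`.
#' @export
bounds_table <- function(df) {
  if (nrow(df) == 0) {
    df <- data.frame(observation = character(), variable = character(),
                     day = integer(), lower = numeric(), upper = numeric())
  }
  req <- c("observation", "variable", "lower", "upper")
  if (!all(req %in% names(df))) {
    stop("bounds need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$day)) df$day <- NA_integer_
  df$observation <- as.character(df$observation)
  df$variable <- as.character(df$variable)
  bad <- which(!is.finite(df$lower) | !is.finite(df$upper))
  if (length(bad)) {
    stop("non-finite bounds for cell(s): ",
         paste(cell_label(df[bad, , drop = FALSE]), collapse = "; "),
         call. = FALSE)
  }
  bad <- which(df$lower > df$upper)
  if (length(bad)) {
    stop("lower > upper for cell(s): ",
         paste(cell_label(df[bad, , drop = FALSE]), collapse = "; "),
         call. = FALSE)
  }
  key <- bounds_key(df)
  if (anyDuplicated(key)) {
    stop("duplicate bound entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  class(df) <- c("bounds_table", "data.frame")
  df
}

cell_label <- function(df) {
  ifelse(is.na(df$day),
         sprintf("(%s, %s)", df$observation, df$variable),
         sprintf("(%s, %s, day %s)", df$observation, df$variable, df$day))
}

bounds_key <- function(df) {
  paste(df$observation, df$variable,
        ifelse(is.na(df$day), ".", df$day), sep = "\r")
}

#' Enumerate missing cells of a dataset
#'
#' @param dataset An [mi_dataset()].
#' @param roles Variable roles to include.
#' @return Data frame `observation`, `variable`, `day` (`NA` for tabular
#'   cells), one row per missing cell.
#' @export
missing_cells <- function(dataset, roles = valid_roles) {
  vars <- dataset$meta$name[dataset$meta$role %in% roles]
  out <- list()
  tab <- intersect(names(dataset$values), vars)
  for (v in tab) {
    idx <- which(is.na(dataset$values[[v]]))
    if (length(idx)) {
      out[[length(out) + 1L]] <- data.frame(
        observation = dataset$obs[idx], variable = v, day = NA_integer_)
    }
  }
  s <- dataset$series
  sel <- is.na(s$value) & s$variable %in% vars
  if (any(sel)) {
    out[[length(out) + 1L]] <- data.frame(
      observation = s$observation[sel], variable = s$variable[sel],
      day = s$day[sel])
  }
  if (!length(out)) {
    return(data.frame(observation = character(), variable = character(),
                      day = integer()))
  }
  do.call(rbind, out)
}

#' Load a dataset triple from delimited text
#'
#' Reads the four comma-delimited files of the on-disk layout
#' (`observations.csv`, `variables.csv`, `bounds.csv` and optionally
#' `series.csv`), normalizes missing markers (empty field or literal `NA`),
#' and cross-validates: a bound entry pointing at an observed cell is dropped
#' with a warning, while a missing predictor cell lacking a bound is an error
#' that lists the offending cells.
#'
#' @param data_path Path to `observations.csv` (columns: `observation`,
#'   `collection_day`, then one column per non-temporal variable).
#' @param meta_path Path to `variables.csv` (columns `name`, `role`, `kind`,
#'   `units`, `temporal`).
#' @param bounds_path Path to `bounds.csv` (columns `observation`,
#'   `variable`, `day`, `lower`, `upper`).
#' @param series_path Optional path to `series.csv` (long form:
#'   `observation`, `variable`, `day`, `value`).
#' @return List with elements `dataset` ([mi_dataset()]), `meta` and
#'   `bounds` ([bounds_table()]).
#' @export
load_dataset <- function(data_path, meta_path, bounds_path,
                         series_path = NULL) {
  stopifnot(file.exists(data_path), file.exists(meta_path),
            file.exists(bounds_path))
  na_marks <- c("", "NA")
  raw <- read.csv(data_path, na.strings = na_marks, check.names = FALSE,
                  stringsAsFactors = FALSE)
  meta <- read.csv(meta_path, na.strings = na_marks, check.names = FALSE,
                   stringsAsFactors = FALSE)
  bnd <- read.csv(bounds_path, na.strings = na_marks, check.names = FALSE,
                  stringsAsFactors = FALSE)
  series <- NULL
  if (!is.null(series_path) && file.exists(series_path)) {
    series <- read.csv(series_path, na.strings = na_marks,
                       check.names = FALSE, stringsAsFactors = FALSE)
  }
  cd <- NULL
  if ("collection_day" %in% names(raw)) {
    cd <- setNames(as.integer(raw$collection_day), as.character(raw$observation))
    raw <- raw[, setdiff(names(raw), "collection_day"), drop = FALSE]
  }
  ds <- mi_dataset(raw, meta, series = series, collection_day = cd)
  bounds <- bounds_table(bnd)

  miss <- missing_cells(ds)
  mkey <- bounds_key(miss)
  bkey <- bounds_key(bounds)
  stale <- !(bkey %in% mkey)
  if (any(stale)) {
    warning("dropping ", sum(stale),
            " bound entr", if (sum(stale) == 1) "y" else "ies",
            " for non-missing cells: ",
            paste(head(cell_label(bounds[stale, , drop = FALSE]), 5),
                  collapse = "; "), call. = FALSE)
    bounds <- bounds_table(as.data.frame(bounds)[!stale, , drop = FALSE])
    bkey <- bounds_key(bounds)
  }
  pred_miss <- missing_cells(ds, roles = "predictor")
  uncovered <- !(bounds_key(pred_miss) %in% bkey)
  if (any(uncovered)) {
    stop("missing predictor cells without bounds: ",
         paste(cell_label(pred_miss[uncovered, , drop = FALSE]),
               collapse = "; "), call. = FALSE)
  }
  list(dataset = ds, meta = ds$meta, bounds = bounds)
}

# full-precision numeric formatting so that write -> read is bit-exact
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a dataset triple as delimited text
#'
#' Inverse of [load_dataset()]: emits `observations.csv`, `variables.csv`,
#' `bounds.csv` and `series.csv` into `dir`. Numbers are written with 17
#' significant digits so the round trip is bit-exact; the canonical missing
#' marker is the literal `NA`.
#'
#' @param dataset An [mi_dataset()].
#' @param bounds A [bounds_table()] (may be empty).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, bounds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- dataset$values
  out <- data.frame(observation = dataset$obs,
                    collection_day = as.integer(dataset$collection_day),
                    stringsAsFactors = FALSE)
  for (v in names(vals)) {
    out[[v]] <- if (is.numeric(vals[[v]])) fmt_num(vals[[v]]) else
      ifelse(is.na(vals[[v]]), "NA", as.character(vals[[v]]))
  }
  write.csv(out, file.path(dir, "observations.csv"), row.names = FALSE,
            quote = FALSE, na = "NA")
  write.csv(dataset$meta, file.path(dir, "variables.csv"), row.names = FALSE,
            quote = FALSE, na = "NA")
  b <- as.data.frame(bounds)
  b$lower <- fmt_num(b$lower); b$upper <- fmt_num(b$upper)
  write.csv(b, file.path(dir, "bounds.csv"), row.names = FALSE,
            quote = FALSE, na = "NA")
  s <- dataset$series
  s$value <- fmt_num(s$value)
  write.csv(s, file.path(dir, "series.csv"), row.names = FALSE,
            quote = FALSE, na = "NA")
  invisible(dir)
}

#' Report on dataset structure and potential problems
#'
#' Report-only companion to [load_dataset()]: tallies roles, counts missing
#' cells per variable, and flags zero-variance predictors (which the
#' standardization step would drop).
#'
#' @param dataset An [mi_dataset()].
#' @return List with `role_tally`, `missing_counts`, `zero_variance`,
#'   `issues` (character vector, empty when nothing was flagged).
#' @export
validate_dataset <- function(dataset) {
  meta <- dataset$meta
  role_tally <- table(meta$role)
  miss <- missing_cells(dataset)
  missing_counts <- table(factor(miss$variable, levels = meta$name))
  zero_var <- character()
  for (v in intersect(meta$name[meta$role == "predictor"],
                      names(dataset$values))) {
    x <- dataset$values[[v]]
    x <- x[!is.na(x)]
    if (length(x) >= 1 && length(unique(x)) == 1L) zero_var <- c(zero_var, v)
  }
  issues <- character()
  if (length(zero_var)) {
    issues <- c(issues, sprintf("zero-variance predictor: %s", zero_var))
  }
  list(role_tally = role_tally,
       missing_counts = missing_counts,
       zero_variance = zero_var,
       issues = issues)
}
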