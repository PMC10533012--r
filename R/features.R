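#' One-hot encode a categorical variable
#'
#' A categorical with `c` observed levels yields `c - 1` binary dummy columns
#' named `<variable><level>`; the reference level is encoded as all zeros.
#' The original column is kept but demoted to role `auxiliary`. Missing
#' category values propagate `NA` into every dummy.
#'
#' @param dataset An [mi_dataset()].
#' @param variable Name of a `categorical_raw` variable.
#' @param reference_level Level encoded as all zeros. `"auto"` (default)
#'   picks the most frequent level (ties broken alphabetically), which keeps
#'   the dummies as dense in zeros as possible.
#' @param role Role given to the new dummy columns: `"predictor"` for
#'   ordinary categoricals such as the nitrogen source, `"blocking_dummy"`
#'   for the data-origin fixed effect.
#' @return The augmented `mi_dataset`; `attr(, "derived_map")` maps each
#'   dummy column to its source variable and level.
#' @export
#' @examples
#' # see vignette for a full round trip
one_hot_encode <- function(dataset, variable, reference_level = "auto",
                           role = c("predictor", "blocking_dummy")) {
  role <- match.arg(role)
  meta <- dataset$meta
  i <- match(variable, meta$name)
  if (is.na(i) || meta$role[i] != "categorical_raw") {
    stop("'", variable, "' is not a categorical_raw variable", call. = FALSE)
  }
  x <- as.character(dataset$values[[variable]])
  levs <- sort(unique(x[!is.na(x)]))
  if (length(levs) < 2) {
    stop("'", variable, "' has fewer than 2 observed levels", call. = FALSE)
  }
  if (identical(reference_level, "auto")) {
    freq <- table(x)
    reference_level <- names(freq)[order(-freq, names(freq))][1]
  }
  if (!reference_level %in% levs) {
    stop("reference level '", reference_level, "' not among observed levels",
         call. = FALSE)
  }
  keep <- setdiff(levs, reference_level)
  new_cols <- paste0(variable, keep)
  clash <- intersect(new_cols, meta$name)
  if (length(clash)) {
    stop("dummy column name(s) already in use: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  vals <- dataset$values
  for (k in seq_along(keep)) {
    vals[[new_cols[k]]] <- ifelse(is.na(x), NA_real_,
                                  as.numeric(x == keep[k]))
  }
  meta$role[i] <- "auxiliary"
  add <- data.frame(name = new_cols, role = role, kind = "binary",
                    units = "", temporal = FALSE, stringsAsFactors = FALSE)
  meta <- rbind(meta[, c("name", "role", "kind", "units", "temporal")], add)
  out <- mi_dataset(cbind(data.frame(observation = dataset$obs), vals),
                    meta, series = dataset$series,
                    collection_day = dataset$collection_day)
  map <- rbind(attr(dataset, "derived_map"),
               data.frame(derived = new_cols, source = variable,
                          level = keep, stringsAsFactors = FALSE))
  attr(out, "derived_map") <- map
  attr(out, "reference_level") <- stats::setNames(reference_level, variable)
  out
}

#' k-day trailing average of a daily series
#'
#' Arithmetic mean over the window ending at the harvest day:
#' days `collection_day - k + 1, ..., collection_day`. Cultures shorter than
#' `k` days are averaged over the available days and flagged with
#' `attr(, "partial") = TRUE` rather than made missing.
#'
#' @param series Named numeric vector of daily values; names are day indices
#'   (day 0 = inoculation).
#' @param collection_day Integer harvest day.
#' @param k Window length, one of 2, 3, 4 (k = 1 degenerates to the
#'   day-of-harvest value).
#' @return Scalar mean; `attr(, "partial")` marks truncated windows.
#' @export
#' @examples
#' temporal_average(c(`6` = 2, `7` = 4), collection_day = 7, k = 2) # 3
temporal_average <- function(series, collection_day, k) {
  stopifnot(k >= 1, collection_day >= 0)
  days <- as.integer(names(series))
  wanted <- seq(max(0L, collection_day - k + 1L), collection_day)
  idx <- match(wanted, days)
  if (anyNA(idx)) {
    stop("series lacks day(s) ", paste(wanted[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  out <- mean(series[idx])
  attr(out, "partial") <- length(wanted) < k
  out
}

#' Ratio of a fatty acid to the C16:0 reference
#'
#' @param fa_percent FA percentage of total fatty acids.
#' @param c16_percent C16:0 percentage of total fatty acids; non-positive
#'   values make the ratio undefined (`NA`, with a warning).
#' @return `fa_percent / c16_percent`, vectorized.
#' @export
ratio_to_reference <- function(fa_percent, c16_percent) {
  bad <- !is.na(c16_percent) & c16_percent <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with non-positive C16:0 set to missing",
            call. = FALSE)
  }
  out <- fa_percent / c16_percent
  out[bad] <- NA_real_
  out
}

temporal_suffixes <- c("_2DaysAv", "_3DaysAv", "_4DaysAv")

#' Assemble the numeric predictor design matrix
#'
#' Collects every predictor and blocking-dummy column into one numeric
#' matrix. Each temporal predictor contributes its day-of-harvest value plus
#' the 2-, 3- and 4-day trailing averages (columns suffixed `_2DaysAv`,
#' `_3DaysAv`, `_4DaysAv`), computed per observation from the daily series.
#'
#' @param dataset An [mi_dataset()] (usually a completed imputation copy).
#' @param include_blocking Append blocking-dummy columns? Default `TRUE`.
#' @return List: `X` (n x p numeric matrix), `blocking` (column names of the
#'   blocking dummies in `X`), `map` (data frame derived column -> source).
#' @export
build_design <- function(dataset, include_blocking = TRUE) {
  meta <- dataset$meta
  pred <- meta$name[meta$role == "predictor"]
  block <- meta$name[meta$role == "blocking_dummy"]
  tvars <- meta$name[meta$temporal]
  plain <- setdiff(pred, tvars)
  cols <- list()
  map <- data.frame(derived = character(), source = character(),
                    stringsAsFactors = FALSE)
  for (v in plain) cols[[v]] <- dataset$values[[v]]
  for (v in intersect(pred, tvars)) {
    s <- dataset$series[dataset$series$variable == v, , drop = FALSE]
    harvest <- rep(NA_real_, length(dataset$obs))
    avg <- matrix(NA_real_, length(dataset$obs), 3)
    for (o in seq_along(dataset$obs)) {
      rows <- s[s$observation == dataset$obs[o], , drop = FALSE]
      if (!nrow(rows)) next
      vec <- setNames(rows$value, rows$day)
      cd <- dataset$collection_day[o]
      hit <- match(as.character(cd), names(vec))
      if (!is.na(hit)) harvest[o] <- vec[hit]
      for (k in 2:4) {
        res <- try(temporal_average(vec, cd, k), silent = TRUE)
        if (!inherits(res, "try-error")) avg[o, k - 1] <- as.numeric(res)
      }
    }
    cols[[v]] <- harvest
    for (k in 2:4) {
      nm <- paste0(v, temporal_suffixes[k - 1])
      cols[[nm]] <- avg[, k - 1]
      map <- rbind(map, data.frame(derived = nm, source = v,
                                   stringsAsFactors = FALSE))
    }
  }
  if (include_blocking) for (v in block) cols[[v]] <- dataset$values[[v]]
  X <- do.call(cbind, cols)
  rownames(X) <- dataset$obs
  list(X = X, blocking = if (include_blocking) block else character(),
       map = map)
}

#' Extract the response matrix
#'
#' @param dataset An [mi_dataset()].
#' @return Numeric matrix, one column per `response` variable.
#' @export
response_matrix <- function(dataset) {
  resp <- dataset$meta$name[dataset$meta$role == "response"]
  as.matrix(dataset$values[, resp, drop = FALSE])
}
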