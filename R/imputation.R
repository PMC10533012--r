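#' Draw multiply-imputed copies of a dataset
#'
#' Fills every missing predictor cell (tabular and daily-series) with an
#' independent uniform draw on its `[lower, upper]` bound interval, once per
#' imputation. Observed cells are identical across all `m` copies; a
#' degenerate interval (`lower == upper`) pins the value. Uniform draws are
#' the maximum-entropy choice on a bounded interval, which is all the bound
#' models assert about the missing truth.
#'
#' @param dataset An [mi_dataset()].
#' @param bounds A [bounds_table()] covering every missing predictor cell.
#' @param m Number of imputations (>= 2).
#' @param seed Integer seed; the whole stack is deterministic given the seed.
#' @return Object of class `imputed_stack`: `m`, `datasets` (list of
#'   completed `mi_dataset` copies), `seed`, `distribution`.
#' @export
draw_imputations <- function(dataset, bounds, m, seed) {
  stopifnot(m >= 2)
  m <- as.integer(m)
  miss <- missing_cells(dataset, roles = "predictor")
  bkey <- bounds_key(as.data.frame(bounds))
  hit <- match(bounds_key(miss), bkey)
  if (anyNA(hit)) {
    stop("missing predictor cells without bounds: ",
         paste(cell_label(miss[is.na(hit), , drop = FALSE]), collapse = "; "),
         call. = FALSE)
  }
  lower <- bounds$lower[hit]
  upper <- bounds$upper[hit]
  n_cells <- nrow(miss)

  # precompute assignment targets, grouped by variable for vectorized fill
  tab_idx <- which(is.na(miss$day))
  ser_idx <- which(!is.na(miss$day))
  tab_row <- match(miss$observation[tab_idx], dataset$obs)
  tab_groups <- split(seq_along(tab_idx), miss$variable[tab_idx])
  skey <- paste(dataset$series$observation, dataset$series$variable,
                dataset$series$day, sep = "\r")
  ser_row <- match(paste(miss$observation[ser_idx], miss$variable[ser_idx],
                         miss$day[ser_idx], sep = "\r"), skey)

  datasets <- vector("list", m)
  with_local_seed(seed, {
    for (i in seq_len(m)) {
      draws <- if (n_cells) lower + runif(n_cells) * (upper - lower) else numeric()
      copy <- dataset
      for (v in names(tab_groups)) {
        g <- tab_groups[[v]]
        copy$values[[v]][tab_row[g]] <- draws[tab_idx[g]]
      }
      if (length(ser_idx)) copy$series$value[ser_row] <- draws[ser_idx]
      datasets[[i]] <- copy
    }
  })
  structure(list(m = m, datasets = datasets, seed = as.integer(seed),
                 distribution = "uniform"),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("imputed_stack: m = %d %s draws, seed %d\n",
              x$m, x$distribution, x$seed))
  invisible(x)
}
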