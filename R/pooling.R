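#' Rubin total variance
#'
#' `T = W + (1 + 1/m) * B`: the within-imputation variance plus the
#' between-imputation variance inflated by the finite number of imputations.
#'
#' @param W Within-imputation variance (mean of squared SEs), >= 0.
#' @param B Between-imputation variance (sample variance of estimates), >= 0.
#' @param m Number of imputations (>= 2).
#' @return Total variance.
#' @export
#' @examples
#' rubin_total_variance(0.5, 0.2, 5) # 0.74
rubin_total_variance <- function(W, B, m) {
  if (m < 2) stop("Rubin's rule needs m >= 2", call. = FALSE)
  stopifnot(W >= 0, B >= 0)
  W + (1 + 1 / m) * B
}

#' Trimmed mean retaining a central fraction
#'
#' Sorts, drops `floor(((1 - retain) / 2) * n)` values from each tail, and
#' averages the rest. `retain = 0.8` is the 80% trimmed mean used for
#' p-value and coefficient summaries across imputations.
#'
#' @param values Nonempty numeric vector.
#' @param retain Central fraction retained, in (0, 1].
#' @return Trimmed mean.
#' @export
trimmed_mean <- function(values, retain = 0.8) {
  stopifnot(length(values) >= 1, retain > 0, retain <= 1)
  n <- length(values)
  # epsilon guards the floor against float error, e.g. (1 - 0.8)/2 * 10
  # evaluating to 0.99999... instead of 1
  k <- floor(((1 - retain) / 2) * n + 1e-9)
  s <- sort(values)
  mean(s[(k + 1):(n - k)])
}

#' Pool per-imputation fits with Rubin's rule
#'
#' Combines `m` stepwise fits of the same response. A term absent from an
#' imputation's model contributes estimate 0, SE 0 and p-value 1 for that
#' imputation, so every pooled summary is formed over exactly `m` values.
#' Per term: mean estimate, `W` (mean squared SE), `B` (sample variance of
#' estimates), `T = W + (1 + 1/m) B`, pooled SD `sqrt(T)`, mean/SD/trimmed
#' mean of p-values, presence count, and two significance flags: `primary`
#' (mean p <= 0.05, printed bold) and `secondary` (80% trimmed mean of
#' p <= 0.05, printed with a dagger).
#'
#' @param fits List of `m` [stepwise_fit()] objects.
#' @param m Number of imputations (defaults to `length(fits)`).
#' @param retain Trimmed-mean retained fraction (default 0.8).
#' @param response Response name stored on the result.
#' @return Object of class `pooled_model`: `response`, `terms` (data frame,
#'   one row per distinct term incl. the intercept), `r2_mean`, `r2_sd`,
#'   `m`.
#' @export
pool_fits <- function(fits, m = length(fits), retain = 0.8,
                      response = NA_character_) {
  stopifnot(length(fits) == m, m >= 2)
  all_terms <- unique(unlist(lapply(fits, function(f) f$coefficients$term)))
  all_terms <- c("(Intercept)", sort(setdiff(all_terms, "(Intercept)")))
  est <- se <- pv <- matrix(NA_real_, m, length(all_terms),
                            dimnames = list(NULL, all_terms))
  for (i in seq_len(m)) {
    cf <- fits[[i]]$coefficients
    hit <- match(all_terms, cf$term)
    est[i, ] <- ifelse(is.na(hit), 0, cf$estimate[hit])
    se[i, ] <- ifelse(is.na(hit), 0, cf$se[hit])
    pv[i, ] <- ifelse(is.na(hit), 1, cf$p[hit])
  }
  W <- colMeans(se^2)
  B <- apply(est, 2, var)
  Tv <- rubin_total_variance(W, B, m)
  p_mean <- colMeans(pv)
  p_trim <- apply(pv, 2, trimmed_mean, retain = retain)
  terms <- data.frame(
    term = all_terms,
    estimate = colMeans(est),
    W = W, B = B, T = Tv, pooled_sd = sqrt(Tv),
    p_mean = p_mean,
    p_sd = apply(pv, 2, sd),
    p_trimmed = p_trim,
    primary = p_mean <= 0.05,
    secondary = p_trim <= 0.05,
    stringsAsFactors = FALSE, row.names = NULL)
  # presence: number of imputations whose model contains the term
  pres <- integer(length(all_terms))
  for (i in seq_len(m)) {
    hit <- !is.na(match(all_terms, fits[[i]]$coefficients$term))
    pres <- pres + hit
  }
  terms$presence <- pres
  r2 <- vapply(fits, function(f) f$adj_r2, numeric(1))
  structure(list(response = response, terms = terms,
                 r2_mean = mean(r2), r2_sd = sd(r2), m = m),
            class = "pooled_model")
}

#' @export
print.pooled_model <- function(x, ...) {
  cat(sprintf("pooled_model: %s (m = %d), adj R^2 = %.3f +/- %.3f\n",
              x$response, x$m, x$r2_mean, x$r2_sd))
  df <- x$terms
  df$flag <- paste0(ifelse(df$primary, "*", ""),
                    ifelse(df$secondary, "†", ""))
  print(df[, c("term", "estimate", "pooled_sd", "p_mean", "p_trimmed",
               "presence", "flag")], digits = 4)
  invisible(x)
}

#' Cross-imputation term selection by trimmed absolute coefficient
#'
#' A term survives if the trimmed mean of its absolute coefficients across
#' imputations is strictly positive — i.e. it is retained in enough
#' imputations that trimming cannot zero it out. Working on absolute values
#' keeps consistently negative terms selectable; trimming discards terms
#' whose occasional large coefficients reflect instability rather than
#' signal.
#'
#' @param coefficient_lists Named list (or matrix with one column per term):
#'   for each term, its coefficient in each of the `m` imputations, with 0
#'   where the term was absent.
#' @param retain Trimmed-mean retained fraction (default 0.8).
#' @return Character vector of selected term names.
#' @export
select_terms <- function(coefficient_lists, retain = 0.8) {
  if (is.matrix(coefficient_lists)) {
    coefficient_lists <- as.list(as.data.frame(coefficient_lists))
  }
  sel <- vapply(coefficient_lists, function(v) {
    trimmed_mean(abs(v), retain = retain) > 0
  }, logical(1))
  names(sel)[sel]
}
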