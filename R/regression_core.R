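#' Z-score standardization of a predictor matrix
#'
#' Per-column `(x - mean) / sd` with the sample SD (n - 1 denominator).
#' Zero-variance columns cannot be scaled and are dropped (recorded in
#' `dropped`).
#'
#' @param X Numeric matrix (n >= 2 rows).
#' @return Object of class `standardized_design`: `X` (scaled matrix over
#'   retained columns), `center`, `scale`, `kept`, `dropped`.
#' @export
zscore <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  keep <- is.finite(sdev) & sdev > 0
  if (!any(keep)) stop("all columns have zero variance", call. = FALSE)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  structure(list(X = Xs, center = mu[keep], scale = sdev[keep],
                 kept = colnames(X)[keep],
                 dropped = colnames(X)[!keep]),
            class = "standardized_design")
}

#' Center a response vector
#'
#' Subtracting the mean guarantees the intercept is never penalized: on the
#' centered problem the optimal intercept is zero and the original-scale
#' intercept equals the stored mean.
#'
#' @param y Numeric response vector (n >= 2).
#' @return Object of class `centered_response`: `y`, `mean`.
#' @export
center_response <- function(y) {
  stopifnot(length(y) >= 2)
  structure(list(y = y - mean(y), mean = mean(y)), class = "centered_response")
}

as_design_matrix <- function(design) {
  if (inherits(design, "standardized_design")) design$X else as.matrix(design)
}
as_response <- function(y) {
  if (inherits(y, "centered_response")) y$y else as.numeric(y)
}

#' Smallest penalty with an all-zero solution
#'
#' @param design Standardized design (or plain matrix).
#' @param y Centered response (or plain vector).
#' @return `max_j |X_j' y| / n`.
#' @export
lambda_max <- function(design, y) {
  X <- as_design_matrix(design); yv <- as_response(y)
  max(abs(crossprod(X, yv))) / nrow(X)
}

#' Log-spaced penalty grid
#'
#' @param design,y Standardized design and centered response.
#' @param n_lambda Grid length (>= 2).
#' @param ratio Smallest / largest penalty, in (0, 1).
#' @return Strictly decreasing penalty grid starting at [lambda_max()].
#' @export
lambda_path <- function(design, y, n_lambda = 100, ratio = 1e-3) {
  stopifnot(n_lambda >= 2, ratio > 0, ratio < 1)
  lmax <- lambda_max(design, y)
  exp(seq(log(lmax), log(ratio * lmax), length.out = n_lambda))
}

#' Coordinate-descent LASSO at a single penalty
#'
#' Minimizes `(1/(2n)) * sum((y - X b)^2) + lambda * sum(|b|)` by cyclic
#' coordinate descent with exact soft-threshold updates; convergence when
#' the largest absolute coefficient change in a sweep falls below `tol`.
#' The returned fit carries the KKT residual: for a zero coefficient
#' `|X_j' r| / n <= lambda + tol`, for a nonzero one
#' `X_j' r / n = lambda * sign(b_j) +/- tol` — a global optimality
#' certificate for this convex problem.
#'
#' @param design [zscore()] output (or an already-standardized matrix).
#' @param y [center_response()] output (or an already-centered vector).
#' @param lambda Penalty (>= 0).
#' @param tol Convergence tolerance (default from [default_config()]).
#' @param max_iter Sweep cap; hitting it returns `converged = FALSE` with a
#'   warning.
#' @param beta_init Optional warm start.
#' @param trace_objective Record the objective after every sweep?
#' @return Object of class `lasso_fit`: `lambda`, `b0` (response mean),
#'   `beta` (named, standardized scale), `objective`, `objective_trace`,
#'   `iterations`, `converged`, `kkt_residual`.
#' @export
lasso_cd <- function(design, y, lambda, tol = 1e-7, max_iter = 1e5,
                     beta_init = NULL, trace_objective = FALSE) {
  stopifnot(lambda >= 0, tol > 0)
  X <- as_design_matrix(design)
  yv <- as_response(y)
  b0 <- if (inherits(y, "centered_response")) y$mean else 0
  if (is.null(beta_init)) beta_init <- numeric(ncol(X))
  fit <- cd_lasso_fit(X, yv, lambda, beta_init, tol, as.integer(max_iter),
                      trace_objective)
  if (!fit$converged) {
    warning("coordinate descent hit max_iter without converging",
            call. = FALSE)
  }
  beta <- setNames(as.numeric(fit$beta), colnames(X))
  r <- yv - X %*% beta
  g <- as.numeric(crossprod(X, r)) / nrow(X)
  kkt <- max(c(0, abs(g[beta == 0]) - lambda,
               abs(g[beta != 0] - lambda * sign(beta[beta != 0]))))
  structure(list(lambda = lambda, b0 = b0, beta = beta,
                 objective = fit$objective,
                 objective_trace = fit$objective_trace,
                 iterations = fit$iterations, converged = fit$converged,
                 kkt_residual = kkt),
            class = "lasso_fit")
}

#' Warm-started coefficient path over a penalty grid
#'
#' @param design,y Standardized design and centered response.
#' @param grid Strictly decreasing penalty grid (default [lambda_path()]).
#' @param tol,max_iter Coordinate-descent controls.
#' @return Object of class `lasso_path`: `lambda`, `beta` (p x n_lambda),
#'   `b0`, `iterations`, `converged`; `cvm`/`cvse` slots are filled by
#'   [cv_lasso()].
#' @export
fit_lasso_path <- function(design, y, grid = NULL, tol = 1e-7,
                           max_iter = 1e5) {
  X <- as_design_matrix(design)
  yv <- as_response(y)
  if (is.null(grid)) grid <- lambda_path(design, y)
  stopifnot(all(diff(grid) < 0))
  res <- cd_lasso_path(X, yv, grid, tol, as.integer(max_iter))
  beta <- res$beta
  rownames(beta) <- colnames(X)
  structure(list(lambda = grid, beta = beta,
                 b0 = if (inherits(y, "centered_response")) y$mean else 0,
                 iterations = res$iterations, converged = res$converged,
                 cvm = NULL, cvse = NULL),
            class = "lasso_path")
}

#' Cross-validated prediction error along the penalty grid
#'
#' K-fold cross-validation with seeded fold assignment. Standardization and
#' centering are re-estimated on the training folds only, then applied to
#' the held-out fold; the per-penalty standard error is the SD of the fold
#' MSEs divided by `sqrt(folds)`.
#'
#' @param X Raw (unstandardized) predictor matrix.
#' @param y Raw response vector.
#' @param grid Decreasing penalty grid.
#' @param folds Number of folds (>= 2; every fold needs >= 2 observations).
#' @param seed Integer seed for the fold split.
#' @param tol,max_iter Coordinate-descent controls.
#' @return List `cvm`, `cvse` (one entry per grid penalty), `fold_id`.
#' @export
cv_lasso <- function(X, y, grid, folds = 10, seed = 1, tol = 1e-7,
                     max_iter = 1e5) {
  X <- as.matrix(X); n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(folds >= 2, n >= folds)
  fold_id <- with_local_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  if (min(table(fold_id)) < 2) {
    stop("a fold has fewer than 2 observations", call. = FALSE)
  }
  mse <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    sd_tr <- zscore(X[tr, , drop = FALSE])
    y_tr <- center_response(y[tr])
    path <- fit_lasso_path(sd_tr, y_tr, grid, tol = tol, max_iter = max_iter)
    Xte <- X[!tr, sd_tr$kept, drop = FALSE]
    Xte <- sweep(sweep(Xte, 2, sd_tr$center), 2, sd_tr$scale, "/")
    pred <- sweep(Xte %*% path$beta, 2, -y_tr$mean) # add back training mean
    mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  list(cvm = colMeans(mse), cvse = apply(mse, 2, sd) / sqrt(folds),
       fold_id = fold_id)
}

#' Fit a cross-validated LASSO path on raw data
#'
#' Convenience wrapper binding [zscore()], [center_response()],
#' [lambda_path()], [fit_lasso_path()] and [cv_lasso()] into one
#' `lasso_path` object ready for [select_lambda()].
#'
#' @param X Raw predictor matrix.
#' @param y Raw response vector.
#' @param config Configuration list (see [default_config()]).
#' @param seed Seed for the fold split.
#' @return A `lasso_path` with `cvm`/`cvse` filled and `kept`/`dropped`
#'   column records.
#' @export
cv_lasso_path <- function(X, y, config = default_config(), seed = 1) {
  lc <- config$lasso
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sdn <- zscore(X)
  yc <- center_response(y)
  grid <- lambda_path(sdn, yc, n_lambda = lc$n_lambda,
                      ratio = lc$lambda_min_ratio)
  path <- fit_lasso_path(sdn, yc, grid, tol = lc$tol, max_iter = lc$max_iter)
  cv <- cv_lasso(X[, sdn$kept, drop = FALSE], y, grid, folds = lc$folds,
                 seed = seed, tol = lc$tol, max_iter = lc$max_iter)
  path$cvm <- cv$cvm
  path$cvse <- cv$cvse
  path$kept <- sdn$kept
  path$dropped <- sdn$dropped
  path
}

#' Choose the penalty under one of three criteria
#'
#' \describe{
#'   \item{`min_mse`}{the penalty with the smallest mean cross-validated
#'     MSE; ties go to the larger penalty (parsimony).}
#'   \item{`one_se`}{the largest penalty whose mean CV MSE is within one
#'     standard error of the minimum.}
#'   \item{`noblocking`}{the smallest grid penalty whose fit has every
#'     blocking coefficient exactly zero — the most permissive model that
#'     still excludes all data-origin dummies. Works off the coefficient
#'     path only (no CV curve needed). If blocking coefficients re-enter
#'     non-monotonically along the path, only the chosen penalty itself is
#'     required to be blocking-free (a message notes the non-monotonicity);
#'     if they are nonzero everywhere below the top of the path, the top
#'     (all-zero fit) is returned with a warning.}
#' }
#'
#' @param path A `lasso_path` (with `cvm`/`cvse` for the CV criteria).
#' @param criterion One of `"min_mse"`, `"one_se"`, `"noblocking"`.
#' @param blocking Names of blocking columns (required for `noblocking`).
#' @return Object of class `lambda_selection`: `criterion`, `lambda`,
#'   `index`, `support` (names of nonzero coefficients), `coef` (named
#'   nonzero coefficients, standardized scale).
#' @export
select_lambda <- function(path, criterion = c("min_mse", "one_se", "noblocking"),
                          blocking = character()) {
  criterion <- match.arg(criterion)
  nl <- length(path$lambda)
  if (criterion %in% c("min_mse", "one_se")) {
    stopifnot(!is.null(path$cvm))
    imin <- which.min(path$cvm) # first index = largest lambda on ties
    idx <- if (criterion == "min_mse") imin else
      min(which(path$cvm <= path$cvm[imin] + path$cvse[imin]))
  } else {
    if (!length(blocking)) {
      stop("noblocking criterion needs a nonempty blocking set", call. = FALSE)
    }
    bl <- intersect(blocking, rownames(path$beta))
    zero_block <- if (length(bl)) {
      colSums(abs(path$beta[bl, , drop = FALSE])) == 0
    } else rep(TRUE, nl)
    ok <- which(zero_block)
    if (!length(ok)) {
      warning("blocking coefficients nonzero at every grid penalty; ",
              "returning the largest penalty", call. = FALSE)
      idx <- 1L
    } else {
      idx <- max(ok) # smallest penalty with an all-zero blocking block
      if (idx < nl && any(!zero_block[seq_len(idx)])) {
        message("blocking coefficients re-enter non-monotonically along the path")
      }
      if (idx == 1 && nl > 1 && !zero_block[2]) {
        warning("blocking coefficients nonzero at every penalty below the ",
                "top of the path; returning the all-zero fit", call. = FALSE)
      }
    }
  }
  b <- path$beta[, idx]
  nz <- b[b != 0]
  if (criterion == "noblocking") {
    # the criterion's support excludes blocking columns by construction;
    # this also covers the degenerate fallback where the top-of-path fit
    # carries a float-level nonzero blocking coefficient
    nz <- nz[!(names(nz) %in% blocking)]
  }
  structure(list(criterion = criterion, lambda = path$lambda[idx],
                 index = idx, support = names(nz), coef = nz),
            class = "lambda_selection")
}
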