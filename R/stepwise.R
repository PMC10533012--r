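#' Build the candidate term pool: mains plus all pairwise interactions
#'
#' @param candidates Character vector of variable names (>= 1).
#' @return Object of class `term_set`: `mains` (the candidates) and
#'   `interactions` (all `choose(n, 2)` unordered pairs, written
#'   `"a:b"` with the pair sorted for determinism).
#' @export
build_terms <- function(candidates) {
  stopifnot(length(candidates) >= 1)
  candidates <- unique(as.character(candidates))
  inter <- character()
  if (length(candidates) >= 2) {
    pairs <- combn(sort(candidates), 2)
    inter <- paste(pairs[1, ], pairs[2, ], sep = ":")
  }
  structure(list(mains = candidates, interactions = inter),
            class = "term_set")
}

term_list <- function(terms) {
  if (inherits(terms, "term_set")) c(terms$mains, terms$interactions)
  else as.character(terms)
}

interaction_members <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

canonical_term <- function(term) {
  vapply(term, function(t) {
    paste(sort(interaction_members(t)), collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

# materialize term columns (mains as-is, interactions as raw elementwise
# products) from a data frame of raw-scale variables
term_matrix <- function(data, terms) {
  terms <- term_list(terms)
  if (!length(terms)) return(matrix(numeric(), nrow(data), 0))
  cols <- lapply(terms, function(t) {
    mem <- interaction_members(t)
    missing <- setdiff(mem, names(data))
    if (length(missing)) {
      stop("unknown variable(s) in term '", t, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    Reduce(`*`, lapply(mem, function(v) data[[v]]))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- terms
  out
}

ols_fit <- function(D, y) {
  n <- length(y)
  X <- cbind("(Intercept)" = 1, D)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) return(NULL)
  cf <- qr.coef(qrx, y)
  res <- y - X %*% cf
  df <- n - ncol(X)
  sse <- sum(res^2)
  sigma2 <- sse / df
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tval <- cf / se
  pval <- 2 * pt(-abs(tval), df)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df
  list(coef = cf, se = se, t = tval, p = pval, sse = sse, df = df,
       sigma2 = sigma2, adj_r2 = adj_r2, residuals = as.numeric(res),
       qr = qrx)
}

# p-values for adding each candidate column to the current fit, via the
# added-variable F-test computed from residualized columns (one QR reuse
# for all candidates)
addition_pvalues <- function(fit, D_out, n) {
  if (!ncol(D_out)) return(numeric())
  Q <- qr.Q(fit$qr)
  Z <- D_out - Q %*% crossprod(Q, D_out)
  znorm <- colSums(Z^2)
  r <- fit$residuals
  drop_sse <- as.numeric(crossprod(Z, r))^2 / znorm
  drop_sse[znorm < 1e-10] <- NA # collinear with current model
  df1 <- fit$df - 1
  Fstat <- drop_sse / ((fit$sse - drop_sse) / df1)
  p <- rep(NA_real_, ncol(D_out))
  valid <- df1 > 0 & is.finite(Fstat) & Fstat >= 0
  p[valid] <- pf(Fstat[valid], 1, df1, lower.tail = FALSE)
  setNames(p, colnames(D_out))
}

# ridge-screen a term list down to a full-rank start: drop the weakest
# interaction columns (smallest standardized ridge coefficient) first,
# then weakest mains, until the design fits with at least `min_df`
# residual degrees of freedom; one pivoted QR then removes any remaining
# collinear columns (weakest-first ordering makes the drop deterministic).
# The default floor of half the observations keeps the starting model's
# F-tests powered instead of saturated.
ridge_screen <- function(D, y, terms, is_interaction,
                         min_df = max(5L, floor(length(y) / 2))) {
  n <- length(y)
  p <- length(terms)
  target <- n - 1L - min_df
  if (target < 1) return(character())
  keep_idx <- seq_len(p)
  if (p > target) {
    Ds <- scale(D)
    Ds[, attr(Ds, "scaled:scale") == 0] <- 0
    lam <- 1e-3 * n
    G <- crossprod(Ds) + diag(lam, ncol(Ds))
    b <- solve(G, crossprod(Ds, y - mean(y)))
    strength <- abs(as.numeric(b))
    # retention priority: mains before interactions, then strength
    ord <- order(is_interaction, -strength)
    keep_idx <- sort(ord[seq_len(target)])
  }
  X <- cbind(1, D[, keep_idx, drop = FALSE])
  qrx <- qr(X, LAPACK = TRUE)
  if (qrx$rank < ncol(X)) {
    ok_cols <- sort(qrx$pivot[seq_len(qrx$rank)])
    ok_cols <- setdiff(ok_cols, 1L) - 1L # drop intercept slot, reindex
    keep_idx <- keep_idx[ok_cols]
  }
  out <- terms[keep_idx]
  attr(out, "screen_dropped") <- terms[-keep_idx]
  out
}

#' Stepwise linear regression with pairwise interactions
#'
#' F-test-driven stepwise selection on raw-scale data, in the semantics of
#' the start-from-full stepping the study pipeline relies on: begin from
#' the full candidate model (or its largest full-rank ridge-screened
#' subset), then alternate removing the in-model term with the largest
#' p-value above `premove` and adding the out-of-model term with the
#' smallest p-value below `penter`, one term per step, until no move
#' qualifies. Removal is considered before addition; ties on p-values break
#' lexicographically on the term name; revisiting a previously seen model
#' stops the procedure (cycle guard). Interactions are raw elementwise
#' products and are not forced to keep their main effects in the model.
#'
#' @param data Data frame of raw-scale variables.
#' @param y Raw-scale response vector.
#' @param pool A [build_terms()] term set (or character vector of terms).
#' @param penter p-value below which an excluded term enters (default 0.05).
#' @param premove p-value above which an included term leaves (default
#'   0.10); `penter <= premove` required.
#' @param max_steps Step cap (default 500).
#' @return Object of class `stepwise_fit`: `terms` (included terms),
#'   `coefficients` (data frame: term, estimate, se, t, p), `adj_r2`,
#'   `sigma2`, `n`, `steps`, `screen_dropped`.
#' @export
stepwise_fit <- function(data, y, pool, penter = 0.05, premove = 0.10,
                         max_steps = 500) {
  stopifnot(penter > 0, penter <= premove, premove < 1)
  keep_rows <- !is.na(y)
  data <- data[keep_rows, , drop = FALSE]
  y <- y[keep_rows]
  n <- length(y)
  all_terms <- sort(term_list(pool))
  is_inter <- grepl(":", all_terms, fixed = TRUE)
  D_all <- term_matrix(data, all_terms)

  start_terms <- ridge_screen(D_all, y, all_terms, is_inter)
  screen_dropped <- attr(start_terms, "screen_dropped")
  attr(start_terms, "screen_dropped") <- NULL
  if (!length(start_terms)) {
    warning("no full-rank start; falling back to forward selection from ",
            "the intercept-only model", call. = FALSE)
  }
  current <- start_terms
  seen <- character()
  steps <- 0L
  repeat {
    sig <- paste(sort(current), collapse = "|")
    if (sig %in% seen) break # cycle guard
    seen <- c(seen, sig)
    if (steps >= max_steps) break
    fit <- ols_fit(D_all[, current, drop = FALSE], y)
    if (is.null(fit) || fit$df < 1) {
      # degenerate: prune the last term and retry
      current <- current[-length(current)]
      steps <- steps + 1L
      next
    }
    moved <- FALSE
    # removal first
    if (length(current)) {
      p_in <- fit$p[current]
      worst <- p_in[p_in > premove | is.na(p_in)]
      if (length(worst)) {
        worst[is.na(worst)] <- Inf
        drop_term <- names(worst)[order(-worst, names(worst))][1]
        current <- setdiff(current, drop_term)
        moved <- TRUE
      }
    }
    if (!moved) {
      out_terms <- setdiff(all_terms, current)
      # same residual-df floor as the start screen: adding must leave a
      # powered F-test, not a saturated fit
      if (fit$df - 1 < max(5L, floor(n / 2))) out_terms <- character()
      if (length(out_terms)) {
        p_out <- addition_pvalues(fit, D_all[, out_terms, drop = FALSE], n)
        cand <- p_out[!is.na(p_out) & p_out < penter]
        if (length(cand)) {
          add_term <- names(cand)[order(cand, names(cand))][1]
          current <- c(current, add_term)
          moved <- TRUE
        }
      }
    }
    steps <- steps + 1L
    if (!moved) break
  }
  fit <- ols_fit(D_all[, current, drop = FALSE], y)
  if (is.null(fit)) { # should not happen; fall back to intercept-only
    current <- character()
    fit <- ols_fit(D_all[, current, drop = FALSE], y)
  }
  coefs <- data.frame(term = names(fit$coef),
                      estimate = as.numeric(fit$coef),
                      se = as.numeric(fit$se),
                      t = as.numeric(fit$t),
                      p = as.numeric(fit$p),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(terms = current, coefficients = coefs,
                 adj_r2 = fit$adj_r2, sigma2 = fit$sigma2, n = n,
                 steps = steps,
                 screen_dropped = screen_dropped %||% character()),
            class = "stepwise_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("stepwise_fit: %d term(s), adj R^2 = %.3f, n = %d\n",
              length(x$terms), x$adj_r2, x$n))
  print(x$coefficients, digits = 4)
  invisible(x)
}
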