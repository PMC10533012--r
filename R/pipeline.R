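# derived design column -> source variable (strips the k-day-average suffix)
source_variable <- function(cols) {
  sub("_(2|3|4)DaysAv$", "", cols)
}

# canonical source-level form of a term, e.g. "tv1_2DaysAv:x01" -> "tv1:x01"
source_term <- function(terms) {
  vapply(terms, function(t) {
    paste(sort(unique(source_variable(interaction_members(t)))), collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

design_frames <- function(stack) {
  lapply(stack$datasets, function(ds) {
    b <- build_design(ds)
    list(df = as.data.frame(b$X), X = b$X, blocking = b$blocking)
  })
}

#' Round-1 LASSO screening across imputations
#'
#' For each response and each imputed copy: standardize the predictors,
#' center the response, fit a cross-validated coordinate-descent LASSO path,
#' and select the penalty under all three criteria (`min_mse`, `one_se`,
#' `noblocking`). Per criterion, a variable is retained when the 80% trimmed
#' mean of its absolute coefficients across imputations is positive
#' ([select_terms()]); the union of the three retained sets forms the
#' candidate pool for round-1 stepwise.
#'
#' @param stack An [draw_imputations()] stack.
#' @param responses Response names (default: all `response` variables).
#' @param config Configuration list.
#' @param seed Base seed for cross-validation fold splits.
#' @param frames Precomputed design frames (one per imputation), as built
#'   internally by [run_pipeline()]; recomputed when `NULL`.
#' @return Named list per response: `per_criterion` (retained variable sets),
#'   `candidates` (their union), `lambda_log` (chosen penalty per imputation
#'   and criterion). Responses with no observed values are skipped with a
#'   warning.
#' @export
run_round1_lasso <- function(stack, responses = NULL,
                             config = default_config(), seed = 1,
                             frames = NULL) {
  if (is.null(frames)) frames <- design_frames(stack)
  meta <- stack$datasets[[1]]$meta
  if (is.null(responses)) responses <- meta$name[meta$role == "response"]
  out <- list()
  for (resp in responses) {
    yfull <- stack$datasets[[1]]$values[[resp]]
    if (all(is.na(yfull))) {
      warning("response '", resp, "' has no observed values; skipped",
              call. = FALSE)
      next
    }
    crits <- c("min_mse", "one_se", "noblocking")
    coefs <- list()
    lambda_log <- list()
    for (i in seq_len(stack$m)) {
      fr <- frames[[i]]
      y <- stack$datasets[[i]]$values[[resp]]
      ok <- !is.na(y)
      # one fold split shared by all imputations: identical completed
      # copies must yield identical selections, so between-imputation
      # variability comes from the draws, not the CV partition
      path <- cv_lasso_path(fr$X[ok, , drop = FALSE], y[ok], config,
                            seed = seed)
      for (cr in crits) {
        sel <- select_lambda(path, cr, blocking = fr$blocking)
        v <- setNames(numeric(ncol(fr$X)), colnames(fr$X))
        v[names(sel$coef)] <- sel$coef
        coefs[[cr]] <- rbind(coefs[[cr]], v)
        lambda_log[[length(lambda_log) + 1L]] <-
          data.frame(response = resp, imputation = i, criterion = cr,
                     lambda = sel$lambda, n_support = length(sel$support))
      }
    }
    per_criterion <- lapply(coefs, select_terms, retain = config$pooling$retain)
    out[[resp]] <- list(per_criterion = per_criterion,
                        candidates = sort(unique(unlist(per_criterion))),
                        lambda_log = do.call(rbind, lambda_log))
  }
  out
}

#' Round-1 stepwise refinement across imputations
#'
#' Per response and imputation, fits [stepwise_fit()] on the raw-scale data
#' with the round-1 candidate mains and all their pairwise interactions,
#' then tallies how often each term appears across imputations.
#'
#' @param stack Imputed stack.
#' @param round1 Output of [run_round1_lasso()].
#' @param config Configuration list.
#' @param frames Precomputed design frames; recomputed when `NULL`.
#' @return Named list per response: `fits` (per-imputation stepwise fits),
#'   `census` (named term counts across imputations).
#' @export
run_round1_stepwise <- function(stack, round1, config = default_config(),
                                frames = NULL) {
  if (is.null(frames)) frames <- design_frames(stack)
  out <- list()
  for (resp in names(round1)) {
    cand <- round1[[resp]]$candidates
    if (!length(cand)) {
      out[[resp]] <- list(fits = list(), census = integer())
      next
    }
    pool <- build_terms(cand)
    fits <- vector("list", stack$m)
    for (i in seq_len(stack$m)) {
      y <- stack$datasets[[i]]$values[[resp]]
      fits[[i]] <- stepwise_fit(frames[[i]]$df, y, pool,
                                penter = config$stepwise$penter,
                                premove = config$stepwise$premove,
                                max_steps = config$stepwise$max_steps)
    }
    terms <- unlist(lapply(fits, function(f) f$terms))
    census <- sort(table(terms), decreasing = TRUE)
    out[[resp]] <- list(fits = fits, census = census)
  }
  out
}

#' Round-2 LASSO and final stepwise across imputations
#'
#' The term pool is every main effect and interaction present in any
#' round-1 stepwise model. Interaction columns are materialized as raw
#' products and then z-scored alongside the mains; a second LASSO is run per
#' imputation and the penalty chosen under the `noblocking` criterion, where
#' any column involving a blocking dummy (as a main or inside a product)
#' counts as blocking — so the surviving set provably contains no origin
#' dummies. Terms survive across imputations by trimmed absolute
#' coefficient ([select_terms()]). The final candidate mains are the
#' variables remaining in the surviving set individually or inside a
#' surviving interaction; the final interactions are the surviving
#' interactions themselves. A last stepwise pass per imputation over that
#' pool is pooled with Rubin's rule.
#'
#' @param stack Imputed stack.
#' @param round1_stepwise Output of [run_round1_stepwise()].
#' @param config Configuration list.
#' @param seed Base seed for round-2 fold splits.
#' @param frames Precomputed design frames; recomputed when `NULL`.
#' @return Named list per response: `surviving`, `final_mains`,
#'   `final_interactions`, `fits`, `pooled` ([pool_fits()] result),
#'   `final_terms` (terms surviving the final trimmed-coefficient screen).
#' @export
run_round2 <- function(stack, round1_stepwise, config = default_config(),
                       seed = 1, frames = NULL) {
  if (is.null(frames)) frames <- design_frames(stack)
  blocking <- frames[[1]]$blocking
  retain <- config$pooling$retain
  out <- list()
  for (resp in names(round1_stepwise)) {
    census <- round1_stepwise[[resp]]$census
    terms <- setdiff(names(census), "(Intercept)")
    if (!length(terms)) {
      out[[resp]] <- intercept_only_result(stack, frames, resp, config)
      next
    }
    terms <- sort(canonical_term(terms))
    term_blocking <- terms[vapply(terms, function(t) {
      any(interaction_members(t) %in% blocking)
    }, logical(1))]
    coefs <- NULL
    for (i in seq_len(stack$m)) {
      y <- stack$datasets[[i]]$values[[resp]]
      ok <- !is.na(y)
      Xt <- term_matrix(frames[[i]]$df, terms)
      path <- cv_lasso_path(Xt[ok, , drop = FALSE], y[ok], config,
                            seed = seed + 10000L)
      if (length(term_blocking)) {
        sel <- select_lambda(path, "noblocking", blocking = term_blocking)
      } else {
        # no blocking column reached round 2: the criterion is trivially
        # satisfied everywhere; take the most permissive (smallest) penalty
        idx <- length(path$lambda)
        b <- path$beta[, idx]
        sel <- list(lambda = path$lambda[idx], support = names(b[b != 0]),
                    coef = b[b != 0])
      }
      v <- setNames(numeric(length(terms)), terms)
      v[names(sel$coef)] <- sel$coef
      coefs <- rbind(coefs, v)
    }
    surviving <- select_terms(coefs, retain = retain)
    surv_mains <- surviving[!grepl(":", surviving, fixed = TRUE)]
    surv_inter <- setdiff(surviving, surv_mains)
    final_mains <- sort(unique(c(surv_mains,
                                 unlist(lapply(surv_inter, interaction_members)))))
    final_mains <- setdiff(final_mains, blocking)
    if (!length(final_mains) && !length(surv_inter)) {
      out[[resp]] <- intercept_only_result(stack, frames, resp, config)
      next
    }
    pool <- structure(list(mains = final_mains, interactions = surv_inter),
                      class = "term_set")
    fits <- vector("list", stack$m)
    coef_final <- NULL
    for (i in seq_len(stack$m)) {
      y <- stack$datasets[[i]]$values[[resp]]
      fits[[i]] <- stepwise_fit(frames[[i]]$df, y, pool,
                                penter = config$stepwise$penter,
                                premove = config$stepwise$premove,
                                max_steps = config$stepwise$max_steps)
      v <- setNames(numeric(length(term_list(pool))), term_list(pool))
      cf <- fits[[i]]$coefficients
      hit <- intersect(cf$term, names(v))
      v[hit] <- cf$estimate[match(hit, cf$term)]
      coef_final <- rbind(coef_final, v)
    }
    pooled <- pool_fits(fits, stack$m, retain = retain, response = resp)
    final_terms <- select_terms(coef_final, retain = retain)
    out[[resp]] <- list(surviving = surviving, final_mains = final_mains,
                        final_interactions = surv_inter, fits = fits,
                        pooled = pooled, final_terms = final_terms)
  }
  out
}

intercept_only_result <- function(stack, frames, resp, config) {
  message("empty surviving set for '", resp, "'; intercept-only final model")
  fits <- vector("list", stack$m)
  for (i in seq_len(stack$m)) {
    y <- stack$datasets[[i]]$values[[resp]]
    ok <- !is.na(y)
    yv <- y[ok]
    f <- ols_fit(matrix(numeric(), length(yv), 0), yv)
    fits[[i]] <- structure(list(
      terms = character(),
      coefficients = data.frame(term = "(Intercept)",
                                estimate = as.numeric(f$coef),
                                se = as.numeric(f$se), t = as.numeric(f$t),
                                p = as.numeric(f$p)),
      adj_r2 = f$adj_r2, sigma2 = f$sigma2, n = length(yv), steps = 0L,
      screen_dropped = character()), class = "stepwise_fit")
  }
  list(surviving = character(), final_mains = character(),
       final_interactions = character(), fits = fits,
       pooled = pool_fits(fits, stack$m, retain = config$pooling$retain,
                          response = resp),
       final_terms = character())
}

#' Run the full two-round selection pipeline
#'
#' Imputation, round-1 LASSO screening under three penalty criteria,
#' round-1 stepwise with interactions, round-2 LASSO under the NoBlocking
#' criterion, final stepwise, and Rubin's-rule pooling — each response
#' modelled independently.
#'
#' @param dataset An [mi_dataset()].
#' @param bounds A [bounds_table()].
#' @param responses Response names (default: all).
#' @param config Configuration list (see [default_config()]).
#' @param seed Master seed; imputation and all fold splits derive from it.
#' @return Object of class `milasso_result`: `round1`, `round1_stepwise`,
#'   `round2` (with one [pool_fits()] model per response), `stack` seed and
#'   `m`, `config`, `seed`.
#' @export
run_pipeline <- function(dataset, bounds, responses = NULL,
                         config = default_config(), seed = 1) {
  seed <- as.integer(seed)
  stack <- draw_imputations(dataset, bounds, m = config$imputation$m,
                            seed = seed)
  frames <- design_frames(stack)
  r1 <- run_round1_lasso(stack, responses, config, seed = seed,
                         frames = frames)
  r1s <- run_round1_stepwise(stack, r1, config, frames = frames)
  r2 <- run_round2(stack, r1s, config, seed = seed, frames = frames)
  structure(list(round1 = r1, round1_stepwise = r1s, round2 = r2,
                 m = stack$m, seed = seed, config = config),
            class = "milasso_result")
}

#' @export
print.milasso_result <- function(x, ...) {
  cat(sprintf("milasso_result: %d response(s), m = %d, seed %d\n",
              length(x$round2), x$m, x$seed))
  for (resp in names(x$round2)) {
    r <- x$round2[[resp]]
    cat(sprintf("  %s: %d final term(s) [%s], adj R^2 %.3f\n", resp,
                length(r$final_terms),
                paste(r$final_terms, collapse = ", "), r$pooled$r2_mean))
  }
  invisible(x)
}

#' Score a pipeline result against simulation ground truth
#'
#' Maps every final-model term to source-variable granularity (k-day
#' averages count as their parent variable) and compares with the design's
#' true terms.
#'
#' @param result A [run_pipeline()] result.
#' @param truth The `truth` element of [generate_study()].
#' @param response Response to score (default: the truth's response).
#' @return List: `mains_recovered`, `mains_total`, `interactions_recovered`,
#'   `interactions_total`, `false_positives`, `blocking_in_final`
#'   (count of blocking dummies among final terms), `final_terms`.
#' @export
evaluate_recovery <- function(result, truth, response = truth$response) {
  r <- result$round2[[response]]
  final <- unique(source_term(r$final_terms))
  true_mains <- unlist(lapply(truth$true_terms,
                              function(t) if (length(t$term) == 1) t$term))
  true_inter <- vapply(Filter(function(t) length(t$term) == 2,
                              truth$true_terms),
                       function(t) paste(sort(t$term), collapse = ":"),
                       character(1))
  final_members <- unique(unlist(lapply(final, interaction_members)))
  mains_rec <- sum(true_mains %in% final_members)
  inter_rec <- sum(true_inter %in% final)
  truth_all <- c(true_mains, true_inter)
  fp <- setdiff(final, truth_all)
  # an interaction both of whose members are true mains is a near-miss, but
  # still counted as a false positive at term granularity
  blocking <- grep("^Origin", final_members, value = TRUE)
  list(mains_recovered = mains_rec, mains_total = length(true_mains),
       interactions_recovered = inter_rec,
       interactions_total = length(true_inter),
       false_positives = length(fp),
       blocking_in_final = length(blocking),
       final_terms = final)
}
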