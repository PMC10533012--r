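test_that("z-scoring standardizes with the sample SD and drops constants", {
  z <- zscore(cbind(a = c(2, 4, 6)))
  expect_equal(unname(z$X[, 1]), c(-1, 0, 1))

  X <- cbind(a = rnorm(10), const = rep(3, 10))
  expect_warning(z2 <- zscore(X), NA) # silent drop, recorded
  expect_equal(z2$dropped, "const")
  expect_equal(z2$kept, "a")
  expect_error(zscore(cbind(a = rep(1, 5))), "zero variance")

  set.seed(8)
  Z <- zscore(matrix(rnorm(500), 50, 10))
  expect_true(all(abs(colMeans(Z$X)) < 1e-10))
  expect_true(all(abs(apply(Z$X, 2, sd) - 1) < 1e-10))
})

test_that("centering removes the mean and stores it for the intercept", {
  cy <- center_response(c(1, 2, 3))
  expect_equal(cy$y, c(-1, 0, 1))
  expect_equal(cy$mean, 2)
  expect_equal(center_response(rep(4, 6))$y, rep(0, 6))
  set.seed(2)
  expect_lt(abs(mean(center_response(rnorm(100, 50))$y)), 1e-12)
})

test_that("penalties at or above lambda_max zero every coefficient", {
  set.seed(3)
  X <- matrix(rnorm(200), 40, 5); y <- rnorm(40)
  sdn <- zscore(X); yc <- center_response(y)
  lmax <- lambda_max(sdn, yc)
  for (lam in c(lmax, 1.5 * lmax, 10 * lmax)) {
    f <- lasso_cd(sdn, yc, lam)
    expect_true(all(f$beta == 0))
  }
})

test_that("the unpenalized fit matches the normal equations", {
  set.seed(4)
  X <- matrix(rnorm(150), 30, 5); y <- rnorm(30)
  sdn <- zscore(X); yc <- center_response(y)
  f <- lasso_cd(sdn, yc, 0, tol = 1e-12)
  ols <- solve(crossprod(sdn$X), crossprod(sdn$X, yc$y))
  expect_lt(max(abs(f$beta - as.numeric(ols))), 1e-8)
})

test_that("orthonormal designs give the exact soft-threshold solution", {
  set.seed(5)
  n <- 32; p <- 6
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  X <- Q * sqrt(n) # X'X = n I
  y <- rnorm(n); y <- y - mean(y)
  bols <- as.numeric(crossprod(X, y)) / n
  for (lam in c(0.01, 0.05, 0.2)) {
    f <- lasso_cd(X, y, lam, tol = 1e-14)
    soft <- sign(bols) * pmax(abs(bols) - lam, 0)
    expect_equal(unname(f$beta), soft, tolerance = 1e-12)
  }
})

test_that("the objective is non-increasing across sweeps and KKT holds", {
  set.seed(6)
  X <- matrix(rnorm(40 * 8), 40, 8)
  X[, 2] <- X[, 1] + rnorm(40, 0, 0.05) # stress with collinearity
  y <- X[, 1] * 2 + rnorm(40)
  sdn <- zscore(X); yc <- center_response(y)
  f <- lasso_cd(sdn, yc, 0.05, tol = 1e-9, trace_objective = TRUE)
  expect_true(all(diff(f$objective_trace) <= 1e-12))
  expect_lt(f$kkt_residual, 1e-9 + 1e-12)
})

test_that("the penalty grid is log-spaced from lambda_max", {
  set.seed(7)
  X <- matrix(rnorm(100), 20, 5); y <- rnorm(20)
  sdn <- zscore(X); yc <- center_response(y)
  g <- lambda_path(sdn, yc, n_lambda = 3, ratio = 0.01)
  lmax <- lambda_max(sdn, yc)
  expect_equal(g, c(lmax, 0.1 * lmax, 0.01 * lmax))
  path <- fit_lasso_path(sdn, yc, g)
  expect_true(all(path$beta[, 1] == 0)) # first grid point: all-zero fit
})

test_that("warm-started path fits are as good as cold starts", {
  set.seed(9)
  X <- matrix(rnorm(50 * 10), 50, 10)
  y <- X[, 1] - X[, 3] + rnorm(50, 0, 0.5)
  sdn <- zscore(X); yc <- center_response(y)
  grid <- lambda_path(sdn, yc, n_lambda = 25, ratio = 1e-3)
  path <- fit_lasso_path(sdn, yc, grid)
  n <- nrow(sdn$X)
  for (k in seq_along(grid)) {
    cold <- lasso_cd(sdn, yc, grid[k], tol = 1e-10)
    b <- path$beta[, k]
    warm_obj <- sum((yc$y - sdn$X %*% b)^2) / (2 * n) + grid[k] * sum(abs(b))
    expect_lte(warm_obj, cold$objective + 1e-7)
  }
})

test_that("cross-validation is seeded and tracks the null and signal cases", {
  set.seed(10)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y_noise <- rnorm(60)
  sdn <- zscore(X); yc <- center_response(y_noise)
  grid <- lambda_path(sdn, yc, 30, 1e-3)
  cv1 <- cv_lasso(X, y_noise, grid, folds = 5, seed = 3)
  cv2 <- cv_lasso(X, y_noise, grid, folds = 5, seed = 3)
  expect_identical(cv1, cv2)
  # pure noise: CV error at the largest penalty is about Var(y)
  expect_equal(cv1$cvm[1], var(y_noise), tolerance = 0.25)

  y_sig <- X[, 2] * 3 + rnorm(60, 0, 0.3)
  sdn2 <- zscore(X); yc2 <- center_response(y_sig)
  grid2 <- lambda_path(sdn2, yc2, 30, 1e-3)
  cv3 <- cv_lasso(X, y_sig, grid2, folds = 5, seed = 3)
  expect_lt(min(cv3$cvm), cv3$cvm[1] / 5)
  expect_error(cv_lasso(X[1:6, ], y_sig[1:6], grid2, folds = 5, seed = 1),
               "fewer than 2")
})

test_that("lambda selection follows the three criteria", {
  fake <- structure(list(
    lambda = c(1.0, 0.5, 0.1),
    beta = matrix(c(0, 0, 0,
                    0.5, 0, 0.2,
                    1.0, 0.4, 0.3), nrow = 3,
                  dimnames = list(c("x1", "blk", "x2"), NULL)),
    cvm = c(1.4, 1.0, 1.1), cvse = c(0.2, 0.5, 0.3)),
    class = "lasso_path")
  expect_equal(select_lambda(fake, "min_mse")$lambda, 0.5)
  # threshold 1.0 + 0.5 covers everything: pick the largest penalty
  expect_equal(select_lambda(fake, "one_se")$lambda, 1.0)
  # blocking coefficient is zero only for the two largest penalties
  nb <- select_lambda(fake, "noblocking", blocking = "blk")
  expect_equal(nb$lambda, 0.5)
  expect_setequal(nb$support, c("x1", "x2"))
  expect_error(select_lambda(fake, "noblocking"), "nonempty blocking")

  # min-MSE ties resolve to the larger penalty
  tie <- fake; tie$cvm <- c(1.0, 1.0, 1.2)
  expect_equal(select_lambda(tie, "min_mse")$lambda, 1.0)

  # blocking active everywhere below the top: fall back to lambda_max
  stuck <- fake
  stuck$beta["blk", ] <- c(0, 0.2, 0.4)
  expect_warning(sl <- select_lambda(stuck, "noblocking", blocking = "blk"),
                 "every penalty")
  expect_equal(sl$lambda, 1.0)
})

test_that("one-SE penalty never falls below the min-MSE penalty", {
  set.seed(11)
  for (r in 1:10) {
    X <- matrix(rnorm(50 * 6), 50, 6)
    y <- X[, 1] + rnorm(50)
    p <- cv_lasso_path(X, y, seed = r)
    expect_gte(select_lambda(p, "one_se")$lambda,
               select_lambda(p, "min_mse")$lambda)
  }
})

test_that("support grows from empty at lambda_max along the path", {
  set.seed(12)
  X <- matrix(rnorm(60 * 10), 60, 10)
  y <- X[, 1] - 2 * X[, 5] + rnorm(60, 0, 0.4)
  sdn <- zscore(X); yc <- center_response(y)
  grid <- lambda_path(sdn, yc, 40, 1e-3)
  path <- fit_lasso_path(sdn, yc, grid)
  supp <- colSums(path$beta != 0)
  expect_equal(supp[1], 0)
  expect_gte(supp[length(grid)], supp[1])
})

test_that("coordinate descent agrees with an independent solver", {
  library(glmnet)
  set.seed(13)
  X <- matrix(rnorm(80 * 12), 80, 12)
  X[, 4] <- X[, 3] + rnorm(80, 0, 0.1)
  y <- X[, 1] - 1.5 * X[, 3] + rnorm(80, 0, 0.5)
  sdn <- zscore(X); yc <- center_response(y)
  for (lam in c(0.02, 0.1, 0.3)) {
    ours <- lasso_cd(sdn, yc, lam, tol = 1e-12)
    ref <- glmnet(sdn$X, yc$y, lambda = lam, standardize = FALSE,
                  intercept = FALSE, thresh = 1e-14)
    expect_equal(unname(ours$beta), as.numeric(ref$beta),
                 tolerance = 1e-5, label = sprintf("lambda %.2f", lam))
  }
})
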