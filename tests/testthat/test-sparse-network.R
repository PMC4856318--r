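# An instance where X'y is exact: one standardized predictor plus an
# orthogonal nuisance direction, so the soft-threshold closed form applies.
single_predictor_instance <- function(n = 100, target_xty = 80, seed = 4) {
  withr::with_seed(seed, {
    x <- pop_standardize(rnorm(n))
    e <- rnorm(n); e <- e - mean(e)
    z <- e - x * sum(e * x) / sum(x * x)
    z <- z / sqrt(mean(z^2))
    y <- (target_xty / n) * x + 0.6 * z
    list(x = x, y = y)
  })
}

test_that("fit_lasso matches the single-predictor soft-threshold closed form", {
  inst <- single_predictor_instance()
  X <- matrix(inst$x, ncol = 1)
  expect_equal(sum(inst$x * inst$y), 80, tolerance = 1e-10)
  # w = S(X'y, lambda/2) / X'X = (80 - 10) / 100
  expect_equal(unname(fit_lasso(inst$y, X, 20)), 0.7, tolerance = 1e-10)
  expect_equal(unname(fit_lasso(inst$y, X, 100)), 0.3, tolerance = 1e-10)
  # KKT shrinkage bound: lambda >= 2 max |X'y| kills every weight
  expect_equal(unname(fit_lasso(inst$y, X, 160)), 0)
  expect_equal(unname(fit_lasso(inst$y, X, 200)), 0)
})

test_that("fit_lasso at lambda 0 with orthonormal-type columns is OLS X'y/n", {
  withr::with_seed(9, {
    n <- 60; p <- 3
    Q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # X'X = n I
    y <- rnorm(n)
  })
  w <- fit_lasso(y, Q, 0)
  expect_equal(unname(w), drop(crossprod(Q, y)) / n, tolerance = 1e-8)
})

test_that("fit_lasso agrees with the KKT sign-enumeration oracle for p <= 4", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(8:30, 1); p <- sample(2:4, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- rnorm(n)
      lam <- runif(1, 0.01, 1) * 2 * max(abs(crossprod(X, y)))
      expect_equal(unname(fit_lasso(y, X, lam)), kkt_lasso_oracle(y, X, lam),
                   tolerance = 1e-5)
    }
  })
  expect_error(fit_lasso(rnorm(5), matrix(rnorm(12), 4, 3), 1), "mismatch")
})

test_that("objective and support are monotone along the penalty path", {
  withr::with_seed(17, {
    n <- 40; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X[, 1:3] %*% c(2, -1, 1)) + rnorm(n)
  })
  grid <- lambda_grid(y, X, n_lambda = 25)
  W <- sapply(grid, function(l) fit_lasso(y, X, l))
  support <- colSums(W != 0)
  expect_true(all(diff(support) >= 0))  # grid is decreasing: support grows
  # each path solution minimizes RSS + lambda*L1 at its own lambda over the
  # other path solutions (all feasible points)
  for (l in seq_along(grid)) {
    vals <- vapply(seq_along(grid), function(k)
      sum((y - X %*% W[, k])^2) + grid[l] * sum(abs(W[, k])), numeric(1))
    expect_lte(vals[l], min(vals) + 1e-6)
  }
  # RSS alone never increases as lambda decreases
  rss <- vapply(seq_along(grid), function(l) sum((y - X %*% W[, l])^2), numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("select_lambda_cv recovers signal, controls noise, is deterministic", {
  withr::with_seed(0, {
    n <- 200; p <- 10
    X <- matrix(rnorm(n * p), n, p)
    w_true <- c(1.5, -2, 1, rep(0, p - 3))
    y <- drop(X %*% w_true)
  })
  lam <- select_lambda_cv(y, X, seed = 0)
  w <- fit_lasso(y, X, lam)
  expect_true(all(1:3 %in% which(abs(w) > 1e-6)))       # support covers truth
  expect_lt(min(attr(lam, "cv_mse")), 0.01 * var(y))    # held-out R^2 > 0.99

  # pure noise: the chosen model must not materially beat the null model's
  # held-out error (the CV curve is flat; any apparent gain is overfit noise)
  withr::with_seed(0, { yn <- rnorm(60); Xn <- matrix(rnorm(60 * 8), 60, 8) })
  lam_n <- select_lambda_cv(yn, Xn, seed = 0)
  mse_n <- attr(lam_n, "cv_mse")
  expect_gt(min(mse_n), 0.95 * mse_n[1])  # mse_n[1] = largest lambda = null model

  expect_identical(as.numeric(select_lambda_cv(y, X, seed = 5)),
                   as.numeric(select_lambda_cv(y, X, seed = 5)))
  expect_error(select_lambda_cv(rnorm(3), matrix(rnorm(6), 3, 2), folds = 5),
               "folds")
})

test_that("select_lambda_cv agrees with an independent glmnet-based CV oracle", {
  # Recompute the fold-wise held-out errors with glmnet (objective
  # (1/2n) RSS + lambda_g L1, so lambda_g = lambda / (2 n_train)) and check
  # the same grid point wins.
  withr::with_seed(33, {
    n <- 50; p <- 6
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X[, 1:2] %*% c(1.2, -0.8)) + rnorm(n, sd = 0.7)
  })
  folds <- 5
  grid <- lambda_grid(y, X, n_lambda = 20)
  lam <- select_lambda_cv(y, X, folds = folds, grid = grid, seed = 11)
  perm <- withr::with_seed(11, sample.int(n))
  bounds <- floor(seq(0, n, length.out = folds + 1))
  sse <- numeric(length(grid))
  for (f in seq_len(folds)) {
    test <- perm[(bounds[f] + 1):bounds[f + 1]]
    ntr <- n - length(test)
    fit <- glmnet::glmnet(X[-test, ], y[-test], lambda = grid / (2 * ntr),
                          standardize = FALSE, intercept = FALSE, thresh = 1e-12)
    pred <- X[test, ] %*% as.matrix(fit$beta)
    sse <- sse + colSums((y[test] - pred)^2)
  }
  oracle_lam <- grid[which.min(sse)]
  expect_equal(as.numeric(lam), oracle_lam, tolerance = 1e-12)
  expect_equal(attr(lam, "cv_mse"), unname(sse / n), tolerance = 1e-4)
})

test_that("fit_condition_network recovers noiseless structure and excludes self", {
  ks <- known_structure_data(seed = 21)
  std <- standardize_by_gene(ks$expr)
  net <- fit_condition_network(std, ks$regulators, seed = 2)
  for (i in seq_along(ks$supports)) {
    w <- net$weights[, paste0("T", i)]
    expect_identical(which(abs(w) > 1e-6), setNames(ks$supports[[i]],
                                                    ks$regulators[ks$supports[[i]]]))
  }
  # all genes as regulators: the self slot stays structurally zero
  m <- standardize_by_gene(toy_expression(6, 30, seed = 5))
  net2 <- fit_condition_network(m, m$gene_ids, seed = 3)
  expect_equal(unname(diag(net2$weights)), rep(0, 6))
  expect_error(fit_condition_network(m, character(0)), "empty")
})

test_that("prediction_error matches the printed formula", {
  withr::with_seed(2, x <- pop_standardize(rnorm(50)))
  y <- x
  expect_equal(prediction_error(y, matrix(x, ncol = 1), 0.9), 0.01,
               tolerance = 1e-12)
  expect_equal(prediction_error(y, matrix(x, ncol = 1), 0), 1, tolerance = 1e-12)
  expect_equal(prediction_error(y, matrix(x, ncol = 1), 1), 0, tolerance = 1e-12)
  # invariant to a common permutation of samples
  perm <- sample(50)
  withr::with_seed(8, {
    X <- matrix(rnorm(150), 50, 3); yy <- rnorm(50); w <- rnorm(3)
  })
  expect_equal(prediction_error(yy[perm], X[perm, ], w),
               prediction_error(yy, X, w), tolerance = 1e-12)
})
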