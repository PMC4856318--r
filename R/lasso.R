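#' Default penalty grid for a lasso problem
#'
#' 50 log-spaced values from `lambda_max = 2 * max_r |X_r' y|` (the smallest
#' penalty at which every weight is zero, by the KKT conditions of the
#' sum-of-squares + lambda*L1 objective) down to `lambda_max * 1e-3`.
#'
#' @param y response vector.
#' @param X predictor matrix (columns are regulators).
#' @param n_lambda grid size.
#' @param min_ratio ratio of smallest to largest grid value.
#' @return decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(y, X, n_lambda = 50, min_ratio = 1e-3) {
  lmax <- 2 * max(abs(crossprod(X, y)))
  if (!is.finite(lmax) || lmax <= 0) return(1)  # degenerate: any penalty gives w = 0
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Fit one L1-penalized regression at a fixed penalty
#'
#' Minimizes `sum((y - X w)^2) + penalty * sum(|w|)` by coordinate descent,
#' stopping when the duality gap falls below `tol * max(1, sum(y^2))`.  Note
#' the first term is a sum of squares, not a mean: penalties quoted anywhere
#' in this package are on that scale.
#'
#' @param y numeric response (length n).
#' @param X numeric matrix n x p of predictors.
#' @param penalty lambda >= 0.
#' @param tol duality-gap tolerance (default 1e-7).
#' @param max_iter maximum coordinate-descent sweeps.
#' @return numeric weight vector of length p (named if X has column names).
#' @export
fit_lasso <- function(y, X, penalty, tol = 1e-7, max_iter = 10000L) {
  X <- as.matrix(X)
  if (length(y) != nrow(X))
    stop("dimension mismatch: length(y) = ", length(y), ", nrow(X) = ", nrow(X))
  if (penalty < 0) stop("penalty must be >= 0")
  w <- drop(lasso_path_cd(X, as.numeric(y), penalty, tol, as.integer(max_iter)))
  names(w) <- colnames(X)
  w
}

# Lasso solutions along a decreasing penalty path (warm-started); p x L matrix.
fit_lasso_path <- function(y, X, grid, tol = 1e-7, max_iter = 10000L) {
  lasso_path_cd(as.matrix(X), as.numeric(y), as.numeric(grid), tol,
                as.integer(max_iter))
}

#' Select the lasso penalty by k-fold cross-validation
#'
#' Samples are split into `folds` contiguous blocks of a seeded random
#' permutation; for each fold the full penalty path is fitted on the
#' remaining samples and the held-out squared error accumulated.  The grid
#' value minimizing the mean held-out squared error is returned; exact ties
#' are broken toward the larger (sparser) penalty.
#'
#' @param y,X as in [fit_lasso()] (already standardized).
#' @param folds number of folds (default 5).
#' @param grid decreasing penalty grid; defaults to [lambda_grid()].
#' @param seed integer seed for the fold permutation (`NULL` = current RNG).
#' @return the selected penalty, with attributes `grid` and `cv_mse`.
#' @export
select_lambda_cv <- function(y, X, folds = 5, grid = NULL, seed = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  if (n != nrow(X)) stop("dimension mismatch between y and X")
  if (n < folds) stop("need at least `folds` samples (n = ", n, ", folds = ", folds, ")")
  if (is.null(grid)) grid <- lambda_grid(y, X)
  if (length(grid) == 0 || any(grid < 0)) stop("penalty grid must be nonempty and nonnegative")
  grid <- sort(grid, decreasing = TRUE)
  perm <- if (is.null(seed)) sample.int(n) else
    withr::with_seed(seed, sample.int(n))
  bounds <- floor(seq(0, n, length.out = folds + 1))
  sse <- numeric(length(grid))
  for (f in seq_len(folds)) {
    test <- perm[(bounds[f] + 1):bounds[f + 1]]
    W <- fit_lasso_path(y[-test], X[-test, , drop = FALSE], grid)
    res <- y[test] - X[test, , drop = FALSE] %*% W
    sse <- sse + colSums(res^2)
  }
  cv_mse <- sse / n
  best <- which(cv_mse <= min(cv_mse) * (1 + 1e-12))[1]  # grid decreasing: first = largest
  structure(grid[best], grid = grid, cv_mse = cv_mse)
}

#' Fit the per-gene sparse regulator network for one condition
#'
#' For every gene, the standardized expression is regressed on the
#' standardized candidate regulators with an L1 penalty selected per gene by
#' cross-validation.  A gene that is itself a regulator is removed from its
#' own predictor set; its weight slot is kept at zero so that weight matrices
#' from two conditions stay column-aligned.
#'
#' @param m standardized `expr_matrix`.
#' @param regs character vector of regulator gene ids (all present in `m`).
#' @param folds,grid passed to [select_lambda_cv()]; `grid = NULL` derives a
#'   per-gene grid from the data.
#' @param seed master seed; each gene gets a deterministic sub-seed, so
#'   results do not depend on gene order.
#' @param lambda optional fixed per-gene penalty vector (names = gene ids or
#'   length 1); skips cross-validation when given.
#' @return object of class `condition_network`: list with `condition`,
#'   `gene_ids`, `regulators`, `weights` (p x G matrix), `lambda` (length G).
#' @export
fit_condition_network <- function(m, regs, folds = 5, grid = NULL, seed = 1,
                                  lambda = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  check_regulators(regs, m)
  V <- t(m$values)                       # samples x genes
  genes <- m$gene_ids
  G <- length(genes)
  p <- length(regs)
  Xall <- V[, regs, drop = FALSE]
  W <- matrix(0, nrow = p, ncol = G, dimnames = list(regs, genes))
  lam <- numeric(G)
  if (!is.null(lambda) && length(lambda) == 1) lambda <- rep(lambda, G)
  for (g in seq_len(G)) {
    y <- V[, g]
    self <- match(genes[g], regs)
    Xg <- if (is.na(self)) Xall else Xall[, -self, drop = FALSE]
    if (ncol(Xg) == 0)
      stop("gene ", genes[g], ": no predictors left after self-exclusion")
    if (is.null(lambda)) {
      lam[g] <- select_lambda_cv(y, Xg, folds = folds, grid = grid,
                                 seed = sub_seed(seed, g))
    } else {
      lam[g] <- if (!is.null(names(lambda))) lambda[[genes[g]]] else lambda[g]
    }
    w <- fit_lasso(y, Xg, lam[g])
    if (is.na(self)) W[, g] <- w else W[-self, g] <- w
  }
  structure(list(condition = m$condition, gene_ids = genes, regulators = regs,
                 weights = W, lambda = lam),
            class = "condition_network")
}

#' @export
print.condition_network <- function(x, ...) {
  nz <- colSums(x$weights != 0)
  cat(sprintf("condition_network (%s): %d genes, %d regulators, median support %d\n",
              x$condition, length(x$gene_ids), length(x$regulators),
              as.integer(stats::median(nz))))
  invisible(x)
}

#' Per-sample squared prediction error
#'
#' `err(s, s') = (1/n_s) * || y^(s) - X^(s) w^(s') ||^2`: the average squared
#' residual when the weights learned in condition s' predict the data of
#' condition s.  For standardized y and all-zero weights this is exactly 1.
#'
#' @param y response vector observed in condition s.
#' @param X predictor matrix in condition s.
#' @param w weight vector (learned in s or s').
#' @return scalar error >= 0.
#' @export
prediction_error <- function(y, X, w) {
  X <- as.matrix(X)
  if (length(y) != nrow(X) || length(w) != ncol(X))
    stop("dimension mismatch in prediction_error")
  mean((y - drop(X %*% w))^2)
}

# Per-gene error vector of a whole network evaluated on a dataset:
# err_i = (1/n) || y_i - X w_i ||^2 for every gene i at once.
network_errors <- function(net, data) {
  stopifnot(inherits(net, "condition_network"), inherits(data, "expr_matrix"))
  if (!identical(net$gene_ids, data$gene_ids))
    stop("network and data cover different gene universes")
  V <- t(data$values)
  R <- V[, net$gene_ids, drop = FALSE] - V[, net$regulators, drop = FALSE] %*% net$weights
  colMeans(R^2)
}
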