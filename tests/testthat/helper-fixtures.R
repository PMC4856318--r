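# Shared fixtures and independent oracles.  Everything is generated in code;
# no data files.

# Small raw expression matrix with named genes/samples.
toy_expression <- function(genes = 10, samples = 12, seed = 1,
                           condition = "unlabeled") {
  withr::with_seed(seed, {
    v <- matrix(rnorm(genes * samples, mean = 5, sd = 2), genes, samples,
                dimnames = list(paste0("G", seq_len(genes)),
                                paste0("S", seq_len(samples))))
    expression_matrix(v, condition)
  })
}

# Write an expr_matrix (or plain matrix) as the TSV the loaders expect.
write_tsv_fixture <- function(m, path) {
  v <- if (inherits(m, "expr_matrix")) m$values else m
  df <- data.frame(gene = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Standardize a plain vector with the population (denominator-n) convention.
pop_standardize <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

# Exact lasso oracle for small p: enumerate all 3^p sign patterns, solve the
# KKT stationarity system on each support, keep the feasible solution with
# the smallest objective  ||y - Xw||^2 + lam * ||w||_1.
kkt_lasso_oracle <- function(y, X, lam) {
  p <- ncol(X)
  obj <- function(w) sum((y - X %*% w)^2) + lam * sum(abs(w))
  best <- NULL; bobj <- Inf
  signs <- expand.grid(rep(list(c(-1, 0, 1)), p))
  for (i in seq_len(nrow(signs))) {
    s <- as.numeric(signs[i, ]); A <- which(s != 0)
    w <- numeric(p)
    if (length(A) > 0) {
      XA <- X[, A, drop = FALSE]
      wA <- try(solve(2 * crossprod(XA), 2 * crossprod(XA, y) - lam * s[A]),
                silent = TRUE)
      if (inherits(wA, "try-error")) next
      w[A] <- wA
      if (any(sign(w[A]) != s[A])) next
    }
    r <- y - X %*% w
    ok <- TRUE
    for (j in setdiff(seq_len(p), A))
      if (abs(2 * sum(X[, j] * r)) > lam + 1e-9) ok <- FALSE
    if (!ok) next
    o <- obj(w)
    if (o < bobj) { bobj <- o; best <- w }
  }
  best
}

# Straight-line Glass d-score oracle: correlate, drop self, standardize with
# the sample sd, L1 distance.  Independent of the package implementation.
dscore_oracle <- function(vals_c, vals_n) {
  cc <- cor(t(vals_c)); cn <- cor(t(vals_n))
  vapply(seq_len(nrow(cc)), function(i) {
    a <- cc[i, -i]; b <- cn[i, -i]
    sum(abs((b - mean(b)) / sd(b) - (a - mean(a)) / sd(a)))
  }, numeric(1))
}

# Brute-force ROC AUC: count positive-negative pairs, half credit for ties.
auc_bruteforce <- function(scores, positives) {
  pos <- scores[positives]; neg <- scores[!positives]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Two-condition dataset with a known sparse regulator structure: `n_reg`
# regulator variables, each target driven by exactly two of them, noiseless.
known_structure_data <- function(n = 150, n_reg = 6, n_targets = 10, seed = 1) {
  withr::with_seed(seed, {
    R <- matrix(rnorm(n * n_reg), n, n_reg)
    supports <- lapply(seq_len(n_targets), function(i) sort(sample(n_reg, 2)))
    Y <- vapply(seq_len(n_targets), function(i) {
      w <- runif(2, 0.5, 1.5) * sample(c(-1, 1), 2, replace = TRUE)
      drop(R[, supports[[i]]] %*% w)
    }, numeric(n))
    vals <- t(cbind(R, Y))
    rownames(vals) <- c(paste0("R", seq_len(n_reg)), paste0("T", seq_len(n_targets)))
    colnames(vals) <- paste0("S", seq_len(n))
    list(expr = expression_matrix(vals),
         regulators = paste0("R", seq_len(n_reg)),
         supports = supports)
  })
}

# Access to the internal whole-network error vector (used to cross-check d0).
network_errors_for_test <- function(net, data) discern:::network_errors(net, data)
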