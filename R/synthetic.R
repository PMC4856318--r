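# Synthetic benchmark: pairs of 100-variable Gaussian graphical models in
# which a known subset of variables ("perturbed") changes its edge weights
# between conditions, a "shared" block keeps identical edges, and "isolated"
# variables have an identity precision block.  Symmetrized elementwise
# Gaussian noise (per-pair sd drawn from U(0.5, 5)) roughens the edge
# weights of the stochastic blocks, spanning easy to near-hopeless recovery
# problems; sample sizes mimic the tumor/normal imbalance of real cohorts.
# The noise respects the category definitions: the perturbed block of each
# condition gets an independent draw (those edges differ anyway), the shared
# block gets ONE draw reused in both conditions (its edge weights must stay
# exactly equal across conditions), and the isolated block stays the
# identity (those variables must stay unconnected).

# Random positive-definite block: crossprod of a U(-1,1) matrix, diagonal
# lifted by |min eigenvalue| + 0.1 whenever the minimum eigenvalue is <= 0.
random_spd_block <- function(k) {
  X <- matrix(runif(k * k, -1, 1), k, k)
  lift_pd(crossprod(X))
}

lift_pd <- function(A, eps = 0) {
  ev <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= eps) A <- A + diag(abs(ev) + 0.1, nrow(A))
  A
}

#' Generate one synthetic precision-matrix pair
#'
#' Draws the number of perturbed variables `p` uniformly from 5..15; the
#' remaining variables split into floor((100-p)/2) shared and the rest
#' isolated.  The perturbed block of each condition's precision matrix is an
#' independent random SPD matrix (so its edge weights differ between
#' conditions); the shared block is one common random SPD matrix; the
#' isolated block is the identity.  Symmetrized elementwise Gaussian noise
#' with a per-pair standard deviation drawn uniformly from 0.5..5 is then
#' added to the stochastic blocks — an independent draw for each condition's
#' perturbed block, a single draw reused in both conditions for the shared
#' block — and positive definiteness is restored by diagonal lifting.  The
#' isolated block receives no noise.  This placement keeps the category
#' ground truth exact: only perturbed variables have edge weights that
#' differ between conditions, and isolated variables stay unconnected.
#'
#' @param seed integer seed.
#' @param n_vars number of variables (default 100).
#' @param p_perturbed optionally fix the perturbed count (default: drawn).
#' @param noise_sd optionally fix the edge-noise standard deviation
#'   (default: drawn from U(0.5, 5)); 0 disables noise.
#' @param identical_blocks if `TRUE` the perturbed block (and its noise) is
#'   reused in both conditions — a fully null pair for calibration checks.
#' @return object of class `synthetic_pair` without data: list with
#'   `precision1`, `precision2`, `categories` (factor with levels perturbed/
#'   shared/isolated), `p`, `noise_sd`, `seed`.
#' @export
generate_precision_pair <- function(seed, n_vars = 100, p_perturbed = NULL,
                                    noise_sd = NULL, identical_blocks = FALSE) {
  withr::local_seed(seed)
  p <- if (is.null(p_perturbed)) sample(5:15, 1) else p_perturbed
  n_shared <- floor((n_vars - p) / 2)
  n_iso <- n_vars - p - n_shared
  A1 <- random_spd_block(p)
  A2 <- if (identical_blocks) A1 else random_spd_block(p)
  B <- random_spd_block(n_shared)
  sig <- if (is.null(noise_sd)) runif(1, 0.5, 5) else noise_sd
  if (sig > 0) {
    sym_noise <- function(k) {
      E <- matrix(rnorm(k * k, sd = sig), k, k)
      (E + t(E)) / 2
    }
    N1 <- sym_noise(p)
    N2 <- if (identical_blocks) N1 else sym_noise(p)
    NB <- sym_noise(n_shared)
    A1 <- lift_pd(A1 + N1, eps = 1e-6)
    A2 <- lift_pd(A2 + N2, eps = 1e-6)
    B <- lift_pd(B + NB, eps = 1e-6)
  }
  blockdiag <- function(Ap) {
    M <- matrix(0, n_vars, n_vars)
    M[seq_len(p), seq_len(p)] <- Ap
    M[p + seq_len(n_shared), p + seq_len(n_shared)] <- B
    M[p + n_shared + seq_len(n_iso), p + n_shared + seq_len(n_iso)] <- diag(n_iso)
    M
  }
  P1 <- blockdiag(A1)
  P2 <- blockdiag(A2)
  vars <- sprintf("V%03d", seq_len(n_vars))
  dimnames(P1) <- dimnames(P2) <- list(vars, vars)
  categories <- factor(rep(c("perturbed", "shared", "isolated"),
                           c(p, n_shared, n_iso)),
                       levels = c("perturbed", "shared", "isolated"))
  names(categories) <- vars
  structure(list(precision1 = P1, precision2 = P2, data1 = NULL, data2 = NULL,
                 categories = categories, p = p, noise_sd = sig, seed = seed),
            class = "synthetic_pair")
}

#' Sample from a zero-mean multivariate normal given its precision matrix
#'
#' Draws `x = R^{-1} z` with `z ~ N(0, I)` and `R` the upper Cholesky factor
#' of the precision matrix, so `cov(x) = precision^{-1}` without ever forming
#' the covariance.
#'
#' @param precision symmetric positive-definite matrix.
#' @param n number of samples.
#' @param seed integer seed (`NULL` = current RNG).
#' @return `n` x `ncol(precision)` matrix (samples in rows).
#' @export
sample_mvn <- function(precision, n, seed = NULL) {
  R <- tryCatch(chol(precision),
                error = function(e) stop("precision matrix is not positive definite"))
  z <- if (is.null(seed)) matrix(rnorm(n * ncol(R)), ncol(R), n) else
    withr::with_seed(seed, matrix(rnorm(n * ncol(R)), ncol(R), n))
  x <- t(backsolve(R, z))
  colnames(x) <- colnames(precision)
  x
}

#' Generate a suite of synthetic condition pairs with data
#'
#' Each pair gets a deterministic sub-seed of the master seed; sample sizes
#' are drawn per pair, `n1` from U\{100..110\} (condition 1, "disease") and
#' `n2` from U\{16..26\} (condition 2, "normal"), mirroring the tumor/normal
#' imbalance of the cohorts the benchmark emulates.
#'
#' @param n_pairs number of pairs (the full-scale benchmark uses 100).
#' @param seed master seed.
#' @param n_vars variables per pair.
#' @return list of `synthetic_pair` objects with `data1` (n1 x vars) and
#'   `data2` (n2 x vars) filled and `n1`, `n2` recorded.
#' @export
generate_suite <- function(n_pairs = 100, seed = 1, n_vars = 100) {
  stopifnot(n_pairs >= 1)
  lapply(seq_len(n_pairs), function(i) {
    pair <- generate_precision_pair(sub_seed(seed, i, 1), n_vars = n_vars)
    sizes <- withr::with_seed(sub_seed(seed, i, 2),
                              c(sample(100:110, 1), sample(16:26, 1)))
    pair$n1 <- sizes[1]; pair$n2 <- sizes[2]
    pair$data1 <- sample_mvn(pair$precision1, pair$n1, seed = sub_seed(seed, i, 3))
    pair$data2 <- sample_mvn(pair$precision2, pair$n2, seed = sub_seed(seed, i, 4))
    pair
  })
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf("synthetic_pair: %d variables (%d perturbed), noise sd %.2f%s\n",
              length(x$categories), x$p, x$noise_sd,
              if (is.null(x$data1)) ", no data" else
                sprintf(", n1 = %d, n2 = %d", nrow(x$data1), nrow(x$data2))))
  invisible(x)
}

# Convert one pair into raw expr_matrix objects (variables as genes).
pair_to_expression <- function(pair) {
  stopifnot(inherits(pair, "synthetic_pair"), !is.null(pair$data1))
  list(case = expression_matrix(t(pair$data1), "case"),
       control = expression_matrix(t(pair$data2), "control"))
}

#' ROC curve and AUC for a perturbation score
#'
#' Rank-based ROC; the AUC equals the Mann-Whitney statistic, with tied
#' scores contributing half.  Higher scores must indicate the positive class
#' (negate similarities/p-values before calling).  `NA` scores are ranked
#' below every finite score.
#'
#' @param scores per-variable scores.
#' @param positives logical vector, `TRUE` for positives (needs both classes).
#' @return list with `auc` and `curve` (data frame `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1)).
#' @export
roc_auc <- function(scores, positives) {
  positives <- as.logical(positives)
  if (length(scores) != length(positives)) stop("length mismatch")
  if (!any(positives) || all(positives))
    stop("need at least one positive and one negative")
  if (anyNA(scores)) scores[is.na(scores)] <- -Inf
  np <- sum(positives); nn <- sum(!positives)
  r <- rank(scores)
  auc <- (sum(r[positives]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(positives[ord]); fp <- cumsum(!positives[ord])
  keep <- !duplicated(scores[ord][seq_along(ord)], fromLast = TRUE)  # threshold ends
  curve <- data.frame(fpr = c(0, fp[keep] / nn), tpr = c(0, tp[keep] / np))
  list(auc = auc, curve = curve)
}

#' Run the ROC benchmark over a synthetic suite
#'
#' For every pair: both datasets are standardized per variable, per-variable
#' lasso networks (all variables as candidate regulators, self excluded) are
#' fitted in each condition with per-gene cross-validated penalties, and the
#' requested scores are computed.  Perturbed variables are the positives.
#' Permutation-p variants (`pd0`, `plns`, `pdscore`) use `n_perms` label
#' permutations per pair, reusing observed penalties for `pd0`.
#'
#' @param suite list of `synthetic_pair` objects from [generate_suite()].
#' @param methods subset of discern, d0, lns, dscore, pd0, plns, pdscore.
#' @param n_perms permutations per pair for the p-variants.
#' @param folds,grid CV settings.
#' @param seed master seed for CV folds and permutations.
#' @param fpr_grid grid for vertical ROC averaging.
#' @return object of class `benchmark_result`: `auc` (pairs x methods
#'   matrix), `mean_auc`, `se_auc`, `avg_roc` (per-method data frames).
#' @export
run_comparison <- function(suite,
                           methods = c("discern", "d0", "lns", "dscore",
                                       "pd0", "plns", "pdscore"),
                           n_perms = 100, folds = 5, grid = NULL, seed = 1,
                           fpr_grid = seq(0, 1, by = 0.01)) {
  if (length(suite) == 0) stop("empty suite")
  known <- c("discern", "d0", "lns", "dscore", "pd0", "plns", "pdscore")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "))
  aucs <- matrix(NA_real_, nrow = length(suite), ncol = length(methods),
                 dimnames = list(NULL, methods))
  tprs <- lapply(methods, function(m)
    matrix(NA_real_, nrow = length(suite), ncol = length(fpr_grid)))
  names(tprs) <- methods
  need_net <- any(c("discern", "d0", "pd0") %in% methods)
  for (i in seq_along(suite)) {
    pair <- suite[[i]]
    ex <- pair_to_expression(pair)
    regs <- ex$case$gene_ids
    std_c <- standardize_by_gene(ex$case)
    std_n <- standardize_by_gene(ex$control)
    nets <- NULL
    if (need_net) {
      nets <- list(
        case = fit_condition_network(std_c, regs, folds = folds, grid = grid,
                                     seed = sub_seed(seed, i, 11)),
        control = fit_condition_network(std_n, regs, folds = folds, grid = grid,
                                        seed = sub_seed(seed, i, 12)))
    }
    ranking <- list()
    if ("discern" %in% methods)
      ranking$discern <- discern(nets$case, nets$control, std_c, std_n)
    if (any(c("d0", "pd0") %in% methods))
      obs_d0 <- d0(nets$case, nets$control, std_c, std_n)
    if ("d0" %in% methods) ranking$d0 <- obs_d0
    if (any(c("lns", "plns") %in% methods))
      obs_lns <- suppressWarnings(lns(std_c, std_n))
    if ("lns" %in% methods) ranking$lns <- -obs_lns
    if (any(c("dscore", "pdscore") %in% methods))
      obs_ds <- glass_dscore(std_c, std_n)
    if ("dscore" %in% methods) ranking$dscore <- obs_ds
    for (pm in intersect(methods, c("pd0", "plns", "pdscore"))) {
      which_raw <- substring(pm, 2)
      null_mat <- permute_scores(ex$case, ex$control, regs = regs,
                                 which = which_raw, n_perms = n_perms,
                                 seed = sub_seed(seed, i, 13),
                                 lambda_case = nets$case$lambda,
                                 lambda_control = nets$control$lambda)
      obs <- switch(which_raw, d0 = obs_d0, lns = obs_lns, dscore = obs_ds)
      lower <- which_raw == "lns"
      p <- vapply(seq_along(obs), function(g) {
        nv <- null_mat[, g]
        hits <- if (lower) sum(nv <= obs[g], na.rm = TRUE)
                else sum(nv >= obs[g], na.rm = TRUE)
        (1 + hits) / (1 + sum(!is.na(nv)))
      }, numeric(1))
      ranking[[pm]] <- -p
    }
    pos <- pair$categories == "perturbed"
    for (m in methods) {
      rc <- roc_auc(ranking[[m]], pos)
      aucs[i, m] <- rc$auc
      tprs[[m]][i, ] <- stats::approx(rc$curve$fpr, rc$curve$tpr,
                                      xout = fpr_grid, ties = max,
                                      rule = 2)$y
    }
  }
  avg_roc <- lapply(tprs, function(M)
    data.frame(fpr = fpr_grid, tpr = colMeans(M)))
  structure(list(auc = aucs,
                 mean_auc = colMeans(aucs),
                 se_auc = apply(aucs, 2, stats::sd) / sqrt(nrow(aucs)),
                 avg_roc = avg_roc,
                 n_pairs = length(suite), methods = methods),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result over %d synthetic pairs (mean AUC +/- se):\n",
              x$n_pairs))
  for (m in x$methods)
    cat(sprintf("  %-8s %.3f +/- %.3f\n", m, x$mean_auc[m], x$se_auc[m]))
  invisible(x)
}

#' Persist a synthetic suite as plain-text files
#'
#' One subdirectory per pair with `case.tsv` / `control.tsv` expression
#' tables, `categories.tsv`, `precision1.tsv` / `precision2.tsv`, plus a
#' top-level `manifest.json` recording seeds and sizes.
#'
#' @param suite list of `synthetic_pair` objects with data.
#' @param dir output directory (created).
#' @param seed master seed to record in the manifest.
#' @return `dir`, invisibly.
#' @export
write_suite <- function(suite, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_pairs = length(suite), master_seed = seed, pairs = list())
  for (i in seq_along(suite)) {
    pair <- suite[[i]]
    pd <- file.path(dir, sprintf("pair%03d", i))
    dir.create(pd, showWarnings = FALSE)
    ex <- pair_to_expression(pair)
    write_expression_table(ex$case, file.path(pd, "case.tsv"))
    write_expression_table(ex$control, file.path(pd, "control.tsv"))
    utils::write.table(
      data.frame(gene = names(pair$categories), category = pair$categories),
      file.path(pd, "categories.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    for (s in 1:2)
      utils::write.table(pair[[paste0("precision", s)]],
                         file.path(pd, sprintf("precision%d.tsv", s)),
                         sep = "\t", quote = FALSE)
    manifest$pairs[[i]] <- list(seed = pair$seed, p = pair$p,
                                noise_sd = pair$noise_sd,
                                n1 = pair$n1, n2 = pair$n2)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a suite written by [write_suite()]
#' @param dir suite directory.
#' @return list of `synthetic_pair` objects.
#' @export
read_suite <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(seq_len(manifest$n_pairs), function(i) {
    pd <- file.path(dir, sprintf("pair%03d", i))
    cats <- utils::read.delim(file.path(pd, "categories.tsv"),
                              stringsAsFactors = FALSE)
    categories <- factor(cats$category,
                         levels = c("perturbed", "shared", "isolated"))
    names(categories) <- cats$gene
    case <- load_expression_table(file.path(pd, "case.tsv"), "case")
    control <- load_expression_table(file.path(pd, "control.tsv"), "control")
    info <- manifest$pairs[[i]]
    structure(list(
      precision1 = as.matrix(utils::read.delim(file.path(pd, "precision1.tsv"))),
      precision2 = as.matrix(utils::read.delim(file.path(pd, "precision2.tsv"))),
      data1 = t(case$values), data2 = t(control$values),
      categories = categories, p = info$p, noise_sd = info$noise_sd,
      n1 = info$n1, n2 = info$n2, seed = info$seed),
      class = "synthetic_pair")
  })
}
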