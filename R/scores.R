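# Perturbation scores: DISCERN, D0, LNS, Glass d-score, ANOVA.
# DISCERN/D0 consume fitted condition networks plus the standardized data
# they were fitted on; LNS and the d-score are correlation-profile scores on
# the standardized data; ANOVA works on the raw (unstandardized) matrices.

check_same_universe <- function(a, b) {
  if (!identical(a$gene_ids, b$gene_ids))
    stop("inputs cover different (or differently ordered) gene universes; ",
         "run align_conditions() first")
  invisible(TRUE)
}

#' DISCERN score
#'
#' For each gene, the ratio of the summed cross-condition prediction errors to
#' the summed within-condition errors:
#' `(err(c,n) + err(n,c)) / (err(c,c) + err(n,n))`, where `err(s, s')` uses
#' the weights learned in condition s' on the data of condition s.  A value of
#' 1 means the regulator model transfers perfectly between conditions; large
#' values flag genes whose regulator wiring differs.  The score is symmetric
#' in the two conditions.
#'
#' @param net_c,net_n `condition_network` objects fitted on `data_c`/`data_n`.
#' @param data_c,data_n the standardized `expr_matrix` inputs the networks
#'   were fitted on.
#' @param floor lower bound applied to the denominator (with a warning) so
#'   that noiseless genes do not produce infinite scores.
#' @return named numeric vector of per-gene scores.
#' @export
discern <- function(net_c, net_n, data_c, data_n, floor = 1e-8) {
  check_same_universe(data_c, data_n)
  check_same_universe(data_c, list(gene_ids = net_c$gene_ids))
  check_same_universe(data_c, list(gene_ids = net_n$gene_ids))
  num <- network_errors(net_n, data_c) + network_errors(net_c, data_n)
  den <- network_errors(net_c, data_c) + network_errors(net_n, data_n)
  low <- den < floor
  if (any(low)) {
    warning(sum(low), " gene(s) with near-zero within-condition error; ",
            "denominator floored at ", floor)
    den[low] <- floor
  }
  num / den
}

#' D0 score (un-normalized cross-prediction error)
#'
#' The numerator of the DISCERN score alone: `err(c,n) + err(n,c)`.  Used as
#' an ablation to show the role of the within-condition denominator.
#'
#' @inheritParams discern
#' @return named numeric vector of per-gene scores.
#' @export
d0 <- function(net_c, net_n, data_c, data_n) {
  check_same_universe(data_c, data_n)
  network_errors(net_n, data_c) + network_errors(net_c, data_n)
}

# Pearson correlation matrix of genes (rows of an expr_matrix).
gene_correlations <- function(data) stats::cor(t(data$values))

#' Local network similarity (LNS)
#'
#' For each gene, the Pearson correlation between its Fisher z-transformed
#' correlation profiles in the two conditions:
#' `corr(atanh(c_ij^n), atanh(c_ij^c))` over all other genes j.  This is a
#' similarity: 1 means the gene's co-expression neighborhood is identical in
#' both conditions.  When ranking genes by perturbation, use `-lns`.
#'
#' Correlations are clipped to `1 - clip_eps` in absolute value before the
#' z-transform.  If a gene's z-profile is constant in either condition the
#' similarity is undefined and returned as `NA` with a warning.
#'
#' @param data_c,data_n standardized `expr_matrix` objects (>= 3 genes).
#' @param clip_eps clipping margin for |correlation|.
#' @return named numeric vector in `[-1, 1]` (possibly `NA`).
#' @export
lns <- function(data_c, data_n, clip_eps = 1e-6) {
  check_same_universe(data_c, data_n)
  G <- length(data_c$gene_ids)
  if (G < 3) stop("LNS requires at least 3 genes")
  cap <- 1 - clip_eps
  zc <- atanh(pmin(pmax(gene_correlations(data_c), -cap), cap))
  zn <- atanh(pmin(pmax(gene_correlations(data_n), -cap), cap))
  out <- vapply(seq_len(G), function(i) {
    a <- zn[i, -i]; b <- zc[i, -i]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (anyNA(out))
    warning(sum(is.na(out)), " gene(s) with a constant z-profile; LNS undefined (NA)")
  names(out) <- data_c$gene_ids
  out
}

#' Glass d-score
#'
#' Each gene's off-diagonal correlation profile is standardized to zero mean
#' and unit variance across the other genes (Glass' d), separately per
#' condition; the score is the L1 distance between the two standardized
#' profiles.  0 means identical (up to location/scale) co-expression
#' neighborhoods.  Symmetric in the two conditions.
#'
#' @inheritParams lns
#' @return named nonnegative numeric vector.
#' @export
glass_dscore <- function(data_c, data_n) {
  check_same_universe(data_c, data_n)
  G <- length(data_c$gene_ids)
  if (G < 3) stop("d-score requires at least 3 genes")
  cc <- gene_correlations(data_c)
  cn <- gene_correlations(data_n)
  out <- vapply(seq_len(G), function(i) {
    a <- cc[i, -i]; b <- cn[i, -i]
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa == 0 || sb == 0)
      stop("constant correlation profile for gene ", data_c$gene_ids[i],
           "; d-score undefined")
    sum(abs((b - mean(b)) / sb - (a - mean(a)) / sa))
  }, numeric(1))
  names(out) <- data_c$gene_ids
  out
}

#' One-way ANOVA differential-expression score
#'
#' For each gene, `-log10(p)` of the one-way F-test comparing the gene's raw
#' expression between the two conditions.  Applied to unstandardized data
#' (per-gene standardization would erase mean differences).  P-values are
#' floored at 1e-300 before the logarithm.  A gene with zero within-group
#' variance and equal group means has an undefined F statistic and is scored
#' 0 with a warning.
#'
#' @param raw_c,raw_n unstandardized `expr_matrix` objects (>= 2 samples each).
#' @return named nonnegative numeric vector.
#' @export
anova_score <- function(raw_c, raw_n) {
  check_same_universe(raw_c, raw_n)
  n1 <- ncol(raw_c$values); n2 <- ncol(raw_n$values)
  if (n1 < 2 || n2 < 2) stop("each condition needs at least 2 samples")
  m1 <- rowMeans(raw_c$values); m2 <- rowMeans(raw_n$values)
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2                 # df = 1
  ssw <- rowSums((raw_c$values - m1)^2) + rowSums((raw_n$values - m2)^2)
  df2 <- n1 + n2 - 2
  f <- (ssb / 1) / (ssw / df2)
  undef <- ssw == 0 & ssb == 0
  if (any(undef)) {
    warning(sum(undef), " gene(s) with zero variance in both groups; ANOVA score set to 0")
    f[undef] <- 0
  }
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb > 0] <- 0                                  # infinite F
  out <- -log10(pmax(p, 1e-300))
  names(out) <- raw_c$gene_ids
  out
}

#' Compute every perturbation score for a condition pair
#'
#' Aligns the two raw matrices, standardizes each condition separately, fits
#' the per-gene lasso regulator networks in both conditions (penalty chosen
#' per gene and condition by cross-validation), and assembles the full score
#' table.  DISCERN, D0, LNS and d-score are computed on the standardized
#' data; ANOVA on the raw data.  `pvalue`/`qvalue` columns are left `NA`; fill
#' them with [add_empirical_significance()] after building a [pooled_null()].
#'
#' @param case,control raw (unstandardized) `expr_matrix` objects.
#' @param regs candidate regulator gene ids.
#' @param folds,grid,seed passed to [fit_condition_network()].
#' @return a data frame of class `score_table` with columns gene, discern,
#'   d0, lns, dscore, anova, pvalue, qvalue; the fitted networks are attached
#'   as attributes `net_case` / `net_control`.
#' @export
score_all <- function(case, control, regs, folds = 5, grid = NULL, seed = 1) {
  al <- align_conditions(case, control)
  case <- al$a; control <- al$b
  check_regulators(regs, case)
  std_c <- standardize_by_gene(case)
  std_n <- standardize_by_gene(control)
  net_c <- fit_condition_network(std_c, regs, folds = folds, grid = grid,
                                 seed = sub_seed(seed, 1))
  net_n <- fit_condition_network(std_n, regs, folds = folds, grid = grid,
                                 seed = sub_seed(seed, 2))
  st <- data.frame(gene = case$gene_ids,
                   discern = discern(net_c, net_n, std_c, std_n),
                   d0 = d0(net_c, net_n, std_c, std_n),
                   lns = lns(std_c, std_n),
                   dscore = glass_dscore(std_c, std_n),
                   anova = anova_score(case, control),
                   pvalue = NA_real_, qvalue = NA_real_,
                   row.names = NULL, stringsAsFactors = FALSE)
  class(st) <- c("score_table", "data.frame")
  attr(st, "net_case") <- net_c
  attr(st, "net_control") <- net_n
  st
}
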