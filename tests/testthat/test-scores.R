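# Hand-constructed two-gene system: in the case condition the target equals
# 0.9 * regulator 1 (plus nothing), in the control condition 0.9 * regulator
# 2, with sample-orthogonal unit-variance regulators.  Evaluating the error
# formula directly gives err_self = 0.01 and err_cross = 1 + 0.81 = 1.81.
orthogonal_cross_instance <- function(n = 40, seed = 12) {
  withr::with_seed(seed, {
    a <- pop_standardize(rnorm(n))
    b0 <- rnorm(n); b0 <- b0 - mean(b0)
    b <- pop_standardize(b0 - a * sum(b0 * a) / sum(a * a))
  })
  genes <- c("T", "X1", "X2")
  mk_net <- function(reg_with_weight, condition) {
    W <- matrix(0, 2, 3, dimnames = list(c("X1", "X2"), genes))
    W[reg_with_weight, "T"] <- 0.9
    W["X1", "X1"] <- 0; W["X2", "X2"] <- 0
    structure(list(condition = condition, gene_ids = genes,
                   regulators = c("X1", "X2"), weights = W, lambda = rep(1, 3)),
              class = "condition_network")
  }
  data_c <- expression_matrix(rbind(T = a, X1 = a, X2 = b), "case")
  data_n <- expression_matrix(rbind(T = b, X1 = a, X2 = b), "control")
  list(net_c = mk_net("X1", "case"), net_n = mk_net("X2", "control"),
       data_c = data_c, data_n = data_n)
}

test_that("discern and d0 evaluate the error-ratio formulas exactly", {
  inst <- orthogonal_cross_instance()
  ds <- discern(inst$net_c, inst$net_n, inst$data_c, inst$data_n)
  d0s <- d0(inst$net_c, inst$net_n, inst$data_c, inst$data_n)
  # target gene: (1.81 + 1.81) / (0.01 + 0.01) = 181, d0 = 3.62
  expect_equal(unname(ds["T"]), 181, tolerance = 1e-8)
  expect_equal(unname(d0s["T"]), 3.62, tolerance = 1e-10)
  # relabeling symmetry: swapping the conditions leaves both scores unchanged
  expect_equal(discern(inst$net_n, inst$net_c, inst$data_n, inst$data_c), ds,
               tolerance = 1e-12)
  expect_equal(d0(inst$net_n, inst$net_c, inst$data_n, inst$data_c), d0s,
               tolerance = 1e-12)
})

test_that("identical condition data pins every score at its null value", {
  m <- toy_expression(8, 14, seed = 31)
  case <- expression_matrix(m$values, "case")
  control <- expression_matrix(m$values, "control")
  st <- score_all(case, control, regs = m$gene_ids, seed = 4)
  expect_equal(st$discern, rep(1, 8), tolerance = 1e-10)
  expect_equal(st$lns, rep(1, 8), tolerance = 1e-10)
  expect_equal(st$dscore, rep(0, 8), tolerance = 1e-10)
  expect_equal(st$anova, rep(0, 8), tolerance = 1e-8)
  std <- standardize_by_gene(case)
  expect_equal(st$d0, 2 * network_errors_for_test(attr(st, "net_case"), std),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("all-zero-weight models on standardized data give DISCERN exactly 1", {
  m1 <- toy_expression(6, 10, seed = 41, condition = "case")
  m2 <- toy_expression(6, 9, seed = 42, condition = "control")
  s1 <- standardize_by_gene(m1); s2 <- standardize_by_gene(m2)
  big <- 1e9
  net1 <- fit_condition_network(s1, m1$gene_ids, lambda = big)
  net2 <- fit_condition_network(s2, m2$gene_ids, lambda = big)
  expect_true(all(net1$weights == 0) && all(net2$weights == 0))
  expect_equal(discern(net1, net2, s1, s2), setNames(rep(1, 6), m1$gene_ids),
               tolerance = 1e-12)
  expect_equal(d0(net1, net2, s1, s2), setNames(rep(2, 6), m1$gene_ids),
               tolerance = 1e-12)
})

test_that("lns clips perfect correlations and flags degenerate profiles", {
  withr::with_seed(6, v <- matrix(rnorm(4 * 20), 4, 20,
                                  dimnames = list(paste0("G", 1:4), NULL)))
  v[2, ] <- 2 * v[1, ] + 3        # correlation exactly 1 with gene 1
  dc <- standardize_by_gene(expression_matrix(v, "case"))
  withr::with_seed(7, v2 <- matrix(rnorm(4 * 20), 4, 20,
                                   dimnames = list(paste0("G", 1:4), NULL)))
  dn <- standardize_by_gene(expression_matrix(v2, "control"))
  out <- lns(dc, dn)
  expect_true(all(is.finite(out)))
  expect_true(all(out >= -1 & out <= 1))
  expect_equal(unname(lns(dc, dc)), rep(1, 4), tolerance = 1e-12)
})

test_that("glass_dscore matches the straight-line oracle and is symmetric", {
  withr::with_seed(13, {
    vc <- matrix(rnorm(4 * 25), 4, 25, dimnames = list(paste0("G", 1:4), NULL))
    vn <- matrix(rnorm(4 * 18), 4, 18, dimnames = list(paste0("G", 1:4), NULL))
  })
  dc <- expression_matrix(vc, "case"); dn <- expression_matrix(vn, "control")
  got <- glass_dscore(dc, dn)
  expect_equal(unname(got), dscore_oracle(vc, vn), tolerance = 1e-10)
  expect_true(all(got >= 0))
  expect_equal(glass_dscore(dn, dc), got, tolerance = 1e-12)
  expect_equal(unname(glass_dscore(dc, dc)), rep(0, 4), tolerance = 1e-12)
})

test_that("anova_score reproduces the F-test and its invariances", {
  g1 <- matrix(c(1, 2, 3), 1, 3, dimnames = list("G1", NULL))
  g2 <- matrix(c(3, 4, 5), 1, 3, dimnames = list("G1", NULL))
  e1 <- expression_matrix(g1, "case"); e2 <- expression_matrix(g2, "control")
  # F = 6 on (1, 4) df -> p = pf(6, 1, 4, lower = FALSE) ~ 0.0705
  p_expected <- pf(6, 1, 4, lower.tail = FALSE)
  expect_equal(unname(anova_score(e1, e2)), -log10(p_expected), tolerance = 1e-10)
  expect_equal(unname(anova_score(e1, e1)), 0, tolerance = 1e-12)
  e1b <- expression_matrix(2 * g1, "case"); e2b <- expression_matrix(2 * g2, "control")
  expect_equal(anova_score(e1b, e2b), anova_score(e1, e2), tolerance = 1e-10)
})

test_that("score_all separates perturbed variables on a small synthetic pair", {
  pair <- generate_precision_pair(0, n_vars = 40, noise_sd = 0.5)
  pair$data1 <- sample_mvn(pair$precision1, 105, seed = 100)
  pair$data2 <- sample_mvn(pair$precision2, 21, seed = 101)
  case <- expression_matrix(t(pair$data1), "case")
  control <- expression_matrix(t(pair$data2), "control")
  st <- score_all(case, control, regs = case$gene_ids, seed = 0)
  perturbed <- pair$categories == "perturbed"
  expect_gt(mean(st$discern[perturbed]), mean(st$discern[!perturbed]))
  expect_error(score_all(case, control, regs = c("nope")), "absent")
})
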