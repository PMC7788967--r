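test_that("variance trajectories equal the quadratic-form oracle", {
  vc <- dfi_vc()
  expect_equal(genetic_variance_at(vc, 0), vc$G0[1, 1])
  expect_equal(pe_variance_at(vc, 0), vc$P0[1, 1])
  # slope contribution at p = 1 rounds to 0.04 kg^2
  expect_equal(round(vc$G0[2, 2], 2), 0.04)
  set.seed(10)
  for (r in 1:20) {
    L <- matrix(stats::rnorm(4), 2)
    G <- crossprod(L)
    v <- variance_components(G0 = G, sigma2_e = 0.1)
    p <- stats::runif(5)
    oracle <- vapply(p, function(pp) drop(c(1, pp) %*% G %*% c(1, pp)),
                     numeric(1))
    expect_equal(genetic_variance_at(v, p), oracle, tolerance = 1e-12)
    expect_true(all(genetic_variance_at(v, seq(0, 1, 0.05)) >= 0))
  }
})

test_that("heritability trajectory matches its defining ratio", {
  vc <- dfi_vc()
  expect_equal(round(heritability_at(vc, 0.30), 2), 0.08)
  expect_equal(round(heritability_at(vc, 1), 2), 0.14)
  toy <- variance_components(G0 = 0.1, P0 = 0.1, sigma2_e = 0.1)
  expect_equal(heritability_at(toy, 0), 1 / 3, tolerance = 1e-12)
  # two-class residual: the class above the threshold enters the denominator
  vc2 <- variance_components(G0 = vc$G0, P0 = vc$P0,
                             sigma2_e = c(normal = 0.120, high = 0.240))
  h_low <- heritability_at(vc2, 0.2, threshold = 0.5)
  h_hi <- heritability_at(vc2, 0.8, threshold = 0.5)
  expect_equal(h_low, heritability_at(vc, 0.2))
  expect_lt(h_hi, heritability_at(vc, 0.8))
})

test_that("the level-by-environment genetic correlation follows the closed
           form", {
  vc <- dfi_vc()
  expect_equal(cor_a0_ap(vc, 0), 1)
  expect_equal(round(cor_a0_ap(vc, 0.15), 2), 0.97)
  expect_equal(round(cor_a0_ap(vc, 1), 2), 0.22)
  g <- vc$G0
  p <- 0.6
  oracle <- (g[1, 1] + g[1, 2] * p) /
    sqrt(g[1, 1] * (g[1, 1] + p^2 * g[2, 2] + 2 * p * g[1, 2]))
  expect_equal(cor_a0_ap(vc, p), oracle, tolerance = 1e-12)
  expect_error(cor_a0_ap(variance_components(
    G0 = matrix(c(0, 0, 0, 0.01), 2), sigma2_e = 0.1), 0.5), "> 0")
})

test_that("the mixture chi-square test matches its survival-function
           oracle", {
  lrt <- likelihood_ratio_test(41219.52, 40685.54)
  expect_equal(lrt$chi2, 533.98, tolerance = 1e-10)
  expect_lt(abs(lrt$p_value - 1.50e-114) / 1.50e-114, 0.05)
  expect_equal(likelihood_ratio_test(100, 100)$p_value, 1)
  # closed form at chi2 = 5.99: 1/2 e^{-x/2} + 1/2 e^{-x/2}(1 + x/2)
  x <- 5.99
  oracle <- 0.5 * exp(-x / 2) + 0.5 * exp(-x / 2) * (1 + x / 2)
  expect_equal(likelihood_ratio_test(x, 0)$p_value, oracle,
               tolerance = 1e-10)
  expect_equal(oracle, 0.1249, tolerance = 1e-3)
  # the mixture p lies between the two pure chi-square p-values
  for (chi in c(0.01, 1, 5, 20, 100, 600)) {
    p <- likelihood_ratio_test(chi, 0)$p_value
    expect_gte(p, stats::pchisq(chi, 2, lower.tail = FALSE) *
                 (1 - 1e-12))
    expect_lte(p, stats::pchisq(chi, 4, lower.tail = FALSE) *
                 (1 + 1e-12))
  }
  expect_error(likelihood_ratio_test(10, 11), "nested")
  expect_error(likelihood_ratio_test(NA, 1), "non-finite")
})

test_that("animals are classified by slope in genetic SD units", {
  fit <- small_fit()
  cls <- classify_resilience(fit)
  expect_equal(nrow(cls), nrow(fit$genetic))
  expect_true(all(table(cls$group) >= 0))
  expect_equal(cls$delta_sd, cls$a1 / sqrt(fit$vc$G0[1, 1]),
               tolerance = 1e-12)
  expect_true(all((abs(cls$delta_sd) <= 1) == (cls$group == "stable")))
  # threshold arithmetic on synthetic fits
  toy <- fit
  toy$genetic <- matrix(c(0, 0, 0, -1.5 * sqrt(fit$vc$G0[1, 1]),
                          0, 1.2 * sqrt(fit$vc$G0[1, 1])),
                        ncol = 2, byrow = TRUE,
                        dimnames = list(c("x", "y", "z"), c("a0", "a1")))
  cls2 <- classify_resilience(toy)
  expect_equal(as.character(cls2$group),
               c("stable", "decreasing", "increasing"))
  # shrinkage keeps most animals near zero slope: a large central group
  expect_gt(mean(cls$group == "stable"), 0.5)
})

test_that("trajectory summaries compose the pointwise operations", {
  vc <- dfi_vc()
  s <- summarize_reaction_norm(vc, grid = c(0, 0.5, 1))
  expect_equal(s$var_genetic, genetic_variance_at(vc, c(0, 0.5, 1)))
  expect_equal(s$h2, heritability_at(vc, c(0, 0.5, 1)))
  expect_equal(s$cor_a0_ap[1], 1)
  # with zero covariance the genetic variance increases monotonically
  v0 <- variance_components(G0 = diag(c(0.02, 0.05)), sigma2_e = 0.1)
  s0 <- summarize_reaction_norm(v0, grid = seq(0, 1, 0.1))
  expect_true(all(diff(s0$var_genetic) > 0))
  # with negative covariance the correlation decays from 1
  sneg <- summarize_reaction_norm(vc, grid = seq(0, 1, 0.05))
  expect_true(all(diff(sneg$cor_a0_ap) <= 1e-12))
  tmp <- withr::local_tempfile(fileext = ".csv")
  summarize_reaction_norm(vc, grid = c(0, 1), path = tmp)
  expect_true(file.exists(tmp))
})
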