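rmix2 <- function(n, w, mu, sd, seed) {
  set.seed(seed)
  z <- stats::rbinom(n, 1, w[2]) + 1L
  stats::rnorm(n, mu[z], sd[z])
}

test_that("a single component recovers the closed-form MLE exactly", {
  set.seed(1)
  x <- stats::rnorm(100, 3, 2)
  m <- fit_mixture(x, 1)
  expect_equal(m$means, mean(x))
  expect_equal(m$sds, sqrt(mean((x - mean(x))^2)))  # 1/n MLE variance
  expect_equal(m$weights, 1)
  expect_true(m$converged)
})

test_that("EM recovers two-component parameters within Monte-Carlo error", {
  x <- rmix2(2000, c(0.91, 0.09), c(-1.60, -1.42), c(0.13, 0.27), seed = 11)
  m <- fit_mixture(x, 2, init_seed = 1)
  expect_true(m$converged)
  expect_true(all(diff(m$sds) >= 0))   # stored sorted by SD
  expect_equal(sum(m$weights), 1, tolerance = 1e-12)
  kc <- which.max(m$means)             # minority challenge component
  kn <- 3L - kc
  # 3 x Monte-Carlo SDs frozen from 200 independent replicate fits
  expect_lt(abs(m$weights[kn] - 0.91), 3 * 0.030)
  expect_lt(abs(m$means[kn] - -1.60), 3 * 0.004)
  expect_lt(abs(m$means[kc] - -1.42), 3 * 0.089)
  expect_lt(abs(m$sds[kn] - 0.13), 3 * 0.0036)
  expect_lt(abs(m$sds[kc] - 0.27), 3 * 0.035)
})

test_that("our EM agrees with the mclust reference EM from the same start",
{
  x <- rmix2(2000, c(0.91, 0.09), c(-1.60, -1.42), c(0.13, 0.27), seed = 11)
  init <- list(weights = c(0.85, 0.15),
               means = as.numeric(stats::quantile(x, c(0.4, 0.9))),
               sds = c(stats::sd(x), stats::sd(x)))
  mine <- resilnorm:::em_run(x, init, tol = 1e-15, max_iter = 20000,
                             sd_floor = 1e-9)
  ref <- mclust::emV(data = x, parameters = list(
    pro = init$weights, mean = init$means,
    variance = list(modelName = "V", d = 1, G = 2,
                    sigmasq = init$sds^2)),
    control = mclust::emControl(tol = c(1e-15, 1e-15),
                                itmax = c(50000, 50000)))
  expect_lt(max(abs(c(ref$parameters$mean - mine$means,
                      sqrt(ref$parameters$variance$sigmasq) - mine$sds,
                      ref$parameters$pro - mine$weights))), 1e-6)
  expect_lt(abs(ref$loglik - mine$loglik), 1e-6)
})

test_that("a higher-k fit never has a lower likelihood", {
  x <- rmix2(500, c(0.8, 0.2), c(-1.6, -1.0), c(0.12, 0.2), seed = 3)
  m1 <- fit_mixture(x, 1)
  m2 <- fit_mixture(x, 2, init_seed = 2)
  expect_gte(m2$loglik, m1$loglik)
})

test_that("component labels do not depend on the initialization", {
  x <- rmix2(600, c(0.85, 0.15), c(-1.6, -0.9), c(0.12, 0.2), seed = 5)
  fits <- lapply(1:4, function(s) fit_mixture(x, 2, init_seed = s))
  for (f in fits[-1]) {
    expect_equal(f$means, fits[[1]]$means, tolerance = 1e-4)
    expect_equal(f$sds, fits[[1]]$sds, tolerance = 1e-4)
  }
})

test_that("posterior probabilities follow Bayes' formula", {
  mod <- structure(list(k = 2L, weights = c(0.9, 0.1),
                        means = c(-1.6, -1.4), sds = c(0.13, 0.27),
                        converged = TRUE), class = "mixture_model")
  x <- -1.0
  oracle <- 0.1 * stats::dnorm(x, -1.4, 0.27) /
    (0.9 * stats::dnorm(x, -1.6, 0.13) + 0.1 * stats::dnorm(x, -1.4, 0.27))
  expect_equal(posterior_probabilities(mod, x), oracle, tolerance = 1e-12)
  # where the weighted densities are equal the posterior is exactly 1/2
  f <- function(x) 0.9 * stats::dnorm(x, -1.6, 0.13) -
    0.1 * stats::dnorm(x, -1.4, 0.27)
  x_eq <- stats::uniroot(f, c(-1.4, -0.8), tol = 1e-12)$root
  expect_equal(posterior_probabilities(mod, x_eq), 0.5, tolerance = 1e-6)
  # responsibilities over all components sum to one
  xs <- seq(-2.5, -0.5, by = 0.1)
  p_hi <- posterior_probabilities(mod, xs)
  d1 <- 0.9 * stats::dnorm(xs, -1.6, 0.13)
  d2 <- 0.1 * stats::dnorm(xs, -1.4, 0.27)
  expect_equal(p_hi + d1 / (d1 + d2), rep(1, length(xs)),
               tolerance = 1e-12)
  # here the largest-mean and largest-SD rules pick the same component
  expect_equal(posterior_probabilities(mod, xs, component = "largest_sd"),
               p_hi, tolerance = 1e-12)
  expect_error(posterior_probabilities(mod, NaN), "non-finite")
})

test_that("bootstrap test retains a single component under the null", {
  ok <- 0L
  for (s in 1:4) {
    set.seed(s)
    x <- stats::rnorm(438, -1.5, 0.15)
    bt <- bootstrap_component_test(x, 1, n_boot = 29, seed = s,
                                   n_restarts = 2)
    expect_equal(bt$p_value,
                 (1 + sum(bt$bootstrap_stats >= bt$observed_lrt)) /
                   (bt$n_boot + 1))
    ok <- ok + (bt$p_value > 0.05)
  }
  expect_gte(ok, 3L)
})

test_that("bootstrap selection finds two well-separated components", {
  set.seed(99)
  z <- stats::rbinom(438, 1, 0.09)
  x <- stats::rnorm(438, ifelse(z == 1, -0.95, -1.55),
                    ifelse(z == 1, 0.15, 0.13))
  sel <- select_num_components(x, k_max = 3, n_boot = 29, seed = 2,
                               n_restarts = 2)
  expect_equal(sel$k, 2L)
  expect_lte(sel$tests[[1]]$p_value, 0.05)
  expect_gt(sel$tests[[2]]$p_value, 0.05)
  # boundary: k_max = 1 returns without testing
  sel1 <- select_num_components(x, k_max = 1)
  expect_equal(sel1$k, 1L)
  expect_length(sel1$tests, 0L)
  expect_error(bootstrap_component_test(x, 1, n_boot = 10), ">= 19")
})

test_that("mixture fits serialize and reload losslessly", {
  x <- rmix2(300, c(0.8, 0.2), c(-1.6, -1.0), c(0.12, 0.2), seed = 13)
  m <- fit_mixture(x, 2, init_seed = 1)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_mixture(m, tmp)
  m2 <- read_mixture(tmp)
  expect_equal(m2$means, m$means, tolerance = 1e-12)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(posterior_probabilities(m2, x),
               posterior_probabilities(m, x), tolerance = 1e-12)
})
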