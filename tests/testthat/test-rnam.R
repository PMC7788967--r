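test_that("the MME reproduce dense GLS with unrelated animals", {
  set.seed(6)
  ped <- founder_ped(20)
  ainv <- a_inverse(ped)
  rec <- data.frame(animal_id = ped$animal, year = "Y1",
                    test_day = rep(1:4, 5), device_id = "D1",
                    dfi = stats::rnorm(20, 2, 0.5))
  spec <- rnam_spec(include_slope = FALSE)
  vc <- variance_components(G0 = 0.05, P0 = 0.03, sigma2_e = 0.12)
  mme <- build_mme(spec, rec, ainv, vc)
  sol <- solve_mme(mme)
  # dense GLS oracle: V = Z G Z' + R, single record per animal
  md <- mme$md
  W <- as.matrix(md$W)
  X <- W[, seq_len(md$p_fix), drop = FALSE]
  Z <- W[, -seq_len(md$p_fix), drop = FALSE]
  G <- diag(rep(c(0.05, 0.03), each = 20))
  V <- Z %*% G %*% t(Z) + diag(0.12, 20)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% rec$dfi)
  u <- G %*% t(Z) %*% Vi %*% (rec$dfi - X %*% b)
  expect_lt(max(abs(sol$solution - c(b, u))), 1e-6)
})

test_that("sparse BLUP equals the dense solver on a pedigreed system", {
  ur <- unrelated_records(30, 10, seed = 14)
  sim <- suppressMessages(
    simulate_dataset(sim_config_small(n_animals = 40, n_days = 10,
                                      n_years = 1, seed = 5)))
  rec <- sim$records
  rec$p <- rec$challenge
  ainv <- a_inverse(sim$ped)
  vc <- variance_components(G0 = matrix(c(0.016, -0.011, -0.011, 0.038), 2),
                            P0 = matrix(c(0.034, -0.031, -0.031, 0.104), 2),
                            sigma2_e = 0.12)
  mme <- build_mme(rnam_spec(), rec, ainv, vc)
  sol <- solve_mme(mme)
  dense <- solve(as.matrix(mme$C), mme$rhs)
  expect_lt(max(abs(sol$solution - dense)), 1e-6)
  # solutions exist for every pedigree animal and every phenotyped one
  expect_equal(nrow(sol$genetic), nrow(sim$ped))
  expect_equal(nrow(sol$pe), length(unique(rec$animal_id)))
})

test_that("with p identically zero the slope carries no information", {
  ur <- unrelated_records(25, 6, seed = 9, p_vals = rep(0, 6))
  vc <- variance_components(G0 = matrix(c(0.03, -0.012, -0.012, 0.05), 2),
                            P0 = matrix(c(0.02, -0.01, -0.01, 0.04), 2),
                            sigma2_e = 0.12)
  sol <- solve_mme(build_mme(rnam_spec(), ur$records, ur$ainv, vc))
  # slope solutions are pure prior regressions of the level solutions
  expect_equal(sol$genetic[, "a1"],
               (-0.012 / 0.03) * sol$genetic[, "a0"], tolerance = 1e-8)
  expect_equal(sol$pe[, "pe1"], (-0.01 / 0.02) * sol$pe[, "pe0"],
               tolerance = 1e-8)
  # and the restricted likelihoods of RNAM and AM coincide
  md_rn <- resilnorm:::rnam_model_data(rnam_spec(), ur$records, ur$ainv)
  st_rn <- resilnorm:::reml_state(md_rn, vc, want_traces = FALSE)
  vc_am <- variance_components(G0 = 0.03, P0 = 0.02, sigma2_e = 0.12)
  md_am <- resilnorm:::rnam_model_data(rnam_spec(include_slope = FALSE),
                                       ur$records, ur$ainv)
  st_am <- resilnorm:::reml_state(md_am, vc_am, want_traces = FALSE)
  expect_equal(st_rn$m2ll, st_am$m2ll, tolerance = 1e-6)
})

test_that("REML equals the closed-form ANOVA solution for a repeatability
           model", {
  set.seed(4)
  n_an <- 60; n_rec <- 8
  ped <- founder_ped(n_an)
  u <- stats::rnorm(n_an, 0, sqrt(0.3))
  rec <- expand.grid(animal_id = ped$animal, test_day = seq_len(n_rec),
                     stringsAsFactors = FALSE)
  rec$dfi <- 2 + u[match(rec$animal_id, ped$animal)] +
    stats::rnorm(nrow(rec), 0, sqrt(0.5))
  spec <- rnam_spec(include_slope = FALSE, include_pe = FALSE,
                    day_covariate = FALSE)
  fit <- suppressWarnings(reml_fit(spec, rec, a_inverse(ped),
                                   em_iters = 20, max_ai_iters = 60))
  m_i <- tapply(rec$dfi, rec$animal_id, mean)
  MSW <- sum((rec$dfi - m_i[rec$animal_id])^2) / (n_an * (n_rec - 1))
  MSB <- n_rec * sum((m_i - mean(rec$dfi))^2) / (n_an - 1)
  expect_true(fit$converged)
  expect_equal(fit$vc$G0[1, 1], (MSB - MSW) / n_rec, tolerance = 1e-8)
  expect_equal(unname(fit$vc$sigma2_e), MSW, tolerance = 1e-8)
})

test_that("EM-REML is monotone and fits stay positive semi-definite", {
  fit <- small_fit()
  em_trace <- fit$trace[1:12]
  expect_true(all(diff(em_trace) <= 1e-6 * (abs(em_trace[-12]) + 1)))
  expect_true(all(eigen(fit$vc$G0, symmetric = TRUE,
                        only.values = TRUE)$values >= 0))
  expect_true(all(eigen(fit$vc$P0, symmetric = TRUE,
                        only.values = TRUE)$values >= 0))
  expect_true(isSymmetric(fit$ai_matrix))
})

test_that("the reaction-norm model never fits worse than the reduced model",
{
  sp <- small_pipeline()
  fit_rn <- small_fit()
  fit_am <- suppressWarnings(
    reml_fit(rnam_spec(include_slope = FALSE, residual = 0.5),
             sp$records, sp$ainv, em_iters = 12, max_ai_iters = 40))
  expect_gte(fit_am$minus_two_loglik, fit_rn$minus_two_loglik - 1e-6)
})

test_that("a genuinely inflated challenge-day residual is recovered and the
           threshold choice hardly matters", {
  sp <- small_pipeline()
  fits <- lapply(c(0.3, 0.5, 0.7), function(t)
    suppressWarnings(fit_heterogeneous_residual(sp$records, sp$ainv, t,
                                                em_iters = 12,
                                                max_ai_iters = 40)))
  for (f in fits) {
    expect_gt(f$vc$sigma2_e[2], f$vc$sigma2_e[1])  # high class inflated
    expect_equal(unname(f$vc$sigma2_e[1]), 0.120, tolerance = 0.05)
  }
  g11 <- vapply(fits, function(f) f$vc$G0[1, 1], numeric(1))
  expect_lt(max(g11) - min(g11), 0.01)
})

test_that("the genetic correlation and its delta-method SE are correct", {
  fit <- small_fit()
  gse <- genetic_correlation_se(fit)
  g <- fit$vc$G0
  expect_equal(gse$correlation, g[1, 2] / sqrt(g[1, 1] * g[2, 2]),
               tolerance = 1e-12)
  expect_gt(gse$se, 0)
  # finite-difference oracle for the delta-method gradient
  V <- solve(fit$ai_matrix)
  idx <- match(c("g11", "g12", "g22"), fit$par_names)
  rfun <- function(th) th[2] / sqrt(th[1] * th[3])
  th0 <- c(g[1, 1], g[1, 2], g[2, 2])
  grad_fd <- vapply(1:3, function(i) {
    h <- 1e-7
    tp <- th0; tp[i] <- tp[i] + h
    tm <- th0; tm[i] <- tm[i] - h
    (rfun(tp) - rfun(tm)) / (2 * h)
  }, numeric(1))
  se_fd <- sqrt(drop(t(grad_fd) %*% V[idx, idx] %*% grad_fd))
  expect_equal(gse$se, se_fd, tolerance = 1e-5)
})

test_that("model and data inconsistencies are rejected up front", {
  ur <- unrelated_records(10, 4, seed = 2)
  vc <- variance_components(G0 = diag(c(0.03, 0.05)),
                            P0 = diag(c(0.02, 0.04)), sigma2_e = 0.12)
  bad <- ur$records
  bad$p <- 2
  expect_error(build_mme(rnam_spec(), bad, ur$ainv, vc), "\\[0, 1\\]")
  bad2 <- ur$records
  bad2$animal_id[1] <- "NOPE"
  expect_error(build_mme(rnam_spec(), bad2, ur$ainv, vc),
               "absent from pedigree")
  # all p on one side of the threshold leaves an empty residual class
  low <- ur$records
  low$p <- 0.1
  expect_error(build_mme(rnam_spec(residual = 0.5), low, ur$ainv,
                         variance_components(G0 = diag(c(0.03, 0.05)),
                                             P0 = diag(c(0.02, 0.04)),
                                             sigma2_e = c(0.1, 0.2))),
               "zero rows")
  expect_error(rnam_spec(residual = 1.2), "in \\(0, 1\\)")
  expect_error(variance_components(G0 = matrix(c(1, 2, 2, 1), 2),
                                   sigma2_e = 0.1), "semi-definite")
})

test_that("fits serialize to JSON/CSV and reload", {
  fit <- small_fit()
  tmp <- withr::local_tempdir()
  write_fit(fit, file.path(tmp, "fit.json"), file.path(tmp, "sol.csv"))
  back <- read_fit_json(file.path(tmp, "fit.json"))
  expect_equal(back$G0, unname(fit$vc$G0), tolerance = 1e-12)
  expect_equal(back$minus_two_loglik, fit$minus_two_loglik,
               tolerance = 1e-9)
  sol <- utils::read.csv(file.path(tmp, "sol.csv"))
  expect_equal(nrow(sol), nrow(fit$genetic))
  expect_equal(sol$a0, unname(fit$genetic[, "a0"]), tolerance = 1e-10)
})
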