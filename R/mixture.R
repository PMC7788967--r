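#' Fit a univariate Gaussian mixture by EM
#'
#' Maximum-likelihood fit of a k-component normal mixture to day-level
#' log-CV values via the expectation-maximization algorithm.  Component
#' means and variances are unconstrained (heteroscedastic).  The fit is
#' repeated from a deterministic quantile-split initialization plus
#' `n_restarts` random-responsibility initializations, and the run with
#' the highest log-likelihood is kept.  Components are returned sorted
#' by increasing standard deviation, so the last component is the
#' high-variance ("challenge") component regardless of initialization.
#'
#' @param values Numeric vector of observations (log CV per day).
#' @param k Number of components (>= 1).
#' @param init_seed Optional seed for the random restarts.
#' @param tol Convergence tolerance on the relative log-likelihood
#'   change (default 1e-8).
#' @param max_iter Maximum EM iterations per run (default 1000).
#' @param n_restarts Number of random restarts (default 5) in addition
#'   to the quantile-split start.
#' @return An object of class `mixture_model`: list with `k`, `weights`,
#'   `means`, `sds`, `loglik`, `n_iter`, `converged`, `n`.
#' @export
fit_mixture <- function(values, k, init_seed = NULL, tol = 1e-8,
                        max_iter = 1000L, n_restarts = 5L) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("non-finite values in mixture input")
  n <- length(x)
  if (k < 1L) stop("k must be >= 1")
  if (n <= 2L * k) stop("need more than 2k observations to fit k components")
  if (!is.null(init_seed)) set.seed(init_seed)

  if (k == 1L) {
    # closed-form single-component MLE (1/n variance)
    mu <- mean(x)
    sd1 <- sqrt(mean((x - mu)^2))
    ll <- sum(stats::dnorm(x, mu, sd1, log = TRUE))
    return(structure(list(k = 1L, weights = 1, means = mu, sds = sd1,
                          loglik = ll, n_iter = 0L, converged = TRUE,
                          n = n), class = "mixture_model"))
  }

  sd_floor <- 1e-6 * stats::sd(x)
  inits <- c(list(mix_init_quantile(x, k)),
             replicate(n_restarts, mix_init_random(x, k), simplify = FALSE))
  best <- NULL
  for (init in inits) {
    fit <- tryCatch(
      em_run(x, init, tol = tol, max_iter = max_iter, sd_floor = sd_floor),
      degenerate = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best)) stop("mixture degenerate")
  ord <- order(best$sds)
  structure(list(k = as.integer(k), weights = best$weights[ord],
                 means = best$means[ord], sds = best$sds[ord],
                 loglik = best$loglik, n_iter = best$n_iter,
                 converged = best$converged, n = n),
            class = "mixture_model")
}

# split at the (1 - q) quantile: upper tail seeds the high component,
# the rest is split into k - 1 equal-size quantile groups
mix_init_quantile <- function(x, k, q = 0.15) {
  cut <- stats::quantile(x, 1 - q)
  hi <- x >= cut
  grp <- integer(length(x))
  grp[hi] <- k
  br <- stats::quantile(x[!hi], seq(0, 1, length.out = k))
  grp[!hi] <- findInterval(x[!hi], br, rightmost.closed = TRUE,
                           all.inside = TRUE)
  par_from_groups(x, grp, k)
}

mix_init_random <- function(x, k) {
  r <- matrix(stats::rexp(length(x) * k), ncol = k)
  r <- r / rowSums(r)
  par_from_resp(x, r)
}

par_from_groups <- function(x, grp, k) {
  w <- m <- s <- numeric(k)
  for (i in seq_len(k)) {
    xi <- x[grp == i]
    if (length(xi) < 2L) xi <- x  # fall back to pooled stats
    w[i] <- max(length(x[grp == i]), 1L) / length(x)
    m[i] <- mean(xi)
    s[i] <- stats::sd(xi)
  }
  list(weights = w / sum(w), means = m, sds = s)
}

par_from_resp <- function(x, r) {
  nk <- colSums(r)
  m <- colSums(r * x) / nk
  v <- colSums(r * outer(x, m, "-")^2) / nk
  list(weights = nk / length(x), means = m, sds = sqrt(v))
}

mix_loglik <- function(x, par) {
  dens <- vapply(seq_along(par$means), function(i)
    par$weights[i] * stats::dnorm(x, par$means[i], par$sds[i]),
    numeric(length(x)))
  sum(log(rowSums(dens)))
}

em_run <- function(x, par, tol, max_iter, sd_floor) {
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_along(par$means), function(i)
      par$weights[i] * stats::dnorm(x, par$means[i], par$sds[i]),
      numeric(length(x)))
    tot <- rowSums(dens)
    if (any(tot <= 0) || any(!is.finite(tot)))
      stop(structure(class = c("degenerate", "error", "condition"),
                     list(message = "mixture degenerate", call = NULL)))
    ll <- sum(log(tot))
    # EM guarantees a non-decreasing likelihood; a real drop is a bug
    if (ll < ll_old - 1e-8 * (abs(ll_old) + 1))
      stop("EM log-likelihood decreased")
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    r <- dens / tot
    par <- par_from_resp(x, r)
    if (any(par$sds < sd_floor))
      stop(structure(class = c("degenerate", "error", "condition"),
                     list(message = "mixture degenerate", call = NULL)))
  }
  list(weights = par$weights, means = par$means, sds = par$sds,
       loglik = ll_old, n_iter = it, converged = converged)
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("Gaussian mixture,", x$k, "component(s), logLik",
      format(x$loglik, digits = 8), "\n")
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}

#' Posterior challenge probabilities
#'
#' Posterior probability, for each observation, of membership in the
#' challenge component of a fitted mixture.  Applied to day-level log
#' CV values this is the probability that an unrecorded environmental
#' challenge occurred on that day, used downstream as the environmental
#' covariate of the reaction-norm model.
#'
#' The challenge component is the one that captures the high-CV days:
#' by default the component with the largest mean log CV.  With
#' `component = "largest_sd"` the largest-SD component is used instead;
#' the two rules coincide for the typical fit in which a broad
#' high-variance minority of days sits to the right of a tight bulk,
#' but the largest-mean rule stays correct when the minority component
#' happens to be fitted with a small spread.
#'
#' @param model A `mixture_model` from [fit_mixture()].
#' @param values Numeric vector at which to evaluate the posterior.
#' @param component Challenge-component rule, `"largest_mean"`
#'   (default) or `"largest_sd"`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
posterior_probabilities <- function(model, values,
                                    component = c("largest_mean",
                                                  "largest_sd")) {
  component <- match.arg(component)
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("non-finite values")
  if (!isTRUE(model$converged)) stop("mixture model did not converge")
  dens <- vapply(seq_len(model$k), function(i)
    model$weights[i] * stats::dnorm(x, model$means[i], model$sds[i]),
    numeric(length(x)))
  dens <- matrix(dens, nrow = length(x))
  kc <- if (component == "largest_mean") which.max(model$means) else model$k
  p <- dens[, kc] / rowSums(dens)
  pmin(pmax(p, 0), 1)
}

#' Attach challenge probabilities to a day-variability table
#'
#' @param model A converged `mixture_model`.
#' @param dayvar Day-variability table from [compute_day_variability()].
#' @return `dayvar` with an added column `p`.
#' @export
challenge_probabilities <- function(model, dayvar) {
  dayvar$p <- posterior_probabilities(model, dayvar$log_cv)
  dayvar
}

#' Simulate from a fitted mixture
#'
#' @param n Number of draws.
#' @param model A `mixture_model`.
#' @return Numeric vector of length `n`.
#' @export
rmixture <- function(n, model) {
  z <- sample.int(model$k, n, replace = TRUE, prob = model$weights)
  stats::rnorm(n, model$means[z], model$sds[z])
}

#' Parametric bootstrap test of the number of mixture components
#'
#' Tests H0: k components against H1: k + 1 components.  The observed
#' statistic is twice the log-likelihood gain of the larger model; its
#' null distribution is obtained by refitting both models to samples
#' simulated from the fitted null model.  The p-value uses the +1
#' correction, `(1 + #{boot >= observed}) / (n_boot + 1)`.
#'
#' @param values Observed data.
#' @param k_null Null number of components.
#' @param n_boot Bootstrap replicates (>= 19, default 100).
#' @param seed Seed controlling the bootstrap streams.
#' @param tol,max_iter,n_restarts Passed to [fit_mixture()].
#' @return Object of class `mixture_boot`: list with `k_null`, `k_alt`,
#'   `observed_lrt`, `bootstrap_stats`, `p_value`, `n_boot`,
#'   `n_failed`, `seed`.
#' @export
bootstrap_component_test <- function(values, k_null, n_boot = 100L,
                                     seed = 1L, tol = 1e-8,
                                     max_iter = 1000L, n_restarts = 5L) {
  if (n_boot < 19L) stop("n_boot must be >= 19")
  x <- as.numeric(values)
  fit0 <- fit_mixture(x, k_null, init_seed = seed, tol = tol,
                      max_iter = max_iter, n_restarts = n_restarts)
  fit1 <- fit_mixture(x, k_null + 1L, init_seed = seed, tol = tol,
                      max_iter = max_iter, n_restarts = n_restarts)
  obs <- max(0, 2 * (fit1$loglik - fit0$loglik))
  stats_b <- numeric(0)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    got <- NA_real_
    for (try in 1:3) {
      sub_seed <- seed + 1000L * b + try
      set.seed(sub_seed)
      xb <- rmixture(length(x), fit0)
      lrt <- tryCatch({
        f0 <- fit_mixture(xb, k_null, init_seed = sub_seed, tol = tol,
                          max_iter = max_iter, n_restarts = n_restarts)
        f1 <- fit_mixture(xb, k_null + 1L, init_seed = sub_seed, tol = tol,
                          max_iter = max_iter, n_restarts = n_restarts)
        max(0, 2 * (f1$loglik - f0$loglik))
      }, error = function(e) NA_real_)
      if (!is.na(lrt)) { got <- lrt; break }
    }
    if (is.na(got)) n_failed <- n_failed + 1L else stats_b <- c(stats_b, got)
  }
  nb <- length(stats_b)
  p <- (1 + sum(stats_b >= obs)) / (nb + 1)
  structure(list(k_null = as.integer(k_null), k_alt = as.integer(k_null + 1L),
                 observed_lrt = obs, bootstrap_stats = stats_b,
                 p_value = p, n_boot = nb, n_failed = n_failed,
                 seed = seed, fit_null = fit0, fit_alt = fit1),
            class = "mixture_boot")
}

#' @export
print.mixture_boot <- function(x, ...) {
  cat(sprintf("Bootstrap LRT of %d vs %d components: LRT = %.3f, p = %.4f (%d replicates)\n",
              x$k_null, x$k_alt, x$observed_lrt, x$p_value, x$n_boot))
  invisible(x)
}

#' Sequential selection of the number of mixture components
#'
#' Tests k against k + 1 components for k = 1, 2, ... and returns the
#' smallest k for which the bootstrap test is not rejected at level
#' `alpha`, stopping at `k_max`.
#'
#' @inheritParams bootstrap_component_test
#' @param k_max Largest k to consider.
#' @param alpha Test level (default 0.05).
#' @return List with `k` (selected) and `tests` (list of
#'   `mixture_boot`).
#' @export
select_num_components <- function(values, k_max = 3L, n_boot = 100L,
                                  alpha = 0.05, seed = 1L, ...) {
  if (k_max < 1L) stop("k_max must be >= 1")
  tests <- list()
  k <- 1L
  while (k < k_max) {
    bt <- bootstrap_component_test(values, k, n_boot = n_boot,
                                   seed = seed + k, ...)
    tests[[length(tests) + 1L]] <- bt
    if (bt$p_value > alpha) break
    k <- k + 1L
  }
  list(k = k, tests = tests)
}

#' Serialize / read a mixture fit
#'
#' @param model A `mixture_model`.
#' @param path JSON path.
#' @return `write_mixture` the path invisibly; `read_mixture` the model.
#' @export
write_mixture <- function(model, path) {
  obj <- unclass(model)
  obj$fit_null <- obj$fit_alt <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mixture
#' @export
read_mixture <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$k <- as.integer(obj$k)
  structure(obj, class = "mixture_model")
}
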