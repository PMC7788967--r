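#' Genetic and permanent-environment variance along the gradient
#'
#' The total genetic variance at environmental value p is the quadratic
#' form `s2_a0 + 2 p s_a0a1 + p^2 s2_a1` (and analogously for the
#' permanent-environment components).
#'
#' @param vc An [variance_components()] with 2x2 `G0` (and `P0`).
#' @param p Environmental value(s) in `[0, 1]`.
#' @return Variance(s), kg^2.
#' @export
genetic_variance_at <- function(vc, p) {
  stopifnot(all(p >= 0 & p <= 1))
  quad_at(vc$G0, p)
}

#' @rdname genetic_variance_at
#' @export
pe_variance_at <- function(vc, p) {
  stopifnot(all(p >= 0 & p <= 1))
  if (is.null(vc$P0)) stop("no permanent-environment components")
  quad_at(vc$P0, p)
}

quad_at <- function(M, p) {
  if (nrow(M) == 1L) return(rep(M[1, 1], length(p)))
  M[1, 1] + 2 * p * M[1, 2] + p^2 * M[2, 2]
}

#' Heritability along the environmental gradient
#'
#' `h2(p) = var_g(p) / (var_g(p) + var_pe(p) + s2_e)`.  For a two-class
#' residual fit, the "normal"-day residual is used below the threshold
#' and the "high" residual above it.
#'
#' @inheritParams genetic_variance_at
#' @param threshold Residual-class threshold when `vc` carries two
#'   residual variances (default 0.5).
#' @return Heritability value(s) in `[0, 1]`.
#' @export
heritability_at <- function(vc, p, threshold = 0.5) {
  vg <- genetic_variance_at(vc, p)
  vp <- if (is.null(vc$P0)) 0 else pe_variance_at(vc, p)
  s2e <- if (length(vc$sigma2_e) == 1L) vc$sigma2_e
         else ifelse(p > threshold, vc$sigma2_e[2], vc$sigma2_e[1])
  den <- vg + vp + s2e
  if (any(den <= 0)) stop("zero phenotypic variance")
  vg / den
}

#' Genetic correlation between breeding values at p = 0 and at p
#'
#' `Cor(a0, ap) = (s2_a0 + s_a0a1 p) /
#'   sqrt(s2_a0 (s2_a0 + p^2 s2_a1 + 2 p s_a0a1))`.
#' Equals 1 at p = 0; values below 1 indicate reranking of animals
#' along the environmental gradient (genotype-by-environment
#' interaction).
#'
#' @inheritParams genetic_variance_at
#' @return Correlation value(s) in `[-1, 1]`.
#' @export
cor_a0_ap <- function(vc, p) {
  stopifnot(all(p >= 0 & p <= 1))
  G <- vc$G0
  if (nrow(G) == 1L) return(rep(1, length(p)))
  if (G[1, 1] <= 0) stop("level genetic variance must be > 0")
  vp <- quad_at(G, p)
  if (any(vp <= 0)) stop("zero genetic variance at some p")
  r <- (G[1, 1] + G[1, 2] * p) / sqrt(G[1, 1] * vp)
  pmin(pmax(r, -1), 1)
}

#' Likelihood-ratio test of the reaction-norm terms
#'
#' Compares the reduced animal model (AM) with the reaction-norm model
#' (RNAM) on the same data: `chi2 = (-2logL_AM) - (-2logL_RNAM)`.
#' Because the null hypothesis places two variance parameters on the
#' boundary of the parameter space and frees two covariances, the
#' p-value is taken from an equal-weight mixture of chi-square
#' distributions with 2 and 4 degrees of freedom.  Survival functions
#' are combined in log space, so p-values far below double-precision
#' underflow of the naive density sum (e.g. 1e-114) are exact.
#'
#' @param m2ll_am,m2ll_rnam The -2 log likelihoods of the reduced and
#'   reaction-norm fits.
#' @return Object of class `lrt_result`: list with `chi2`, `p_value`,
#'   `dfs = c(2, 4)`, `weights = c(0.5, 0.5)`.
#' @export
likelihood_ratio_test <- function(m2ll_am, m2ll_rnam) {
  if (!is.finite(m2ll_am) || !is.finite(m2ll_rnam))
    stop("non-finite likelihoods")
  chi2 <- m2ll_am - m2ll_rnam
  if (chi2 < -1e-6) stop("models not nested or fit failed (negative chi2)")
  if (chi2 < 0) {
    warning("slightly negative chi2 clamped to 0")
    chi2 <- 0
  }
  lp2 <- stats::pchisq(chi2, 2, lower.tail = FALSE, log.p = TRUE)
  lp4 <- stats::pchisq(chi2, 4, lower.tail = FALSE, log.p = TRUE)
  # log(0.5 e^lp2 + 0.5 e^lp4), stably
  mx <- max(lp2, lp4)
  lp <- mx + log(0.5 * exp(lp2 - mx) + 0.5 * exp(lp4 - mx))
  structure(list(chi2 = chi2, p_value = exp(lp), log_p = lp,
                 dfs = c(2, 4), weights = c(0.5, 0.5)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.4f, mixture(0.5 chi2_2 + 0.5 chi2_4) p = %.4g\n",
              x$chi2, x$p_value))
  invisible(x)
}

#' Three-group resilience classification of animals
#'
#' Classifies each animal by its change in breeding value between the
#' non-challenging (p = 0) and fully challenging (p = 1) environment,
#' `delta = a1`, expressed in genetic standard deviations.  Animals
#' within one genetic SD are "stable" (resilient); the others
#' "decreasing" or "increasing" according to the sign of the slope.
#'
#' @param fit An `rnam_fit` with slope breeding values.
#' @param vc Variance components used for the standardization; defaults
#'   to the fit's own.
#' @param sd_type Which genetic SD standardizes the change: `"level"`
#'   (SD of a0, the default) or `"total_p1"` (total additive SD at
#'   p = 1).
#' @return Data frame with `animal_id`, `a0`, `a1`, `delta_sd`,
#'   `group` (factor: decreasing / stable / increasing).
#' @export
classify_resilience <- function(fit, vc = fit$vc, sd_type = c("level",
                                                              "total_p1")) {
  sd_type <- match.arg(sd_type)
  if (!fit$spec$include_slope) stop("fit has no slope breeding values")
  s2 <- switch(sd_type, level = vc$G0[1, 1],
               total_p1 = genetic_variance_at(vc, 1))
  if (s2 <= 0) stop("genetic variance for standardization must be > 0")
  delta_sd <- fit$genetic[, "a1"] / sqrt(s2)
  group <- cut(delta_sd, c(-Inf, -1, 1, Inf),
               labels = c("decreasing", "stable", "increasing"))
  data.frame(animal_id = rownames(fit$genetic),
             a0 = fit$genetic[, "a0"], a1 = fit$genetic[, "a1"],
             delta_sd = delta_sd, group = group, row.names = NULL)
}

#' Reaction-norm trajectory summaries on a grid
#'
#' Evaluates the genetic and permanent-environment variance,
#' heritability and `Cor(a0, ap)` trajectories on a grid of p values.
#'
#' @inheritParams heritability_at
#' @param grid Grid of p values in `[0, 1]`.
#' @param path Optional CSV output path.
#' @return Data frame with columns `p`, `var_genetic`, `var_pe`, `h2`,
#'   `cor_a0_ap`.
#' @export
summarize_reaction_norm <- function(vc, grid = seq(0, 1, by = 0.01),
                                    threshold = 0.5, path = NULL) {
  stopifnot(all(grid >= 0 & grid <= 1))
  out <- data.frame(p = grid,
                    var_genetic = genetic_variance_at(vc, grid),
                    var_pe = if (is.null(vc$P0)) NA_real_
                             else pe_variance_at(vc, grid),
                    h2 = heritability_at(vc, grid, threshold = threshold),
                    cor_a0_ap = cor_a0_ap(vc, grid))
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
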