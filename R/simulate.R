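#' Simulation configuration
#'
#' Default settings emulate a multi-year lamb feed-intake test: eight
#' yearly cohorts of about 119 phenotyped male lambs (951 in total)
#' recorded daily over roughly 55 days on test per year (438 day cells
#' in total), a pedigree of about 5,100 animals, and true variance
#' components on the scale reported for daily feed intake (kg^2):
#' level/slope genetic covariance matrix `G0`, permanent-environment
#' matrix `P0` and residual variance 0.120.  A fraction `pi_challenge`
#' of days carries an unrecorded environmental challenge: on those
#' days the slope effects are switched on and the residual standard
#' deviation is multiplied by `residual_inflation`.  Day-to-day
#' lognormal jitter of the residual SD (`day_sd_jitter`) spreads the
#' day-level log CV within each class.
#'
#' @param n_years Number of yearly cohorts.
#' @param cohort_sizes Phenotyped animals per year (recycled to
#'   `n_years`).
#' @param days_per_year Test days per year (recycled).
#' @param devices_per_year Feeder devices per year; year x device forms
#'   the fixed contemporary group.
#' @param n_founders,gen_sizes Pedigree structure: founders, then
#'   discrete generations of the given sizes; the phenotyped cohorts
#'   are offspring of the last generation.
#' @param pi_challenge Probability that a day carries a challenge.
#' @param G0,P0,sigma2_e True (co)variance components.
#' @param residual_inflation Multiplier of the residual SD on challenge
#'   days.
#' @param day_sd_jitter Lognormal SD of the day-level residual-SD
#'   multiplier, `c(normal, challenge)`.
#' @param baseline Mean intake (kg) at day 0.
#' @param b1 Growth regression of intake on day-on-test (kg/day).
#' @param yearACF_sd SD of contemporary-group effects (kg).
#' @param mean_visits Mean feeder visits per animal-day (for the
#'   visit-level simulator).
#' @param seed Seed from which all randomness flows.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_years = 8L,
                       cohort_sizes = c(119L, 119L, 119L, 119L, 119L,
                                        119L, 119L, 118L),
                       days_per_year = c(55L, 55L, 55L, 55L, 55L, 55L,
                                         54L, 54L),
                       devices_per_year = 6L,
                       n_founders = 1500L,
                       gen_sizes = c(1400L, 1265L),
                       pi_challenge = 0.09,
                       G0 = matrix(c(0.016, -0.011, -0.011, 0.038), 2),
                       P0 = matrix(c(0.034, -0.031, -0.031, 0.104), 2),
                       sigma2_e = 0.120,
                       residual_inflation = 2,
                       day_sd_jitter = c(0.08, 0.22),
                       baseline = 1.7, b1 = 0.012, yearACF_sd = 0.1,
                       mean_visits = 14.56,
                       seed = 1L) {
  cfg <- list(n_years = as.integer(n_years),
              cohort_sizes = rep_len(as.integer(cohort_sizes), n_years),
              days_per_year = rep_len(as.integer(days_per_year), n_years),
              devices_per_year = as.integer(devices_per_year),
              n_founders = as.integer(n_founders),
              gen_sizes = as.integer(gen_sizes),
              pi_challenge = pi_challenge, G0 = as.matrix(G0),
              P0 = as.matrix(P0), sigma2_e = sigma2_e,
              residual_inflation = residual_inflation,
              day_sd_jitter = rep_len(day_sd_jitter, 2L),
              baseline = baseline, b1 = b1, yearACF_sd = yearACF_sd,
              mean_visits = mean_visits, seed = as.integer(seed))
  stopifnot(cfg$pi_challenge >= 0, cfg$pi_challenge <= 1,
            cfg$sigma2_e > 0, cfg$n_founders >= 2)
  if (any(eigen(cfg$G0, symmetric = TRUE, only.values = TRUE)$values < 0) ||
      any(eigen(cfg$P0, symmetric = TRUE, only.values = TRUE)$values < 0))
    stop("true G0 and P0 must be positive semi-definite")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a pedigree with discrete generations
#'
#' Founders, then `gen_sizes` generations of random mating (sires and
#' dams drawn from the previous generation, no selfing), then the
#' phenotyped cohorts (one per year) as offspring of the last
#' generation.
#'
#' @param config A [sim_config()].
#' @return List with `ped` (a sorted `pedigree`), `phenotyped` (data
#'   frame: `animal_id`, `year`) and `sex` assignments.
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  id <- 0L
  new_ids <- function(n) {
    out <- sprintf("A%05d", id + seq_len(n)); id <<- id + n; out
  }
  founders <- new_ids(config$n_founders)
  rows <- data.frame(animal = founders, sire = "0", dam = "0",
                     stringsAsFactors = FALSE)
  sex <- stats::setNames(sample(c("M", "F"), length(founders), TRUE),
                         founders)
  prev <- founders
  mate <- function(n, parents) {
    sires <- parents[sex[parents] == "M"]
    dams <- parents[sex[parents] == "F"]
    if (length(sires) < 1L || length(dams) < 1L)
      stop("need both sexes among parents")
    kids <- new_ids(n)
    out <- data.frame(animal = kids,
                      sire = sample(sires, n, replace = TRUE),
                      dam = sample(dams, n, replace = TRUE),
                      stringsAsFactors = FALSE)
    sex[kids] <<- sample(c("M", "F"), n, TRUE)
    out
  }
  for (g in config$gen_sizes) {
    gen <- mate(g, prev)
    rows <- rbind(rows, gen)
    prev <- gen$animal
  }
  phen <- NULL
  for (yr in seq_len(config$n_years)) {
    coh <- mate(config$cohort_sizes[yr], prev)
    rows <- rbind(rows, coh)
    phen <- rbind(phen, data.frame(animal_id = coh$animal,
                                   year = sprintf("Y%d", yr),
                                   stringsAsFactors = FALSE))
  }
  list(ped = sort_pedigree(rows), phenotyped = phen, sex = sex)
}

#' Simulate the challenge-day process
#'
#' Each (year, test day) independently carries an unrecorded challenge
#' with probability `pi_challenge`.  Every day receives a residual-SD
#' multiplier: lognormal jitter around 1 on normal days and around
#' `residual_inflation` on challenge days.
#'
#' @param config A [sim_config()].
#' @return Data frame with `year`, `test_day`, `challenge` (0/1) and
#'   `resid_mult`.
#' @export
simulate_days <- function(config) {
  set.seed(config$seed + 1L)
  out <- do.call(rbind, lapply(seq_len(config$n_years), function(yr)
    data.frame(year = sprintf("Y%d", yr),
               test_day = seq_len(config$days_per_year[yr]),
               stringsAsFactors = FALSE)))
  n <- nrow(out)
  out$challenge <- stats::rbinom(n, 1L, config$pi_challenge)
  jit <- config$day_sd_jitter[out$challenge + 1L]
  out$resid_mult <- ifelse(out$challenge == 1L,
                           config$residual_inflation, 1) *
    exp(stats::rnorm(n, 0, jit))
  out
}

#' Simulate daily phenotypes under the reaction-norm model
#'
#' Breeding-value pairs (a0, a1) are generated over the whole pedigree
#' by the Mendelian-sampling recursion (so their covariance is
#' `G0 (x) A`, with inbreeding accounted for), permanent-environment
#' pairs i.i.d. from `P0`, and each record built as
#' `y = yearACF + b1 day + a0 + a1 s_j + pe0 + pe1 s_j + e`, where
#' `s_j` is the day's true challenge indicator and the residual SD on
#' day j is `sqrt(sigma2_e) * resid_mult_j`.  Non-positive intakes are
#' dropped with a message.
#'
#' @param pedsim Output of [simulate_pedigree()].
#' @param days Output of [simulate_days()].
#' @param config A [sim_config()].
#' @return List with `records` (daily intake records incl. true day
#'   indicator columns), and `truth` (true breeding values, pe effects,
#'   fixed effects, day table, config echo).
#' @export
simulate_phenotypes <- function(pedsim, days, config) {
  set.seed(config$seed + 2L)
  ped <- pedsim$ped
  n_ped <- nrow(ped)
  f <- inbreeding(ped)
  mvar <- mendelian_variance(ped, f)
  pc <- ped_codes(ped)
  cG <- chol(config$G0 + diag(1e-12, 2))
  # genetic values by generation-order recursion
  a <- matrix(0, n_ped, 2, dimnames = list(ped$animal, c("a0", "a1")))
  Zm <- matrix(stats::rnorm(2L * n_ped), n_ped, 2) %*% cG
  for (i in seq_len(n_ped)) {
    par_mean <- c(0, 0)
    if (pc$sire[i] > 0L) par_mean <- par_mean + 0.5 * a[pc$sire[i], ]
    if (pc$dam[i] > 0L) par_mean <- par_mean + 0.5 * a[pc$dam[i], ]
    a[i, ] <- par_mean + sqrt(mvar[i]) * Zm[i, ]
  }
  phen <- pedsim$phenotyped
  n_ph <- nrow(phen)
  cP <- chol(config$P0 + diag(1e-12, 2))
  pe <- matrix(stats::rnorm(2L * n_ph), n_ph, 2) %*% cP
  dimnames(pe) <- list(phen$animal_id, c("pe0", "pe1"))
  # contemporary groups: animals split over devices within year
  years <- unique(phen$year)
  dev_of <- unlist(lapply(years, function(yr) {
    n <- sum(phen$year == yr)
    sample(rep_len(sprintf("D%d", seq_len(config$devices_per_year)), n))
  }))
  names(dev_of) <- phen$animal_id[order(match(phen$year, years))]
  dev_of <- dev_of[phen$animal_id]
  grp <- paste(phen$year, dev_of, sep = ":")
  grp_levels <- sort(unique(grp))
  grp_eff <- stats::setNames(
    config$baseline + stats::rnorm(length(grp_levels), 0, config$yearACF_sd),
    grp_levels)

  # expand to records: every phenotyped animal on every day of its year
  recs <- do.call(rbind, lapply(seq_along(years), function(k) {
    yr <- years[k]
    dsub <- days[days$year == yr, , drop = FALSE]
    asub <- which(phen$year == yr)
    data.frame(animal_id = rep(phen$animal_id[asub], each = nrow(dsub)),
               year = yr,
               test_day = rep(dsub$test_day, length(asub)),
               challenge = rep(dsub$challenge, length(asub)),
               resid_mult = rep(dsub$resid_mult, length(asub)),
               stringsAsFactors = FALSE)
  }))
  recs$device_id <- dev_of[recs$animal_id]
  gidx <- match(recs$animal_id, ped$animal)
  pidx <- match(recs$animal_id, phen$animal_id)
  s <- recs$challenge
  mu <- grp_eff[paste(recs$year, recs$device_id, sep = ":")] +
    config$b1 * recs$test_day +
    a[gidx, 1] + a[gidx, 2] * s + pe[pidx, 1] + pe[pidx, 2] * s
  e <- stats::rnorm(nrow(recs), 0,
                    sqrt(config$sigma2_e) * recs$resid_mult)
  recs$dfi <- as.numeric(mu + e)
  neg <- recs$dfi <= 0
  if (any(neg)) {
    message(sum(neg), " non-positive simulated intake(s) dropped")
    recs <- recs[!neg, , drop = FALSE]
  }
  rownames(recs) <- NULL
  truth <- list(breeding_values = a, pe = pe, inbreeding = f,
                group_effects = grp_eff, days = days, config = config)
  list(records = recs, truth = truth)
}

#' Simulate a complete dataset
#'
#' Runs [simulate_pedigree()], [simulate_days()] and
#' [simulate_phenotypes()] under one configuration; all randomness
#' flows from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `ped`, `phenotyped`, `days`, `records`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  pedsim <- simulate_pedigree(config)
  days <- simulate_days(config)
  sim <- simulate_phenotypes(pedsim, days, config)
  list(ped = pedsim$ped, phenotyped = pedsim$phenotyped, days = days,
       records = sim$records, truth = sim$truth)
}

#' Split daily records into feeder visits
#'
#' For visit-level testing: each daily intake is split into a
#' Poisson-distributed number of visits (at least one) with a symmetric
#' Dirichlet split of the intake, plus lognormal visit durations.
#'
#' @param records Daily records with `dfi`.
#' @param config A [sim_config()] (mean visit count, seed).
#' @return Data frame of visits (`animal_id`, `year`, `test_day`,
#'   `device_id`, `intake`, `duration`).
#' @export
simulate_visits <- function(records, config = sim_config()) {
  set.seed(config$seed + 3L)
  nv <- pmax(1L, stats::rpois(nrow(records), config$mean_visits))
  idx <- rep(seq_len(nrow(records)), nv)
  g <- stats::rgamma(length(idx), shape = 1)
  tot <- tapply(g, idx, sum)
  frac <- g / tot[as.character(idx)]
  data.frame(animal_id = records$animal_id[idx],
             year = records$year[idx],
             test_day = records$test_day[idx],
             device_id = records$device_id[idx],
             intake = records$dfi[idx] * frac,
             duration = stats::rlnorm(length(idx), log(60), 0.5),
             stringsAsFactors = FALSE)
}

#' A reduced-scale simulation configuration
#'
#' Convenience wrapper used for estimation studies: fewer, smaller
#' cohorts and a shallower pedigree, with the same true variance
#' components as [sim_config()].
#'
#' @param n_animals Total phenotyped animals (split over `n_years`).
#' @param n_days Test days per year.
#' @param n_years Number of cohorts.
#' @param seed Seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_small <- function(n_animals = 300L, n_days = 40L, n_years = 2L,
                             seed = 1L, ...) {
  per <- ceiling(n_animals / n_years)
  sizes <- rep(per, n_years)
  sizes[n_years] <- n_animals - per * (n_years - 1L)
  sim_config(n_years = n_years, cohort_sizes = sizes,
             days_per_year = n_days, devices_per_year = 3L,
             n_founders = 60L, gen_sizes = 80L, seed = seed, ...)
}
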