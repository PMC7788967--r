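# Shared fixtures, built in code and memoized for the duration of the run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# full default-scale simulated dataset (8 cohorts, 438 day cells)
full_sim <- function() memo("full_sim", suppressMessages(
  simulate_dataset(sim_config(seed = 1))))

# reduced-scale dataset plus the two-stage covariate estimate
small_pipeline <- function() memo("small_pipeline", suppressMessages({
  cfg <- sim_config_small(n_animals = 150, n_days = 30, n_years = 2,
                          seed = 21)
  sim <- simulate_dataset(cfg)
  dv <- suppressWarnings(compute_day_variability(sim$records, 10))
  m <- fit_mixture(dv$log_cv, 2, init_seed = 3)
  dv <- challenge_probabilities(m, dv)
  rec <- merge(sim$records, dv[, c("year", "test_day", "p")],
               by = c("year", "test_day"))
  list(sim = sim, dayvar = dv, mixture = m, records = rec,
       ainv = a_inverse(sim$ped))
}))

# reduced-scale REML fit of the reaction-norm model (two-class residual)
small_fit <- function() memo("small_fit", {
  sp <- small_pipeline()
  suppressWarnings(reml_fit(rnam_spec(residual = 0.5), sp$records, sp$ainv,
                            em_iters = 12, max_ai_iters = 40))
})

# unrelated-founder pedigree of n animals
founder_ped <- function(n, prefix = "A") {
  sort_pedigree(data.frame(animal = sprintf("%s%03d", prefix, seq_len(n)),
                           sire = "0", dam = "0"))
}

# three-generation toy pedigree: founders 1,2; full sibs 3,4; 5 = 3 x 4
toy_ped <- function() {
  sort_pedigree(data.frame(animal = c(1, 2, 3, 4, 5),
                           sire = c(0, 0, 1, 1, 3),
                           dam = c(0, 0, 2, 2, 4)))
}

# random valid pedigree with overlapping generations
random_ped <- function(n, seed) {
  set.seed(seed)
  sire <- dam <- integer(n)
  for (i in 3:n) {
    if (stats::runif(1) < 0.7) {
      par <- sample(seq_len(i - 1L), 2L)
      sire[i] <- par[1]; dam[i] <- par[2]
    } else if (stats::runif(1) < 0.5) {
      sire[i] <- sample(seq_len(i - 1L), 1L)
    }
  }
  sort_pedigree(data.frame(animal = seq_len(n), sire = sire, dam = dam))
}

# balanced records on unrelated animals for dense-oracle checks
unrelated_records <- function(n_an, n_day, seed, p_vals = NULL) {
  set.seed(seed)
  ped <- founder_ped(n_an)
  days <- data.frame(test_day = seq_len(n_day),
                     p = if (is.null(p_vals))
                       stats::rbinom(n_day, 1, 0.25) else p_vals)
  rec <- expand.grid(animal_id = ped$animal, test_day = days$test_day,
                     stringsAsFactors = FALSE)
  rec$year <- "Y1"
  rec$device_id <- "D1"
  rec$p <- days$p[rec$test_day]
  G0 <- matrix(c(0.03, -0.012, -0.012, 0.05), 2)
  a <- matrix(stats::rnorm(2 * n_an), n_an, 2) %*% chol(G0)
  idx <- match(rec$animal_id, ped$animal)
  rec$dfi <- 1.5 + 0.01 * rec$test_day + a[idx, 1] + a[idx, 2] * rec$p +
    stats::rnorm(nrow(rec), 0, sqrt(0.12))
  list(ped = ped, ainv = a_inverse(ped), records = rec, days = days,
       G0 = G0, a = a)
}

# variance components at the scale of a daily-feed-intake analysis
dfi_vc <- function() {
  variance_components(G0 = matrix(c(0.016, -0.011, -0.011, 0.038), 2),
                      P0 = matrix(c(0.034, -0.031, -0.031, 0.104), 2),
                      sigma2_e = 0.120)
}
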