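#' Reaction-norm animal model specification
#'
#' Describes the linear (reaction-norm) animal model for a repeatedly
#' recorded trait y observed on animal k on day j in contemporary group
#' (year x feeder device) i:
#'
#'   y_ijk = yearACF_i + b1 * day_j + a0_k + a1_k * p_j
#'           + pe0_k + pe1_k * p_j + e_ijk
#'
#' where p_j in `[0, 1]` is the day's environmental-challenge
#' probability.  (a0, a1) are genetic level and environmental-sensitivity
#' effects with covariance `G0 (x) A` (A the pedigree relationship
#' matrix); (pe0, pe1) are permanent-environmental effects with
#' covariance `P0 (x) I`.  `include_slope = FALSE` drops the two slope
#' terms, giving the reduced animal model (AM).  The residual is either
#' homogeneous or split into a "normal" and a "high" class at a
#' threshold on p_j.
#'
#' @param include_slope Fit the reaction-norm slope terms (default
#'   TRUE); FALSE gives the reduced animal model.
#' @param include_pe Fit permanent-environmental effects (default TRUE).
#'   Disabling is only sensible for oracle checks or single records per
#'   animal.
#' @param residual `"homogeneous"`, or a number in (0, 1): the p
#'   threshold above which records belong to the high-variance residual
#'   class.
#' @param day_covariate Include the growth regression on day-on-test
#'   (default TRUE; the covariate is centred internally for
#'   conditioning and reported on the raw scale).
#' @return An object of class `rnam_spec`.
#' @export
rnam_spec <- function(include_slope = TRUE, include_pe = TRUE,
                      residual = "homogeneous", day_covariate = TRUE) {
  if (is.numeric(residual)) {
    if (residual <= 0 || residual >= 1)
      stop("residual threshold must be in (0, 1)")
    res <- list(type = "threshold", t = residual)
  } else if (identical(residual, "homogeneous")) {
    res <- list(type = "homogeneous")
  } else stop("residual must be \"homogeneous\" or a threshold in (0,1)")
  structure(list(include_slope = isTRUE(include_slope),
                 include_pe = isTRUE(include_pe), residual = res,
                 day_covariate = isTRUE(day_covariate)),
            class = "rnam_spec")
}

#' Variance components of the reaction-norm animal model
#'
#' @param G0 Genetic (co)variance matrix for (level, slope), kg^2; a
#'   scalar for the reduced model.
#' @param P0 Permanent-environment (co)variance matrix, same layout, or
#'   NULL when permanent environment is excluded.
#' @param sigma2_e Residual variance(s), kg^2: a single value, or a
#'   named vector `c(normal = , high = )` for the two-class residual.
#' @return An object of class `rnam_vc`.
#' @export
variance_components <- function(G0, P0 = NULL, sigma2_e) {
  G0 <- as.matrix(G0)
  if (!isSymmetric(unname(G0), tol = 1e-8)) stop("G0 must be symmetric")
  if (any(eigen(G0, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    stop("G0 must be positive semi-definite")
  if (!is.null(P0)) {
    P0 <- as.matrix(P0)
    if (!isSymmetric(unname(P0), tol = 1e-8)) stop("P0 must be symmetric")
    if (any(eigen(P0, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
      stop("P0 must be positive semi-definite")
  }
  if (any(sigma2_e <= 0)) stop("residual variances must be > 0")
  structure(list(G0 = G0, P0 = P0, sigma2_e = sigma2_e), class = "rnam_vc")
}

#' @export
print.rnam_vc <- function(x, ...) {
  cat("G0 (genetic):\n"); print(x$G0)
  if (!is.null(x$P0)) { cat("P0 (permanent environment):\n"); print(x$P0) }
  cat("residual:", paste(format(x$sigma2_e, digits = 6), collapse = " / "),
      "\n")
  invisible(x)
}

# ---- internal model frame ------------------------------------------------

# Assemble design matrices and bookkeeping shared by all fitting routines.
rnam_model_data <- function(spec, data, a_inv) {
  need <- c("animal_id", "test_day", "dfi")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L)
    stop("data is missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(data)
  if (n == 0L) stop("no data rows")
  y <- as.numeric(data$dfi)
  if (any(!is.finite(y))) stop("non-finite phenotypes")

  needs_p <- spec$include_slope || spec$residual$type == "threshold"
  if (is.null(data$p)) {
    if (needs_p) stop("data must contain a challenge probability column p")
    p <- rep(0, n)
  } else {
    p <- as.numeric(data$p)
    if (any(!is.finite(p) | p < -1e-9 | p > 1 + 1e-9))
      stop("challenge probabilities must lie in [0, 1]")
    p <- pmin(pmax(p, 0), 1)
  }

  # fixed effects: yearACF contemporary group + regression on day-on-test
  grp <- if (!is.null(data$device_id) && !is.null(data$year)) {
    interaction(data$year, data$device_id, drop = TRUE, lex.order = TRUE)
  } else if (!is.null(data$year)) {
    factor(data$year)
  } else factor(rep("all", n))
  day <- as.numeric(data$test_day)
  day_mean <- mean(day)
  if (nlevels(grp) > 1L) {
    X <- Matrix::sparse.model.matrix(~ 0 + grp)
  } else {
    X <- Matrix::Matrix(1, n, 1, sparse = TRUE)
  }
  colnames(X) <- paste0("yearACF:", levels(grp))
  has_day <- spec$day_covariate && stats::sd(day) > 0
  if (has_day) {
    X <- cbind(X, Matrix::Matrix(day - day_mean, ncol = 1,
                                 dimnames = list(NULL, "b1_day")))
  }
  Xd <- as.matrix(Matrix::crossprod(X))
  qrX <- qr(Xd)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("confounded fixed-effect level(s): ", paste(bad, collapse = ", "))
  }

  animals <- a_inv$animals
  ai <- match(as.character(data$animal_id), animals)
  if (anyNA(ai))
    stop("animal(s) in data absent from pedigree: ",
         paste(utils::head(unique(data$animal_id[is.na(ai)]), 5L),
               collapse = ", "))
  ka <- if (spec$include_slope) 2L else 1L
  n_ped <- length(animals)
  rows <- rep(seq_len(n), each = ka)
  cols <- as.vector(vapply(ai, function(i) (i - 1L) * ka + seq_len(ka),
                           integer(ka)))
  vals <- if (ka == 2L) as.vector(rbind(1, p)) else rep(1, n)
  Za <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                             dims = c(n, ka * n_ped))

  if (spec$include_pe) {
    ph_idx <- sort(unique(ai))          # phenotyped animals, pedigree order
    pi_map <- match(ai, ph_idx)
    n_ph <- length(ph_idx)
    colsp <- as.vector(vapply(pi_map, function(i) (i - 1L) * ka + seq_len(ka),
                              integer(ka)))
    Zp <- Matrix::sparseMatrix(i = rows, j = colsp, x = vals,
                               dims = c(n, ka * n_ph))
  } else {
    ph_idx <- sort(unique(ai)); n_ph <- length(ph_idx); Zp <- NULL
  }

  cls <- rep(1L, n)
  if (spec$residual$type == "threshold") {
    cls[p > spec$residual$t] <- 2L
    if (!any(cls == 1L)) stop("residual class \"normal\" has zero rows")
    if (!any(cls == 2L)) stop("residual class \"high\" has zero rows")
  }
  n_cls <- if (spec$residual$type == "threshold") 2L else 1L

  W <- if (is.null(Zp)) cbind(X, Za) else cbind(X, Za, Zp)
  WtW <- vector("list", n_cls)
  Wty <- vector("list", n_cls)
  for (c in seq_len(n_cls)) {
    sel <- cls == c
    Wc <- W[sel, , drop = FALSE]
    WtW[[c]] <- Matrix::crossprod(Wc)
    Wty[[c]] <- as.numeric(Matrix::crossprod(Wc, y[sel]))
  }

  list(spec = spec, y = y, p = p, n = n, W = W, X = X, Za = Za, Zp = Zp,
       p_fix = ncol(X), ka = ka, n_ped = n_ped, n_ph = n_ph,
       ph_idx = ph_idx, ai = ai, cls = cls, n_cls = n_cls,
       n_per_cls = tabulate(cls, n_cls), WtW = WtW, Wty = Wty,
       day_mean = day_mean, has_day = has_day,
       fix_names = colnames(X), animals = animals,
       Ainv = a_inv$Ainv, log_det_A = a_inv$log_det_A,
       Ainv_trip = sparse_triplets(a_inv$Ainv))
}

sparse_triplets <- function(M) {
  T <- as(as(M, "generalMatrix"), "TsparseMatrix")
  list(i = T@i + 1L, j = T@j + 1L, x = T@x)
}

vc_check_dims <- function(md, vc) {
  if (nrow(vc$G0) != md$ka) stop("G0 dimension does not match the model")
  if (md$spec$include_pe && (is.null(vc$P0) || nrow(vc$P0) != md$ka))
    stop("P0 dimension does not match the model")
  if (length(vc$sigma2_e) != md$n_cls)
    stop("number of residual variances does not match the residual structure")
}

# G-side inverse prior block (genetic + pe) for the MME
ginv_block <- function(md, vc) {
  G0inv <- solve(vc$G0)
  Ga <- Matrix::kronecker(md$Ainv, G0inv)
  if (md$spec$include_pe) {
    P0inv <- solve(vc$P0)
    Gp <- Matrix::kronecker(Matrix::Diagonal(md$n_ph), P0inv)
    Matrix::bdiag(Matrix::Matrix(0, md$p_fix, md$p_fix, sparse = TRUE), Ga, Gp)
  } else {
    Matrix::bdiag(Matrix::Matrix(0, md$p_fix, md$p_fix, sparse = TRUE), Ga)
  }
}

mme_C_rhs <- function(md, vc) {
  C <- ginv_block(md, vc)
  rhs <- numeric(ncol(md$W))
  for (c in seq_len(md$n_cls)) {
    C <- C + md$WtW[[c]] / vc$sigma2_e[c]
    rhs <- rhs + md$Wty[[c]] / vc$sigma2_e[c]
  }
  list(C = Matrix::forceSymmetric(C), rhs = rhs)
}

#' Build the mixed-model equations
#'
#' Assembles Henderson's mixed-model equations for a reaction-norm (or
#' reduced) animal model at given variance components: coefficient
#' matrix `C = W' R^-1 W + G*` and right-hand side `W' R^-1 y`, with
#' the genetic block structured as `G0^-1 (x) A^-1` and the
#' permanent-environment block as `P0^-1` per animal.
#'
#' @param spec An [rnam_spec()].
#' @param data Daily records joined to day probabilities: columns
#'   `animal_id`, `year`, `test_day`, `device_id` (optional), `dfi`,
#'   `p`.
#' @param a_inv An [a_inverse()] object covering all animals in `data`.
#' @param vc An [variance_components()] object.
#' @return List of class `rnam_mme` with `C` (sparse), `rhs`, and the
#'   internal model frame `md`.
#' @export
build_mme <- function(spec, data, a_inv, vc) {
  md <- rnam_model_data(spec, data, a_inv)
  vc_check_dims(md, vc)
  cr <- mme_C_rhs(md, vc)
  structure(list(C = cr$C, rhs = cr$rhs, md = md, vc = vc),
            class = "rnam_mme")
}

#' Solve mixed-model equations
#'
#' Sparse-Cholesky solve of an [build_mme()] system; returns BLUE/BLUP
#' solutions split by effect.
#'
#' @param mme An `rnam_mme` object.
#' @return List with `fixed` (named vector, day regression reported on
#'   the raw day scale), `genetic` (matrix n_ped x k), `pe` (matrix
#'   n_ph x k or NULL) and the raw solution vector `solution`.
#' @export
solve_mme <- function(mme) {
  md <- mme$md
  Ch <- Matrix::Cholesky(mme$C, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(Ch, mme$rhs))
  split_solutions(md, sol)
}

split_solutions <- function(md, sol) {
  fixed <- sol[seq_len(md$p_fix)]
  names(fixed) <- md$fix_names
  if (md$has_day) {
    b1 <- fixed[["b1_day"]]
    lev <- grepl("^yearACF:", names(fixed))
    fixed[lev] <- fixed[lev] - b1 * md$day_mean  # undo internal centering
  }
  ua <- matrix(sol[md$p_fix + seq_len(md$ka * md$n_ped)],
               ncol = md$ka, byrow = TRUE,
               dimnames = list(md$animals,
                               c("a0", "a1")[seq_len(md$ka)]))
  up <- NULL
  if (md$spec$include_pe) {
    up <- matrix(sol[md$p_fix + md$ka * md$n_ped +
                       seq_len(md$ka * md$n_ph)],
                 ncol = md$ka, byrow = TRUE,
                 dimnames = list(md$animals[md$ph_idx],
                                 c("pe0", "pe1")[seq_len(md$ka)]))
  }
  list(fixed = fixed, genetic = ua, pe = up, solution = sol)
}

# ---- REML ----------------------------------------------------------------

# Per-iteration state: solutions, residuals, -2logL, inverse-based traces.
reml_state <- function(md, vc, want_traces = TRUE) {
  cr <- mme_C_rhs(md, vc)
  Ch <- Matrix::Cholesky(cr$C, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(Ch, cr$rhs))
  w <- 1 / vc$sigma2_e[md$cls]
  e_hat <- md$y - as.numeric(md$W %*% sol)
  yPy <- sum(w * md$y^2) - sum(sol * cr$rhs)
  log_det_C <- 2 * as.numeric(
    Matrix::determinant(Matrix::expand(Ch)$L, logarithm = TRUE)$modulus)
  # -2 restricted log-likelihood
  m2ll <- (md$n - md$p_fix) * log(2 * pi) +
    sum(log(vc$sigma2_e[md$cls])) +
    md$ka * md$log_det_A + md$n_ped * determinant(vc$G0)$modulus +
    (if (md$spec$include_pe)
       md$n_ph * determinant(vc$P0)$modulus else 0) +
    log_det_C + yPy
  st <- list(sol = sol, rhs = cr$rhs, Ch = Ch, e_hat = e_hat, w = w,
             yPy = yPy, m2ll = as.numeric(m2ll))
  if (want_traces) {
    m <- ncol(md$W)
    Cinv <- as.matrix(Matrix::solve(Ch, diag(m)))
    ka <- md$ka
    idx_a <- function(i, r) md$p_fix + (i - 1L) * ka + r
    Ta <- matrix(0, ka, ka)
    tr <- md$Ainv_trip
    for (r in seq_len(ka)) for (s in seq_len(ka)) {
      # tr(Ainv %*% Cinv[genetic r rows, genetic s cols])
      Ta[r, s] <- sum(tr$x * Cinv[cbind(idx_a(tr$j, r), idx_a(tr$i, s))])
    }
    Tp <- NULL
    if (md$spec$include_pe) {
      idx_p <- function(i, r) md$p_fix + ka * md$n_ped + (i - 1L) * ka + r
      Tp <- matrix(0, ka, ka)
      iseq <- seq_len(md$n_ph)
      for (r in seq_len(ka)) for (s in seq_len(ka))
        Tp[r, s] <- sum(Cinv[cbind(idx_p(iseq, r), idx_p(iseq, s))])
    }
    tr_res <- numeric(md$n_cls)
    for (c in seq_len(md$n_cls)) {
      tw <- sparse_triplets(md$WtW[[c]])
      tr_res[c] <- sum(tw$x * Cinv[cbind(tw$j, tw$i)])
    }
    sp <- split_solutions(md, sol)
    Qa <- t(sp$genetic) %*% as.matrix(md$Ainv %*% sp$genetic)
    Qp <- if (md$spec$include_pe) crossprod(sp$pe) else NULL
    st <- c(st, list(Ta = (Ta + t(Ta)) / 2, Tp = Tp, tr_res = tr_res,
                     Qa = (Qa + t(Qa)) / 2, Qp = Qp, sp = sp))
  }
  st
}

em_update <- function(md, vc, st) {
  G0 <- (st$Qa + st$Ta) / md$n_ped
  P0 <- if (md$spec$include_pe) (st$Qp + st$Tp) / md$n_ph else NULL
  s2 <- numeric(md$n_cls)
  for (c in seq_len(md$n_cls)) {
    sel <- md$cls == c
    s2[c] <- (sum(st$e_hat[sel]^2) + st$tr_res[c]) / md$n_per_cls[c]
  }
  names(s2) <- names(vc$sigma2_e)
  variance_components(G0 = G0, P0 = P0, sigma2_e = s2)
}

# parameter vector <-> variance components
par_table <- function(md) {
  ka <- md$ka
  tab <- data.frame(block = character(0), r = integer(0), s = integer(0))
  for (r in seq_len(ka)) for (s in r:ka)
    tab <- rbind(tab, data.frame(block = "g", r = r, s = s))
  if (md$spec$include_pe)
    for (r in seq_len(ka)) for (s in r:ka)
      tab <- rbind(tab, data.frame(block = "p", r = r, s = s))
  for (c in seq_len(md$n_cls))
    tab <- rbind(tab, data.frame(block = "e", r = c, s = c))
  nm <- function(b, r, s) {
    if (b == "g") paste0("g", r, s)
    else if (b == "p") paste0("pe", r, s)
    else if (md$n_cls == 1L) "s2e" else paste0("s2e_", c("normal", "high")[r])
  }
  tab$name <- mapply(nm, tab$block, tab$r, tab$s)
  tab
}

theta_get <- function(vc, tab) {
  vapply(seq_len(nrow(tab)), function(i) {
    b <- tab$block[i]
    if (b == "g") vc$G0[tab$r[i], tab$s[i]]
    else if (b == "p") vc$P0[tab$r[i], tab$s[i]]
    else vc$sigma2_e[tab$r[i]]
  }, numeric(1))
}

theta_set <- function(vc, tab, theta) {
  for (i in seq_len(nrow(tab))) {
    b <- tab$block[i]
    if (b == "g") {
      vc$G0[tab$r[i], tab$s[i]] <- vc$G0[tab$s[i], tab$r[i]] <- theta[i]
    } else if (b == "p") {
      vc$P0[tab$r[i], tab$s[i]] <- vc$P0[tab$s[i], tab$r[i]] <- theta[i]
    } else vc$sigma2_e[tab$r[i]] <- theta[i]
  }
  vc
}

theta_valid <- function(vc, md) {
  ok <- all(vc$sigma2_e > 0) &&
    all(eigen(vc$G0, symmetric = TRUE, only.values = TRUE)$values > 0)
  if (ok && md$spec$include_pe)
    ok <- all(eigen(vc$P0, symmetric = TRUE, only.values = TRUE)$values > 0)
  ok
}

# symmetric single-entry derivative matrix
e_mat <- function(k, r, s) {
  E <- matrix(0, k, k)
  E[r, s] <- E[s, r] <- 1
  E
}

# average-information matrix and score vector at the current state
ai_score <- function(md, vc, st, tab) {
  npar <- nrow(tab)
  G0inv <- solve(vc$G0)
  P0inv <- if (md$spec$include_pe) solve(vc$P0) else NULL
  U <- st$sp$genetic
  Pm <- st$sp$pe
  Fm <- matrix(0, md$n, npar)
  score <- numeric(npar)
  for (i in seq_len(npar)) {
    b <- tab$block[i]; r <- tab$r[i]; s <- tab$s[i]
    if (b == "g") {
      E <- e_mat(md$ka, r, s)
      M <- G0inv %*% E %*% G0inv
      Fm[, i] <- as.numeric(md$Za %*% as.vector(t(U %*% t(E %*% G0inv))))
      quad <- sum(M * st$Qa)                      # tr(M Qa), both symmetric
      trd <- md$n_ped * sum(E * G0inv) - sum(M * st$Ta)
      score[i] <- 0.5 * (quad - trd)
    } else if (b == "p") {
      E <- e_mat(md$ka, r, s)
      M <- P0inv %*% E %*% P0inv
      Fm[, i] <- as.numeric(md$Zp %*% as.vector(t(Pm %*% t(E %*% P0inv))))
      quad <- sum(M * st$Qp)
      trd <- md$n_ph * sum(E * P0inv) - sum(M * st$Tp)
      score[i] <- 0.5 * (quad - trd)
    } else {
      c <- r
      sel <- md$cls == c
      f <- numeric(md$n)
      f[sel] <- st$e_hat[sel] / vc$sigma2_e[c]
      Fm[, i] <- f
      quad <- sum((st$e_hat[sel] / vc$sigma2_e[c])^2)
      trd <- md$n_per_cls[c] / vc$sigma2_e[c] -
        st$tr_res[c] / vc$sigma2_e[c]^2
      score[i] <- 0.5 * (quad - trd)
    }
  }
  # P f = R^-1 (f - W C^-1 W' R^-1 f)
  PF <- matrix(0, md$n, npar)
  for (i in seq_len(npar)) {
    f <- Fm[, i]
    t1 <- as.numeric(Matrix::crossprod(md$W, st$w * f))
    t2 <- as.numeric(Matrix::solve(st$Ch, t1))
    PF[, i] <- st$w * (f - as.numeric(md$W %*% t2))
  }
  AI <- 0.5 * crossprod(Fm, PF)
  AI <- (AI + t(AI)) / 2
  dimnames(AI) <- list(tab$name, tab$name)
  list(AI = AI, score = score)
}

#' Fit the reaction-norm animal model by REML
#'
#' Variance components are estimated by restricted maximum likelihood:
#' `em_iters` expectation-maximization iterations (slow but monotone in
#' the restricted likelihood and robust to poor starting values),
#' followed by average-information (AI) Newton updates until the
#' relative parameter change falls below `tol`.  An AI step that leaves
#' the parameter space is step-halved and, failing that, replaced by an
#' EM step for that iteration.
#'
#' @inheritParams build_mme
#' @param start Starting [variance_components()]; by default the
#'   residual starts at half the phenotypic variance, intercept
#'   variances at a quarter of it, slope variances at 0.01 kg^2 and
#'   covariances at zero.
#' @param em_iters Initial EM iterations (default 50).
#' @param tol Convergence tolerance on the relative parameter change
#'   (default 1e-8).
#' @param max_ai_iters Maximum AI iterations (default 100); exceeding
#'   it returns the fit flagged `converged = FALSE`.
#' @param verbose Print iteration progress.
#' @return An object of class `rnam_fit`: list with `vc`, `fixed`,
#'   `genetic` (per-animal a0/a1), `pe`, `minus_two_loglik`,
#'   `ai_matrix`, `converged`, `n_iter`, `trace` (per-iteration -2logL)
#'   and the model `spec`.
#' @export
reml_fit <- function(spec, data, a_inv, start = NULL, em_iters = 50L,
                     tol = 1e-8, max_ai_iters = 100L, verbose = FALSE) {
  md <- rnam_model_data(spec, data, a_inv)
  vc <- if (is.null(start)) default_start(md) else start
  vc_check_dims(md, vc)
  tab <- par_table(md)
  trace <- numeric(0)
  m2ll_prev <- Inf
  st <- NULL
  for (it in seq_len(em_iters)) {
    st <- reml_state(md, vc)
    trace <- c(trace, st$m2ll)
    # EM-REML is monotone; allow only tiny numerical slack
    if (st$m2ll > m2ll_prev + 1e-6 * (abs(m2ll_prev) + 1))
      warning("EM-REML -2logL increased at iteration ", it)
    m2ll_prev <- st$m2ll
    vc <- em_update(md, vc, st)
    if (verbose) message(sprintf("EM %3d  -2logL %.6f", it, st$m2ll))
  }
  converged <- FALSE
  n_ai <- 0L
  for (it in seq_len(max_ai_iters)) {
    n_ai <- it
    st <- reml_state(md, vc)
    trace <- c(trace, st$m2ll)
    as_ <- ai_score(md, vc, st, tab)
    theta <- theta_get(vc, tab)
    delta <- tryCatch(solve(as_$AI, as_$score), error = function(e) NULL)
    vc_new <- NULL
    if (!is.null(delta)) {
      step <- 1
      for (h in 1:10) {
        cand <- theta_set(vc, tab, theta + step * delta)
        cand <- bend_vc(cand, md)
        # accept only steps that do not worsen the restricted likelihood
        if (theta_valid(cand, md)) {
          m2 <- reml_state(md, cand, want_traces = FALSE)$m2ll
          if (m2 <= st$m2ll + 1e-8 * (abs(st$m2ll) + 1)) {
            vc_new <- cand
            break
          }
        }
        step <- step / 2
      }
    }
    if (is.null(vc_new)) vc_new <- em_update(md, vc, st)  # fallback
    rel <- max(abs(theta_get(vc_new, tab) - theta) / (abs(theta) + 1e-10))
    vc <- vc_new
    if (verbose) message(sprintf("AI %3d  -2logL %.6f  rel %.3e",
                                 it, st$m2ll, rel))
    if (rel < tol) { converged <- TRUE; break }
  }
  st <- reml_state(md, vc)
  as_ <- ai_score(md, vc, st, tab)
  out <- list(vc = vc, fixed = st$sp$fixed, genetic = st$sp$genetic,
              pe = st$sp$pe, minus_two_loglik = st$m2ll,
              ai_matrix = as_$AI, converged = converged,
              n_iter = em_iters + n_ai, trace = c(trace, st$m2ll),
              spec = spec, n_records = md$n, par_names = tab$name)
  class(out) <- "rnam_fit"
  out
}

default_start <- function(md) {
  vy <- stats::var(md$y)
  G0 <- diag(c(vy / 4, 0.01)[seq_len(md$ka)], md$ka)
  P0 <- if (md$spec$include_pe) G0 else NULL
  s2 <- rep(vy / 2, md$n_cls)
  if (md$n_cls == 2L) names(s2) <- c("normal", "high")
  variance_components(G0 = G0, P0 = P0, sigma2_e = s2)
}

# eigenvalue bending: lift slightly-negative eigenvalues to keep a
# nearly-PSD update inside the cone
bend_vc <- function(vc, md) {
  vc$G0 <- bend_psd(vc$G0)
  if (md$spec$include_pe) vc$P0 <- bend_psd(vc$P0)
  vc
}

bend_psd <- function(M) {
  ev <- eigen(M, symmetric = TRUE)
  floor_ <- 1e-8 * sum(abs(diag(M)))
  if (all(ev$values >= floor_)) return(M)
  if (any(ev$values < -0.1 * sum(abs(diag(M))))) return(M)  # truly invalid
  v <- pmax(ev$values, floor_)
  ev$vectors %*% (v * t(ev$vectors))
}

#' @export
print.rnam_fit <- function(x, ...) {
  cat("Reaction-norm animal model",
      if (x$spec$include_slope) "(RNAM)" else "(reduced AM)",
      if (x$converged) "- converged" else "- NOT converged",
      "in", x$n_iter, "iterations\n")
  print(x$vc)
  cat("-2 logL:", format(x$minus_two_loglik, digits = 10), "\n")
  invisible(x)
}

#' Level-slope genetic correlation and its standard error
#'
#' Correlation between the genetic level (a0) and slope (a1) with an
#' asymptotic standard error obtained by the delta method, using the
#' inverse average-information matrix of the REML fit as the sampling
#' covariance of the variance components (Houle-Meyer style).
#'
#' @param fit An `rnam_fit` from [reml_fit()] with slope terms.
#' @return List with `correlation` and `se`.
#' @export
genetic_correlation_se <- function(fit) {
  if (!fit$spec$include_slope) stop("fit has no slope term")
  g11 <- fit$vc$G0[1, 1]; g12 <- fit$vc$G0[1, 2]; g22 <- fit$vc$G0[2, 2]
  r <- g12 / sqrt(g11 * g22)
  V <- tryCatch(solve(fit$ai_matrix), error = function(e)
    stop("AI matrix is singular"))
  idx <- match(c("g11", "g12", "g22"), fit$par_names)
  grad <- c(-g12 / (2 * g11^1.5 * sqrt(g22)),
            1 / sqrt(g11 * g22),
            -g12 / (2 * g22^1.5 * sqrt(g11)))
  se <- sqrt(drop(t(grad) %*% V[idx, idx] %*% grad))
  list(correlation = r, se = se)
}

#' Fit the RNAM with a two-class (heterogeneous) residual
#'
#' Convenience wrapper: records with day probability p above the
#' threshold form the "high" residual class, all machinery otherwise
#' unchanged.
#'
#' @inheritParams reml_fit
#' @param threshold p threshold in (0, 1).
#' @param include_slope,include_pe Model structure flags.
#' @param ... Passed to [reml_fit()].
#' @return An `rnam_fit`.
#' @export
fit_heterogeneous_residual <- function(data, a_inv, threshold,
                                       include_slope = TRUE,
                                       include_pe = TRUE, ...) {
  spec <- rnam_spec(include_slope = include_slope, include_pe = include_pe,
                    residual = threshold)
  reml_fit(spec, data, a_inv, ...)
}

# ---- Gibbs ---------------------------------------------------------------

#' Fit the reaction-norm animal model by Gibbs sampling
#'
#' Markov-chain Monte Carlo over the joint posterior: all location
#' effects are drawn as one block from their multivariate-normal full
#' conditional (via the sparse Cholesky factor of the mixed-model
#' equations), G0 and P0 from inverse-Wishart full conditionals, and
#' the residual variance(s) from scaled inverse-chi-square full
#' conditionals.  Priors are weakly informative: flat for fixed
#' effects and residuals (nu = -2), inverse-Wishart with scale 1e-4 * I
#' and k + 1 degrees of freedom for G0 and P0.
#'
#' @inheritParams reml_fit
#' @param n_iter Total chain length.
#' @param burn_in Discarded initial iterations.
#' @param thin Sampling interval; `(n_iter - burn_in) / thin` draws are
#'   retained.
#' @param seed RNG seed for the chain.
#' @return Object of class `rnam_gibbs`: `draws` (data frame of
#'   retained variance-parameter draws), `post_mean` (an `rnam_vc`),
#'   `post_sd`, `n_redraws`, and the chain `settings`.
#' @export
gibbs_fit <- function(spec, data, a_inv, n_iter = 20000L, burn_in = 2000L,
                      thin = 10L, seed = 1L, start = NULL) {
  if (n_iter <= 0L || burn_in < 0L || thin <= 0L || burn_in >= n_iter)
    stop("invalid chain settings")
  set.seed(seed)
  md <- rnam_model_data(spec, data, a_inv)
  vc <- if (is.null(start)) default_start(md) else start
  vc_check_dims(md, vc)
  tab <- par_table(md)
  m <- ncol(md$W)
  ka <- md$ka
  nu_g <- ka + 1
  S0 <- diag(1e-4, ka)
  n_keep <- floor((n_iter - burn_in) / thin)
  draws <- matrix(NA_real_, n_keep, nrow(tab),
                  dimnames = list(NULL, tab$name))
  kept <- 0L
  n_redraws <- 0L
  Ch <- NULL
  for (it in seq_len(n_iter)) {
    cr <- mme_C_rhs(md, vc)
    Ch <- if (is.null(Ch)) Matrix::Cholesky(cr$C, LDL = FALSE, perm = TRUE)
          else Matrix::update(Ch, cr$C)
    mu <- as.numeric(Matrix::solve(Ch, cr$rhs))
    z <- stats::rnorm(m)
    dev <- as.numeric(Matrix::solve(Ch, Matrix::solve(Ch, z, system = "Lt"),
                                    system = "Pt"))
    sol <- mu + dev
    sp <- split_solutions(md, sol)
    # genetic covariance: inverse-Wishart full conditional
    SG <- as.matrix(t(sp$genetic) %*% (md$Ainv %*% sp$genetic)) + S0
    SG <- (SG + t(SG)) / 2
    G0 <- draw_invwishart(md$n_ped + nu_g, SG)
    while (is.null(G0)) { n_redraws <- n_redraws + 1L
      G0 <- draw_invwishart(md$n_ped + nu_g, SG) }
    vc$G0 <- G0
    if (md$spec$include_pe) {
      SP <- crossprod(sp$pe) + S0
      P0 <- draw_invwishart(md$n_ph + nu_g, (SP + t(SP)) / 2)
      while (is.null(P0)) { n_redraws <- n_redraws + 1L
        P0 <- draw_invwishart(md$n_ph + nu_g, (SP + t(SP)) / 2) }
      vc$P0 <- P0
    }
    e <- md$y - as.numeric(md$W %*% sol)
    for (c in seq_len(md$n_cls)) {
      sse <- sum(e[md$cls == c]^2)
      df <- md$n_per_cls[c] - 2          # flat scaled-inv-chi2 (nu = -2)
      vc$sigma2_e[c] <- sse / stats::rchisq(1, df)
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L && kept < n_keep) {
      kept <- kept + 1L
      draws[kept, ] <- theta_get(vc, tab)
    }
  }
  pm <- colMeans(draws)
  post_mean <- theta_set(vc, tab, pm)
  structure(list(draws = as.data.frame(draws), post_mean = post_mean,
                 post_sd = apply(draws, 2, stats::sd),
                 n_redraws = n_redraws,
                 settings = list(n_iter = n_iter, burn_in = burn_in,
                                 thin = thin, seed = seed,
                                 n_retained = n_keep)),
            class = "rnam_gibbs")
}

draw_invwishart <- function(df, S) {
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) return(NULL)
  W <- stats::rWishart(1, df, (Sinv + t(Sinv)) / 2)[, , 1]
  out <- tryCatch(solve(W), error = function(e) NULL)
  if (is.null(out)) return(NULL)
  out <- (out + t(out)) / 2
  if (any(eigen(out, symmetric = TRUE, only.values = TRUE)$values <= 0))
    return(NULL)
  out
}

#' @export
print.rnam_gibbs <- function(x, ...) {
  cat("Gibbs chain:", x$settings$n_iter, "iterations, burn-in",
      x$settings$burn_in, ", thin", x$settings$thin, "->",
      x$settings$n_retained, "retained draws\n")
  cat("posterior means:\n")
  print(x$post_mean)
  invisible(x)
}

#' Serialize a REML fit
#'
#' Writes variance components, likelihood and settings to JSON, and the
#' per-animal solutions to CSV (`animal_id`, `a0`, `a1`, `pe0`, `pe1`).
#'
#' @param fit An `rnam_fit`.
#' @param json_path,solutions_path Output paths (either may be NULL).
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, json_path = NULL, solutions_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(model = if (fit$spec$include_slope) "rnam" else "am",
                residual = fit$spec$residual,
                G0 = fit$vc$G0, P0 = fit$vc$P0,
                sigma2_e = as.list(as.numeric(fit$vc$sigma2_e)),
                minus_two_loglik = fit$minus_two_loglik,
                converged = fit$converged, n_iter = fit$n_iter,
                n_records = fit$n_records,
                ai_matrix = fit$ai_matrix, par_names = fit$par_names,
                fixed = as.list(fit$fixed))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(solutions_path)) {
    sol <- data.frame(animal_id = rownames(fit$genetic),
                      a0 = fit$genetic[, 1],
                      a1 = if (fit$spec$include_slope) fit$genetic[, 2]
                           else NA_real_)
    if (!is.null(fit$pe)) {
      at <- match(sol$animal_id, rownames(fit$pe))
      sol$pe0 <- fit$pe[at, 1]
      sol$pe1 <- if (fit$spec$include_slope) fit$pe[at, 2] else NA_real_
    }
    utils::write.csv(sol, solutions_path, row.names = FALSE, quote = FALSE)
  }
  invisible(c(json_path, solutions_path))
}

#' @rdname write_fit
#' @param path Path of a fit JSON written by [write_fit()].
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$G0 <- matrix(unlist(obj$G0), nrow = sqrt(length(unlist(obj$G0))))
  if (!is.null(obj$P0))
    obj$P0 <- matrix(unlist(obj$P0), nrow = sqrt(length(unlist(obj$P0))))
  obj$sigma2_e <- unlist(obj$sigma2_e)
  obj
}
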