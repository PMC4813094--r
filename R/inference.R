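# Laplace (empirical Bayes) inference for the latent Gaussian binomial model,
# an MCMC verification oracle, gridded prevalence prediction and seasonal
# effect summaries.

#' Binomial log-likelihood with derivatives
#'
#' Grouped binomial log-likelihood with logit link, up to the additive
#' binomial-coefficient constant:
#' \code{sum(y * eta - n * log(1 + exp(eta)))}. The per-observation second
#' derivative is \code{-n p (1 - p)}; the returned \code{curvature} is its
#' magnitude \code{n p (1 - p)}.
#'
#' @param eta linear predictor vector.
#' @param successes,trials aligned count vectors, \code{0 <= successes <=
#'   trials}.
#' @return list with \code{value}, \code{gradient} (\code{y - n p}) and
#'   \code{curvature} (\code{n p (1 - p)}).
#' @export
binomial_loglik <- function(eta, successes, trials) {
  y <- as.numeric(successes); n <- as.numeric(trials)
  stopifnot(length(eta) == length(y), length(y) == length(n))
  if (any(y < 0) || any(y > n)) stop("need 0 <= successes <= trials")
  p <- stats::plogis(eta)
  list(value = sum(y * eta - n * log1pexp(eta)),
       gradient = y - n * p,
       curvature = n * p * (1 - p))
}

gaussian_loglik <- function(eta, y, sd) {
  r <- y - eta
  list(value = -0.5 * sum(r^2) / sd^2 - length(y) * log(sd) -
         0.5 * length(y) * log(2 * pi),
       gradient = r / sd^2,
       curvature = rep(1 / sd^2, length(y)))
}

#' Model configuration for the space-time fit
#'
#' Model 1 places the AR(2) dynamics on the 4 x n_years year--season axis
#' (seasonality absorbed into the temporal field); model 2 places AR(2) on
#' years only and adds an explicit period-4 seasonal component over the
#' year--season axis, from which per-season effect sizes are read off.
#'
#' @param mesh optional \code{wm_mesh}; built from the data extent when NULL.
#' @param covariates names of covariate columns to include as fixed effects
#'   (standardized internally).
#' @param model 1 or 2 (see Details).
#' @param nonstationary if TRUE, log tau / log kappa use the intercept + x +
#'   y basis; the default (FALSE) is the stationary intercept-only basis,
#'   keeping the hyperparameter dimension small.
#' @param family \code{"binomial"} (the analysis model) or \code{"gaussian"}
#'   (a conjugate test hook; the response is then column \code{y} of the
#'   observations, with known noise SD \code{gaussian_sd}).
#' @param gaussian_sd known noise SD for the Gaussian hook.
#' @param prior_fixed_prec prior precision of intercept and fixed effects.
#' @param max_edge_km,buffer_km mesh parameters used when \code{mesh} is NULL
#'   (defaults: extent/8 and extent/4).
#' @param predict_mc Monte-Carlo samples for prediction averaging (0 = delta
#'   method only).
#' @return list of class \code{wm_model_config}.
#' @export
model_config <- function(mesh = NULL, covariates = character(), model = 1,
                         nonstationary = FALSE, family = "binomial",
                         gaussian_sd = 1, prior_fixed_prec = 1e-4,
                         max_edge_km = NULL, buffer_km = NULL,
                         predict_mc = 0) {
  stopifnot(model %in% c(1, 2), family %in% c("binomial", "gaussian"))
  structure(list(mesh = mesh, covariates = covariates, model = model,
                 nonstationary = nonstationary, family = family,
                 gaussian_sd = gaussian_sd,
                 prior_fixed_prec = prior_fixed_prec,
                 max_edge_km = max_edge_km, buffer_km = buffer_km,
                 predict_mc = predict_mc),
            class = "wm_model_config")
}

# Build mesh, FEM, layout, sparse design matrix and response for a data set.
build_structures <- function(obs, config) {
  stopifnot(inherits(config, "wm_model_config"))
  obs$season <- canonical_season(obs$season)
  years <- min(obs$year):max(obs$year)
  n_years <- length(years)
  if (config$model == 2 && n_years < 2) {
    stop("model 2 needs at least 2 years of data")
  }
  si <- match(obs$season, WM_SEASONS)
  ys_idx <- 4L * (obs$year - years[1]) + si      # 1 .. 4 n_years

  mesh <- config$mesh
  if (is.null(mesh)) {
    ext <- max(diff(range(obs$x_km)), diff(range(obs$y_km)))
    mesh <- build_mesh(cbind(obs$x_km, obs$y_km),
                       max_edge_km = config$max_edge_km %||% (ext / 8),
                       buffer_km = config$buffer_km %||% (ext / 4))
  }
  fem <- fem_matrices(mesh)
  n_v <- nrow(mesh$vertices)
  A_sp <- projection_matrix(mesh, cbind(obs$x_km, obs$y_km))

  n_t <- if (config$model == 1) 4L * n_years else n_years
  t_ar <- if (config$model == 1) ys_idx else obs$year - years[1] + 1L
  n_seas <- if (config$model == 2) 4L * n_years else 0L

  cl <- factor(obs$cluster_id, levels = unique(obs$cluster_id))
  n_clusters <- nlevels(cl)
  p <- length(config$covariates)
  layout <- latent_layout(p, n_v, n_t, n_seas, n_clusters)

  centers <- scales <- NULL
  Xstd <- NULL
  if (p > 0) {
    if (!all(config$covariates %in% names(obs))) {
      stop("covariate column(s) missing from observations: ",
           paste(setdiff(config$covariates, names(obs)), collapse = ", "))
    }
    Xraw <- as.matrix(obs[config$covariates])
    centers <- colMeans(Xraw)
    scales <- apply(Xraw, 2, stats::sd)
    scales[scales < 1e-12] <- 1
    Xstd <- sweep(sweep(Xraw, 2, centers), 2, scales, "/")
  }

  n_obs <- nrow(obs)
  trip <- Matrix::summary(A_sp)
  ii <- c(seq_len(n_obs),                                    # intercept
          if (p > 0) rep(seq_len(n_obs), p),                 # fixed effects
          trip$i,                                            # space-time
          if (n_seas > 0) seq_len(n_obs),                    # seasonal
          seq_len(n_obs))                                    # cluster
  jj <- c(rep(layout$intercept, n_obs),
          if (p > 0) rep(layout$beta, each = n_obs),
          layout$spacetime[1] - 1L + (t_ar[trip$i] - 1L) * n_v + trip$j,
          if (n_seas > 0) layout$seasonal[1] - 1L + ys_idx,
          layout$cluster[1] - 1L + as.integer(cl))
  xx <- c(rep(1, n_obs),
          if (p > 0) as.vector(Xstd),
          trip$x,
          if (n_seas > 0) rep(1, n_obs),
          rep(1, n_obs))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n_obs, layout$total))

  basis <- parameter_field_basis(mesh,
                                 degree = if (config$nonstationary) 1 else 0)
  seasonal <- if (n_seas > 0) seasonal_structure(n_seas, 4) else NULL

  list(mesh = mesh, fem = fem, layout = layout, A = A,
       basis = basis, seasonal = seasonal,
       years = years, n_years = n_years, n_t = n_t, n_seas = n_seas,
       t_ar = t_ar, ys_idx = ys_idx,
       cluster_levels = levels(cl),
       centers = centers, scales = scales,
       y = if (config$family == "gaussian") obs$y else obs$n_wasted,
       n = obs$n_examined,
       extent = max(diff(range(mesh$vertices[, 1])),
                    diff(range(mesh$vertices[, 2]))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hyperparameter vector <-> natural parameters. Transformed scale:
# log tau / log kappa basis coefficients, Fisher-z of the AR pacfs
# (pacf = 2 plogis(z) - 1), log precisions.
psi_template <- function(st, config) {
  nb <- ncol(st$basis$B_tau)
  kappa0 <- sqrt(8) / (0.3 * st$extent)
  tau0 <- 1 / (2 * sqrt(pi) * kappa0 * 0.5)
  nm <- c(paste0("theta_tau", seq_len(nb)), paste0("theta_kappa", seq_len(nb)),
          "z_pacf1", "z_pacf2", "log_prec_cluster",
          if (config$model == 2) "log_prec_seasonal")
  init <- c(log(tau0), rep(0, nb - 1), log(kappa0), rep(0, nb - 1),
            0.8, 0.2, log(1 / 0.3^2),
            if (config$model == 2) log(1 / 0.1^2))
  stats::setNames(init, nm)
}

psi_natural <- function(psi, st, config) {
  nb <- ncol(st$basis$B_tau)
  theta_tau <- psi[seq_len(nb)]
  theta_kappa <- psi[nb + seq_len(nb)]
  pacf <- 2 * stats::plogis(psi[c("z_pacf1", "z_pacf2")]) - 1
  fields <- evaluate_parameter_fields(st$basis, theta_tau, theta_kappa)
  list(theta_tau = theta_tau, theta_kappa = theta_kappa,
       tau = fields$tau, kappa = fields$kappa, pacf = unname(pacf),
       prec_cluster = exp(psi[["log_prec_cluster"]]),
       prec_seasonal = if (config$model == 2) exp(psi[["log_prec_seasonal"]])
       else NULL)
}

make_joint_precision <- function(psi, st, config, with_logdet = FALSE) {
  nat <- psi_natural(psi, st, config)
  Q_s <- spatial_precision(st$fem, nat$tau, nat$kappa)
  Q_t <- if (st$n_t >= 3) ar2_precision(st$n_t, nat$pacf)
  else Matrix::Diagonal(st$n_t)
  Q_st <- spacetime_precision(Q_s, Q_t, max_dim = 1e6)
  Q <- assemble_joint_precision(st$layout, Q_st, seasonal = st$seasonal,
                                cluster_prec = nat$prec_cluster,
                                fixed_prior_prec = config$prior_fixed_prec,
                                seasonal_prec = nat$prec_seasonal %||% 1)
  if (!with_logdet) return(Q)
  # log|Q| assembled from the blocks; the Kronecker identity
  # log|Qt x Qs| = n_t log|Qs| + n_v log|Qt| avoids a full-dimension Cholesky
  lay <- st$layout
  nfix <- length(lay$intercept) + length(lay$beta)
  ld <- nfix * log(config$prior_fixed_prec) +
    st$n_t * logdet_sparse(Q_s) +
    nrow(Q_s) * logdet_sparse(Q_t) +
    length(lay$cluster) * log(nat$prec_cluster)
  if (length(lay$seasonal) > 0) {
    Sblk <- nat$prec_seasonal * as.matrix(st$seasonal$S) +
      diag(1e-6, st$seasonal$n)
    ld <- ld + as.numeric(determinant(Sblk, logarithm = TRUE)$modulus)
  }
  list(Q = Q, logdet = ld)
}

# Gaussian hyperpriors on the transformed scale: SD 3 on log-scale
# parameters, SD 1.5 on the Fisher-z of the pacfs.
log_hyperprior <- function(psi) {
  sds <- ifelse(grepl("^z_pacf", names(psi)), 1.5, 3)
  sum(stats::dnorm(psi, 0, sds, log = TRUE))
}

obs_loglik <- function(eta, st, config) {
  if (config$family == "binomial") binomial_loglik(eta, st$y, st$n)
  else gaussian_loglik(eta, st$y, config$gaussian_sd)
}

# Newton maximization of log p(y | u) - u' Q u / 2 with step halving.
# `cache` (an environment) reuses the symbolic Cholesky factorization across
# iterations and across hyperparameter evaluations.
inner_newton <- function(Q, st, config, u0 = NULL,
                         max_iter = 50, tol = 1e-6, cache = NULL) {
  A <- st$A
  u <- u0 %||% rep(0, ncol(A))
  factorize <- function(H) {
    if (!is.null(cache) && !is.null(cache$ch)) {
      ch <- tryCatch(Matrix::update(cache$ch, H), error = function(e) NULL)
      if (!is.null(ch)) {
        if (!is.null(cache)) cache$ch <- ch
        return(ch)
      }
    }
    ch <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE, super = TRUE)
    if (!is.null(cache)) cache$ch <- ch
    ch
  }
  objective <- function(u) {
    obs_loglik(as.vector(A %*% u), st, config)$value -
      0.5 * as.numeric(Matrix::crossprod(u, Q %*% u))
  }
  f <- objective(u)
  converged <- FALSE
  ch <- NULL
  for (it in seq_len(max_iter)) {
    lik <- obs_loglik(as.vector(A %*% u), st, config)
    grad <- as.vector(Matrix::crossprod(A, lik$gradient)) -
      as.vector(Q %*% u)
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    H <- Matrix::forceSymmetric(Q + Matrix::crossprod(A, A * lik$curvature))
    ch <- tryCatch(factorize(H), error = function(e) NULL)
    if (is.null(ch)) {
      stop("indefinite or singular Hessian in the inner Newton loop")
    }
    step <- as.vector(Matrix::solve(ch, grad, system = "A"))
    alpha <- 1
    repeat {
      u_new <- u + alpha * step
      f_new <- objective(u_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) { u_new <- u; f_new <- f; break }
    }
    moved <- max(abs(u_new - u))
    u <- u_new; f <- f_new
    if (moved < 1e-12) { converged <- max(abs(grad)) < 1e-2; break }
  }
  lik <- obs_loglik(as.vector(A %*% u), st, config)
  H <- Matrix::forceSymmetric(Q + Matrix::crossprod(A, A * lik$curvature))
  ch <- factorize(H)
  logdet_H <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                                 sqrt = TRUE)$modulus)
  list(mode = u, H = H, chol = ch, logdet_H = logdet_H, value = f,
       converged = converged, iterations = it)
}

logdet_sparse <- function(M) {
  as.numeric(Matrix::determinant(M, logarithm = TRUE)$modulus)
}

#' Fit the latent Gaussian model by Laplace approximation
#'
#' Inner loop: Newton iterations (sparse solves, step halving) on the latent
#' field at fixed hyperparameters. Outer loop: derivative-free Nelder--Mead
#' maximization of the Laplace-approximate marginal posterior of the
#' hyperparameters (empirical Bayes at the marginal mode), optionally
#' restarted from a jittered start.
#'
#' @param observations cluster data frame (as from [simulate_wasting_data()]
#'   or [read_clusters_csv()]).
#' @param config a [model_config()].
#' @param optimizer_config list: \code{maxit} (Nelder--Mead iterations,
#'   default 150), \code{restarts} (default 2), \code{jitter_sd} (default
#'   0.5).
#' @param seed seed for the restart jitter.
#' @param fixed_psi optional named hyperparameter vector (transformed scale);
#'   when supplied the outer optimization is skipped.
#' @return object of class \code{wm_fit}: latent \code{mode}, skewness-
#'   corrected posterior \code{mean} (a third-derivative correction moves the
#'   summary from the joint mode toward the marginal means), posterior
#'   precision \code{H} of the Gaussian approximation, \code{marginal_sd},
#'   hyperparameters (\code{psi} transformed, \code{psi_natural}, and their
#'   Laplace covariance \code{psi_vcov}), \code{log_posterior},
#'   \code{fixed_effects} summary table (posterior mean, SD, 95\% interval,
#'   odds; the SDs fold in hyperparameter uncertainty propagated from the
#'   marginal posterior curvature), structures and diagnostics.
#' @export
laplace_fit <- function(observations, config, optimizer_config = list(),
                        seed = 1, fixed_psi = NULL) {
  st <- build_structures(observations, config)
  psi0 <- psi_template(st, config)
  warm <- new.env()
  warm$u <- NULL

  fix_idx_pre <- c(st$layout$intercept, st$layout$beta)
  marginal <- function(psi_vec, keep_mode = FALSE) {
    psi <- stats::setNames(psi_vec, names(psi0))
    Qld <- tryCatch(make_joint_precision(psi, st, config, with_logdet = TRUE),
                    error = function(e) NULL)
    if (is.null(Qld) || !is.finite(Qld$logdet)) return(-Inf)
    fit <- tryCatch(inner_newton(Qld$Q, st, config, u0 = warm$u, cache = warm),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$logdet_H)) return(-Inf)
    warm$u <- fit$mode
    val <- fit$value + 0.5 * Qld$logdet - 0.5 * fit$logdet_H +
      log_hyperprior(psi)
    if (keep_mode) return(list(value = val, fixed = fit$mode[fix_idx_pre]))
    val
  }

  if (is.null(fixed_psi)) {
    oc <- utils::modifyList(list(maxit = 150, restarts = 2, jitter_sd = 0.5),
                            optimizer_config)
    best <- NULL
    starts <- with_seed(seed, {
      lapply(seq_len(oc$restarts), function(r) {
        if (r == 1) psi0
        else psi0 + stats::rnorm(length(psi0), 0, oc$jitter_sd)
      })
    })
    for (start in starts) {
      warm$u <- NULL
      opt <- stats::optim(start, function(p) -marginal(p),
                          method = "Nelder-Mead",
                          control = list(maxit = oc$maxit, reltol = 1e-6))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    psi_hat <- stats::setNames(best$par, names(psi0))
    outer_conv <- best$convergence == 0
    logpost <- -best$value
  } else {
    psi_hat <- stats::setNames(as.numeric(fixed_psi[names(psi0)]), names(psi0))
    if (anyNA(psi_hat)) {
      stop("fixed_psi must name all of: ", paste(names(psi0), collapse = ", "))
    }
    outer_conv <- NA
    logpost <- marginal(psi_hat)
  }

  Q <- make_joint_precision(psi_hat, st, config)
  fit <- inner_newton(Q, st, config, u0 = warm$u, cache = warm)
  if (!fit$converged) {
    warning("inner Newton loop did not fully converge; result flagged")
  }

  # third-derivative skewness correction: the posterior mean of a latent
  # binomial model sits away from the joint mode by ~ H^-1 A' (l''' * var(eta))/2
  post_mean <- fit$mode
  if (config$family == "binomial") {
    eta_hat <- as.vector(st$A %*% fit$mode)
    p_hat <- stats::plogis(eta_hat)
    lik3 <- -st$n * p_hat * (1 - p_hat) * (1 - 2 * p_hat)
    VA <- Matrix::solve(fit$chol, Matrix::t(st$A), system = "A")
    var_eta <- pmax(Matrix::colSums(Matrix::t(st$A) * VA), 0)
    shift <- 0.5 * as.vector(
      Matrix::solve(fit$chol,
                    as.vector(Matrix::crossprod(st$A, lik3 * var_eta)),
                    system = "A"))
    post_mean <- fit$mode + shift
  }

  msd <- marginal_sds(fit$H, fit$chol)
  lay <- st$layout
  fix_idx <- c(lay$intercept, lay$beta)

  # propagate hyperparameter uncertainty into the fixed-effect intervals:
  # forward-difference Hessian of the log marginal posterior at psi-hat gives
  # cov(psi); the same evaluations yield the sensitivity d beta-hat / d psi,
  # so var_extra = J cov(psi) J'. Skipped at fixed psi.
  fixed_sd_extra <- rep(0, length(fix_idx))
  psi_vcov <- NULL
  if (is.null(fixed_psi)) {
    hstep <- 0.1
    d <- length(psi_hat)
    f0 <- marginal(psi_hat, keep_mode = TRUE)
    f_i <- vector("list", d)
    for (i in seq_len(d)) {
      f_i[[i]] <- marginal(psi_hat + hstep * (seq_len(d) == i),
                           keep_mode = TRUE)
    }
    ok <- is.list(f0) && all(vapply(f_i, is.list, logical(1)))
    if (ok) {
      Hpsi <- matrix(NA_real_, d, d)
      for (i in seq_len(d)) {
        for (j in i:d) {
          fij <- marginal(psi_hat + hstep * ((seq_len(d) == i) +
                                               (seq_len(d) == j)))
          if (!is.finite(fij)) { ok <- FALSE; break }
          Hpsi[i, j] <- Hpsi[j, i] <-
            -(fij - f_i[[i]]$value - f_i[[j]]$value + f0$value) / hstep^2
        }
        if (!ok) break
      }
      if (ok) {
        ch_psi <- tryCatch(chol(Hpsi), error = function(e) NULL)
        if (!is.null(ch_psi)) {
          psi_vcov <- chol2inv(ch_psi)
          J <- vapply(seq_len(d),
                      function(i) (f_i[[i]]$fixed - f0$fixed) / hstep,
                      numeric(length(fix_idx)))
          fixed_sd_extra <- sqrt(pmax(rowSums((J %*% psi_vcov) * J), 0))
        }
      }
    }
  }
  fixed_sd <- sqrt(msd[fix_idx]^2 + fixed_sd_extra^2)

  fx <- data.frame(
    term = c("(Intercept)", config$covariates),
    mean = post_mean[fix_idx],
    sd = fixed_sd,
    lower = post_mean[fix_idx] - 1.96 * fixed_sd,
    upper = post_mean[fix_idx] + 1.96 * fixed_sd,
    stringsAsFactors = FALSE
  )
  fx$odds <- exp(fx$mean)

  structure(list(
    mode = fit$mode, mean = post_mean, H = fit$H, chol = fit$chol,
    marginal_sd = msd,
    psi = psi_hat, psi_natural = psi_natural(psi_hat, st, config),
    psi_vcov = psi_vcov,
    log_posterior = logpost, fixed_effects = fx,
    structures = st, config = config,
    convergence = list(inner = fit$converged, outer = outer_conv,
                       inner_iterations = fit$iterations),
    seed = seed
  ), class = "wm_fit")
}

marginal_sds <- function(H, ch = NULL) {
  d <- nrow(H)
  if (is.null(ch)) ch <- Matrix::Cholesky(H, LDL = FALSE, super = TRUE)
  if (d <= 5000) {
    V <- Matrix::solve(ch, Matrix::Diagonal(d), system = "A")
    sqrt(pmax(Matrix::diag(V), 0))
  } else {
    out <- numeric(d)
    for (start in seq(1, d, by = 1000)) {
      cols <- start:min(start + 999, d)
      E <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                                dims = c(d, length(cols)))
      V <- Matrix::solve(ch, E)
      out[cols] <- vapply(seq_along(cols),
                          function(k) V[cols[k], k], numeric(1))
    }
    sqrt(pmax(out, 0))
  }
}

#' @export
print.wm_fit <- function(x, ...) {
  cat(sprintf("<wm_fit> model %d, %s family, latent dim %d\n",
              x$config$model, x$config$family, length(x$mode)))
  cat(sprintf("  log-posterior %.3f; inner converged: %s\n",
              x$log_posterior, x$convergence$inner))
  print(x$fixed_effects, row.names = FALSE, digits = 4)
  invisible(x)
}

#' MCMC oracle for the latent field at fixed hyperparameters
#'
#' Preconditioned Metropolis-adjusted Langevin sampler targeting the exact
#' latent posterior at fixed psi, used as an independent check on the Laplace
#' approximation at test scale (latent dimension capped at 2000). The
#' preconditioner is the curvature at the posterior mode; step size adapts
#' during burn-in only.
#'
#' @param observations cluster data frame.
#' @param config a [model_config()].
#' @param fixed_psi named hyperparameter vector (transformed scale).
#' @param n_iter post-burn-in iterations.
#' @param seed RNG seed.
#' @param burn_in burn-in iterations (default \code{n_iter / 4}).
#' @return list: \code{mean}, \code{sd}, \code{ess}, \code{se_mean} per
#'   latent component, acceptance rate, and the layout.
#' @export
mcmc_oracle <- function(observations, config, fixed_psi, n_iter = 4000,
                        seed = 1, burn_in = NULL) {
  st <- build_structures(observations, config)
  d <- st$layout$total
  if (d > 2000) stop("latent dimension ", d, " exceeds the oracle guard (2000)")
  psi0 <- psi_template(st, config)
  psi <- stats::setNames(as.numeric(fixed_psi[names(psi0)]), names(psi0))
  if (anyNA(psi)) {
    stop("fixed_psi must name all of: ", paste(names(psi0), collapse = ", "))
  }
  Q <- make_joint_precision(psi, st, config)
  mode_fit <- inner_newton(Q, st, config)
  M <- as.matrix(mode_fit$H)          # preconditioner
  R <- chol(M)                        # M = R'R
  Qd <- as.matrix(Q)
  A <- st$A
  burn_in <- burn_in %||% max(200L, as.integer(n_iter / 4))

  logpost <- function(u) {
    obs_loglik(as.vector(A %*% u), st, config)$value -
      0.5 * sum(u * (Qd %*% u))
  }
  grad <- function(u) {
    as.vector(Matrix::crossprod(A, obs_loglik(as.vector(A %*% u), st,
                                              config)$gradient)) -
      as.vector(Qd %*% u)
  }

  with_seed(seed, {
    u <- mode_fit$mode
    lp <- logpost(u); g <- grad(u)
    eps <- 0.8
    samples <- matrix(NA_real_, n_iter, d)
    n_acc <- 0L
    total <- burn_in + n_iter
    for (it in seq_len(total)) {
      Minv_g <- backsolve(R, forwardsolve(t(R), g))
      mean_prop <- u + (eps^2 / 2) * Minv_g
      z <- stats::rnorm(d)
      u_prop <- mean_prop + eps * backsolve(R, z)
      lp_prop <- logpost(u_prop)
      g_prop <- grad(u_prop)
      # proposal densities under the preconditioned Langevin kernel
      mean_back <- u_prop + (eps^2 / 2) * backsolve(R, forwardsolve(t(R), g_prop))
      qf <- function(a, b) {      # -0.5 ||R (a - b)||^2 / eps^2
        r <- as.vector(R %*% (a - b))
        -0.5 * sum(r^2) / eps^2
      }
      log_alpha <- lp_prop - lp + qf(u, mean_back) - qf(u_prop, mean_prop)
      if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
        u <- u_prop; lp <- lp_prop; g <- g_prop
        if (it > burn_in) n_acc <- n_acc + 1L
        acc <- 1
      } else acc <- 0
      if (it <= burn_in) {
        eps <- exp(log(eps) + (acc - 0.574) / sqrt(it))
      } else {
        samples[it - burn_in, ] <- u
      }
    }
    ess <- apply(samples, 2, ess_ips)
    mu <- colMeans(samples)
    sdv <- apply(samples, 2, stats::sd)
    list(mean = mu, sd = sdv, ess = ess,
         se_mean = sdv / sqrt(pmax(ess, 1)),
         accept_rate = n_acc / n_iter,
         layout = st$layout, n_iter = n_iter, eps = eps)
  })
}

# Effective sample size via the initial-positive-sequence truncation of the
# autocorrelation sum.
ess_ips <- function(x) {
  n <- length(x)
  if (stats::sd(x) < 1e-14) return(n)
  rho <- stats::acf(x, lag.max = min(n - 2, 400), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] <= 0) break
    s <- s + rho[k]
  }
  n / (1 + 2 * s)
}

#' Predict posterior prevalence on a pixel grid
#'
#' Evaluates the linear predictor at the posterior mode on each requested
#' (year, season): intercept + standardized covariates + space--time field
#' (+ seasonal effect under model 2); cluster effects enter at their prior
#' mean of zero (prediction for a new location). The posterior SD of the
#' linear predictor comes from the Gaussian approximation and is mapped to
#' the prevalence scale by the delta method \code{p (1 - p) sd(eta)};
#' optionally the inverse-logit is averaged over Gaussian samples of the
#' latent field. Pixels outside the mesh are masked (NA) and counted.
#'
#' @param fit a [laplace_fit()] result.
#' @param grid a [pixel_grid()] or [make_study_region()] giving pixel
#'   geometry.
#' @param covariate_rasters named list of covariate [pixel_grid()]s covering
#'   the model's covariates.
#' @param which list of \code{c(year, season)} pairs (or a data.frame with
#'   columns \code{year}, \code{season}).
#' @param seed seed for optional Monte-Carlo averaging.
#' @return object of class \code{wm_prevalence}: per year--season, grids of
#'   posterior mean prevalence and SD; \code{n_masked}, \code{n_predicted}.
#' @export
predict_prevalence <- function(fit, grid, covariate_rasters = list(),
                               which, seed = 1) {
  stopifnot(inherits(fit, "wm_fit"))
  if (inherits(grid, "wm_region")) grid <- region_grid(grid)
  stopifnot(inherits(grid, "wm_grid"))
  st <- fit$structures
  config <- fit$config
  if (is.data.frame(which)) {
    which <- lapply(seq_len(nrow(which)),
                    function(i) c(which$year[i], which$season[i]))
  }
  px <- grid_df(grid)
  inside <- mesh_contains(st$mesh, px[c("x", "y")])
  n_masked <- sum(!inside)
  pin <- px[inside, , drop = FALSE]
  n_pix <- nrow(pin)
  A_sp <- projection_matrix(st$mesh, cbind(pin$x, pin$y))
  p <- length(config$covariates)
  Z <- NULL
  if (p > 0) {
    miss <- setdiff(config$covariates, names(covariate_rasters))
    if (length(miss)) stop("covariate raster(s) missing: ",
                           paste(miss, collapse = ", "))
    Z <- vapply(config$covariates, function(nm) {
      (grid_lookup(covariate_rasters[[nm]], pin$x, pin$y) -
         st$centers[[nm]]) / st$scales[[nm]]
    }, numeric(n_pix))
    if (n_pix == 1) Z <- matrix(Z, nrow = 1)
  }

  lay <- st$layout
  n_v <- lay$n_v
  out <- list()
  mc <- config$predict_mc
  mc_draws <- NULL
  if (mc > 0) {
    mc_draws <- with_seed(seed, {
      ch <- fit$chol
      z <- matrix(stats::rnorm(length(fit$mode) * mc), length(fit$mode), mc)
      as.matrix(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"),
                              system = "Pt")) + fit$mean
    })
  }
  for (w in which) {
    year <- as.integer(w[1]); season <- canonical_season(w[2])
    if (!(year %in% st$years)) stop("year ", year, " outside the fitted range")
    si <- match(season, WM_SEASONS)
    ys <- 4L * (year - st$years[1]) + si
    t_ar <- if (config$model == 1) ys else year - st$years[1] + 1L
    trip <- Matrix::summary(A_sp)
    ii <- c(seq_len(n_pix), if (p > 0) rep(seq_len(n_pix), p), trip$i,
            if (config$model == 2) seq_len(n_pix))
    jj <- c(rep(lay$intercept, n_pix),
            if (p > 0) rep(lay$beta, each = n_pix),
            lay$spacetime[1] - 1L + (t_ar - 1L) * n_v + trip$j,
            if (config$model == 2) rep(lay$seasonal[1] - 1L + ys, n_pix))
    xx <- c(rep(1, n_pix), if (p > 0) as.vector(Z), trip$x,
            if (config$model == 2) rep(1, n_pix))
    Ad <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                               dims = c(n_pix, lay$total))
    eta <- as.vector(Ad %*% fit$mean)
    V <- Matrix::solve(fit$chol, Matrix::t(Ad), system = "A")
    var_eta <- pmax(Matrix::colSums(Matrix::t(Ad) * V), 0)
    pm <- if (mc > 0) {
      rowMeans(stats::plogis(as.matrix(Ad %*% mc_draws)))
    } else {
      stats::plogis(eta)
    }
    psd <- stats::plogis(eta) * (1 - stats::plogis(eta)) * sqrt(var_eta)

    mean_vals <- rep(NA_real_, nrow(px)); mean_vals[inside] <- pm
    sd_vals <- rep(NA_real_, nrow(px)); sd_vals[inside] <- psd
    key <- paste0(year, "_", season)
    out[[key]] <- list(
      year = year, season = season,
      mean = pixel_grid(grid$xs, grid$ys,
                        matrix(mean_vals, length(grid$xs), length(grid$ys))),
      sd = pixel_grid(grid$xs, grid$ys,
                      matrix(sd_vals, length(grid$xs), length(grid$ys)))
    )
  }
  structure(list(surfaces = out, n_masked = n_masked, n_predicted = n_pix),
            class = "wm_prevalence")
}

#' Seasonal effect sizes from a model-2 fit
#'
#' Posterior mean log-odds effect of each season: the seasonal component
#' averaged over years for each season, centred to sum to zero
#' (identifiability against the intercept), with delta-method credible
#' intervals from the Gaussian approximation.
#'
#' @param fit a model-2 [laplace_fit()].
#' @return data.frame with columns \code{season}, \code{mean}, \code{sd},
#'   \code{lower}, \code{upper}; the means sum to zero.
#' @export
seasonal_effect_estimates <- function(fit) {
  stopifnot(inherits(fit, "wm_fit"))
  if (fit$config$model != 2) {
    stop("seasonal effects require a model-2 fit")
  }
  st <- fit$structures
  lay <- st$layout
  n_years <- st$n_years
  d <- lay$total
  M <- matrix(0, 4, d)
  for (s in 1:4) {
    cols <- lay$seasonal[1] - 1L + (4L * (seq_len(n_years) - 1L) + s)
    M[s, cols] <- 1 / n_years
  }
  Mc <- M - matrix(colMeans(M), 4, d, byrow = TRUE)
  est <- as.vector(Mc %*% fit$mean)
  V <- Matrix::solve(fit$chol, t(Mc), system = "A")
  vars <- pmax(colSums(t(Mc) * as.matrix(V)), 0)
  data.frame(season = WM_SEASONS, mean = est, sd = sqrt(vars),
             lower = est - 1.96 * sqrt(vars),
             upper = est + 1.96 * sqrt(vars),
             stringsAsFactors = FALSE)
}
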