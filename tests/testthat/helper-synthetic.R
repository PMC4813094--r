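# Shared builders for small synthetic instances used across the suite.

# 4x4 km region with a 25-node mesh and n clusters observed in one year.
tiny_instance <- function(n_obs = 40, n_examined = 50, prevalence = 0.2,
                          seed = 3) {
  region <- make_study_region(4, 4, 1)
  mesh <- build_mesh(region, 1.5, 0)
  locs <- sample_cluster_locations(region, n_obs, seed = seed)
  obs <- withr::with_seed(seed, {
    df <- data.frame(
      cluster_id = sprintf("c%03d", seq_len(n_obs)),
      x_km = locs$x, y_km = locs$y,
      year = rep(2007L, n_obs),
      season = rep(WM_SEASONS, length.out = n_obs),
      n_examined = rep(n_examined, n_obs)
    )
    df$n_wasted <- stats::rbinom(n_obs, n_examined, prevalence)
    df
  })
  list(region = region, mesh = mesh, obs = obs)
}

# hyperparameters for tiny fixed-psi fits (stationary, model 1)
tiny_psi <- function(model = 1) {
  c(theta_tau1 = 0.5, theta_kappa1 = 0.2, z_pacf1 = 0.8, z_pacf2 = 0.2,
    log_prec_cluster = 1,
    if (model == 2) c(log_prec_seasonal = 2))
}

# a fit whose latent field is replaced by a hand-set state, for exercising
# the prediction path against known linear predictors
handmade_fit <- function(beta0 = stats::qlogis(0.2), beta = NULL,
                         covariates = character(), seed = 3) {
  inst <- tiny_instance(seed = seed)
  obs <- inst$obs
  if (length(covariates) > 0) {
    for (nm in covariates) obs[[nm]] <- stats::runif(nrow(obs))
  }
  cfg <- model_config(mesh = inst$mesh, covariates = covariates, model = 1)
  fit <- laplace_fit(obs, cfg, fixed_psi = tiny_psi())
  state <- rep(0, length(fit$mode))
  state[fit$structures$layout$intercept] <- beta0
  if (!is.null(beta)) state[fit$structures$layout$beta] <- beta
  fit$mode <- state
  fit$mean <- state
  # neutralize standardization so raster values enter the predictor directly
  if (length(covariates) > 0) {
    fit$structures$centers[covariates] <- 0
    fit$structures$scales[covariates] <- 1
  }
  list(fit = fit, region = inst$region)
}
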