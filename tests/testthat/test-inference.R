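test_that("binomial log-likelihood derivatives are exact", {
  # stationary point at eta = 0 when y = n/2
  l0 <- binomial_loglik(rep(0, 5), rep(10, 5), rep(20, 5))
  expect_equal(max(abs(l0$gradient)), 0)
  # finite-difference oracle
  set.seed(6)
  eta <- rnorm(20); y <- rbinom(20, 30, 0.3); n <- rep(30, 20)
  l <- binomial_loglik(eta, y, n)
  h <- 1e-5
  fd <- sapply(seq_along(eta), function(i) {
    ep <- eta; em <- eta
    ep[i] <- ep[i] + h; em[i] <- em[i] - h
    (binomial_loglik(ep, y, n)$value - binomial_loglik(em, y, n)$value) / (2 * h)
  })
  expect_lt(max(abs(l$gradient - fd)), 1e-6)
  # concavity: all second derivatives (-curvature) nonpositive
  expect_true(all(l$curvature >= 0))
  expect_error(binomial_loglik(eta, y + 40, n), "successes <= trials")
})

test_that("Gaussian-likelihood fit equals the conjugate closed form", {
  inst <- tiny_instance(seed = 3)
  obs <- inst$obs
  obs$y <- withr::with_seed(4, rnorm(nrow(obs)))
  cfg <- model_config(mesh = inst$mesh, model = 1, family = "gaussian",
                      gaussian_sd = 0.7)
  fit <- laplace_fit(obs, cfg, fixed_psi = tiny_psi())
  st <- fit$structures
  Q <- wastemap:::make_joint_precision(fit$psi, st, cfg)
  H <- Q + Matrix::crossprod(st$A) / 0.7^2
  mu <- as.vector(Matrix::solve(H, Matrix::crossprod(st$A, obs$y) / 0.7^2))
  expect_lt(max(abs(fit$mode - mu)), 1e-8)
  expect_lt(max(abs(fit$mean - mu)), 1e-8)   # no skew correction for gaussian
  expect_true(all(fit$marginal_sd >= 0))
  expect_equal(fit$fixed_effects$odds, exp(fit$fixed_effects$mean))
})

test_that("MCMC oracle matches conjugate means and obeys MC scaling", {
  inst <- tiny_instance(n_obs = 20, seed = 5)
  obs <- inst$obs
  obs$y <- withr::with_seed(6, rnorm(nrow(obs), 0, 0.5))
  cfg <- model_config(mesh = inst$mesh, model = 1, family = "gaussian",
                      gaussian_sd = 0.5)
  psi <- tiny_psi()
  mc <- mcmc_oracle(obs, cfg, psi, n_iter = 3000, seed = 8)
  fit <- laplace_fit(obs, cfg, fixed_psi = psi)   # exact posterior mean here
  z <- abs(mc$mean - fit$mode) / pmax(mc$se_mean, 1e-10)
  expect_lt(max(z), 3.5)

  # prior-only: a binomial data set with zero trials leaves the prior intact
  obs0 <- inst$obs
  obs0$n_examined <- 0L; obs0$n_wasted <- 0L
  cfg0 <- model_config(mesh = inst$mesh, model = 1)
  mc0 <- mcmc_oracle(obs0, cfg0, psi, n_iter = 3000, seed = 9)
  z0 <- abs(mc0$mean) / pmax(mc0$se_mean, 1e-10)
  expect_lt(stats::quantile(z0, 0.99), 3.5)

  # quadrupling the iterations roughly halves the MC standard error
  mc4 <- mcmc_oracle(obs, cfg, psi, n_iter = 12000, seed = 8)
  ratio <- stats::median(mc$se_mean / mc4$se_mean)
  expect_gt(ratio, 2 / 1.4)
  expect_lt(ratio, 2 * 1.4)

  expect_error(
    mcmc_oracle(obs, model_config(mesh = build_mesh(inst$region, 0.1, 1),
                                  model = 1, family = "gaussian"),
                psi, n_iter = 10, seed = 1),
    "guard")
})

test_that("prediction reproduces known linear predictors on the grid", {
  hm <- handmade_fit(beta0 = stats::qlogis(0.2))
  pv <- predict_prevalence(hm$fit, hm$region, which = list(c(2007, "Jilaal")))
  vals <- pv$surfaces[["2007_Jilaal"]]$mean$values
  expect_equal(pv$n_masked, 0)
  expect_equal(pv$n_predicted, length(vals))
  expect_true(all(abs(vals - 0.2) < 1e-12))
  sds <- pv$surfaces[["2007_Jilaal"]]$sd$values
  expect_true(all(sds >= 0))

  # monotone in a covariate with positive coefficient
  hm2 <- handmade_fit(beta0 = 0, beta = 0.8, covariates = "rainfall")
  xs <- region_pixel_xs(hm2$region); ys <- region_pixel_ys(hm2$region)
  rain <- pixel_grid(xs, ys, matrix(seq(0, 1, length.out = 16), 4, 4))
  pv2 <- predict_prevalence(hm2$fit, hm2$region, list(rainfall = rain),
                            which = list(c(2007, "Gu")))
  m2 <- as.vector(pv2$surfaces[["2007_Gu"]]$mean$values)
  expect_true(all(diff(m2[order(as.vector(rain$values))]) > 0))
})

test_that("a saturated cluster dominates the prediction at its pixel", {
  region <- make_study_region(4, 4, 1)
  mesh <- build_mesh(region, 1.5, 0)
  obs <- withr::with_seed(12, {
    locs <- sample_cluster_locations(region, 30, seed = 12)
    data.frame(cluster_id = sprintf("c%02d", 1:30),
               x_km = locs$x, y_km = locs$y, year = 2007L,
               season = "Gu", n_examined = 50L,
               n_wasted = rbinom(30, 50, 0.35))
  })
  obs$x_km[1] <- 2.5; obs$y_km[1] <- 2.5      # pixel centre
  obs$n_examined[1] <- 10000L
  obs$n_wasted[1] <- 3500L
  psi <- c(theta_tau1 = -1.5, theta_kappa1 = 0.2, z_pacf1 = 0.8,
           z_pacf2 = 0.2, log_prec_cluster = 10)  # clusters pinned near zero
  cfg <- model_config(mesh = mesh, model = 1)
  fit <- laplace_fit(obs, cfg, fixed_psi = psi)
  pv <- predict_prevalence(fit, region, which = list(c(2007, "Gu")))
  g <- pv$surfaces[["2007_Gu"]]$mean
  pix <- grid_lookup(g, 2.5, 2.5)
  expect_lt(abs(pix - 0.35), 0.02)
})

test_that("pixels outside the mesh are masked and counted", {
  region <- make_study_region(4, 4, 1)
  inst <- tiny_instance(seed = 3)
  cfg <- model_config(mesh = inst$mesh, model = 1)
  fit <- laplace_fit(inst$obs, cfg, fixed_psi = tiny_psi())
  wide <- pixel_grid(seq(-3.5, 7.5, by = 1), seq(0.5, 3.5, by = 1),
                     matrix(0, 12, 4))
  pv <- predict_prevalence(fit, wide, which = list(c(2007, "Deyr")))
  expect_gt(pv$n_masked, 0)
  expect_equal(pv$n_masked + pv$n_predicted, 12 * 4)
  vals <- pv$surfaces[["2007_Deyr"]]$mean$values
  expect_equal(sum(is.na(vals)), pv$n_masked)
  expect_true(all(vals[!is.na(vals)] > 0 & vals[!is.na(vals)] < 1))
})

test_that("inner Newton objective is monotone across accepted steps", {
  inst <- tiny_instance(seed = 7)
  cfg <- model_config(mesh = inst$mesh, model = 1)
  st <- wastemap:::build_structures(inst$obs, cfg)
  psi <- stats::setNames(tiny_psi(), names(wastemap:::psi_template(st, cfg)))
  Q <- wastemap:::make_joint_precision(psi, st, cfg)
  # trace the objective through the iterations by re-running with caps
  objs <- sapply(1:6, function(k) {
    wastemap:::inner_newton(Q, st, cfg, max_iter = k)$value
  })
  expect_true(all(diff(objs) >= -1e-10))
  fit <- wastemap:::inner_newton(Q, st, cfg)
  expect_true(fit$converged)
})

test_that("seasonal effects come from model 2, sum to zero, recover signs", {
  region <- make_study_region(200, 200, 20)
  mesh <- build_mesh(region, 60, 40)
  covs <- simulate_covariate_surfaces(region, seed = 31)
  truth_seas <- c(Jilaal = 0.5, Gu = -0.5, Hagaa = 0.5, Deyr = -0.5)
  tp <- true_parameters(beta0 = stats::qlogis(0.2),
                        beta = c(rainfall = 0), spatial_range = 70,
                        spatial_sd = 0.2, ar_pacf = c(0.4, 0.1),
                        seasonal = truth_seas, cluster_sd = 0.2)
  psi2 <- tiny_psi(model = 2)

  hits <- 0L
  for (rep in 1:20) {
    locs <- sample_cluster_locations(region, 300, seed = 700 + rep)
    obs <- simulate_wasting_data(region, locs, covs["rainfall"], tp,
                                 years = 2007:2008, seed = 800 + rep)
    cfg2 <- model_config(mesh = mesh, model = 2)
    fit2 <- laplace_fit(obs, cfg2, fixed_psi = psi2)
    se <- seasonal_effect_estimates(fit2)
    expect_equal(sum(se$mean), 0, tolerance = 1e-8)
    if (all(sign(se$mean) == sign(unname(truth_seas)))) hits <- hits + 1L
  }
  expect_gte(hits, 18L)

  # model-1 fits must be rejected
  inst <- tiny_instance(seed = 3)
  cfg1 <- model_config(mesh = inst$mesh, model = 1)
  fit1 <- laplace_fit(inst$obs, cfg1, fixed_psi = tiny_psi())
  expect_error(seasonal_effect_estimates(fit1), "model-2")
})
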