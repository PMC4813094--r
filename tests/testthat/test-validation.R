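make_split_data <- function(n = 1000, seed = 30) {
  withr::with_seed(seed, {
    data.frame(
      cluster_id = sprintf("c%04d", seq_len(n)),
      x_km = runif(n, 0, 300), y_km = runif(n, 0, 300),
      year = sample(2007:2010, n, replace = TRUE),
      season = sample(WM_SEASONS, n, replace = TRUE),
      n_examined = rep(50L, n), n_wasted = rbinom(n, 50, 0.2)
    )
  })
}

test_that("the 10% hold-out is exact, disjoint and exhaustive", {
  obs <- make_split_data(1000)
  sp <- spatiotemporal_holdout(obs, 0.10, seed = 2)
  expect_equal(nrow(sp$test), 100)
  expect_equal(nrow(sp$train), 900)
  expect_equal(length(intersect(sp$train$cluster_id, sp$test$cluster_id)), 0)
  expect_setequal(c(sp$train$cluster_id, sp$test$cluster_id), obs$cluster_id)
  # deterministic under the same seed
  sp2 <- spatiotemporal_holdout(obs, 0.10, seed = 2)
  expect_identical(sp$test$cluster_id, sp2$test$cluster_id)
  expect_error(spatiotemporal_holdout(obs, 0), "in \\(0, 1\\)")
  expect_error(spatiotemporal_holdout(obs, 1.2), "in \\(0, 1\\)")
})

test_that("every well-populated year-season contributes test points", {
  obs <- make_split_data(1600, seed = 33)
  sp <- spatiotemporal_holdout(obs, 0.10, seed = 5)
  counts <- table(interaction(sp$test$year, sp$test$season))
  present <- table(interaction(obs$year, obs$season))
  expect_true(all(counts[names(present)[present >= 20]] >= 1))
})

test_that("validation metrics match hand arithmetic and identities", {
  v <- validation_metrics(c(0.2, 0.4), c(0.1, 0.5))
  expect_equal(v$rmse, 0.1)
  expect_equal(v$me, 0)
  expect_equal(v$mae, 0.1)
  expect_equal(v$correlation, 1)

  # perfect prediction
  v0 <- validation_metrics(c(0.1, 0.3, 0.5), c(0.1, 0.3, 0.5))
  expect_equal(v0$rmse, 0)
  expect_equal(v0$me, 0)
  expect_equal(v0$mae, 0)

  # RMSE^2 = ME^2 + population variance of the errors
  set.seed(40)
  o <- runif(50); p <- o + rnorm(50, 0.02, 0.1)
  v1 <- validation_metrics(o, p)
  err <- p - o
  expect_equal(v1$rmse^2, v1$me^2 + mean((err - mean(err))^2),
               tolerance = 1e-12)
  expect_gte(v1$rmse, abs(v1$me))
  expect_gte(v1$rmse, 0)

  # order invariance
  idx <- sample(50)
  v2 <- validation_metrics(o[idx], p[idx])
  expect_equal(v1$rmse, v2$rmse)
  expect_equal(v1$correlation, v2$correlation)

  # constant vectors leave the correlation undefined, flagged
  vc <- validation_metrics(rep(0.2, 5), runif(5))
  expect_true(is.na(vc$correlation))
  expect_false(vc$correlation_defined)
  expect_error(validation_metrics(1:3, 1:4), "equal-length")
})

test_that("hold-out RMSE improves when the survey densifies", {
  region <- make_study_region(200, 200, 20)
  mesh <- build_mesh(region, 60, 40)
  covs <- simulate_covariate_surfaces(region, seed = 50)
  tp <- true_parameters(beta0 = stats::qlogis(0.2),
                        beta = c(rainfall = -0.3, temperature = 0.2),
                        spatial_range = 70, spatial_sd = 0.35,
                        seasonal = c(Jilaal = 0, Gu = 0, Hagaa = 0, Deyr = 0),
                        cluster_sd = 0.15)
  rmse_at <- function(n_clusters, seed) {
    locs <- sample_cluster_locations(region, n_clusters, seed = seed)
    obs <- simulate_wasting_data(region, locs,
                                 covs[c("rainfall", "temperature")], tp,
                                 years = 2007, n_per_cluster = 60,
                                 seed = seed + 1)
    sp <- spatiotemporal_holdout(obs, 0.10, seed = seed + 2)
    cfg <- model_config(mesh = mesh,
                        covariates = c("rainfall", "temperature"), model = 1)
    fit <- laplace_fit(sp$train, cfg, fixed_psi = c(
      theta_tau1 = log(1 / (2 * sqrt(pi) * (sqrt(8) / 70) * 0.35)),
      theta_kappa1 = log(sqrt(8) / 70), z_pacf1 = 0.8, z_pacf2 = 0.2,
      log_prec_cluster = log(1 / 0.15^2)))
    validate_fit(fit, sp$test)$rmse
  }
  rmse_small <- mean(sapply(1:5, function(k) rmse_at(80, 900 + 10 * k)))
  rmse_big <- mean(sapply(1:5, function(k) rmse_at(320, 900 + 10 * k + 5)))
  expect_lt(rmse_big, rmse_small)
})
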