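test_that("study region grid arithmetic and zone partition", {
  r <- make_study_region(300, 300, 10)
  expect_equal(length(region_pixel_xs(r)), 30)
  expect_equal(length(region_pixel_ys(r)), 30)
  expect_equal(unname(zone_areas(r)), rep(300 * 300 / 3, 3))
  expect_equal(sum(zone_areas(r)), 300 * 300)

  r1 <- make_study_region(300, 300, 300)
  expect_equal(length(region_pixel_xs(r1)) * length(region_pixel_ys(r1)), 1)

  expect_error(make_study_region(-1, 300, 10), "positive")
  expect_error(make_study_region(300, 300, 0), "positive")

  # every pixel belongs to exactly one zone
  z <- zone_of(r, rep(region_pixel_xs(r), 30), rep(region_pixel_ys(r), each = 30))
  expect_false(anyNA(z))
  expect_setequal(unique(z), names(r$zones))
})

test_that("cluster locations are in-region, sized, and seed-deterministic", {
  r <- make_study_region(300, 300, 10)
  expect_equal(nrow(sample_cluster_locations(r, 0, seed = 1)), 0)

  loc <- sample_cluster_locations(r, 1066, seed = 7)
  expect_equal(nrow(loc), 1066)
  expect_true(all(loc$x > 0 & loc$x < 300 & loc$y > 0 & loc$y < 300))

  loc2 <- sample_cluster_locations(r, 1066, seed = 7)
  expect_identical(loc, loc2)
  expect_false(identical(loc, sample_cluster_locations(r, 1066, seed = 8)))
})

test_that("covariate surfaces respect their physical ranges and determinism", {
  r <- make_study_region(200, 200, 10)
  covs <- simulate_covariate_surfaces(r, seed = 11)
  expect_setequal(names(covs),
                  c("rainfall", "evi", "temperature", "dist_water", "urban"))
  expect_true(all(covs$rainfall$values >= 2 & covs$rainfall$values <= 104))
  expect_true(all(covs$evi$values >= 0 & covs$evi$values <= 1))
  expect_true(all(covs$urban$values %in% c(0, 1)))
  expect_true(all(covs$dist_water$values >= 0))

  covs2 <- simulate_covariate_surfaces(r, seed = 11)
  expect_identical(covs, covs2)
})

test_that("with all structure zeroed, pooled prevalence matches the intercept", {
  r <- make_study_region(300, 300, 10)
  covs <- simulate_covariate_surfaces(r, seed = 2)
  tp <- true_parameters(beta0 = stats::qlogis(0.2),
                        beta = c(rainfall = 0, evi = 0, temperature = 0,
                                 dist_water = 0, urban = 0),
                        spatial_sd = 0,
                        seasonal = c(Jilaal = 0, Gu = 0, Hagaa = 0, Deyr = 0),
                        cluster_sd = 0)
  locs <- sample_cluster_locations(r, 200, seed = 2)
  obs <- simulate_wasting_data(r, locs, covs, tp, years = 2007,
                               n_per_cluster = 100, seed = 2)
  n_children <- sum(obs$n_examined)
  expect_equal(n_children, 200 * 100)
  phat <- sum(obs$n_wasted) / n_children
  se <- sqrt(0.2 * 0.8 / n_children)
  expect_lt(abs(phat - 0.2), 3 * se)
})

test_that("dry-season offsets raise dry-season prevalence", {
  r <- make_study_region(300, 300, 10)
  covs <- simulate_covariate_surfaces(r, seed = 4)
  a <- 0.5
  tp <- true_parameters(beta0 = stats::qlogis(0.2),
                        beta = c(rainfall = 0, evi = 0, temperature = 0,
                                 dist_water = 0, urban = 0),
                        spatial_sd = 0,
                        seasonal = c(Jilaal = a, Gu = -a, Hagaa = a, Deyr = -a),
                        cluster_sd = 0)
  locs <- sample_cluster_locations(r, 300, seed = 4)
  obs <- simulate_wasting_data(r, locs, covs, tp, years = 2007,
                               n_per_cluster = 60, seed = 4)
  expect_gte(sum(obs$n_examined), 10000)
  dry <- obs$season %in% c("Jilaal", "Hagaa")
  p_dry <- sum(obs$n_wasted[dry]) / sum(obs$n_examined[dry])
  p_wet <- sum(obs$n_wasted[!dry]) / sum(obs$n_examined[!dry])
  expect_gt(p_dry, p_wet)
})

test_that("zero random-effect SDs give identical eta at identical covariates", {
  r <- make_study_region(100, 100, 10)
  flat <- pixel_grid(region_pixel_xs(r), region_pixel_ys(r),
                     matrix(5, 10, 10))
  tp <- true_parameters(beta0 = -1, beta = c(rainfall = 0.7),
                        spatial_sd = 0,
                        seasonal = c(Jilaal = 0, Gu = 0, Hagaa = 0, Deyr = 0),
                        cluster_sd = 0)
  locs <- sample_cluster_locations(r, 50, seed = 5)
  obs <- simulate_wasting_data(r, locs, list(rainfall = flat), tp,
                               years = 2007, seed = 5)
  eta <- attr(obs, "truth")$eta
  expect_equal(max(eta) - min(eta), 0, tolerance = 1e-12)

  expect_error(
    simulate_wasting_data(r, locs, list(evi = flat), tp, years = 2007, seed = 5),
    "unknown covariate"
  )
})

test_that("latent field variogram increases with distance up to the range", {
  r <- make_study_region(100, 100, 10)
  mesh <- build_mesh(r, 12, 30)
  fem <- fem_matrices(mesh)
  nv <- nrow(mesh$vertices)
  range_km <- 40
  kappa <- sqrt(8) / range_km
  tau <- 1 / (2 * sqrt(pi) * kappa)
  Q <- spatial_precision(fem, rep(tau, nv), rep(kappa, nv))
  vario <- withr::with_seed(99, {
    W <- gmrf_sample(Q, 8)
    d <- as.matrix(dist(mesh$vertices))
    bins <- cut(d[upper.tri(d)], breaks = c(0, 10, 20, 30, 40))
    semiv <- sapply(seq_len(8), function(k) {
      g <- 0.5 * outer(W[, k], W[, k], function(a, b) (a - b)^2)
      tapply(g[upper.tri(g)], bins, mean)
    })
    rowMeans(semiv)
  })
  expect_true(all(diff(vario) > 0))
})

test_that("population grid allocates the national total exactly", {
  r <- make_study_region(200, 200, 20)
  expect_error(simulate_population_grid(r, -5), ">= 0")
  g0 <- simulate_population_grid(r, 0, seed = 1)
  expect_true(all(g0$values == 0))
  g <- simulate_population_grid(r, 123457, seed = 1)
  expect_equal(sum(g$values), 123457)
  expect_true(all(g$values >= 0))
  expect_identical(g, simulate_population_grid(r, 123457, seed = 1))
})

test_that("generator truth validates its invariants", {
  expect_error(true_parameters(ar_pacf = c(1.2, 0)), "(-1, 1)", fixed = TRUE)
  expect_error(true_parameters(seasonal = c(Jilaal = 1, Gu = 0, Hagaa = 0,
                                            Deyr = 0)), "sum to zero")
  expect_error(true_parameters(spatial_sd = -1), "nonnegative")
})
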