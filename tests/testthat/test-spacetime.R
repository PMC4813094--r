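test_that("parameter fields are exponentiated basis expansions", {
  r <- make_study_region(10, 10, 1)
  m <- build_mesh(r, 3, 0)
  b0 <- parameter_field_basis(m, degree = 0)
  f <- evaluate_parameter_fields(b0, 1.3, -0.4)
  expect_true(all(f$tau == exp(1.3)))
  expect_true(all(f$kappa == exp(-0.4)))

  b1 <- parameter_field_basis(m, degree = 1)
  f1 <- evaluate_parameter_fields(b1, c(0, 0, 0), c(-1, 0.8, 0))
  ord <- order(m$vertices[, 1])
  expect_true(all(diff(f1$kappa[ord][!duplicated(m$vertices[ord, 1])]) > 0))
  # round trip through the log
  expect_lt(max(abs(log(f1$kappa) - as.vector(b1$B_kappa %*% c(-1, 0.8, 0)))),
            1e-12)
  expect_error(evaluate_parameter_fields(b1, c(0, NA, 0), c(0, 0, 0)),
               "non-finite")
  expect_error(evaluate_parameter_fields(b1, c(0, 0), c(0, 0, 0)), "length")
})

test_that("spatial precision is symmetric positive definite and validated", {
  r <- make_study_region(10, 10, 1)
  m <- build_mesh(r, 2, 2)
  fem <- fem_matrices(m)
  nv <- nrow(m$vertices)
  set.seed(2)
  tau <- exp(rnorm(nv, 0, 0.1)); kappa <- exp(rnorm(nv, -0.5, 0.1))
  Q <- spatial_precision(fem, tau, kappa)
  expect_lt(max(abs(as.matrix(Q - Matrix::t(Q)))), 1e-10)
  ev <- eigen(as.matrix(Q), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(spatial_precision(fem, -tau, kappa), "strictly positive")
})

test_that("AR(2) precision reduces to AR(1) and matches Yule-Walker", {
  # AR(1) reduction: pacf2 = 0
  rho <- 0.6
  Q <- as.matrix(ar2_precision(8, c(rho, 0)))
  Q_ar1 <- matrix(0, 8, 8)
  diag(Q_ar1) <- c(1, rep(1 + rho^2, 6), 1)
  for (i in 1:7) Q_ar1[i, i + 1] <- Q_ar1[i + 1, i] <- -rho
  Q_ar1 <- Q_ar1 / (1 - rho^2)
  expect_lt(max(abs(Q - Q_ar1)), 1e-10)

  # dense inverse reproduces the Yule-Walker autocovariances, unit variance
  pac <- c(0.5, 0.2)
  Qt <- ar2_precision(16, pac)
  S <- solve(as.matrix(Qt))
  expect_lt(max(abs(diag(S) - 1)), 1e-8)
  r_yw <- ar2_autocorrelations(pac, 15)
  expect_lt(max(abs(S[1, ] - r_yw)), 1e-8)
  expect_lt(max(abs(S[8, 8:16] - r_yw[1:9])), 1e-8)

  expect_error(ar2_precision(2, pac), ">= 3")
  expect_error(ar2_precision(10, c(1.1, 0)), "nonstationary")
})

test_that("seasonal structure has the increment rank and density", {
  s <- seasonal_structure(16, 4)
  expect_equal(s$rank, 13)
  expect_equal(as.integer(Matrix::rankMatrix(as.matrix(s$S))), 13)
  set.seed(5)
  x <- rnorm(16); tau <- 2.7
  direct <- (13 / 2) * log(tau) -
    (tau / 2) * sum(sapply(1:13, function(i) sum(x[i:(i + 3)])^2))
  expect_equal(seasonal_logdensity(s, x, tau), direct, tolerance = 1e-10)
  # period-4 pattern with zero cycle sum lies in the null space
  xn <- rep(c(2, -1, 1, -2), 4)
  expect_equal(as.numeric(Matrix::crossprod(xn, s$S %*% xn)), 0,
               tolerance = 1e-12)
  expect_error(seasonal_structure(4, 4), "exceed")
})

test_that("Kronecker space-time precision obeys the inverse identity", {
  r <- make_study_region(4, 4, 1)
  m <- build_mesh(r, 2.5, 0)   # <= 20 vertices
  fem <- fem_matrices(m)
  nv <- nrow(m$vertices)
  Qs <- spatial_precision(fem, rep(1, nv), rep(1, nv))
  Qt <- ar2_precision(5, c(0.4, 0.1))
  Qst <- spacetime_precision(Qs, Qt)
  expect_equal(dim(Qst), c(nv * 5L, nv * 5L))
  lhs <- solve(as.matrix(Qst))
  rhs <- kronecker(solve(as.matrix(Qt)), solve(as.matrix(Qs)))
  expect_lt(max(abs(lhs - rhs)), 1e-8)
  expect_error(spacetime_precision(Qs, Qt, max_dim = 10), "exceeds the cap")
})

test_that("sampled space-time fields carry the AR temporal correlation", {
  r <- make_study_region(10, 10, 1)
  m <- build_mesh(r, 4, 4)
  fem <- fem_matrices(m)
  nv <- nrow(m$vertices)
  kappa <- sqrt(8) / 5; tau <- 1 / (2 * sqrt(pi) * kappa)
  Qs <- spatial_precision(fem, rep(tau, nv), rep(kappa, nv))
  pac <- c(0.6, 0.0)
  Qt <- ar2_precision(12, pac)
  Qst <- spacetime_precision(Qs, Qt)
  W <- withr::with_seed(21, gmrf_sample(Qst, 80))
  node <- which.min(rowSums((m$vertices - 5)^2))
  series <- W[node + nv * (0:11), ]      # one node across time, 80 draws
  # pool consecutive-time pairs across draws to estimate the lag-1 correlation
  lag1 <- stats::cor(as.vector(series[-1, ]), as.vector(series[-12, ]))
  expect_lt(abs(lag1 - 0.6), 0.1)
})

test_that("joint precision assembly is exhaustive and positive definite", {
  lay <- latent_layout(p_fixed = 2, n_v = 10, n_t = 4, n_seasonal = 8,
                       n_clusters = 5)
  expect_equal(lay$total, 1 + 2 + 40 + 8 + 5)
  all_idx <- c(lay$intercept, lay$beta, lay$spacetime, lay$seasonal,
               lay$cluster)
  expect_identical(sort(all_idx), seq_len(lay$total))

  # identity blocks with unit priors give (nearly) the identity matrix
  lay0 <- latent_layout(1, 3, 2, 0, 2)
  Q0 <- assemble_joint_precision(lay0, Matrix::Diagonal(6), NULL,
                                 cluster_prec = 1, fixed_prior_prec = 1)
  expect_lt(max(abs(as.matrix(Q0) - diag(lay0$total))), 1e-12)

  s <- seasonal_structure(8, 4)
  m2 <- build_mesh(make_study_region(4, 4, 1), 2.5, 0)
  fem2 <- fem_matrices(m2)
  nv2 <- nrow(m2$vertices)
  lay2 <- latent_layout(2, nv2, 4, 8, 5)
  Qs <- spatial_precision(fem2, rep(1, nv2), rep(1, nv2))
  # dimensions must match the layout
  expect_error(assemble_joint_precision(lay2, Matrix::Diagonal(6), s),
               "space-time block")
  Qst <- spacetime_precision(Qs, ar2_precision(4, c(0.3, 0)))
  Q <- assemble_joint_precision(lay2, Qst, s, cluster_prec = 2,
                                fixed_prior_prec = 1e-4)
  expect_lt(max(abs(as.matrix(Q - Matrix::t(Q)))), 1e-10)
  ch <- Matrix::Cholesky(Q, LDL = FALSE)   # positive definiteness
  expect_s4_class(ch, "CHMfactor")
})
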