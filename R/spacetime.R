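# Structured precision matrices: the (non-stationary) spatial SPDE precision,
# stationary AR(2) temporal precision, their Kronecker space-time product, the
# period-4 seasonal precision, and the assembled joint latent-field precision.

#' Log-linear basis for the spatially varying SPDE parameters
#'
#' The non-stationary model expresses log tau(u) and log kappa(u) as linear
#' combinations of basis functions evaluated at mesh nodes. The default basis
#' is intercept + linear x + linear y (coordinates rescaled to [-1, 1] over
#' the mesh for conditioning); \code{degree = 0} gives the intercept-only
#' (stationary) basis.
#'
#' @param mesh a \code{wm_mesh}.
#' @param degree 0 (intercept only) or 1 (intercept + x + y).
#' @return list with matrices \code{B_tau}, \code{B_kappa} (first column all
#'   ones) of dimension n_v x (1 + p_b).
#' @export
parameter_field_basis <- function(mesh, degree = 1) {
  stopifnot(inherits(mesh, "wm_mesh"), degree %in% c(0, 1))
  v <- mesh$vertices
  B <- matrix(1, nrow(v), 1)
  if (degree == 1) {
    sx <- 2 * (v[, 1] - min(v[, 1])) / max(diff(range(v[, 1])), 1e-12) - 1
    sy <- 2 * (v[, 2] - min(v[, 2])) / max(diff(range(v[, 2])), 1e-12) - 1
    B <- cbind(B, sx, sy)
  }
  colnames(B) <- c("intercept", if (degree == 1) c("x", "y"))
  list(B_tau = B, B_kappa = B)
}

#' Evaluate the tau(u) and kappa(u) parameter fields at mesh nodes
#'
#' @param basis a [parameter_field_basis()] object.
#' @param theta_tau,theta_kappa coefficient vectors on the log scale.
#' @return list with strictly positive vectors \code{tau}, \code{kappa}.
#' @export
evaluate_parameter_fields <- function(basis, theta_tau, theta_kappa) {
  if (!all(is.finite(theta_tau)) || !all(is.finite(theta_kappa))) {
    stop("non-finite basis coefficients")
  }
  if (length(theta_tau) != ncol(basis$B_tau) ||
      length(theta_kappa) != ncol(basis$B_kappa)) {
    stop("coefficient length does not match basis dimension")
  }
  list(tau = exp(as.vector(basis$B_tau %*% theta_tau)),
       kappa = exp(as.vector(basis$B_kappa %*% theta_kappa)))
}

#' SPDE spatial precision matrix
#'
#' The Matern (alpha = 2, i.e. nu = 1 in 2-D) GMRF precision with spatially
#' varying parameter fields: \code{Q = T (K2 C K2 + K2 G1 + G1 K2 + G2) T}
#' with \code{T = diag(tau_i)}, \code{K2 = diag(kappa_i^2)}. In the
#' stationary case the implied field has range \code{sqrt(8)/kappa} and
#' marginal variance \code{1 / (4 pi kappa^2 tau^2)}.
#'
#' @param fem [fem_matrices()] of the mesh.
#' @param tau_i,kappa_i strictly positive parameter fields at mesh nodes.
#' @return sparse symmetric positive-definite matrix.
#' @export
spatial_precision <- function(fem, tau_i, kappa_i) {
  if (any(tau_i <= 0) || any(kappa_i <= 0)) {
    stop("tau and kappa fields must be strictly positive")
  }
  nv <- nrow(fem$G1)
  stopifnot(length(tau_i) == nv, length(kappa_i) == nv)
  Tm <- Matrix::Diagonal(x = tau_i)
  K2 <- Matrix::Diagonal(x = kappa_i^2)
  M <- K2 %*% fem$C %*% K2 + K2 %*% fem$G1 + Matrix::t(fem$G1) %*% K2 + fem$G2
  Q <- Tm %*% M %*% Tm
  Matrix::forceSymmetric((Q + Matrix::t(Q)) / 2)
}

# AR coefficients and innovation variance (unit marginal variance) from
# partial autocorrelations.
ar2_coefficients <- function(pacf) {
  stopifnot(length(pacf) == 2)
  if (any(abs(pacf) >= 1)) stop("nonstationary AR(2): |pacf| must be < 1")
  phi1 <- pacf[1] * (1 - pacf[2])
  phi2 <- pacf[2]
  sigma2 <- (1 - pacf[1]^2) * (1 - pacf[2]^2)
  list(phi = c(phi1, phi2), sigma2 = sigma2)
}

#' Stationary AR(2) precision matrix with unit marginal variance
#'
#' Exact joint precision of a stationary zero-mean AR(2) of length
#' \code{n_t}, parameterized by partial autocorrelations and scaled to unit
#' marginal variance (the field's overall variance is carried by the spatial
#' tau). Banded with bandwidth 2.
#'
#' @param n_t series length (>= 3).
#' @param pacf length-2 partial autocorrelations, each in (-1, 1).
#' @return sparse symmetric positive-definite \code{n_t x n_t} matrix.
#' @export
ar2_precision <- function(n_t, pacf) {
  if (n_t < 3) stop("n_t must be >= 3")
  co <- ar2_coefficients(pacf)
  phi <- co$phi; s2 <- co$sigma2
  n_t <- as.integer(n_t)
  # stationary density factorized as p(x1,x2) * prod_t p(x_t | x_{t-1}, x_{t-2})
  r1 <- pacf[1]  # lag-1 autocorrelation equals the first pacf
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  # precision of the bivariate stationary margin (x1, x2)
  det2 <- 1 - r1^2
  add(1, 1, 1 / det2); add(2, 2, 1 / det2)
  add(1, 2, -r1 / det2); add(2, 1, -r1 / det2)
  # conditional terms: (x_t - phi1 x_{t-1} - phi2 x_{t-2})^2 / s2
  a <- c(-phi[2], -phi[1], 1)
  for (t in 3:n_t) {
    id <- c(t - 2L, t - 1L, t)
    for (p in 1:3) for (q in 1:3) add(id[p], id[q], a[p] * a[q] / s2)
  }
  Qm <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_t, n_t))
  Matrix::forceSymmetric((Qm + Matrix::t(Qm)) / 2)
}

#' Yule-Walker autocorrelations of an AR(2)
#'
#' Closed-form autocorrelation sequence used as the independent check on
#' [ar2_precision()].
#'
#' @param pacf length-2 partial autocorrelations.
#' @param lag_max maximum lag.
#' @return numeric vector of autocorrelations for lags 0..lag_max.
#' @export
ar2_autocorrelations <- function(pacf, lag_max) {
  co <- ar2_coefficients(pacf)
  phi <- co$phi
  r <- numeric(lag_max + 1)
  r[1] <- 1
  if (lag_max >= 1) r[2] <- phi[1] / (1 - phi[2])
  if (lag_max >= 2) {
    for (k in 3:(lag_max + 1)) r[k] <- phi[1] * r[k - 1] + phi[2] * r[k - 2]
  }
  r
}

#' Period-m seasonal structure
#'
#' The seasonal GMRF penalizing m-term moving sums: with D the
#' (n - m + 1) x n matrix whose row i sums x_i..x_{i+m-1}, the structure
#' matrix is \code{S = D'D} and the (improper) log-density is
#' \code{((n - m + 1)/2) log(tau) - (tau/2) x' S x + const}. For quarterly
#' seasons m = 4.
#'
#' @param n component length (> m).
#' @param m period (>= 2), default 4.
#' @return object of class \code{wm_seasonal}: \code{n}, \code{m}, the sparse
#'   structure matrix \code{S}, and its rank \code{n - m + 1}.
#' @export
seasonal_structure <- function(n, m = 4) {
  if (m < 2) stop("m must be >= 2")
  if (n <= m) stop("n must exceed the period m")
  n <- as.integer(n); m <- as.integer(m)
  rows <- n - m + 1L
  D <- Matrix::sparseMatrix(
    i = rep(seq_len(rows), each = m),
    j = as.vector(vapply(seq_len(rows), function(i) i:(i + m - 1L),
                         integer(m))),
    x = 1, dims = c(rows, n)
  )
  S <- Matrix::forceSymmetric(Matrix::crossprod(D))
  structure(list(n = n, m = m, S = S, D = D, rank = rows),
            class = "wm_seasonal")
}

#' Seasonal log-density (up to a constant)
#'
#' @param seasonal a [seasonal_structure()] object.
#' @param x numeric vector of length \code{seasonal$n}.
#' @param tau precision parameter (> 0).
#' @return \code{((n-m+1)/2) log(tau) - (tau/2) x' S x}.
#' @export
seasonal_logdensity <- function(seasonal, x, tau) {
  stopifnot(inherits(seasonal, "wm_seasonal"), tau > 0,
            length(x) == seasonal$n)
  quad <- as.numeric(Matrix::crossprod(x, seasonal$S %*% x))
  (seasonal$rank / 2) * log(tau) - (tau / 2) * quad
}

#' Separable space-time precision (Kronecker product)
#'
#' \code{Q_st = Q_t \%x\% Q_s}; the latent space-time weights are stored
#' space-fastest, i.e. entry \code{(t - 1) n_v + v} is node v at time t.
#'
#' @param Q_s spatial precision (n_v x n_v).
#' @param Q_t temporal precision (n_t x n_t).
#' @param max_dim guard on the product dimension.
#' @return sparse symmetric matrix of dimension n_v * n_t.
#' @export
spacetime_precision <- function(Q_s, Q_t, max_dim = 2e5) {
  d <- nrow(Q_s) * nrow(Q_t)
  if (d > max_dim) {
    stop(sprintf("space-time dimension %d exceeds the cap %d", d, max_dim))
  }
  Matrix::forceSymmetric(Matrix::kronecker(Q_t, Q_s))
}

#' Index layout of the joint latent field
#'
#' @param p_fixed number of covariate fixed effects (excluding intercept).
#' @param n_v,n_t mesh nodes and temporal steps of the space-time block.
#' @param n_seasonal length of the seasonal block (0 for model 1).
#' @param n_clusters number of iid cluster effects.
#' @return object of class \code{wm_layout} with disjoint, exhaustive index
#'   ranges \code{intercept}, \code{beta}, \code{spacetime}, \code{seasonal},
#'   \code{cluster} and \code{total}.
#' @export
latent_layout <- function(p_fixed, n_v, n_t, n_seasonal = 0, n_clusters = 0) {
  sizes <- c(intercept = 1L, beta = as.integer(p_fixed),
             spacetime = as.integer(n_v * n_t),
             seasonal = as.integer(n_seasonal),
             cluster = as.integer(n_clusters))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  ranges <- Map(function(s, e, k) if (k == 0L) integer(0) else s:e,
                starts, ends, sizes)
  structure(c(ranges, list(total = unname(ends[length(ends)]),
                           n_v = as.integer(n_v), n_t = as.integer(n_t))),
            class = "wm_layout")
}

#' Assemble the joint latent precision Q(psi)
#'
#' Block-diagonal over (intercept, beta) with weak Gaussian priors, the
#' space-time weights, the seasonal block, and iid cluster effects. The
#' seasonal block gets a tiny ridge (1e-6) so the assembled matrix is
#' strictly positive definite (the pure seasonal structure matrix is rank
#' n - m + 1).
#'
#' @param layout a [latent_layout()].
#' @param Q_st space-time precision, dimension \code{n_v * n_t} (or NULL if
#'   that block is empty).
#' @param seasonal a [seasonal_structure()] or NULL; scaled by
#'   \code{seasonal_prec}.
#' @param cluster_prec precision of iid cluster effects.
#' @param fixed_prior_prec prior precision of intercept and betas.
#' @param seasonal_prec precision multiplier for the seasonal structure.
#' @return sparse symmetric positive-definite matrix of dimension
#'   \code{layout$total}.
#' @export
assemble_joint_precision <- function(layout, Q_st = NULL, seasonal = NULL,
                                     cluster_prec = 1, fixed_prior_prec = 1e-4,
                                     seasonal_prec = 1) {
  stopifnot(inherits(layout, "wm_layout"))
  blocks <- list()
  nfix <- length(layout$intercept) + length(layout$beta)
  blocks$fixed <- Matrix::Diagonal(nfix, x = fixed_prior_prec)
  if (length(layout$spacetime) > 0) {
    if (is.null(Q_st) || nrow(Q_st) != length(layout$spacetime)) {
      stop("Q_st does not match the layout's space-time block")
    }
    blocks$st <- Q_st
  }
  if (length(layout$seasonal) > 0) {
    if (is.null(seasonal) || seasonal$n != length(layout$seasonal)) {
      stop("seasonal structure does not match the layout's seasonal block")
    }
    blocks$seas <- seasonal_prec * seasonal$S +
      Matrix::Diagonal(seasonal$n, x = 1e-6)
  }
  if (length(layout$cluster) > 0) {
    blocks$clust <- Matrix::Diagonal(length(layout$cluster), x = cluster_prec)
  }
  Q <- Matrix::bdiag(blocks)
  if (nrow(Q) != layout$total) stop("assembled blocks do not match the layout")
  Matrix::forceSymmetric(Q)
}

#' Draw samples from a GMRF with sparse precision Q
#'
#' @param Q sparse symmetric positive-definite precision.
#' @param n number of samples.
#' @return matrix (dim(Q) x n) of samples, or a vector when n = 1.
#' @export
gmrf_sample <- function(Q, n = 1) {
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Q), LDL = FALSE, perm = TRUE)
  d <- nrow(Q)
  z <- matrix(stats::rnorm(d * n), d, n)
  # solve P' L^-T z: x = P^-1 (L')^-1 z with Q = P' L L' P
  y <- Matrix::solve(ch, z, system = "Lt")
  x <- as.matrix(Matrix::solve(ch, y, system = "Pt"))
  if (n == 1) as.vector(x) else x
}
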