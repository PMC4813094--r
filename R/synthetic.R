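# Synthetic-data generator: a fully artificial study (region, covariate
# surfaces, latent fields, cluster survey records, population grid) with the
# statistical structure the downstream model assumes, so the whole pipeline
# is testable without any external data.

#' Generator truth for the synthetic study
#'
#' Bundles the parameters from which synthetic survey data are simulated:
#' intercept and covariate effects on the log-odds scale (covariate effects
#' apply to z-scored surfaces, i.e. per-SD), the Matern field's range and
#' marginal SD, AR(2) partial autocorrelations for the year--season dynamics,
#' sum-to-zero seasonal offsets, and the SD of iid cluster effects.
#'
#' Defaults reflect the study conditions the analysis targets: a pooled
#' prevalence near 21\% (intercept \code{qlogis(0.2133)}), negative rainfall
#' and vegetation effects with a positive temperature effect, null effects
#' for distance-to-water and urbanization, and dry seasons (Jilaal, Hagaa)
#' worse than wet ones (Gu, Deyr).
#'
#' @param beta0 intercept, log-odds.
#' @param beta named covariate effects (log-odds per covariate SD).
#' @param spatial_range Matern correlation range of the latent field, km.
#' @param spatial_sd marginal SD of the latent space-time field, log-odds.
#' @param ar_pacf length-2 partial autocorrelations of the AR(2) year-season
#'   dynamics; each must be strictly inside (-1, 1).
#' @param seasonal named length-4 seasonal log-odds offsets
#'   (Jilaal, Gu, Hagaa, Deyr); must sum to zero.
#' @param cluster_sd SD of iid cluster-level effects, log-odds.
#' @return an object of class \code{wm_true_params}.
#' @export
true_parameters <- function(beta0 = stats::qlogis(0.2133),
                            beta = c(rainfall = -0.30, evi = -0.25,
                                     temperature = 0.20,
                                     dist_water = 0, urban = 0),
                            spatial_range = 100,
                            spatial_sd = 0.30,
                            ar_pacf = c(0.5, 0.1),
                            seasonal = c(Jilaal = 0.035, Gu = -0.035,
                                         Hagaa = 0.025, Deyr = -0.025),
                            cluster_sd = 0.25) {
  stopifnot(length(ar_pacf) == 2)
  if (any(abs(ar_pacf) >= 1)) stop("AR(2) partial autocorrelations must lie in (-1, 1)")
  if (length(seasonal) != 4) stop("seasonal must have 4 entries")
  names(seasonal) <- canonical_season(names(seasonal))
  if (abs(sum(seasonal)) > 1e-8) stop("seasonal offsets must sum to zero")
  if (spatial_sd < 0 || cluster_sd < 0 || spatial_range <= 0) {
    stop("SDs must be nonnegative and spatial_range positive")
  }
  structure(list(beta0 = beta0, beta = beta,
                 spatial_range = spatial_range, spatial_sd = spatial_sd,
                 ar_pacf = ar_pacf,
                 seasonal = seasonal[WM_SEASONS], cluster_sd = cluster_sd),
            class = "wm_true_params")
}

#' Sample cluster locations uniformly inside a region
#'
#' @param region a [make_study_region()] object.
#' @param n_clusters number of clusters (>= 0).
#' @param seed RNG seed; the same seed yields identical coordinates.
#' @return data.frame with columns \code{x}, \code{y} (km), strictly inside
#'   the region.
#' @export
sample_cluster_locations <- function(region, n_clusters, seed = 1) {
  stopifnot(inherits(region, "wm_region"))
  if (n_clusters < 0) stop("n_clusters must be >= 0")
  n_clusters <- as.integer(n_clusters)
  with_seed(seed, {
    eps <- 1e-6 * max(diff(region$xlim), diff(region$ylim))
    data.frame(
      x = stats::runif(n_clusters, region$xlim[1] + eps, region$xlim[2] - eps),
      y = stats::runif(n_clusters, region$ylim[1] + eps, region$ylim[2] - eps)
    )
  })
}

# Smooth low-frequency random surface on a pixel lattice: a sum of random
# plane cosines with wavelengths a sizable fraction of the domain.
smooth_surface <- function(xs, ys, n_waves = 8, wavelength_frac = c(0.4, 1.2)) {
  extent <- max(diff(range(xs)) + 1e-9, diff(range(ys)) + 1e-9)
  vals <- matrix(0, length(xs), length(ys))
  for (k in seq_len(n_waves)) {
    lambda <- extent * stats::runif(1, wavelength_frac[1], wavelength_frac[2])
    omega <- 2 * pi / lambda
    theta <- stats::runif(1, 0, 2 * pi)
    phase <- stats::runif(1, 0, 2 * pi)
    amp <- stats::rnorm(1)
    proj <- outer(cos(theta) * xs, sin(theta) * ys, "+")
    vals <- vals + amp * cos(omega * proj + phase)
  }
  vals
}

rescale_to <- function(m, lo, hi) {
  rng <- range(m)
  if (diff(rng) < 1e-12) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - rng[1]) / diff(rng) * (hi - lo)
}

#' Simulate the five environmental covariate surfaces
#'
#' Smooth low-frequency random fields standing in for seasonal-average
#' rasters: rainfall (mm, clipped to the observed 2--104 mm monthly range),
#' enhanced vegetation index in [0, 1], mean temperature (deg C), distance
#' to water (km, distance to a handful of random water features), and a
#' binary urbanization indicator (top ~5\% of a smooth field).
#'
#' @param region a [make_study_region()] object.
#' @param seed RNG seed.
#' @return named list of [pixel_grid()]s:
#'   \code{rainfall}, \code{evi}, \code{temperature}, \code{dist_water},
#'   \code{urban}.
#' @export
simulate_covariate_surfaces <- function(region, seed = 1) {
  stopifnot(inherits(region, "wm_region"))
  xs <- region_pixel_xs(region); ys <- region_pixel_ys(region)
  with_seed(seed, {
    rainfall <- rescale_to(smooth_surface(xs, ys), 2, 104)
    evi <- rescale_to(smooth_surface(xs, ys), 0.05, 0.9)
    temperature <- rescale_to(smooth_surface(xs, ys), 18, 34)
    n_water <- 4L
    wx <- stats::runif(n_water, region$xlim[1], region$xlim[2])
    wy <- stats::runif(n_water, region$ylim[1], region$ylim[2])
    dw <- matrix(Inf, length(xs), length(ys))
    for (k in seq_len(n_water)) {
      dw <- pmin(dw, sqrt(outer((xs - wx[k])^2, (ys - wy[k])^2, "+")))
    }
    uf <- smooth_surface(xs, ys, n_waves = 12, wavelength_frac = c(0.15, 0.5))
    urban <- (uf >= stats::quantile(uf, 0.95)) * 1
    list(
      rainfall = pixel_grid(xs, ys, rainfall),
      evi = pixel_grid(xs, ys, evi),
      temperature = pixel_grid(xs, ys, temperature),
      dist_water = pixel_grid(xs, ys, dw),
      urban = pixel_grid(xs, ys, urban)
    )
  })
}

# z-score covariate values against the pixel distribution of their surface,
# so generator effects are per-SD and selection/fitting see a stable scale.
standardize_against_grid <- function(values, grid) {
  mu <- mean(grid$values); sdv <- stats::sd(as.vector(grid$values))
  if (sdv < 1e-12) return(values * 0)
  (values - mu) / sdv
}

#' Simulate cluster-level wasting survey records
#'
#' Each cluster is surveyed at one (year, season): years are assigned with
#' probabilities mirroring the survey effort profile (36/27/22/14\% over four
#' years when \code{length(years) == 4}, else uniform), seasons uniformly.
#' The true log-odds at a cluster is the sum of the intercept, per-SD
#' covariate effects, one draw of a separable space--time Gaussian field
#' (Matern-SPDE in space, stationary AR(2) over the 4 x n_years year--season
#' axis), the seasonal offset of its season, and an iid cluster effect;
#' wasted counts are Binomial(n_examined, plogis(eta)).
#'
#' @param region a [make_study_region()] object.
#' @param locations data.frame with \code{x}, \code{y} from
#'   [sample_cluster_locations()].
#' @param covariates named list of covariate [pixel_grid()]s.
#' @param true_params a [true_parameters()] object; every name in
#'   \code{true_params$beta} must exist in \code{covariates}.
#' @param years contiguous integer years, e.g. \code{2007:2010}.
#' @param n_per_cluster children examined per cluster: a length-2 range for
#'   uniform draws (default 30--120) or a single fixed count.
#' @param seed RNG seed.
#' @param year_probs optional year-assignment probabilities.
#' @return data.frame of cluster observations (columns \code{cluster_id},
#'   \code{x_km}, \code{y_km}, \code{year}, \code{season},
#'   \code{n_examined}, \code{n_wasted}, then raw covariate columns), with
#'   the generating linear predictor attached as \code{attr(, "truth")}.
#' @export
simulate_wasting_data <- function(region, locations, covariates, true_params,
                                  years = 2007:2010,
                                  n_per_cluster = c(30, 120), seed = 1,
                                  year_probs = NULL) {
  stopifnot(inherits(region, "wm_region"), inherits(true_params, "wm_true_params"))
  if (!all(names(true_params$beta) %in% names(covariates))) {
    missing_cov <- setdiff(names(true_params$beta), names(covariates))
    stop("unknown covariate name(s) in beta: ", paste(missing_cov, collapse = ", "))
  }
  n <- nrow(locations)
  if (any(locations$x < region$xlim[1] | locations$x > region$xlim[2] |
          locations$y < region$ylim[1] | locations$y > region$ylim[2])) {
    stop("all locations must lie inside the region")
  }
  years <- sort(unique(as.integer(years)))
  n_years <- length(years)
  n_t <- 4L * n_years
  if (is.null(year_probs)) {
    year_probs <- if (n_years == 4) c(0.36, 0.27, 0.22, 0.14) else rep(1, n_years)
  }
  year_probs <- year_probs / sum(year_probs)

  with_seed(seed, {
    year <- years[sample.int(n_years, n, replace = TRUE, prob = year_probs)]
    season <- sample(WM_SEASONS, n, replace = TRUE)
    t_idx <- 4L * (year - years[1]) + match(season, WM_SEASONS)  # 1..n_t

    # covariate values (raw) and standardized contributions
    covvals <- lapply(covariates, grid_lookup, x = locations$x, y = locations$y)
    eta <- rep(true_params$beta0, n)
    for (nm in names(true_params$beta)) {
      z <- standardize_against_grid(covvals[[nm]], covariates[[nm]])
      eta <- eta + true_params$beta[[nm]] * z
    }

    # separable space-time latent field, marginal SD = spatial_sd
    st <- rep(0, n)
    if (true_params$spatial_sd > 0 && n > 0) {
      kappa <- sqrt(8) / true_params$spatial_range
      tau <- 1 / (2 * sqrt(pi) * kappa * true_params$spatial_sd)
      max_edge <- max(true_params$spatial_range / 2,
                      min(diff(region$xlim), diff(region$ylim)) / 15)
      mesh <- build_mesh(region, max_edge_km = max_edge,
                         buffer_km = true_params$spatial_range)
      fem <- fem_matrices(mesh)
      nv <- nrow(mesh$vertices)
      Qs <- spatial_precision(fem, rep(tau, nv), rep(kappa, nv))
      Qt <- if (n_t >= 3 && any(true_params$ar_pacf != 0)) {
        ar2_precision(n_t, true_params$ar_pacf)
      } else {
        Matrix::Diagonal(n_t)
      }
      Qst <- spacetime_precision(Qs, Qt)
      w <- gmrf_sample(Qst, 1)
      A <- projection_matrix(mesh, cbind(locations$x, locations$y))
      Wmat <- matrix(w, nrow = nv, ncol = n_t)  # space fastest
      st <- vapply(seq_len(n), function(i) {
        sum(A[i, ] %*% Wmat[, t_idx[i]])
      }, numeric(1))
    }
    eta <- eta + st

    eta <- eta + unname(true_params$seasonal[season])
    clust_eff <- stats::rnorm(n, 0, true_params$cluster_sd)
    eta <- eta + clust_eff

    n_ex <- if (length(n_per_cluster) == 1) {
      rep(as.integer(n_per_cluster), n)
    } else {
      as.integer(floor(stats::runif(n, n_per_cluster[1], n_per_cluster[2] + 1)))
    }
    p <- stats::plogis(eta)
    n_w <- stats::rbinom(n, n_ex, p)

    out <- data.frame(
      cluster_id = sprintf("c%04d", seq_len(n)),
      x_km = locations$x, y_km = locations$y,
      year = year, season = season,
      n_examined = n_ex, n_wasted = n_w,
      stringsAsFactors = FALSE
    )
    for (nm in names(covariates)) out[[nm]] <- covvals[[nm]]
    attr(out, "truth") <- list(eta = eta, spacetime = st,
                               cluster_effect = clust_eff, t_idx = t_idx,
                               params = true_params, years = years)
    out
  })
}

#' Simulate an under-five population grid
#'
#' Allocates a national under-five total to pixels with a smooth lognormal
#' intensity plus urban concentration; pixel counts are a multinomial draw,
#' so they sum to the total exactly.
#'
#' @param region a [make_study_region()] object.
#' @param total_under5 total children under five (>= 0).
#' @param seed RNG seed.
#' @return a [pixel_grid()] of nonnegative integer counts.
#' @export
simulate_population_grid <- function(region, total_under5, seed = 1) {
  stopifnot(inherits(region, "wm_region"))
  if (total_under5 < 0) stop("total_under5 must be >= 0")
  xs <- region_pixel_xs(region); ys <- region_pixel_ys(region)
  with_seed(seed, {
    f <- smooth_surface(xs, ys, n_waves = 10, wavelength_frac = c(0.2, 0.8))
    w <- exp(1.5 * (f - mean(f)) / max(stats::sd(as.vector(f)), 1e-12))
    counts <- if (total_under5 == 0) {
      matrix(0, length(xs), length(ys))
    } else {
      matrix(stats::rmultinom(1, size = total_under5,
                              prob = as.vector(w))[, 1],
             length(xs), length(ys))
    }
    pixel_grid(xs, ys, counts)
  })
}
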