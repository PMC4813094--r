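# De-clustered hold-out split and the four predictive-performance indices.

#' Space-time de-clustered hold-out split
#'
#' Stratifies observations by (year, season) crossed with spatial blocks
#' (k-means on coordinates, k = ceiling(1/fraction)) and samples the test set
#' proportionally from each non-empty stratum (largest-remainder allocation),
#' so held-out points are spread over space and time rather than clumped.
#' Test size is exactly \code{round(fraction * N)}.
#'
#' @param observations cluster data frame with \code{x_km}, \code{y_km},
#'   \code{year}, \code{season}.
#' @param fraction test fraction in (0, 1); default 0.10.
#' @param seed RNG seed.
#' @return list with \code{train}, \code{test} (disjoint, exhaustive) and
#'   \code{meta} (seed, fraction, block count, strata sizes).
#' @export
spatiotemporal_holdout <- function(observations, fraction = 0.10, seed = 1) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- nrow(observations)
  if (n < 10) stop("need at least 10 observations to split")
  k <- as.integer(ceiling(1 / fraction))
  n_test <- round(fraction * n)

  with_seed(seed, {
    xy <- cbind(observations$x_km, observations$y_km)
    k_eff <- min(k, nrow(unique(xy)))
    block <- if (k_eff > 1) {
      stats::kmeans(xy, centers = k_eff, nstart = 3, iter.max = 50)$cluster
    } else rep(1L, n)
    strata <- interaction(observations$year,
                          canonical_season(observations$season),
                          block, drop = TRUE)
    sizes <- table(strata)
    # largest-remainder proportional allocation of n_test over strata
    quota <- n_test * as.numeric(sizes) / n
    alloc <- floor(quota)
    rem <- n_test - sum(alloc)
    if (rem > 0) {
      extra <- order(quota - alloc, decreasing = TRUE)[seq_len(rem)]
      alloc[extra] <- alloc[extra] + 1L
    }
    alloc <- pmin(alloc, as.numeric(sizes))
    deficit <- n_test - sum(alloc)
    if (deficit > 0) {   # redistribute if any stratum was capped
      room <- as.numeric(sizes) - alloc
      for (i in order(room, decreasing = TRUE)) {
        if (deficit == 0) break
        add <- min(room[i], deficit)
        alloc[i] <- alloc[i] + add
        deficit <- deficit - add
      }
    }
    test_idx <- integer(0)
    lv <- levels(strata)
    for (i in seq_along(lv)) {
      members <- which(strata == lv[i])
      if (alloc[i] > 0) {
        test_idx <- c(test_idx, sample(members, alloc[i]))
      }
    }
    test_idx <- sort(test_idx)
    list(
      train = observations[setdiff(seq_len(n), test_idx), , drop = FALSE],
      test = observations[test_idx, , drop = FALSE],
      meta = list(seed = seed, fraction = fraction, n = n,
                  n_test = length(test_idx), k_blocks = k_eff,
                  n_strata = length(lv))
    )
  })
}

#' Predictive-performance indices
#'
#' Errors are predicted minus observed. Reports the root-mean-square error,
#' mean (signed) prediction error, mean absolute prediction error and the
#' Pearson correlation between predicted and observed. When either vector is
#' constant the correlation is undefined and reported as NA with a flag.
#'
#' @param observed,predicted equal-length nonzero numeric vectors (cluster
#'   proportions).
#' @return list of class \code{wm_validation}: \code{rmse}, \code{me},
#'   \code{mae}, \code{correlation}, \code{n}, \code{correlation_defined}.
#' @export
validation_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0) {
    stop("observed and predicted must be nonzero equal-length vectors")
  }
  err <- predicted - observed
  const <- stats::sd(observed) < 1e-14 || stats::sd(predicted) < 1e-14
  structure(list(
    rmse = sqrt(mean(err^2)),
    me = mean(err),
    mae = mean(abs(err)),
    correlation = if (const) NA_real_ else stats::cor(observed, predicted),
    correlation_defined = !const,
    n = length(observed)
  ), class = "wm_validation")
}

#' @export
print.wm_validation <- function(x, ...) {
  cat(sprintf("<wm_validation> n = %d: RMSE %.4f, ME %.4f, MAE %.4f, r %s\n",
              x$n, x$rmse, x$me, x$mae,
              if (x$correlation_defined) sprintf("%.4f", x$correlation)
              else "NA (constant input)"))
  invisible(x)
}

#' Hold-out validation of a fitted model
#'
#' Convenience wrapper: predicts held-out cluster proportions from a fit on
#' the training data and computes [validation_metrics()] against observed
#' proportions \code{n_wasted / n_examined}. Held-out clusters are predicted
#' as new locations (cluster effect at its prior mean of zero).
#'
#' @param fit a [laplace_fit()] on the training data.
#' @param test held-out cluster data frame.
#' @return a [validation_metrics()] result.
#' @export
validate_fit <- function(fit, test) {
  stopifnot(inherits(fit, "wm_fit"))
  eta <- predict_eta_clusters(fit, test)
  validation_metrics(test$n_wasted / test$n_examined, stats::plogis(eta))
}

# Linear predictor for new cluster records (cluster effect = 0).
predict_eta_clusters <- function(fit, obs) {
  st <- fit$structures
  config <- fit$config
  lay <- st$layout
  obs$season <- canonical_season(obs$season)
  if (any(!(obs$year %in% st$years))) {
    stop("test years outside the fitted range")
  }
  si <- match(obs$season, WM_SEASONS)
  ys <- 4L * (obs$year - st$years[1]) + si
  t_ar <- if (config$model == 1) ys else obs$year - st$years[1] + 1L
  A_sp <- projection_matrix(st$mesh, cbind(obs$x_km, obs$y_km))
  n <- nrow(obs)
  eta <- rep(fit$mean[lay$intercept], n)
  for (j in seq_along(config$covariates)) {
    nm <- config$covariates[j]
    z <- (obs[[nm]] - st$centers[[nm]]) / st$scales[[nm]]
    eta <- eta + fit$mean[lay$beta[j]] * z
  }
  W <- matrix(fit$mean[lay$spacetime], nrow = lay$n_v, ncol = st$n_t)
  field <- vapply(seq_len(n), function(i) {
    as.numeric(A_sp[i, , drop = FALSE] %*% W[, t_ar[i]])
  }, numeric(1))
  eta <- eta + field
  if (config$model == 2) {
    eta <- eta + fit$mean[lay$seasonal[1] - 1L + ys]
  }
  eta
}
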