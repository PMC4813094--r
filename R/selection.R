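# Extended-BIC best-subset covariate selection for the binomial GLM.

#' Fit a binomial (logit) GLM by iteratively reweighted least squares
#'
#' Direct IRLS implementation with the logit link for grouped binomial data.
#' The residual deviance is twice the saturated-minus-fitted log-likelihood.
#' Non-convergence (including complete separation) is flagged, never silent.
#'
#' @param design_matrix n x q numeric matrix, full column rank (include the
#'   intercept column explicitly).
#' @param successes,trials integer vectors, \code{0 <= successes <= trials}.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   relative deviance change.
#' @return object of class \code{wm_glm}: \code{coefficients} (named),
#'   \code{deviance}, \code{n_obs}, \code{converged}, \code{fitted},
#'   \code{vcov}, \code{iterations}.
#' @export
fit_binomial_glm <- function(design_matrix, successes, trials,
                             max_iter = 50, tol = 1e-10) {
  X <- as.matrix(design_matrix)
  y <- as.numeric(successes); n <- as.numeric(trials)
  if (nrow(X) != length(y) || length(y) != length(n)) {
    stop("design matrix, successes and trials must align")
  }
  if (any(y < 0) || any(y > n)) stop("need 0 <= successes <= trials")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  beta <- rep(0, ncol(X))
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  XtWX <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- n * mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - n * mu) / w
    XtWX <- crossprod(X, X * w)
    beta_new <- tryCatch(solve(XtWX, crossprod(X, w * z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta <- as.vector(beta_new)
    dev <- binomial_deviance(y, n, stats::plogis(as.vector(X %*% beta)))
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  dev <- binomial_deviance(y, n, mu)
  # complete separation shows up as coefficients drifting off to +-Inf while
  # the deviance plateaus; flag anything far beyond a plausible log-odds scale
  if (max(abs(beta)) > 12) converged <- FALSE
  vc <- tryCatch(solve(crossprod(X, X * pmax(n * mu * (1 - mu), 1e-10))),
                 error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    deviance = dev, n_obs = length(y), converged = converged,
    fitted = mu, vcov = vc, iterations = iter
  ), class = "wm_glm")
}

binomial_deviance <- function(y, n, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  term <- function(a, b) ifelse(a > 0, a * log(a / b), 0)
  2 * sum(term(y, n * mu) + term(n - y, n * (1 - mu)))
}

#' Extended Bayesian information criterion
#'
#' \code{BIC_gamma = D + k log(n) + 2 gamma log(choose(p, k))}: deviance plus
#' the classical BIC penalty plus the extended penalty corresponding to a
#' uniform prior over models of fixed size. \code{gamma = 0} recovers the
#' classical BIC.
#'
#' @param D residual deviance.
#' @param k number of covariates in the model (intercept not counted).
#' @param n number of observations (>= 1).
#' @param p number of candidate covariates.
#' @param gamma nonnegative extended-penalty weight.
#' @return the criterion value.
#' @export
ebic <- function(D, k, n, p, gamma = 1) {
  if (k > p) stop("k cannot exceed p")
  if (k < 0 || n < 1 || gamma < 0) stop("invalid ebic arguments")
  if (!is.finite(D)) return(Inf)
  D + k * log(n) + 2 * gamma * lchoose(p, k)
}

#' Best-subset covariate selection by extended BIC
#'
#' Exhaustively fits all 2^p subsets of the candidate covariates (intercept
#' always included, covariates standardized to zero mean / unit SD before
#' fitting), scores each with [ebic()], and returns the minimizer. Ties are
#' broken by smaller subset size, then lexicographic subset order. Subsets
#' whose fit fails to converge are scored +Inf and flagged in the table.
#'
#' @param data cluster data frame with columns \code{n_examined},
#'   \code{n_wasted} and the candidate covariate columns.
#' @param candidate_covariates character vector (<= 20) of column names.
#' @param gamma extended-BIC weight, default 1.
#' @return object of class \code{wm_selection}: \code{table} (one row per
#'   subset: subset label, k, deviance, ebic, converged), \code{chosen}
#'   (character vector of selected covariates), \code{gamma},
#'   \code{chosen_fit}, and the standardization parameters
#'   (\code{centers}, \code{scales}).
#' @export
select_best_subset <- function(data, candidate_covariates, gamma = 1) {
  p <- length(candidate_covariates)
  if (p > 20) stop("exhaustive enumeration supports at most 20 candidates")
  if (!all(candidate_covariates %in% names(data))) {
    stop("candidate covariate(s) missing from data: ",
         paste(setdiff(candidate_covariates, names(data)), collapse = ", "))
  }
  Xall <- as.matrix(data[candidate_covariates])
  centers <- colMeans(Xall)
  scales <- apply(Xall, 2, stats::sd)
  scales[scales < 1e-12] <- 1
  Xstd <- sweep(sweep(Xall, 2, centers), 2, scales, "/")
  y <- data$n_wasted; n <- data$n_examined
  nobs <- nrow(data)

  subsets <- lapply(0:p, function(k) {
    if (k == 0) list(integer(0)) else
      utils::combn(p, k, simplify = FALSE)
  })
  subsets <- unlist(subsets, recursive = FALSE)

  rows <- vector("list", length(subsets))
  fits <- vector("list", length(subsets))
  for (s in seq_along(subsets)) {
    id <- subsets[[s]]
    X <- cbind(`(Intercept)` = 1, Xstd[, id, drop = FALSE])
    fit <- tryCatch(fit_binomial_glm(X, y, n), error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged
    D <- if (!is.null(fit)) fit$deviance else NA_real_
    score <- if (ok) ebic(D, length(id), nobs, p, gamma) else Inf
    rows[[s]] <- data.frame(
      subset = paste(candidate_covariates[id], collapse = "+"),
      k = length(id), deviance = D, ebic = score, converged = ok,
      stringsAsFactors = FALSE
    )
    fits[[s]] <- fit
  }
  tab <- do.call(rbind, rows)
  # minimizer; ties -> smaller k, then lexicographic subset label
  ord <- order(tab$ebic, tab$k, tab$subset)
  best <- ord[1]
  structure(list(
    table = tab,
    chosen = candidate_covariates[subsets[[best]]],
    chosen_score = tab$ebic[best],
    chosen_fit = fits[[best]],
    gamma = gamma, n_obs = nobs,
    centers = centers, scales = scales
  ), class = "wm_selection")
}

#' @export
print.wm_selection <- function(x, ...) {
  cat(sprintf("<wm_selection> gamma = %g over %d subsets\n",
              x$gamma, nrow(x$table)))
  cat("chosen:", if (length(x$chosen)) paste(x$chosen, collapse = ", ")
      else "(intercept only)", sprintf(" [ebic = %.2f]\n", x$chosen_score))
  invisible(x)
}
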