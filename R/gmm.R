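# Full-covariance Gaussian mixture fitted by EM with seeded k-means++
# restarts. Small dimensionality (2-4 ICs), possibly many voxels; the
# E step works in log space with log-sum-exp.

.kmeanspp_centers <- function(x, k) {
  m <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(m, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  if (k > 1) {
    for (j in 2:k) {
      p <- d2 / sum(d2)
      i <- sample.int(m, 1, prob = p)
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

.log_dmvnorm <- function(x, mean, cov) {
  d <- ncol(x)
  ch <- chol(cov)
  logdet <- 2 * sum(log(diag(ch)))
  xc <- sweep(x, 2, mean)
  q <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + logdet + colSums(q^2))
}

.gmm_em <- function(x, k, reg, max_iter, tol) {
  m <- nrow(x); d <- ncol(x)
  km <- suppressWarnings(
    stats::kmeans(x, centers = .kmeanspp_centers(x, k), iter.max = 50,
                  algorithm = "Lloyd"))
  means <- km$centers
  covs <- array(0, c(d, d, k))
  weights <- as.numeric(table(factor(km$cluster, levels = 1:k))) / m
  weights <- pmax(weights, 1e-6); weights <- weights / sum(weights)
  gcov <- stats::cov(x) + diag(reg, d)
  for (j in 1:k) {
    idx <- which(km$cluster == j)
    covs[, , j] <- if (length(idx) > d + 1) {
      stats::cov(x[idx, , drop = FALSE]) + diag(reg, d)
    } else gcov
  }
  loglik <- -Inf
  loglik_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lp <- vapply(1:k, function(j) {
      log(weights[j]) + .log_dmvnorm(x, means[j, ], covs[, , j])
    }, numeric(m))
    if (is.null(dim(lp))) lp <- matrix(lp, nrow = 1)
    mx <- do.call(pmax, as.data.frame(lp))
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    weights <- nk / m
    for (j in 1:k) {
      means[j, ] <- colSums(resp[, j] * x) / nk[j]
      xc <- sweep(x, 2, means[j, ])
      covs[, , j] <- crossprod(xc * sqrt(resp[, j])) / nk[j] + diag(reg, d)
    }
    if (is.finite(loglik) && abs(ll - loglik) < tol * abs(ll)) {
      loglik <- ll
      break
    }
    loglik <- ll
  }
  list(weights = weights, means = means, covs = covs, loglik = loglik,
       loglik_trace = loglik_trace, n_iter = it)
}

#' Fit a full-covariance Gaussian mixture model in IC space
#'
#' EM with `n_init` seeded k-means++ initial restarts (best final
#' log-likelihood wins) and a small diagonal covariance regularization.
#' Restart sampling is made invariant to row order by drawing the initial
#' centres after a canonical lexicographic sort of the data.
#'
#' @param x matrix of IC scores (voxels x components).
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param n_init number of restarts.
#' @param max_iter,tol EM controls.
#' @param reg diagonal covariance regularization.
#' @return object of class `stx_gmm` with weights, means, covariances,
#'   log-likelihood and BIC (`-2 logL + npar log m`; lower is better).
#' @export
fit_gmm <- function(x, k = 5, seed = 1, n_init = 10, max_iter = 500,
                    tol = 1e-6, reg = 1e-6) {
  x <- as.matrix(x)
  m <- nrow(x); d <- ncol(x)
  stopifnot(k >= 1, m > k * (d + 1))
  ord <- do.call(order, as.data.frame(x))
  xs <- x[ord, , drop = FALSE]
  if (k == 1) {
    best <- list(weights = 1, means = matrix(colMeans(x), 1, d),
                 covs = array(stats::cov(x) + diag(reg, d), c(d, d, 1)),
                 loglik = NA_real_, loglik_trace = numeric(0), n_iter = 0)
    best$loglik <- sum(.log_dmvnorm(x, best$means[1, ], best$covs[, , 1]))
    best$loglik_trace <- best$loglik
  } else {
    best <- NULL
    for (i in seq_len(n_init)) {
      set.seed(seed + i - 1)
      fit <- .gmm_em(xs, k, reg, max_iter, tol)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  }
  npar <- (k - 1) + k * d + k * d * (d + 1) / 2
  structure(list(
    k = k, d = d, weights = best$weights, means = best$means,
    covs = best$covs, loglik = best$loglik,
    loglik_trace = best$loglik_trace,
    bic = -2 * best$loglik + npar * log(m),
    n_obs = m, seed = seed
  ), class = "stx_gmm")
}

#' @export
print.stx_gmm <- function(x, ...) {
  cat(sprintf("stx_gmm: %d clusters in %dD, logL = %.1f, BIC = %.1f\n",
              x$k, x$d, x$loglik, x$bic))
  invisible(x)
}

#' Posterior cluster membership under a fitted GMM
#'
#' @param model an `stx_gmm`.
#' @param x matrix of IC scores.
#' @return list with `cluster` (hard assignment) and `posterior`
#'   (voxels x k responsibilities).
#' @export
predict_gmm <- function(model, x) {
  stopifnot(inherits(model, "stx_gmm"))
  x <- as.matrix(x)
  m <- nrow(x)
  lp <- vapply(1:model$k, function(j) {
    log(model$weights[j]) + .log_dmvnorm(x, model$means[j, ],
                                         model$covs[, , j])
  }, numeric(m))
  if (is.null(dim(lp))) lp <- matrix(lp, nrow = 1)
  mx <- do.call(pmax, as.data.frame(lp))
  post <- exp(lp - (mx + log(rowSums(exp(lp - mx)))))
  list(cluster = max.col(lp), posterior = post)
}

#' Select the number of clusters by the BIC gradient
#'
#' Fits mixtures for k = 1..`k_max` and examines the BIC improvements
#' `max(BIC(k-1) - BIC(k), 0)`, which drop sharply towards zero at the
#' optimal count and stay flat after (beyond it the parameter penalty
#' dominates and BIC stops decreasing). The selected k is the smallest for
#' which every later improvement is below `f` times the largest
#' improvement; if BIC never improves, k = 1.
#'
#' @param x matrix of IC scores.
#' @param k_max maximum cluster count.
#' @param seed RNG seed.
#' @param f flatness threshold (fraction of the maximum |dBIC|).
#' @param n_init restarts per k.
#' @return list with `k`, the `bic` vector, and the `dbic` increments.
#' @export
select_n_clusters_bic <- function(x, k_max = 10, seed = 1, f = 0.05,
                                  n_init = 3) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 20 * k_max)
  bic <- vapply(1:k_max, function(k) {
    fit_gmm(x, k = k, seed = seed, n_init = n_init)$bic
  }, numeric(1))
  dbic <- diff(bic)
  imp <- pmax(-dbic, 0)    # improvement of k over k-1, indexed by k = 2..
  if (max(imp) == 0) {
    return(list(k = 1L, bic = bic, dbic = dbic))
  }
  thr <- f * max(imp)
  ks <- 1:(k_max - 1)
  flat_after <- vapply(1:k_max, function(k) {
    all(imp[ks >= k] < thr) || k == k_max
  }, logical(1))
  k_star <- which(flat_after)[1]
  if (k_star > 1 && any(imp[seq_len(k_star - 1)] < thr)) {
    warning("BIC improvements are not monotone in k; selected k = ",
            k_star, " may be unstable")
  }
  list(k = k_star, bic = bic, dbic = dbic)
}
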