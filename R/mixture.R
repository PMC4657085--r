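#' Fit a one-dimensional normal mixture by expectation-maximization
#'
#' EM with k-means initialization plus randomized restarts. Components are
#' returned sorted by ascending mean. For `k = 1` the closed-form maximum
#' likelihood fit is returned.
#'
#' @param x Numeric data vector (n >= 2).
#' @param k Number of components.
#' @param restarts Number of random restarts (the first uses plain k-means).
#' @param seed RNG seed for the restarts.
#' @param equal_var Constrain all components to a common variance (default
#'   TRUE). With a few hundred points and strongly overlapping components
#'   the heteroscedastic fit is weakly identified and its component means
#'   wander; the homoscedastic fit is the stabler estimator of the peak
#'   positions.
#' @param max_iter,tol EM stopping controls.
#' @return A list: `means`, `sds`, `weights` (ascending-mean order),
#'   `loglik`, `bic`, `k`.
#' @export
fit_normal_mixture <- function(x, k = 2L, restarts = 50L, seed = 1L,
                               equal_var = TRUE, max_iter = 500L, tol = 1e-8) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  if (k == 1L) {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    sigma <- max(sigma, 1e-8)
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    return(list(means = mu, sds = sigma, weights = 1, loglik = ll,
                bic = -2 * ll + 2 * log(n), k = 1L))
  }
  set.seed(as.integer(seed))
  sd_floor <- max(stats::sd(x) * 1e-3, 1e-8)
  run_em <- function(mu, sigma, w) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j)
        w[j] * stats::dnorm(x, mu[j], sigma[j]), numeric(n))
      rowsum_ <- rowSums(dens)
      rowsum_[rowsum_ < 1e-300] <- 1e-300
      ll <- sum(log(rowsum_))
      r <- dens / rowsum_
      nk <- colSums(r)
      if (any(nk < 1e-8)) return(NULL) # collapsed component
      w <- nk / n
      mu <- colSums(r * x) / nk
      if (equal_var) {
        s2 <- sum(vapply(seq_len(k), function(j)
          sum(r[, j] * (x - mu[j])^2), numeric(1))) / n
        sigma <- rep(max(sqrt(s2), sd_floor), k)
      } else {
        sigma <- sqrt(vapply(seq_len(k), function(j)
          sum(r[, j] * (x - mu[j])^2) / nk[j], numeric(1)))
        sigma <- pmax(sigma, sd_floor)
      }
      if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    list(means = mu, sds = sigma, weights = w, loglik = ll)
  }
  best <- NULL
  km <- tryCatch(stats::kmeans(x, centers = k, nstart = 5),
                 error = function(e) NULL)
  inits <- vector("list", restarts)
  if (!is.null(km)) {
    inits[[1]] <- list(
      mu = as.numeric(km$centers),
      sigma = pmax(vapply(seq_len(k), function(j) {
        xs <- x[km$cluster == j]
        if (length(xs) > 1) stats::sd(xs) else sd_floor
      }, numeric(1)), sd_floor),
      w = as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
    )
  }
  for (r in seq_len(restarts)) {
    if (!is.null(inits[[r]])) next
    inits[[r]] <- list(mu = sample(x, k), sigma = rep(max(stats::sd(x), sd_floor), k),
                       w = rep(1 / k, k))
  }
  for (init in inits) {
    fit <- run_em(init$mu, init$sigma, init$w)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("EM failed to fit the mixture")
  ord <- order(best$means)
  p <- if (equal_var) 2 * k else 3 * k - 1 # means + sds + free weights
  list(means = best$means[ord], sds = best$sds[ord],
       weights = best$weights[ord], loglik = best$loglik,
       bic = -2 * best$loglik + p * log(n), k = as.integer(k))
}
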