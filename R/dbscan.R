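#' Density-based clustering of 2D points (DBSCAN)
#'
#' Plain DBSCAN: a point is a core point if it has at least `min_pts`
#' neighbours (itself included) within `eps`; clusters are the connected
#' components of core points, plus border points attached to the first core
#' cluster that reaches them; everything else is noise (label 0).
#'
#' @param x Numeric n x 2 (or n x d) matrix of point coordinates.
#' @param eps Neighbourhood radius, same units as `x`.
#' @param min_pts Minimum neighbourhood size for a core point.
#' @return Integer vector of cluster labels (0 = noise).
#' @export
dbscan_points <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0) return(integer(0))
  if (eps <= 0) stop("eps must be positive")
  d <- as.matrix(stats::dist(x))
  nb <- d <= eps
  n_neigh <- rowSums(nb)
  core <- n_neigh >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      neighbours <- which(nb[p, ])
      for (q in neighbours) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}
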