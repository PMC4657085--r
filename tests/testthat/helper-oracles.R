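# Independent oracles used by the writhe and energy tests. These never call
# the package's Gauss-integral writhe; agreement between the two routes is
# what the tests establish.

# Quasi-uniform directions on the sphere (Fibonacci lattice).
fibonacci_sphere <- function(n_dirs) {
  k <- seq_len(n_dirs) - 0.5
  phi <- acos(1 - 2 * k / n_dirs)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Writhe as the average signed crossing number of the projection of the
# closed polygon over many viewing directions.
writhe_projection_oracle <- function(verts, n_dirs = 1200) {
  verts <- as.matrix(verts)
  n <- nrow(verts)
  nxt <- c(2:n, 1)
  pr <- which(outer(seq_len(n), seq_len(n),
                    function(i, j) j > i + 1 & !(i == 1 & j == n)),
              arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  dirs <- fibonacci_sphere(n_dirs)
  total <- 0
  for (d in seq_len(n_dirs)) {
    u <- dirs[d, ]
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * u) * u
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    x <- as.numeric(verts %*% e1)
    y <- as.numeric(verts %*% e2)
    h <- as.numeric(verts %*% u)
    d1x <- x[nxt[i]] - x[i]; d1y <- y[nxt[i]] - y[i]
    d2x <- x[nxt[j]] - x[j]; d2y <- y[nxt[j]] - y[j]
    den <- d1x * d2y - d1y * d2x
    wx <- x[j] - x[i]; wy <- y[j] - y[i]
    ok <- abs(den) > 1e-14
    t <- (wx * d2y - wy * d2x) / den
    s <- (wx * d1y - wy * d1x) / den
    crossing <- ok & t > 0 & t < 1 & s > 0 & s < 1
    if (any(crossing)) {
      h1 <- h[i] + t * (h[nxt[i]] - h[i])
      h2 <- h[j] + s * (h[nxt[j]] - h[j])
      total <- total + sum(sign(den[crossing]) *
                           sign((h1 - h2)[crossing]))
    }
  }
  total / n_dirs
}

# Random closed equal-segment chains: a circle scrambled by random
# closure-preserving crankshaft rotations (no Metropolis, no energies).
random_closed_chain <- function(n = 50, n_moves = 200, radius = 100,
                                seed = 1) {
  set.seed(seed)
  th <- 2 * pi * (seq_len(n) - 1) / n
  v <- cbind(radius * cos(th), radius * sin(th), 0)
  for (m in seq_len(n_moves)) {
    i <- sample.int(n, 1)
    sep <- sample(2:(n - 2), 1)
    jj <- (i + sep - 1) %% n + 1
    ax <- v[jj, ] - v[i, ]
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, -pi / 3, pi / 3)
    ca <- cos(ang); sa <- sin(ang)
    for (s in seq_len(sep - 1)) {
      vv <- (i + s - 1) %% n + 1
      r <- v[vv, ] - v[i, ]
      axr <- c(ax[2] * r[3] - ax[3] * r[2],
               ax[3] * r[1] - ax[1] * r[3],
               ax[1] * r[2] - ax[2] * r[1])
      v[vv, ] <- v[i, ] + r * ca + axr * sa + ax * sum(ax * r) * (1 - ca)
    }
  }
  v
}

# Chain fixtures are shared across test files; build them once per session.
fixture_env <- new.env()
get_fixtures <- function() {
  if (is.null(fixture_env$fx)) fixture_env$fx <- gen_fixture_chains()
  fixture_env$fx
}
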