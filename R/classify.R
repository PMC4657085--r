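#' Count crossings of a chain projected onto its best-fit plane
#'
#' Projects the closed chain onto the least-squares plane of its vertices
#' (principal components 1-2), intersects every non-adjacent projected
#' segment pair, and assigns each crossing a sign from the handedness of the
#' over/under pass.
#'
#' @param chain A `chain_conformation` or n x 3 vertex matrix.
#' @return A list with `n_crossings`, `signed_sum`, and the projected
#'   coordinates (`xy`, n x 2) and residual height (`z`).
#' @export
projected_crossings <- function(chain) {
  verts <- if (inherits(chain, "chain_conformation")) chain$vertices
           else as.matrix(chain)
  n <- nrow(verts)
  ctr <- colMeans(verts)
  vc <- sweep(verts, 2, ctr)
  pc <- svd(vc, nu = 0, nv = 3)$v
  xy <- vc %*% pc[, 1:2, drop = FALSE]
  z <- as.numeric(vc %*% pc[, 3])
  nx <- 0L
  ss <- 0
  nxt <- c(2:n, 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1) next
      if (i == 1 && j == n) next
      p <- xy[i, ]; p2 <- xy[nxt[i], ]
      q <- xy[j, ]; q2 <- xy[nxt[j], ]
      d1 <- p2 - p; d2 <- q2 - q
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      if (abs(den) < 1e-14) next
      w <- q - p
      t <- (w[1] * d2[2] - w[2] * d2[1]) / den
      u <- (w[1] * d1[2] - w[2] * d1[1]) / den
      if (t > 0 && t < 1 && u > 0 && u < 1) {
        nx <- nx + 1L
        z1 <- z[i] + t * (z[nxt[i]] - z[i])
        z2 <- z[j] + u * (z[nxt[j]] - z[j])
        # sign convention: handedness of (over, under) segment directions
        ss <- ss + sign(den) * sign(z1 - z2)
      }
    }
  }
  list(n_crossings = nx, signed_sum = ss, xy = xy, z = z)
}

#' Classify a chain conformation into a packaging stage and spool count
#'
#' Heuristic mirror of the AFM staging of auto-packaging plasmids: the chain
#' is projected onto its best-fit plane, crossings are counted, and segment
#' midpoints are clustered by density into "lobes" (candidate spools).
#' Stage rules (module constants, calibrated on constructed fixtures):
#' stage 0 when at most 2 crossings and a single lobe; stages 1-3 by
#' crossing bins 3-4, 5-6, 7-9; stage 4 and above additionally requires
#' exactly two lobes each holding at least 30% of segments (the symmetric
#' dual spool, stage 5 when crossings exceed 9). The spool count is the
#' number of lobes containing at least 20% of the segments; when density
#' clustering finds no dense lobe the chain is treated as one diffuse lobe.
#'
#' @param chain A `chain_conformation`.
#' @param lobe_eps_factor Lobe clustering radius as a fraction of the
#'   segment length, default 0.6 (stacked circles within a spool sit far
#'   closer than one segment length; consecutive midpoints of a loose ring
#'   do not).
#' @param lobe_min_pts DBSCAN min_pts for lobe detection, default 3.
#' @return A list with `stage` (0-5), `spool_count`, `n_crossings`,
#'   `lobe_fractions`.
#' @export
classify_conformation <- function(chain, lobe_eps_factor = 0.6,
                                  lobe_min_pts = 3L) {
  stopifnot(inherits(chain, "chain_conformation"))
  pr <- projected_crossings(chain)
  n <- nrow(chain$vertices)
  nxt <- c(2:n, 1)
  mids <- (pr$xy + pr$xy[nxt, , drop = FALSE]) / 2
  eps <- lobe_eps_factor * chain$segment_length_nm
  labels <- dbscan_points(mids, eps, lobe_min_pts)
  if (all(labels == 0L)) {
    lobe_frac <- 1 # no dense lobe: one diffuse lobe holding everything
  } else {
    tab <- tabulate(labels[labels > 0L])
    lobe_frac <- tab / n
    if (sum(tab) < 0.5 * n) lobe_frac <- 1 # mostly unclustered: diffuse
  }
  spool_count <- sum(lobe_frac >= 0.20)
  cx <- pr$n_crossings
  two_balanced <- length(lobe_frac) == 2 && all(lobe_frac >= 0.30)
  stage <- if (cx <= 2 && length(lobe_frac) == 1) 0L
  else if (two_balanced && cx > 9) 5L
  else if (two_balanced) 4L
  else if (cx <= 4) 1L
  else if (cx <= 6) 2L
  else if (cx <= 9) 3L
  else 3L
  list(stage = stage, spool_count = spool_count, n_crossings = cx,
       lobe_fractions = lobe_frac)
}
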