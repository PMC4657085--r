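#' Read PALM localization tables into per-cell localization sets
#'
#' Expects two CSV files: a localization table with columns `cell_id`,
#' `frame`, `x_um`, `y_um`, `precision_nm` and a cell-outline table with
#' columns `cell_id`, `length_um`, `diameter_um`, `cx_um`, `cy_um`,
#' `angle_deg`. Points are registered into the cell frame (origin at the
#' cell centroid, x along the major axis).
#'
#' @param locs_path Path to the localization CSV.
#' @param cells_path Path to the cell-outline CSV.
#' @return A named list of `localization_set` objects, one per cell_id, each
#'   a list with `cell_id`, `points` (n x 2 matrix, cell frame, um),
#'   `precision_nm`, `frame`, and `cell` (length_um, diameter_um).
#' @export
read_localizations <- function(locs_path, cells_path) {
  locs <- utils::read.csv(locs_path, stringsAsFactors = FALSE)
  cells <- utils::read.csv(cells_path, stringsAsFactors = FALSE)
  need_l <- c("cell_id", "frame", "x_um", "y_um", "precision_nm")
  need_c <- c("cell_id", "length_um", "diameter_um", "cx_um", "cy_um",
              "angle_deg")
  if (!all(need_l %in% names(locs)))
    stop("localization CSV must have columns: ", paste(need_l, collapse = ", "))
  if (!all(need_c %in% names(cells)))
    stop("cell CSV must have columns: ", paste(need_c, collapse = ", "))
  ids <- unique(locs$cell_id)
  missing <- setdiff(ids, cells$cell_id)
  if (length(missing) > 0)
    stop("no cell outline for cell_id(s): ", paste(missing, collapse = ", "))
  out <- lapply(as.character(unique(cells$cell_id)), function(id) {
    cr <- cells[cells$cell_id == id, ][1, ]
    lr <- locs[locs$cell_id == id, , drop = FALSE]
    a <- -cr$angle_deg * pi / 180
    rot <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
    pts <- cbind(lr$x_um - cr$cx_um, lr$y_um - cr$cy_um) %*% t(rot)
    colnames(pts) <- c("x_um", "y_um")
    list(cell_id = id, points = pts, precision_nm = lr$precision_nm,
         frame = lr$frame,
         cell = list(length_um = cr$length_um, diameter_um = cr$diameter_um))
  })
  names(out) <- as.character(unique(cells$cell_id))
  out[names(out) %in% as.character(ids)]
}

#' Detect clusters in a localization set by density
#'
#' DBSCAN on the 2D localizations: clusters smaller than
#' `min_cluster_size` localizations are discarded along with noise. Zero
#' clusters is a valid result. Clusters are sorted by centroid x along the
#' cell's major axis.
#'
#' @param locs A localization set (from [read_localizations()] or
#'   [gen_cell()]), or a bare n x 2 matrix of points in um.
#' @param eps_nm DBSCAN neighbourhood radius, nm. Default 30 (about half the
#'   cluster spread: small enough that two clusters separated by ~4 sigma do
#'   not bridge, large enough that a 300-localization cluster is one dense
#'   component; tuned on the synthetic generator).
#' @param min_pts DBSCAN core threshold. Default 15.
#' @param min_cluster_size Minimum localizations per reported cluster.
#'   Default 50.
#' @return A data.frame (class `cluster_set`) with columns `cluster_id`,
#'   `cx_um`, `cy_um`, `n_localizations`, `radius_of_gyration_um`.
#' @export
detect_clusters <- function(locs, eps_nm = 30, min_pts = 15,
                            min_cluster_size = 50) {
  pts <- if (is.list(locs) && !is.null(locs$points)) locs$points
         else as.matrix(locs)
  if (nrow(pts) == 0) {
    out <- data.frame(cluster_id = integer(), cx_um = numeric(),
                      cy_um = numeric(), n_localizations = integer(),
                      radius_of_gyration_um = numeric())
    class(out) <- c("cluster_set", "data.frame")
    return(out)
  }
  labels <- dbscan_points(pts, eps_nm / 1000, min_pts)
  keep <- setdiff(unique(labels), 0L)
  rows <- lapply(keep, function(cl) {
    p <- pts[labels == cl, , drop = FALSE]
    if (nrow(p) < min_cluster_size) return(NULL)
    ctr <- colMeans(p)
    rg <- sqrt(mean(rowSums(sweep(p, 2, ctr)^2)))
    data.frame(cx_um = ctr[1], cy_um = ctr[2],
               n_localizations = nrow(p), radius_of_gyration_um = rg)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(cluster_id = integer(), cx_um = numeric(),
                      cy_um = numeric(), n_localizations = integer(),
                      radius_of_gyration_um = numeric())
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$cx_um), , drop = FALSE]
    out <- cbind(cluster_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
  }
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Centroid-to-centroid distances between detected clusters
#'
#' @param clusters A `cluster_set` (>= 2 rows).
#' @param which `"consecutive"` for neighbours in axis order (the clusters
#'   are already sorted by x) or `"all"` for every unordered pair.
#' @return Numeric vector of distances, um.
#' @export
pair_distances <- function(clusters, which = c("consecutive", "all")) {
  which <- match.arg(which)
  if (nrow(clusters) < 2) stop("need at least 2 clusters")
  xy <- as.matrix(clusters[, c("cx_um", "cy_um")])
  if (which == "consecutive") {
    d <- sqrt(rowSums((xy[-1, , drop = FALSE] -
                       xy[-nrow(xy), , drop = FALSE])^2))
  } else {
    d <- as.numeric(stats::dist(xy))
  }
  unname(d)
}

#' Angle at the middle of three clusters
#'
#' The vertex is the cluster with the intermediate axial (x) position; the
#' angle between the rays to the two flanking centroids is returned in
#' degrees, in (0, 180].
#'
#' @param clusters A `cluster_set` with exactly 3 rows.
#' @return Angle in degrees.
#' @export
cluster_angle <- function(clusters) {
  if (nrow(clusters) != 3) stop("need exactly 3 clusters")
  xy <- as.matrix(clusters[, c("cx_um", "cy_um")])
  ord <- order(xy[, 1])
  v <- xy[ord[2], ]
  a <- xy[ord[1], ] - v
  b <- xy[ord[3], ] - v
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) stop("coincident centroids: angle undefined")
  deg <- acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
  if (deg <= 0) deg <- 180 # antipodal numerical edge
  deg
}

#' Summarize a distance sample, with mixture-peak detection
#'
#' Reports mean and SD (n-1 denominator) and fits 1- and 2-component normal
#' mixtures by EM (k-means initialization, 50 restarts, fixed seed),
#' selecting the model by BIC with ties broken toward fewer components.
#' `peaks_um` holds the component means of the selected model, ascending.
#'
#' @param distances Numeric vector of distances, um (n >= 2).
#' @param restarts,seed Passed to [fit_normal_mixture()].
#' @return A list (class `distance_summary`): `n`, `mean_um`, `sd_um`,
#'   `peaks_um`, `mixture_weights`, `bic` (named, both models),
#'   `fit1`, `fit2`.
#' @export
summarize_distances <- function(distances, restarts = 50L, seed = 1L) {
  x <- as.numeric(distances)
  if (length(x) < 2) stop("need at least 2 distances")
  fit1 <- fit_normal_mixture(x, k = 1L)
  fit2 <- if (stats::sd(x) > 0)
    tryCatch(fit_normal_mixture(x, k = 2L, restarts = restarts, seed = seed),
             error = function(e) NULL)
  else NULL
  use2 <- !is.null(fit2) && fit2$bic < fit1$bic
  sel <- if (use2) fit2 else fit1
  structure(
    list(n = length(x), mean_um = mean(x), sd_um = stats::sd(x),
         peaks_um = sel$means, mixture_weights = sel$weights,
         bic = c(k1 = fit1$bic, k2 = if (is.null(fit2)) NA_real_ else fit2$bic),
         fit1 = fit1, fit2 = fit2),
    class = "distance_summary"
  )
}

#' Classify a cell into a division-cycle phase from its clusters
#'
#' Rule table over the detected cluster count and cell length, mirroring the
#' slow-growth cycle: two clusters in a short cell are newborn (`"i"`, or
#' `"ii"` once the parental cluster has shrunk to less than half the size of
#' its partner); three clusters mark active replication (`"iii"`); two
#' clusters in a long cell are the post-replication pair (`"iv"`); at most
#' one detectable cluster mid-cycle is the smeared phase (`"v"`); four
#' clusters close the cycle (`"vi"`).
#'
#' @param clusters A `cluster_set`.
#' @param cell_length_um Cell length, um.
#' @param short_max_um Upper cell length for phases i/ii (default 2.5).
#' @param long_min_um Lower cell length for phase iv (default 2.6; lengths
#'   in the open gap are split at the midpoint).
#' @return Phase label, one of "i".."vi" (NA when no rule applies).
#' @export
classify_phase <- function(clusters, cell_length_um,
                           short_max_um = 2.5, long_min_um = 2.6) {
  k <- nrow(clusters)
  cut <- (short_max_um + long_min_um) / 2
  if (k == 3) return("iii")
  if (k == 4) return("vi")
  if (k <= 1) return("v")
  if (k == 2) {
    if (cell_length_um < cut) {
      sizes <- sort(clusters$n_localizations)
      return(if (sizes[2] / max(sizes[1], 1) > 2) "ii" else "i")
    }
    return("iv")
  }
  NA_character_
}

#' Reduce a cluster-count series to its mode string
#'
#' Runs shorter than `min_run` consecutive time points are treated as
#' detection flicker and removed; zero counts (no detectable clusters, the
#' smeared phase) are dropped; the remaining series is run-length encoded
#' and joined with hyphens.
#'
#' @param counts Integer vector of cluster counts over time.
#' @param min_run Minimum run length to keep, default 2.
#' @param drop_zero Drop zero-count frames before encoding, default TRUE.
#' @return Mode string such as `"2-3-2-4"`.
#' @export
mode_string <- function(counts, min_run = 2L, drop_zero = TRUE) {
  x <- as.integer(counts)
  if (drop_zero) x <- x[x != 0L]
  if (length(x) == 0) return("")
  r <- rle(x)
  keep <- r$lengths >= min_run
  vals <- r$values[keep]
  if (length(vals) == 0) return("")
  r2 <- rle(vals) # merge runs that became adjacent after filtering
  paste(r2$values, collapse = "-")
}

#' Track clusters across a time series of cluster sets
#'
#' Greedy nearest-neighbour matching between consecutive frames with a
#' distance gate: unmatched new clusters start lineages, unmatched old ones
#' end theirs.
#'
#' @param series A list of `cluster_set` objects, ordered in time.
#' @param gate_um Maximum centroid displacement to match, default 0.4.
#' @return A data.frame with columns `lineage`, `frame`, `cx_um`, `cy_um`,
#'   `n_localizations`.
#' @export
track_clusters <- function(series, gate_um = 0.4) {
  if (length(series) < 2) stop("need at least 2 time points")
  lineage_of <- NULL # lineage id per cluster of the previous frame
  next_lineage <- 0L
  rows <- list()
  for (f in seq_along(series)) {
    cs <- series[[f]]
    k <- nrow(cs)
    lin <- rep(NA_integer_, k)
    if (f == 1L || is.null(lineage_of) || length(lineage_of) == 0) {
      if (k > 0) {
        lin <- next_lineage + seq_len(k)
        next_lineage <- next_lineage + k
      }
    } else if (k > 0) {
      prev <- series[[f - 1L]]
      d <- outer(seq_len(nrow(prev)), seq_len(k), Vectorize(function(i, j)
        sqrt((prev$cx_um[i] - cs$cx_um[j])^2 +
             (prev$cy_um[i] - cs$cy_um[j])^2)))
      d[d > gate_um] <- NA
      while (any(!is.na(d))) {
        ij <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)[1, ]
        lin[ij[2]] <- lineage_of[ij[1]]
        d[ij[1], ] <- NA
        d[, ij[2]] <- NA
      }
      for (j in which(is.na(lin))) {
        next_lineage <- next_lineage + 1L
        lin[j] <- next_lineage
      }
    }
    if (k > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = lin, frame = f, cx_um = cs$cx_um, cy_um = cs$cy_um,
        n_localizations = cs$n_localizations)
    }
    lineage_of <- lin
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$lineage, out$frame), , drop = FALSE]
}
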