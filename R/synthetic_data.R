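#' Phase parameters for the localization-set generator
#'
#' Bundles the statistical description of one cell-cycle phase under one
#' growth condition: number of clusters, the separation model (normal or
#' two-component normal mixture, um), the angle model for three-cluster
#' layouts, cluster spread, localization counts, background density and the
#' cell geometry. `phase_params()` returns the built-in defaults:
#'
#' * slow growth, phase i: 2 clusters, separation ~ N(0.88, 0.10) um,
#'   cell length 1.7-2.5 um (phase ii identical, with a shrunken parental
#'   cluster);
#' * slow iii: 3 clusters, adjacent separation ~ N(0.70, 0.10), near-collinear
#'   angle ~ N(180, 10) truncated to (0, 180];
#' * slow iv: 2 clusters, separation from the mixture 0.6 N(1.41, 0.09) +
#'   0.4 N(1.65, 0.09) (overall mean 1.506, SD ~0.15), length 2.6-3.7 um;
#' * slow v: diffuse sub-threshold signal, no detectable cluster;
#' * slow vi: 4 clusters as two pairs at the quarter positions;
#' * fast newborn: 3 clusters, adjacent separation ~ N(0.43, 0.11), angle
#'   uniform in (40, 180) degrees (bilobed sister masses);
#' * fast old: 3 clusters, adjacent separation ~ N(0.70, 0.20), angle
#'   uniform in (40, 180) — the distal distance arises geometrically by the
#'   law of cosines rather than being drawn;
#' * fast single: 1 cluster at midcell (the docked single spool).
#'
#' @param condition `"slow"` or `"fast"`.
#' @param phase Phase label: `"i"`..`"vi"` (slow), or `"newborn"`, `"old"`,
#'   `"single"` (fast).
#' @param ... Overrides for any returned field.
#' @return A list of class `phase_params`.
#' @export
phase_params <- function(condition = c("slow", "fast"), phase = "i", ...) {
  condition <- match.arg(condition)
  base <- list(
    condition = condition, phase = phase,
    cluster_sigma_nm = 60, locs_per_cluster = 300,
    precision_nm = 25, background_per_um2 = 2,
    cell_diameter_um = if (condition == "slow") 0.9 else 1.0,
    angle_model = NULL, cluster_size_factors = NULL
  )
  key <- paste(condition, phase)
  preset <- switch(
    key,
    "slow i" = list(n_clusters = 2L,
                    separation_model = list(type = "normal", mean = 0.88, sd = 0.10),
                    cell_length_range_um = c(1.7, 2.5)),
    "slow ii" = list(n_clusters = 2L,
                     separation_model = list(type = "normal", mean = 0.88, sd = 0.10),
                     cell_length_range_um = c(1.7, 2.5),
                     cluster_size_factors = c(1, 0.35)),
    "slow iii" = list(n_clusters = 3L,
                      separation_model = list(type = "normal", mean = 0.70, sd = 0.10),
                      angle_model = list(type = "normal", mean = 180, sd = 10),
                      cell_length_range_um = c(2.2, 3.0),
                      cluster_size_factors = c(0.7, 1, 0.7)),
    "slow iv" = list(n_clusters = 2L,
                     separation_model = list(type = "mixture",
                                             weights = c(0.6, 0.4),
                                             means = c(1.41, 1.65),
                                             sds = c(0.09, 0.09)),
                     cell_length_range_um = c(2.6, 3.7)),
    "slow v" = list(n_clusters = 0L,
                    separation_model = list(type = "normal", mean = 1.0, sd = 0.1),
                    cell_length_range_um = c(2.8, 3.7)),
    "slow vi" = list(n_clusters = 4L,
                     separation_model = list(type = "normal", mean = 0.60, sd = 0.08),
                     cell_length_range_um = c(3.0, 3.7)),
    "fast newborn" = list(n_clusters = 3L,
                          separation_model = list(type = "normal", mean = 0.43, sd = 0.11),
                          angle_model = list(type = "uniform", min = 40, max = 180),
                          cell_length_range_um = c(2.0, 3.0)),
    "fast old" = list(n_clusters = 3L,
                      separation_model = list(type = "normal", mean = 0.70, sd = 0.20),
                      angle_model = list(type = "uniform", min = 40, max = 180),
                      cell_length_range_um = c(2.5, 3.5)),
    "fast single" = list(n_clusters = 1L,
                         separation_model = list(type = "normal", mean = 0, sd = 0),
                         cell_length_range_um = c(2.0, 3.0)),
    stop("unknown condition/phase combination: ", key)
  )
  params <- utils::modifyList(base, preset)
  params <- utils::modifyList(params, list(...))
  if (params$separation_model$type == "mixture" &&
      abs(sum(params$separation_model$weights) - 1) > 1e-9)
    stop("mixture weights must sum to 1")
  class(params) <- "phase_params"
  params
}

draw_separation <- function(model) {
  if (model$type == "normal") {
    stats::rnorm(1, model$mean, model$sd)
  } else {
    j <- sample.int(length(model$weights), 1, prob = model$weights)
    stats::rnorm(1, model$means[j], model$sds[j])
  }
}

draw_angle_deg <- function(model) {
  if (is.null(model)) return(180)
  if (model$type == "uniform") return(stats::runif(1, model$min, model$max))
  for (i in 1:100) {
    a <- stats::rnorm(1, model$mean, model$sd)
    if (a > 0 && a <= 180) return(a)
    if (a > 180) return(360 - a) # fold at the collinear boundary
  }
  180
}

in_spherocylinder <- function(pts, length_um, diameter_um) {
  r <- diameter_um / 2
  hl <- length_um / 2 - r # half-length of the cylindrical body
  x <- pts[, 1]; y <- pts[, 2]
  body <- abs(x) <= hl & abs(y) <= r
  caps <- (abs(x) > hl) & ((abs(x) - hl)^2 + y^2 <= r^2)
  body | caps
}

spherocylinder_area <- function(length_um, diameter_um) {
  r <- diameter_um / 2
  (length_um - diameter_um) * diameter_um + pi * r^2
}

# Cluster centre layout for one cell; returns a k x 2 matrix plus the drawn
# separations (consecutive, along the layout) and the angle (3-cluster only).
layout_centres <- function(params, length_um) {
  k <- params$n_clusters
  if (k == 0L) { # smeared phase: no localized cluster
    return(list(centres = matrix(numeric(0), 0, 2), separations = numeric(0),
                angle_deg = NA_real_))
  }
  if (k == 1L) {
    return(list(centres = matrix(0, 1, 2), separations = numeric(0),
                angle_deg = NA_real_))
  }
  if (k == 2L) {
    s <- draw_separation(params$separation_model)
    if (s <= 0) return(NULL)
    centres <- cbind(c(-s / 2, s / 2), c(0, 0))
    return(list(centres = centres, separations = s, angle_deg = NA_real_))
  }
  if (k == 3L) {
    s1 <- draw_separation(params$separation_model)
    s2 <- draw_separation(params$separation_model)
    if (s1 <= 0 || s2 <= 0) return(NULL)
    th <- draw_angle_deg(params$angle_model) * pi / 180
    # middle cluster is the vertex; rays at +/- theta/2 about the -y bisector
    d1 <- c(-sin(th / 2), -cos(th / 2))
    d2 <- c(sin(th / 2), -cos(th / 2))
    h <- mean(c(s1, s2)) * cos(th / 2) / 2 # centre the triangle radially
    mid <- c(0, h)
    centres <- rbind(mid + s1 * d1, mid, mid + s2 * d2)
    return(list(centres = centres, separations = c(s1, s2),
                angle_deg = th * 180 / pi))
  }
  if (k == 4L) {
    s1 <- draw_separation(params$separation_model)
    s2 <- draw_separation(params$separation_model)
    if (s1 <= 0 || s2 <= 0) return(NULL)
    q <- length_um / 4
    centres <- cbind(c(-q - s1 / 2, -q + s1 / 2, q - s2 / 2, q + s2 / 2),
                     rep(0, 4))
    return(list(centres = centres, separations = c(s1, s2), angle_deg = NA_real_))
  }
  stop("unsupported n_clusters: ", k)
}

#' Generate one synthetic PALM cell
#'
#' Draws a cell length, places cluster centres according to the phase's
#' layout (symmetric about midcell), scatters `locs_per_cluster`
#' localizations per cluster (isotropic normal cluster spread plus normal
#' localization error), adds uniform background over the spherocylinder,
#' and discards points falling outside the cell. The generating truth
#' (centres, separations, angle) is recorded alongside.
#'
#' @param params A [phase_params()].
#' @param seed Integer seed; identical seeds give identical cells.
#' @param cell_id Identifier stored in the outputs.
#' @return A list with `locs` (a localization set: `cell_id`, `points` in
#'   the cell frame, `precision_nm`, `frame`, `cell`) and `truth` (a list:
#'   centres, separations, angle_deg, phase, n_clusters, seed).
#' @export
gen_cell <- function(params, seed = 1L, cell_id = "cell1") {
  stopifnot(inherits(params, "phase_params"))
  set.seed(as.integer(seed))
  length_um <- stats::runif(1, params$cell_length_range_um[1],
                            params$cell_length_range_um[2])
  d <- params$cell_diameter_um
  margin_x <- 0.15
  margin_y <- 0.10
  lay <- NULL
  for (attempt in 1:100) {
    cand <- layout_centres(params, length_um)
    if (is.null(cand)) next
    ok <- all(abs(cand$centres[, 1]) <= length_um / 2 - margin_x) &&
          all(abs(cand$centres[, 2]) <= d / 2 - margin_y)
    if (ok) { lay <- cand; break }
  }
  if (is.null(lay))
    stop("could not place clusters inside the cell after 100 attempts")
  k <- params$n_clusters
  sigma_c <- params$cluster_sigma_nm / 1000
  sigma_p <- params$precision_nm / 1000
  size_f <- params$cluster_size_factors
  if (is.null(size_f)) size_f <- rep(1, max(k, 1))
  pts <- NULL
  if (k > 0) {
    pts <- do.call(rbind, lapply(seq_len(k), function(j) {
      m <- round(params$locs_per_cluster * size_f[j])
      cbind(stats::rnorm(m, lay$centres[j, 1], sigma_c),
            stats::rnorm(m, lay$centres[j, 2], sigma_c))
    }))
  } else {
    # smeared phase: broad diffuse blobs, below the detection density
    for (ctr in list(c(-0.5, 0), c(0.5, 0))) {
      pts <- rbind(pts, cbind(stats::rnorm(150, ctr[1], 0.4),
                              stats::rnorm(150, ctr[2], 0.4)))
    }
  }
  # localization error on top of the molecular spread
  pts <- pts + cbind(stats::rnorm(nrow(pts), 0, sigma_p),
                     stats::rnorm(nrow(pts), 0, sigma_p))
  n_bg <- stats::rpois(1, params$background_per_um2 *
                            spherocylinder_area(length_um, d))
  if (n_bg > 0) {
    bg <- matrix(numeric(0), 0, 2)
    while (nrow(bg) < n_bg) {
      cand <- cbind(stats::runif(2 * n_bg, -length_um / 2, length_um / 2),
                    stats::runif(2 * n_bg, -d / 2, d / 2))
      bg <- rbind(bg, cand[in_spherocylinder(cand, length_um, d), , drop = FALSE])
    }
    pts <- rbind(pts, bg[seq_len(n_bg), , drop = FALSE])
  }
  keep <- in_spherocylinder(pts, length_um, d)
  pts <- pts[keep, , drop = FALSE]
  colnames(pts) <- c("x_um", "y_um")
  locs <- list(cell_id = cell_id, points = pts,
               precision_nm = rep(params$precision_nm, nrow(pts)),
               frame = seq_len(nrow(pts)),
               cell = list(length_um = length_um, diameter_um = d))
  truth <- list(cell_id = cell_id, phase = params$phase,
                condition = params$condition,
                n_clusters = k, centres = lay$centres,
                separations = lay$separations, angle_deg = lay$angle_deg,
                cell_length_um = length_um, seed = as.integer(seed))
  list(locs = locs, truth = truth)
}

#' Generate a synthetic cell population, optionally writing pipeline CSVs
#'
#' Each cell is generated with [gen_cell()] under the phase defaults for the
#' requested condition, placed at a random position and orientation in the
#' field of view, and (when `out_dir` is given) written in the cluster
#' pipeline's CSV dialect: `locs.csv`, `cells.csv` and a `truth.csv` table
#' of generator ground truth.
#'
#' @param n_cells Number of cells (>= 1).
#' @param condition `"slow"` or `"fast"`.
#' @param phase Phase label understood by [phase_params()].
#' @param seed Integer master seed; per-cell seeds are drawn from it.
#' @param out_dir Output directory, or `NULL` to skip file output.
#' @param params Optional [phase_params()] override.
#' @return A list with `cells` (list of per-cell `gen_cell()` results),
#'   `truth` (data.frame: cell_id, phase, n_clusters, mean_separation,
#'   angle_deg, cell_length_um), and `files` (named paths or NULL).
#' @export
gen_population <- function(n_cells, condition = "slow", phase = "i",
                           seed = 1L, out_dir = NULL, params = NULL) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (is.null(params)) params <- phase_params(condition, phase)
  set.seed(as.integer(seed))
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  cells <- lapply(seq_len(n_cells), function(j) {
    gen_cell(params, seed = cell_seeds[j],
             cell_id = sprintf("cell%04d", j))
  })
  truth <- do.call(rbind, lapply(cells, function(cl) {
    t <- cl$truth
    data.frame(cell_id = t$cell_id, phase = t$phase,
               n_clusters = t$n_clusters,
               mean_separation = if (length(t$separations) > 0)
                 mean(t$separations) else NA_real_,
               angle_deg = t$angle_deg,
               cell_length_um = t$cell_length_um)
  }))
  files <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    set.seed(as.integer(seed))
    loc_rows <- list()
    cell_rows <- list()
    for (j in seq_len(n_cells)) {
      cl <- cells[[j]]
      ctr <- stats::runif(2, 0, 100)
      ang <- stats::runif(1, 0, 360)
      a <- ang * pi / 180
      rot <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
      lab <- cl$locs$points %*% t(rot)
      lab <- sweep(lab, 2, ctr, `+`)
      loc_rows[[j]] <- data.frame(
        cell_id = cl$locs$cell_id, frame = cl$locs$frame,
        x_um = lab[, 1], y_um = lab[, 2],
        precision_nm = cl$locs$precision_nm)
      cell_rows[[j]] <- data.frame(
        cell_id = cl$locs$cell_id,
        length_um = cl$locs$cell$length_um,
        diameter_um = cl$locs$cell$diameter_um,
        cx_um = ctr[1], cy_um = ctr[2], angle_deg = ang)
    }
    files <- list(locs = file.path(out_dir, "locs.csv"),
                  cells = file.path(out_dir, "cells.csv"),
                  truth = file.path(out_dir, "truth.csv"))
    utils::write.csv(do.call(rbind, loc_rows), files$locs, row.names = FALSE)
    utils::write.csv(do.call(rbind, cell_rows), files$cells, row.names = FALSE)
    utils::write.csv(truth, files$truth, row.names = FALSE)
  }
  list(cells = cells, truth = truth, files = files)
}

#' Default slow-growth phase schedule over a normalized 120-minute cycle
#'
#' @return A data.frame with columns `phase`, `start_min`, `end_min`.
#' @export
phase_schedule <- function() {
  data.frame(phase = c("i", "ii", "iii", "iv", "v", "vi"),
             start_min = c(0, 20, 30, 60, 80, 100),
             end_min = c(20, 30, 60, 80, 100, 120))
}

#' Generate a time course of localization snapshots over one cell cycle
#'
#' The cycle is divided into the slow-growth phase schedule (normalized to
#' 120 minutes by default); one cell snapshot is emitted every `dt_minutes`
#' with the layout of the phase active at that time (the smeared phase emits
#' sub-threshold diffuse signal only).
#'
#' @param cycle_minutes Cycle length, default 120.
#' @param dt_minutes Snapshot interval (> 0).
#' @param seed Integer master seed.
#' @return A list with `times_min`, `phases`, `cells` (list of `gen_cell()`
#'   results), and `true_counts` (generator cluster count per snapshot).
#' @export
gen_timecourse <- function(cycle_minutes = 120, dt_minutes = 10, seed = 1L) {
  if (dt_minutes <= 0) stop("dt_minutes must be positive")
  times <- seq(0, cycle_minutes, by = dt_minutes)
  sched <- phase_schedule()
  # rescale the normalized schedule to the requested cycle length
  sched$start_min <- sched$start_min * cycle_minutes / 120
  sched$end_min <- sched$end_min * cycle_minutes / 120
  phases <- vapply(times, function(t) {
    i <- which(t >= sched$start_min & t < sched$end_min)
    if (length(i) == 0) "vi" else sched$phase[i[1]] # t == cycle end -> vi
  }, character(1))
  cells <- lapply(seq_along(times), function(j) {
    gen_cell(phase_params("slow", phases[j]), seed = as.integer(seed) + j,
             cell_id = sprintf("t%03d", as.integer(times[j])))
  })
  true_counts <- vapply(cells, function(cl) cl$truth$n_clusters, integer(1))
  list(times_min = times, phases = phases, cells = cells,
       true_counts = true_counts)
}

#' Default platinum-adduct accumulation series
#'
#' Deterministic series at t = 0..4 h with divalent Pt counts 0, 7.6, 11.3,
#' 14.7 and 37.6 per molecule and the 16% sharp-bend fraction. In noise
#' mode the counts are jittered with the measured SD of 3.8 (truncated at
#' zero), reproducibly under the given seed.
#'
#' @param seed Integer seed (used in noise mode only).
#' @param noise Add measurement noise, default FALSE.
#' @param noise_sd SD of the count jitter, default 3.8.
#' @return A list of [adduct_state()] objects sorted by time.
#' @export
gen_adduct_series <- function(seed = 1L, noise = FALSE, noise_sd = 3.8) {
  t_h <- 0:4
  pt <- c(0, 7.6, 11.3, 14.7, 37.6)
  if (noise) {
    set.seed(as.integer(seed))
    jit <- stats::rnorm(length(pt), 0, noise_sd)
    jit[1] <- 0
    pt <- pmax(0, pt + jit)
  }
  lapply(seq_along(t_h), function(i) adduct_state(t_h[i], pt[i]))
}

#' Analytic chain fixtures with known topology
#'
#' Constructs closed, equal-segment chains whose writhe sign/magnitude and
#' spool count are known by construction: a planar circle (writhe 0, one
#' lobe); a lifted figure-eight with a single positive crossing (writhe ~ +1);
#' a single solenoid of `circles` stacked circles (one dense lobe); and a
#' dual solenoid, two stacked-coil lobes joined by a crossover (the
#' idealized dual toroidal spool, two lobes).
#'
#' @param n Segments per fixture chain, default 80 (120 for the dual
#'   solenoid).
#' @param radius_nm Lobe/circle radius, default 60.
#' @param pitch_nm Vertical rise per coil turn, default 6.
#' @param circles Coil turns per solenoid lobe, default 3.
#' @param crossing_sign Sign (+1/-1) of the figure-eight crossing.
#' @return A named list of `chain_conformation` objects: `circle`,
#'   `figure_eight`, `solenoid`, `dual_solenoid`.
#' @export
gen_fixture_chains <- function(n = 80L, radius_nm = 60, pitch_nm = 6,
                               circles = 3L, crossing_sign = 1) {
  R <- radius_nm
  p <- pitch_nm
  cc <- circles
  dense <- function(f, t) t(vapply(t, f, numeric(3)))
  mk <- function(pts, n_out) {
    chain_conformation(resample_equal_segments(pts, n_out))
  }

  th <- 2 * pi * (seq_len(n) - 1) / n
  circle <- chain_conformation(cbind(R * cos(th), R * sin(th), 0))

  tt <- seq(0, 2 * pi, length.out = 4000)[-4000]
  eight <- dense(function(t) c(1.8 * R * cos(t), 1.8 * R * sin(t) * cos(t),
                               sign(crossing_sign) * 0.02 * R * sin(t)), tt)
  figure_eight <- mk(eight, n)

  helix <- function(t, cx) c(cx + R * cos(t), R * sin(t), p * t / (2 * pi))
  ts <- seq(0, 2 * pi * cc, length.out = 6000)
  sol <- dense(function(t) helix(t, 0), ts)
  ss <- seq(0, pi, length.out = 800)[-1]
  ret <- dense(function(s) c(R + 0.5 * R * sin(s), 0,
                             cc * p * (1 + cos(s)) / 2), ss)
  solenoid <- mk(rbind(sol, ret), n)

  D <- 2.5 * R
  hA <- dense(function(t) c(-D + R * cos(t), R * sin(t), p * t / (2 * pi)), ts)
  bridge1 <- dense(function(u) c(-D + R + u * (2 * D - 2 * R), 0, cc * p),
                   seq(0.02, 0.98, length.out = 300))
  hB <- dense(function(t) c(D - R * cos(t), -R * sin(t),
                            cc * p * (1 - t / (2 * pi * cc))), ts)
  bridge2 <- dense(function(u) c(D - R - u * (2 * D - 2 * R), 0, 0),
                   seq(0.02, 0.98, length.out = 300))
  dual <- rbind(hA, bridge1, hB, bridge2)
  dual_solenoid <- mk(dual, as.integer(max(n, 120L)))

  list(circle = circle, figure_eight = figure_eight,
       solenoid = solenoid, dual_solenoid = dual_solenoid)
}
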