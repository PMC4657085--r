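make_cluster_set <- function(xy, n = 300) {
  out <- data.frame(cluster_id = seq_len(nrow(xy)), cx_um = xy[, 1],
                    cy_um = xy[, 2],
                    n_localizations = rep_len(n, nrow(xy)),
                    radius_of_gyration_um = 0.06)
  out <- out[order(out$cx_um), ]
  out$cluster_id <- seq_len(nrow(out))
  class(out) <- c("cluster_set", "data.frame")
  out
}

test_that("noiseless blobs are recovered exactly", {
  pts <- rbind(matrix(rep(c(-0.45, 0), each = 60), ncol = 2),
               matrix(rep(c(0.45, 0), each = 60), ncol = 2))
  cs <- detect_clusters(pts)
  expect_equal(nrow(cs), 2L)
  expect_equal(cs$cx_um, c(-0.45, 0.45))
  expect_equal(pair_distances(cs), 0.9)
  expect_equal(cs$radius_of_gyration_um, c(0, 0))
})

test_that("sparse uniform background yields zero clusters", {
  set.seed(2)
  pts <- cbind(runif(30, -1.5, 1.5), runif(30, -0.45, 0.45))
  cs <- detect_clusters(pts)
  expect_equal(nrow(cs), 0L)
})

test_that("phase-i cells yield two clusters in at least 95% of seeded cells", {
  params <- phase_params("slow", "i")
  hits <- 0L
  for (s in 1:200) {
    cell <- gen_cell(params, seed = 20000 + s)
    if (nrow(detect_clusters(cell$locs)) == 2L) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("pair distances: variants, symmetry and invariance", {
  cs <- make_cluster_set(cbind(c(0, 0.7, 1.4), c(0, 0, 0)))
  expect_equal(pair_distances(cs, "consecutive"), c(0.7, 0.7))
  expect_equal(sort(pair_distances(cs, "all")), c(0.7, 0.7, 1.4))
  expect_error(pair_distances(make_cluster_set(cbind(0, 0))), "at least 2")
  # translation/rotation invariance
  a <- 0.7
  rot <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  xy <- cbind(c(0, 0.7, 1.4), c(0.1, -0.2, 0.05))
  moved <- sweep(xy %*% rot, 2, c(3, -1), `+`)
  expect_equal(sort(pair_distances(make_cluster_set(xy), "all")),
               sort(pair_distances(make_cluster_set(moved), "all")))
})

test_that("three-cluster angle uses the axially middle cluster as vertex", {
  collinear <- make_cluster_set(cbind(c(-0.7, 0, 0.7), c(0, 0, 0)))
  expect_equal(cluster_angle(collinear), 180)
  eq <- make_cluster_set(cbind(c(0, 0.5, 1), c(0, sqrt(3) / 2, 0)))
  expect_equal(cluster_angle(eq), 60)
  right <- make_cluster_set(cbind(c(0, 1, 1), c(0, 0, 1)))
  expect_equal(cluster_angle(right), 90)
  expect_error(cluster_angle(make_cluster_set(cbind(c(0, 1), c(0, 0)))),
               "exactly 3")
  expect_error(cluster_angle(make_cluster_set(cbind(c(0, 0, 1), c(0, 0, 0)))),
               "coincident")
})

test_that("phase classification follows the rule table", {
  two_eq <- make_cluster_set(cbind(c(-0.4, 0.4), 0), n = 300)
  expect_equal(classify_phase(two_eq, 2.0), "i")
  two_uneq <- make_cluster_set(cbind(c(-0.4, 0.4), 0))
  two_uneq$n_localizations <- c(300, 100)
  expect_equal(classify_phase(two_uneq, 2.0), "ii")
  expect_equal(classify_phase(two_eq, 3.0), "iv")
  expect_equal(classify_phase(make_cluster_set(cbind(c(-0.7, 0, 0.7), 0)),
                              2.8), "iii")
  expect_equal(classify_phase(make_cluster_set(cbind(c(-1, -0.4, 0.4, 1), 0)),
                              3.4), "vi")
  expect_equal(classify_phase(detect_clusters(matrix(numeric(0), 0, 2)), 3.0),
               "v")
})

test_that("mode strings reduce count series as printed", {
  expect_equal(mode_string(c(2, 2, 3, 3, 3, 2, 2, 4, 4)), "2-3-2-4")
  expect_equal(mode_string(c(1, 1, 3, 3, 2, 2)), "1-3-2")
  expect_equal(mode_string(c(2, 2, 2)), "2")
  # flicker shorter than 2 frames is removed
  expect_equal(mode_string(c(2, 2, 3, 2, 2, 4, 4)), "2-4")
  # zero-count (smeared) frames are dropped before encoding
  expect_equal(mode_string(c(2, 2, 3, 3, 2, 2, 0, 0, 4, 4)), "2-3-2-4")
  expect_equal(mode_string(integer(0)), "")
})

test_that("cluster tracking links lineages across frames", {
  static <- lapply(1:5, function(f)
    make_cluster_set(cbind(c(-0.4, 0.4), 0)))
  tr <- track_clusters(static)
  expect_equal(length(unique(tr$lineage)), 2L)
  expect_true(all(table(tr$lineage) == 5))
  # a cluster disappearing at frame 3 ends its lineage at frame 2
  vanish <- list(make_cluster_set(cbind(c(-0.4, 0.4), 0)),
                 make_cluster_set(cbind(c(-0.4, 0.4), 0)),
                 make_cluster_set(cbind(0.4, 0)))
  tr2 <- track_clusters(vanish)
  lens <- tapply(tr2$frame, tr2$lineage, max)
  expect_setequal(as.numeric(lens), c(2, 3))
  # shrink/grow schedule: monotone size trends recovered
  series <- lapply(1:6, function(f) {
    cs <- make_cluster_set(cbind(c(-0.4, 0.4), 0))
    cs$n_localizations <- c(400 - 50 * f, 100 + 50 * f)
    cs
  })
  tr3 <- track_clusters(series)
  for (lin in unique(tr3$lineage)) {
    sizes <- tr3$n_localizations[tr3$lineage == lin]
    rho <- suppressWarnings(cor(seq_along(sizes), sizes, method = "spearman"))
    expect_equal(abs(rho), 1)
  }
  expect_error(track_clusters(static[1]), "at least 2")
})

test_that("generated populations round-trip through the readers", {
  out <- withr::local_tempdir()
  pop <- gen_population(3, "slow", "i", seed = 77, out_dir = out)
  sets <- read_localizations(pop$files$locs, pop$files$cells)
  expect_length(sets, 3L)
  for (j in 1:3) {
    orig <- pop$cells[[j]]$locs
    got <- sets[[orig$cell_id]]
    expect_equal(nrow(got$points), nrow(orig$points))
    # registration into the cell frame inverts the random placement
    expect_equal(unname(got$points), unname(orig$points), tolerance = 1e-9)
    expect_equal(got$cell$length_um, orig$cell$length_um)
  }
  expect_error(read_localizations(pop$files$locs, pop$files$locs), "columns")
  # outline missing for a cell id
  cells <- utils::read.csv(pop$files$cells)
  cut <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cells[-1, ], cut, row.names = FALSE)
  expect_error(read_localizations(pop$files$locs, cut), "no cell outline")
})
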