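test_that("degenerate limits put all localizations at the true centres", {
  params <- phase_params("slow", "i", background_per_um2 = 0,
                         cluster_sigma_nm = 1e-9, precision_nm = 1e-9)
  cell <- gen_cell(params, seed = 5)
  expect_equal(nrow(cell$locs$points), 600L)
  got <- unique(round(cell$locs$points, 6))
  expect_equal(nrow(got), 2L)
  expect_equal(sort(got[, 1]), sort(cell$truth$centres[, 1]),
               tolerance = 1e-5)
})

test_that("generation is deterministic under a fixed seed", {
  params <- phase_params("fast", "newborn")
  a <- gen_cell(params, seed = 11)
  b <- gen_cell(params, seed = 11)
  expect_identical(a, b)
  expect_false(identical(gen_cell(params, seed = 12)$locs$points,
                         a$locs$points))
  p1 <- gen_population(4, "slow", "iv", seed = 3)
  p2 <- gen_population(4, "slow", "iv", seed = 3)
  expect_identical(p1$truth, p2$truth)
})

test_that("empirical separation moments match the phase model", {
  # law-of-large-numbers check against generator truth, 3 sem tolerance
  pop <- gen_population(600, "slow", "i", seed = 900)
  seps <- pop$truth$mean_separation
  expect_equal(mean(seps), 0.88, tolerance = 3 * 0.10 / sqrt(600) / 0.88)
  # phase-iv mixture model moments (analytic, not sampled)
  m <- phase_params("slow", "iv")$separation_model
  mu <- sum(m$weights * m$means)
  sdv <- sqrt(sum(m$weights * (m$sds^2 + m$means^2)) - mu^2)
  expect_lt(abs(mu - 1.50), 0.02)
  expect_lt(abs(sdv - 0.15), 0.02)
})

test_that("fast-growth layouts encode separations and angles geometrically", {
  params <- phase_params("fast", "newborn")
  cell <- gen_cell(params, seed = 21)
  ctr <- cell$truth$centres
  s <- cell$truth$separations
  expect_length(s, 2L)
  expect_equal(sqrt(sum((ctr[1, ] - ctr[2, ])^2)), s[1])
  expect_equal(sqrt(sum((ctr[3, ] - ctr[2, ])^2)), s[2])
  # distal distance follows the law of cosines (emergent, not drawn)
  th <- cell$truth$angle_deg * pi / 180
  distal <- sqrt(sum((ctr[1, ] - ctr[3, ])^2))
  expect_equal(distal, sqrt(s[1]^2 + s[2]^2 - 2 * s[1] * s[2] * cos(th)))
  expect_true(cell$truth$angle_deg >= 40 && cell$truth$angle_deg <= 180)
})

test_that("time course follows the two-three-two-four schedule", {
  tc <- gen_timecourse(120, 10, seed = 2)
  expect_length(tc$times_min, 13L)
  expect_equal(tc$phases[1:3], c("i", "i", "ii"))
  expect_equal(mode_string(tc$true_counts), "2-3-2-4")
  expect_length(gen_timecourse(120, 120, seed = 2)$times_min, 2L)
  expect_identical(gen_timecourse(120, 10, seed = 2), tc)
  expect_error(gen_timecourse(120, 0), "positive")
})

test_that("adduct series carries the printed counts and the 16% arithmetic", {
  ser <- gen_adduct_series()
  expect_equal(vapply(ser, function(s) s$time_h, numeric(1)), 0:4)
  expect_equal(vapply(ser, sharp_bends, numeric(1)),
               c(0, 1.216, 1.808, 2.352, 6.016))
  noisy1 <- gen_adduct_series(seed = 4, noise = TRUE)
  noisy2 <- gen_adduct_series(seed = 4, noise = TRUE)
  expect_identical(noisy1, noisy2)
  expect_equal(sharp_bends(noisy1[[1]]), 0) # t = 0 stays exact
  expect_false(identical(vapply(noisy1, sharp_bends, numeric(1)),
                         vapply(ser, sharp_bends, numeric(1))))
})

test_that("every generated file parses through the pipeline readers", {
  out <- withr::local_tempdir()
  for (cfg in list(c("slow", "iv"), c("fast", "newborn"), c("slow", "vi"))) {
    dir <- file.path(out, paste(cfg, collapse = "_"))
    pop <- gen_population(2, cfg[1], cfg[2], seed = 60, out_dir = dir)
    expect_silent(sets <- read_localizations(pop$files$locs, pop$files$cells))
    expect_length(sets, 2L)
  }
  one <- gen_population(1, "slow", "i", seed = 61,
                        out_dir = file.path(out, "single"))
  sets <- read_localizations(one$files$locs, one$files$cells)
  expect_length(sets, 1L)
})

test_that("fixture chains have their stated writhe", {
  fx <- get_fixtures()
  expect_equal(writhe_gauss(fx$circle), 0, tolerance = 1e-9)
  expect_equal(writhe_gauss(fx$figure_eight), 1, tolerance = 0.05)
  neg <- gen_fixture_chains(crossing_sign = -1)
  expect_equal(writhe_gauss(neg$figure_eight), -1, tolerance = 0.05)
})
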