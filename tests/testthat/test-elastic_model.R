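test_that("contour length and molecule invariants", {
  expect_equal(contour_length(dna_molecule(4361)), 1482.74)
  expect_equal(contour_length(dna_molecule(10)), 3.4)
  expect_error(dna_molecule(0), "positive")
  expect_error(dna_molecule(100, rise_nm_per_bp = -1), "positive")
  expect_error(dna_molecule(100, bend_persistence_nm = 0), "positive")
})

test_that("single-circle bending energy matches the closed form and quadrature", {
  L <- 4361 * 0.34
  expect_equal(circle_bending_energy(L, 52.2), 0.695, tolerance = 2e-4)
  # 1/L scaling
  expect_equal(circle_bending_energy(2 * L, 52.2),
               circle_bending_energy(L, 52.2) / 2)
  # brute-force quadrature oracle: (A/2) * kappa^2 line integral on a
  # 10,000-point discretized circle of circumference L
  n <- 10000
  R <- L / (2 * pi)
  th <- 2 * pi * (seq_len(n) - 1) / n
  ds <- L / n
  kappa <- 1 / R # curvature of the circle, exact at every point
  quad <- sum(0.5 * 52.2 * kappa^2 * rep(ds, n))
  expect_equal(quad, circle_bending_energy(L, 52.2), tolerance = 1e-4)
  # quadrature with curvature estimated by finite differences
  pts <- cbind(R * cos(th), R * sin(th))
  d1 <- (pts[c(2:n, 1), ] - pts[c(n, 1:(n - 1)), ]) / (2 * ds)
  d2 <- (pts[c(2:n, 1), ] - 2 * pts + pts[c(n, 1:(n - 1)), ]) / ds^2
  kap <- abs(d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) /
    (rowSums(d1^2))^1.5
  quad2 <- sum(0.5 * 52.2 * kap^2 * ds)
  expect_equal(quad2, circle_bending_energy(L, 52.2), tolerance = 1e-4)
  expect_error(circle_bending_energy(-1, 52.2), "positive")
  expect_error(circle_bending_energy(100, 0), "positive")
})

test_that("k-spool energies reproduce the printed single/dual/triplex values", {
  mol <- dna_molecule(4361)
  e1 <- kspool_bending_energy(mol, spool_configuration(1))
  e2 <- kspool_bending_energy(mol, spool_configuration(2))
  e3 <- kspool_bending_energy(mol, spool_configuration(3))
  expect_equal(e1, 0.695, tolerance = 3e-4)
  expect_equal(e2, 2.778, tolerance = 1e-3)
  expect_equal(e3, 6.255, tolerance = 2e-4)
  # exact algebra regardless of parameters
  expect_identical(e2, 4 * e1)
  expect_identical(e3, 9 * e1)
  expect_identical(e1, circle_bending_energy(contour_length(mol), 52.2))
})

test_that("k-spool closed form equals (k c)^2 times the single circle", {
  mol <- dna_molecule(2000, bend_persistence_nm = 45)
  e1 <- circle_bending_energy(contour_length(mol), 45)
  for (k in 1:6) for (cc in 1:6) {
    expect_equal(kspool_bending_energy(mol, spool_configuration(k, cc)),
                 (k * cc)^2 * e1)
  }
  # strictly increasing in k
  es <- vapply(1:6, function(k)
    kspool_bending_energy(mol, spool_configuration(k)), numeric(1))
  expect_true(all(diff(es) > 0))
})

test_that("explicit radii reduce to the equal-circle closed form", {
  mol <- dna_molecule(4361)
  L <- contour_length(mol)
  # two equal circles of circumference L/2
  r <- L / (4 * pi)
  cfg <- spool_configuration(2, circle_radii_nm = c(r, r))
  expect_equal(kspool_bending_energy(mol, cfg),
               kspool_bending_energy(mol, spool_configuration(2)),
               tolerance = 1e-12)
  expect_error(
    kspool_bending_energy(mol, spool_configuration(2,
                                                   circle_radii_nm = c(r, r / 2))),
    "contour length")
})

test_that("per-circle energy from radius", {
  A <- 52.2
  expect_equal(circle_energy_from_radius(pi * A, A), 1.0)
  expect_equal(circle_energy_from_radius(180.2, A), 0.910, tolerance = 1e-3)
  expect_equal(circle_energy_from_radius(30.15, A), 5.44, tolerance = 1e-3)
  expect_error(circle_energy_from_radius(0, A), "positive")
})

test_that("spool multiplicity probabilities", {
  expect_equal(spool_multiplicity_probability(2, 10), 0.01)
  expect_equal(relative_spool_probability(3, 2, 10), 0.1)
  expect_equal(spool_multiplicity_probability(5, 1), 1)
  expect_error(spool_multiplicity_probability(1, 10), "k must be")
  # strictly decreasing in k for N >= 2
  for (N in c(2, 7, 100)) {
    p <- vapply(2:6, spool_multiplicity_probability, numeric(1), N = N)
    expect_true(all(diff(p) < 0))
  }
})

test_that("rank_configurations orders by energy with the dual-spool balanced", {
  mol <- dna_molecule(4361)
  tab <- rank_configurations(mol, c(3, 1, 2))
  expect_equal(tab$k, c(1L, 2L, 3L))
  expect_equal(tab$energy_kBT, c(0.695, 2.778, 6.255), tolerance = 1e-3)
  expect_equal(tab$self_balanced, c(FALSE, TRUE, FALSE))
  expect_equal(tab$k[tab$self_balanced][1], 2L)
  one <- rank_configurations(mol, 2)
  expect_equal(nrow(one), 1L)
  expect_true(one$self_balanced)
  four <- rank_configurations(mol, 4)
  expect_equal(four$energy_kBT,
               16 * kspool_bending_energy(mol, spool_configuration(1)))
  expect_error(rank_configurations(mol, integer(0)), "non-empty")
})
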