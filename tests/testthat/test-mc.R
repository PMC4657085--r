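test_that("crankshaft moves preserve closure and segment lengths exactly", {
  mol <- dna_molecule(4361)
  ch <- make_circle_chain(mol, 50, -4)
  res <- mc_relax(ch, mol, sim_params(steps = 2000L, seed = 2L,
                                      record_every = 500L))
  v <- res$chain$vertices
  n <- nrow(v)
  lens <- sqrt(rowSums((v[c(2:n, 1), ] - v)^2))
  b <- ch$segment_length_nm
  expect_lt(max(abs(lens - b)) / b, 1e-9)
})

test_that("identical seeds give bitwise-identical trajectories", {
  mol <- dna_molecule(4361)
  ch <- make_circle_chain(mol, 40, -3)
  p <- sim_params(steps = 1500L, seed = 31L, record_every = 300L)
  r1 <- mc_relax(ch, mol, p)
  r2 <- mc_relax(ch, mol, p)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$chain$vertices, r2$chain$vertices)
  r3 <- mc_relax(ch, mol, sim_params(steps = 1500L, seed = 32L,
                                     record_every = 300L))
  expect_false(identical(r1$trajectory$writhe, r3$trajectory$writhe))
})

test_that("linking number is conserved and White's theorem holds on every frame", {
  mol <- dna_molecule(4361)
  ch <- make_circle_chain(mol, 50, -5)
  ch <- inject_adducts(ch, 14.7, seed = 8)
  p <- sim_params(steps = 4000L, seed = 17L, record_every = 400L,
                  snapshots = TRUE)
  res <- mc_relax(ch, mol, p)
  tr <- res$trajectory
  # recorded bookkeeping: lk constant, lk = tw + wr by construction
  expect_true(all(abs(tr$lk - ch$linking_number) < 1e-6))
  # independent check: writhe recomputed from each snapshot
  for (i in seq_along(res$snapshots)) {
    wr_i <- writhe_gauss(res$snapshots[[i]])
    expect_lt(abs(ch$linking_number - (tr$twist[i] + wr_i)), 0.05)
  }
})

test_that("nicked mode relaxes twist to the helical ground state", {
  mol <- dna_molecule(4361)
  ch <- make_circle_chain(mol, 40, -6)
  res <- mc_relax(ch, mol, sim_params(steps = 500L, seed = 5L,
                                      record_every = 250L,
                                      torsionally_constrained = FALSE))
  expect_equal(chain_twist(res$chain), relaxed_turns(mol))
  expect_true(all(res$trajectory$e_twist == 0))
})

test_that("equipartition: excess bend energy is kBT/2 per internal mode", {
  # stiff ring, nicked, no excluded volume; the 2n-6 internal modes share
  # the energy in excess of the discrete ground-state ring energy
  n <- 30L
  mol <- dna_molecule(200) # A/b ~ 23
  ch <- make_circle_chain(mol, n)
  e_min <- chain_energy(ch, mol, excluded_diameter_nm = 0)$bend
  p <- sim_params(steps = 250000L, seed = 42L, excluded_diameter_nm = 0,
                  record_every = 25L, torsionally_constrained = FALSE,
                  crankshaft_max_deg = 40)
  res <- mc_relax(ch, mol, p)
  tr <- res$trajectory
  samp <- tr$e_bend[tr$step > 50000]
  expect_gt(length(samp), 5000)
  per_mode <- (mean(samp) - e_min) / (2 * n - 6)
  expect_equal(per_mode, 0.5, tolerance = 0.1)
})

test_that("torsional stress converts into writhe", {
  mol <- dna_molecule(4361)
  ch <- make_circle_chain(mol, 50, -6)
  res <- mc_relax(ch, mol, sim_params(steps = 5000L, seed = 7L,
                                      record_every = 5000L))
  expect_gt(abs(writhe_gauss(res$chain)), 0.5) # |Wr| grew from 0
  expect_lt(writhe_gauss(res$chain), 0)        # and carries the deficit sign
})

test_that("mean |writhe| is non-decreasing along the adduct schedule", {
  mol <- dna_molecule(4361)
  sched <- gen_adduct_series()
  p <- sim_params(steps = 4000L, seed = 11L, record_every = 4000L)
  tc <- simulate_time_course(mol, sched, p, n_segments = 50L,
                             replicates = 3L)
  expect_equal(nrow(tc), 5L)
  expect_equal(tc$n_kinks, c(0L, 1L, 2L, 2L, 6L))
  # non-decreasing within one (combined) standard error
  for (i in 2:5) {
    slack <- tc$sem_abs_writhe[i] + tc$sem_abs_writhe[i - 1]
    expect_gt(tc$mean_abs_writhe[i] - tc$mean_abs_writhe[i - 1], -slack)
  }
})

test_that("degenerate schedules are handled", {
  mol <- dna_molecule(4361)
  base <- simulate_time_course(mol, list(), sim_params(steps = 10L),
                               n_segments = 30L)
  expect_equal(base$mean_abs_writhe, 0, tolerance = 1e-9)
  zero <- simulate_time_course(mol, list(adduct_state(0, 0)),
                               sim_params(steps = 0L, record_every = 1L),
                               n_segments = 30L, replicates = 1L)
  expect_equal(zero$mean_abs_writhe, 0, tolerance = 1e-9)
  expect_error(
    simulate_time_course(mol, list(adduct_state(2, 5), adduct_state(1, 3)),
                         sim_params(steps = 10L), n_segments = 30L),
    "sorted")
})
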