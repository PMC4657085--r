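test_that("chain construction enforces closure and equal segments", {
  mol <- dna_molecule(4361)
  ch <- make_circle_chain(mol, 100)
  expect_equal(ch$segment_length_nm, 1482.74 / 100)
  expect_equal(chain_twist(ch), 4361 / 10.5)
  ch2 <- make_circle_chain(mol, 100, delta_linking = -2)
  expect_equal(ch2$linking_number - relaxed_turns(mol), -2)
  expect_equal(writhe_gauss(ch2), 0, tolerance = 1e-9)
  expect_error(make_circle_chain(mol, 5), "at least 6")
  bad <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 5, 0), c(15, 20, 0),
               c(0, 25, 0), c(-5, 10, 0))
  expect_error(chain_conformation(bad), "length b")
  expect_error(chain_conformation(make_circle_chain(mol, 50)$vertices,
                                  kinks = data.frame(index = c(2, 2),
                                                     preferred_bend_deg = 150,
                                                     stiffness_factor = 0.3)),
               "distinct")
})

test_that("XYZ round-trip preserves geometry, twist and kinks", {
  mol <- dna_molecule(2000)
  ch <- make_circle_chain(mol, 40, -1.5)
  ch <- inject_adducts(ch, 20, seed = 3)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_chain_xyz(ch, path)
  back <- read_chain_xyz(path)
  expect_equal(back$vertices, ch$vertices, tolerance = 1e-9)
  expect_equal(back$total_twist_turns, ch$total_twist_turns)
  expect_equal(back$linking_number, ch$linking_number)
  expect_equal(back$kinks, ch$kinks)
})

test_that("equal-chord resampling produces valid chains from analytic curves", {
  tt <- seq(0, 2 * pi, length.out = 3000)[-3000]
  # a bumpy non-circular closed curve
  pts <- cbind((50 + 8 * cos(3 * tt)) * cos(tt),
               (50 + 8 * cos(3 * tt)) * sin(tt),
               5 * sin(2 * tt))
  v <- resample_equal_segments(pts, 64)
  lens <- sqrt(rowSums((v[c(2:64, 1), ] - v)^2))
  expect_lt((max(lens) - min(lens)) / mean(lens), 1e-7)
  expect_s3_class(chain_conformation(v), "chain_conformation")
})

test_that("adduct injection places kinks and unwinds the duplex", {
  mol <- dna_molecule(4361)
  ch <- make_circle_chain(mol, 60, -2)
  injected <- inject_adducts(ch, 37.6, fraction = 0.16,
                             untwist_turn_per_adduct = 0.05, seed = 9)
  expect_equal(nrow(injected$kinks), 6L) # round(0.16 * 37.6)
  expect_equal(injected$linking_number, ch$linking_number - 37.6 * 0.05)
  expect_equal(injected$vertices, ch$vertices) # geometry untouched
  expect_identical(inject_adducts(ch, 0), ch)
  same <- inject_adducts(ch, 37.6, seed = 9)
  expect_identical(same$kinks, injected$kinks)
  other <- inject_adducts(ch, 37.6, seed = 10)
  expect_false(identical(other$kinks$index, injected$kinks$index))
  expect_error(inject_adducts(ch, 100, fraction = 1), "exceed")
})
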