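#' Monte-Carlo simulation parameters
#'
#' @param steps Number of Metropolis steps (>= 1).
#' @param seed Integer RNG seed.
#' @param kBT_temperature_factor Dimensionless temperature factor, default 1.
#' @param crankshaft_max_deg Maximum crankshaft rotation, degrees, default 90.
#' @param excluded_diameter_nm Hard-wall excluded diameter, nm, default 4
#'   (0 disables excluded volume).
#' @param record_every Record a summary every this many steps.
#' @param torsionally_constrained Keep Lk fixed (unnicked duplex, the
#'   default); when `FALSE` ("nicked" mode) twist relaxes to the relaxed
#'   turns and carries no energy.
#' @param snapshots Also record vertex snapshots at each recorded frame.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(steps = 10000L, seed = 1L,
                       kBT_temperature_factor = 1,
                       crankshaft_max_deg = 90,
                       excluded_diameter_nm = 4,
                       record_every = 1000L,
                       torsionally_constrained = TRUE,
                       snapshots = FALSE) {
  if (steps < 0) stop("steps must be >= 0")
  if (kBT_temperature_factor <= 0) stop("temperature factor must be positive")
  if (excluded_diameter_nm < 0) stop("excluded_diameter_nm must be >= 0")
  if (record_every < 1) stop("record_every must be >= 1")
  structure(
    list(steps = as.integer(steps), seed = as.integer(seed),
         kBT_temperature_factor = kBT_temperature_factor,
         crankshaft_max_deg = crankshaft_max_deg,
         excluded_diameter_nm = excluded_diameter_nm,
         record_every = as.integer(record_every),
         torsionally_constrained = torsionally_constrained,
         snapshots = snapshots),
    class = "sim_params"
  )
}

#' Relax a chain by Metropolis crankshaft Monte Carlo
#'
#' Crankshaft moves rotate the sub-chain between two randomly chosen
#' vertices about their chord by a uniform angle, which preserves closure
#' and every segment length exactly; moves are accepted with probability
#' `min(1, exp(-dE))`. In torsionally constrained mode the linking number is
#' held fixed and twist is recomputed as Lk - Wr after each accepted move,
#' so torsional stress converts into writhe. Identical seeds give identical
#' trajectories.
#'
#' @param chain A `chain_conformation`.
#' @param mol A [dna_molecule()].
#' @param params A [sim_params()].
#' @return A list with `chain` (final conformation), `trajectory` (a
#'   data.frame: step, writhe, twist, lk, e_bend, e_twist, e_kink,
#'   accept_rate), `accept_rate`, and `snapshots` (list of vertex matrices
#'   when requested).
#' @export
mc_relax <- function(chain, mol, params = sim_params()) {
  stopifnot(inherits(chain, "chain_conformation"),
            inherits(mol, "dna_molecule"),
            inherits(params, "sim_params"))
  set.seed(params$seed)
  tw0 <- relaxed_turns(mol)
  res <- mc_relax_cpp(
    chain$vertices, chain$segment_length_nm,
    mol$bend_persistence_nm, mol$twist_persistence_nm, contour_length(mol),
    tw0, chain$linking_number, params$torsionally_constrained,
    as.integer(chain$kinks$index - 1L), chain$kinks$preferred_bend_deg,
    chain$kinks$stiffness_factor,
    params$steps, params$crankshaft_max_deg, params$excluded_diameter_nm,
    params$record_every, params$kBT_temperature_factor, params$snapshots
  )
  out_chain <- chain_conformation(
    res$vertices, chain$segment_length_nm,
    total_twist_turns = res$twist, kinks = chain$kinks,
    linking_number = if (params$torsionally_constrained)
      chain$linking_number else NULL
  )
  list(chain = out_chain, trajectory = res$trajectory,
       accept_rate = res$accepted / max(1L, params$steps),
       snapshots = res$snapshots)
}

#' Simulate the auto-packaging time course under an adduct schedule
#'
#' For each time point of a (time-sorted) adduct schedule, a fresh planar
#' circle is built, the cumulative adducts at that time are injected (kinks
#' plus unwinding), and the chain is relaxed by Monte Carlo over several
#' replicate seeds. Reports the mean unsigned writhe and its spread per
#' time point together with the final-frame classification of the first
#' replicate.
#'
#' @param mol A [dna_molecule()].
#' @param adduct_schedule List of [adduct_state()] sorted by time.
#' @param params A [sim_params()]; `params$seed` seeds replicate 1, seed + 1
#'   replicate 2, and so on.
#' @param n_segments Chain discretization.
#' @param delta_linking Initial linking deficit of the intact molecule.
#' @param replicates Number of replicate relaxations per time point.
#' @param untwist_turn_per_adduct Unwinding per divalent adduct, turns.
#' @return A data.frame with one row per time point: time_h, pt_divalent,
#'   n_kinks, mean_abs_writhe, sem_abs_writhe, twist, lk, stage, spools.
#' @export
simulate_time_course <- function(mol, adduct_schedule, params = sim_params(),
                                 n_segments = 60L, delta_linking = -2,
                                 replicates = 4L,
                                 untwist_turn_per_adduct = 0.05) {
  stopifnot(inherits(mol, "dna_molecule"), inherits(params, "sim_params"))
  if (length(adduct_schedule) == 0) {
    ch <- make_circle_chain(mol, n_segments, delta_linking)
    cls <- classify_conformation(ch)
    return(data.frame(time_h = NA_real_, pt_divalent = 0, n_kinks = 0L,
                      mean_abs_writhe = abs(writhe_gauss(ch)),
                      sem_abs_writhe = 0, twist = chain_twist(ch),
                      lk = ch$linking_number, stage = cls$stage,
                      spools = cls$spool_count))
  }
  times <- vapply(adduct_schedule, function(s) s$time_h, numeric(1))
  if (is.unsorted(times)) stop("adduct_schedule must be sorted by time")
  rows <- lapply(seq_along(adduct_schedule), function(i) {
    st <- adduct_schedule[[i]]
    wr <- numeric(replicates)
    last <- NULL
    for (r in seq_len(replicates)) {
      seed_r <- params$seed + 1000L * (i - 1L) + r
      ch <- make_circle_chain(mol, n_segments, delta_linking)
      ch <- inject_adducts(ch, st$pt_divalent, st$sharp_bend_fraction,
                           untwist_turn_per_adduct, seed = seed_r)
      p <- params
      p$seed <- seed_r
      res <- mc_relax(ch, mol, p)
      wr[r] <- abs(writhe_gauss(res$chain))
      if (r == 1L) last <- res$chain
    }
    cls <- classify_conformation(last)
    data.frame(time_h = st$time_h, pt_divalent = st$pt_divalent,
               n_kinks = nrow(last$kinks),
               mean_abs_writhe = mean(wr),
               sem_abs_writhe = if (replicates > 1)
                 stats::sd(wr) / sqrt(replicates) else 0,
               twist = chain_twist(last), lk = last$linking_number,
               stage = cls$stage, spools = cls$spool_count)
  })
  do.call(rbind, rows)
}
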