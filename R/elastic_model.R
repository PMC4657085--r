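#' Spool configuration of a circular DNA
#'
#' Describes how a circular molecule is partitioned into `n_spools` toroidal
#' spools with `circles_per_spool` DNA circles each. By default all circles
#' are equal (contour evenly split); an explicit radius list may be supplied
#' for unequal circles, in which case the circle circumferences must sum to
#' the molecule's contour length.
#'
#' @param n_spools Number of spools k (positive integer).
#' @param circles_per_spool Circles per spool c (positive integer, default 1).
#' @param circle_radii_nm Optional numeric vector of per-circle radii, nm.
#' @return An object of class `spool_configuration`.
#' @export
spool_configuration <- function(n_spools, circles_per_spool = 1L,
                                circle_radii_nm = NULL) {
  if (!is.numeric(n_spools) || length(n_spools) != 1L ||
      n_spools < 1 || n_spools != round(n_spools))
    stop("n_spools must be a positive integer")
  if (!is.numeric(circles_per_spool) || length(circles_per_spool) != 1L ||
      circles_per_spool < 1 || circles_per_spool != round(circles_per_spool))
    stop("circles_per_spool must be a positive integer")
  if (!is.null(circle_radii_nm)) {
    if (!is.numeric(circle_radii_nm) || any(circle_radii_nm <= 0))
      stop("circle_radii_nm must be positive")
  }
  structure(
    list(
      n_spools = as.integer(n_spools),
      circles_per_spool = as.integer(circles_per_spool),
      circle_radii_nm = circle_radii_nm
    ),
    class = "spool_configuration"
  )
}

#' Bending energy of a single DNA circle of given circumference
#'
#' Closed-form worm-like-chain bending energy of one full circle of
#' circumference `contour_nm`: the line integral (A/2) * kappa^2 over the
#' circle, which evaluates to `2 * pi^2 * A / L` (in kBT).
#'
#' @param contour_nm Circle circumference L, nm.
#' @param A Bending persistence length, nm.
#' @return Energy in kBT.
#' @examples
#' circle_bending_energy(4361 * 0.34, 52.2) # ~0.695 kBT
#' @export
circle_bending_energy <- function(contour_nm, A) {
  stopifnot(is.numeric(contour_nm), is.numeric(A))
  if (any(contour_nm <= 0)) stop("contour_nm must be positive")
  if (any(A <= 0)) stop("A must be positive")
  2 * pi^2 * A / contour_nm
}

#' Bending energy of one circle of given radius
#'
#' `pi * A / R` in kBT: the bending energy of a full circle of radius R.
#' Inside a compacted spool the radius shrinks from periphery to core, so
#' this per-circle cost grows inward.
#'
#' @param R_nm Circle radius, nm.
#' @param A Bending persistence length, nm.
#' @return Energy per circle, kBT.
#' @export
circle_energy_from_radius <- function(R_nm, A) {
  stopifnot(is.numeric(R_nm), is.numeric(A))
  if (any(R_nm <= 0)) stop("R_nm must be positive")
  if (any(A <= 0)) stop("A must be positive")
  pi * A / R_nm
}

#' Total bending energy of a k-spool arrangement
#'
#' With m = k * c equal circles each of length L/m, the total bending energy
#' is m^2 times the single-circle energy 2 pi^2 A / L. If explicit radii are
#' supplied, the per-circle energies (pi*A/R_i weighted by the number of
#' turns L_i / (2 pi R_i) = 1 per full circle) are summed instead; the two
#' forms coincide for equal circles.
#'
#' @param mol A [dna_molecule()].
#' @param config A [spool_configuration()].
#' @return Total bending energy in kBT.
#' @examples
#' mol <- dna_molecule(4361)
#' kspool_bending_energy(mol, spool_configuration(2)) # ~2.778 kBT
#' @export
kspool_bending_energy <- function(mol, config) {
  stopifnot(inherits(mol, "dna_molecule"),
            inherits(config, "spool_configuration"))
  L <- contour_length(mol)
  A <- mol$bend_persistence_nm
  if (!is.null(config$circle_radii_nm)) {
    radii <- config$circle_radii_nm
    circ <- 2 * pi * radii
    if (abs(sum(circ) - L) > 1e-6 * L)
      stop("circle circumferences must sum to the contour length")
    return(sum(circle_energy_from_radius(radii, A)))
  }
  m <- config$n_spools * config$circles_per_spool
  m^2 * circle_bending_energy(L, A)
}

#' Probability of a k-spool mechanically balanced state
#'
#' With N possible transient force distributions along the molecule, a
#' k-spool must balance k independent sub-systems simultaneously, giving a
#' probability N^(-k). The argument starts at the dual spool (k = 2).
#'
#' @param k Number of spools (integer >= 2).
#' @param N Number of possible force distributions (integer >= 1).
#' @return `N^(-k)`.
#' @export
spool_multiplicity_probability <- function(k, N) {
  stopifnot(is.numeric(k), is.numeric(N), length(k) == 1L, length(N) == 1L)
  if (k < 2 || k != round(k)) stop("k must be an integer >= 2")
  if (N < 1 || N != round(N)) stop("N must be a positive integer")
  N^(-k)
}

#' Relative probability of a k1-spool versus a k2-spool
#'
#' @param k1,k2 Spool multiplicities (integers >= 2).
#' @param N Number of possible force distributions.
#' @return `N^(k2 - k1)`, the ratio P(k1) / P(k2).
#' @export
relative_spool_probability <- function(k1, k2, N) {
  spool_multiplicity_probability(k1, N) / spool_multiplicity_probability(k2, N)
}

#' Rank spool configurations by bending energy
#'
#' Evaluates the equal-circle k-spool closed form for each requested k and
#' returns a table sorted by ascending energy. The `self_balanced` flag is a
#' model constant: only the dual spool (k = 2) is taken to achieve a
#' self-balanced state in which the coiled strands hold each other under
#' tension; a single spool, though lower in energy, cannot.
#'
#' @param mol A [dna_molecule()].
#' @param ks Integer vector of spool counts to evaluate.
#' @param circles_per_spool Circles per spool, default 1.
#' @return A data.frame with columns `k`, `energy_kBT`, `self_balanced`,
#'   sorted by ascending energy.
#' @export
rank_configurations <- function(mol, ks, circles_per_spool = 1L) {
  stopifnot(inherits(mol, "dna_molecule"))
  if (length(ks) == 0) stop("ks must be non-empty")
  if (any(ks < 1) || any(ks != round(ks))) stop("ks must be positive integers")
  energy <- vapply(ks, function(k) {
    kspool_bending_energy(mol, spool_configuration(k, circles_per_spool))
  }, numeric(1))
  out <- data.frame(
    k = as.integer(ks),
    energy_kBT = energy,
    self_balanced = as.integer(ks) == 2L
  )
  out[order(out$energy_kBT), , drop = FALSE]
}
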