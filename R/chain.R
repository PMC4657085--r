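#' Closed, inextensible chain conformation
#'
#' A discretized circular DNA: `n` vertices in 3D (nm), interpreted
#' cyclically, all segments of equal length `b`; a stored total duplex twist
#' in turns; and an optional set of kink defects, each pinned to a junction
#' with a preferred bend angle and a softened stiffness.
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates, nm.
#' @param segment_length_nm Segment length b, nm. Inferred from the vertices
#'   when `NULL`.
#' @param total_twist_turns Total duplex twist Tw, turns.
#' @param kinks `NULL` or a data.frame with columns `index` (1-based junction
#'   index), `preferred_bend_deg`, `stiffness_factor` in (0, 1].
#' @param linking_number Optional stored linking number; defaults to
#'   `total_twist_turns` + the writhe of the vertices.
#' @param tolerance Relative tolerance for the equal-segment-length check.
#' @return An object of class `chain_conformation`.
#' @export
chain_conformation <- function(vertices, segment_length_nm = NULL,
                               total_twist_turns = 0, kinks = NULL,
                               linking_number = NULL, tolerance = 1e-6) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  n <- nrow(vertices)
  if (n < 6) stop("a closed chain needs at least 6 vertices")
  seg <- vertices[c(2:n, 1), , drop = FALSE] - vertices
  lens <- sqrt(rowSums(seg^2))
  b <- if (is.null(segment_length_nm)) mean(lens) else segment_length_nm
  if (any(abs(lens - b) > tolerance * b))
    stop("segments must all have length b (closed, inextensible chain)")
  if (!is.null(kinks)) {
    kinks <- as.data.frame(kinks)
    stopifnot(all(c("index", "preferred_bend_deg", "stiffness_factor")
                  %in% names(kinks)))
    if (anyDuplicated(kinks$index)) stop("kink indices must be distinct")
    if (any(kinks$index < 1 | kinks$index > n)) stop("kink index out of range")
    if (any(kinks$stiffness_factor <= 0 | kinks$stiffness_factor > 1))
      stop("stiffness_factor must lie in (0, 1]")
  } else {
    kinks <- data.frame(index = integer(), preferred_bend_deg = numeric(),
                        stiffness_factor = numeric())
  }
  ch <- structure(
    list(vertices = unname(vertices), segment_length_nm = b,
         total_twist_turns = total_twist_turns, kinks = kinks,
         linking_number = NA_real_),
    class = "chain_conformation"
  )
  ch$linking_number <- if (is.null(linking_number))
    total_twist_turns + writhe_gauss(ch) else linking_number
  ch
}

#' @export
print.chain_conformation <- function(x, ...) {
  cat(sprintf(
    "<chain_conformation> n = %d, b = %.3f nm, Tw = %.3f turns, Lk = %.3f, %d kink(s)\n",
    nrow(x$vertices), x$segment_length_nm, x$total_twist_turns,
    x$linking_number, nrow(x$kinks)
  ))
  invisible(x)
}

#' Build a planar circular chain for a molecule
#'
#' Regular n-gon whose perimeter equals the molecule's contour length, lying
#' in the xy-plane. The writhe of a planar circle is zero, so any linking
#' deficit `delta_linking` initially lives entirely in twist:
#' Tw = relaxed turns + delta_linking.
#'
#' @param mol A [dna_molecule()].
#' @param n_segments Number of segments (>= 6).
#' @param delta_linking Linking-number deficit in turns (default 0).
#' @return A `chain_conformation`.
#' @export
make_circle_chain <- function(mol, n_segments = 100L, delta_linking = 0) {
  stopifnot(inherits(mol, "dna_molecule"))
  n <- as.integer(n_segments)
  if (n < 6) stop("n_segments must be at least 6")
  L <- contour_length(mol)
  b <- L / n
  R <- b / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1) / n
  verts <- cbind(R * cos(th), R * sin(th), 0)
  tw <- relaxed_turns(mol) + delta_linking
  chain_conformation(verts, segment_length_nm = b, total_twist_turns = tw,
                     linking_number = tw) # Wr = 0 exactly for a planar circle
}

#' Writhe of a closed chain (Gauss double integral)
#'
#' Exact pairwise segment-segment evaluation of the Gauss linking integral
#' of the centerline with itself; adjacent segment pairs contribute zero and
#' are skipped. Invariant under rigid motion and uniform scaling.
#'
#' @param chain A `chain_conformation` (or bare n x 3 vertex matrix).
#' @return The writhe, a real number.
#' @export
writhe_gauss <- function(chain) {
  verts <- if (inherits(chain, "chain_conformation")) chain$vertices
           else as.matrix(chain)
  if (min_nonadjacent_distance_cpp(verts) < 1e-9)
    stop("chain has (near-)intersecting segment pairs; writhe undefined")
  writhe_gauss_cpp(verts)
}

#' Stored twist of a chain, in turns
#' @param chain A `chain_conformation`.
#' @return Tw in turns.
#' @export
chain_twist <- function(chain) {
  stopifnot(inherits(chain, "chain_conformation"))
  chain$total_twist_turns
}

#' Linking number of a chain
#'
#' White/Calugareanu bookkeeping: Lk = Tw + Wr, with Wr from the Gauss
#' integral over the current vertices.
#'
#' @param chain A `chain_conformation`.
#' @return Lk (real; integer-valued for a physically closed duplex up to
#'   discretization).
#' @export
linking_number <- function(chain) {
  stopifnot(inherits(chain, "chain_conformation"))
  chain$total_twist_turns + writhe_gauss(chain)
}

#' Elastic energy components of a chain
#'
#' Discrete worm-like-chain energies (kBT): bend = (A/b) * sum(1 - cos
#' theta_i) over non-kink junctions; kink junctions contribute
#' `stiffness_factor * (A/b) * (1 - cos(theta - preferred))`; twist =
#' 2 pi^2 C (Tw - Tw0)^2 / L; overlap is an infinite hard-wall penalty when
#' any non-adjacent segment pair approaches closer than
#' `excluded_diameter_nm`.
#'
#' @param chain A `chain_conformation`.
#' @param mol A [dna_molecule()].
#' @param excluded_diameter_nm Hard-wall diameter, nm (default 4; 0 disables).
#' @return A list with components `bend`, `twist`, `kink`, `overlap`, and
#'   `total` (all kBT).
#' @export
chain_energy <- function(chain, mol, excluded_diameter_nm = 4) {
  stopifnot(inherits(chain, "chain_conformation"), inherits(mol, "dna_molecule"))
  e <- chain_energy_cpp(
    chain$vertices, chain$segment_length_nm,
    mol$bend_persistence_nm, mol$twist_persistence_nm, contour_length(mol),
    chain$total_twist_turns, relaxed_turns(mol),
    as.integer(chain$kinks$index - 1L), chain$kinks$preferred_bend_deg,
    chain$kinks$stiffness_factor, excluded_diameter_nm
  )
  e$total <- e$bend + e$twist + e$kink + e$overlap
  e
}

#' Inject platinum-adduct defects into a chain
#'
#' Places `round(fraction * n_divalent)` kink defects at uniformly sampled
#' distinct junctions (preferred bend 150 degrees, stiffness factor 0.3 by
#' default — sharp bends of up to 180 degrees with a softened hinge), and
#' reduces the linking number by `n_divalent * untwist_turn_per_adduct` to
#' model local duplex unwinding.
#'
#' @param chain A `chain_conformation`.
#' @param n_divalent Divalent Pt adducts per molecule (real).
#' @param fraction Sharp-bend fraction, default 0.16.
#' @param untwist_turn_per_adduct Unwinding per divalent adduct, turns,
#'   default 0.05.
#' @param seed Integer seed for kink placement.
#' @param preferred_bend_deg,stiffness_factor Kink defect parameters.
#' @return A new `chain_conformation` with kinks and reduced Lk (the Lk
#'   change is booked into stored twist, leaving the geometry untouched).
#' @export
inject_adducts <- function(chain, n_divalent, fraction = 0.16,
                           untwist_turn_per_adduct = 0.05, seed = 1L,
                           preferred_bend_deg = 150, stiffness_factor = 0.3) {
  stopifnot(inherits(chain, "chain_conformation"))
  if (n_divalent < 0) stop("n_divalent must be non-negative")
  n <- nrow(chain$vertices)
  n_kinks <- round(fraction * n_divalent)
  if (n_kinks > n) stop("requested kinks exceed available junctions")
  if (n_divalent == 0) return(chain)
  set.seed(as.integer(seed))
  idx <- sort(sample.int(n, n_kinks))
  kinks <- data.frame(index = idx,
                      preferred_bend_deg = rep(preferred_bend_deg, n_kinks),
                      stiffness_factor = rep(stiffness_factor, n_kinks))
  dlk <- n_divalent * untwist_turn_per_adduct
  chain_conformation(chain$vertices, chain$segment_length_nm,
                     total_twist_turns = chain$total_twist_turns - dlk,
                     kinks = kinks,
                     linking_number = chain$linking_number - dlk)
}

#' Write a chain to an XYZ-style text file
#'
#' One vertex per line (`x y z`), preceded by a count line and a comment
#' line carrying `b=`, `tw=`, `lk=` and the kink table as `key=value`
#' fields.
#'
#' @param chain A `chain_conformation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chain_xyz <- function(chain, path) {
  stopifnot(inherits(chain, "chain_conformation"))
  n <- nrow(chain$vertices)
  kstr <- if (nrow(chain$kinks) > 0) {
    paste(apply(chain$kinks, 1, function(r)
      sprintf("%d:%g:%g", as.integer(r[["index"]]), r[["preferred_bend_deg"]],
              r[["stiffness_factor"]])), collapse = ",")
  } else ""
  comment <- sprintf("b=%.12g tw=%.12g lk=%.12g kinks=%s",
                     chain$segment_length_nm, chain$total_twist_turns,
                     chain$linking_number, kstr)
  lines <- c(as.character(n), comment,
             apply(chain$vertices, 1, function(v)
               sprintf("%.12g %.12g %.12g", v[1], v[2], v[3])))
  writeLines(lines, path)
  invisible(path)
}

#' Read a chain from an XYZ-style text file written by [write_chain_xyz()]
#'
#' @param path Input file path.
#' @return A `chain_conformation`.
#' @export
read_chain_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  fields <- strsplit(strsplit(lines[2], " ")[[1]], "=")
  kv <- stats::setNames(
    vapply(fields, function(f) paste(f[-1], collapse = "="), character(1)),
    vapply(fields, `[`, character(1), 1)
  )
  verts <- do.call(rbind, lapply(lines[3:(2 + n)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  kinks <- NULL
  if (nzchar(kv[["kinks"]])) {
    parts <- strsplit(strsplit(kv[["kinks"]], ",")[[1]], ":")
    kinks <- data.frame(
      index = vapply(parts, function(p) as.integer(p[1]), integer(1)),
      preferred_bend_deg = vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
      stiffness_factor = vapply(parts, function(p) as.numeric(p[3]), numeric(1))
    )
  }
  chain_conformation(verts, as.numeric(kv[["b"]]),
                     total_twist_turns = as.numeric(kv[["tw"]]),
                     kinks = kinks, linking_number = as.numeric(kv[["lk"]]))
}

#' Resample a closed curve into equal-length chords
#'
#' Turns a densely sampled closed polyline into a closed polygon of `n`
#' equal edges: vertices are first placed at uniform arc-length spacing
#' (edges then already agree to the corner-cutting error), after which
#' iterative distance-constraint projection (Gauss-Seidel over edges, as in
#' SHAKE) equalizes every edge to the common mean. The correction is a small
#' perturbation of the inscribed polygon, so the curve's topology and
#' writhe are preserved.
#'
#' @param points Dense m x 3 matrix tracing the closed curve (m >> n).
#' @param n Number of chords wanted.
#' @return An n x 3 matrix of vertices with equal edges to ~1e-9 relative.
#' @export
resample_equal_segments <- function(points, n) {
  pts <- as.matrix(points)
  m <- nrow(pts)
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seglen <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                          closed[-(m + 1), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[m + 1]
  # uniform arc-length placement
  targets <- total * (seq_len(n) - 1) / n
  idx <- findInterval(targets, cum, rightmost.closed = TRUE)
  frac <- (targets - cum[idx]) / pmax(seglen[idx], 1e-300)
  v <- closed[idx, , drop = FALSE] +
    (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE]) * frac
  # Gauss-Seidel projection onto the equal-edge constraint manifold
  nxt <- c(2:n, 1)
  b <- mean(sqrt(rowSums((v[nxt, , drop = FALSE] - v)^2)))
  for (sweep in 1:10000) {
    worst <- 0
    for (i in seq_len(n)) {
      j <- nxt[i]
      d <- v[j, ] - v[i, ]
      l <- sqrt(sum(d^2))
      err <- (l - b) / l
      worst <- max(worst, abs(l - b))
      corr <- 0.5 * err * d
      v[i, ] <- v[i, ] + corr
      v[j, ] <- v[j, ] - corr
    }
    if (worst < 1e-10 * b) break
  }
  lens <- sqrt(rowSums((v[nxt, , drop = FALSE] - v)^2))
  if ((max(lens) - min(lens)) > 1e-7 * b)
    stop("equal-chord resampling did not converge for this curve")
  v
}
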