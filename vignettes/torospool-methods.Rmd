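---
title: "Toroidal-spool mechanics and nucleoid cluster analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Toroidal-spool mechanics and nucleoid cluster analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`torospool` models how a mechanically stressed circular DNA molecule packages
itself into toroidal spools, and analyses how the corresponding structures
(HNS protein clusters marking DNA spool cores) develop in live *E. coli*
imaged by PALM. It has five parts: closed-form worm-like-chain (WLC)
energetics of k-spool arrangements; bookkeeping that converts platinum-adduct
counts into predicted sharp bends; a closed elastic-rod Metropolis Monte-Carlo
simulator with writhe/twist/linking-number accounting; a density-based cluster
pipeline for 2D localization tables; and seeded synthetic-data generators that
stand in for AFM and PALM raw data, which are not publicly archived.

# The elastic model

A circle of circumference $L$ made of WLC material with bending persistence
length $A$ carries bending energy (in $k_BT$)

$$E_1 = \frac{A}{2}\oint \kappa^2\, ds = \frac{A}{2}\cdot\frac{1}{R^2}\cdot L
      = \frac{2\pi^2 A}{L}.$$

Splitting the molecule into $m = k\,c$ equal circles (k spools of c circles)
multiplies the curvature by $m$ and divides each circle's length by $m$, so
the total is $E_m = m^2 E_1$. For a 4,361-bp plasmid (rise 0.34 nm/bp,
$L = 1482.74$ nm) at $A = 52.2$ nm this gives 0.695, 2.780 and 6.254 $k_BT$
for one, two and three circles. Note the reference values quoted for this
system (0.695 / 2.778 / 6.255) are not mutually consistent at the third
decimal — exact algebra forces the dual spool to be exactly $4\times$ the
single — so the package reports the closed form unmodified.

$A = 52.2$ nm is itself obtained by inverting $2\pi^2A/L = 0.695$; it is a
configurable default, as are the rise (0.34 nm/bp), the torsional persistence
length $C = 95$ nm and the helical repeat (10.5 bp/turn). Energies are in
$k_BT$ throughout; there is no absolute-temperature parameter.

The per-circle form $E(R) = \pi A/R$ expresses the same energy through the
circle radius: spool compaction drives radii down and per-circle cost up
(0.91 $k_BT$ at $R \approx 180$ nm, 5.44 $k_BT$ at $R \approx 30$ nm; these
radii are reconstructions by inversion, not measured values). The
multi-spool probability argument is kept symbolic: a k-spool must balance k
sub-systems simultaneously, probability $N^{-k}$ in the number $N$ of
possible transient force distributions; $N$ is never assigned a magnitude.
The `self_balanced` flag in `rank_configurations()` encodes, as a documented
model constant, that only the dual spool achieves a self-balanced state: the
single spool is lower in energy but has no opposing partner to hold it under
tension.

# Adduct stress bookkeeping

Sharp bends per molecule are 16% of the divalently crosslinked Pt atoms
(`sharp_bends()`, unrounded; display rounding is one decimal, half-up). The
module deliberately *reports* the comparison between predicted bends and the
writhe increase over the intact baseline rather than asserting equality:
at the 4-hour point the prediction (6.016) exceeds the observed increase
(4.2) under the "increase over intact" reading, and the quoted ~1.3 bends at
1 h disagrees with $0.16 \times 7.6 = 1.216$; both discrepancies are
surfaced, not hidden. Two comparison modes ("increase", "absolute") are
exposed; "increase" is the default.

# The chain simulator

The molecule is a closed polygon of $n$ equal segments of length $b$ with

* bend energy $(A/b)\sum_i(1-\cos\theta_i)$ over ordinary junctions,
* kink junctions (adduct defects) contributing
  $f\,(A/b)\,(1-\cos(\theta_i - \theta_0))$ with preferred bend
  $\theta_0 = 150^\circ$ and stiffness factor $f = 0.3$ by default — the
  source material says only "sharp bends of up to 180°", so both are
  configurable,
* twist energy $2\pi^2 C\,\Delta Tw^2/L$ with $\Delta Tw$ in turns,
* a hard-wall overlap penalty when non-adjacent segments approach closer
  than 4 nm (helix diameter plus hydration; configurable, 0 disables).

Writhe is computed by the exact polygon segment-pair formula for the Gauss
double integral (adjacent pairs are skipped; they contribute zero). The
independent test oracle computes writhe a second way, as the average signed
crossing number over ~10^3 Fibonacci-distributed projection directions, and
the two routes must agree within 0.05.

Monte Carlo uses only crankshaft moves — rotate the sub-chain between two
random vertices about their chord by a uniform angle up to 90° — because
they preserve closure and every segment length *exactly*; no pivot or
reptation moves are needed for a closed chain and they would complicate
correctness. Moves are accepted with $\min(1, e^{-\Delta E})$. In the
default torsionally constrained (unnicked) mode the linking number is fixed
and $Tw = Lk - Wr$ is recomputed after each accepted move, so torsional
stress converts into writhe; "nicked" mode pins $Tw$ at the relaxed value
and carries no twist energy. One seeded generator drives each run and the
seed is recorded; identical seeds give bitwise-identical trajectories.

Adduct injection places `round(0.16 * n_divalent)` kinks at uniformly
sampled distinct junctions and reduces $Lk$ by 0.05 turn per divalent adduct
(the unwinding per adduct is quantified only qualitatively in the source;
0.05 is a configurable default). The intact molecule starts at
$\Delta Lk = -2$, chosen so the relaxed surface-like conformation carries a
writhe magnitude of order the observed ~1.9; solution supercoiling density
is not modelled.

Two numerical points are worth recording. First, the equipartition check:
for a closed ring the bending ground state is *not* zero energy — the
regular n-gon carries $n(A/b)(1-\cos(2\pi/n))$ — and the $2n-6$ internal
modes share only the energy in excess of that minimum. The excess per mode
equals $k_BT/2$ within a few percent across stiffnesses $A/b$ from ~9 to
~90, which validates both the move set and the acceptance rule. Second, the
incremental writhe update after a crankshaft move only needs the pairs that
cross the moved/unmoved boundary; accumulated drift is removed by a full
recomputation every 2000 steps.

The conformation classifier mirrors the pictorial staging of auto-packaging
AFM images and is explicitly heuristic: the chain is projected onto its
best-fit plane, crossings counted, and segment midpoints clustered by
density (radius $0.6\,b$: stacked circles within a spool sit much closer
than one segment length, while a loose ring's midpoints do not) into lobes.
Stage 0 is at most two crossings and one lobe; stages 1–3 are crossing bins
3–4, 5–6, 7–9; the dual-spool stages (4–5) additionally require exactly two
lobes each holding at least 30% of segments. The bins are module constants
calibrated on constructed fixtures (planar circle, lifted figure-eight,
single and dual solenoids), which are generated analytically with known
writhe sign and lobe count.

Deliberately out of scope: Brownian dynamics, hydrodynamics, sequence
effects, electrostatics/salt, and any modelling of AFM surface deposition —
which is why measured AFM writhe values (1.9 → 6.1) and the ≥90% dual-spool
fraction are replaced by property-based checks (monotone writhe growth under
the adduct schedule, White's theorem $Lk = Tw + Wr$ on every frame,
classifier correctness on fixtures).

# The PALM cluster pipeline

Localization tables (cell id, frame, x, y, precision) and spherocylindrical
cell outlines enter as CSV; points are registered into the cell frame
(origin at the centroid, x along the major axis). Detection is plain DBSCAN
with defaults eps = 30 nm, min_pts = 15, and a 50-localization minimum
cluster size. The radius deserves a note: with ~300 localizations per
cluster spread over ~65 nm (60 nm cluster spread plus 25 nm localization
error), an eps of 60 nm lets two clusters bridge whenever their centres
approach ~0.33 um, which happens often in the fast-growth newborn geometry
(adjacent separations ~0.43 ± 0.11 um) and silently biases the surviving
distance sample upward by ~0.05 um. At eps = 30 nm the merge threshold
drops to ~0.25 um, the phase-i detection rate stays at 100%, and the
residual selection bias is below 0.01 um. These defaults were tuned once on
generator truth and are exposed in the API and CLI.

Distances are 2D Euclidean centroid separations ("consecutive" = neighbours
in axis order; "all" = every pair); the three-cluster angle is measured at
the axially middle cluster. Distance samples are summarized by mean, SD, and
a 1- vs 2-component normal mixture fit chosen by BIC (ties toward fewer
components). The EM fit constrains components to a common variance by
default: with a few hundred distances and peaks ~2.7 SD apart the
heteroscedastic fit is weakly identified and its component means wander by
more than the acceptance band, while the homoscedastic fit recovers the
1.41/1.65 um peaks stably. The free-variance fit remains available
(`equal_var = FALSE`).

Phase classification uses the published cell-length ranges (1.7–2.5 um for
newborn, 2.6–3.7 um for middle-aged/old; the open gap is split at 2.55 um):
two clusters short → i (ii once the parental cluster is less than half its
partner's size), three → iii, two long → iv, at most one detectable
mid-cycle → v, four → vi. Mode strings run-length-encode the count series
after dropping runs shorter than two time points (detection flicker) and
zero-count frames (the smeared phase has no countable clusters — without
this the canonical "2-3-2-4" series would read "2-3-2-0-4"). Cluster
lineages are tracked by greedy nearest-neighbour matching with a 0.4 um
gate. Individual cycles are normalized to a 120-minute schedule before
phase aggregation.

# The synthetic generators

The generators state a world and keep it fixed: slow-growth phase-i cells
carry two clusters at separations N(0.88, 0.10) um in cells 1.7–2.5 um long;
phase-iv cells draw separations from the mixture 0.6 N(1.41, 0.09) +
0.4 N(1.65, 0.09), whose weights and widths were chosen once so the overall
mean/SD match 1.50/0.15 while the component means sit at the published
peaks; fast-growth newborns place three clusters with adjacent separations
N(0.43, 0.11) and vertex angle uniform(40°, 180°), so the distal distance
arises by the law of cosines rather than being drawn — any distal peak is
emergent. Each cluster emits 300 localizations (60 nm isotropic spread plus
25 nm localization error — a typical PALM precision, not a published one)
over a 2 points/um^2 uniform background, clipped to the spherocylinder.
Values the source does not state were chosen once at realistic scales and
documented here: phase-iii adjacent separations N(0.70, 0.10) with
near-collinear angles N(180°, 10°); phase-vi pairs at quarter positions with
intra-pair separations N(0.60, 0.08); fast cells 1.0 um wide, 2.0–3.0 um
long; the smeared phase emits two diffuse 0.4-um blobs below the detection
density. Generator truth (centres, separations, angles, seed) is recorded
for every cell; all randomness flows from one seed per call.

What a green end-to-end test establishes is therefore parameter *recovery*:
generate → write CSV → read → detect → measure returns the stated
population parameters within three standard errors. It does not establish
anything about mEos2 photophysics (blinking and repeated localizations are
not modelled; each table row is one localization), drift, 3D structure, or
the ~15% of cells that stop growing under 405-nm irradiation — all
deliberately outside the generator.

# Numerical choices and degenerate inputs

* Equal-chord resampling of analytic fixture curves places vertices at
  uniform arc length and then equalizes edges by Gauss–Seidel
  distance-constraint projection (SHAKE); greedy chord-walking has no exact
  solution on coiled curves.
* `writhe_gauss()` refuses chains with a non-adjacent segment pair at
  (near-)zero distance, where the integrand is singular.
* Mixture EM floors component SDs at 1e-3 of the sample SD, discards
  collapsed components, and breaks BIC ties toward one component; a
  zero-variance sample short-circuits to a single peak.
* `simulate_time_course(steps = 0)` returns the initial summary; empty
  adduct schedules return the baseline chain.
* Separations that do not fit the drawn cell are redrawn (at most 100
  attempts); with the default phase parameters the truncation affects
  < 0.1% of draws and shifts means by far less than a standard error.
* All CLI configuration is JSON (`jsonlite`); no YAML parser is assumed.

# Known limitations

The stage classifier is a heuristic calibrated on idealized fixtures; its
bins have no claim to AFM ground truth. The simulator's kink and untwist
parameters are plausible defaults, not fits, so the fraction of simulated
molecules reaching a dual-spool state is reported, never asserted. Writhe
observations are treated as unsigned magnitudes. The MC move set, while
exact, equilibrates slowly for tightly compacted chains with excluded
volume; the packaged tests run at chain sizes (n = 30–60) where mixing is
demonstrably adequate.
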