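#' Platinum adduct state of a molecule population at one time point
#'
#' Records the measured total and divalently crosslinked platinum adduct
#' counts per DNA molecule at a given incubation time, together with the
#' fraction of divalent adducts that produce a sharp bend (default 0.16, the
#' empirical 16% rule from combined ICP-MS and denaturing-gel measurements).
#'
#' @param time_h Incubation time, hours (non-negative).
#' @param pt_divalent Divalent Pt adducts per molecule (non-negative).
#' @param pt_total Total Pt adducts per molecule; defaults to `pt_divalent`.
#' @param sharp_bend_fraction Fraction of divalent adducts causing a sharp
#'   bend, in \[0, 1\]. Default 0.16.
#' @return An object of class `adduct_state`.
#' @export
adduct_state <- function(time_h, pt_divalent, pt_total = pt_divalent,
                         sharp_bend_fraction = 0.16) {
  stopifnot(is.numeric(time_h), is.numeric(pt_divalent), is.numeric(pt_total),
            is.numeric(sharp_bend_fraction))
  if (time_h < 0) stop("time_h must be non-negative")
  if (pt_divalent < 0) stop("pt_divalent must be non-negative")
  if (pt_divalent > pt_total) stop("pt_divalent cannot exceed pt_total")
  if (sharp_bend_fraction < 0 || sharp_bend_fraction > 1)
    stop("sharp_bend_fraction must lie in [0, 1]")
  structure(
    list(time_h = time_h, pt_total = pt_total, pt_divalent = pt_divalent,
         sharp_bend_fraction = sharp_bend_fraction),
    class = "adduct_state"
  )
}

#' AFM writhe observation at one time point
#'
#' @param time_h Incubation time, hours.
#' @param mean_writhe Mean unsigned writhe number per molecule.
#' @param sem Standard error of the mean (non-negative).
#' @param n_molecules Number of molecules scored (positive integer).
#' @return An object of class `writhe_observation`.
#' @export
writhe_observation <- function(time_h, mean_writhe, sem = 0, n_molecules = 1L) {
  stopifnot(is.numeric(time_h), is.numeric(mean_writhe), is.numeric(sem))
  if (time_h < 0) stop("time_h must be non-negative")
  if (sem < 0) stop("sem must be non-negative")
  if (n_molecules < 1 || n_molecules != round(n_molecules))
    stop("n_molecules must be a positive integer")
  structure(
    list(time_h = time_h, mean_writhe = mean_writhe, sem = sem,
         n_molecules = as.integer(n_molecules)),
    class = "writhe_observation"
  )
}

#' Expected sharp bends per molecule from an adduct state
#'
#' Applies the 16% rule: sharp bends = fraction x divalent Pt count,
#' unrounded.
#'
#' @param state An [adduct_state()].
#' @return Expected sharp-bend count per molecule (numeric, unrounded).
#' @examples
#' sharp_bends(adduct_state(2, 11.3)) # 1.808, displays as 1.8
#' @export
sharp_bends <- function(state) {
  stopifnot(inherits(state, "adduct_state"))
  state$sharp_bend_fraction * state$pt_divalent
}

#' Round half up to a number of decimals (display convention)
#'
#' Base R `round()` rounds half to even; measured counts here are displayed
#' with one decimal, half rounded up, matching the printed precision of the
#' source measurements.
#'
#' @param x Numeric.
#' @param digits Decimal places, default 1.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Increase in writhe over a baseline observation
#'
#' @param obs,baseline [writhe_observation()] objects.
#' @return A list with `delta` (obs minus baseline mean writhe) and `sem`
#'   (propagated in quadrature).
#' @export
increased_writhe <- function(obs, baseline) {
  stopifnot(inherits(obs, "writhe_observation"),
            inherits(baseline, "writhe_observation"))
  list(delta = obs$mean_writhe - baseline$mean_writhe,
       sem = sqrt(obs$sem^2 + baseline$sem^2))
}

#' Compare predicted sharp bends with observed writhe changes
#'
#' For each paired time point, tabulates the predicted sharp-bend count
#' (16% rule) against the writhe change relative to baseline (mode
#' `"increase"`, the default) or the absolute writhe (mode `"absolute"`),
#' and summarizes the agreement. Agreement is reported, never asserted: the
#' two quantities track each other over the early time course but are not
#' equal by construction.
#'
#' @param series A list of `list(adducts = adduct_state, writhe =
#'   writhe_observation)` pairs.
#' @param baseline A [writhe_observation()] for the intact molecule.
#' @param mode `"increase"` (writhe minus baseline) or `"absolute"`.
#' @return A list with a per-row `table` (data.frame: time_h, pt_divalent,
#'   predicted_bends, observed_writhe, abs_diff), `max_abs_diff`, and
#'   `pearson_r` (NA when fewer than 2 distinct rows).
#' @export
stress_writhe_agreement <- function(series, baseline,
                                    mode = c("increase", "absolute")) {
  mode <- match.arg(mode)
  if (length(series) == 0) stop("series must contain at least one pair")
  stopifnot(inherits(baseline, "writhe_observation"))
  rows <- lapply(series, function(pair) {
    stopifnot(inherits(pair$adducts, "adduct_state"),
              inherits(pair$writhe, "writhe_observation"))
    pred <- sharp_bends(pair$adducts)
    obs <- if (mode == "increase")
      increased_writhe(pair$writhe, baseline)$delta
    else pair$writhe$mean_writhe
    data.frame(time_h = pair$adducts$time_h,
               pt_divalent = pair$adducts$pt_divalent,
               predicted_bends = pred,
               observed_writhe = obs,
               abs_diff = abs(pred - obs))
  })
  tab <- do.call(rbind, rows)
  r <- if (nrow(tab) >= 2 &&
           stats::sd(tab$predicted_bends) > 0 &&
           stats::sd(tab$observed_writhe) > 0) {
    stats::cor(tab$predicted_bends, tab$observed_writhe)
  } else NA_real_
  list(table = tab, max_abs_diff = max(tab$abs_diff), pearson_r = r)
}
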