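#' Respiratory exchange ratio
#'
#' RER = VCO2 / VO2, the ratio of carbon dioxide produced to oxygen
#' consumed. Values near 1 indicate preferential carbohydrate oxidation,
#' values near 0.7 preferential fat oxidation. Scale-invariant: units
#' cancel as long as both gas rates share them.
#'
#' @param vo2 O2 consumption rate (> 0), vectorized.
#' @param vco2 CO2 production rate (>= 0), vectorized.
#' @return Numeric vector of RER values.
#' @examples
#' rer(vo2 = 1, vco2 = 1)    # carbohydrate limit
#' rer(vo2 = 1, vco2 = 0.7)  # fat limit
#' @export
rer <- function(vo2, vco2) {
  if (any(vo2 <= 0)) stop("input error: vo2 must be > 0")
  vco2 / vo2
}

#' Glucose oxidation rate from gas exchange
#'
#' `((4.585 * VCO2) - (3.226 * VO2)) * 4`, the standard stoichiometric
#' estimate of carbohydrate-derived energy expenditure from indirect
#' calorimetry. Negative values (possible at very low RER) are reported
#' as-is, never clipped; callers may flag them.
#'
#' @inheritParams rer
#' @return Numeric vector of glucose oxidation rates (energy per time, in
#'   the units implied by the gas rates).
#' @examples
#' glucoseOxidation(vo2 = 1, vco2 = 1)  # 5.436
#' @export
glucoseOxidation <- function(vo2, vco2) {
  ((4.585 * vco2) - (3.226 * vo2)) * 4
}

#' Fat oxidation rate from gas exchange
#'
#' `((1.695 * VO2) - (1.701 * VCO2)) * 9`. At RER = 1 (pure carbohydrate
#' oxidation) this is near zero and slightly negative — a property of the
#' coefficients, reported as-is.
#'
#' @inheritParams rer
#' @return Numeric vector of fat oxidation rates.
#' @examples
#' fatOxidation(vo2 = 1, vco2 = 1)    # -0.054
#' fatOxidation(vo2 = 1, vco2 = 0.7)  # fat limit, positive
#' @export
fatOxidation <- function(vo2, vco2) {
  ((1.695 * vo2) - (1.701 * vco2)) * 9
}

#' Correct measurements for lean body mass
#'
#' Elementwise division of a measurement by each animal's lean mass, the
#' usual normalization of whole-animal gas-exchange rates.
#'
#' @param values numeric vector of measurements.
#' @param leanMass lean mass per record (> 0), recycled against `values`.
#' @return `values / leanMass`.
#' @export
leanMassCorrect <- function(values, leanMass) {
  if (any(leanMass <= 0)) stop("input error: leanMass must be > 0")
  values / leanMass
}

#' Per-animal, per-phase calorimetry summary
#'
#' Applies [rer()], [glucoseOxidation()] and [fatOxidation()] to
#' time-binned records, corrects the oxidation rates for lean mass, and
#' averages within each animal x phase (fed / fasted / refed) cell. Phase
#' labels come from an explicit column, not from food-intake inference.
#' Records with negative oxidation rates are counted per summary row in a
#' warning column rather than being clipped, which would bias phase means.
#'
#' @param records a data.frame with columns `animal_id`, `time_bin`,
#'   `vo2`, `vco2`, `lean_mass` and `phase`.
#' @return A data.frame with one row per animal x phase: mean RER, mean
#'   lean-mass-corrected glucose and fat oxidation, number of bins, and
#'   `n_negative_oxidation`.
#' @export
summarizeCalorimetry <- function(records) {
  need <- c("animal_id", "vo2", "vco2", "lean_mass", "phase")
  if (!all(need %in% names(records)))
    stop("input error: records need columns ",
         paste(need, collapse = ", "))
  if (any(records$vo2 <= 0)) stop("input error: vo2 must be > 0")
  if (any(records$vco2 < 0)) stop("input error: vco2 must be >= 0")
  if (any(records$lean_mass <= 0))
    stop("input error: lean_mass must be > 0")
  r <- rer(records$vo2, records$vco2)
  gox <- leanMassCorrect(glucoseOxidation(records$vo2, records$vco2),
                         records$lean_mass)
  fox <- leanMassCorrect(fatOxidation(records$vo2, records$vco2),
                         records$lean_mass)
  key <- interaction(records$animal_id, records$phase, drop = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  lev <- levels(key)
  split1 <- vapply(strsplit(lev, ".", fixed = TRUE), `[`, "", 1L)
  split2 <- sub("^[^.]*\\.", "", lev)
  out <- data.frame(
    animal_id = split1,
    phase = split2,
    mean_rer = agg(r, mean),
    mean_glucose_oxidation = agg(gox, mean),
    mean_fat_oxidation = agg(fox, mean),
    n_bins = as.integer(tapply(r, key, length)),
    n_negative_oxidation = as.integer(tapply(gox < 0 | fox < 0, key, sum)),
    stringsAsFactors = FALSE)
  out[order(out$animal_id, out$phase), , drop = FALSE]
}
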