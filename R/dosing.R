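#' Porcine body surface area
#'
#' Allometric BSA formula for pigs, \eqn{SA = 0.0970 \cdot W^{0.633}} with
#' \eqn{W} the body weight in kg and SA in m2.
#'
#' @param weightKg body weight in kg (> 0); vectorised.
#' @return Body surface area in m2.
#' @examples
#' bodySurfaceArea(71)  # 1.4408 m2
#' @export
bodySurfaceArea <- function(weightKg) {
  if (any(weightKg <= 0)) stop("weight must be > 0")
  0.0970 * weightKg^0.633
}

#' BSA-based carboplatin dose
#'
#' Dose in mg for a given body weight and dosing rate per m2 body surface
#' area. The value is returned unrounded; printed doses are conventionally
#' rounded to the nearest mg (see [doseTable()]). At 800 mg/m2 the 71-83 kg
#' weight range gives 1153-1272 mg.
#'
#' @param weightKg body weight in kg (> 0); vectorised.
#' @param dosePerM2 dose rate in mg/m2 (>= 0).
#' @return Dose in mg.
#' @examples
#' round(carboplatinDose(c(71, 83), 800))  # 1153, 1272
#' @export
carboplatinDose <- function(weightKg, dosePerM2) {
  if (any(dosePerM2 < 0)) stop("dosePerM2 must be >= 0")
  dosePerM2 * bodySurfaceArea(weightKg)
}

#' Dosing table for a set of animals
#'
#' The doses.csv contract: per-animal surface area and dose, with the dose
#' rounded to the nearest mg for reporting.
#'
#' @param weightsKg numeric body weights (kg).
#' @param dosePerM2 dose rate (mg/m2).
#' @param animalIds optional identifiers; defaults to pig1..pigN.
#' @return data.frame: animal_id, weight_kg, surface_area_m2, dose_mg.
#' @export
doseTable <- function(weightsKg, dosePerM2,
                      animalIds = paste0("pig", seq_along(weightsKg))) {
  data.frame(animal_id = animalIds, weight_kg = weightsKg,
             surface_area_m2 = bodySurfaceArea(weightsKg),
             dose_mg = round(carboplatinDose(weightsKg, dosePerM2)))
}

#' Convert micromolar concentration to ug/mL
#'
#' \eqn{\mu M \times M / 1000} where M is the molar mass in g/mol; e.g.
#' a 51.3 uM carboplatin threshold is 19 ug/mL at 371.25 g/mol.
#'
#' @param concUM concentration in umol/L (> 0); vectorised.
#' @param molarMassGPerMol molar mass in g/mol (> 0); carboplatin is
#'   371.25 g/mol.
#' @return Concentration in ug/mL.
#' @examples
#' round(micromolarToUgPerMl(51.3, 371.25))  # 19
#' @export
micromolarToUgPerMl <- function(concUM, molarMassGPerMol = 371.25) {
  if (any(concUM <= 0)) stop("concentration must be > 0")
  if (any(molarMassGPerMol <= 0)) stop("molar mass must be > 0")
  concUM * molarMassGPerMol / 1000
}
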