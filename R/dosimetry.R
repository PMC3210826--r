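## Inhalation dosimetry arithmetic: cumulative inhaled mass, regional
## deposited mass from user-supplied deposition fractions, tissue dose,
## particle surface-area dose, and lung retention. Deposition fractions
## come from an external deposition model and are inputs here, not outputs.

#' Cumulative inhaled mass
#'
#' `days x hours/day x aerosol concentration (mg/m^3) x inhaled volume rate
#' (m^3/hr)`, in mg per animal. For a mouse, a typical inhaled volume rate
#' is 0.0018 m^3/hr.
#'
#' @param days Exposure days.
#' @param hoursPerDay Exposure hours per day.
#' @param concentration Aerosol mass concentration, mg/m^3.
#' @param inhaledVolumePerHour Inhaled volume rate, m^3/hr.
#' @return Inhaled mass in mg per animal.
#' @examples
#' cumulativeInhaledMass(11, 1, 42.4, 0.0018)   # ~0.840 mg/animal
#' @export
cumulativeInhaledMass <- function(days, hoursPerDay, concentration,
                                  inhaledVolumePerHour) {
  args <- c(days, hoursPerDay, concentration, inhaledVolumePerHour)
  if (any(!is.finite(args)) || any(args < 0))
    stop("all regimen parameters must be finite and non-negative")
  days * hoursPerDay * concentration * inhaledVolumePerHour
}

#' Regional deposited mass
#'
#' Splits an inhaled mass over respiratory-tract regions using deposition
#' fractions (each in `[0, 1]`, sum at most 1). The undeposited remainder is
#' returned as `residual`, so mass is conserved exactly.
#'
#' @param total Inhaled mass (any mass unit; outputs share it).
#' @param fractions Named numeric vector of region deposition fractions,
#'   e.g. `c(pulmonary = ..., tracheobronchial = ...)`.
#' @return Named numeric vector of per-region masses plus `residual`.
#' @examples
#' regionalDeposition(840, c(pulmonary = 72.5 / 840,
#'                           tracheobronchial = 48 / 840,
#'                           gastrointestinal = 356 / 840,
#'                           head = 267 / 840))
#' @export
regionalDeposition <- function(total, fractions) {
  if (!is.finite(total) || total < 0) stop("'total' must be >= 0")
  if (any(fractions < 0 | fractions > 1))
    stop("deposition fractions must be in [0, 1]")
  if (sum(fractions) > 1 + 1e-12)
    stop("deposition fractions must sum to at most 1")
  c(total * fractions, residual = total * (1 - sum(fractions)))
}

#' Tissue dose
#'
#' Deposited mass divided by organ mass, reported as mg analyte per kg
#' tissue. Inputs use the units the quantities are usually reported in
#' (deposited mass in micrograms, organ mass in milligrams); the result is
#' an intensive quantity, invariant to consistent rescaling.
#'
#' @param depositedUg Deposited mass, micrograms.
#' @param organMassMg Organ (e.g. lung) mass, milligrams.
#' @return Dose in mg/kg.
#' @examples
#' tissueDose(72.5, 274)   # ~265 mg/kg
#' @export
tissueDose <- function(depositedUg, organMassMg) {
  if (any(organMassMg <= 0)) stop("organ mass must be > 0")
  if (any(depositedUg < 0)) stop("deposited mass must be >= 0")
  (depositedUg * 1e-3) / (organMassMg * 1e-6)   # mg / kg
}

#' Lung retention percentage
#'
#' Measured tissue concentration as a percentage of the predicted deposited
#' concentration.
#'
#' @param measured Measured concentration (e.g. mg/kg).
#' @param predicted Predicted deposited concentration, same units, > 0.
#' @return Percentage (0-100 scale, may exceed 100).
#' @examples
#' retentionPercent(38, 112)   # ~34 %
#' retentionPercent(38, 159)   # ~24 %
#' @export
retentionPercent <- function(measured, predicted) {
  if (any(predicted <= 0)) stop("'predicted' must be > 0")
  if (any(measured < 0)) stop("'measured' must be >= 0")
  100 * measured / predicted
}

#' Particle surface-area dose
#'
#' Deposited mass times the specific surface area of the material, in cm^2.
#'
#' @param massUg Deposited mass, micrograms.
#' @param ssaM2PerG Specific surface area, m^2/g.
#' @return Surface area in cm^2.
#' @examples
#' surfaceAreaDose(72.5, 107.7)   # ~78.1 cm^2
#' @export
surfaceAreaDose <- function(massUg, ssaM2PerG) {
  if (any(ssaM2PerG <= 0)) stop("specific surface area must be > 0")
  if (any(massUg < 0)) stop("mass must be >= 0")
  massUg * 1e-6 * ssaM2PerG * 1e4             # g * m^2/g -> cm^2
}

#' Dosimetry report
#'
#' Computes the full dose chain for one exposure scenario: cumulative
#' inhaled mass, regional deposited masses, pulmonary tissue dose,
#' surface-area dose, and (if a measured concentration is given) lung
#' retention. Reported values follow the conventional printed precision:
#' 3 decimals for mg, nearest integer for mg/kg and percent.
#'
#' @param days,hoursPerDay,concentration,inhaledVolumePerHour Exposure
#'   regimen (see [cumulativeInhaledMass]).
#' @param fractions Named deposition fractions (see [regionalDeposition]).
#' @param lungMassMg Lung mass in mg.
#' @param ssaM2PerG Specific surface area of the material, m^2/g.
#' @param measuredMgKg Optional measured tissue concentration, mg/kg.
#' @param predictedMgKg Optional predicted concentration(s) for retention.
#' @return A data.frame with columns `quantity`, `value`, `unit`.
#' @examples
#' doseReport(11, 1, 42.4, 0.0018,
#'            fractions = c(pulmonary = 72.5 / 840,
#'                          tracheobronchial = 48 / 840),
#'            lungMassMg = 274, ssaM2PerG = 107.7)
#' @export
doseReport <- function(days, hoursPerDay, concentration,
                       inhaledVolumePerHour, fractions, lungMassMg,
                       ssaM2PerG = NULL, measuredMgKg = NULL,
                       predictedMgKg = NULL) {
  inhaledMg <- cumulativeInhaledMass(days, hoursPerDay, concentration,
                                     inhaledVolumePerHour)
  dep <- regionalDeposition(inhaledMg * 1000, fractions)   # micrograms
  rows <- data.frame(
    quantity = c("cumulative inhaled mass",
                 paste("deposited mass,", names(dep))),
    value = c(round(inhaledMg, 3), round(unname(dep), 1)),
    unit = c("mg/animal", rep("ug", length(dep))))
  if ("pulmonary" %in% names(fractions)) {
    pulm <- unname(dep[["pulmonary"]])
    rows <- rbind(rows, data.frame(
      quantity = "pulmonary tissue dose",
      value = round(tissueDose(pulm, lungMassMg)), unit = "mg/kg"))
    if (!is.null(ssaM2PerG))
      rows <- rbind(rows, data.frame(
        quantity = "pulmonary surface-area dose",
        value = round(surfaceAreaDose(pulm, ssaM2PerG), 1), unit = "cm2"))
  }
  if (!is.null(measuredMgKg) && !is.null(predictedMgKg))
    rows <- rbind(rows, data.frame(
      quantity = paste0("retention vs predicted ", predictedMgKg, " mg/kg"),
      value = round(retentionPercent(measuredMgKg, predictedMgKg)),
      unit = "%"))
  rows
}
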