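#' Cockcroft-Gault creatinine clearance
#'
#' `CrCl (mL/min) = (140 - age) * weight / (72 * Scr)`, multiplied by 0.85
#' for female patients. This is the renal-function measure that feeds the
#' clearance covariate model (after conversion to L/h with [crcl_to_L_h()]).
#'
#' @param age Age in years (> 17; adult cohort).
#' @param weight Total body weight in kg (> 0).
#' @param scr Serum creatinine in mg/dL (> 0).
#' @param sex Character vector, `"male"` or `"female"`.
#' @return Creatinine clearance in mL/min.
#' @export
#' @examples
#' cockcroft_gault(age = 60, weight = 70, scr = 1, sex = "male")
cockcroft_gault <- function(age, weight, scr, sex) {
  sex <- match_sex(sex)
  if (any(age <= 17)) abort("`age` must be > 17 years.")
  if (any(weight <= 0)) abort("`weight` must be > 0 kg.")
  if (any(scr <= 0)) abort("`scr` must be > 0 mg/dL.")
  crcl <- (140 - age) * weight / (72 * scr)
  ifelse(sex == "female", 0.85 * crcl, crcl)
}

#' CKD-EPI estimated glomerular filtration rate (2009 creatinine equation)
#'
#' `eGFR = 141 * min(Scr/kappa, 1)^alpha * max(Scr/kappa, 1)^-1.209 *
#' 0.993^age * 1.018 [female] * 1.159 [black]` with `kappa` 0.7 (female) /
#' 0.9 (male) and `alpha` -0.329 (female) / -0.411 (male). Used to place
#' patients into KDIGO chronic-kidney-disease categories.
#'
#' @inheritParams cockcroft_gault
#' @param black Logical; apply the 1.159 race coefficient of the original
#'   2009 equation. Default `FALSE`.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
#' @examples
#' ckd_epi(scr = 0.9, age = 55, sex = "female")
ckd_epi <- function(scr, age, sex, black = FALSE) {
  sex <- match_sex(sex)
  if (any(scr <= 0)) abort("`scr` must be > 0 mg/dL.")
  if (any(age <= 0)) abort("`age` must be > 0 years.")
  kappa <- ifelse(sex == "female", 0.7, 0.9)
  alpha <- ifelse(sex == "female", -0.329, -0.411)
  egfr <- 141 *
    pmin(scr / kappa, 1)^alpha *
    pmax(scr / kappa, 1)^-1.209 *
    0.993^age
  egfr <- ifelse(sex == "female", egfr * 1.018, egfr)
  ifelse(rep_len(black, length(egfr)), egfr * 1.159, egfr)
}

#' KDIGO glomerular filtration rate category
#'
#' Maps eGFR (mL/min/1.73 m^2) onto the KDIGO chronic-kidney-disease GFR
#' bands. Boundaries are lower-inclusive: 90 is `G1_normal`, 15 is
#' `G4_severe`.
#'
#' @param gfr eGFR in mL/min/1.73 m^2 (> 0).
#' @return Factor with levels `G1_normal` (>= 90), `G2` (60--89), `G3a`
#'   (45--59), `G3b` (30--44), `G4_severe` (15--29), `G5_failure` (< 15).
#' @export
#' @examples
#' kdigo_category(c(95, 20, 10))
kdigo_category <- function(gfr) {
  if (any(gfr <= 0)) abort("`gfr` must be > 0.")
  cut(
    gfr,
    breaks = c(0, 15, 30, 45, 60, 90, Inf),
    labels = c("G5_failure", "G4_severe", "G3b", "G3a", "G2", "G1_normal"),
    right = FALSE
  )
}

match_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  bad <- !sex %in% c("male", "female")
  if (any(bad)) abort("`sex` must be \"male\" or \"female\".")
  sex
}
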