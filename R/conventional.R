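# Conventional echocardiographic and hemodynamic measures. Units are locked:
# lengths cm, velocities cm/s, pressures mmHg, volumes mL, mass g.

#' Total left-ventricular wall thickness
#'
#' LVWT is the interventricular septum width plus the posterior wall width.
#'
#' @param ivs_cm,pw_cm septal and posterior wall widths, cm, `> 0`.
#' @return LVWT in cm.
#' @export
lvwt <- function(ivs_cm, pw_cm) {
  check_positive(ivs_cm = ivs_cm, pw_cm = pw_cm)
  ivs_cm + pw_cm
}

#' Relative wall thickness
#'
#' RWT is total wall thickness (septum + posterior wall) divided by the LV
#' end-diastolic diameter — note this is the total-thickness definition, not
#' the `2*PW/LVDD` variant.
#'
#' @param lvwt_cm total wall thickness, cm.
#' @param lvdd_cm LV end-diastolic diameter, cm.
#' @return dimensionless RWT.
#' @examples
#' rwt(1.8, 4.0)  # 0.45
#' @export
rwt <- function(lvwt_cm, lvdd_cm) {
  check_positive(lvwt_cm = lvwt_cm, lvdd_cm = lvdd_cm)
  lvwt_cm / lvdd_cm
}

#' Mean arterial pressure
#'
#' `MAP = DBP + (SBP - DBP)/3`. Strictly between DBP and SBP.
#'
#' @param sbp,dbp systolic and diastolic pressures, mmHg, with `sbp > dbp > 0`.
#' @return MAP in mmHg.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  check_positive(dbp = dbp)
  if (any(sbp <= dbp)) stop("sbp must exceed dbp")
  dbp + (sbp - dbp) / 3
}

#' Teichholz LV volumes and ejection fraction
#'
#' Converts linear LV diameters to volumes with the Teichholz cubic
#' `V = 7.0 / (2.4 + D) * D^3` (D in cm, V in mL) and derives the ejection
#' fraction `EF = 100 * (EDV - ESV) / EDV`.
#'
#' @param lvdd_cm,lvsd_cm end-diastolic and end-systolic diameters, cm,
#'   with `0 < lvsd_cm < lvdd_cm`.
#' @return List with `edv_ml`, `esv_ml`, `ef_pct`.
#' @examples
#' teichholz_volumes_ef(4.0, 2.88)
#' @export
teichholz_volumes_ef <- function(lvdd_cm, lvsd_cm) {
  check_positive(lvdd_cm = lvdd_cm, lvsd_cm = lvsd_cm)
  if (any(lvsd_cm >= lvdd_cm)) stop("lvsd must be smaller than lvdd")
  edv <- teichholz_volume(lvdd_cm)
  esv <- teichholz_volume(lvsd_cm)
  list(edv_ml = edv, esv_ml = esv, ef_pct = 100 * (edv - esv) / edv)
}

teichholz_volume <- function(d_cm) 7.0 / (2.4 + d_cm) * d_cm^3

#' Fractional shortening
#'
#' `FS = (LVDD - LVSD) / LVDD`, dimensionless in `(0, 1)`.
#'
#' @inheritParams teichholz_volumes_ef
#' @return dimensionless FS.
#' @export
fractional_shortening <- function(lvdd_cm, lvsd_cm) {
  check_positive(lvdd_cm = lvdd_cm, lvsd_cm = lvsd_cm)
  if (any(lvsd_cm >= lvdd_cm)) stop("lvsd must be smaller than lvdd")
  (lvdd_cm - lvsd_cm) / lvdd_cm
}

#' Left-ventricular mass (linear method)
#'
#' ASE linear-method cube formula:
#' `0.8 * 1.04 * ((IVS + LVDD + PW)^3 - LVDD^3) + 0.6` grams.
#'
#' @param ivs_cm,lvdd_cm,pw_cm linear measures, cm, `> 0`.
#' @return LV mass in grams.
#' @export
lv_mass_devereux <- function(ivs_cm, lvdd_cm, pw_cm) {
  check_positive(ivs_cm = ivs_cm, lvdd_cm = lvdd_cm, pw_cm = pw_cm)
  0.8 * 1.04 * ((ivs_cm + lvdd_cm + pw_cm)^3 - lvdd_cm^3) + 0.6
}

#' Diastolic velocity ratios
#'
#' `E/A` (transmitral early to atrial peak velocity) and `E/e'` (transmitral
#' early to lateral-annulus early tissue velocity).
#'
#' @param e_vel,a_vel,e_prime peak velocities, cm/s, `> 0`.
#' @return List with `e_a_ratio`, `e_eprime_ratio`.
#' @export
diastolic_ratios <- function(e_vel, a_vel, e_prime) {
  check_positive(e_vel = e_vel, a_vel = a_vel, e_prime = e_prime)
  list(e_a_ratio = e_vel / a_vel, e_eprime_ratio = e_vel / e_prime)
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || anyNA(x) || any(x <= 0))
      stop(nm, " must be positive")
  }
  invisible(TRUE)
}
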