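#' Chemical-shift calibration constants for pH and free Mg2+
#'
#' Bundles the titration constants that map chemical shifts to physiology:
#' the Henderson--Hasselbalch calibration of the intracellular inorganic
#' phosphate (Pi) shift relative to PCr, and the 1:1 Mg--ATP binding isotherm
#' for the alpha--beta ATP shift difference. Defaults are the values in common
#' use for in-vivo 31P work; all are configurable because published
#' calibrations differ slightly between laboratories.
#'
#' @param pka acid dissociation constant of the Pi titration (unitless).
#' @param delta_acid limiting Pi shift of the fully protonated form, ppm
#'   relative to PCr at 0 ppm.
#' @param delta_base limiting Pi shift of the fully deprotonated form, ppm.
#' @param kd_mgatp dissociation constant of the Mg-ATP complex, mM.
#' @param delta_ab_free alpha-beta ATP shift difference of Mg-free ATP, ppm.
#' @param delta_ab_bound alpha-beta ATP shift difference of fully Mg-bound
#'   ATP, ppm.
#' @return an object of class \code{mrs_calibration}.
#' @examples
#' calib <- mrs_calibration()
#' ph_from_delta(4.82, calib)
#' @export
mrs_calibration <- function(pka = 6.75,
                            delta_acid = 3.27,
                            delta_base = 5.69,
                            kd_mgatp = 0.05,
                            delta_ab_free = 10.82,
                            delta_ab_bound = 8.24) {
  stopifnot(is.numeric(pka), length(pka) == 1L)
  if (delta_acid == delta_base) stop("delta_acid and delta_base must differ")
  if (delta_ab_free == delta_ab_bound)
    stop("delta_ab_free and delta_ab_bound must differ")
  if (kd_mgatp <= 0) stop("kd_mgatp must be > 0")
  structure(list(pka = pka,
                 delta_acid = delta_acid,
                 delta_base = delta_base,
                 kd_mgatp = kd_mgatp,
                 delta_ab_free = delta_ab_free,
                 delta_ab_bound = delta_ab_bound),
            class = "mrs_calibration")
}

#' @export
print.mrs_calibration <- function(x, ...) {
  cat("31P MRS calibration constants\n")
  cat(sprintf("  Pi titration : pKa %.3f, limits %.3f (acid) .. %.3f (base) ppm\n",
              x$pka, x$delta_acid, x$delta_base))
  cat(sprintf("  Mg-ATP       : Kd %.3f mM, delta(a-b) %.3f (free) .. %.3f (bound) ppm\n",
              x$kd_mgatp, x$delta_ab_free, x$delta_ab_bound))
  invisible(x)
}

#' Intracellular pH from the Pi chemical shift
#'
#' Henderson--Hasselbalch relation: the observed Pi shift is the
#' population-weighted average of the protonated and deprotonated limiting
#' shifts, so \eqn{pH = pKa + \log_{10}((\delta_{Pi} - \delta_{acid}) /
#' (\delta_{base} - \delta_{Pi}))}. Strictly monotone on the open interval
#' between the two limiting shifts.
#'
#' @param delta_pi Pi chemical shift in ppm relative to PCr at 0 ppm.
#' @param calib an \code{\link{mrs_calibration}} object.
#' @return pH (unitless).
#' @export
ph_from_delta <- function(delta_pi, calib = mrs_calibration()) {
  lo <- min(calib$delta_acid, calib$delta_base)
  hi <- max(calib$delta_acid, calib$delta_base)
  if (any(delta_pi <= lo) || any(delta_pi >= hi))
    stop(sprintf("delta_pi must lie strictly inside (%.4f, %.4f) ppm", lo, hi))
  calib$pka + log10((delta_pi - calib$delta_acid) /
                    (calib$delta_base - delta_pi))
}

#' Pi chemical shift from pH (inverse titration map)
#'
#' Exact inverse of \code{\link{ph_from_delta}}; used by the simulator to
#' position the intracellular Pi resonance for a prescribed ground-truth pH.
#'
#' @param ph pH value(s), strictly inside the admissible range implied by the
#'   calibration (the titration map is a bijection of the whole real line onto
#'   the open shift interval, so any finite pH is admissible).
#' @param calib an \code{\link{mrs_calibration}} object.
#' @return Pi shift in ppm relative to PCr.
#' @export
delta_pi_from_ph <- function(ph, calib = mrs_calibration()) {
  if (any(!is.finite(ph)))
    stop("pH must be finite; the admissible shift interval is (delta_acid, delta_base)")
  r <- 10^(ph - calib$pka)
  (calib$delta_acid + r * calib$delta_base) / (1 + r)
}

#' Free Mg2+ concentration from the alpha-beta ATP shift difference
#'
#' 1:1 Mg-ATP binding isotherm: the observed shift difference interpolates
#' between the Mg-free and Mg-bound limits with the bound fraction
#' \eqn{[Mg]/(K_d + [Mg])}, giving
#' \eqn{[Mg] = K_d (\delta_{ab} - \delta_{free}) / (\delta_{bound} -
#' \delta_{ab})}.
#'
#' @param delta_ab shift difference delta(alpha-ATP) - delta(beta-ATP) in ppm,
#'   strictly between the free and bound limiting values.
#' @param calib an \code{\link{mrs_calibration}} object.
#' @return free Mg2+ concentration in mM.
#' @export
mg_from_delta <- function(delta_ab, calib = mrs_calibration()) {
  f <- calib$delta_ab_free
  b <- calib$delta_ab_bound
  lo <- min(f, b); hi <- max(f, b)
  if (any(delta_ab <= lo) || any(delta_ab >= hi)) {
    bad <- delta_ab[delta_ab <= lo | delta_ab >= hi][1L]
    side <- if (abs(bad - b) <= abs(bad - f)) "Mg-saturated (bound)" else "Mg-free"
    stop(sprintf(
      "delta_ab = %.4f ppm is at/outside the admissible interval (%.4f, %.4f); %s limit reached",
      bad, lo, hi, side))
  }
  calib$kd_mgatp * (delta_ab - f) / (b - delta_ab)
}

#' Alpha-beta ATP shift difference from free Mg2+ (inverse binding map)
#'
#' Exact inverse of \code{\link{mg_from_delta}}; used by the simulator to set
#' the beta-ATP position for a prescribed ground-truth Mg2+ concentration.
#'
#' @param mg free Mg2+ concentration in mM, > 0.
#' @param calib an \code{\link{mrs_calibration}} object.
#' @return shift difference delta(alpha) - delta(beta) in ppm.
#' @export
delta_ab_from_mg <- function(mg, calib = mrs_calibration()) {
  if (any(mg <= 0)) stop("mg must be > 0 mM")
  f <- calib$delta_ab_free
  b <- calib$delta_ab_bound
  f + (b - f) * mg / (calib$kd_mgatp + mg)
}
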