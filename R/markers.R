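#' Total-ATP signal
#'
#' The t-ATP signal is the arithmetic mean (not the sum) of the alpha-, beta-
#' and gamma-ATP resonance areas.
#'
#' @param alpha,beta,gamma non-negative resonance areas.
#' @return mean of the three areas.
#' @export
total_atp <- function(alpha, beta, gamma) {
  if (any(c(alpha, beta, gamma) < 0)) stop("ATP areas must be >= 0")
  (alpha + beta + gamma) / 3
}

#' p-BEM markers for one region from a spectral fit
#'
#' Converts fitted peak areas and chemical shifts into the phosphate
#' brain-energy-metabolism markers: energy reserve (PCr/t-ATP), energy
#' consumption (intracellular Pi/t-ATP), metabolic state (intracellular
#' Pi/PCr), the extracellular-Pi ratios, the membrane phospholipid index
#' PME/PDE = (PE+PC)/(GPE+GPC) (sums, not means), intracellular pH from the
#' Pi_in shift, and free Mg2+ from the alpha-beta ATP shift difference. pH and
#' Mg2+ depend only on chemical shifts; all ratio indices are invariant to a
#' common scaling of the areas.
#'
#' @param fit a \code{fit_result} from \code{\link{fit_spectrum}}.
#' @param region region label (frontal, temporal, parietal, occipital).
#' @param calib an \code{\link{mrs_calibration}} object.
#' @return one-row data.frame of class \code{region_markers} with columns
#'   region, energy_reserve, energy_consumption, metabolic_state,
#'   pi_ex_over_tatp, pi_ex_over_pcr, pme_pde, ph, mg, t_atp.
#' @export
bem_indices <- function(fit, region, calib = mrs_calibration()) {
  stopifnot(inherits(fit, "fit_result"))
  if (!isTRUE(fit$convergence$converged))
    stop("bem_indices: fit did not converge")
  a <- function(nm) fit$peaks$area[fit$peaks$name == nm]
  t_atp <- total_atp(a("aATP"), a("bATP"), a("gATP"))
  pcr <- a("PCr")
  pde <- a("GPE") + a("GPC")
  if (t_atp == 0) stop("bem_indices: t-ATP area is zero")
  if (pcr == 0) stop("bem_indices: PCr area is zero")
  if (pde == 0) stop("bem_indices: PDE (GPE+GPC) sum is zero")
  out <- data.frame(
    region = region,
    energy_reserve = pcr / t_atp,
    energy_consumption = a("Pi_in") / t_atp,
    metabolic_state = a("Pi_in") / pcr,
    pi_ex_over_tatp = a("Pi_ex") / t_atp,
    pi_ex_over_pcr = a("Pi_ex") / pcr,
    pme_pde = (a("PE") + a("PC")) / pde,
    ph = ph_from_delta(fit$delta_pi, calib),
    mg = mg_from_delta(fit$delta_ab, calib),
    t_atp = t_atp,
    stringsAsFactors = FALSE)
  class(out) <- c("region_markers", class(out))
  out
}

marker_names <- function() {
  c("energy_reserve", "energy_consumption", "metabolic_state",
    "pi_ex_over_tatp", "pi_ex_over_pcr", "pme_pde", "ph", "mg")
}

region_names <- function() {
  c("frontal", "temporal", "parietal", "occipital")
}
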