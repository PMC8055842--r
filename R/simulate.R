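#' Acquisition parameters for a simulated 31P experiment
#'
#' Defaults mirror a 7T whole-brain 31P protocol: 2048 complex points
#' (zero-filled to 4096 before Fourier transform by the preprocessing chain),
#' TR 0.5 s, TE 0.5 ms. The spectral width and transmitter frequency determine
#' the ppm axis; the carrier is placed at \code{center_ppm} relative to PCr so
#' the whole metabolite range (about +7 to -16.5 ppm) sits well inside the
#' window.
#'
#' @param n_points number of complex samples (>= 2, power of two by default).
#' @param spectral_width sampling bandwidth in Hz; dwell time is its inverse.
#' @param transmitter_frequency 31P carrier frequency in MHz (about 120.6 at
#'   7T). One ppm equals \code{transmitter_frequency} Hz.
#' @param repetition_time TR in seconds.
#' @param echo_time TE in milliseconds.
#' @param center_ppm carrier position on the PCr-referenced ppm axis.
#' @return an object of class \code{acq_params}.
#' @export
acq_params <- function(n_points = 2048L,
                       spectral_width = 6000,
                       transmitter_frequency = 120.6,
                       repetition_time = 0.5,
                       echo_time = 0.5,
                       center_ppm = -5) {
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be >= 2")
  if (spectral_width <= 0) stop("spectral_width must be > 0")
  if (transmitter_frequency <= 0) stop("transmitter_frequency must be > 0")
  structure(list(n_points = n_points,
                 spectral_width = spectral_width,
                 transmitter_frequency = transmitter_frequency,
                 repetition_time = repetition_time,
                 echo_time = echo_time,
                 center_ppm = center_ppm,
                 dwell_time = 1 / spectral_width),
            class = "acq_params")
}

#' The 13-resonance 31P metabolite panel
#'
#' Returns the default resonance templates: phosphoethanolamine (PE),
#' phosphocholine (PC), extracellular and intracellular inorganic phosphate
#' (Pi_ex, Pi_in), glycerophosphoethanolamine (GPE), glycerophosphocholine
#' (GPC), phosphocreatine (PCr, fixed at 0 ppm by convention), the three ATP
#' phosphate spins (gamma, alpha, beta), NAD, UDPG, and a broad macromolecule
#' (MM) component. Centers are standard 31P positions relative to PCr; only
#' PCr = 0 ppm is fixed by the referencing convention. Areas are relative
#' signal units; widths are Gaussian/Lorentzian FWHM in ppm.
#'
#' @param areas optional named numeric vector overriding default areas.
#' @param centers optional named numeric vector overriding default centers.
#' @return data.frame with columns name, center, area, gaussian_width,
#'   lorentzian_width.
#' @export
resonance_panel <- function(areas = NULL, centers = NULL) {
  panel <- data.frame(
    name = c("PE", "PC", "Pi_ex", "Pi_in", "GPE", "GPC", "MM",
             "PCr", "gATP", "aATP", "NAD", "UDPG", "bATP"),
    center = c(6.78, 6.24, 5.25, 4.82, 3.50, 3.01, 2.05,
               0.00, -2.53, -7.63, -8.31, -9.81, -16.39),
    area = c(1.2, 1.0, 0.4, 1.1, 0.9, 1.3, 2.5,
             3.3, 3.0, 3.0, 0.9, 0.6, 3.0),
    gaussian_width = c(rep(0.06, 6), 0.45, rep(0.06, 6)),
    lorentzian_width = c(rep(0.04, 6), 0.30, rep(0.04, 6)),
    stringsAsFactors = FALSE
  )
  if (!is.null(areas)) {
    stopifnot(all(names(areas) %in% panel$name))
    panel$area[match(names(areas), panel$name)] <- unname(areas)
  }
  if (!is.null(centers)) {
    stopifnot(all(names(centers) %in% panel$name))
    panel$center[match(names(centers), panel$name)] <- unname(centers)
  }
  validate_panel(panel)
  panel
}

panel_names <- function() {
  c("PE", "PC", "Pi_ex", "Pi_in", "GPE", "GPC", "MM",
    "PCr", "gATP", "aATP", "NAD", "UDPG", "bATP")
}

validate_panel <- function(panel) {
  need <- panel_names()
  if (!setequal(panel$name, need) || nrow(panel) != 13L)
    stop("panel must contain exactly the 13 named resonances")
  if (any(panel$area < 0)) stop("areas must be >= 0")
  if (panel$center[panel$name == "PCr"] != 0)
    stop("PCr center is fixed at 0 ppm (referencing convention)")
  if (any(panel$gaussian_width < 0) || any(panel$lorentzian_width < 0))
    stop("widths must be >= 0")
  if (any(panel$gaussian_width == 0 & panel$lorentzian_width == 0 &
          panel$area > 0))
    stop("a resonance with signal must have at least one nonzero width")
  invisible(panel)
}

#' Ground truth for one simulated spectrum
#'
#' Houses everything the simulator needs: the 13-resonance panel, the
#' physiological state (pH and free Mg2+, which position the intracellular Pi
#' and beta-ATP resonances through the calibration maps), the complex noise
#' level, frequency-domain polynomial baseline coefficients, and the seed.
#'
#' @param panel resonance templates, see \code{\link{resonance_panel}}.
#' @param ph ground-truth intracellular pH.
#' @param mg ground-truth free Mg2+ in mM (> 0).
#' @param noise_sd standard deviation of the additive circular complex
#'   Gaussian noise per FID sample (real and imaginary parts each).
#' @param baseline_coefficients polynomial coefficients (constant first) of a
#'   smooth frequency-domain baseline evaluated on ppm/10.
#' @param seed integer RNG seed.
#' @param calib calibration constants used by the shift maps.
#' @return an object of class \code{ground_truth}; \code{$panel} has Pi_in and
#'   bATP centers overridden by the pH and Mg maps.
#' @export
ground_truth <- function(panel = resonance_panel(),
                         ph = 7.0,
                         mg = 0.2,
                         noise_sd = 0,
                         baseline_coefficients = 0,
                         seed = 1L,
                         calib = mrs_calibration()) {
  validate_panel(panel)
  if (mg <= 0) stop("mg must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  panel$center[panel$name == "Pi_in"] <- delta_pi_from_ph(ph, calib)
  delta_ab <- delta_ab_from_mg(mg, calib)
  panel$center[panel$name == "bATP"] <-
    panel$center[panel$name == "aATP"] - delta_ab
  structure(list(panel = panel, ph = ph, mg = mg,
                 noise_sd = noise_sd,
                 baseline_coefficients = baseline_coefficients,
                 seed = seed, calib = calib),
            class = "ground_truth")
}

#' Simulate a 31P free induction decay
#'
#' Sums one damped complex exponential per resonance. The decay envelope is
#' exponential for the Lorentzian width and Gaussian for the Gaussian width,
#' so the real part of the Fourier transform of the noiseless signal is an
#' exact Voigt profile for each resonance, with FWHM contributions equal to
#' the panel widths and frequency-domain (ppm) integral equal to the panel
#' area. Additive circular complex Gaussian noise models thermal noise; a
#' frequency-domain polynomial baseline (if requested in the truth) is added
#' after transform by \code{\link{to_spectrum}}.
#'
#' @param truth a \code{\link{ground_truth}} object.
#' @param acq an \code{\link{acq_params}} object.
#' @return an object of class \code{fid}.
#' @export
simulate_fid <- function(truth, acq = acq_params()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(acq, "acq_params"))
  f0 <- acq$transmitter_frequency          # Hz per ppm
  half_sw_ppm <- acq$spectral_width / 2 / f0
  lo <- acq$center_ppm - half_sw_ppm
  hi <- acq$center_ppm + half_sw_ppm
  out <- truth$panel$center <= lo | truth$panel$center >= hi
  if (any(out))
    stop(sprintf("resonance %s at %.2f ppm falls outside the spectral window [%.2f, %.2f]",
                 truth$panel$name[which(out)[1L]],
                 truth$panel$center[which(out)[1L]], lo, hi))
  tt <- (seq_len(acq$n_points) - 1L) * acq$dwell_time
  sig <- rep(0 + 0i, acq$n_points)
  for (k in seq_len(nrow(truth$panel))) {
    a <- truth$panel$area[k]
    if (a == 0) next
    nu <- (truth$panel$center[k] - acq$center_ppm) * f0       # Hz offset
    lhz <- truth$panel$lorentzian_width[k] * f0               # FWHM Hz
    ghz <- truth$panel$gaussian_width[k] * f0                 # FWHM Hz
    env <- exp(-pi * lhz * tt - (pi * ghz * tt)^2 / (4 * log(2)))
    # amplitude 2*a*f0 makes the ppm-axis integral of the absorptive part = a
    sig <- sig + (2 * a * f0) * env * exp(2i * pi * nu * tt)
  }
  if (truth$noise_sd > 0) {
    noise <- with_seed(truth$seed,
      complex(real = stats::rnorm(acq$n_points, sd = truth$noise_sd),
              imaginary = stats::rnorm(acq$n_points, sd = truth$noise_sd)))
    sig <- sig + noise
  }
  new_fid(sig, acq,
          history = "simulate_fid",
          baseline_coefficients = truth$baseline_coefficients)
}

#' Time-domain noise level giving a target spectral SNR
#'
#' Computes the FID noise standard deviation such that the ratio of the PCr
#' peak height (real part, after Fourier transform with the package's default
#' scaling) to the frequency-domain noise standard deviation equals
#' \code{snr}.
#'
#' @param truth a \code{\link{ground_truth}} object (noise ignored).
#' @param acq acquisition parameters.
#' @param snr target PCr-height / noise-SD ratio.
#' @param zero_fill_to zero-filling length used downstream (affects both peak
#'   height interpolation and noise scaling); default 2 * n_points.
#' @return noise SD in FID units.
#' @export
noise_for_snr <- function(truth, acq = acq_params(), snr = 20,
                          zero_fill_to = 2L * acq$n_points) {
  clean <- ground_truth(panel = truth$panel, ph = truth$ph, mg = truth$mg,
                        noise_sd = 0, seed = truth$seed, calib = truth$calib)
  # panel centers were already overridden; rebuild via state to stay exact
  fid <- simulate_fid(clean, acq)
  spec <- to_spectrum(zero_fill(fid, zero_fill_to))
  pcr_h <- max(Re(spec$y[abs(spec$ppm) < 0.5]))
  # DFT of iid complex noise: per-point SD = sd * sqrt(n_time) * dwell (with
  # the package's dwell-time scaling); zero filling does not add noise power.
  n_eff <- acq$n_points
  pcr_h / snr / (sqrt(n_eff) * acq$dwell_time)
}
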