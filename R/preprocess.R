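new_fid <- function(samples, acq, history = character(),
                    baseline_coefficients = 0) {
  structure(list(samples = samples,
                 acq = acq,
                 history = history,
                 baseline_coefficients = baseline_coefficients),
            class = "fid")
}

#' @export
print.fid <- function(x, ...) {
  cat(sprintf("31P FID: %d complex points, sw %.0f Hz, f0 %.2f MHz\n",
              length(x$samples), x$acq$spectral_width,
              x$acq$transmitter_frequency))
  cat("  history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
print.spectrum31p <- function(x, ...) {
  cat(sprintf("31P spectrum: %d points, %.2f .. %.2f ppm (PCr = 0)\n",
              length(x$y), max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' Zero-fill an FID
#'
#' Appends zeros to the time-domain signal, interpolating the spectrum to a
#' finer digital resolution without changing peak integrals. The pipeline
#' default acquisition (2048 points) is zero-filled to 4096 before transform.
#'
#' @param fid an \code{fid} object.
#' @param n_target total length after filling (>= current length).
#' @return the zero-filled \code{fid}; acquisition metadata and history are
#'   updated, original samples are unchanged.
#' @export
zero_fill <- function(fid, n_target = 4096L) {
  stopifnot(inherits(fid, "fid"))
  n_target <- as.integer(n_target)
  n <- length(fid$samples)
  if (n_target < n) stop("n_target must be >= current length")
  if (n_target > n)
    fid$samples <- c(fid$samples, rep(0 + 0i, n_target - n))
  fid$acq$n_points <- n_target
  fid$history <- c(fid$history, sprintf("zero_fill(%d)", n_target))
  fid
}

#' Apodize an FID
#'
#' Multiplies the signal by a decaying window. The exponential component adds
#' exactly \code{line_broadening} Hz to every Lorentzian FWHM; an optional
#' Gaussian component (\code{gaussian_broadening}) adds in Gaussian quadrature
#' to the Gaussian FWHM, giving a Voigt-type window.
#'
#' @param fid an \code{fid} object.
#' @param line_broadening exponential line broadening in Hz (>= 0).
#' @param gaussian_broadening Gaussian broadening in Hz (>= 0).
#' @return the apodized \code{fid}.
#' @export
apodize <- function(fid, line_broadening = 0, gaussian_broadening = 0) {
  stopifnot(inherits(fid, "fid"))
  if (line_broadening < 0 || gaussian_broadening < 0)
    stop("broadening must be >= 0")
  if (line_broadening > 0 || gaussian_broadening > 0) {
    tt <- (seq_along(fid$samples) - 1L) * fid$acq$dwell_time
    w <- exp(-pi * line_broadening * tt -
             (pi * gaussian_broadening * tt)^2 / (4 * log(2)))
    fid$samples <- fid$samples * w
  }
  fid$history <- c(fid$history,
                   sprintf("apodize(lb=%g,gb=%g)", line_broadening,
                           gaussian_broadening))
  fid
}

#' Fourier transform an FID to a spectrum
#'
#' Discrete Fourier transform scaled by the dwell time (so intensities
#' approximate the continuous transform and peak integrals over the ppm axis
#' are length-independent), with the frequency axis centered on the carrier
#' and converted to ppm referenced to PCr at 0 ppm. The ppm axis is stored
#' strictly decreasing left to right (NMR convention). By convention the first
#' time-domain point is halved before the transform, which removes the
#' constant baseline offset of a truncated FID; set \code{halve_first = FALSE}
#' for a plain unitary transform.
#'
#' @param fid an \code{fid} object.
#' @param halve_first halve the first sample before transforming.
#' @return an object of class \code{spectrum31p} with fields \code{ppm}
#'   (decreasing), \code{y} (complex intensities) and \code{acq}.
#' @export
to_spectrum <- function(fid, halve_first = TRUE) {
  stopifnot(inherits(fid, "fid"))
  n <- length(fid$samples)
  if (n == 0L) stop("empty FID")
  s <- fid$samples
  if (halve_first) s[1L] <- s[1L] / 2
  S <- stats::fft(s) * fid$acq$dwell_time
  dfq <- fid$acq$spectral_width / n
  freq <- c(seq.int(0L, n %/% 2 - 1L), seq.int(-(n %/% 2), -1L)) * dfq
  ppm <- fid$acq$center_ppm + freq / fid$acq$transmitter_frequency
  o <- order(ppm, decreasing = TRUE)
  y <- S[o]
  ppm <- ppm[o]
  bc <- fid$baseline_coefficients
  if (any(bc != 0)) {
    bl <- rep(0, n)
    for (j in seq_along(bc)) bl <- bl + bc[j] * (ppm / 10)^(j - 1L)
    y <- y + bl
  }
  structure(list(ppm = ppm, y = y, acq = fid$acq,
                 history = c(fid$history, "to_spectrum")),
            class = "spectrum31p")
}

#' Inverse transform a spectrum back to an FID
#'
#' Inverts \code{\link{to_spectrum}} (with \code{halve_first = FALSE} the
#' round trip is exact to floating point). Any added baseline is not removed.
#'
#' @param spec a \code{spectrum31p} object.
#' @param halve_first whether the forward transform halved the first point;
#'   if so the first sample is doubled back.
#' @return an \code{fid} object.
#' @export
from_spectrum <- function(spec, halve_first = TRUE) {
  stopifnot(inherits(spec, "spectrum31p"))
  n <- length(spec$y)
  # undo the descending-ppm reordering back to FFT bin order
  dfq <- spec$acq$spectral_width / n
  freq <- (spec$ppm - spec$acq$center_ppm) * spec$acq$transmitter_frequency
  bins <- as.integer(round(freq / dfq))
  bins[bins < 0L] <- bins[bins < 0L] + n
  S <- complex(length.out = n)
  S[bins + 1L] <- spec$y
  s <- stats::fft(S, inverse = TRUE) / n / spec$acq$dwell_time
  if (halve_first) s[1L] <- s[1L] * 2
  new_fid(s, spec$acq, history = c(spec$history, "from_spectrum"))
}

#' Apply zero- and first-order phase correction
#'
#' Rotates the complex intensities by \code{phi0 + phi1 * (ppm - pivot)}
#' degrees. The magnitude spectrum is unchanged.
#'
#' @param spec a \code{spectrum31p} object.
#' @param phi0 zero-order phase in degrees.
#' @param phi1 first-order phase in degrees per ppm.
#' @param pivot ppm value about which the first-order term pivots.
#' @return the phased \code{spectrum31p}.
#' @export
phase_correct <- function(spec, phi0 = 0, phi1 = 0, pivot = 0) {
  stopifnot(inherits(spec, "spectrum31p"),
            is.finite(phi0), is.finite(phi1), is.finite(pivot))
  phase <- (phi0 + phi1 * (spec$ppm - pivot)) * pi / 180
  spec$y <- spec$y * exp(1i * phase)
  spec$history <- c(spec$history,
                    sprintf("phase_correct(%g,%g,%g)", phi0, phi1, pivot))
  spec
}

# Automatic phasing objective: entropy of the normalized absolute first
# derivative of the real part (minimal for pure absorption lineshapes) plus a
# quadratic penalty on negative real intensities.
.phase_objective <- function(par, spec, pivot, penalty = 1000) {
  r <- Re(phase_correct(spec, par[1L], par[2L], pivot)$y)
  h <- abs(diff(r))
  sh <- sum(h)
  if (sh == 0) return(Inf)
  p <- h / sh
  p <- p[p > 0]
  ent <- -sum(p * log(p))
  neg <- r[r < 0]
  ent + penalty * sum(neg^2) / sum(r^2)
}

#' Automatic phase correction
#'
#' Finds zero- and first-order phases minimizing a derivative-entropy
#' objective with a negativity penalty on the real part (the ACME approach).
#' Deterministic: a fixed grid of zero-order starts is refined by Nelder-Mead.
#'
#' @param spec a \code{spectrum31p} object with at least one resolvable peak.
#' @param pivot ppm pivot for the first-order term.
#' @return list with elements \code{spec} (phased spectrum), \code{phi0},
#'   \code{phi1} and \code{objective}.
#' @export
auto_phase <- function(spec, pivot = 0) {
  stopifnot(inherits(spec, "spectrum31p"))
  if (max(Mod(spec$y)) == 0) stop("auto_phase: spectrum has no signal")
  best <- NULL
  for (start0 in c(0, 90, 180, 270)) {
    fit <- stats::optim(c(start0, 0), .phase_objective, spec = spec,
                        pivot = pivot, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value))
    stop("auto_phase: optimization failed (objective not finite)")
  phi0 <- ((best$par[1L] + 180) %% 360) - 180
  phi1 <- best$par[2L]
  in_obj <- .phase_objective(c(0, 0), spec, pivot)
  if (best$value > in_obj) {  # never worse than the input phases
    phi0 <- 0; phi1 <- 0
  }
  list(spec = phase_correct(spec, phi0, phi1, pivot),
       phi0 = phi0, phi1 = phi1,
       objective = min(best$value, in_obj))
}

#' Sum spectra over a brain region
#'
#' Pointwise complex sum of spectra sharing one ppm axis, as used to form the
#' region-summed spectra from which chemical shifts (hence pH and Mg2+) are
#' measured.
#'
#' @param spectra list of \code{spectrum31p} objects with identical ppm axes.
#' @return the summed \code{spectrum31p}.
#' @export
sum_region <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  ref <- spectra[[1L]]
  acc <- ref$y
  if (length(spectra) > 1L) {
    for (s in spectra[-1L]) {
      if (length(s$ppm) != length(ref$ppm) ||
          max(abs(s$ppm - ref$ppm)) > 1e-9)
        stop("sum_region: ppm axes differ between spectra")
      acc <- acc + s$y
    }
  }
  ref$y <- acc
  ref$history <- c(ref$history, sprintf("sum_region(k=%d)", length(spectra)))
  ref
}
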