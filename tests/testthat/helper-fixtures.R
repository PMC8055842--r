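# Shared fixtures for the test suite; everything is generated in code.

# a panel with every resonance silenced except those named in `keep`
panel_only <- function(keep, areas = NULL) {
  a <- setNames(rep(0, 13), pbem31p:::panel_names())
  base <- resonance_panel()
  a[keep] <- base$area[match(keep, base$name)]
  if (!is.null(areas)) a[names(areas)] <- areas
  resonance_panel(areas = a)
}

# noiseless default spectrum, zero-filled to 4096
default_spectrum <- function(truth = ground_truth(seed = 1),
                             acq = acq_params(), zf = 4096L) {
  to_spectrum(zero_fill(simulate_fid(truth, acq), zf))
}

# measure the FWHM of a single well-resolved peak by linear interpolation
measure_fwhm_hz <- function(spec, center_ppm, half_window = 2) {
  w <- abs(spec$ppm - center_ppm) <= half_window
  x <- spec$ppm[w]; yv <- Re(spec$y[w])
  pk <- which.max(yv)
  half <- yv[pk] / 2
  left <- which(yv[seq_len(pk)] <= half)
  right <- pk - 1L + which(yv[pk:length(yv)] <= half)
  cross <- function(i1, i2) {
    x[i1] + (half - yv[i1]) * (x[i2] - x[i1]) / (yv[i2] - yv[i1])
  }
  l <- cross(max(left), max(left) + 1L)
  r <- cross(min(right) - 1L, min(right))
  abs(l - r) * spec$acq$transmitter_frequency
}

# build a minimal converged fit_result from explicit areas/shifts (unit seam
# for the marker calculations)
fake_fit <- function(areas, delta_pi = 4.82, delta_ab = 8.756) {
  peaks <- resonance_panel()
  peaks$area <- unname(areas[peaks$name])
  structure(list(peaks = peaks, baseline = NULL, residual_rms = 0,
                 convergence = list(converged = TRUE, info = 1,
                                    message = "ok", iterations = 0),
                 delta_pi = delta_pi, delta_ab = delta_ab),
            class = "fit_result")
}
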