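test_that("zero filling appends zeros, keeps integrals, records history", {
  tr <- ground_truth(panel = panel_only("PCr"), seed = 1)
  fid <- simulate_fid(tr)
  zf <- zero_fill(fid, 4096L)
  expect_length(zf$samples, 4096L)
  expect_identical(zf$samples[1:2048], fid$samples)
  expect_true(all(zf$samples[2049:4096] == 0))
  expect_match(tail(zf$history, 1), "zero_fill")
  expect_error(zero_fill(fid, 1000L), ">=")
  # identity case
  expect_identical(zero_fill(fid, 2048L)$samples, fid$samples)
  # integral before/after changes by < 0.5%
  a0 <- pbem31p:::trapz_int(to_spectrum(fid)$ppm, Re(to_spectrum(fid)$y))
  a1 <- pbem31p:::trapz_int(to_spectrum(zf)$ppm, Re(to_spectrum(zf)$y))
  expect_lt(abs(a1 - a0) / abs(a0), 0.005)
})

test_that("8 Hz exponential apodization widens a Lorentzian line by 8 Hz", {
  panel <- panel_only("PCr")
  panel$gaussian_width[panel$name == "PCr"] <- 0
  panel$lorentzian_width[panel$name == "PCr"] <- 0.1
  tr <- ground_truth(panel = panel, seed = 1)
  fid <- simulate_fid(tr)
  f0 <- measure_fwhm_hz(to_spectrum(zero_fill(fid, 16384L)), 0)
  f8 <- measure_fwhm_hz(to_spectrum(zero_fill(apodize(fid, 8), 16384L)), 0)
  expect_lt(abs((f8 - f0) - 8), 0.5)
  # zero broadening is the identity
  expect_identical(apodize(fid, 0)$samples, fid$samples)
  expect_error(apodize(fid, -1), ">= 0")
})

test_that("Fourier transform: delta input, unitarity, Parseval, position", {
  acq <- acq_params(n_points = 256L)
  delta <- pbem31p:::new_fid(c(1 + 0i, rep(0 + 0i, 255L)), acq)
  sp <- to_spectrum(delta, halve_first = FALSE)
  expect_lt(diff(range(Mod(sp$y))), 1e-12)

  tr <- ground_truth(panel = panel_only("Pi_in"), ph = 7.0, seed = 3,
                     mg = 0.2)
  fid <- simulate_fid(tr)
  sp <- to_spectrum(fid, halve_first = FALSE)
  # Parseval with the package's dwell-time scaling
  lhs <- sum(Mod(fid$samples)^2) * fid$acq$dwell_time^2 * length(sp$y)
  rhs <- sum(Mod(sp$y)^2)
  expect_lt(abs(lhs - rhs) / rhs, 1e-9)
  # round trip restores the FID
  back <- from_spectrum(sp, halve_first = FALSE)
  expect_lt(max(Mod(back$samples - fid$samples)), 1e-10)
  # the lone Pi_in resonance lands at its pH-determined shift
  apex <- sp$ppm[which.max(Re(to_spectrum(fid)$y))]
  step <- fid$acq$spectral_width / length(sp$y) /
    fid$acq$transmitter_frequency
  expect_lt(abs(apex - delta_pi_from_ph(7.0)), step + 1e-9)
  # ppm axis is strictly decreasing
  expect_true(all(diff(sp$ppm) < 0))
})

test_that("phasing rotates intensities but never the magnitude", {
  sp <- default_spectrum(ground_truth(seed = 4))
  expect_identical(phase_correct(sp, 0, 0)$y, sp$y)
  ph <- phase_correct(sp, 37, 2.5, pivot = 1)
  expect_lt(max(abs(Mod(ph$y) - Mod(sp$y))), 1e-9)
  ang <- (37 + 2.5 * (sp$ppm - 1)) * pi / 180
  expect_lt(max(Mod(ph$y - sp$y * exp(1i * ang))), 1e-9)
})

test_that("auto_phase recovers applied phases within 1 degree", {
  sp <- default_spectrum(ground_truth(seed = 5))
  dephased <- phase_correct(sp, -30, 1.5, pivot = 0)
  res <- auto_phase(dephased, pivot = 0)
  expect_lt(abs(res$phi0 + (-30)) %% 360, 1)
  expect_lt(abs(res$phi1 + 1.5), 0.1)
  # already-phased input: returned phases are near zero and never worsen
  res0 <- auto_phase(sp, pivot = 0)
  expect_lt(abs(res0$phi0), 1)
  expect_lt(abs(res0$phi1), 0.1)
  obj_in <- pbem31p:::.phase_objective(c(0, 0), sp, 0)
  expect_lte(res0$objective, obj_in + 1e-12)
})

test_that("region summation is linear and grows SNR like sqrt(k)", {
  tr <- ground_truth(seed = 6)
  sp <- default_spectrum(tr)
  expect_identical(sum_region(list(sp))$y, sp$y)
  s3 <- sum_region(list(sp, sp, sp))
  expect_lt(max(Mod(s3$y - 3 * sp$y)), 1e-9)
  other <- default_spectrum(tr, acq = acq_params(spectral_width = 5000))
  expect_error(sum_region(list(sp, other)), "axes differ")

  # Monte-Carlo: summing 16 iid-noise replicates of the same signal
  k <- 16L
  nsd <- noise_for_snr(tr, snr = 10)
  specs <- lapply(seq_len(k), function(i) {
    tri <- ground_truth(ph = tr$ph, mg = tr$mg, noise_sd = nsd,
                        seed = 100 + i)
    default_spectrum(tri)
  })
  snr_of <- function(s) {
    max(Re(s$y[abs(s$ppm) < 0.5])) / stats::sd(Re(s$y[s$ppm > 12]))
  }
  snr1 <- mean(vapply(specs, snr_of, numeric(1)))
  snrk <- snr_of(sum_region(specs))
  expect_lt(abs(snrk / snr1 - sqrt(k)) / sqrt(k), 0.10)
})

test_that("preprocessing chain is linear in the input signal", {
  tr1 <- ground_truth(panel = panel_only(c("PCr", "gATP")), seed = 7)
  tr2 <- ground_truth(panel = panel_only(c("Pi_in", "PE")), seed = 8)
  f1 <- simulate_fid(tr1); f2 <- simulate_fid(tr2)
  chain <- function(f) {
    phase_correct(to_spectrum(zero_fill(apodize(f, 4), 4096L)), 20, 1)
  }
  fsum <- f1; fsum$samples <- f1$samples + f2$samples
  expect_lt(max(Mod(chain(fsum)$y - (chain(f1)$y + chain(f2)$y))), 1e-9)
})
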