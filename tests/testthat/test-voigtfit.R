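test_that("Voigt profile limits agree with pure Gaussian and Lorentzian", {
  x <- seq(-2, 2, 0.005)
  sig <- 0.2 / (2 * sqrt(2 * log(2)))
  gauss <- exp(-x^2 / (2 * sig^2)) / (sig * sqrt(2 * pi))
  expect_lt(max(abs(voigt_profile(x, 0, 1, 0.2, 1e-9) - gauss)), 1e-6)
  gam <- 0.1
  lor <- gam / pi / (x^2 + gam^2)
  expect_lt(max(abs(voigt_profile(x, 0, 1, 1e-9, 0.2) - lor)), 1e-6)
  expect_error(voigt_profile(x, 0, 1, 0, 0), "degenerate")
})

test_that("Voigt profile integrates to its area and matches a brute-force
           Gaussian x Lorentzian convolution", {
  # adaptive quadrature over the whole line (the Lorentzian tails carry a
  # few tenths of a percent beyond any finite window)
  a <- stats::integrate(voigt_profile, -Inf, Inf, center = 0, area = 2.5,
                        gaussian_width = 0.3, lorentzian_width = 0.2,
                        rel.tol = 1e-8)$value
  expect_lt(abs(a - 2.5) / 2.5, 1e-3)

  # independent oracle: numerical convolution integral
  conv_voigt <- function(x0, gw, lw) {
    sig <- gw / (2 * sqrt(2 * log(2))); gam <- lw / 2
    vapply(x0, function(xx) {
      stats::integrate(function(u)
        exp(-u^2 / (2 * sig^2)) / (sig * sqrt(2 * pi)) *
          (gam / pi) / ((xx - u)^2 + gam^2),
        -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  for (wl in list(c(0.3, 0.2), c(0.05, 0.4), c(0.5, 0.02))) {
    xs <- seq(-1.5, 1.5, length.out = 31)
    expect_lt(max(abs(voigt_profile(xs, 0, 1, wl[1], wl[2]) -
                      conv_voigt(xs, wl[1], wl[2]))), 1e-8)
  }
})

test_that("baseline estimation recovers constants and smooth polynomials", {
  acq <- acq_params()
  n <- 4096L
  ppm <- acq$center_ppm +
    seq(acq$spectral_width / 2, -acq$spectral_width / 2,
        length.out = n) / acq$transmitter_frequency
  flat <- structure(list(ppm = ppm, y = complex(real = rep(2.5, n)),
                         acq = acq, history = character()),
                    class = "spectrum31p")
  ew <- cbind(resonance_panel()$center - 0.7, resonance_panel()$center + 0.7)
  bl <- estimate_baseline(flat, ew, degree = 4L)
  expect_lt(max(abs(bl$baseline - 2.5)), 1e-6)

  # cubic baseline under a real spectrum, recovered to < 2% of peak height
  tr <- ground_truth(panel = panel_only("PCr"), seed = 2)
  sp <- default_spectrum(tr)
  cubic <- 0.5 + 0.8 * (sp$ppm / 10) - 0.6 * (sp$ppm / 10)^3
  spb <- sp; spb$y <- spb$y + cubic
  blb <- estimate_baseline(spb, ew, degree = 4L)
  peak_h <- max(Re(sp$y))
  expect_lt(max(abs(blb$baseline - cubic)), 0.02 * peak_h)
  # integral of the well-separated peak changes < 1% after subtraction
  w <- abs(sp$ppm) < 1.5
  a0 <- pbem31p:::trapz_int(sp$ppm[w], Re(sp$y[w]))
  a1 <- pbem31p:::trapz_int(sp$ppm[w], Re(spb$y[w]) - blb$baseline[w])
  expect_lt(abs(a1 - a0) / a0, 0.01)

  expect_error(estimate_baseline(flat, cbind(-1000, 1000)), "signal-free")
})

test_that("noiseless 13-peak spectrum is recovered to 1% areas, 0.005 ppm
           centers, with residuals at numerical noise", {
  tr <- ground_truth(seed = 1)
  sp <- default_spectrum(tr)
  fit <- fit_spectrum(sp)
  expect_true(fit$convergence$converged)
  m <- match(fit$peaks$name, tr$panel$name)
  expect_true(all(abs(fit$peaks$area - tr$panel$area[m]) /
                    tr$panel$area[m] < 0.01))
  expect_true(all(abs(fit$peaks$center - tr$panel$center[m]) < 0.005))
  expect_lt(fit$residual_rms, 1e-6 * max(abs(Re(sp$y))))
  # alpha-beta shift difference matches the Mg ground truth
  expect_lt(abs(fit$delta_ab - delta_ab_from_mg(tr$mg)), 0.01)
})

test_that("fitting is equivariant under scaling and ppm shift", {
  tr <- ground_truth(seed = 2)
  sp <- default_spectrum(tr)
  fit <- fit_spectrum(sp)

  sp_scaled <- sp; sp_scaled$y <- 3.7 * sp$y
  fit_s <- fit_spectrum(sp_scaled)
  expect_lt(max(abs(fit_s$peaks$area - 3.7 * fit$peaks$area) /
                  (3.7 * fit$peaks$area)), 1e-3)

  # shifting the axis moves every fitted center by the same amount (the
  # default prior windows still contain the shifted peaks)
  dppm <- 0.12
  sp_shift <- sp; sp_shift$ppm <- sp$ppm + dppm
  fit_t <- fit_spectrum(sp_shift)
  expect_lt(max(abs((fit_t$peaks$center - fit$peaks$center) - dppm)), 0.005)
  expect_lt(max(abs(fit_t$peaks$area - fit$peaks$area) /
                  fit$peaks$area), 5e-3)
})

test_that("SNR-20 Monte-Carlo recovery of the major resonances", {
  tr0 <- ground_truth(seed = 1)
  nsd <- noise_for_snr(tr0, snr = 20)
  big <- c("PCr", "gATP", "aATP", "bATP", "Pi_in")
  nrep <- 40L
  errs <- vapply(seq_len(nrep), function(s) {
    trs <- ground_truth(seed = 4000 + s, noise_sd = nsd)
    ft <- fit_spectrum(default_spectrum(trs))
    m <- match(big, ft$peaks$name); tm <- match(big, trs$panel$name)
    (ft$peaks$area[m] - trs$panel$area[tm]) / trs$panel$area[tm]
  }, numeric(5))
  # typical-case recovery inside 5% for all five; the PCr/ATP RMS sits near
  # the information limit (~3%), while intracellular Pi is wider because it
  # shares its window with the extracellular pool and the broad MM component
  expect_true(all(apply(abs(errs), 1L, median) < 0.05))
  expect_true(all(sqrt(rowMeans(errs[1:4, ]^2)) < 0.06))
  expect_true(all(abs(rowMeans(errs)) < 0.03))
})

test_that("non-finite or missing templates are rejected", {
  sp <- default_spectrum(ground_truth(seed = 3))
  templ <- resonance_panel()[-1, ]
  expect_error(fit_spectrum(sp, templates = templ), "13")
})
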