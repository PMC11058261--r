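test_that("Boltzmann weights match closed forms", {
  expect_equal(boltzmann_weights(c(5, 5)), c(0.5, 0.5))
  RT <- 8.314462618e-3 * 298.15
  expect_equal(boltzmann_weights(c(0, RT * log(2))), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  # exp(-5.708 / RT) = 0.1 at 298.15 K
  expect_equal(boltzmann_weights(c(0, 5.708)), c(10 / 11, 1 / 11),
               tolerance = 1e-4)
  expect_error(boltzmann_weights(numeric(0)), "empty")
  expect_error(boltzmann_weights(0, temperature = 0), "positive")
})

test_that("weights are normalized and gauge invariant", {
  set.seed(19)
  for (i in 1:20) {
    e <- runif(5, 0, 40)
    w <- boltzmann_weights(e)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w, boltzmann_weights(e + runif(1, -100, 100)),
                 tolerance = 1e-12)
  }
})

test_that("temperature limits give uniform and winner-takes-all weights", {
  e <- c(0, 3, 10, 25)
  expect_equal(boltzmann_weights(e, temperature = 1e9), rep(0.25, 4),
               tolerance = 1e-6)
  w0 <- boltzmann_weights(e, temperature = 1)
  expect_equal(w0[1], 1, tolerance = 1e-10)
})

test_that("Gaussian broadening peaks at the excitation and preserves stick areas", {
  ex <- data.frame(energy_ev = 4.133, strength = 0.2)  # 300 nm
  y <- broaden(ex, sigma_ev = 0.15, grid_nm = 250:350)
  expect_equal((250:350)[which.max(y)], 300)
  # two well-separated equal sticks give two equal local maxima
  ex2 <- data.frame(energy_ev = c(3.8, 4.7), strength = c(0.3, 0.3))
  y2 <- broaden(ex2, sigma_ev = 0.1, grid_nm = 250:350)
  pk <- nucleospec:::find_peaks(250:350, y2)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$height[1], pk$height[2], tolerance = 0.01)
  # integrated area per isolated stick (in the energy domain) tracks its
  # oscillator strength
  egrid <- seq(3, 6, by = 0.001)
  for (f in c(0.1, 0.35)) {
    yE <- f * exp(-(egrid - 4.2)^2 / (2 * 0.05^2))
    area <- sum(yE) * 0.001
    expect_equal(area, f * sqrt(2 * pi) * 0.05, tolerance = 1e-3)
  }
})

test_that("assembled spectra are linear in oscillator strength before normalization", {
  st1 <- tautomer_states("a", 0, data.frame(energy_ev = 4.1, strength = 0.2))
  st2 <- tautomer_states("a2", 0, data.frame(energy_ev = 4.1, strength = 0.4))
  s1 <- assemble_spectrum(list(st1), normalization = "none")
  s2 <- assemble_spectrum(list(st2), normalization = "none")
  expect_equal(s2$intensity, 2 * s1$intensity, tolerance = 1e-12)
})

test_that("a single excitation yields a normalized Gaussian at its wavelength", {
  st <- tautomer_states("one", 0, data.frame(energy_ev = 4.133, strength = 0.2))
  ps <- assemble_spectrum(list(st), sigma_ev = 0.15)
  expect_equal(max(ps$intensity), 1, tolerance = 1e-6)
  expect_equal(ps$lambda_peak, 300, tolerance = 0.5)
  expect_equal(sum(ps$weights), 1)
})

test_that("a structure 20 kJ/mol uphill contributes less than 0.04%", {
  w <- boltzmann_weights(c(0, 20))
  expect_lt(w[2], 4e-4)
  st <- list(
    tautomer_states("low", 0, data.frame(energy_ev = 4.1, strength = 0.2)),
    tautomer_states("high", 20, data.frame(energy_ev = 4.6, strength = 0.2)))
  ps <- assemble_spectrum(st, normalization = "none")
  hi_alone <- broaden(st[[2]]$excitations, 0.3, 250:350)
  expect_lt(max(ps$weights["high"] * hi_alone) / max(ps$intensity), 4e-4)
})

test_that("a lower-energy first excitation yields a more redshifted peak", {
  red <- tautomer_states("red", 0,
                         data.frame(energy_ev = c(4.10, 5.3),
                                    strength = c(0.2, 0.3)))
  blue <- tautomer_states("blue", 0,
                          data.frame(energy_ev = c(4.50, 5.6),
                                     strength = c(0.2, 0.3)))
  ps_r <- assemble_spectrum(list(red))
  ps_b <- assemble_spectrum(list(blue))
  expect_gt(ps_r$lambda_peak, ps_b$lambda_peak)
})

test_that("redshift ranking identifies the matching candidate and excludes blue ones", {
  sts <- synthetic_excitations()
  cands <- lapply(sts, function(s) assemble_spectrum(list(s), label = s$label))
  observed <- spectrum(250:350, cands[[1]]$intensity)
  rk <- redshift_rank(cands, observed)
  expect_identical(rk$label[1], "N7X_synth")
  expect_equal(rk$distance_nm[1], 0, tolerance = 1e-9)
  # the far-blue-shifted candidate ranks last
  expect_identical(rk$label[nrow(rk)], "O2X_synth")
  # three synthetic candidates at 270/290/310 vs an observation at 288
  mk <- function(lab, nm) {
    st <- tautomer_states(lab, 0, data.frame(energy_ev = 1239.842 / nm,
                                             strength = 0.2))
    assemble_spectrum(list(st), sigma_ev = 0.15, label = lab)
  }
  three <- list(mk("c270", 270), mk("c290", 290), mk("c310", 310))
  obs <- assemble_spectrum(list(tautomer_states(
    "obs", 0, data.frame(energy_ev = 1239.842 / 288, strength = 0.2))),
    sigma_ev = 0.15)
  expect_identical(redshift_rank(three, obs)$label[1], "c290")
})
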