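test_that("absorbance-to-conversion applies the extinction-difference calibration", {
  cond <- reaction_conditions(100, 500, path_length = 1)
  cfg <- monitoring_config()
  # flat trace -> zero conversion, no drift
  tc <- timecourse(0:10 * 60, rep(0.5, 11), rep(0.4, 11), cond)
  cc <- absorbance_to_conversion(tc, cfg)
  expect_equal(cc$chi, rep(0, 11))
  expect_false(cc$drift_flag)
  # dA = 0.18 with delta-eps 3.6, X0 = 100, l = 1 -> chi = 0.5
  tc2 <- timecourse(0:10 * 60, 0.5 + seq(0, 0.18, length.out = 11),
                    rep(0.4, 11), cond)
  expect_equal(absorbance_to_conversion(tc2, cfg)$chi[11], 0.5)
  # control-wavelength ramp beyond tolerance flags drift
  tc3 <- timecourse(0:10 * 60, rep(0.5, 11),
                    0.4 + seq(0, 0.05, length.out = 11), cond)
  expect_true(absorbance_to_conversion(tc3, cfg)$drift_flag)
})

test_that("degenerate monitoring signals are refused", {
  cond <- reaction_conditions(1e-6, 1, path_length = 1e-4)
  tc <- timecourse(1:10, rep(0.1, 10), rep(0.1, 10), cond)
  expect_error(absorbance_to_conversion(tc), "degenerate")
})

test_that("plateau detection accepts equilibrated and rejects rising courses", {
  cond <- reaction_conditions(100, 500)
  mk <- function(chi) structure(list(times = seq(0, 7200, 30), chi = chi,
                                     drift_flag = FALSE, chi_eq = NA_real_,
                                     conditions = cond),
                                class = "conversion_course")
  n <- length(seq(0, 7200, 30))
  expect_equal(detect_equilibrium(mk(rep(0.9, n))), 0.9)
  expect_true(is.na(detect_equilibrium(mk(seq(0, 0.5, length.out = n)))))
  short <- structure(list(times = seq(0, 1000, 30),
                          chi = rep(0.5, length(seq(0, 1000, 30))),
                          drift_flag = FALSE, chi_eq = NA_real_,
                          conditions = cond), class = "conversion_course")
  expect_error(detect_equilibrium(short), "twice the plateau window")
})

test_that("solve_equilibrium matches hand-solved quadratics and the grid oracle", {
  # no co-substrate: nothing can react
  expect_equal(solve_equilibrium(0.5, reaction_conditions(100, 0)), 0)
  # K = 0.5, X0 = 100, R0 = 500: x = (1200 - sqrt(1040000)) / 2
  chi1 <- solve_equilibrium(0.5, reaction_conditions(100, 500))
  expect_equal(chi1, (1200 - sqrt(1040000)) / 2 / 100, tolerance = 1e-12)
  expect_equal(chi1, 0.90098, tolerance = 1e-4)
  chi2 <- solve_equilibrium(0.5, reaction_conditions(150, 500))
  expect_equal(chi2, 0.8532, tolerance = 1e-3)
  expect_equal(chi2, brute_force_chi(0.5, reaction_conditions(150, 500)),
               tolerance = 1e-3)
})

test_that("solve_equilibrium agrees with the brute-force oracle on random inputs", {
  set.seed(17)
  for (i in 1:40) {
    cond <- reaction_conditions(runif(1, 20, 300), runif(1, 10, 800),
                                N0 = runif(1, 0, 50), P0 = runif(1, 0, 50))
    K <- 10^runif(1, -2, 2)
    expect_lt(abs(solve_equilibrium(K, cond) - brute_force_chi(K, cond)), 1e-3)
  }
})

test_that("equilibrium conversion is monotone in R0 and in K", {
  chis_R <- vapply(c(25, 50, 100, 200, 500), function(R)
    solve_equilibrium(0.5, reaction_conditions(100, R)), numeric(1))
  expect_true(all(diff(chis_R) > 0))
  chis_K <- vapply(c(0.05, 0.2, 0.5, 2, 10), function(K)
    solve_equilibrium(K, reaction_conditions(100, 200)), numeric(1))
  expect_true(all(diff(chis_K) < 0))
})

test_that("the single-run constant is the algebraic inverse of the solver", {
  set.seed(29)
  for (i in 1:25) {
    cond <- reaction_conditions(runif(1, 50, 200), runif(1, 25, 600),
                                N0 = runif(1, 0, 20), P0 = runif(1, 0, 20))
    K <- 10^runif(1, -2, 2)
    chi <- solve_equilibrium(K, cond)
    if (chi > 0 && chi < 1)
      expect_equal(equilibrium_constant_single(chi, cond), K,
                   tolerance = 1e-9)
  }
  expect_equal(equilibrium_constant_single(0.901, reaction_conditions(100, 500)),
               0.5, tolerance = 0.01)
  expect_error(equilibrium_constant_single(0, reaction_conditions(100, 500)),
               "strictly between")
  expect_error(equilibrium_constant_single(1, reaction_conditions(100, 500)),
               "strictly between")
})

test_that("the global K fit is exact on noiseless endpoints", {
  runs <- gen_equilibrium_endpoints(K = 0.5, noise = noise_model(0, 0), seed = 1)
  fit <- fit_K_global(runs)
  expect_equal(fit$K, 0.5, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-9)
  expect_true(all(fit$per_run$chi_pred >= 0 & fit$per_run$chi_pred <= 1))
})

test_that("the global K fit recovers K within 10% under absorbance noise", {
  K_hat <- vapply(1:25, function(i) {
    runs <- gen_equilibrium_endpoints(K = 0.5, noise = noise_model(),
                                      seed = 1000 + i)
    fit_K_global(runs)$K
  }, numeric(1))
  expect_lt(sqrt(mean((K_hat / 0.5 - 1)^2)), 0.10)
})

test_that("the fit refuses drift-flagged data and reports a profile CI", {
  runs <- gen_equilibrium_endpoints(K = 0.5, noise = noise_model(), seed = 8)
  for (i in seq_along(runs)) runs[[i]]$drift_flag <- TRUE
  expect_error(fit_K_global(runs), "drift")
  runs2 <- gen_equilibrium_endpoints(K = 0.5, noise = noise_model(), seed = 9)
  fit <- fit_K_global(runs2)
  expect_true(fit$ci95[1] < fit$K && fit$K < fit$ci95[2])
})

test_that("enzyme mass concentrations convert to the printed molarities", {
  expect_equal(mass_conc_to_molar(0.4, 26.0), 15.4, tolerance = 0.01)
  expect_equal(mass_conc_to_molar(0.1, 26.3), 3.8, tolerance = 0.01)
  expect_equal(mass_conc_to_molar(1, 1000), 1)
  expect_error(mass_conc_to_molar(0, 26), "positive")
})
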