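test_that("spectrum and extinction constructors enforce their invariants", {
  expect_error(spectrum(c(250, 251, 251.5), c(0, 0, 0)), "uniform step")
  expect_error(spectrum(250:252, c(0, NA, 0)), "finite")
  expect_error(spectrum(250:252, c(0, 0, 0), path_length = 0), "positive")
  expect_error(spectrum(250:252, c(0, 0)), "length")
  expect_error(extinction_spectrum(250:252, c(1, -0.1, 1)), "non-negative")
  s <- spectrum(250:350, rep(0.1, 101), meta = list(pH = 7))
  expect_s3_class(s, "spectrum")
})

test_that("beer_lambert_mix reproduces hand-computed absorbances", {
  eps <- extinction_spectrum(grid_nm, rep(3.6, 101), "X")
  # zero concentration -> all-zero spectrum
  expect_equal(beer_lambert_mix(eps, 0)$absorbance, rep(0, 101))
  # eps 3.6 mM^-1 cm^-1, 100 uM, 1 cm -> A = 0.36
  expect_equal(beer_lambert_mix(eps, 100, 1)$absorbance[1], 0.36)
  # at an isosbestic wavelength only total concentration matters
  pair <- preset_pair("glycosylation_pH10")
  iso <- 288
  mixes <- lapply(list(c(100, 0), c(50, 50), c(0, 100)), function(cc)
    beer_lambert_mix(list(pair$HA, pair$A), cc, 1))
  A_iso <- vapply(mixes, function(m) m$absorbance[m$wavelengths == iso],
                  numeric(1))
  expect_lt(diff(range(A_iso)), 1e-9)
})

test_that("beer_lambert_mix is linear in each concentration and validates input", {
  pair <- preset_pair("xanthine_titration")
  set.seed(11)
  for (i in 1:10) {
    c1 <- runif(1, 0, 300); c2 <- runif(1, 0, 300); a <- runif(1, 0.1, 3)
    lhs <- beer_lambert_mix(list(pair$HA, pair$A), c(a * c1, c2))$absorbance
    rhs <- a * beer_lambert_mix(list(pair$HA, pair$A), c(c1, 0))$absorbance +
      beer_lambert_mix(list(pair$HA, pair$A), c(0, c2))$absorbance
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  short <- extinction_spectrum(250:300, rep(1, 51))
  expect_error(beer_lambert_mix(list(pair$HA, short), c(1, 1)), "incompatible")
  expect_error(beer_lambert_mix(pair$HA, -5), "non-negative")
})

test_that("calibrate_extinction inverts the forward model", {
  pair <- preset_pair("xanthine_titration")
  spec <- beer_lambert_mix(pair$HA, 100, 1)
  eps <- calibrate_extinction(spec, 100)
  expect_equal(eps$epsilon, pair$HA$epsilon, tolerance = 1e-12)
  # simple arithmetic: A = 0.36 at 100 uM, 1 cm -> eps = 3.6
  flat <- spectrum(250:350, rep(0.36, 101), 1)
  expect_equal(calibrate_extinction(flat, 100)$epsilon[1], 3.6)
  expect_error(calibrate_extinction(flat, 0), "positive")
  # round trip on random non-negative curves
  set.seed(7)
  for (i in 1:5) {
    e <- extinction_spectrum(grid_nm, runif(101, 0, 12))
    cc <- runif(1, 10, 400)
    expect_equal(calibrate_extinction(beer_lambert_mix(e, cc, 0.56), cc)$epsilon,
                 e$epsilon, tolerance = 1e-10)
  }
})

test_that("calibrate_extinction clips negative values and counts them", {
  A <- rep(0.2, 101); A[1:20] <- -0.01
  spec <- spectrum(250:350, A)
  expect_warning(eps <- calibrate_extinction(spec, 100), "clipped")
  expect_true(all(eps$epsilon >= 0))
  expect_equal(eps$meta$n_clipped, 20)
})

test_that("find_isosbestic locates designed crossings to sub-nm accuracy", {
  lines <- line_pair_280()
  res <- find_isosbestic(list(lines$e1, lines$e2))
  expect_equal(length(res$wavelengths_iso), 1L)
  expect_lt(abs(res$wavelengths_iso - 280), 0.5)
  # tuned presets cross at the literature wavelengths
  expect_lt(abs(preset_pair("xanthine_titration")$isosbestic$wavelengths_iso - 274), 1)
  expect_lt(abs(preset_pair("n7x_titration")$isosbestic$wavelengths_iso - 279), 1)
  expect_lt(abs(preset_pair("glycosylation_pH10")$isosbestic$wavelengths_iso - 288), 1)
  # a deprotonation pair with two crossings reports both
  two <- preset_pair("n9x_titration")$isosbestic$wavelengths_iso
  expect_equal(length(two), 2L)
  expect_lt(abs(two[1] - 259), 1)
  expect_lt(abs(two[2] - 268), 1)
})

test_that("find_isosbestic agrees with a brute-force crossing search", {
  set.seed(23)
  for (i in 1:20) {
    c1 <- runif(1, 260, 285)
    e1 <- extinction_spectrum(grid_nm, gaussian_curve(grid_nm, c1, 12, 8))
    e2 <- extinction_spectrum(grid_nm, gaussian_curve(grid_nm, c1 + 12, 14, 7))
    res <- find_isosbestic(list(e1, e2))
    # oracle: dense-grid argmin of |eps_a - eps_b| near each sign change
    d <- e1$epsilon - e2$epsilon
    fine <- seq(250, 350, by = 0.001)
    dfine <- approx(grid_nm, d, fine)$y
    sgn <- which(dfine[-1] * dfine[-length(dfine)] <= 0)
    brute <- fine[sgn]
    # the main crossing (between the peak centers) must be recovered
    main <- brute[brute > c1 - 15 & brute < c1 + 30][1]
    expect_true(any(abs(res$wavelengths_iso - main) <= 1))
    # and every reported crossing must sit at a brute-force sign change
    for (lam in res$wavelengths_iso)
      expect_lt(min(abs(brute - lam)), 1)
  }
})

test_that("no-crossing input yields an empty result, not an error", {
  e1 <- extinction_spectrum(grid_nm, rep(1, 101))
  e2 <- extinction_spectrum(grid_nm, rep(3, 101))
  res <- find_isosbestic(list(e1, e2))
  expect_equal(length(res$wavelengths_iso), 0L)
})

test_that("isosbestic normalization pins the series at lambda_iso exactly", {
  pair <- preset_pair("xanthine_titration")
  set.seed(5)
  series <- lapply(1:8, function(i) {
    f <- (i - 1) / 7
    cc <- 100 * (1 + rnorm(1, 0, 0.05))  # 5% concentration jitter
    beer_lambert_mix(list(pair$HA, pair$A), c((1 - f) * cc, f * cc), 0.56)
  })
  iso <- pair$isosbestic$wavelengths_iso[1]
  norm <- isosbestic_normalize(series, iso)
  A_iso <- vapply(norm, function(s) approx(s$wavelengths, s$absorbance, iso)$y,
                  numeric(1))
  expect_lt(sd(A_iso) / mean(A_iso), 1e-12)  # CV zero to machine precision
  # already-equal series is returned unchanged
  norm2 <- isosbestic_normalize(norm, iso)
  expect_equal(norm2[[1]]$absorbance, norm[[1]]$absorbance, tolerance = 1e-12)
  # non-positive absorbance names the offending sample
  bad <- series
  bad[[2]]$absorbance <- -bad[[2]]$absorbance
  bad[[2]]$meta$label <- "well_B2"
  expect_error(isosbestic_normalize(bad, iso), "well_B2")
})

test_that("operations conserve the input wavelength grid", {
  pair <- preset_pair("n7x_titration")
  spec <- beer_lambert_mix(pair$HA, 120, 0.56)
  expect_equal(spec$wavelengths, as.numeric(grid_nm))
  expect_equal(calibrate_extinction(spec, 120)$wavelengths, as.numeric(grid_nm))
  expect_equal(isosbestic_normalize(list(spec), 279)[[1]]$wavelengths,
               as.numeric(grid_nm))
})

test_that("calibration transfer recovers the target extinction through lambda_iso", {
  pair <- preset_pair("glycosylation_pH10")
  iso <- 288
  spec_ref <- beer_lambert_mix(pair$HA, 100, 0.56)
  # target with a 12% concentration error -- the situation transfer corrects
  spec_tgt <- beer_lambert_mix(pair$A, 112, 0.56)
  eps_tgt <- transfer_calibration(pair$HA, spec_ref, spec_tgt, iso,
                                  species = "N7X")
  expect_equal(eps_tgt$epsilon, pair$A$epsilon, tolerance = 0.01)
  rel <- abs(eps_tgt$epsilon - pair$A$epsilon) /
    pmax(pair$A$epsilon, 0.01 * max(pair$A$epsilon))
  expect_lt(max(rel), 0.01)
  # identity: transferring the reference onto itself returns its own curve
  eps_self <- transfer_calibration(pair$HA, spec_ref, spec_ref, iso)
  expect_equal(eps_self$epsilon, pair$HA$epsilon, tolerance = 1e-10)
})
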