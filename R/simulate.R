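# Forward simulators. These generate every input the analysis consumes, with
# the statistical structure the analysis assumes: two-species Beer-Lambert
# spectra with per-well concentration error, additive Gaussian absorbance
# noise, two-state protonation, and reversible bimolecular glycosylation
# kinetics relaxing to a thermodynamic equilibrium.

#' Plate-reader noise model
#'
#' @param sigma_A additive Gaussian absorbance noise, AU (default 0.002)
#' @param conc_jitter_rel relative per-sample concentration error (Gaussian
#'   sd; default 0.05 -- the pipetting error that isosbestic normalization is
#'   designed to remove)
#' @param seed integer seed; generators are pure functions of
#'   (parameters, seed)
#' @return an object of class `"noise_model"`
#' @export
noise_model <- function(sigma_A = 0.002, conc_jitter_rel = 0.05, seed = NULL) {
  if (sigma_A < 0) stop_domain("sigma_A must be >= 0")
  if (conc_jitter_rel < 0 || conc_jitter_rel >= 0.5)
    stop_domain("conc_jitter_rel must lie in [0, 0.5)")
  structure(list(sigma_A = sigma_A, conc_jitter_rel = conc_jitter_rel,
                 seed = seed), class = "noise_model")
}

# Sum-of-Gaussians extinction curve from a peak table.
gaussian_sum <- function(grid, peaks) {
  y <- numeric(length(grid))
  for (i in seq_len(nrow(peaks))) {
    y <- y + peaks$height[i] *
      exp(-(grid - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  }
  y
}

#' Built-in synthetic extinction presets
#'
#' Gaussian peak tables for xanthine-family acid-base and glycosylation pairs.
#' The peak heights are frozen constants tuned (analytically, once) so that
#' each pair crosses at its literature isosbestic wavelength -- 274 nm for the
#' xanthine HA/A pair, 279 nm for the N7-xanthosine pair -- and so that the
#' glycosylation pair (xanthine vs N7-xanthosine anions at pH 10) crosses at
#' 288 nm with an extinction difference of 3.6 mM^-1 cm^-1 at 300 nm. These
#' are synthetic stand-ins shaped like the real curves, not measured data.
#'
#' @param name one of `"xanthine_titration"`, `"n7x_titration"`,
#'   `"n9x_titration"` (a pair with two crossings, at 259 and 268 nm),
#'   `"glycosylation_pH10"`
#' @return list with peak tables `peaks_HA`, `peaks_A` (columns `center`,
#'   `width`, `height`), the nominal `lambda_iso`, and species labels
#' @export
extinction_preset <- function(name = c("xanthine_titration", "n7x_titration",
                                       "n9x_titration", "glycosylation_pH10")) {
  name <- match.arg(name)
  switch(name,
    xanthine_titration = list(
      peaks_HA = data.frame(center = 267, width = 12, height = 9.0),
      peaks_A  = data.frame(center = 277, width = 13, height = 7.796796213),
      lambda_iso = 274, species = c("X(HA)", "X(A-)")),
    n7x_titration = list(
      peaks_HA = data.frame(center = 272, width = 10, height = 7.5),
      peaks_A  = data.frame(center = 293, width = 13.2540, height = 10.255066851),
      lambda_iso = 279, species = c("N7X(HA)", "N7X(A-)")),
    n9x_titration = list(
      peaks_HA = data.frame(center = 263, width = 12, height = 8.5),
      peaks_A  = data.frame(center = 263.277777778, width = 8,
                            height = 9.276409229),
      lambda_iso = c(259, 268), species = c("N9X(HA)", "N9X(A-)")),
    glycosylation_pH10 = list(
      peaks_HA = data.frame(center = 277, width = 13, height = 7.796796213),
      peaks_A  = data.frame(center = 293, width = 17.0298, height = 5.690659213),
      lambda_iso = 288, species = c("X(A-)", "N7X(A-)")))
}

#' Generate a crossing pair of extinction spectra
#'
#' Builds sum-of-Gaussians extinction curves for a protonation (or
#' substrate/product) pair, verifies that the curves cross inside the grid (an
#' isosbestic point exists), and records the crossing wavelength(s).
#'
#' @param peaks_HA,peaks_A peak tables (columns `center`, `width`, `height`),
#'   e.g. from [extinction_preset()]
#' @param grid_nm wavelength grid
#' @param species character(2) species labels
#' @return list with `HA` and `A` ([extinction_spectrum()]) and `isosbestic`
#'   (an `"isosbestic_result"`)
#' @export
gen_extinction_pair <- function(peaks_HA, peaks_A, grid_nm = 250:350,
                                species = c("HA", "A")) {
  stopifnot(all(peaks_HA$width > 0), all(peaks_A$width > 0),
            all(peaks_HA$height >= 0), all(peaks_A$height >= 0))
  yH <- gaussian_sum(grid_nm, peaks_HA)
  yA <- gaussian_sum(grid_nm, peaks_A)
  if (max(abs(yH - yA)) < 1e-9)
    stop_domain("degenerate pair: the two curves are identical")
  eH <- extinction_spectrum(grid_nm, yH, species[1L], "neutral")
  eA <- extinction_spectrum(grid_nm, yA, species[2L], "anion")
  iso <- find_isosbestic(list(eH, eA))
  if (length(iso$wavelengths_iso) == 0L)
    stop_domain("invariant violation: the pair does not cross within the grid")
  list(HA = eH, A = eA, isosbestic = iso)
}

#' Simulate a pH titration series of UV spectra
#'
#' For each pH, the sample concentration is drawn with relative Gaussian
#' jitter, the two-state spectrum is built from the Henderson-Hasselbalch
#' fraction, A(lambda) = \[(1-f) eps_HA + f eps_A\] (c/1000) l, and additive
#' Gaussian absorbance noise is applied. Deterministic under a fixed seed.
#'
#' @param eps_HA,eps_A [extinction_spectrum()] pair on one grid
#' @param pKa generating acid dissociation constant
#' @param pH_grid pH values (default 2 to 12 in steps of 0.5)
#' @param conc_uM nominal concentration, uM
#' @param path_cm path length, cm
#' @param noise a [noise_model()]
#' @param seed seed override (default: the noise model's seed)
#' @return a [titration_series()]
#' @export
gen_titration <- function(eps_HA, eps_A, pKa, pH_grid = seq(2, 12, by = 0.5),
                          conc_uM = 100, path_cm = 0.56,
                          noise = noise_model(), seed = noise$seed) {
  stopifnot(same_grid(eps_HA, eps_A))
  w <- eps_HA$wavelengths
  with_local_seed(seed, {
    spectra <- lapply(pH_grid, function(pH) {
      f <- fraction_deprotonated(pH, pKa)
      c_s <- conc_uM * (1 + stats::rnorm(1, 0, noise$conc_jitter_rel))
      eps_mix <- (1 - f) * eps_HA$epsilon + f * eps_A$epsilon
      A <- absorbance_from(eps_mix, c_s, path_cm) +
        stats::rnorm(length(w), 0, noise$sigma_A)
      spectrum(w, A, path_cm,
               meta = list(label = sprintf("pH_%04.1f", pH), pH = pH,
                           conc_uM = conc_uM))
    })
    titration_series(spectra, buffer = "synthetic universal buffer")
  })
}

#' Simulate a continuous two-wavelength glycosylation time course
#'
#' Integrates the mass-action kinetics of the reversible reaction
#' X + Rib1P <-> N7X + Pi in the single extent-of-reaction coordinate x:
#' dx/dt = k_f \[(X0-x)(R0-x) - K (N0+x)(P0+x)\], whose stationary point is
#' the equilibrium of [solve_equilibrium()]. Integration uses
#' [deSolve::ode()] (lsoda, rtol = atol = 1e-10). The extent is mapped to the
#' analysis-wavelength absorbance through the species' extinction
#' coefficients; the control-wavelength trace is flat at the isosbestic
#' absorbance (plus an optional injected linear drift) and both traces carry
#' additive Gaussian noise.
#'
#' @param K generating phosphorolysis equilibrium constant
#' @param k_forward bimolecular forward (glycosylation) rate constant,
#'   uM^-1 s^-1; the default 2e-5 brings the reference design to > 99.5% of
#'   equilibrium within the simulated 4 h
#' @param cond a [reaction_conditions()]
#' @param cfg a [monitoring_config()]
#' @param duration_s,dt_s sampling span and interval (default 4 h every 30 s)
#' @param noise a [noise_model()]
#' @param drift_rate injected control-wavelength drift, AU s^-1 (default 0)
#' @param seed seed override
#' @return a [timecourse()]; the true final extent is attached as attribute
#'   `"x_final"` (uM)
#' @export
gen_reaction_course <- function(K, k_forward = 2e-5, cond,
                                cfg = monitoring_config(),
                                duration_s = 14400, dt_s = 30,
                                noise = noise_model(), drift_rate = 0,
                                seed = noise$seed) {
  stopifnot(inherits(cond, "reaction_conditions"))
  if (K <= 0 || k_forward < 0) stop_domain("K must be > 0 and k_forward >= 0")
  pre <- extinction_preset("glycosylation_pH10")
  grid <- 250:350
  eps_X <- gaussian_sum(grid, pre$peaks_HA)
  eps_N <- gaussian_sum(grid, pre$peaks_A)
  eX_an <- interp_at(grid, eps_X, cfg$lambda_analysis)
  eN_an <- interp_at(grid, eps_N, cfg$lambda_analysis)
  e_iso <- interp_at(grid, eps_X, cfg$lambda_control)
  times <- seq(0, duration_s, by = dt_s)
  deriv <- function(t, x, parms) {
    list(k_forward * ((cond$X0 - x) * (cond$R0 - x) -
                        K * (cond$N0 + x) * (cond$P0 + x)))
  }
  sol <- deSolve::ode(y = c(x = 0), times = times, func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-10)
  x <- sol[, "x"]
  l <- cond$path_length
  A_an <- absorbance_from(eX_an, cond$X0 - x, l) +
    absorbance_from(eN_an, cond$N0 + x, l)
  A_ct <- absorbance_from(e_iso, cond$X0 + cond$N0, l) + drift_rate * times
  with_local_seed(seed, {
    A_an <- A_an + stats::rnorm(length(times), 0, noise$sigma_A)
    A_ct <- A_ct + stats::rnorm(length(times), 0, noise$sigma_A)
    tc <- timecourse(times, A_an, A_ct, cond)
    attr(tc, "x_final") <- unname(x[length(x)])
    tc
  })
}

#' Simulate noisy equilibrium endpoints for an equilibrium-constant design
#'
#' Endpoint-level shortcut used for recovery studies: for every combination of
#' `X0` and `R0` the exact equilibrium conversion at the generating `K` is
#' computed, mapped to an absorbance change through delta-eps and the path
#' length, perturbed with additive Gaussian absorbance noise, and mapped back
#' to a conversion.
#'
#' @param K generating phosphorolysis equilibrium constant
#' @param X0,R0 vectors of initial concentrations (uM); the full grid is used
#' @param cfg a [monitoring_config()]
#' @param noise a [noise_model()]
#' @param path_cm path length, cm
#' @param seed seed override
#' @return list of `"conversion_course"` endpoint runs for [fit_K_global()]
#' @export
gen_equilibrium_endpoints <- function(K = 0.5, X0 = c(100, 150),
                                      R0 = c(25, 50, 100, 200, 500),
                                      cfg = monitoring_config(),
                                      noise = noise_model(), path_cm = 0.56,
                                      seed = noise$seed) {
  design <- expand.grid(X0 = X0, R0 = R0)
  with_local_seed(seed, {
    lapply(seq_len(nrow(design)), function(i) {
      cond <- reaction_conditions(design$X0[i], design$R0[i], pH = 10,
                                  path_length = path_cm)
      chi <- solve_equilibrium(K, cond)
      dA <- absorbance_from(cfg$delta_eps_analysis, chi * cond$X0, path_cm) +
        stats::rnorm(1, 0, noise$sigma_A)
      chi_obs <- 1000 * dA / (cfg$delta_eps_analysis * cond$X0 * path_cm)
      equilibrium_run(chi_obs, cond)
    })
  })
}

#' Simulate initial-rate traces for Michaelis-Menten kinetics
#'
#' For each substrate concentration S, short linear traces with slope
#' dA/dt = delta_eps (l/1000) \[E\] kcat S / (KM + S) plus additive Gaussian
#' noise, replicated with distinct sub-seeds.
#'
#' @param kcat turnover number, s^-1
#' @param KM Michaelis constant, uM
#' @param S_grid substrate concentrations, uM
#' @param enzyme_uM enzyme molar concentration, uM
#' @param R0 co-substrate concentration held saturating, uM
#' @param cfg a [monitoring_config()]
#' @param duration_s,dt_s trace span and interval (default 20 min every 5 s)
#' @param noise a [noise_model()]
#' @param replicates replicates per concentration
#' @param path_cm path length, cm
#' @param seed seed
#' @return list of [timecourse()] objects
#' @export
gen_kinetics_series <- function(kcat, KM,
                                S_grid = c(20, 50, 100, 150, 200, 300, 400, 500),
                                enzyme_uM = 3.8, R0 = 200,
                                cfg = monitoring_config(),
                                duration_s = 1200, dt_s = 5,
                                noise = noise_model(), replicates = 4,
                                path_cm = 0.56, seed = noise$seed) {
  pre <- extinction_preset("glycosylation_pH10")
  grid <- 250:350
  eX_an <- interp_at(grid, gaussian_sum(grid, pre$peaks_HA), cfg$lambda_analysis)
  times <- seq(0, duration_s, by = dt_s)
  with_local_seed(seed, {
    out <- list()
    for (S in S_grid) {
      for (r in seq_len(replicates)) {
        v0 <- enzyme_uM * kcat * S / (KM + S)             # uM s^-1
        slope <- absorbance_from(cfg$delta_eps_analysis, v0, path_cm)  # AU s^-1
        A0 <- absorbance_from(eX_an, S, path_cm)
        A_an <- A0 + slope * times + stats::rnorm(length(times), 0, noise$sigma_A)
        A_ct <- absorbance_from(interp_at(grid, gaussian_sum(grid, pre$peaks_HA),
                                          cfg$lambda_control), S, path_cm) +
          stats::rnorm(length(times), 0, noise$sigma_A)
        cond <- reaction_conditions(S, R0, enzyme_uM = enzyme_uM, pH = 10,
                                    path_length = path_cm)
        tc <- timecourse(times, A_an, A_ct, cond)
        tc$conditions$replicate <- r
        out[[length(out) + 1L]] <- tc
      }
    }
    out
  })
}

#' Simulate observed rate constants directly
#'
#' Rate-level shortcut for model-discrimination studies: kobs values are drawn
#' from either a Michaelis-Menten hyperbola or a proportional model with
#' multiplicative Gaussian noise.
#'
#' @param model `"mm"` or `"linear"`
#' @param S_grid substrate concentrations, uM
#' @param kcat,KM Michaelis-Menten parameters (used when `model = "mm"`)
#' @param a proportionality constant, uM^-1 s^-1 (used when `model = "linear"`)
#' @param replicates replicates per concentration
#' @param rel_sd relative rate noise (default 0.02)
#' @param seed seed
#' @return `data.frame(S, kobs, replicate)`
#' @export
gen_rate_data <- function(model = c("mm", "linear"),
                          S_grid = c(20, 50, 100, 150, 200, 300, 400, 500),
                          kcat = 0.08, KM = 250, a = 2e-4,
                          replicates = 4, rel_sd = 0.02, seed = NULL) {
  model <- match.arg(model)
  df <- expand.grid(S = S_grid, replicate = seq_len(replicates))
  mu <- if (model == "mm") kcat * df$S / (KM + df$S) else a * df$S
  with_local_seed(seed, {
    df$kobs <- mu * (1 + stats::rnorm(nrow(df), 0, rel_sd))
    df[, c("S", "kobs", "replicate")]
  })
}

#' Synthetic excitation tables for candidate xanthosine structures
#'
#' Invented stand-ins shaped like tabulated excited-state output for four
#' glycosylation/tautomer candidates (labelled `_synth` throughout): the
#' N7-like candidate is the ensemble energy minimum and carries the most
#' redshifted first transition, while the O2-like candidate is far
#' blue-shifted -- the configuration in which redshift screening should keep
#' the former and exclude the latter.
#'
#' @return list of [tautomer_states()] objects
#' @export
synthetic_excitations <- function() {
  list(
    tautomer_states("N7X_synth", 0,
                    data.frame(energy_ev = c(4.10, 5.30),
                               strength = c(0.20, 0.35))),
    tautomer_states("O6X_synth", 4.5,
                    data.frame(energy_ev = c(4.20, 5.35),
                               strength = c(0.18, 0.30))),
    tautomer_states("N9X_synth", 9.0,
                    data.frame(energy_ev = c(4.49, 5.60),
                               strength = c(0.20, 0.30))),
    tautomer_states("O2X_synth", 3.0,
                    data.frame(energy_ev = c(4.90, 6.00),
                               strength = c(0.25, 0.20))))
}

#' Write a complete synthetic fixture set for one analysis scenario
#'
#' Emits the delimited-text input files of the corresponding pipeline stage
#' plus a `manifest.json` recording the true generating parameters, so
#' downstream recovery can be asserted against ground truth. Re-running with
#' the same seed reproduces byte-identical files.
#'
#' @param out_dir output directory (created if needed)
#' @param scenario `"pka"`, `"keq"`, `"kinetics"`, or `"dft"`
#' @param seed integer seed
#' @param pKa,K,kcat,KM generating parameters for the respective scenarios
#' @param noise a [noise_model()]
#' @return invisibly, the manifest as a list
#' @export
write_fixtures <- function(out_dir, scenario = c("pka", "keq", "kinetics", "dft"),
                           seed = 1L, pKa = 8.5, K = 0.5, kcat = 0.08, KM = 250,
                           noise = noise_model()) {
  scenario <- match.arg(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(scenario = scenario, seed = seed,
                   sigma_A = noise$sigma_A,
                   conc_jitter_rel = noise$conc_jitter_rel)
  files <- character(0)
  if (scenario == "pka") {
    pre <- extinction_preset("n7x_titration")
    pair <- gen_extinction_pair(pre$peaks_HA, pre$peaks_A, species = pre$species)
    series <- gen_titration(pair$HA, pair$A, pKa, noise = noise, seed = seed)
    for (s in series) {
      f <- file.path(out_dir, paste0(s$meta$label, ".csv"))
      write_spectrum(s, f)
      files <- c(files, basename(f))
    }
    manifest <- c(manifest, list(pKa = pKa, conc_uM = 100, path_cm = 0.56,
                                 lambda_iso = pre$lambda_iso))
  } else if (scenario == "keq") {
    design <- expand.grid(X0 = c(100, 150), R0 = c(0, 25, 50, 100, 200, 500))
    k_forward <- 2e-5
    for (i in seq_len(nrow(design))) {
      cond <- reaction_conditions(design$X0[i], design$R0[i], enzyme_gL = 0.4,
                                  pH = 10, path_length = 0.56)
      tc <- gen_reaction_course(K, k_forward, cond, noise = noise,
                                seed = seed + i)
      f <- file.path(out_dir, sprintf("timecourse_X%03d_R%03d.csv",
                                      design$X0[i], design$R0[i]))
      write_timecourse(tc, f)
      files <- c(files, basename(f))
    }
    manifest <- c(manifest, list(K = K, k_forward = k_forward,
                                 design = list(X0 = c(100, 150),
                                               R0 = c(0, 25, 50, 100, 200, 500))))
  } else if (scenario == "kinetics") {
    tcs <- gen_kinetics_series(kcat, KM, noise = noise, seed = seed)
    for (i in seq_along(tcs)) {
      cond <- tcs[[i]]$conditions
      f <- file.path(out_dir, sprintf("kinetics_S%03d_rep%d.csv",
                                      round(cond$X0), cond$replicate))
      write_timecourse(tcs[[i]], f)
      files <- c(files, basename(f))
    }
    manifest <- c(manifest, list(kcat = kcat, KM = KM, enzyme_uM = 3.8))
  } else if (scenario == "dft") {
    states <- synthetic_excitations()
    f <- file.path(out_dir, "excitations.csv")
    write_excitations(states, f)
    files <- c(files, basename(f))
    manifest <- c(manifest,
                  list(structures = vapply(states, `[[`, character(1), "label"),
                       temperature_K = 298.15, sigma_ev = 0.3))
  }
  manifest$files <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
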