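#' Excited-state data for one candidate structure
#'
#' Holds the tabulated output of an excited-state (e.g. TDDFT) calculation for
#' one candidate tautomer/regioisomer: its relative electronic energy within
#' the ensemble and a stick spectrum of (excitation energy, oscillator
#' strength) pairs.
#'
#' @param label structure label, e.g. `"N7X"`, `"N9X"`, `"O6X"`, `"O2X"`
#' @param energy_rel relative electronic energy, kJ mol^-1 (>= 0; the ensemble
#'   minimum is 0)
#' @param excitations data.frame with columns `energy_ev` (> 0) and `strength`
#'   (oscillator strength, >= 0); at least one row
#' @return an object of class `"tautomer_states"`
#' @export
tautomer_states <- function(label, energy_rel, excitations) {
  stopifnot(is.data.frame(excitations),
            all(c("energy_ev", "strength") %in% names(excitations)))
  if (nrow(excitations) < 1L) stop_domain("at least one excitation is required")
  if (any(excitations$strength < 0)) stop_domain("oscillator strengths must be >= 0")
  if (any(excitations$energy_ev <= 0)) stop_domain("excitation energies must be positive")
  if (energy_rel < 0) stop_domain("relative energy must be >= 0")
  structure(list(label = label, energy_rel = energy_rel,
                 excitations = excitations[, c("energy_ev", "strength")]),
            class = "tautomer_states")
}

#' Boltzmann population weights from relative electronic energies
#'
#' w_i = exp(-E_i / RT) / sum_j exp(-E_j / RT), computed shift-stabilized
#' (energies are referenced to their minimum before exponentiation) and
#' renormalized so the weights sum to exactly 1. Invariant to adding a
#' constant to all energies.
#'
#' @param energies_rel relative electronic energies, kJ mol^-1
#' @param temperature temperature in K (> 0), default 298.15
#' @return numeric vector of weights (names preserved), summing to 1
#' @export
boltzmann_weights <- function(energies_rel, temperature = 298.15) {
  if (length(energies_rel) == 0L) stop_domain("empty energy list")
  if (temperature <= 0) stop_domain("temperature must be positive")
  e <- energies_rel - min(energies_rel)
  w <- exp(-e / (.r_gas_kj * temperature))
  w / sum(w)
}

#' Gaussian broadening of a stick spectrum onto a wavelength grid
#'
#' Convolves excitations with Gaussians in the energy domain,
#' S(E) = sum_k f_k * exp(-(E - E_k)^2 / (2 sigma^2)), and evaluates the
#' result on a wavelength grid through E(eV) = 1239.842 / lambda(nm).
#'
#' @param excitations data.frame with columns `energy_ev`, `strength`
#' @param sigma_ev Gaussian standard deviation in eV (> 0)
#' @param grid_nm wavelength grid in nm
#' @return intensity (dimensionless) per grid wavelength
#' @export
broaden <- function(excitations, sigma_ev = 0.3, grid_nm = 250:350) {
  if (sigma_ev <= 0) stop_domain("sigma_ev must be positive")
  E <- .nm_ev / grid_nm
  S <- numeric(length(E))
  for (k in seq_len(nrow(excitations))) {
    S <- S + excitations$strength[k] *
      exp(-(E - excitations$energy_ev[k])^2 / (2 * sigma_ev^2))
  }
  S
}

#' Assemble a Boltzmann-weighted predicted UV spectrum
#'
#' Builds the ensemble spectrum sum_i w_i * broaden(excitations_i) with
#' Boltzmann weights from the structures' relative electronic energies, then
#' (by default) rescales so the most redshifted peak -- the largest-wavelength
#' interior local maximum above 5% of the global maximum -- has height 1. If
#' no local maximum exists the global maximum is used, with a warning.
#'
#' @param ensemble list of [tautomer_states()] objects
#' @param temperature temperature in K for the Boltzmann weights
#' @param sigma_ev Gaussian broadening width, eV
#' @param grid_nm wavelength grid in nm
#' @param normalization `"redshifted-peak"` (default), `"max"`, or `"none"`
#' @param label optional label for the assembled spectrum
#' @return an object of class `"predicted_spectrum"`: `wavelengths`,
#'   `intensity`, `weights` (named), `sigma_ev`, `normalization`,
#'   `lambda_peak` (most redshifted peak, nm), `label`
#' @export
assemble_spectrum <- function(ensemble, temperature = 298.15, sigma_ev = 0.3,
                              grid_nm = 250:350,
                              normalization = c("redshifted-peak", "max", "none"),
                              label = NULL) {
  normalization <- match.arg(normalization)
  if (length(ensemble) == 0L) stop_domain("empty ensemble")
  stopifnot(all(vapply(ensemble, inherits, logical(1), "tautomer_states")))
  energies <- vapply(ensemble, `[[`, numeric(1), "energy_rel")
  labels <- vapply(ensemble, `[[`, character(1), "label")
  w <- stats::setNames(boltzmann_weights(energies, temperature), labels)
  intensity <- numeric(length(grid_nm))
  for (i in seq_along(ensemble)) {
    intensity <- intensity + w[i] *
      broaden(ensemble[[i]]$excitations, sigma_ev, grid_nm)
  }
  peaks <- find_peaks(grid_nm, intensity, min_frac = 0.05)
  lambda_peak <- if (nrow(peaks)) max(peaks$position) else NA_real_
  if (normalization == "redshifted-peak") {
    if (nrow(peaks)) {
      h <- peaks$height[which.max(peaks$position)]
    } else {
      warning("no interior local maximum; normalizing to the global maximum",
              call. = FALSE)
      h <- max(intensity)
      lambda_peak <- grid_nm[which.max(intensity)]
    }
    intensity <- intensity / h
  } else if (normalization == "max") {
    intensity <- intensity / max(intensity)
    lambda_peak <- lambda_peak %||% grid_nm[which.max(intensity)]
  }
  structure(list(wavelengths = as.numeric(grid_nm), intensity = intensity,
                 weights = w, sigma_ev = sigma_ev,
                 normalization = normalization, lambda_peak = lambda_peak,
                 label = label %||% paste(labels, collapse = "+")),
            class = "predicted_spectrum")
}

#' @export
print.predicted_spectrum <- function(x, ...) {
  cat(sprintf("<predicted_spectrum> %s: redshifted peak at %.1f nm (sigma %.2g eV, %s)\n",
              x$label, x$lambda_peak, x$sigma_ev, x$normalization))
  cat("  weights:", paste(sprintf("%s %.3g", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}

# Most redshifted prominent peak of an observed or predicted spectrum.
redshifted_peak <- function(x) {
  y <- if (inherits(x, "spectrum")) x$absorbance else x$intensity
  w <- x$wavelengths
  peaks <- find_peaks(w, y, min_frac = 0.05)
  if (nrow(peaks)) max(peaks$position) else w[which.max(y)]
}

#' Rank candidate structures by agreement with an observed redshifted peak
#'
#' Screens candidate predicted spectra against a measured spectrum by the
#' distance between their most redshifted peaks; ties (within 0.5 nm) are
#' broken by the Pearson correlation of the curves over the shared grid.
#' Useful for excluding candidates whose absorption is far blue-shifted from
#' the observation.
#'
#' @param candidates list of `"predicted_spectrum"` objects
#' @param observed a [spectrum()] (or `"predicted_spectrum"`) to match
#' @return `data.frame(label, lambda_peak, distance_nm, shape_cor)` sorted
#'   best-first
#' @export
redshift_rank <- function(candidates, observed) {
  if (length(candidates) < 1L) stop_domain("at least one candidate is required")
  obs_peak <- redshifted_peak(observed)
  obs_y <- if (inherits(observed, "spectrum")) observed$absorbance else observed$intensity
  rows <- lapply(candidates, function(cand) {
    y <- stats::approx(cand$wavelengths, cand$intensity,
                       xout = observed$wavelengths, rule = 1)$y
    ok <- is.finite(y)
    shape_cor <- if (sum(ok) > 2L) stats::cor(y[ok], obs_y[ok]) else NA_real_
    data.frame(label = cand$label %||% "?",
               lambda_peak = redshifted_peak(cand),
               distance_nm = abs(redshifted_peak(cand) - obs_peak),
               shape_cor = shape_cor)
  })
  out <- do.call(rbind, rows)
  out <- out[order(round(out$distance_nm / 0.5), -out$shape_cor), , drop = FALSE]
  rownames(out) <- NULL
  out
}
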