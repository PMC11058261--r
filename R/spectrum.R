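#' Construct an absorbance spectrum
#'
#' A spectrum is an absorbance trace on a strictly increasing, uniformly
#' spaced wavelength grid (the plate-reader convention is 250-350 nm in 1-nm
#' steps), together with the optical path length and free-form metadata
#' (sample label, pH, nominal concentration, temperature).
#'
#' @param wavelengths wavelength grid in nm, strictly increasing, uniform step
#' @param absorbance absorbance values (AU), one per wavelength, all finite
#' @param path_length optical path length in cm (> 0); 1.0 for a standard
#'   cuvette, 0.56 for a 200 uL fill of a 96-well UV plate
#' @param meta named list of metadata; recognized keys include `label`, `pH`,
#'   `conc_uM`, `temperature`
#' @return an object of class `"spectrum"`
#' @export
spectrum <- function(wavelengths, absorbance, path_length = 1, meta = list()) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.numeric(absorbance)
  if (length(wavelengths) != length(absorbance))
    stop_domain("wavelength grid and absorbance differ in length")
  if (length(wavelengths) < 2L)
    stop_domain("a spectrum needs at least two wavelengths")
  if (!is_uniform_grid(wavelengths))
    stop_domain("wavelengths must be strictly increasing with a uniform step")
  if (!all(is.finite(absorbance)))
    stop_domain("absorbance values must all be finite")
  if (!is.numeric(path_length) || length(path_length) != 1L || path_length <= 0)
    stop_domain("path_length must be a single positive number (cm)")
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 path_length = path_length, meta = meta),
            class = "spectrum")
}

#' Construct a molar extinction spectrum
#'
#' Extinction coefficients (mM^-1 cm^-1) on the same grid contract as
#' [spectrum()]. The protonation state records whether the curve refers to the
#' neutral species, the (mono)anion, or an apparent mixture at a stated pH.
#'
#' @param wavelengths wavelength grid in nm
#' @param epsilon extinction coefficients, mM^-1 cm^-1, all >= 0
#' @param species species label, e.g. `"X"`, `"N7X"`
#' @param protonation_state one of `"neutral"`, `"anion"`, `"apparent-at-pH"`
#' @param meta named list of metadata
#' @return an object of class `"extinction_spectrum"`
#' @export
extinction_spectrum <- function(wavelengths, epsilon, species = "",
                                protonation_state = c("apparent-at-pH",
                                                      "neutral", "anion"),
                                meta = list()) {
  protonation_state <- match.arg(protonation_state)
  wavelengths <- as.numeric(wavelengths)
  epsilon <- as.numeric(epsilon)
  if (length(wavelengths) != length(epsilon))
    stop_domain("wavelength grid and epsilon differ in length")
  if (!is_uniform_grid(wavelengths))
    stop_domain("wavelengths must be strictly increasing with a uniform step")
  if (!all(is.finite(epsilon)) || any(epsilon < 0))
    stop_domain("epsilon must be finite and non-negative everywhere")
  structure(list(wavelengths = wavelengths, epsilon = epsilon,
                 species = species, protonation_state = protonation_state,
                 meta = meta),
            class = "extinction_spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- range(x$wavelengths)
  cat(sprintf("<spectrum> %g-%g nm (%d points), path %g cm",
              rng[1], rng[2], length(x$wavelengths), x$path_length))
  if (!is.null(x$meta$label)) cat(", label:", x$meta$label)
  if (!is.null(x$meta$pH)) cat(sprintf(", pH %.2f", as.numeric(x$meta$pH)))
  cat("\n")
  invisible(x)
}

#' @export
print.extinction_spectrum <- function(x, ...) {
  rng <- range(x$wavelengths)
  cat(sprintf("<extinction_spectrum> %s (%s), %g-%g nm, max eps %.3g mM^-1 cm^-1\n",
              if (nzchar(x$species)) x$species else "?", x$protonation_state,
              rng[1], rng[2], max(x$epsilon)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelengths) == length(b$wavelengths) &&
    all(abs(a$wavelengths - b$wavelengths) < tol)
}

#' Beer-Lambert forward model for a mixture
#'
#' Computes the absorbance spectrum of a mixture of absorbing species:
#' A(lambda) = sum_i eps_i(lambda) * (c_i / 1000) * l, with extinction in
#' mM^-1 cm^-1, concentrations in uM and the path length in cm.
#'
#' @param components list of [extinction_spectrum()] objects sharing one grid
#' @param concentrations concentrations in uM, one per component, all >= 0
#' @param path_length optical path length in cm
#' @return a [spectrum()] whose metadata records the composition
#' @export
beer_lambert_mix <- function(components, concentrations, path_length = 1) {
  if (inherits(components, "extinction_spectrum")) components <- list(components)
  if (length(components) != length(concentrations))
    stop_domain("one concentration per component is required")
  if (any(concentrations < 0))
    stop_domain("concentrations must be non-negative")
  ref <- components[[1L]]
  A <- numeric(length(ref$wavelengths))
  labels <- character(length(components))
  for (i in seq_along(components)) {
    comp <- components[[i]]
    if (!inherits(comp, "extinction_spectrum"))
      stop_domain("components must be extinction_spectrum objects")
    if (!same_grid(ref, comp))
      stop_domain("component wavelength grids are incompatible")
    A <- A + absorbance_from(comp$epsilon, concentrations[i], path_length)
    labels[i] <- if (nzchar(comp$species)) comp$species else paste0("component", i)
  }
  spectrum(ref$wavelengths, A, path_length,
           meta = list(label = "mixture",
                       composition = stats::setNames(concentrations, labels)))
}

#' Calibrate extinction coefficients from a reference spectrum
#'
#' Inverts the Beer-Lambert law for a single-species sample of known
#' concentration: eps(lambda) = A(lambda) * 1000 / (c * l). Negative values
#' (baseline noise) are clipped to zero; the number of clipped wavelengths is
#' recorded in the result's metadata and a warning is raised when more than 5%
#' of the grid is affected.
#'
#' @param spec a [spectrum()] of a single species
#' @param concentration sample concentration in uM (> 0)
#' @param species,protonation_state labels passed to [extinction_spectrum()]
#' @return an [extinction_spectrum()]
#' @export
calibrate_extinction <- function(spec, concentration, species = "",
                                 protonation_state = "apparent-at-pH") {
  stopifnot(inherits(spec, "spectrum"))
  if (!is.numeric(concentration) || concentration <= 0)
    stop_domain("concentration must be positive (uM)")
  eps <- spec$absorbance * 1000 / (concentration * spec$path_length)
  n_clip <- sum(eps < 0)
  if (n_clip > 0.05 * length(eps))
    warning(sprintf("%d of %d wavelengths gave negative extinction and were clipped",
                    n_clip, length(eps)), call. = FALSE)
  eps[eps < 0] <- 0
  extinction_spectrum(spec$wavelengths, eps, species, protonation_state,
                      meta = c(spec$meta, list(n_clipped = n_clip,
                                               calib_conc_uM = concentration)))
}
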