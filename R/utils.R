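# Internal helpers shared across modules.

# photon energy (eV) x wavelength (nm); E = .nm_ev / lambda
.nm_ev <- 1239.842
# gas constant, kJ mol^-1 K^-1
.r_gas_kj <- 8.314462618e-3

#' Beer-Lambert absorbance from extinction, concentration and path length
#'
#' The single place where the microM -> mM unit conversion happens:
#' A = epsilon (mM^-1 cm^-1) * c (uM) / 1000 * l (cm).
#'
#' @param epsilon molar extinction, mM^-1 cm^-1 (vectorized over wavelength)
#' @param conc_uM concentration in micromolar
#' @param path_cm optical path length in cm
#' @return absorbance (AU)
#' @export
absorbance_from <- function(epsilon, conc_uM, path_cm) {
  epsilon * (conc_uM / 1000) * path_cm
}

#' @rdname absorbance_from
#' @param A absorbance (AU)
#' @return `conc_from_absorbance`: concentration in micromolar
#' @export
conc_from_absorbance <- function(A, epsilon, path_cm) {
  1000 * A / (epsilon * path_cm)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so generators behave as pure functions.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

is_uniform_grid <- function(w, tol = 1e-6) {
  if (length(w) < 2L) return(TRUE)
  d <- diff(w)
  all(d > 0) && (max(d) - min(d)) < tol * max(abs(d))
}

# Linear interpolation of y(w) at `at`; errors if `at` is outside the grid.
interp_at <- function(w, y, at) {
  if (at < w[1L] || at > w[length(w)])
    stop("wavelength ", at, " nm lies outside the grid [", w[1L], ", ",
         w[length(w)], "] nm", call. = FALSE)
  stats::approx(w, y, xout = at)$y
}

# Parabolic (three-point) refinement of an extremum location.
# Returns c(position, value) of the vertex through (x0-step, ym), (x0, y0),
# (x0+step, yp); falls back to the grid point when the parabola degenerates.
parabolic_vertex <- function(x0, step, ym, y0, yp) {
  denom <- ym - 2 * y0 + yp
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(c(x0, y0))
  delta <- 0.5 * (ym - yp) / denom
  delta <- max(-1, min(1, delta))
  c(x0 + delta * step, y0 - 0.25 * (ym - yp) * delta)
}

# Interior local maxima of y over x above `min_frac` of the global maximum,
# with parabolic sub-grid refinement. Returns a data.frame(position, height).
find_peaks <- function(x, y, min_frac = 0.05) {
  n <- length(y)
  out <- data.frame(position = numeric(0), height = numeric(0))
  if (n < 3L) return(out)
  floor_h <- min_frac * max(y)
  step <- x[2L] - x[1L]
  for (i in 2:(n - 1L)) {
    if (y[i] >= y[i - 1L] && y[i] > y[i + 1L] && y[i] >= floor_h) {
      v <- parabolic_vertex(x[i], step, y[i - 1L], y[i], y[i + 1L])
      out <- rbind(out, data.frame(position = v[1L], height = v[2L]))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Domain/validation errors carry their own condition class so callers (and
# the CLI exit-code logic) can distinguish bad inputs from runtime failures.
stop_domain <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("nucleospec_validation_error",
                                "error", "condition")))
}
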