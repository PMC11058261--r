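#' Two-state deprotonated fraction (Henderson-Hasselbalch)
#'
#' For a monoprotic acid-base pair HA/A- the deprotonated fraction at a given
#' pH is f = 1 / (1 + 10^(pKa - pH)). Vectorized over both arguments.
#'
#' @param pH solution pH
#' @param pKa acid dissociation constant (negative log)
#' @return fraction of the deprotonated species, in (0, 1)
#' @export
fraction_deprotonated <- function(pH, pKa) {
  1 / (1 + 10^(pKa - pH))
}

#' Bundle pH-indexed spectra into a titration series
#'
#' @param spectra list of [spectrum()] objects, each carrying a distinct
#'   numeric `pH` in its metadata; at least 4 pH values in \[0, 14\], one
#'   shared wavelength grid
#' @param buffer free-text description of the buffer system
#' @return an object of class `"titration_series"` (a list of spectra sorted
#'   by pH, with a `buffer` attribute)
#' @export
titration_series <- function(spectra, buffer = "") {
  pH <- vapply(spectra, function(s) as.numeric(s$meta$pH %||% NA_real_), numeric(1))
  if (anyNA(pH)) stop_domain("every spectrum needs a numeric pH in its metadata")
  if (any(pH < 0 | pH > 14)) stop_domain("pH values must lie in [0, 14]")
  if (length(unique(pH)) < 4L) stop_domain("at least 4 distinct pH values required")
  ref <- spectra[[1L]]
  for (s in spectra[-1L]) if (!same_grid(ref, s))
    stop_domain("titration spectra are on incompatible grids")
  out <- spectra[order(pH)]
  attr(out, "buffer") <- buffer
  class(out) <- c("titration_series", "list")
  out
}

series_pH <- function(series) {
  vapply(series, function(s) as.numeric(s$meta$pH), numeric(1))
}

#' Fit a spectrophotometric pKa to a titration series
#'
#' Implements the isosbestic-normalized two-state analysis: (1) detect (or
#' accept) the isosbestic point of deprotonation; (2) normalize all spectra to
#' a common absorbance there, removing per-sample concentration error; (3)
#' choose a reporter wavelength by maximum endpoint contrast
#' |A(lambda, pH_max) - A(lambda, pH_min)| (optionally averaging the most
#' contrasting wavelengths); (4) fit
#' A(pH) = A_HA + (A_A - A_HA) * f(pH; pKa), with f the Henderson-Hasselbalch
#' fraction, by least squares. The pKa is profiled on a 1-D grid with the two
#' endpoint absorbances solved linearly at each step (variable projection),
#' then polished by golden-section search; the 95% CI comes from the
#' linearized parameter covariance.
#'
#' @param series a [titration_series()] (or plain list of pH-tagged spectra)
#' @param lambda_iso isosbestic wavelength (nm); detected when `NULL`
#' @param lambda_reporter reporter wavelength (nm); chosen by contrast when
#'   `NULL`
#' @param normalize apply isosbestic normalization (default `TRUE`); turning
#'   it off exposes the raw fit to concentration error
#' @param n_reporter number of top-contrast wavelengths to average (default 1)
#' @return an object of class `"deprotonation_model"`: `pKa`, `ci95`,
#'   `lambda_iso`, `lambda_reporter`, endpoint absorbances `A_HA` and `A_A`,
#'   `residual_rms`, `extrapolated` flag, `fraction_curve` (a function of pH),
#'   and the fitted (pH, A) table in `$data`
#' @export
fit_pka <- function(series, lambda_iso = NULL, lambda_reporter = NULL,
                    normalize = TRUE, n_reporter = 1L) {
  if (!inherits(series, "titration_series")) series <- titration_series(series)
  pH <- series_pH(series)
  if (normalize) {
    if (is.null(lambda_iso)) {
      iso <- find_isosbestic(unclass(series))
      if (length(iso$wavelengths_iso) == 0L) {
        warning("no isosbestic point detected; fitting without normalization",
                call. = FALSE)
        normalize <- FALSE
      } else {
        lambda_iso <- iso$wavelengths_iso[which.min(iso$residual_spread)]
      }
    }
    if (normalize)
      series[] <- isosbestic_normalize(unclass(series), lambda_iso, "mean")
  }
  w <- series[[1L]]$wavelengths
  Amat <- vapply(series, function(s) s$absorbance, numeric(length(w)))
  if (is.null(lambda_reporter)) {
    contrast <- abs(Amat[, which.max(pH)] - Amat[, which.min(pH)])
    if (n_reporter > 1L) {
      idx <- order(contrast, decreasing = TRUE)[seq_len(n_reporter)]
      lambda_reporter <- w[idx]
    } else {
      lambda_reporter <- w[which.max(contrast)]
    }
  }
  y <- if (length(lambda_reporter) > 1L) {
    colMeans(Amat[match(round(lambda_reporter), round(w)), , drop = FALSE])
  } else {
    vapply(seq_along(series), function(i)
      interp_at(w, Amat[, i], lambda_reporter), numeric(1))
  }
  n <- length(y)
  rss_at <- function(pKa) {
    f <- fraction_deprotonated(pH, pKa)
    X <- cbind(1 - f, f)
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  grid <- seq(min(pH) - 1, max(pH) + 1, length.out = 81L)
  rss_grid <- vapply(grid, rss_at, numeric(1))
  i0 <- which.min(rss_grid)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(rss_at, c(lo, hi), tol = 1e-10)
  pKa_hat <- opt$minimum
  f <- fraction_deprotonated(pH, pKa_hat)
  X <- cbind(1 - f, f)
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e)
    stop_domain("pKa fit failed: ", conditionMessage(e)))
  if (fit$rank < 2L) stop_domain("pKa fit is singular (degenerate endpoints)")
  A_HA <- fit$coefficients[1L]; A_A <- fit$coefficients[2L]
  resid <- fit$residuals
  rss <- sum(resid^2)
  dof <- max(n - 3L, 1L)
  sigma2 <- rss / dof
  # linearized covariance: columns d/dA_HA, d/dA_A, d/dpKa
  J <- cbind(1 - f, f, (A_A - A_HA) * (-log(10)) * f * (1 - f))
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ) * sigma2, error = function(e) NULL)
  se_pKa <- if (is.null(cov)) NA_real_ else sqrt(max(cov[3L, 3L], 0))
  tcrit <- stats::qt(0.975, dof)
  ci95 <- pKa_hat + c(-1, 1) * tcrit * se_pKa
  extrapolated <- (pKa_hat - min(pH) < 0.5) || (max(pH) - pKa_hat < 0.5)
  if (extrapolated)
    warning("fitted midpoint is not bracketed by >= 0.5 pH units on both sides",
            call. = FALSE)
  structure(list(pKa = pKa_hat, ci95 = ci95, lambda_iso = lambda_iso,
                 lambda_reporter = lambda_reporter,
                 A_HA = unname(A_HA), A_A = unname(A_A),
                 residual_rms = sqrt(rss / n), extrapolated = extrapolated,
                 normalized = normalize,
                 fraction_curve = local({
                   p <- pKa_hat
                   function(pH) fraction_deprotonated(pH, p)
                 }),
                 data = data.frame(pH = pH, A = y), n = n),
            class = "deprotonation_model")
}

#' @export
print.deprotonation_model <- function(x, ...) {
  cat(sprintf("<deprotonation_model> pKa = %.3f (95%% CI %.3f-%.3f)\n",
              x$pKa, x$ci95[1], x$ci95[2]))
  cat(sprintf("  lambda_iso = %s nm, reporter = %s nm, residual rms = %.2g AU\n",
              if (is.null(x$lambda_iso)) "none" else
                paste(signif(x$lambda_iso, 4), collapse = "/"),
              paste(signif(x$lambda_reporter, 4), collapse = "/"),
              x$residual_rms))
  if (x$extrapolated) cat("  warning: midpoint poorly bracketed (extrapolated)\n")
  invisible(x)
}

#' Measured species distribution from a fitted two-state model
#'
#' Converts the reporter-wavelength absorbances of a titration series into
#' per-pH measured deprotonated fractions using the fitted endpoints:
#' f_hat = (A - A_HA) / (A_A - A_HA), clipped to \[-0.1, 1.1\].
#'
#' @param series the [titration_series()] the model was fitted to
#' @param model a `"deprotonation_model"` from [fit_pka()]
#' @return `data.frame(pH, fraction, fraction_fit)`
#' @export
species_distribution <- function(series, model) {
  if (!inherits(series, "titration_series")) series <- titration_series(series)
  stopifnot(inherits(model, "deprotonation_model"))
  dA <- model$A_A - model$A_HA
  if (abs(dA) < 3 * model$residual_rms)
    stop_domain("uninformative reporter: endpoint absorbances are < 3 sigma apart")
  if (model$normalized)
    series[] <- isosbestic_normalize(unclass(series), model$lambda_iso, "mean")
  pH <- series_pH(series)
  w <- series[[1L]]$wavelengths
  y <- if (length(model$lambda_reporter) > 1L) {
    Amat <- vapply(series, function(s) s$absorbance, numeric(length(w)))
    colMeans(Amat[match(round(model$lambda_reporter), round(w)), , drop = FALSE])
  } else {
    vapply(series, function(s)
      interp_at(w, s$absorbance, model$lambda_reporter), numeric(1))
  }
  f_hat <- pmin(pmax((y - model$A_HA) / dA, -0.1), 1.1)
  data.frame(pH = pH, fraction = f_hat,
             fraction_fit = fraction_deprotonated(pH, model$pKa))
}
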