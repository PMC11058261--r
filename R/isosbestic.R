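#' Locate isosbestic points in a family of spectra
#'
#' An isosbestic point is a wavelength at which two interconverting species
#' have identical extinction, so the total absorbance there is invariant to
#' their ratio. Candidates are significant sign changes of the signed
#' difference between the two most dissimilar curves (the difference must
#' exceed the threshold on both flanks, which rejects noise wiggles in
#' near-zero tails); each candidate is refined to sub-grid precision by a
#' local quadratic root and then accepted only if the across-spectra spread
#' there -- the standard deviation of absorbance for a series, or
#' |eps_a - eps_b| for a pair -- falls below the threshold (default 2% of the
#' series' median signal). Several crossings may be reported (deprotonation
#' of 9-ribosylated xanthosine shows two, at 259 and 268 nm); an empty result
#' means no crossing, not an error.
#'
#' @param spectra a list of two or more [spectrum()] objects on one grid, or a
#'   list of exactly two [extinction_spectrum()] objects
#' @param window optional `c(min_nm, max_nm)` restricting the search
#' @param threshold spread threshold (same units as the spread); default 2% of
#'   the median absolute signal over the searched window
#' @return an object of class `"isosbestic_result"` with fields
#'   `wavelengths_iso` (nm, ascending), `residual_spread` (spread at each
#'   candidate), `method_window`, and `threshold`
#' @export
find_isosbestic <- function(spectra, window = NULL, threshold = NULL) {
  if (length(spectra) < 2L)
    stop_domain("at least two spectra are required")
  is_eps <- all(vapply(spectra, inherits, logical(1), "extinction_spectrum"))
  is_abs <- all(vapply(spectra, inherits, logical(1), "spectrum"))
  if (!is_eps && !is_abs)
    stop_domain("spectra must all be 'spectrum' or all 'extinction_spectrum'")
  ref <- spectra[[1L]]
  for (s in spectra[-1L]) {
    if (!same_grid(ref, s)) stop_domain("spectra are on incompatible grids")
  }
  w <- ref$wavelengths
  val <- vapply(spectra, function(s) if (is_eps) s$epsilon else s$absorbance,
                numeric(length(w)))
  keep <- rep(TRUE, length(w))
  if (!is.null(window)) keep <- w >= window[1L] & w <= window[2L]
  if (sum(keep) < 3L) stop_domain("search window contains fewer than 3 grid points")
  wk <- w[keep]
  vk <- val[keep, , drop = FALSE]
  spread <- if (is_eps && length(spectra) == 2L) {
    abs(vk[, 1L] - vk[, 2L])
  } else {
    apply(vk, 1L, stats::sd)
  }
  if (is.null(threshold)) threshold <- 0.02 * stats::median(abs(vk))
  step <- wk[2L] - wk[1L]
  nk <- length(wk)
  # signed difference of the two most dissimilar curves; its zero crossings
  # are the candidate isosbestic wavelengths (a sign change is detectable even
  # when the crossing falls between grid points of a steep difference curve,
  # where the sampled spread never dips below the threshold)
  if (ncol(vk) == 2L) {
    dsig <- vk[, 1L] - vk[, 2L]
  } else {
    dmat <- as.matrix(stats::dist(t(vk)))
    ij <- which(dmat == max(dmat), arr.ind = TRUE)[1L, ]
    dsig <- vk[, ij[1L]] - vk[, ij[2L]]
  }
  refine <- function(i) {
    # local quadratic in t = (lambda - wk[i]) / step through i-1, i, i+1
    # (shifted to i, i+1, i+2 at the left edge); root inside the bracket
    j <- if (i == 1L) 2L else if (i >= nk - 1L) nk - 1L else
      if (abs(dsig[i]) <= abs(dsig[i + 1L])) i else i + 1L
    co <- c(dsig[j],
            (dsig[j + 1L] - dsig[j - 1L]) / 2,
            (dsig[j + 1L] - 2 * dsig[j] + dsig[j - 1L]) / 2)
    disc <- co[2L]^2 - 4 * co[3L] * co[1L]
    t0 <- if (abs(co[3L]) < 1e-12 * max(abs(co), 1e-300)) {
      if (co[2L] != 0) -co[1L] / co[2L] else 0
    } else if (disc >= 0) {
      r <- (-co[2L] + c(-1, 1) * sqrt(disc)) / (2 * co[3L])
      r <- r[abs(r) <= 1.5]
      if (length(r)) r[which.min(abs(r))] else 0
    } else 0
    wk[j] + max(-1.5, min(1.5, t0)) * step
  }
  spread_at <- function(lambda) {
    v <- apply(vk, 2L, function(y) stats::approx(wk, y, xout = lambda)$y)
    if (is_eps && length(spectra) == 2L) abs(v[1L] - v[2L]) else stats::sd(v)
  }
  flank_ok <- function(i) {
    left <- max(1L, i - 5L):i
    right <- (i + 1L):min(nk, i + 6L)
    max(abs(dsig[left])) >= threshold && max(abs(dsig[right])) >= threshold
  }
  pos <- numeric(0); res <- numeric(0)
  for (i in seq_len(nk - 1L)) {
    crossing <- (dsig[i] * dsig[i + 1L] < 0) ||
      (dsig[i] == 0 && (i == 1L || dsig[i - 1L] * dsig[i + 1L] < 0 ||
                          (i > 1L && dsig[i - 1L] != 0 && dsig[i + 1L] == 0)))
    if (!crossing || !flank_ok(i)) next
    lam <- refine(i)
    lam <- max(wk[1L], min(wk[nk], lam))
    sp <- spread_at(lam)
    if (is.finite(sp) && sp < threshold) {
      pos <- c(pos, lam); res <- c(res, sp)
    }
  }
  if (length(pos) > 1L) {
    keep <- !duplicated(round(pos / (0.25 * step)))
    pos <- pos[keep]; res <- res[keep]
  }
  o <- order(pos)
  structure(list(wavelengths_iso = pos[o], residual_spread = res[o],
                 method_window = c(wk[1L], wk[length(wk)]),
                 threshold = threshold),
            class = "isosbestic_result")
}

#' @export
print.isosbestic_result <- function(x, ...) {
  if (length(x$wavelengths_iso) == 0L) {
    cat("<isosbestic_result> no crossing found in",
        sprintf("[%g, %g] nm\n", x$method_window[1], x$method_window[2]))
  } else {
    cat("<isosbestic_result>",
        paste(sprintf("%.1f nm (spread %.2g)", x$wavelengths_iso,
                      x$residual_spread), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Normalize a series of spectra at an isosbestic point
#'
#' Scales every spectrum so that its absorbance at `lambda_iso` equals a
#' common reference value. Because the true absorbance at an isosbestic point
#' depends only on the total concentration, this removes per-well
#' concentration (pipetting/dilution) error from a titration or reaction
#' series.
#'
#' @param series list of [spectrum()] objects on one grid
#' @param lambda_iso isosbestic wavelength (nm); interpolated if off-grid
#' @param reference `"mean"` (default), `"first"`, or an explicit absorbance
#'   value to pin the series to
#' @return the series with each spectrum rescaled; each spectrum's metadata
#'   gains the applied `norm_scale`
#' @export
isosbestic_normalize <- function(series, lambda_iso, reference = "mean") {
  stopifnot(length(series) >= 1L)
  A_iso <- vapply(series, function(s)
    interp_at(s$wavelengths, s$absorbance, lambda_iso), numeric(1))
  bad <- which(A_iso <= 0)
  if (length(bad)) {
    lab <- series[[bad[1L]]]$meta$label %||% paste("sample", bad[1L])
    stop_domain("non-positive absorbance at the isosbestic point for ", lab)
  }
  ref_val <- if (is.numeric(reference)) {
    reference
  } else if (identical(reference, "mean")) {
    mean(A_iso)
  } else if (identical(reference, "first")) {
    A_iso[1L]
  } else stop_domain("reference must be 'mean', 'first' or a number")
  lapply(seq_along(series), function(i) {
    s <- series[[i]]
    sc <- ref_val / A_iso[i]
    s$absorbance <- s$absorbance * sc
    s$meta$norm_scale <- sc
    s
  })
}

#' Transfer an absolute extinction calibration through an isosbestic point
#'
#' When a compound cannot be weighed in accurately (e.g. a nucleoside only
#' available in small purified amounts), its extinction coefficients can be
#' anchored to those of a well-characterized partner species through a shared
#' isosbestic point of their interconversion: after normalizing both spectra
#' at `lambda_iso`, the target spectrum is scaled by
#' eps_ref(lambda_iso) / A_ref(lambda_iso).
#'
#' @param eps_ref calibrated [extinction_spectrum()] of the reference species
#' @param spec_ref measured [spectrum()] of the reference species
#' @param spec_target measured [spectrum()] of the target species
#' @param lambda_iso isosbestic wavelength (nm) shared by the two species
#' @param species,protonation_state labels for the returned extinction curve
#' @return the target's [extinction_spectrum()] on an absolute scale
#' @export
transfer_calibration <- function(eps_ref, spec_ref, spec_target, lambda_iso,
                                 species = "", protonation_state = "apparent-at-pH") {
  stopifnot(inherits(eps_ref, "extinction_spectrum"),
            inherits(spec_ref, "spectrum"), inherits(spec_target, "spectrum"))
  if (!same_grid(spec_ref, spec_target))
    stop_domain("reference and target spectra are on incompatible grids")
  norm <- isosbestic_normalize(list(spec_ref, spec_target), lambda_iso,
                               reference = "first")
  A_ref_iso <- interp_at(norm[[1L]]$wavelengths, norm[[1L]]$absorbance, lambda_iso)
  eps_iso <- interp_at(eps_ref$wavelengths, eps_ref$epsilon, lambda_iso)
  factor <- eps_iso / A_ref_iso
  eps_t <- norm[[2L]]$absorbance * factor
  n_clip <- sum(eps_t < 0)
  eps_t[eps_t < 0] <- 0
  extinction_spectrum(spec_target$wavelengths, eps_t, species, protonation_state,
                      meta = list(lambda_iso = lambda_iso, scale_factor = factor,
                                  n_clipped = n_clip))
}
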