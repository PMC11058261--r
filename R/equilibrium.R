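#' Reaction conditions for a glycosylation / phosphorolysis run
#'
#' Initial totals for the reversible reaction X + Rib1P <-> N7X + Pi
#' (glycosylation direction), plus enzyme loading and optics. All
#' concentrations are totals over protonation states, in uM.
#'
#' @param X0 initial nucleobase (xanthine) concentration, uM
#' @param R0 initial ribose 1-phosphate concentration, uM
#' @param N0 initial nucleoside (N7X) concentration, uM
#' @param P0 initial phosphate concentration, uM
#' @param enzyme_gL enzyme mass concentration, g L^-1
#' @param enzyme_uM enzyme molar concentration, uM (per subunit)
#' @param pH,temperature solution pH and temperature (deg C)
#' @param path_length optical path length in cm (default 0.56, a 200 uL fill
#'   of a 96-well UV plate)
#' @return an object of class `"reaction_conditions"`
#' @export
reaction_conditions <- function(X0, R0, N0 = 0, P0 = 0, enzyme_gL = NA_real_,
                                enzyme_uM = NA_real_, pH = NA_real_,
                                temperature = NA_real_, path_length = 0.56) {
  conc <- c(X0 = X0, R0 = R0, N0 = N0, P0 = P0)
  if (any(conc < 0)) stop_domain("concentrations must be non-negative")
  if (X0 + N0 <= 0) stop_domain("X0 + N0 must be positive")
  structure(list(X0 = X0, R0 = R0, N0 = N0, P0 = P0, enzyme_gL = enzyme_gL,
                 enzyme_uM = enzyme_uM, pH = pH, temperature = temperature,
                 path_length = path_length),
            class = "reaction_conditions")
}

#' Two-wavelength monitoring configuration
#'
#' Wavelengths and difference extinction for continuous UV monitoring of the
#' glycosylation of xanthine: the analysis wavelength sits near the maximum
#' positive extinction difference between product and substrate
#' (300 nm, delta-eps = 3.6 mM^-1 cm^-1 at pH 10) and the control wavelength
#' at the isosbestic point of the transformation (288 nm at pH 10), where any
#' change flags drift or a side reaction.
#'
#' @param lambda_analysis analysis wavelength, nm
#' @param lambda_control control (isosbestic) wavelength, nm
#' @param delta_eps_analysis extinction difference product - substrate at the
#'   analysis wavelength, mM^-1 cm^-1 (non-zero)
#' @param drift_tolerance maximum tolerated excursion at the control
#'   wavelength, AU
#' @return an object of class `"monitoring_config"`
#' @export
monitoring_config <- function(lambda_analysis = 300, lambda_control = 288,
                              delta_eps_analysis = 3.6, drift_tolerance = 0.01) {
  if (delta_eps_analysis == 0) stop_domain("delta_eps_analysis must be non-zero")
  structure(list(lambda_analysis = lambda_analysis,
                 lambda_control = lambda_control,
                 delta_eps_analysis = delta_eps_analysis,
                 drift_tolerance = drift_tolerance),
            class = "monitoring_config")
}

#' Two-wavelength absorbance time course
#'
#' @param times time points in s, strictly increasing
#' @param A_analysis absorbance at the analysis wavelength, AU
#' @param A_control absorbance at the control (isosbestic) wavelength, AU
#' @param conditions a [reaction_conditions()] object
#' @return an object of class `"timecourse"`
#' @export
timecourse <- function(times, A_analysis, A_control, conditions) {
  stopifnot(inherits(conditions, "reaction_conditions"))
  if (length(times) != length(A_analysis) || length(times) != length(A_control))
    stop_domain("times and absorbance traces differ in length")
  if (any(diff(times) <= 0)) stop_domain("times must be strictly increasing")
  structure(list(times = as.numeric(times), A_analysis = as.numeric(A_analysis),
                 A_control = as.numeric(A_control), conditions = conditions),
            class = "timecourse")
}

#' Convert an absorbance time course to a conversion trace
#'
#' The fraction of X converted at time t follows from the Beer-Lambert law on
#' the extinction difference:
#' chi(t) = (A(t) - A(t0)) / (delta_eps * (X0/1000) * l).
#' chi is soft-clipped to \[-0.02, 1.02\] (values outside raise a calibration
#' warning) and the run is drift-flagged when the control-wavelength trace
#' moves by more than the configured tolerance.
#'
#' @param tc a [timecourse()]
#' @param cfg a [monitoring_config()]
#' @return an object of class `"conversion_course"`: `times`, `chi`,
#'   `drift_flag`, `chi_eq` (NA until [detect_equilibrium()]), `conditions`
#' @export
absorbance_to_conversion <- function(tc, cfg = monitoring_config()) {
  stopifnot(inherits(tc, "timecourse"))
  cond <- tc$conditions
  if (cond$X0 <= 0) stop_domain("X0 must be positive for conversion analysis")
  denom <- absorbance_from(cfg$delta_eps_analysis, cond$X0, cond$path_length)
  if (abs(denom) < 1e-9)
    stop_domain("degenerate signal: delta_eps * X0 * l below numeric floor")
  chi <- (tc$A_analysis - tc$A_analysis[1L]) / denom
  if (any(chi < -0.02 | chi > 1.02))
    warning("conversions outside [-0.02, 1.02] were clipped; check calibration",
            call. = FALSE)
  chi <- pmin(pmax(chi, -0.02), 1.02)
  drift <- max(abs(tc$A_control - tc$A_control[1L])) > cfg$drift_tolerance
  structure(list(times = tc$times, chi = chi, drift_flag = drift,
                 chi_eq = NA_real_, conditions = cond),
            class = "conversion_course")
}

# Minimal conversion course holding only an equilibrium endpoint, as produced
# by endpoint-level simulation.
equilibrium_run <- function(chi_eq, conditions) {
  structure(list(times = c(0, 1), chi = c(chi_eq, chi_eq), drift_flag = FALSE,
                 chi_eq = chi_eq, conditions = conditions),
            class = "conversion_course")
}

#' Detect an equilibrium plateau in a conversion trace
#'
#' The course is considered equilibrated when the mean conversion over the
#' final window differs from the mean over the preceding window by less than
#' `rel_tol` relative to the plateau level (windowed means are used rather
#' than endpoint differences so measurement noise does not veto a true
#' plateau). Returns the plateau value, or `NA` when the criterion is not met
#' -- a non-equilibrated run is data, not an error.
#'
#' @param cc a `"conversion_course"`
#' @param window_s plateau window length in s (default 1800, i.e. 30 min)
#' @param rel_tol maximum relative change between consecutive windows
#'   (default 0.005)
#' @param abs_tol absolute change floor (conversion units, default 0.005), so
#'   that low-conversion plateaus are not vetoed by measurement noise alone
#' @return equilibrium conversion `chi_eq`, or `NA_real_`
#' @export
detect_equilibrium <- function(cc, window_s = 1800, rel_tol = 0.005,
                               abs_tol = 0.005) {
  stopifnot(inherits(cc, "conversion_course"))
  t_end <- cc$times[length(cc$times)]
  if (t_end - cc$times[1L] < 2 * window_s)
    stop_domain("course must span at least twice the plateau window")
  last <- cc$times > t_end - window_s
  prev <- cc$times > t_end - 2 * window_s & !last
  m_last <- mean(cc$chi[last]); m_prev <- mean(cc$chi[prev])
  tol <- max(rel_tol * abs(m_last), abs_tol)
  if (abs(m_last - m_prev) < tol) m_last else NA_real_
}

#' Equilibrium extent of the glycosylation from a known constant
#'
#' Solves the mass-balance equilibrium of X + Rib1P <-> N7X + Pi for the
#' extent x of glycosylation, with K stated in the phosphorolysis convention:
#' K * (N0 + x) * (P0 + x) = (X0 - x) * (R0 - x). The physically admissible
#' root (x within \[-min(N0, P0), min(X0, R0)\]) of the quadratic is selected;
#' the returned value is the equilibrium conversion chi_eq = x / X0.
#'
#' @param K phosphorolysis equilibrium constant (> 0)
#' @param cond a [reaction_conditions()]
#' @return equilibrium conversion of X, chi_eq
#' @export
solve_equilibrium <- function(K, cond) {
  stopifnot(inherits(cond, "reaction_conditions"))
  if (!is.numeric(K) || K <= 0) stop_domain("K must be positive")
  X0 <- cond$X0; R0 <- cond$R0; N0 <- cond$N0; P0 <- cond$P0
  # (1 - K) x^2 - [X0 + R0 + K (N0 + P0)] x + (X0 R0 - K N0 P0) = 0
  a <- 1 - K
  b <- -(X0 + R0 + K * (N0 + P0))
  c0 <- X0 * R0 - K * N0 * P0
  lo <- -min(N0, P0); hi <- min(X0, R0)
  roots <- if (abs(a) < 1e-12) {
    if (b == 0) stop_domain("infeasible equilibrium inputs") else -c0 / b
  } else {
    disc <- b^2 - 4 * a * c0
    if (disc < 0) stop_domain("infeasible equilibrium inputs (no real root)")
    q <- -0.5 * (b + sign(b) * sqrt(disc))
    unique(c(q / a, if (q != 0) c0 / q else -b / a))
  }
  tol <- 1e-9 * max(1, X0, R0, N0, P0)
  adm <- roots[roots >= lo - tol & roots <= hi + tol]
  if (length(adm) == 0L) stop_domain("infeasible equilibrium inputs (no admissible root)")
  if (length(adm) > 1L && diff(range(adm)) > tol) {
    warning("two admissible roots; choosing the smaller extent", call. = FALSE)
    adm <- min(adm)
  }
  x <- min(max(adm[1L], lo), hi)
  x / X0
}

#' Apparent equilibrium constant from a single equilibrated run
#'
#' Inverts the mass-balance relation of [solve_equilibrium()]: with
#' x = chi_eq * X0, K = (X0 - x)(R0 - x) / ((N0 + x)(P0 + x)), in the
#' phosphorolysis convention.
#'
#' @param chi_eq equilibrium conversion, strictly between 0 and 1
#' @param cond a [reaction_conditions()]
#' @return apparent phosphorolysis equilibrium constant K
#' @export
equilibrium_constant_single <- function(chi_eq, cond) {
  stopifnot(inherits(cond, "reaction_conditions"))
  if (!is.finite(chi_eq) || chi_eq <= 0 || chi_eq >= 1)
    stop_domain("chi_eq must lie strictly between 0 and 1")
  x <- chi_eq * cond$X0
  num <- (cond$X0 - x) * (cond$R0 - x)
  den <- (cond$N0 + x) * (cond$P0 + x)
  if (den <= 0) stop_domain("degenerate denominator: (N0+x)(P0+x) must be positive")
  num / den
}

#' Global equilibrium-constant fit over multiple runs
#'
#' Least-squares estimate of the apparent phosphorolysis constant K from the
#' equilibrium conversions of several runs at different substrate ratios:
#' minimizes sum over runs of (chi_eq_obs - chi_eq_pred(K))^2 by bounded 1-D
#' optimization on log K; the 95% CI is a likelihood-ratio profile over log K.
#' Runs without a detected plateau (`chi_eq` NA) are dropped; drift-flagged
#' runs are dropped with a warning, and the fit refuses to run if all runs are
#' drift-flagged.
#'
#' @param runs list of `"conversion_course"` objects with `chi_eq` set (see
#'   [detect_equilibrium()])
#' @param K_bounds search bounds for K (default `c(1e-6, 1e6)`)
#' @return an object of class `"equilibrium_fit"`: `K`, `ci95`, `per_run`
#'   table, `residual_rms`, `n_runs`
#' @export
fit_K_global <- function(runs, K_bounds = c(1e-6, 1e6)) {
  stopifnot(length(runs) >= 1L)
  drifted <- vapply(runs, function(r) isTRUE(r$drift_flag), logical(1))
  if (all(drifted))
    stop_domain("all runs are drift-flagged; refusing to fit (data quality)")
  if (any(drifted))
    warning(sum(drifted), " drift-flagged run(s) excluded from the fit",
            call. = FALSE)
  runs <- runs[!drifted]
  has_eq <- vapply(runs, function(r) is.finite(r$chi_eq), logical(1))
  runs <- runs[has_eq]
  if (length(runs) < 2L)
    stop_domain("need at least 2 equilibrated runs with distinct compositions")
  chi_obs <- vapply(runs, function(r) r$chi_eq, numeric(1))
  conds <- lapply(runs, function(r) r$conditions)
  pred <- function(K) vapply(conds, function(cd) solve_equilibrium(K, cd), numeric(1))
  rss <- function(logK) sum((chi_obs - pred(exp(logK)))^2)
  lb <- log(K_bounds[1L]); ub <- log(K_bounds[2L])
  opt <- stats::optimize(rss, c(lb, ub), tol = 1e-10)
  K_hat <- exp(opt$minimum)
  rss_min <- opt$objective
  n <- length(runs)
  ci95 <- if (rss_min < 1e-16) {
    c(K_hat, K_hat)
  } else {
    thr <- rss_min * exp(stats::qchisq(0.95, 1) / n)
    g <- function(l) rss(l) - thr
    lo_ci <- if (g(lb) < 0) 0 else
      exp(stats::uniroot(g, c(lb, opt$minimum), tol = 1e-8)$root)
    hi_ci <- if (g(ub) < 0) Inf else
      exp(stats::uniroot(g, c(opt$minimum, ub), tol = 1e-8)$root)
    c(lo_ci, hi_ci)
  }
  chi_pred <- pred(K_hat)
  per_run <- data.frame(
    X0 = vapply(conds, `[[`, numeric(1), "X0"),
    R0 = vapply(conds, `[[`, numeric(1), "R0"),
    N0 = vapply(conds, `[[`, numeric(1), "N0"),
    P0 = vapply(conds, `[[`, numeric(1), "P0"),
    chi_eq = chi_obs, chi_pred = chi_pred, residual = chi_obs - chi_pred)
  structure(list(K = K_hat, ci95 = ci95, per_run = per_run,
                 residual_rms = sqrt(rss_min / n), n_runs = n),
            class = "equilibrium_fit")
}

#' @export
print.equilibrium_fit <- function(x, ...) {
  cat(sprintf("<equilibrium_fit> K(phosphorolysis) = %.4g (95%% CI %.3g-%.3g), %d runs, rms %.3g\n",
              x$K, x$ci95[1], x$ci95[2], x$n_runs, x$residual_rms))
  cat(sprintf("  glycosylation-direction constant 1/K = %.4g (reporting only)\n",
              1 / x$K))
  invisible(x)
}

#' Convert an enzyme mass concentration to molar concentration
#'
#' @param mass_conc mass concentration, g L^-1
#' @param molar_mass molar mass, kDa (per subunit)
#' @return molar concentration in uM
#' @export
mass_conc_to_molar <- function(mass_conc, molar_mass) {
  if (mass_conc <= 0 || molar_mass <= 0)
    stop_domain("mass concentration and molar mass must be positive")
  1000 * mass_conc / molar_mass
}
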