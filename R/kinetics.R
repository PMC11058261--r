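#' Initial rate from an absorbance time course
#'
#' Approximates the early, linear part of a progress curve by ordinary least
#' squares on the analysis-wavelength trace and converts the slope to a rate:
#' v0 = slope * 1000 / (delta_eps * l) in uM s^-1, and the observed rate
#' constant kobs = v0 / \[E\] per enzyme subunit. A curvature check refits
#' with a quadratic term and flags the window as nonlinear when that improves
#' the residual sum of squares by more than 20%.
#'
#' @param tc a [timecourse()]
#' @param cfg a [monitoring_config()]
#' @param window_s `c(start, end)` fit window in s; default the first 20% of
#'   the trace or the first 300 s, whichever is shorter
#' @param enzyme_uM enzyme molar concentration in uM; defaults to the value in
#'   the conditions, or is derived from `enzyme_gL` via [mass_conc_to_molar()]
#'   with `subunit_kDa`
#' @param subunit_kDa enzyme subunit molar mass used for the mass-to-molar
#'   conversion (default 26)
#' @return an object of class `"rate_result"`: `substrate_conc` (uM), `v0`
#'   (uM s^-1), `kobs` (s^-1), `fit_window_s`, `slope_se`, `nonlinear` flag
#' @export
initial_rate <- function(tc, cfg = monitoring_config(), window_s = NULL,
                         enzyme_uM = NULL, subunit_kDa = 26) {
  stopifnot(inherits(tc, "timecourse"))
  cond <- tc$conditions
  span <- tc$times[length(tc$times)] - tc$times[1L]
  if (is.null(window_s))
    window_s <- tc$times[1L] + c(0, min(300, 0.2 * span))
  idx <- tc$times >= window_s[1L] & tc$times <= window_s[2L]
  if (sum(idx) < 5L) stop_domain("fit window must contain at least 5 points")
  t <- tc$times[idx]; A <- tc$A_analysis[idx]
  fit <- stats::lm(A ~ t)
  slope <- unname(stats::coef(fit)[2L])
  rss_lin <- sum(stats::residuals(fit)^2)
  slope_se <- sqrt(rss_lin / (length(t) - 2L) / sum((t - mean(t))^2))
  fit_q <- stats::lm(A ~ t + I(t^2))
  rss_q <- sum(stats::residuals(fit_q)^2)
  # the curvature check is meaningless once residuals sit at machine noise
  rss_floor <- (1e-10 * (max(abs(A)) + 1))^2 * length(t)
  nonlinear <- rss_lin > rss_floor && (rss_lin - rss_q) / rss_lin > 0.2
  if (nonlinear)
    warning("fit window shows curvature (quadratic term improves RSS > 20%)",
            call. = FALSE)
  v0 <- slope * 1000 / (cfg$delta_eps_analysis * cond$path_length)
  E <- enzyme_uM %||%
    (if (is.finite(cond$enzyme_uM)) cond$enzyme_uM
     else if (is.finite(cond$enzyme_gL))
       mass_conc_to_molar(cond$enzyme_gL, subunit_kDa)
     else NA_real_)
  kobs <- v0 / E
  structure(list(substrate_conc = cond$X0, v0 = v0, kobs = kobs,
                 fit_window_s = window_s,
                 slope_se = slope_se * 1000 / (cfg$delta_eps_analysis * cond$path_length),
                 enzyme_uM = E, nonlinear = nonlinear),
            class = "rate_result")
}

#' @export
as.data.frame.rate_result <- function(x, ...) {
  data.frame(S = x$substrate_conc, v0 = x$v0, kobs = x$kobs,
             slope_se = x$slope_se, nonlinear = x$nonlinear)
}

# Variable-projection Michaelis-Menten fit: for fixed KM the optimal kcat is
# a linear solve, so the problem reduces to a bounded 1-D profile over log KM.
fit_mm_profile <- function(df, KM_bounds = c(1e-3, 1e8)) {
  rss_at <- function(logKM) {
    u <- df$S / (exp(logKM) + df$S)
    kcat <- sum(u * df$kobs) / sum(u^2)
    sum((df$kobs - kcat * u)^2)
  }
  opt <- stats::optimize(rss_at, log(KM_bounds), tol = 1e-10)
  KM <- exp(opt$minimum)
  u <- df$S / (KM + df$S)
  kcat <- sum(u * df$kobs) / sum(u^2)
  n <- nrow(df)
  sigma2 <- opt$objective / max(n - 3L, 1L)
  J <- cbind(u, -kcat * df$S / (KM + df$S)^2)
  se_KM <- tryCatch(sqrt((solve(crossprod(J)) * sigma2)[2L, 2L]),
                    error = function(e) NA_real_)
  list(kcat = kcat, KM = KM, rss = opt$objective, se_KM = se_KM)
}

# Small-sample corrected Akaike information criterion for a least-squares fit;
# k counts the mean-function parameters plus the residual variance.
aicc_ls <- function(rss, n, k, correct = TRUE) {
  aic <- n * log(rss / n) + 2 * k
  if (correct) aic <- aic + 2 * k * (k + 1) / (n - k - 1)
  aic
}

#' Michaelis-Menten fit with AIC model discrimination
#'
#' Fits the observed rate constants to both a Michaelis-Menten hyperbola,
#' kobs = kcat * S / (KM + S), and a proportional (first-order) model
#' kobs = a * S, and prefers the model with the lower small-sample corrected
#' Akaike criterion (AICc; parameter counts k = 3 and k = 2, counting the
#' residual variance). Replicates are fitted pooled so the criterion sees the
#' true number of observations. When the fitted KM exceeds the largest assayed
#' substrate concentration more than twofold the KM confidence interval is
#' reported one-sided ("exceeds range") -- the hallmark of a substrate whose
#' KM lies beyond its solubility limit.
#'
#' @param rates a list of `"rate_result"` objects, or a data.frame with
#'   columns `S` (uM) and `kobs` (s^-1)
#' @param aic `"aicc"` (default) or `"aic"` for the uncorrected criterion
#' @return an object of class `"michaelis_menten_fit"`: `kcat`, `KM`,
#'   `ci95_KM`, `KM_exceeds_range`, `a_linear`, `aic_mm`, `aic_linear`,
#'   `preferred`, `data`, `diagnostic`
#' @export
fit_michaelis_menten <- function(rates, aic = c("aicc", "aic")) {
  aic <- match.arg(aic)
  correct <- aic == "aicc"
  df <- if (is.data.frame(rates)) rates else
    do.call(rbind, lapply(rates, as.data.frame))
  stopifnot(all(c("S", "kobs") %in% names(df)))
  df <- df[is.finite(df$S) & is.finite(df$kobs), , drop = FALSE]
  if (length(unique(df$S)) < 4L)
    stop_domain("at least 4 distinct substrate concentrations are required")
  n <- nrow(df)
  # proportional model through the origin
  a_hat <- sum(df$S * df$kobs) / sum(df$S^2)
  rss_lin <- sum((df$kobs - a_hat * df$S)^2)
  aic_linear <- aicc_ls(rss_lin, n, 2L, correct)
  diagnostic <- NULL
  mm <- tryCatch({
    start <- list(kcat = max(df$kobs) * 1.2,
                  KM = stats::median(df$S))
    minpack.lm::nlsLM(kobs ~ kcat * S / (KM + S), data = df, start = start,
                      lower = c(kcat = 1e-12, KM = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) e)
  if (inherits(mm, "error")) {
    # nls-type fitters lose rank when KM runs far beyond the assayed range
    # (both gradient columns become proportional to S); the variable-projection
    # profile below handles that degenerate limit without a gradient.
    diagnostic <- paste("gradient-based fit degenerate (",
                        conditionMessage(mm), "); used profile fit")
    prof <- fit_mm_profile(df)
    kcat_hat <- prof$kcat; KM <- prof$KM; rss_mm <- prof$rss
    se_KM <- prof$se_KM
  } else {
    cf <- stats::coef(mm)
    kcat_hat <- unname(cf["kcat"]); KM <- unname(cf["KM"])
    rss_mm <- sum(stats::residuals(mm)^2)
    se_KM <- tryCatch(unname(sqrt(diag(stats::vcov(mm)))["KM"]),
                      error = function(e) NA_real_)
  }
  aic_mm <- aicc_ls(rss_mm, n, 3L, correct)
  preferred <- if (aic_mm < aic_linear) "MM" else "linear"
  exceeds <- KM > 2 * max(df$S)
  ci95_KM <- if (exceeds) {
    c(max(df$S), Inf)
  } else {
    KM + c(-1, 1) * stats::qt(0.975, n - 3L) * se_KM
  }
  structure(list(kcat = kcat_hat, KM = KM, ci95_KM = ci95_KM,
                 KM_exceeds_range = exceeds, a_linear = a_hat,
                 aic_mm = aic_mm, aic_linear = aic_linear,
                 preferred = preferred, data = df, aic_variant = aic,
                 diagnostic = diagnostic),
            class = "michaelis_menten_fit")
}

#' @export
print.michaelis_menten_fit <- function(x, ...) {
  cat("<michaelis_menten_fit> preferred model:", x$preferred,
      sprintf("(%s MM %.2f vs linear %.2f)\n", toupper(x$aic_variant),
              x$aic_mm, x$aic_linear))
  if (is.finite(x$kcat)) {
    cat(sprintf("  kcat = %.4g s^-1, KM = %.4g uM", x$kcat, x$KM))
    if (isTRUE(x$KM_exceeds_range)) cat(" (exceeds assayed range)")
    cat(sprintf(", 95%% CI KM %.3g-%.3g uM\n", x$ci95_KM[1], x$ci95_KM[2]))
  }
  invisible(x)
}
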