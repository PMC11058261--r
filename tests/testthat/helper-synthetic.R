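# Shared builders for synthetic test inputs.

grid_nm <- 250:350

preset_pair <- function(name) {
  p <- extinction_preset(name)
  gen_extinction_pair(p$peaks_HA, p$peaks_A, species = p$species)
}

# Two positive straight-line extinction curves crossing at exactly 280 nm.
line_pair_280 <- function() {
  e1 <- extinction_spectrum(grid_nm, 1.0 + 0.02 * (grid_nm - 250), "up")
  e2 <- extinction_spectrum(grid_nm, 2.2 - 0.02 * (grid_nm - 250), "down")
  list(e1 = e1, e2 = e2)
}

# Brute-force equilibrium oracle: minimize the mass-action imbalance over a
# dense extent grid, independent of the quadratic solver.
brute_force_chi <- function(K, cond, n_grid = 1e5) {
  lo <- -min(cond$N0, cond$P0)
  hi <- min(cond$X0, cond$R0)
  x <- seq(lo, hi, length.out = n_grid)
  imb <- abs(K * (cond$N0 + x) * (cond$P0 + x) -
               (cond$X0 - x) * (cond$R0 - x))
  x[which.min(imb)] / cond$X0
}

gaussian_curve <- function(grid, center, width, height) {
  height * exp(-(grid - center)^2 / (2 * width^2))
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
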