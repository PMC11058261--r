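# Parameter-recovery studies: repeated simulate -> analyze cycles under the
# reference plate-reader noise model. These define the package's reference
# protocols for validating the pKa and equilibrium-constant pipelines.

#' pKa recovery study
#'
#' Repeatedly simulates a pH 2-12 titration (0.5 steps, 100 uM nominal, 5%
#' concentration jitter, 0.002 AU absorbance noise by default) at a known
#' generating pKa, runs the isosbestic-normalized two-state fit, and collects
#' the estimates. Normalization uses the generating pair's known crossing
#' wavelength -- the experimental situation, where the isosbestic point of
#' deprotonation is established on reference material before titration wells
#' with independent pipetting error are analyzed.
#'
#' @param pKa generating pKa
#' @param n_rep number of simulated titrations
#' @param preset [extinction_preset()] name; defaults to the species preset
#'   matching the pKa regime (`n7x_titration` for pKa of 8 and above,
#'   `xanthine_titration` for 6.5 and above, `n9x_titration` below)
#' @param noise a [noise_model()]
#' @param seed base seed; replicate r uses `seed + r`
#' @return `data.frame(replicate, pKa_hat, error)`
#' @export
pka_recovery <- function(pKa, n_rep = 100, preset = NULL,
                         noise = noise_model(), seed = 1L) {
  preset <- preset %||% if (pKa >= 8) "n7x_titration" else
    if (pKa >= 6.5) "xanthine_titration" else "n9x_titration"
  pre <- extinction_preset(preset)
  pair <- gen_extinction_pair(pre$peaks_HA, pre$peaks_A, species = pre$species)
  lambda_iso <- pair$isosbestic$wavelengths_iso[
    which.min(pair$isosbestic$residual_spread)]
  est <- vapply(seq_len(n_rep), function(r) {
    series <- gen_titration(pair$HA, pair$A, pKa, noise = noise,
                            seed = seed + r)
    fit_pka(series, lambda_iso = lambda_iso)$pKa
  }, numeric(1))
  data.frame(replicate = seq_len(n_rep), pKa_hat = est, error = est - pKa)
}

#' Equilibrium-constant recovery study
#'
#' Repeatedly simulates noisy equilibrium endpoints of the reference
#' substrate-titration design (X0 in {100, 150} uM crossed with Rib1P levels,
#' absorbance noise mapped through the 300 nm extinction difference) at a
#' known generating constant and re-estimates K by the global least-squares
#' fit.
#'
#' @param K generating phosphorolysis equilibrium constant
#' @param n_rep number of replicate designs
#' @param X0,R0 design concentrations (uM)
#' @param noise a [noise_model()]
#' @param seed base seed; replicate r uses `seed + r`
#' @return `data.frame(replicate, K_hat, rel_error)`
#' @export
keq_recovery <- function(K = 0.5, n_rep = 100, X0 = c(100, 150),
                         R0 = c(25, 50, 100, 200, 500),
                         noise = noise_model(), seed = 1L) {
  est <- vapply(seq_len(n_rep), function(r) {
    runs <- gen_equilibrium_endpoints(K, X0 = X0, R0 = R0, noise = noise,
                                      seed = seed + r)
    fit_K_global(runs)$K
  }, numeric(1))
  data.frame(replicate = seq_len(n_rep), K_hat = est,
             rel_error = (est - K) / K)
}
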