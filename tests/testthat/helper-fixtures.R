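# Shared fixtures: the characterization study conditions used across tests.
# FP endpoints and noise scale follow the synthetic-data conventions: free
# dye ~50 mP, covalent adduct ~250 mP, measurement noise 2% of the dynamic
# range unless a test states otherwise.

study <- list(
  a0 = 0.5e-9,             # substrate (dye), M
  b0 = 2.5e-9,             # protein fragment, M
  k_max = 1e5,             # rate at saturating peptide, 1/M/s
  fp_free = 50, fp_bound = 250,
  fp_sd_2pct = 0.02 * 200, # 2% of the FP dynamic range, mP
  ec50_delta3 = 1.654e-9,  # high-affinity variant, M
  ec50_delta2 = 8.217e-9,
  ec50_delta1 = 47.65e-9,
  ec50_pep11 = 25.4e-9,
  kd_fp = 6.5e-9,          # saturation-titration K_d, M
  kd_bli = 4.3e-9, koff_bli = 2.14e-4,
  mT = 46.3,               # degC
  fwhm = 84                # nm
)
study$kon_bli <- study$koff_bli / study$kd_bli

# One full synthetic EC50 experiment -> fitted EC50 with Monte Carlo CI.
run_ec50_experiment <- function(ec50, seed, sd = study$fp_sd_2pct,
                                n_mc = 1000) {
  tab <- sim_ec50_dataset(ec50, study$k_max, study$fp_free, study$fp_bound,
                          a0 = study$a0, b0 = study$b0,
                          noise = noise_spec(sd = sd,
                                             seed = child_seed(seed, 0),
                                             replicates = 2))
  ec50_pipeline(tab, n_mc = n_mc, seed = child_seed(seed, 1))
}

# Peak height of the area-parameterized Gaussian (for intensity-noise scales).
gauss_peak_height <- function(fwhm, area) {
  omega <- fwhm / sqrt(2 * log(2))
  area / (omega * sqrt(pi / 2))
}
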