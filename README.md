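# halokin

Quantitative analysis of split-protein complementation labeling assays.

Split-tag systems of the split-HaloTag kind pair a short peptide tag (Hpep,
14 residues) with a large, inactive protein fragment (cpHaloΔ). The peptide
binds the fragment spontaneously and reconstitutes a tag that reacts
covalently with chloroalkane-dye substrates, so the interaction is read out
through the *labeling reaction itself* — and characterizing such a system
means extracting a family of constants from a family of assays. halokin
implements that whole analysis chain for R users (protein engineers and
chemical biologists running plate-reader, biosensor, nanoDSF, microscopy and
NGS experiments):

* **Labeling kinetics** — fluorescence polarization (FP) time courses fitted
  with the irreversible bimolecular model

  $$FP(t) = FP_{bound} + (FP_{free}-FP_{bound})\,
  \frac{([A]_0-[B]_0)\,e^{([A]_0-[B]_0)k_{app}t}}
       {[A]_0 e^{([A]_0-[B]_0)k_{app}t}-[B]_0},$$

  with dead-time handling, an equal-concentration limit form, a linear
  fallback for non-plateauing conditions, initial slopes
  $s_{t=0}=k_{app}[B]_0(FP_{bound}-FP_{free})$, and a pseudo-first-order
  model for residual background labeling ($t_{1/2} = \ln 2/k_{obs}$).
* **EC50 of complementation** — per-concentration rates fitted against
  peptide concentration with a fixed-Hill-slope-1 dose-response curve
  $Y = Bottom + X\,(Top-Bottom)/(EC_{50}+X)$, with Monte Carlo confidence
  intervals (N = 1000 refits, 5% worst discarded, percentile interval).
* **Binding affinity** — equilibrium $K_d$ from FP saturation titrations
  ($FP = bottom + (top-bottom)\,c/(K_d+c)$) and kinetic
  $k_{on}, k_{off}, K_d = k_{off}/k_{on}$ from bio-layer interferometry via
  baseline alignment, Savitzky–Golay smoothing, and a global 1:1 Langmuir
  fit across analyte concentrations.
* **Assay support** — dye-corrected protein concentrations
  $(A_{280}-A_{max}CF)/\varepsilon \times dilution$ (TMR $CF=0.34$, SiR
  $0.147$), Lambert–Beer substrate quantification, fluorescence turn-on fold
  changes, nanoDSF melting temperatures (derivative-maximum inflection), and
  Gaussian line-profile widths ($FWHM = \omega\sqrt{2\ln 2}$).
* **NNK enrichment** — per-position amino-acid frequencies and
  round-over-round enrichment from saturation-mutagenesis library reads, by
  position-based codon extraction with an identity gate (stop codons kept as
  a 21st symbol).
* **Synthetic data** — generators reproducing each assay's design (dilution
  series, replicate counts, phase timings, scan grids), so every estimator
  is testable by parameter recovery from a single seed.

## Worked example

Simulate a peptide titration at the standard kinetic-assay design (twofold
dilution series 1000–0.98 nM, dye 0.5 nM, fragment 2.5 nM, two technical
replicates, 4 mP noise) with a true EC50 of 1.654 nM, then run the full
kinetics → dose-response pipeline:

```r
library(halokin)

tab <- sim_ec50_dataset(ec50 = 1.654e-9, k_max = 1e5,
                        fp_free = 50, fp_bound = 250,
                        noise = noise_spec(sd = 4, seed = 7, replicates = 2))
fit <- ec50_pipeline(tab, n_mc = 1000, seed = 11)
fit
#> <dose_response_fit (log_sigmoid): EC50=1.639 nM, k_max/Top=1.004e+05, Bottom=0, n=11>
#>   95% Monte Carlo CI: (1.585 - 1.692) nM  [N=1000, 5% worst discarded]
```

Each of the 11 concentrations was fitted with the second-order model
(`fit$kinetics` holds the per-concentration fits), the fitted rates were
aggregated into the EC50 estimate — 1.639 nM against a truth of 1.654 nM,
with the truth inside the 95% Monte Carlo interval — and `k_max` recovered
the saturating rate constant $10^5\ \mathrm{M^{-1}s^{-1}}$ to 0.4%.
Comparing variants the way results are reported:

```r
format_fold(fold_change(47.65e-9, fit$ec50))
#> [1] "29-fold"
```

The same pattern runs for the other assays:

```r
sat <- sim_saturation_binding(6.5e-9, top = 300, bottom = 60,
                              noise = noise_spec(sd = 4.8, seed = 3, replicates = 3))
fit_saturation_kd(sat, n_mc = 1000, seed = 4)
#> <saturation_fit: K_d=5.841 nM, bottom=58.98, top=297.1 mP>
#>   95% CI: (5.357 - 6.41) nM

bli <- sim_bli_sensorgrams(kon = 2.14e-4 / 4.3e-9, koff = 2.14e-4, rmax = 1.2,
                           noise = noise_spec(sd = 0.024, seed = 5))
bli_global_fit(bli_preprocess(bli))
#> <bli_fit 1:1 global: k_on=4.973e+04 1/M/s, k_off=0.0002118 1/s, K_d=4.259 nM, R_max=1.2, sse=3.142, converged=TRUE>

melt <- sim_melt_curve(46.3, noise = noise_spec(sd = 0.0025, seed = 2, replicates = 2))
melting_temperature(melt)
#> <melt_fit: mT=46.35 degC (sd 0.05, N=2)>
```

A thin command-line front end (`inst/cli/halokin`) exposes the same
functionality as subcommands (`simulate`, `fit-kinetics`, `fit-ec50`,
`fit-kd`, `fit-bli`, `melt`, `fwhm`, `enrich`) over tidy CSV, YAML and
FASTA/FASTQ files.

The methods vignette (`vignettes/split-tag-analysis-methods.Rmd`) documents
the models, assumptions, default parameters and numerical choices in detail.

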