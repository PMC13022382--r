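---
title: "Models and methods behind halokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind halokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halokin)
```

halokin analyzes the quantitative assays used to characterize split-protein
complementation labeling systems, of the split-HaloTag kind: a short peptide
tag (Hpep) binds a large, catalytically inactive protein fragment (cpHaloΔ)
and restores its ability to react covalently with a chloroalkane-dye
substrate. The package covers the full chain from raw assay tables to the
derived constants: labeling kinetics, complementation EC~50~, equilibrium and
kinetic binding affinity, thermostability, fluorogenic turn-on, imaging
resolution metrics, and library-enrichment counting. This vignette documents
the models, their assumptions, the tunable parameters, and the numerical
choices — including the choices we had to make where more than one reasonable
design existed.

## Second-order labeling kinetics

A labeling reaction between substrate A (chloroalkane dye, initial
concentration $[A]_0$) and reconstituted protein B ($[B]_0$) is irreversible
and bimolecular, $A + B \xrightarrow{k_{app}} P$. With fluorescence
polarization (FP) as the readout the trace is

$$FP(t) = FP_{bound} + \bigl(FP_{free} - FP_{bound}\bigr)\,\frac{A(t)}{[A]_0},
\qquad
\frac{A(t)}{[A]_0} =
\frac{([A]_0-[B]_0)\,e^{([A]_0-[B]_0)k_{app}t}}
     {[A]_0\,e^{([A]_0-[B]_0)k_{app}t}-[B]_0},$$

with the analytic limit $A(t)/[A]_0 = 1/(1+[A]_0 k_{app} t)$ when
$[A]_0 = [B]_0$. `fp_second_order()` switches to the limit form when the two
concentrations agree within $10^{-6}$ relative (avoiding 0/0) and rearranges
the exponential so its argument is never positive (avoiding overflow at long
times when $[A]_0 > [B]_0$).

Assumptions: the FP signal is linear in the bound fraction, the peptide/
fragment complex is at (quasi-)equilibrium on the labeling timescale so a
single apparent rate describes the trace, and replicates are exchangeable
(they are averaged point-wise before fitting, with the per-time SD kept as a
diagnostic).

`fit_second_order()` estimates $(k_{app}, FP_{free}, FP_{bound})$ by
Levenberg–Marquardt least squares, with $k_{app}$ parameterized as
$\log_{10}k_{app}$ (positivity, scale stabilization) and started from a
coarse log-grid scan over $10^2$–$10^7\,\mathrm{M^{-1}s^{-1}}$. Optimizer
failure is reported through `converged = FALSE`, never silently.

**Dead time.** Plate-reader runs lose the first seconds between substrate
addition and the first read, so the true reaction time is `t + dead_time`.
The dead time is a *fixed, known* offset, not a free parameter — a free
offset is weakly identified against $k_{app}$ at early times. Rather than
hard-wiring one number in two places, the `time_course` object carries its
dead time: generators record the dead time they applied (default 0 s, so the
analytic $t=0$ limits of the model hold exactly for simulated data), fits
default to the recorded value, and the `fit-kinetics` command-line tool
defaults to 30 s, a typical dispensing delay for robotic injection.

**Linear fallback.** Conditions whose reactions do not approach plateau
within the window carry information only about the initial speed.
`choose_model()` predicts the completion at the last time point from the
second-order fit and falls back to a straight-line fit below 20% completion
(inclusive at the boundary: exactly 20% keeps the second-order model). The
threshold is our choice — no published value exists — set where the trace is
still within the near-linear regime so that the reported initial slope is
insensitive to the model used.

**Initial slopes.** The analytic derivative at $t = 0$ is
$s_{t=0} = k_{app}[B]_0 (FP_{bound}-FP_{free})$; at fixed $[B]_0$ and
endpoints it is proportional to $k_{app}$, which is why the dose-response
stage accepts either ordinate (it records which one was used and refuses to
mix them within a dataset).

Residual background labeling of the fragment alone is pseudo-first-order
(protein in vast excess over dye): `fit_background()` fits
$y(t) = y_0 + (plateau-y_0)(1-e^{-k_{obs}t})$ and reports
$t_{1/2} = \ln 2 / k_{obs}$, flagging half-times that are unbounded on the
measurement window ($k_{obs} t_{end} < 0.01$ or negligible amplitude).

## EC50 with Monte Carlo confidence intervals

Per-concentration rates are aggregated with a sigmoidal dose-response model
of fixed Hill slope 1, in either of two algebraically identical forms:

$$k_{app}([\mathrm{Hpep}]) = \frac{k_{max}}{1+10^{\log_{10}EC_{50}-\log_{10}[\mathrm{Hpep}]}}
\quad\Longleftrightarrow\quad
Y = Bottom + X\,\frac{Top-Bottom}{EC_{50}+X}\ (Bottom=0).$$

`fit_ec50()` exploits the conditional linearity of the amplitudes: for a
fixed $EC_{50}$ the best $k_{max}$ (or $Top$/$Bottom$) is a linear
least-squares solve, so the fit reduces to a 1-D profile over
$\log_{10}EC_{50}$, bracketed by a coarse grid spanning the tested
concentration range ±3 decades and polished with golden-section search.
This parameterization keeps $EC_{50} > 0$, makes the fit exactly
scale-equivariant, and — because one profile evaluation costs microseconds —
makes the $N=1000$ Monte Carlo refits cheap. An estimate more than 10× past
either end of the tested range raises a warning flag.

`monte_carlo_ci()` follows the standard curve-fit Monte Carlo recipe:
$N = 1000$ synthetic datasets are drawn around the fitted curve, each refit,
the 5% of refits with the highest SSE are discarded, and the 95% CI is the
2.5/97.5 percentile interval of the surviving $EC_{50}$ estimates. Three
designs were open here and resolved as follows: (i) the noise is *parametric*
Gaussian with scale equal to the fit's residual SD (or the per-point rate SD
when supplied) rather than a residual bootstrap — with ≤ 11 points per
dataset, resampled residuals are too granular; (ii) "worst fits" means
highest refit SSE, the natural fit-quality metric, not most extreme
$EC_{50}$; (iii) the interval is a plain percentile interval. More than 20%
refit failures aborts with an instability error rather than reporting a CI
from a broken ensemble.

`ec50_pipeline()` chains replicate averaging → per-concentration kinetic
fits → ordinate selection ($k_{app}$ when all second-order fits converged,
otherwise initial slopes) → EC~50~ fit → Monte Carlo CI.
`fold_change()`/`format_fold()` reproduce the conventional reporting of
variant improvements ("29-fold", "fivefold").

## Binding affinity

**Equilibrium.** In a saturation titration a fixed ~1 nM fluorescent tracer
is titrated with the fragment in excess, so free ≈ total concentration and
$FP(c) = bottom + (top-bottom)\,c/(K_d+c)$ — the same hyperbola as the
dose-response model with the same profiled fit and, on request, the same
Monte Carlo CI machinery. The tracer-in-excess assumption fails for $K_d$
well below the tracer concentration; a fit flagged `inverted` (top < bottom)
indicates a signal that decreases with binding.

**Kinetics (BLI).** Sensorgrams at several analyte concentrations are
preprocessed (`bli_preprocess()`: subtract the baseline-phase mean —
idempotent — then Savitzky–Golay smoothing; window 11 / order 2 are our
defaults for 5 Hz data, as the filter itself is standard but no settings are
published) and globally fitted with a 1:1 Langmuir model
(`bli_global_fit()`): shared $(k_{on}, k_{off}, R_{max})$,

$$R_{assoc}(t) = R_{eq}\bigl(1-e^{-(k_{on}c+k_{off})t}\bigr),\quad
R_{eq} = \frac{R_{max}c}{K_d+c},\qquad
R_{dissoc}(t) = R_{end}e^{-k_{off}t},$$

$K_d = k_{off}/k_{on}$ by construction, and a per-trace constant offset as
nuisance (absorbing immobilization differences). For fixed rate constants
the model is linear in $R_{max}$ and the offsets, so those are profiled out
and a 2-D Nelder–Mead search (with restarts; started from a log-linear
dissociation regression for $k_{off}$ and a grid scan for $k_{on}$) does the
rest. Mass-transport limitation, ligand depletion and reference-sensor
subtraction are not modeled — standard assumptions for solution-phase
analyte and low surface capacity; a $k_{off}$ ending at its lower bound is
flagged as the slow-dissociator regime rather than trusted.

## Assay-support computations

* `corrected_concentration()`: labeled-protein concentration
  $([A_{280}-A_{max}\cdot CF]/\varepsilon_{protein})\times dilution$, with
  built-in 280 nm correction factors TMR 0.34 and SiR 0.147 (extensible).
* `beer_lambert_concentration()`: $c = A/(\varepsilon \ell)$.
* `turn_on_fold()`: fluorogenic turn-on as the with/without-peptide emission
  ratio; `peak` mode (ratio of spectral maxima, the default, matching how
  emission profiles are usually presented) or `integral` mode (trapezoid
  areas); both agree for shape-preserving changes.
* `melting_temperature()`: the melting temperature is the inflection of the
  nanoDSF 350/330 nm ratio curve, located as the maximum of a
  Savitzky–Golay first derivative (window 9, order 3 — our choice; no
  derivative-estimation method is published) refined by local quadratic
  interpolation, which removes the 1 °C grid quantization. A derivative
  maximum at the scan boundary, or an essentially constant derivative, is
  flagged `no_transition` instead of reporting a number.
* `fit_profile_fwhm()`: microscopy line profiles are fitted with the
  area-parameterized Gaussian
  $y = y_0 + \frac{A}{\omega\sqrt{\pi/2}}e^{-2(x-x_c)^2/\omega^2}$ and the
  width reported as $FWHM = \omega\sqrt{2\ln 2}$. Apparent filament
  diameters are reported per-profile and summarized as mean ± SD over
  profiles (`profile_fwhm_summary()`) rather than from one pooled fit —
  profiles differ in amplitude and background, and per-profile fitting is
  what the SD is meant to describe.

## NNK-library enrichment

Saturation-mutagenesis libraries randomize a handful of codons with NNK
degeneracy (N = A/C/G/T, K = G/T: all 20 amino acids plus the amber stop in
32 codons). Because the sequenced amplicon is a fixed-length window around
the randomized stretch, short-read alignment is unnecessary:
`extract_variable_codons()` accepts reads of exactly the template length
that match ≥ 90% of the non-randomized bases, discards the rest with a
recorded reason (`length`, `identity`, `ambiguous` for N inside a randomized
codon), and `aa_frequencies()` translates the extracted codons (stop
retained as a 21st symbol — NNK permits TAG, and silently dropping it would
bias the remaining frequencies) and divides counts by the number of *usable*
reads; both total and usable counts are reported since "total reads" is
ambiguous as a denominator. `enrichment_ratio()` compares rounds on
frequencies with a pseudo-count ($10^{-4}$ by default) so residues absent in
the reference round give large finite, rather than infinite, ratios; being
frequency-based it is invariant to sequencing depth.

## The synthetic-data generator

The generators in `sim_*()` exist to make every fitting stage testable by
parameter recovery, and they reproduce the *designs* of the characterization
assays, not just their models: the twofold 1000–0.98 nM peptide dilution
series (11 concentrations, two technical replicates, 10 h of FP at 5-min
intervals), fivefold saturation titrations in triplicate, 300–2 nM BLI
concentration series with 60/300/300 s baseline/association/dissociation
phases at 5 Hz, 20–95 °C nanoDSF ramps at 1 °C steps in duplicate, 20 nm
pixel line profiles, and NNK codon sampling. Noise is additive i.i.d.
Gaussian on the observable; since no measurement-noise magnitude is
published for these assays, our working convention is 2% of the signal's
dynamic range (e.g. 4 mP on a 200 mP FP span) — large enough that recovery
tolerances mean something, small enough that the assays remain informative,
and in line with plate-reader replicate scatter. All generators are pure
functions of (parameters, seed); one root seed fans out deterministically to
per-series child seeds (`child_seed()`, a Lehmer step modulo $2^{31}-1$).

What the generators deliberately do not emulate: photobleaching and
evaporation drifts in 10 h FP runs, heteroscedastic detector noise,
BLI mass-transport artifacts and sensor-to-sensor $R_{max}$ variation,
non-Gaussian profile backgrounds, and PCR/sequencing bias beyond a uniform
per-base substitution error. Passing recovery tests therefore demonstrate
correctness of the estimators under the stated stochastic model, not
robustness to every instrument artifact. A full coupled
binding-plus-labeling ODE simulation is likewise out of scope: the analysis
operates at the level of the reduced per-concentration rate model, and the
generator matches that level.

## Verification, problem sizes, and reproducibility

The test suite verifies each stage against independent oracles: closed-form
limits and finite differences for the kinetic model, an ODE integration
(deSolve) for the BLI traces, quadrature for the Gaussian area,
hand-tallied counts and binomial sampling bounds for enrichment, and
double implementations for the isotherms. End-to-end checks rerun the whole
kinetics → EC~50~ pipeline at the study's designs: 100 seeded runs per
ground truth for EC~50~ coverage (the 95% Monte Carlo CI must contain the
truth in ≥ 90 of them), 50 seeds each for $K_d$, BLI, FWHM and melting
recoveries, and 200 datasets for CI-coverage calibration. These sizes hold
the Monte Carlo error of each summary near or below the tolerance it is
compared against while keeping the default suite comfortably desk-scale.
`scripts/acceptance.R` re-derives the headline quantities from scratch from
a single command-line seed.

```{r example, eval = FALSE}
tab <- sim_ec50_dataset(ec50 = 1.654e-9, k_max = 1e5,
                        fp_free = 50, fp_bound = 250,
                        noise = noise_spec(sd = 4, seed = 7, replicates = 2))
fit <- ec50_pipeline(tab, n_mc = 1000, seed = 11)
fit
#> <dose_response_fit (log_sigmoid): EC50=1.639 nM, k_max/Top=1.004e+05, Bottom=0, n=11>
#>   95% Monte Carlo CI: (1.585 - 1.692) nM  [N=1000, 5% worst discarded]
```

## Known limitations

* The EC~50~ and $K_d$ hyperbola fits fix the Hill slope at 1; cooperative
  binding would need a different model.
* Per-curve $FP_{free}$/$FP_{bound}$ are fitted independently across a
  dilution series (matching the per-condition fitting convention); sharing
  endpoints across the series could tighten low-concentration rate
  estimates but is not implemented.
* The BLI model is strictly 1:1; heterogeneous or conformational-change
  binding is out of scope.
* The enrichment counter requires reads pre-trimmed to the template window;
  merging and adapter trimming are upstream of this package.
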