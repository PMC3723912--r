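---
title: "Methods: rhythm quantification, CK1 pharmacology and phospho-site statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm quantification, CK1 pharmacology and phospho-site statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ck1clock)
library(dplyr)
```

`ck1clock` implements the computational side of a standard experimental
programme in circadian cell biology: casein kinase 1 (CK1) activity is
manipulated — by overexpression or by small-molecule inhibitors such as
IC261 and PF-670462 — in a cell line carrying a clock-driven luciferase
reporter (e.g. *CCA1-LUC*), and the consequences are read out at three
levels: free-running period, phase resetting, and the phospho-proteome.
This vignette documents the models, the tunable parameters, and the design
decisions behind each stage.

## Rhythm quantification by harmonic regression

A bioluminescence trace recorded after transfer to constant light is
modelled as a truncated Fourier series with an unknown fundamental period
$T$:

$$x(t) = \mu + \beta t + \sum_{k=1}^{K}\left[a_k \cos\frac{2\pi k t}{T}
       + b_k \sin\frac{2\pi k t}{T}\right] + \varepsilon_t .$$

For fixed $T$ the model is linear, so `fit_harmonics()` solves it by
ordinary least squares; `estimate_period()` minimises the residual sum of
squares over a period grid and refines the minimum by local parabolic
interpolation. The reported **phase** $\phi$ is the peak time of the fitted
fundamental component, wrapped into $[0, T)$; the **amplitude** is the
fundamental magnitude $\sqrt{a_1^2 + b_1^2}$.

Parameters that matter, with defaults and rationale:

* `window = c(16, 40)` h — the circadian search range; estimates at the
  boundary indicate an unreliable fit.
* `grid_step = 0.05` h — grid resolution; with parabolic refinement the
  effective resolution is finer, and noiseless traces are recovered to
  well under one grid step.
* `n_harmonics = 3` — captures the visibly non-sinusoidal waveforms of
  luciferase reporters without overfitting; the fit is insensitive to
  $K \in \{2, 3, 4\}$ on synthetic traces.
* `detrend_method = "linear"` — the slow drift of a reporter signal is
  fitted **jointly** with the harmonics as a linear term in the design
  matrix. Pre-subtracting an OLS line instead would leak part of the
  oscillation into the trend (the OLS slope of a sinusoid over a finite
  window is not zero) and bias the period search; fitting the trend
  jointly makes noiseless recovery exact.
* `burn_in = 24` h — the first day after release into constant light is
  discarded as transient.
* `rhythm_gate = 2` — a trace is called rhythmic when the fundamental
  amplitude exceeds twice the residual SD. An all-constant trace returns an
  arrhythmic result (period `NA`), never an exception.

`compare_periods()` applies a Welch (unequal-variance) two-tailed t-test to
fitted periods; with degenerate zero-variance groups the mean difference is
still reported and the p-value is `NA`.

## Pharmacology: dose-response and phase-response curves

The experimental convention emulated throughout is **plate pairing**: every
treated well is compared to the identical well position on a different,
vehicle-treated plate, with 8 replicate wells per condition.
`dose_response()` reports the mean ± SD of the fitted period per dose and
the difference from the paired vehicle mean; unmatched wells are dropped
with a warning, and a dose with no matched pairs is an error.

`phase_change()` computes the phase shift after a pulse-and-washout
experiment as the **circular mean** of per-pair phase differences,
converted to minutes. Phases are angles: averaging wrapped differences
naively breaks near the wrap point, so differences are mapped to unit
vectors, averaged, and wrapped into $(-T/2, T/2]$. By consensus **delays
are negative** (the treated peak occurs later), and a shift of exactly half
a cycle reports as an advance $+T/2$. Per-pair differences (rather than the
difference of group means) were chosen so a replicate-level dispersion and
a t-test against zero are available for each curve point.

`build_prc()` assembles one point per pulse start time. A point whose wells
are arrhythmic after washout is flagged in the `note` column rather than
aborting the curve. When asking *which* pulse times shift phase, a curve of
a dozen points tested at a raw per-point $\alpha = 0.05$ would produce at
least one false positive in roughly half of all null experiments
($1 - 0.95^{12} \approx 0.46$), so the `significant` column is based on
Holm-corrected p-values across the curve (familywise $\alpha = 0.05$); raw
p-values are also reported. This is why a flat (all-null) PRC is clean in
well over 90% of simulated experiments while a genuine 150-minute delay
still stands out.

## Phospho-proteomics: collation and differential testing

`collate_sites()` reduces the occurrence-level quantification table (one
row per peptide × charge state × missed-cleavage × modification variant) to
unique phospho-sites by summing abundances per sample, keyed on the protein
accession plus the sorted phosphorylated positions. Total abundance is
conserved exactly, and conflicting residue annotations at one position are
a named data error.

`differential_sites()` follows the standard label-free procedure:

* the two-tailed independent-samples t-test runs on **arcsinh-transformed**
  abundances (label-free intensities are right-skewed; arcsinh behaves like
  a log for large values but tolerates zeros);
* the fold change is the ratio of **raw** within-group means (comparison
  group over control) — the transform never touches it;
* a site is significant when $p < 0.05$ **and** FC $> 1.5$ or $< 1/1.5$;
* no multiple-testing correction enters the gate (a Benjamini–Hochberg
  column is emitted for information only);
* the Welch variant is the default (`var_equal = FALSE`) since the original
  testing tool is not specified further than "t-test for independent
  samples";
* a site needs at least two finite abundances per group to be testable, and
  a zero control-group mean leaves the fold change undefined; both cases
  are flagged (`testable`, `note`), never dropped silently.

`overlap_counts()` produces the per-direction counts and pairwise
intersections that drive a chord diagram of shared differential sites
across comparisons.

## Motif enrichment by Monte-Carlo permutation

`permutation_enrichment()` tests whether CK1-target sites have a different
mean fold change than the remaining sites. The statistic is
$\bar{fc}_{\text{target}} - \bar{fc}_{\text{non-target}}$ on the raw ratio
scale (a log-scale alternative was considered; the raw scale matches the
phrase "mean fold-change" as the quantity of interest, and the test is
invariant to shared shifts). Labels are permuted preserving the observed
partition dimensions; the two-tailed p-value is the frequency with which
$|\text{stat}_{\text{perm}}| \ge |\text{stat}_{\text{obs}}|$ — ties count
toward the tail, the conservative standard. The default is $10^5$
permutations (raise `n_permutations` to $10^7$ to resolve p-values near
$10^{-6}$); `plus_one = TRUE` switches to the $(b+1)/(n+1)$ estimator.
`exhaustive_enrichment()` enumerates all $\binom{n}{k}$ label placements
(bounded at $10^6$) and serves as the exact oracle the Monte-Carlo version
is tested against.

The background set is configurable: all remaining sites (default) or only
non-differential sites, since both conventions are in use.

`scan_ck1_consensus()` is a deliberately simple stand-in for trained
kinase-substrate classifiers: CK1 prefers an acidic or phospho-primed
determinant at position $p-3$, so a site is called a target when $p-3$
holds S, T, D or E, and the score counts acidic residues in $p-7..p-1$ plus
a primed bonus. Imported predictions (via `read_site_labels()`) bypass the
scorer entirely and are the recommended route when a real classifier's
output is available.

## What the synthetic generator emulates — and what it does not

`simulate_trace()` draws damped cosines with linear drift and i.i.d.
Gaussian noise: the minimal generative model reproducing the morphology of
reporter rhythms damping out in constant light. Defaults: baseline 1000,
amplitude 500 counts, damping 0.005 h⁻¹ (amplitude halves in about six
days, matching reporters that stay scoreable for a week), sampling every
1 h for 120 h (≥4 cycles for stable fits; imaging cadence and run length
are assay choices, exposed as parameters). Trace noise in the recovery
studies is 20% of amplitude. Not emulated: non-Gaussian photon statistics,
waveform asymmetry beyond the fitted harmonics, and inter-well coupling —
so passing recovery tests demonstrates estimator correctness under the
stated model, not robustness to every artefact of a real imager.

`simulate_phospho_table()` draws per-site baselines log-normally
(between-site SD 1.0 on the log scale), replicate noise log-normally
(`abundance_log_sd`, default 0.25), spikes a configurable fraction of sites
with a true fold change in the comparison group (default: 85% up-spikes at
FC ≈ 3, mirroring the predominance of up-regulation under kinase
overexpression), splits each site over 1–3 occurrence rows with fixed
proportions (so collation can be tested against exact conservation), and
plants the CK1 consensus determinant into generated protein sequences
according to the true motif label (enriched among up-spiked sites, default
0.6 versus 0.25 background). Groups have n = 5 replicates. Not emulated:
identification error, site-localisation ambiguity, intensity-dependent
missingness (a missing-at-random rate is available, default 0).

## Numerical choices and degenerate inputs

* Period refinement uses the parabola through the three grid points around
  the rss minimum; boundary minima are returned unrefined and clamped to
  the window.
* Permutation ties are detected with a small relative tolerance
  ($10^{-12}$) so floating-point jitter cannot push an exact tie out of the
  tail.
* All generators and the permutation test are pure functions of
  `(parameters, seed)`; the caller's RNG state is saved and restored.
* Rank-deficient harmonic designs (period far beyond the trace span) raise
  a degenerate-fit error; constant traces yield arrhythmic results.

## Problem sizes used in the test suite

The recovery studies run at the design scale of the emulated experiments:
1,000 traces (25 batches × 5 period conditions × 8 wells) for the period
bias study, 100 simulated 12-point PRC experiments for the null
calibration, ~1,000 sites for the differential null, and ~600 sites for the
power study. Batched fitting (one QR factorisation per trial period shared
by all wells on a common time grid) keeps 1,000 traces under half a minute
on one core.

## Known limitations

* The harmonic estimator assumes a single stationary period; it will
  average over period changes within the window rather than track them.
* The per-point PRC t-test treats wrapped per-pair differences as linear
  quantities, which is accurate away from the ±T/2 wrap point but
  conservative exactly at it.
* The consensus motif scorer is a sequence heuristic; its labels should not
  be interpreted as classifier predictions.
* Dose-response summaries are model-free (per-dose means); the Hill-shaped
  effect is part of the generator, not of the analysis.
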