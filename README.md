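# ck1clock

Casein kinase 1 (CK1) is a conserved regulator of circadian period: raising
its activity (overexpression) or lowering it (inhibitors such as IC261 and
PF-670462) changes the free-running period of clock-driven reporters, shifts
the phase of the rhythm in a time-of-day-dependent way, and remodels the
phospho-proteome. `ck1clock` is an R package for analysing exactly this kind
of experiment in a luminescent reporter cell line: it quantifies rhythms,
builds the pharmacological response curves, and calls and interprets
differential phospho-sites — with a synthetic-data generator so every stage
runs, with known ground truth, without any external data.

It is intended for chronobiologists and proteomics analysts who have (or
want to simulate) plate-based bioluminescence time series and label-free
phospho-peptide quantification tables.

## The models at the core

**Rhythm quantification.** A trace is fitted by harmonic regression with the
fundamental period as the free nonlinear parameter:

    x(t) = mu + beta*t + sum_{k=1..K} [ a_k cos(2*pi*k*t/T) + b_k sin(2*pi*k*t/T) ] + e_t

For fixed `T` this is ordinary least squares; the residual sum of squares is
minimised over a period grid (default 16–40 h in 0.05 h steps) with local
parabolic refinement. Phase `phi` is the peak time of the fitted fundamental
in `[0, T)`; amplitude is `sqrt(a1^2 + b1^2)`.

**Pharmacology.** `dose_response()` summarises period versus dose against
paired vehicle plates (identical well positions, n = 8); `phase_change()` /
`build_prc()` compute the phase-response curve as circular means of per-pair
phase differences in minutes, with delays negative by consensus and values
wrapped into `(-T/2, T/2]`.

**Phospho-proteomics.** `collate_sites()` sums all peptide occurrences
(charge states, missed cleavages, further modifications) per unique
phospho-site; `differential_sites()` tests arcsinh-transformed abundances
with a two-tailed independent-samples t-test, computes fold changes from raw
within-group means, and gates at `p < 0.05` and `FC > 1.5` (or `< 1/1.5`).
`permutation_enrichment()` tests whether CK1-motif target sites differ in
mean fold change from the remaining sites by Monte-Carlo label permutation
(two-tailed tail frequency, ties counted), with
`exhaustive_enrichment()` as the exact small-case oracle.

## Worked example

```r
library(ck1clock)

# a synthetic reporter trace: true period 26.5 h, phase 8 h, 20% noise
p  <- trace_params(period = 26.5, phase = 8, noise_sd = 100)
tr <- simulate_trace(p, seed = 11, metadata = list(well = "W1", plate = "P1"))
estimate_period(tr$time_h, tr$lum)
#> <rhythm_fit> period 26.40 h, phase 8.23 h, amplitude 345.5
```

The estimate lands within ~0.1 h of the generated 26.5 h period and ~0.2 h
of the generated phase; the amplitude is the fitted fundamental magnitude
(smaller than the generative 500 counts because the envelope damps over the
fit window).

```r
# a synthetic phospho experiment: 5 replicates per group, ~10% spiked sites
sim   <- simulate_phospho_table(phospho_sim_params(), seed = 42)
sites <- collate_sites(sim$peptides)
d     <- differential_sites(sites, "parent", "ox")
sum(d$significant)                    # 46 of 372 sites pass p<0.05 & FC>1.5
table(d$direction[d$significant])     # 39 up, 7 down

lab <- scan_ck1_consensus(sim$proteins,
                          sim$truth[, c("site_key", "protein_id", "position")])
j   <- merge(d[d$testable, ], lab, by = "site_key")
permutation_enrichment(j$fold_change, j$is_target, 1e5, seed = 1)
#> <enrichment_result> mean fold-change difference (target - non-target): 0.3967
#>   two-tailed p = 1e-05 (100000 permutations, groups 103/269, seed 1)
```

Most significant sites are up-regulated (the generator spikes mostly
upward, as kinase overexpression would), and CK1-motif targets are
significantly enriched in fold change — the pattern the pipeline is built
to detect. `run_pipeline(pipeline_config(), out_dir = "out")` chains every
stage (simulate → fit → dose-response/PRC → collate → differential →
overlap → enrichment) and writes all tables plus a JSON run manifest.

## Documentation

The methods vignette (`vignettes/ck1clock-methods.Rmd`) documents the
models, parameter defaults and their rationale, the design decisions
(joint trend fitting, circular phase averaging, Holm correction across a
PRC, tie handling in the permutation test), what the synthetic generator
does and does not emulate, and known limitations.
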