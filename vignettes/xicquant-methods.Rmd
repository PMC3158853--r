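---
title: "Targeted MS1 quantification of phosphopeptides: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted MS1 quantification of phosphopeptides: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`xicquant` quantifies identified peptide ions from centroided MS1 spectra.
The measurement model is deliberately simple and matches how modern
Orbitrap-class DDA data behave at the MS1 level:

* A peptide ion is fully specified by its sequence, modifications, charge
  `z` and a reference retention time. Its elemental composition is the sum
  of residue compositions plus one water plus modification deltas; the
  monoisotopic mass is the composition dotted with the lightest-isotope
  masses; the ion m/z is `(M + z·1.00727646)/z`.
* The theoretical isotope envelope is the *aggregated* (unit-mass-binned)
  isotopic distribution, computed by truncated convolution of the
  per-element natural-abundance vectors. Fine structure is irrelevant here:
  the envelope is only used in a three-point Pearson correlation against
  observed apex intensities, which cannot resolve isotopologues within a
  nominal mass bin. Envelopes are truncated to the first three isotopes and
  rescaled so the largest retained peak equals 1; the correlation is
  scale-invariant, so this convention is cosmetic but fixed for
  serialization. Element masses and abundances are frozen in
  `inst/extdata/element_isotopes.tsv` so envelopes are bit-reproducible.
* Chromatographic elution is treated as Gaussian. A "peak width of ~30 s at
  base" is read as base = 4σ, i.e. σ = 7.5 s; the base then spans ±2σ and
  contains ~95% of the peak area.

Modifications are compositional deltas only (no fragmentation chemistry):
carbamidomethyl-C, oxidation-M, phospho-S/T/Y, and N-terminal pyroglutamate.
The literature names "Pyro-glu" without fixing its chemistry; both variants
are registered — loss of NH₃ from N-terminal Gln (`Pyro-glu`, the default)
and loss of H₂O from N-terminal Glu (`Pyro-glu-E`).

# Quantification rules and their parameters

All windows/thresholds are arguments with these defaults:

| parameter | default | units | meaning |
|---|---|---|---|
| `ppm` | 7 | ppm | m/z half-window, **closed** (a centroid at exactly 7 ppm is included), applied around each isotope's own m/z |
| `tR_window` | 5 | min | retention-time half-window around the reference tR |
| `iso_threshold` | 0.95 | – | strict lower bound on the observed-vs-theoretical isotope correlation |
| `n_isotopes` | 3 | – | isotopes per XIC (A, A+1, A+2) |
| `min_frac` | 0.05 | – | peak-bound threshold as a fraction of apex height |

Design choices where the method description is silent:

* **Apex on the summed trace.** The apex is the scan maximizing the summed
  three-isotope intensity: this is robust to single-isotope shot noise. The
  reported peptide intensity is the summed-trace apex height (and
  trapezoidal area in counts·seconds); `mono_only = TRUE` switches to the
  monoisotopic trace alone, since the convention is not standardized.
* **Peak bounds.** From the apex outward to the first scan below 5% of the
  apex or the first local minimum, whichever comes first. Truncating a
  Gaussian at 5% of apex (±2.45σ) loses ~1.4% of the analytic area, which
  is why the area-recovery tolerance is 3% while height recovery is ~0.5%.
* **Centroid selection.** Within the ppm window the *most intense* centroid
  wins (not the nearest in m/z); with several co-eluting signals this
  biases toward the stronger, which is what a human reading an XIC does.
* **Isotope correlation at the apex scan only.** A per-scan correlation
  would be noisier at the peak edges and the acceptance decision concerns
  the peak, not each scan. Zero variance in the observed triple (e.g. all
  equal) gives r = 0 and rejection.
* **NA, never zero.** Absence of signal is missing data, not a measured
  zero; every `NA` cell carries exactly one rejection reason
  (`out_of_tR_window`, `no_signal`, `low_iso_correlation`).
* **No cross-run tR alignment.** Reference retention times come from the
  peptide database; the ±5 min window is wide relative to the ~0.3 min
  run-to-run jitter the generator emulates, and no alignment step is
  modelled because the workflow being reproduced uses none.

# Normalization and outliers

`normalize_total()` divides each column by the run's **total MS1 intensity**
(TIC). The alternative reading — normalizing to the summed quantified
intensities — is available via `denominator = "quantified_sum"`; TIC is the
default because it is identification-independent. After division, columns
are rescaled by the mean of the totals purely to keep magnitudes
interpretable; every downstream statistic (percent-of-max, CV, R², %Acc) is
invariant to that constant. The normalization state is an append-only trail
(`raw → total_normalized → percent_of_max`) and re-application is refused.

`detect_outliers()` flags a replicate when the median across peptides of
|log2(value / median of the other replicates)| exceeds a threshold
(default 1). The criterion is invented — the original workflow judged the
outlier "by eye" — and the flag-then-confirm design forces that user
decision: removal is a separate `drop_runs()` call. An aberrant replicate
typically combines a global intensity shift with per-peptide
heterogeneity; TIC normalization absorbs the global part (which is why
normalization "compensates to a great extent" but not fully), so
`run_pipeline()` flags on the raw matrix and removes from the normalized
one.

# Evaluation statistics

* **Precision**: per-peptide `CV = 100·sd/mean` (sample SD) over replicate
  columns; histogram bins fixed at 0–10, 10–20, …, ≥100% (the bin layout is
  a package convention, stated in the output).
* **Linearity**: per-peptide OLS of normalized intensity on mixing
  proportion; R² is the squared Pearson correlation. Significance uses the
  two-sided critical correlation `r* = t_{1-α/2,n-2}/√(t² + n − 2)`
  (0.878 for n = 5, α = 0.05). The protocol this implements applies that
  number as a threshold on *R²*; 0.878 is in fact the critical *r* (the
  critical R² for n = 5 would be ≈ 0.771). The package applies it to |r| —
  the statistically correct reading — and reports both `r` and `r2` so the
  discrepancy is visible rather than guessed away.
* **Accuracy**: per point, `%Acc = |fitted − observed|/observed · 100`,
  where "fitted" is the per-peptide regression value at that proportion.
  The denominator is read as the observed intensity, and the absolute value
  prevents cancellation. At the 0% mixing point the observed value can be
  near zero, where this ratio is ill-defined; observations below 1% of the
  row maximum (configurable) are excluded from the mean and counted.
* **Site localization**: a placement is `localized` when
  (best − second-best) score ≥ a user-supplied delta threshold. No default
  is claimed; the cutoff depends on the search engine and dataset.

# The synthetic generator

`sim_config()` defaults encode the acquisition geometry being emulated: a
45-min gradient sampled every 2.5 s (so a 30 s peak base contains ≥ 12
MS1 scans, comfortably above the 10-points-per-XIC rule of thumb),
three-isotope envelopes at exact theoretical m/z with ±2 ppm uniform mass
jitter (inside the 7 ppm window, so window logic is exercised without
breaking matching), tR jitter of σ = 0.3 min across runs, multiplicative
lognormal noise applied to *whole elution profiles* per peptide-run
(matching replicate-level variability readouts; per-scan noise would mimic
shot noise instead), per-run global scale factors, and a complement of
background peptides carrying 0–3 phosphates.

Background peptides matter for the mixing design: if every simulated
peptide rose with the mixing proportion, the TIC itself would track the
proportion and TIC normalization would cancel the very signal being
measured. Real samples are dominated by composition-stable bulk signal;
the generator reproduces that by giving background peptides constant
abundances whose summed intensity dominates the TIC (default
`background_fraction = 0.5` with heights log-uniform in [50, 5000]).

Noise levels used in the shipped evaluations are the two regimes the
method's own characterization distinguishes: σ_log = 0.04 for the
dilution series (instrument-plus-fit noise on normalized data) and
σ_log = 0.198 for independent replicate extractions — chosen because a
lognormal with σ = 0.198 has CV = √(exp(σ²) − 1) ≈ 20%, the replicate
precision level the method achieves after normalization. The injected
outlier replicate multiplies each peptide by an independent U(0.1, 0.5)
draw: a wide, heterogeneous distortion that global normalization cannot
fully repair, which is exactly the behaviour that motivates
flag-and-remove. This failure mode is a synthetic stand-in; the original
outlier's mechanism is not characterized anywhere.

What the generator does **not** emulate: peak tailing and fronting,
chimeric/overlapping features beyond random m/z collisions, dynamic
exclusion and MS2 scheduling, charge-state envelopes sharing an elution
profile, electrospray ionization drift within a run, and missingness that
correlates with abundance. Passing the shipped tests therefore shows the
engine is correct under its stated model, not that real chromatography is
this clean.

## Numerical notes and degenerate inputs

* A Gaussian apex falling between two scans of a 2.5 s grid reads up to
  ~1.4% low at σ = 7.5 s (mean ~0.5%); the noise-free recovery checks
  place apexes on the scan grid (`tR_on_grid = TRUE`) so they test the
  quantifier, not the sampling phase. With noise present the grid effect
  is negligible against σ_log ≥ 0.04.
* Coincident simulated centroids within a scan are summed so m/z stays
  strictly ascending; random m/z collisions between peptides within 7 ppm
  and ±5 min do occur at realistic densities (~1–2% of pairs at 900
  peptides) and are left in deliberately — they are resolved, or rejected
  by the isotope-correlation filter, exactly as in real data.
* Ties at the apex resolve to the first maximum (`which.max`); two peaks
  in one window resolve to the taller apex.
* All randomness flows from `rng_seed`; a fixed seed reproduces runs and
  written mzML files byte for byte.

## Problem sizes in the shipped evaluations

The test suite and acceptance script use 200 peptides × 5 runs for the
dilution series and 900 peptides × 6 runs for the replicate design — the
same ion counts as the characterization they mirror — with smaller
fixtures (tens of peptides, 8–15 min gradients) for unit-level oracles.
These sizes give Monte-Carlo-stable summaries (the median R² and mean CV
move by well under their acceptance margins across seeds) while keeping a
full run in the minutes range on one CPU.

# Known limitations

* MS1-only: no MS2-based quantification, fragment prediction or search
  scoring; identifications arrive as tables.
* No untargeted feature detection, charge-state deconvolution or cross-run
  alignment.
* The outlier criterion is a heuristic on replicate medians; with fewer
  than ~5 replicates its reference median is itself fragile.
* `%Acc` is undefined at true-zero observations; the floor rule excludes
  rather than imputes them.
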