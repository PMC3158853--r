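# xicquant

Identification-driven, label-free quantification of phosphopeptides from
centroided MS1 spectra.

## The problem

Data-dependent acquisition (DDA) identifies peptides stochastically: a
phosphopeptide confidently identified in one LC-MS/MS run is often never
fragmented in the next, so quantifying only what was identified per run
leaves large holes in the peptide-by-run table. The remedy implemented here
is *targeted* MS1 quantification: every identified peptide ion — annotated
with its sequence, modifications, charge `z` and reference retention time
`tR` — is quantified in **every** run by extracting ion chromatograms (XICs)
from the survey spectra, whether or not it was identified there.

For each peptide ion the package:

1. computes the elemental composition and monoisotopic mass of the modified
   peptide, the ion m/z `(M + z·m_H⁺)/z`, and the theoretical isotope
   envelope (aggregated isotopic distribution by convolution of element
   isotope-abundance vectors);
2. builds XICs for the first three isotopes (A, A+1, A+2) with a closed
   ±7 ppm m/z window per isotope and a ±5 min `tR` window;
3. detects the chromatographic peak (apex of the summed three-isotope
   trace; bounds at 5% of apex or the first local minimum) and reports both
   apex height and trapezoidal area;
4. accepts the measurement only if the Pearson correlation between the
   observed apex isotope intensities and the theoretical envelope exceeds
   0.95 — otherwise the cell is `NA` with an explicit rejection reason;
5. normalizes the peptides × runs matrix to the total chromatogram
   intensity of each run, then expresses each peptide as a percentage of
   its largest value across samples;
6. evaluates quantification quality as precision
   (`CV = 100·sd/mean` over replicates), dilution-series linearity
   (per-peptide OLS of intensity on mixing proportion, R² with the
   small-sample critical value, e.g. 0.878 for n = 5 at p < 0.05) and
   accuracy (`%Acc = |fitted − observed|/observed · 100`), plus
   outlier-replicate flagging and delta-score site localization.

A synthetic LC-MS1 generator (Gaussian elution peaks ~30 s at base, 2.5 s
MS1 sampling, three-isotope envelopes, lognormal intensity noise, per-run
scale factors, background peptides, injected outlier replicates) produces
runs with ground-truth ledgers, so the whole pipeline is testable without
any raw data.

## Worked example

```r
library(xicquant)

# a 5-point mixing series: responsive peptides rise linearly 20 -> 100
cfg <- sim_config(n_peptides = 30, gradient_length = 12,
                  noise_sigma_log = 0.04, run_scale_range = c(0.7, 1.4),
                  rng_seed = 7)
sim <- simulate_mixing_series(cfg)

q    <- quantify(sim$runs, sim$peptides)       # every peptide x every run
pct  <- percent_of_max(normalize_total(q$height, sim$runs))
fits <- linearity(pct, sim$design$proportion)
acc  <- accuracy(pct, sim$design$proportion, fits)

q$height
#> <intensity matrix> 30 peptides x 5 runs, readout=height, state=raw, 0 NA
mean(q$results$accepted)
#> [1] 1
median(fits$r2, na.rm = TRUE)
#> [1] 0.9959275
acc$mean_acc
#> [1] 3.007601
```

Every one of the 30 × 5 (peptide, run) pairs was quantified and passed the
isotope-distribution filter. The dilution response is recovered with a
median R² of 0.996 (all fits significant at the n = 5 critical value
`critical_r(5) = 0.878`), and the observed intensities deviate from the
fitted line by 3.0% on average — at this noise level the signal is read
back almost exactly.

The same API runs from files (`read_mzml()`, `read_peptide_db()`,
`run_pipeline()`), and `inst/scripts/xicquant.R` wraps it for the shell
with `simulate`, `quantify`, `normalize`, `outliers`, `qc` and `run-all`
subcommands.

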