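# Shared (lazily computed, cached) simulation pipelines so that several
# test files can assert on the same experiment without re-running it.

.sim_cache <- new.env(parent = emptyenv())

# Clean 5-point mixing series at the dilution-series noise level
# (sigma_log 0.04, per-run scale factors), quantified and normalized.
cached_mixing_pipeline <- function() {
  if (!is.null(.sim_cache$mix)) return(.sim_cache$mix)
  cfg <- sim_config(n_peptides = 200, noise_sigma_log = 0.04,
                    run_scale_range = c(0.7, 1.4), rng_seed = 1234)
  sim <- simulate_mixing_series(cfg)
  q <- quantify(sim$runs, sim$peptides)
  pct <- percent_of_max(normalize_total(q$height, sim$runs))
  fits <- linearity(pct, sim$design$proportion)
  acc <- accuracy(pct, sim$design$proportion, fits)
  .sim_cache$mix <- list(sim = sim, q = q, pct = pct, fits = fits, acc = acc)
  .sim_cache$mix
}

# Six-replicate experiment of 900 peptides at the replicate noise level
# (sigma_log 0.198, scale factors log-uniform in [0.5, 2]).
cached_replicate_pipeline <- function() {
  if (!is.null(.sim_cache$rep)) return(.sim_cache$rep)
  cfg <- sim_config(n_peptides = 900, noise_sigma_log = 0.198,
                    run_scale_range = c(0.5, 2), rng_seed = 1234)
  sim <- simulate_replicates(cfg, n_replicates = 6)
  q <- quantify(sim$runs, sim$peptides)
  norm <- normalize_total(q$height, sim$runs)
  prec <- precision_summary(norm, sim$design)
  .sim_cache$rep <- list(sim = sim, q = q, norm = norm, prec = prec)
  .sim_cache$rep
}

# Small noise-free simulation (apexes on the scan grid) for ground-truth
# recovery checks.
cached_clean_pipeline <- function() {
  if (!is.null(.sim_cache$clean)) return(.sim_cache$clean)
  cfg <- sim_config(n_peptides = 40, gradient_length = 15,
                    noise_sigma_log = 0, run_scale_range = c(1, 1),
                    mass_error_ppm = 0, tR_jitter_sd = 0,
                    background_fraction = 0, tR_on_grid = TRUE, rng_seed = 42)
  sim <- simulate_replicates(cfg, n_replicates = 2)
  q <- quantify(sim$runs, sim$peptides)
  .sim_cache$clean <- list(sim = sim, q = q, cfg = cfg)
  .sim_cache$clean
}
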