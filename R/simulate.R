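## Synthetic LC-MS1 run generator: Gaussian elution peaks, three-isotope
## envelopes, multiplicative noise, per-run scale factors, background
## peptides and ground-truth ledgers for parameter-recovery testing.

#' Simulation configuration
#'
#' Defaults emulate a 45-min nano-LC gradient acquired with a 2.5 s MS1 duty
#' cycle, chromatographic peaks of about 30 s at the base (modelled as
#' Gaussians with sigma = base/4), multiplicative lognormal intensity noise
#' acting on whole elution profiles, per-run global scale factors, small
#' mass and retention-time jitter, and a complement of unmodified background
#' peptides that dominate the total chromatogram intensity.
#'
#' @param n_peptides Number of quantifiable (foreground) peptides.
#' @param charges Charge states to sample from.
#' @param mz_range Acceptable precursor m/z range (Th).
#' @param length_range Peptide length range (residues).
#' @param gradient_length Gradient length in minutes.
#' @param scan_interval MS1 sampling interval (duty cycle) in seconds.
#' @param peak_base_width Chromatographic peak width at base in seconds;
#'   the Gaussian sigma is `peak_base_width / 4`.
#' @param noise_sigma_log SD of the lognormal multiplicative noise applied
#'   to each peptide's whole elution profile, per run.
#' @param run_scale_range Bounds of the log-uniform per-run global intensity
#'   scale factor.
#' @param mass_error_ppm Half-width of the uniform per-peptide-per-run m/z
#'   jitter (ppm).
#' @param tR_jitter_sd SD (minutes) of the per-peptide-per-run retention
#'   time jitter.
#' @param background_fraction Fraction of all simulated peptides that are
#'   constant-abundance background (not in the quantification database).
#' @param background_height_range Log-uniform apex-height range of
#'   background peptides (arbitrary counts).
#' @param background_phospho_probs Probabilities of 0-3 phosphate groups on
#'   background peptides.
#' @param height_range Log-uniform apex-height range for replicate-design
#'   foreground peptides.
#' @param mixing_height_range `c(baseline, top)`: the true apex height of a
#'   responsive peptide rises linearly from `baseline` at 0% to `top` at
#'   100% treated extract.
#' @param n_isotopes Isotopes injected per peptide.
#' @param tR_on_grid If TRUE, elution apexes are placed exactly on scan
#'   times (used for grid-free parameter-recovery checks).
#' @param rng_seed Integer seed; fixed seed implies identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_peptides = 100, charges = 2:3,
                       mz_range = c(375, 1800), length_range = c(8, 20),
                       gradient_length = 45, scan_interval = 2.5,
                       peak_base_width = 30, noise_sigma_log = 0.198,
                       run_scale_range = c(0.5, 2), mass_error_ppm = 2,
                       tR_jitter_sd = 0.3, background_fraction = 0.5,
                       background_height_range = c(50, 5000),
                       background_phospho_probs = c(0.5, 0.3, 0.15, 0.05),
                       height_range = c(1e3, 1e6),
                       mixing_height_range = c(20, 100),
                       n_isotopes = 3L, tR_on_grid = FALSE, rng_seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$scan_interval <= 0) stop("scan_interval must be > 0")
  if (cfg$peak_base_width / 60 >= cfg$gradient_length)
    stop("peak base width must be smaller than the gradient span")
  if (cfg$background_fraction < 0 || cfg$background_fraction >= 1)
    stop("background_fraction must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Expected MS1 points per chromatographic peak
#'
#' The number of MS1 scans falling within one peak base given the duty cycle
#' and peak width of the configuration.
#'
#' @param config A `sim_config`.
#' @return Integer count of scans per peak base.
#' @export
points_per_peak <- function(config) {
  as.integer(floor(config$peak_base_width / config$scan_interval)) + 1L
}

# Random tryptic-like peptides; n_phospho phosphates are placed on S/T/Y.
.random_peptide <- function(config, n_phospho) {
  sty <- c("S", "T", "Y")
  others <- setdiff(names(AMINO_ACID_FORMULAS), c("K", "R"))
  for (try in 1:60) {
    len <- sample(config$length_range[1]:config$length_range[2], 1L)
    seq_body <- sample(others, len - 1L, replace = TRUE)
    if (n_phospho > 0) {
      pos <- sample(len - 1L, min(n_phospho, len - 1L))
      seq_body[pos] <- sample(sty, length(pos), replace = TRUE)
    }
    sequence <- paste(c(seq_body, sample(c("K", "R"), 1L)), collapse = "")
    mods <- ""
    if (n_phospho > 0) {
      sty_pos <- which(strsplit(sequence, "")[[1]] %in% sty)
      sty_pos <- sty_pos[seq_len(min(n_phospho, length(sty_pos)))]
      mods <- paste(paste0(sty_pos, ":Phospho"), collapse = ";")
    }
    charge <- if (length(config$charges) > 1L) sample(config$charges, 1L)
              else config$charges
    mass <- monoisotopic_mass(composition_of(sequence, mods))
    mz <- ion_mz(mass, charge)
    if (mz >= config$mz_range[1] && mz <= config$mz_range[2])
      return(list(sequence = sequence, modifications = mods, charge = charge,
                  mass = mass, mz = mz))
  }
  stop("could not draw a peptide inside the m/z range")
}

#' Draw a random peptide set
#'
#' @param n Number of peptides.
#' @param config A `sim_config`.
#' @param n_phospho Number of phosphates per peptide: a single integer, or a
#'   vector of length `n`.
#' @param prefix Id prefix.
#' @return A peptide database data.frame (`id`, `sequence`,
#'   `modifications`, `charge`, `tR_min`, `mass`, `mz`).
#' @export
sim_peptides <- function(n, config, n_phospho = 1L, prefix = "pep") {
  if (length(n_phospho) == 1L) n_phospho <- rep(n_phospho, n)
  tR <- stats::runif(n, 0.08 * config$gradient_length,
                     0.92 * config$gradient_length)
  if (config$tR_on_grid)
    tR <- round(tR / (config$scan_interval / 60)) * (config$scan_interval / 60)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- .random_peptide(config, n_phospho[i])
    rows[[i]] <- data.frame(id = sprintf("%s%04d", prefix, i),
                            sequence = p$sequence,
                            modifications = p$modifications,
                            charge = p$charge, tR_min = tR[i], mass = p$mass,
                            mz = p$mz, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Envelope cache for a peptide table.
.peptide_envelopes <- function(db, n_isotopes = 3L) {
  lapply(seq_len(nrow(db)), function(i)
    theoretical_envelope(composition_of(db$sequence[i], db$modifications[i]),
                         db$charge[i], n_isotopes))
}

.logunif <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Simulate one MS1 run
#'
#' Each peptide contributes its first `n_isotopes` theoretical isotopes as
#' Gaussian elution profiles sampled at the scan times; centroids sit at the
#' exact isotope m/z values times a per-peptide mass-error factor. The
#' per-run scale factor and per-peptide lognormal profile noise are applied
#' multiplicatively. Uses the current RNG state; seed upstream for
#' determinism.
#'
#' @param peptides Peptide table (as from [sim_peptides()]); must carry a
#'   `tR_min` inside the gradient.
#' @param heights True (clean) summed-isotope apex heights, one per peptide.
#' @param config A `sim_config`.
#' @param run_id Run identifier.
#' @param scale Per-run global intensity scale factor.
#' @param envelopes Optional precomputed envelope list (speeds up multi-run
#'   designs).
#' @return List with the `ms_run` and a `truth` data.frame holding, per
#'   peptide, the realized retention time and the apex height/area both
#'   before (`*_true`) and after (`*_applied`) noise and run scaling. Areas
#'   obey the Gaussian closed form `area = height * sigma * sqrt(2*pi)` in
#'   counts * seconds.
#' @export
simulate_run <- function(peptides, heights, config, run_id, scale = 1,
                         envelopes = NULL) {
  n <- nrow(peptides)
  stopifnot(length(heights) == n)
  if (any(peptides$tR_min <= 0 | peptides$tR_min >= config$gradient_length))
    stop("peptide tR outside the gradient")
  if (is.null(envelopes))
    envelopes <- .peptide_envelopes(peptides, config$n_isotopes)
  sigma_s <- config$peak_base_width / 4
  scan_t <- seq(0, config$gradient_length, by = config$scan_interval / 60)
  noise <- if (config$noise_sigma_log > 0)
    exp(stats::rnorm(n, 0, config$noise_sigma_log)) else rep(1, n)
  tR <- peptides$tR_min +
    if (config$tR_jitter_sd > 0) stats::rnorm(n, 0, config$tR_jitter_sd)
    else 0
  if (config$tR_on_grid)
    tR <- round(tR / (config$scan_interval / 60)) * (config$scan_interval / 60)
  ppm_jit <- if (config$mass_error_ppm > 0)
    stats::runif(n, -config$mass_error_ppm, config$mass_error_ppm) else rep(0, n)

  ev_scan <- vector("list", n); ev_mz <- vector("list", n)
  ev_int <- vector("list", n)
  half_min <- 4 * sigma_s / 60
  for (i in seq_len(n)) {
    env <- envelopes[[i]]
    amp <- heights[i] * noise[i] * scale * env$abundance / sum(env$abundance)
    sel <- which(scan_t >= tR[i] - half_min & scan_t <= tR[i] + half_min)
    if (!length(sel)) next
    g <- exp(-((scan_t[sel] - tR[i]) * 60)^2 / (2 * sigma_s^2))
    k <- length(env$mz)
    ev_scan[[i]] <- rep(sel, k)
    ev_mz[[i]] <- rep(env$mz * (1 + ppm_jit[i] * 1e-6), each = length(sel))
    ev_int[[i]] <- as.vector(outer(g, amp))
  }
  scan_idx <- unlist(ev_scan); mzv <- unlist(ev_mz); iv <- unlist(ev_int)
  peaks <- rep(list(matrix(numeric(0), 0, 2,
                           dimnames = list(NULL, c("mz", "intensity")))),
               length(scan_t))
  if (length(scan_idx)) {
    ord <- order(scan_idx, mzv)
    scan_idx <- scan_idx[ord]; mzv <- mzv[ord]; iv <- iv[ord]
    # merge coincident centroids so m/z stays strictly ascending per scan
    grp <- split(seq_along(scan_idx), scan_idx)
    for (s in names(grp)) {
      j <- grp[[s]]
      mz_s <- mzv[j]; in_s <- iv[j]
      if (anyDuplicated(mz_s)) {
        in_s <- as.numeric(tapply(in_s, mz_s, sum))
        mz_s <- sort(unique(mz_s))
      }
      peaks[[as.integer(s)]] <- cbind(mz = mz_s, intensity = in_s)
    }
  }
  truth <- data.frame(
    peptide_id = peptides$id, run_id = run_id, tR = tR,
    height_true = heights,
    height_applied = heights * noise * scale,
    area_true = heights * sigma_s * sqrt(2 * pi),
    area_applied = heights * noise * scale * sigma_s * sqrt(2 * pi),
    stringsAsFactors = FALSE)
  list(run = ms_run(run_id, scan_t, peaks), truth = truth)
}

#' Simulate a replicate experiment
#'
#' Replicate runs share true peptide intensities and differ by a log-uniform
#' per-run global scale factor plus per-peptide lognormal profile noise.
#' Optionally one replicate is turned into an outlier by per-peptide
#' multiplicative distortions drawn from a wide uniform range, so that
#' global normalization alone cannot fully repair it.
#'
#' @param config A `sim_config`; `rng_seed` fixes all randomness.
#' @param n_replicates Number of replicate runs (>= 2).
#' @param outlier_spec Optional `list(run = <index>, factor_range = c(lo, hi))`.
#' @return List with `runs`, `peptides` (the quantification database),
#'   `background`, `truth`, `design` (run_id, group) and `config`.
#' @export
simulate_replicates <- function(config, n_replicates = 6, outlier_spec = NULL) {
  if (n_replicates < 2) stop("need at least two replicates")
  set.seed(config$rng_seed)
  n_fg <- config$n_peptides
  n_bg <- round(n_fg * config$background_fraction /
                  (1 - config$background_fraction))
  fg <- sim_peptides(n_fg, config, n_phospho = 1L, prefix = "pep")
  h_fg <- .logunif(n_fg, config$height_range)
  bg <- NULL; h_bg <- numeric(0)
  if (n_bg > 0) {
    nph <- sample(0:3, n_bg, replace = TRUE,
                  prob = config$background_phospho_probs)
    bg <- sim_peptides(n_bg, config, n_phospho = nph, prefix = "bg")
    h_bg <- .logunif(n_bg, config$background_height_range)
  }
  all_pep <- rbind(fg, bg)
  envs <- .peptide_envelopes(all_pep, config$n_isotopes)
  scales <- .logunif(n_replicates, config$run_scale_range)
  runs <- vector("list", n_replicates); truth <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    h <- c(h_fg, h_bg)
    if (!is.null(outlier_spec) && r == outlier_spec$run)
      h <- h * stats::runif(length(h), outlier_spec$factor_range[1],
                            outlier_spec$factor_range[2])
    sim <- simulate_run(all_pep, h, config, sprintf("rep%02d", r),
                        scale = scales[r], envelopes = envs)
    runs[[r]] <- sim$run
    truth[[r]] <- cbind(sim$truth, scale = scales[r])
  }
  list(runs = runs, peptides = fg, background = bg,
       truth = do.call(rbind, truth),
       design = data.frame(run_id = sprintf("rep%02d", seq_len(n_replicates)),
                           group = "rep", stringsAsFactors = FALSE),
       config = config)
}

#' Simulate a mixing (dilution) series
#'
#' One run per mixing proportion. Each responsive foreground peptide's true
#' apex height at proportion p (percent treated extract) is
#' `baseline + slope * p`, rising from `mixing_height_range[1]` at 0% to
#' `mixing_height_range[2]` at 100%. Background peptides are constant, so
#' the total chromatogram intensity tracks the per-run scale factor rather
#' than the mixture composition.
#'
#' @param config A `sim_config`.
#' @param proportions Percent treated extract per run, each in [0, 100].
#' @return List with `runs`, `peptides`, `background`, `truth` (including
#'   `baseline`, `slope`, `proportion`), `design` (run_id, proportion) and
#'   `config`.
#' @export
simulate_mixing_series <- function(config,
                                   proportions = c(0, 25, 50, 75, 100)) {
  if (any(proportions < 0 | proportions > 100))
    stop("mixing proportions must lie in [0, 100]")
  set.seed(config$rng_seed)
  n_fg <- config$n_peptides
  n_bg <- round(n_fg * config$background_fraction /
                  (1 - config$background_fraction))
  fg <- sim_peptides(n_fg, config, n_phospho = 1L, prefix = "pep")
  baseline <- rep(config$mixing_height_range[1], n_fg)
  slope <- rep((config$mixing_height_range[2] -
                  config$mixing_height_range[1]) / 100, n_fg)
  bg <- NULL; h_bg <- numeric(0)
  if (n_bg > 0) {
    nph <- sample(0:3, n_bg, replace = TRUE,
                  prob = config$background_phospho_probs)
    bg <- sim_peptides(n_bg, config, n_phospho = nph, prefix = "bg")
    h_bg <- .logunif(n_bg, config$background_height_range)
  }
  all_pep <- rbind(fg, bg)
  envs <- .peptide_envelopes(all_pep, config$n_isotopes)
  n_runs <- length(proportions)
  scales <- .logunif(n_runs, config$run_scale_range)
  runs <- vector("list", n_runs); truth <- vector("list", n_runs)
  run_ids <- sprintf("mix%03d_%d", round(proportions), seq_len(n_runs))
  for (r in seq_len(n_runs)) {
    h_fg <- baseline + slope * proportions[r]
    sim <- simulate_run(all_pep, c(h_fg, h_bg), config, run_ids[r],
                        scale = scales[r], envelopes = envs)
    runs[[r]] <- sim$run
    truth[[r]] <- cbind(sim$truth,
                        baseline = c(baseline, rep(NA_real_, length(h_bg))),
                        slope = c(slope, rep(0, length(h_bg))),
                        proportion = proportions[r], scale = scales[r])
  }
  list(runs = runs, peptides = fg, background = bg,
       truth = do.call(rbind, truth),
       design = data.frame(run_id = run_ids, proportion = proportions,
                           stringsAsFactors = FALSE),
       config = config)
}

#' Write a simulated experiment to disk
#'
#' Emits one mzML per run plus the peptide database, design and
#' ground-truth TSVs, making the simulated experiment consumable by the
#' file-based pipeline entry points.
#'
#' @param sim Output of [simulate_replicates()] or
#'   [simulate_mixing_series()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (run in sim$runs)
    write_mzml(run, file.path(dir, paste0(run$run_id, ".mzML")))
  write_peptide_db(sim$peptides, file.path(dir, "peptides.tsv"))
  utils::write.table(sim$design, file.path(dir, "design.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
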