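# XIC construction, peak detection, isotope correlation and cross-run
# quantification.

test_that("XIC traces reproduce a manually injected Gaussian exactly", {
  env <- theoretical_envelope(composition_of("GGSK", "3:Phospho"), 2)
  run <- manual_gaussian_run(env, tR = 10, height = 1000, span_min = 20)
  xic <- build_xic(run, env, reference_tR = 10)
  amps <- 1000 * env$abundance / sum(env$abundance)
  expected <- outer(exp(-((xic$times - 10) * 60)^2 / (2 * 7.5^2)), amps)
  big <- expected > 1e-6
  expect_equal(xic$intensities[big], expected[big], tolerance = 1e-9)
  expect_true(all(xic$intensities[!big] < 1e-6))
})

test_that("empty spectra give all-zero traces; empty windows raise the tR condition", {
  env <- theoretical_envelope(composition_of("GGK"), 1)
  empty <- ms_run("e", seq(0, 5, by = 0.5), rep(list(
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("mz", "intensity")))), 11))
  xic <- build_xic(empty, env, reference_tR = 2.5)
  expect_true(all(xic$intensities == 0))
  expect_null(detect_peak(xic))
  expect_error(build_xic(empty, env, reference_tR = 50),
               class = "xicquant_out_of_tR_window")
})

test_that("the ppm window is closed at exactly 7 ppm", {
  env <- theoretical_envelope(composition_of("GGK"), 1)
  target <- env$mz[1]
  mk_run <- function(dev_ppm) {
    ms_run("b", 1.0, list(cbind(mz = target * (1 + dev_ppm * 1e-6),
                                intensity = 100)))
  }
  at7 <- build_xic(mk_run(7.0), env, reference_tR = 1)
  expect_equal(at7$intensities[1, 1], 100)
  at701 <- build_xic(mk_run(7.01), env, reference_tR = 1)
  expect_equal(at701$intensities[1, 1], 0)
})

test_that("each isotope trace uses the window around its own m/z", {
  env <- theoretical_envelope(composition_of("GGSK", "3:Phospho"), 2)
  run <- ms_run("iso", 1.0,
                list(cbind(mz = env$mz[2], intensity = 55)))
  xic <- build_xic(run, env, reference_tR = 1)
  expect_equal(xic$intensities[1, ], c(0, 55, 0))
})

test_that("peak detection matches the Gaussian closed form on the scan grid", {
  env <- theoretical_envelope(composition_of("GGSK", "3:Phospho"), 2)
  run <- manual_gaussian_run(env, tR = 10, height = 2000, sigma_s = 7.5)
  xic <- build_xic(run, env, reference_tR = 10)
  peak <- detect_peak(xic)
  expect_equal(peak$apex_height, 2000, tolerance = 0.005)
  expect_equal(peak$area, 2000 * 7.5 * sqrt(2 * pi), tolerance = 0.03)
  expect_true(peak$left_bound <= peak$apex_time &&
                peak$apex_time <= peak$right_bound)
  expect_gte(peak$n_points, 10)
})

test_that("with two peaks in the window the taller apex wins", {
  env <- theoretical_envelope(composition_of("GGK"), 1)
  times <- seq(0, 10, by = 2.5 / 60)
  g1 <- 100 * exp(-((times - 4) * 60)^2 / (2 * 7.5^2))
  g2 <- 60 * exp(-((times - 6) * 60)^2 / (2 * 7.5^2))
  peaks <- lapply(g1 + g2, function(v)
    if (v > 1e-9) cbind(mz = env$mz[1], intensity = v)
    else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("mz", "intensity"))))
  run <- ms_run("two", times, peaks)
  pk <- detect_peak(build_xic(run, env, reference_tR = 5))
  expect_equal(pk$apex_time, 4, tolerance = 0.05)
  expect_equal(pk$apex_height, 100, tolerance = 0.01)
})

test_that("isotope correlation follows the Pearson formula with a zero-variance guard", {
  env <- theoretical_envelope(composition_of("GGSK", "3:Phospho"), 2)
  run <- manual_gaussian_run(env, tR = 5, span_min = 10)
  xic <- build_xic(run, env, reference_tR = 5)
  peak <- detect_peak(xic)
  expect_equal(isotope_correlation(xic, env, peak), 1.0, tolerance = 1e-9)

  # hand-computed Pearson r for observed (1000, 0, 180) vs (1, 0.53, 0.18)
  obs <- c(1000, 0, 180); theo <- c(1, 0.53, 0.18)
  r_hand <- sum((obs - mean(obs)) * (theo - mean(theo))) /
    sqrt(sum((obs - mean(obs))^2) * sum((theo - mean(theo))^2))
  fake <- xic
  fake$intensities[peak$apex_index, ] <- obs
  fake_env <- env; fake_env$abundance <- theo
  expect_equal(isotope_correlation(fake, fake_env, peak), r_hand,
               tolerance = 1e-12)

  flat <- xic
  flat$intensities[peak$apex_index, ] <- c(500, 500, 500)
  expect_equal(isotope_correlation(flat, env, peak), 0)
})

test_that("quantification is homogeneous of degree 1 in spectrum intensities", {
  p <- cached_clean_pipeline()
  run <- p$sim$runs[[1]]
  doubled <- run
  doubled$peaks <- lapply(run$peaks, function(m) {
    m[, 2] <- m[, 2] * 2; m })
  q2 <- quantify(list(doubled), p$sim$peptides)
  expect_equal(unclass(q2$height)[, 1], unclass(p$q$height)[, "rep01"] * 2,
               tolerance = 1e-9)
  expect_equal(unclass(q2$area)[, 1], unclass(p$q$area)[, "rep01"] * 2,
               tolerance = 1e-9)
})

test_that("every pair is attempted and NA cells carry exactly one rejection reason", {
  p <- cached_clean_pipeline()
  pep <- p$sim$peptides
  pep$tR_min[1] <- 60  # outside the simulated gradient
  q <- quantify(p$sim$runs, pep)
  expect_equal(nrow(q$results), nrow(pep) * length(p$sim$runs))
  r1 <- q$results[q$results$peptide_id == pep$id[1], ]
  expect_true(all(r1$rejection_reason == "out_of_tR_window"))
  expect_true(all(is.na(unclass(q$height)[1, ])))
  ok <- q$results$accepted
  expect_true(all(is.na(q$results$rejection_reason[ok])))
  expect_true(all(!is.na(q$results$rejection_reason[!ok])))
  expect_error(quantify(p$sim$runs, rbind(pep, pep)), "duplicate")
})

test_that("enlarging ppm or tR windows never loses accepted quantifications", {
  cfg <- sim_config(n_peptides = 25, gradient_length = 10,
                    noise_sigma_log = 0.1, mass_error_ppm = 4, rng_seed = 31)
  sim <- simulate_replicates(cfg, 2)
  acc <- function(ppm, tw)
    sum(quantify(sim$runs, sim$peptides, ppm = ppm,
                 tR_window = tw)$results$accepted)
  a_base <- acc(2, 1)
  expect_lte(a_base, acc(7, 1))
  expect_lte(acc(7, 1), acc(7, 5))
  expect_lte(acc(2, 1), acc(12, 8))
})

test_that("mono-only readout reports the monoisotopic trace only", {
  p <- cached_clean_pipeline()
  q_mono <- quantify(list(p$sim$runs[[1]]), p$sim$peptides, mono_only = TRUE)
  q_sum <- quantify(list(p$sim$runs[[1]]), p$sim$peptides)
  expect_true(all(unclass(q_mono$height)[, 1] < unclass(q_sum$height)[, 1]))
})
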