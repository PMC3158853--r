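# Precision, linearity, accuracy and site-localization statistics.

test_that("CV follows the sample-SD-over-mean definition with guards", {
  expect_equal(cv(c(90, 100, 110)), 10)
  expect_equal(cv(c(7, 7, 7)), 0)
  expect_true(is.na(cv(c(5))))
  expect_true(is.na(cv(c(NA, 5))))
  expect_true(is.na(cv(c(-10, 10))))      # mean <= 0
  expect_equal(cv(c(90, NA, 100, 110)), 10)
})

test_that("CV is invariant to positive rescaling", {
  set.seed(4)
  for (i in 1:10) {
    v <- stats::rlnorm(6, 5, 0.3)
    c <- stats::runif(1, 0.1, 50)
    expect_equal(cv(c * v), cv(v), tolerance = 1e-12)
  }
})

test_that("precision summaries bin CVs and label the readout", {
  m <- intensity_matrix(
    matrix(rep(c(100, 105, 95, 100), 3), 3, 4, byrow = TRUE,
           dimnames = list(paste0("p", 1:3), paste0("r", 1:4))), "area")
  ps <- precision_summary(m)
  expect_equal(ps$readout, "area")
  expect_equal(ps$n_peptides, 3)
  expect_true(all(ps$per_peptide$cv == ps$per_peptide$cv[1]))
  expect_equal(sum(ps$histogram), ps$n_peptides)
  # identical replicates: all CVs zero, mean zero
  same <- intensity_matrix(
    matrix(50, 4, 5, dimnames = list(paste0("p", 1:4), paste0("r", 1:5))),
    "height")
  expect_equal(precision_summary(same)$mean_cv, 0)
})

test_that("height and area summaries from the same runs stay distinct records", {
  p <- cached_clean_pipeline()
  ph <- precision_summary(p$q$height, p$sim$design)
  pa <- precision_summary(p$q$area, p$sim$design)
  expect_equal(ph$readout, "height")
  expect_equal(pa$readout, "area")
  expect_equal(ph$n_peptides, pa$n_peptides)
})

test_that("critical correlation matches t-distribution tables", {
  expect_equal(round(critical_r(5), 3), 0.878)
  t1 <- stats::qt(0.975, 1)
  expect_equal(critical_r(3), t1 / sqrt(t1^2 + 1), tolerance = 1e-12)
  expect_equal(round(critical_r(3), 3), 0.997)
  expect_lt(critical_r(5, alpha = 0.999), 0.01)
  expect_error(critical_r(2), "at least 3")
})

test_that("per-row OLS agrees with lm() to 1e-10 and flags degenerate rows", {
  props <- c(0, 25, 50, 75, 100)
  perfect <- c(20, 40, 60, 80, 100)
  perturbed <- c(20, 40, 50, 80, 100)
  mm <- rbind(p1 = perfect, p2 = perturbed, p3 = c(5, 5, 5, 5, 5),
              p4 = c(NA, NA, NA, 10, 20))
  colnames(mm) <- paste0("r", 1:5)
  fits <- linearity(intensity_matrix(mm, "height"), props)
  expect_equal(fits$r2[1], 1.0, tolerance = 1e-12)
  expect_equal(fits$slope[1], 0.8, tolerance = 1e-12)
  expect_equal(fits$intercept[1], 20, tolerance = 1e-12)
  expect_equal(fits$log2_fold[1], log2(5), tolerance = 1e-12)
  ref <- stats::lm(perturbed ~ props)
  expect_equal(fits$slope[2], unname(stats::coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fits$intercept[2], unname(stats::coef(ref)[1]),
               tolerance = 1e-10)
  expect_equal(fits$r2[2], summary(ref)$r.squared, tolerance = 1e-10)
  expect_equal(fits$critical_r[2], critical_r(5))
  expect_true(is.na(fits$r2[3]))       # zero variance
  expect_true(is.na(fits$significant[4]))  # < 3 points
})

test_that("accuracy applies the percent-deviation formula with the observation floor", {
  props <- c(0, 25, 50, 75, 100)
  mm <- rbind(p1 = c(20, 40, 60, 80, 100), p2 = c(20, 40, 50, 80, 100),
              p3 = c(0.1, 40, 60, 80, 100))
  colnames(mm) <- paste0("r", 1:5)
  acc <- accuracy(intensity_matrix(mm, "height"), props)
  p1 <- acc$per_point[acc$per_point$peptide_id == "p1", ]
  expect_equal(p1$pct_dev, rep(0, 5), tolerance = 1e-10)
  # hand-check p2 against the lm() fit
  ref <- stats::lm(c(20, 40, 50, 80, 100) ~ props)
  theo <- unname(stats::fitted(ref))
  expect_equal(acc$per_point$pct_dev[acc$per_point$peptide_id == "p2"],
               abs(theo - c(20, 40, 50, 80, 100)) / c(20, 40, 50, 80, 100) * 100,
               tolerance = 1e-10)
  # p3's first observation is below 1% of the row max: floored and counted
  pep3 <- acc$per_peptide[acc$per_peptide$peptide_id == "p3", ]
  expect_equal(pep3$n_floored, 1L)
  expect_equal(pep3$n_retained, 4L)
})

test_that("R2 and %Acc are invariant to row rescaling", {
  props <- c(0, 25, 50, 75, 100)
  set.seed(9)
  y <- 20 + 0.8 * props * exp(rnorm(5, 0, 0.05))
  m1 <- rbind(p1 = y); m2 <- rbind(p1 = y * 37.5)
  colnames(m1) <- colnames(m2) <- paste0("r", 1:5)
  m1 <- intensity_matrix(m1, "height"); m2 <- intensity_matrix(m2, "height")
  f1 <- linearity(m1, props); f2 <- linearity(m2, props)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
  expect_equal(accuracy(m1, props, f1)$mean_acc,
               accuracy(m2, props, f2)$mean_acc, tolerance = 1e-10)
})

test_that("fitted slopes recover injected slopes on the mixing simulation", {
  p <- cached_mixing_pipeline()
  # all responsive peptides share the injected 20 -> 100 line; after
  # percent-of-max the fitted line should hit ~20% at 0 and ~100% at 100
  expect_equal(median(p$fits$intercept, na.rm = TRUE), 20, tolerance = 0.15)
  expect_equal(median(p$fits$slope, na.rm = TRUE), 0.8, tolerance = 0.15)
  expect_true(mean(p$fits$significant, na.rm = TRUE) > 0.95)
})

test_that("delta-score localization distinguishes clear and ambiguous sites", {
  expect_equal(localize_site(60, 20, 10), "localized")
  expect_equal(localize_site(30, 29, 10), "ambiguous")
  expect_equal(localize_site(30, 30, 0.001), "ambiguous")
  expect_equal(localize_site(c(60, 30), c(20, 29), 10),
               c("localized", "ambiguous"))
  expect_error(localize_site(20, 60, 10), ">=")
  expect_error(localize_site(60, 20), "delta_threshold")
})
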