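## Evaluation statistics: precision (CV), dilution-series linearity
## (R squared with a small-sample significance threshold), accuracy (%Acc),
## fold change and delta-score site localization.

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation. Undefined
#' (NA) for fewer than two non-missing values or a non-positive mean.
#'
#' @param values Numeric vector of replicate intensities (NA allowed).
#' @return CV in percent, or NA.
#' @export
cv <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) return(NA_real_)
  m <- mean(v)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(v) / m
}

#' Precision summary over replicates
#'
#' Per-peptide CV across the replicate columns of each group, a histogram of
#' CVs over fixed 10-percentage-point bins (0-10, 10-20, ..., 90-100, >=100)
#' and the mean CV, labelled with the readout (height or area) the matrix
#' carries.
#'
#' @param m An `intensity_matrix`.
#' @param groups Optional replicate-group assignment (named vector or design
#'   data.frame); default: all columns are one group.
#' @return A `precision_summary`: list with `per_peptide` (peptide_id,
#'   group, n, cv), `mean_cv`, `histogram`, `readout`, `n_peptides`.
#' @export
precision_summary <- function(m, groups = NULL) {
  cols <- colnames(m)
  grp <- if (is.null(groups)) stats::setNames(rep("all", length(cols)), cols)
         else if (is.data.frame(groups))
           stats::setNames(as.character(groups$group), groups$run_id)[cols]
         else groups[cols]
  per <- vector("list", 0)
  for (g in unique(grp)) {
    sub <- unclass(m)[, which(grp == g), drop = FALSE]
    cvs <- apply(sub, 1, cv)
    per[[g]] <- data.frame(peptide_id = rownames(m), group = g,
                           n = rowSums(!is.na(sub)), cv = cvs,
                           stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  cvs <- per$cv[!is.na(per$cv)]
  breaks <- c(seq(0, 100, 10), Inf)
  hist <- table(cut(cvs, breaks, right = FALSE,
                    labels = c(paste(utils::head(breaks, -2),
                                     breaks[2:(length(breaks) - 1)],
                                     sep = "-"), ">=100")))
  structure(list(per_peptide = per, mean_cv = mean(cvs),
                 histogram = hist, readout = attr(m, "readout"),
                 n_peptides = length(cvs)),
            class = "precision_summary")
}

#' @export
print.precision_summary <- function(x, ...) {
  cat(sprintf("<precision summary> readout=%s, n=%d peptides, mean CV %.1f%%\n",
              x$readout, x$n_peptides, x$mean_cv))
  print(x$histogram)
  invisible(x)
}

#' Plot a precision summary as a CV histogram
#' @param x A `precision_summary`.
#' @param ... Passed to `barplot`.
#' @export
plot.precision_summary <- function(x, ...) {
  graphics::barplot(as.numeric(x$histogram), names.arg = names(x$histogram),
                    xlab = "CV range (%)", ylab = "phosphopeptides",
                    las = 2, ...)
  invisible(x)
}

#' Critical Pearson correlation for a given sample size
#'
#' Two-sided critical value at level `alpha` via the t quantile with `n - 2`
#' degrees of freedom: `r* = t / sqrt(t^2 + n - 2)`. For five points at
#' alpha = 0.05 this is 0.878. Note this is the critical value of r; when
#' reported against R squared, the corresponding bound on R squared is
#' `r*^2`.
#'
#' @param n_points Number of points in the regression (>= 3).
#' @param alpha Two-sided significance level. Default 0.05.
#' @return The critical correlation.
#' @export
critical_r <- function(n_points, alpha = 0.05) {
  if (n_points < 3) stop("need at least 3 points for a significance threshold")
  t <- stats::qt(1 - alpha / 2, df = n_points - 2)
  t / sqrt(t^2 + n_points - 2)
}

#' Dilution-series linearity per peptide
#'
#' Ordinary least squares of intensity on mixing proportion for every row of
#' the matrix; reports slope, intercept, r, R squared, a significance flag
#' (|r| above [critical_r()] recomputed for the row's n), and the log2 fold
#' between the fitted values at the largest and smallest proportion.
#'
#' @param m An `intensity_matrix` (or plain matrix) with one column per
#'   mixing run.
#' @param proportions Percent treated extract per column.
#' @param alpha Significance level for the critical correlation.
#' @return A `linearity_result` data.frame: `peptide_id`, `n`, `slope`,
#'   `intercept`, `r`, `r2`, `critical_r`, `significant`, `log2_fold`.
#'   Rows with < 3 non-missing points or zero intensity variance get NA
#'   statistics and `significant = NA`.
#' @export
linearity <- function(m, proportions, alpha = 0.05) {
  if (length(proportions) != ncol(m))
    stop("one proportion per matrix column required")
  mm <- unclass(m)
  out <- vector("list", nrow(mm))
  for (i in seq_len(nrow(mm))) {
    y <- mm[i, ]; ok <- !is.na(y)
    n <- sum(ok)
    row <- list(peptide_id = rownames(mm)[i], n = n, slope = NA_real_,
                intercept = NA_real_, r = NA_real_, r2 = NA_real_,
                critical_r = NA_real_, significant = NA,
                log2_fold = NA_real_)
    if (n >= 3) {
      x <- proportions[ok]; yy <- y[ok]
      if (stats::sd(yy) > 0 && stats::sd(x) > 0) {
        b <- stats::cov(x, yy) / stats::var(x)
        a <- mean(yy) - b * mean(x)
        r <- stats::cor(x, yy)
        rc <- critical_r(n, alpha)
        fit_lo <- a + b * min(x); fit_hi <- a + b * max(x)
        row$slope <- b; row$intercept <- a; row$r <- r; row$r2 <- r^2
        row$critical_r <- rc; row$significant <- abs(r) > rc
        row$log2_fold <- if (fit_lo > 0 && fit_hi > 0)
          log2(max(fit_lo, fit_hi) / min(fit_lo, fit_hi)) else NA_real_
      }
    }
    out[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("linearity_result", "data.frame")
  res
}

#' Dilution-series accuracy (%Acc) per peptide
#'
#' For each retained dilution point, the percent deviation between the
#' intensity predicted by the per-peptide regression and the observed
#' intensity: `|theoretical - observed| / observed * 100`. Observations
#' below `floor_frac` of the row maximum (near-zero points, where the
#' relative deviation is ill-defined) are excluded from the mean and
#' counted. The per-peptide %Acc is the mean over retained points; the
#' global mean averages the per-peptide means.
#'
#' @param m Intensity matrix (one column per mixing run).
#' @param proportions Percent treated extract per column.
#' @param fits Optional precomputed [linearity()] result for `m`.
#' @param floor_frac Observation floor as a fraction of the row maximum.
#'   Default 0.01.
#' @return An `accuracy_result`: list with `per_point` (peptide_id,
#'   proportion, observed, theoretical, pct_dev, retained), `per_peptide`
#'   (peptide_id, n_retained, n_floored, mean_acc) and `mean_acc` (global).
#' @export
accuracy <- function(m, proportions, fits = NULL, floor_frac = 0.01) {
  if (is.null(fits)) fits <- linearity(m, proportions)
  mm <- unclass(m)
  pts <- vector("list", nrow(mm)); pep <- vector("list", nrow(mm))
  for (i in seq_len(nrow(mm))) {
    y <- mm[i, ]; ok <- which(!is.na(y))
    f <- fits[i, ]
    if (!length(ok) || is.na(f$slope)) {
      pep[[i]] <- data.frame(peptide_id = rownames(mm)[i], n_retained = 0L,
                             n_floored = 0L, mean_acc = NA_real_,
                             stringsAsFactors = FALSE)
      next
    }
    obs <- y[ok]; x <- proportions[ok]
    theo <- f$intercept + f$slope * x
    retained <- obs >= floor_frac * max(obs)
    dev <- abs(theo - obs) / obs * 100
    pts[[i]] <- data.frame(peptide_id = rownames(mm)[i], proportion = x,
                           observed = obs, theoretical = theo,
                           pct_dev = dev, retained = retained,
                           stringsAsFactors = FALSE)
    pep[[i]] <- data.frame(
      peptide_id = rownames(mm)[i], n_retained = sum(retained),
      n_floored = sum(!retained),
      mean_acc = if (any(retained)) mean(dev[retained]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  per_peptide <- do.call(rbind, pep)
  structure(list(per_point = do.call(rbind, pts), per_peptide = per_peptide,
                 mean_acc = mean(per_peptide$mean_acc, na.rm = TRUE),
                 floor_frac = floor_frac),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy> mean %%Acc %.2f%% over %d peptides (%d floored points)\n",
              x$mean_acc, nrow(x$per_peptide),
              sum(x$per_peptide$n_floored)))
  invisible(x)
}

#' Delta-score phosphosite localization
#'
#' A site assignment is considered localized when the score difference
#' between the best and second-best candidate placements reaches the
#' user-supplied delta threshold; ties and small deltas are ambiguous.
#'
#' @param score_first Best-hit score(s); must be >= `score_second`.
#' @param score_second Second-hit score(s).
#' @param delta_threshold Required score difference (no default is claimed:
#'   the cutoff is a user decision).
#' @return Character vector: `"localized"` or `"ambiguous"`.
#' @export
localize_site <- function(score_first, score_second, delta_threshold) {
  if (missing(delta_threshold) || delta_threshold <= 0)
    stop("delta_threshold must be supplied and positive")
  if (any(score_first < score_second))
    stop("score_first must be >= score_second")
  ifelse(score_first - score_second >= delta_threshold, "localized",
         "ambiguous")
}
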