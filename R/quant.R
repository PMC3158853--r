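## Targeted XIC construction and chromatographic peak quantification with
## m/z, retention-time and isotope-distribution acceptance rules.

# Flatten a run into mz-sorted centroid vectors for fast windowed lookup.
.flatten_run <- function(run) {
  npk <- vapply(run$peaks, nrow, 0L)
  mz <- unlist(lapply(run$peaks, function(p) p[, 1]), use.names = FALSE)
  int <- unlist(lapply(run$peaks, function(p) p[, 2]), use.names = FALSE)
  scan <- rep.int(seq_along(run$peaks), npk)
  ord <- order(mz)
  list(mz = mz[ord], intensity = int[ord], scan = scan[ord])
}

#' Build an extracted ion chromatogram (XIC)
#'
#' For every MS1 scan inside the retention-time window and for each isotope
#' of the envelope, the trace value is the maximum centroid intensity within
#' the closed ppm window around that isotope's own m/z (0 when no centroid
#' falls in the window).
#'
#' @param run An `ms_run`.
#' @param envelope An `isotope_envelope` (defines the target m/z values).
#' @param reference_tR Reference retention time in minutes.
#' @param ppm m/z window half-width in ppm (closed: a centroid at exactly
#'   `ppm` is included). Default 7.
#' @param tR_window Retention-time window half-width in minutes. Default 5.
#' @param flat Optional precomputed index from the internal flattener (used
#'   by [quantify()] to amortize across peptides).
#' @return An `xic`: list with `times` (minutes), `intensities` (scans x
#'   isotopes matrix), `target_mz`, `ppm`, `reference_tR`, `tR_window`.
#'   Errors with class `xicquant_out_of_tR_window` when no scan lies in the
#'   window.
#' @export
build_xic <- function(run, envelope, reference_tR, ppm = 7, tR_window = 5,
                      flat = NULL) {
  sel <- which(abs(run$scan_times - reference_tR) <= tR_window)
  if (!length(sel))
    stop(structure(class = c("xicquant_out_of_tR_window", "error", "condition"),
                   list(message = sprintf(
                     "no MS1 scans within %.3g min of tR %.3g", tR_window,
                     reference_tR), call = sys.call())))
  if (is.null(flat)) flat <- .flatten_run(run)
  k <- length(envelope$mz)
  traces <- matrix(0, length(sel), k)
  s0 <- sel[1]
  for (j in seq_len(k)) {
    target <- envelope$mz[j]
    lo <- target * (1 - ppm * 1e-6); hi <- target * (1 + ppm * 1e-6)
    i1 <- findInterval(lo * (1 - 1e-12), flat$mz) + 1L
    i2 <- findInterval(hi * (1 + 1e-12), flat$mz)
    if (i2 < i1) next
    idx <- i1:i2
    dev_ppm <- abs(flat$mz[idx] - target) / target * 1e6
    keep <- dev_ppm <= ppm + 1e-9
    idx <- idx[keep]
    if (!length(idx)) next
    sc <- flat$scan[idx]
    inwin <- sc >= sel[1] & sc <= sel[length(sel)]
    idx <- idx[inwin]; sc <- sc[inwin]
    if (!length(idx)) next
    # per-scan maximum: order by intensity so the last write wins
    o <- order(flat$intensity[idx])
    traces[sc[o] - s0 + 1L, j] <- flat$intensity[idx][o]
  }
  structure(list(times = run$scan_times[sel], intensities = traces,
                 target_mz = envelope$mz, ppm = ppm,
                 reference_tR = reference_tR, tR_window = tR_window),
            class = "xic")
}

#' @export
print.xic <- function(x, ...) {
  cat(sprintf("<xic> %d scans x %d isotopes around tR %.2f min, target m/z %.4f\n",
              nrow(x$intensities), ncol(x$intensities), x$reference_tR,
              x$target_mz[1]))
  invisible(x)
}

#' Plot an XIC
#'
#' @param x An `xic`.
#' @param ... Passed to `matplot`.
#' @export
plot.xic <- function(x, ...) {
  graphics::matplot(x$times, x$intensities, type = "l", lty = 1,
                    xlab = "retention time (min)", ylab = "intensity", ...)
  invisible(x)
}

#' Detect the chromatographic peak in an XIC
#'
#' The apex is the scan maximizing the summed isotope trace. Peak bounds
#' extend outward from the apex to the first scan where the summed trace
#' falls below 5% of the apex height, or to the first local minimum,
#' whichever comes first. The area is the trapezoidal integral of the summed
#' trace between the bounds, in counts * seconds.
#'
#' @param xic An `xic`.
#' @param min_frac Bound threshold as a fraction of apex height (default
#'   0.05).
#' @return A `chrom_peak` (`apex_time`, `apex_height`, `area`, `left_bound`,
#'   `right_bound`, `n_points`, `apex_index`) or `NULL` when the trace
#'   carries no signal.
#' @export
detect_peak <- function(xic, min_frac = 0.05) {
  s <- rowSums(xic$intensities)
  if (!any(s > 0)) return(NULL)
  apex <- which.max(s)
  h <- s[apex]
  thr <- min_frac * h
  left <- apex
  while (left > 1L && s[left - 1L] >= thr && s[left - 1L] <= s[left])
    left <- left - 1L
  right <- apex
  n <- length(s)
  while (right < n && s[right + 1L] >= thr && s[right + 1L] <= s[right])
    right <- right + 1L
  idx <- left:right
  area <- if (length(idx) > 1L)
    sum(diff(xic$times[idx] * 60) * (s[idx][-1] + s[idx][-length(idx)]) / 2)
  else 0
  structure(list(apex_time = xic$times[apex], apex_height = h, area = area,
                 left_bound = xic$times[left], right_bound = xic$times[right],
                 n_points = length(idx), apex_index = apex),
            class = "chrom_peak")
}

#' @export
print.chrom_peak <- function(x, ...) {
  cat(sprintf(
    "<chrom peak> apex %.3f min, height %.4g, area %.4g counts*s, %d points [%.3f, %.3f]\n",
    x$apex_time, x$apex_height, x$area, x$n_points, x$left_bound,
    x$right_bound))
  invisible(x)
}

#' Observed-vs-theoretical isotope distribution correlation
#'
#' Pearson correlation between the per-isotope intensities observed at the
#' apex scan and the theoretical relative abundances. When either vector has
#' zero variance the correlation is defined as 0 (and the quantification is
#' rejected downstream).
#'
#' @param xic An `xic`.
#' @param envelope The `isotope_envelope` used to build it.
#' @param peak The detected `chrom_peak`.
#' @return Pearson r in [-1, 1].
#' @export
isotope_correlation <- function(xic, envelope, peak) {
  obs <- xic$intensities[peak$apex_index, ]
  if (stats::sd(obs) == 0 || stats::sd(envelope$abundance) == 0) return(0)
  stats::cor(obs, envelope$abundance)
}

#' Quantify a peptide database across runs
#'
#' Every (peptide, run) pair is attempted, including runs where the peptide
#' was never identified: this is the identification-driven remedy for DDA
#' undersampling. A pair is accepted when a peak is found and the
#' observed-vs-theoretical isotope correlation exceeds the threshold;
#' otherwise the matrices carry `NA` and the QC log records exactly one
#' rejection reason (`out_of_tR_window`, `no_signal`,
#' `low_iso_correlation`).
#'
#' @param runs List of `ms_run` objects.
#' @param peptides Peptide database data.frame (see [read_peptide_db()]).
#' @param ppm m/z window (ppm, closed). Default 7.
#' @param tR_window Retention-time window (minutes). Default 5.
#' @param iso_threshold Acceptance threshold on the isotope-distribution
#'   correlation (strict `>`). Default 0.95.
#' @param n_isotopes Isotopes per XIC. Default 3.
#' @param mono_only If TRUE, report the monoisotopic trace's apex height and
#'   area instead of the summed three-isotope trace.
#' @return List with `height` and `area` intensity matrices and a `results`
#'   QC data.frame (one row per pair).
#' @export
quantify <- function(runs, peptides, ppm = 7, tR_window = 5,
                     iso_threshold = 0.95, n_isotopes = 3L,
                     mono_only = FALSE) {
  if (anyDuplicated(peptides$id))
    stop("duplicate peptide ids: ",
         paste(unique(peptides$id[duplicated(peptides$id)]), collapse = ", "))
  run_ids <- vapply(runs, function(r) r$run_id, "")
  if (anyDuplicated(run_ids)) stop("duplicate run ids")
  envs <- .peptide_envelopes(peptides, n_isotopes)
  np <- nrow(peptides); nr <- length(runs)
  H <- matrix(NA_real_, np, nr, dimnames = list(peptides$id, run_ids))
  A <- H
  res <- vector("list", np * nr)
  for (r in seq_len(nr)) {
    flat <- .flatten_run(runs[[r]])
    for (i in seq_len(np)) {
      rec <- list(peptide_id = peptides$id[i], run_id = run_ids[r],
                  accepted = FALSE, rejection_reason = NA_character_,
                  iso_correlation = NA_real_, apex_time = NA_real_,
                  height = NA_real_, area = NA_real_, n_points = NA_integer_)
      xic <- tryCatch(
        build_xic(runs[[r]], envs[[i]], peptides$tR_min[i], ppm, tR_window,
                  flat = flat),
        xicquant_out_of_tR_window = function(e) NULL)
      if (is.null(xic)) {
        rec$rejection_reason <- "out_of_tR_window"
      } else {
        peak <- detect_peak(xic)
        if (is.null(peak)) {
          rec$rejection_reason <- "no_signal"
        } else {
          r_iso <- isotope_correlation(xic, envs[[i]], peak)
          rec$iso_correlation <- r_iso
          if (r_iso > iso_threshold) {
            if (mono_only) {
              mono <- xic
              mono$intensities <- xic$intensities[, 1, drop = FALSE]
              mpk <- detect_peak(mono)
              rec$height <- mpk$apex_height; rec$area <- mpk$area
              rec$apex_time <- mpk$apex_time; rec$n_points <- mpk$n_points
            } else {
              rec$height <- peak$apex_height; rec$area <- peak$area
              rec$apex_time <- peak$apex_time; rec$n_points <- peak$n_points
            }
            rec$accepted <- TRUE
            H[i, r] <- rec$height; A[i, r] <- rec$area
          } else {
            rec$rejection_reason <- "low_iso_correlation"
          }
        }
      }
      res[[(r - 1L) * np + i]] <- rec
    }
  }
  results <- do.call(rbind, lapply(res, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  list(height = intensity_matrix(H, "height"),
       area = intensity_matrix(A, "area"),
       results = results)
}
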