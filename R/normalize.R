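## Two-step normalization (total chromatogram intensity, then
## percent-of-maximum per peptide) and replicate-outlier flagging.

#' Normalize to total chromatogram intensity
#'
#' Divides each column by its run's total MS1 intensity and rescales by the
#' mean of the totals so magnitudes stay near the raw scale (any positive
#' constant is equivalent downstream: percent-of-max, CV, R squared and
#' %Acc are all invariant to it). The matrix must be in the raw state;
#' re-application is refused.
#'
#' @param m A raw `intensity_matrix`.
#' @param runs Either a list of `ms_run` objects covering every column, or a
#'   named numeric vector of per-run total intensities. With
#'   `denominator = "quantified_sum"` the per-column sum of quantified
#'   intensities is used instead and `runs` may be omitted.
#' @param denominator `"tic"` (total MS1 intensity of the run; default) or
#'   `"quantified_sum"` (summed quantified intensities per column).
#' @return A total-normalized `intensity_matrix` with a
#'   `normalization_report` attached as attribute `report`.
#' @export
normalize_total <- function(m, runs = NULL,
                            denominator = c("tic", "quantified_sum")) {
  denominator <- match.arg(denominator)
  st <- .im_state(m)
  if (st[length(st)] != "raw")
    stop("matrix is already normalized (state: ",
         paste(st, collapse = ">"), ")")
  if (denominator == "tic") {
    if (is.null(runs)) stop("runs (or named totals) required for TIC denominator")
    totals <- if (is.numeric(runs)) runs
              else stats::setNames(vapply(runs, total_ms1_intensity, 0),
                                   vapply(runs, function(r) r$run_id, ""))
    miss <- setdiff(colnames(m), names(totals))
    if (length(miss))
      stop("no run total for column(s): ", paste(miss, collapse = ", "))
    totals <- totals[colnames(m)]
  } else {
    totals <- colSums(m, na.rm = TRUE)
  }
  if (any(totals <= 0)) stop("run with zero (or negative) total intensity")
  factors <- mean(totals) / totals
  out <- sweep(unclass(m), 2, factors, `*`)
  report <- data.frame(run_id = colnames(m), total_intensity = unname(totals),
                       scale_factor = unname(factors),
                       stringsAsFactors = FALSE)
  structure(out, readout = attr(m, "readout"),
            state = c(st, "total_normalized"), report = report,
            class = "intensity_matrix")
}

#' Express each peptide as percent of its maximum across samples
#'
#' Scales every row so that its largest non-missing value equals 100.
#' Requires a total-normalized matrix; all-missing rows stay all-missing.
#'
#' @param m A total-normalized `intensity_matrix`.
#' @return A percent-of-max `intensity_matrix`.
#' @export
percent_of_max <- function(m) {
  st <- .im_state(m)
  if (st[length(st)] != "total_normalized")
    stop("percent_of_max requires a total-normalized matrix (state: ",
         paste(st, collapse = ">"), ")")
  mm <- unclass(m)
  rmax <- apply(mm, 1, function(x) if (all(is.na(x))) NA_real_
                                   else max(x, na.rm = TRUE))
  out <- mm / rmax * 100
  structure(out, readout = attr(m, "readout"),
            state = c(st, "percent_of_max"), class = "intensity_matrix")
}

#' Flag outlier replicates
#'
#' For each replicate column, computes the median across peptides of the
#' absolute log2 ratio between the column's value and the median of the
#' remaining replicates in its group; columns whose deviation exceeds
#' `threshold_log2` are flagged. Flagging does not remove anything: removal
#' is a separate, explicit call ([drop_runs()]), mirroring the
#' remove-after-normalization order of the replicate workflow.
#'
#' The deviation is computed on whatever matrix is supplied. An aberrant
#' replicate usually shows both a global intensity shift and per-peptide
#' heterogeneity; total-intensity normalization absorbs the global part, so
#' flagging is most sensitive on the raw matrix (the default in
#' [run_pipeline()]), while removal is applied to the normalized one.
#'
#' @param m An `intensity_matrix`.
#' @param groups Optional named vector or design data.frame (`run_id`,
#'   `group`) assigning columns to replicate groups; by default all columns
#'   form one group. Every group needs >= 3 replicates.
#' @param threshold_log2 Flagging threshold on the median |log2 ratio|.
#'   Default 1.
#' @return An `outlier_report` data.frame: `run_id`, `group`,
#'   `median_abs_log2`, `flagged`, with the threshold as an attribute.
#' @export
detect_outliers <- function(m, groups = NULL, threshold_log2 = 1) {
  cols <- colnames(m)
  grp <- if (is.null(groups)) stats::setNames(rep("all", length(cols)), cols)
         else if (is.data.frame(groups))
           stats::setNames(as.character(groups$group), groups$run_id)[cols]
         else groups[cols]
  if (any(is.na(grp))) stop("every column needs a replicate group")
  out <- vector("list", length(cols))
  for (j in seq_along(cols)) {
    same <- setdiff(which(grp == grp[j]), j)
    if (length(same) < 2)
      stop("group '", grp[j], "' has fewer than 3 replicates; ",
           "outlier status is undecidable")
    ref <- apply(unclass(m)[, same, drop = FALSE], 1, stats::median,
                 na.rm = TRUE)
    ratio <- unclass(m)[, j] / ref
    d <- stats::median(abs(log2(ratio[is.finite(log2(ratio)) & ratio > 0])),
                       na.rm = TRUE)
    out[[j]] <- data.frame(run_id = cols[j], group = grp[j],
                           median_abs_log2 = d, flagged = !is.na(d) &&
                             d > threshold_log2, stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, out)
  attr(rep, "threshold_log2") <- threshold_log2
  class(rep) <- c("outlier_report", "data.frame")
  rep
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier report> threshold |log2| >", attr(x, "threshold_log2"), "\n")
  print.data.frame(x)
  invisible(x)
}

#' Drop runs (columns) from an intensity matrix
#'
#' The explicit removal step that follows outlier review.
#'
#' @param m An `intensity_matrix`.
#' @param run_ids Column names to remove.
#' @return The matrix without those columns, metadata preserved.
#' @export
drop_runs <- function(m, run_ids) {
  miss <- setdiff(run_ids, colnames(m))
  if (length(miss)) stop("unknown run id(s): ", paste(miss, collapse = ", "))
  .im_subset(m, cols = setdiff(colnames(m), run_ids))
}
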