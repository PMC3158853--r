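## End-to-end pipeline: read runs + peptide database + design, quantify,
## normalize, flag outliers and emit QC reports, with the exact parameter
## set echoed into every output header.

#' Pipeline configuration
#'
#' Collects every window/threshold parameter with its default: 7 ppm m/z
#' window, 5 min retention-time window, isotope-distribution correlation
#' threshold 0.95, first three isotopes.
#'
#' @param mzml_dir Directory of mzML files (one per run).
#' @param peptide_db Path to the peptide database TSV.
#' @param design Path to the design TSV (optional; enables replicate /
#'   dilution statistics).
#' @param out_dir Output directory.
#' @param ppm,tR_window,iso_threshold,n_isotopes Quantification windows and
#'   thresholds (see [quantify()]).
#' @param readout `"height"`, `"area"` or `"both"` for the QC reports.
#' @param outlier_threshold_log2 Outlier flag threshold (see
#'   [detect_outliers()]).
#' @param drop_outliers If TRUE, flagged replicates are removed before the
#'   final precision summary (flag-only otherwise).
#' @param denominator Normalization denominator (see [normalize_total()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mzml_dir, peptide_db, design = NULL, out_dir,
                            ppm = 7, tR_window = 5, iso_threshold = 0.95,
                            n_isotopes = 3L, readout = "height",
                            outlier_threshold_log2 = 1,
                            drop_outliers = FALSE,
                            denominator = "tic") {
  structure(as.list(environment()), class = "pipeline_config")
}

.config_echo <- function(config) {
  flat <- vapply(config, function(x)
    paste(format(x, trim = TRUE), collapse = ","), "")
  stats::setNames(flat, names(config))
}

#' Run the full pipeline
#'
#' Stages: read mzML runs, read and validate the peptide database, targeted
#' quantification of every (peptide, run) pair, total-intensity
#' normalization, percent-of-max scaling, outlier flagging (and optional
#' removal), and precision / linearity / accuracy reports as the design
#' allows. All outputs are TSVs whose headers echo the exact configuration;
#' outputs are deterministic given the inputs.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory results (`runs_n`,
#'   `matrices`, `results`, and any reports).
#' @export
run_pipeline <- function(config) {
  echo <- .config_echo(config)
  if (!dir.exists(config$mzml_dir))
    stop("[stage:read_runs] mzML directory not found: ", config$mzml_dir)
  files <- list.files(config$mzml_dir, pattern = "\\.mzML$", full.names = TRUE)
  if (!length(files))
    stop("[stage:read_runs] no mzML files in ", config$mzml_dir)
  message("reading ", length(files), " run(s)")
  runs <- lapply(sort(files), read_mzml)
  if (!file.exists(config$peptide_db))
    stop("[stage:read_db] peptide database not found: ", config$peptide_db)
  peptides <- read_peptide_db(config$peptide_db)
  message("quantifying ", nrow(peptides), " peptide(s) x ", length(runs),
          " run(s)")
  q <- quantify(runs, peptides, ppm = config$ppm,
                tR_window = config$tR_window,
                iso_threshold = config$iso_threshold,
                n_isotopes = config$n_isotopes)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(q$height, file.path(config$out_dir, "height_raw.tsv"), echo)
  write_matrix(q$area, file.path(config$out_dir, "area_raw.tsv"), echo)
  .write_report(q$results, file.path(config$out_dir, "quant_qc.tsv"), echo)

  design <- if (!is.null(config$design)) read_design(config$design) else NULL
  out <- list(runs_n = length(runs), results = q$results)
  readouts <- if (config$readout == "both") c("height", "area")
              else config$readout
  for (ro in readouts) {
    norm <- normalize_total(q[[ro]], runs, denominator = config$denominator)
    pct <- percent_of_max(norm)
    write_matrix(norm, file.path(config$out_dir,
                                 paste0(ro, "_normalized.tsv")), echo)
    write_matrix(pct, file.path(config$out_dir,
                                paste0(ro, "_percent_of_max.tsv")), echo)
    out[[paste0(ro, "_normalized")]] <- norm
    if (!is.null(design) && "group" %in% names(design)) {
      rep <- detect_outliers(q[[ro]], design, config$outlier_threshold_log2)
      .write_report(rep, file.path(config$out_dir,
                                   paste0(ro, "_outliers.tsv")), echo)
      use <- norm
      if (config$drop_outliers && any(rep$flagged))
        use <- drop_runs(norm, rep$run_id[rep$flagged])
      prec <- precision_summary(use, design)
      .write_report(prec$per_peptide,
                    file.path(config$out_dir, paste0(ro, "_precision.tsv")),
                    c(echo, mean_cv = format(prec$mean_cv)))
      out[[paste0(ro, "_precision")]] <- prec
      out[[paste0(ro, "_outliers")]] <- rep
    }
    if (!is.null(design) && "proportion" %in% names(design)) {
      props <- stats::setNames(design$proportion, design$run_id)[colnames(pct)]
      fits <- linearity(pct, props)
      acc <- accuracy(pct, props, fits)
      .write_report(fits, file.path(config$out_dir,
                                    paste0(ro, "_linearity.tsv")), echo)
      .write_report(acc$per_peptide,
                    file.path(config$out_dir, paste0(ro, "_accuracy.tsv")),
                    c(echo, mean_acc = format(acc$mean_acc)))
      out[[paste0(ro, "_linearity")]] <- fits
      out[[paste0(ro, "_accuracy")]] <- acc
    }
  }
  message("pipeline complete: outputs in ", config$out_dir)
  invisible(out)
}

.write_report <- function(df, path, echo = NULL) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (length(echo)) writeLines(paste0("# ", names(echo), ": ", echo), con)
  utils::write.table(as.data.frame(df), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
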