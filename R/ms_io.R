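## External formats: mzML MS1 spectra (via mzR), peptide-database and design
## tables, and intensity-matrix TSVs with append-only normalization state.

#' Construct an MS1 run
#'
#' @param run_id Run identifier.
#' @param scan_times Scan times in minutes, strictly increasing.
#' @param peaks List (one element per scan) of two-column matrices
#'   `(mz, intensity)` with strictly ascending m/z.
#' @return An `ms_run` object.
#' @export
ms_run <- function(run_id, scan_times, peaks) {
  if (length(scan_times) != length(peaks))
    stop("scan_times and peaks must have the same length")
  if (length(scan_times) > 1 && any(diff(scan_times) <= 0))
    stop("scan times must be strictly increasing")
  if (any(scan_times < 0)) stop("scan times must be >= 0")
  for (i in seq_along(peaks)) {
    p <- peaks[[i]]
    if (!is.matrix(p) || ncol(p) != 2)
      stop("peaks[[", i, "]] is not a two-column matrix")
    if (nrow(p) > 1 && any(diff(p[, 1]) <= 0))
      stop("m/z not strictly ascending in scan ", i)
    if (any(p[, 2] < 0)) stop("negative intensity in scan ", i)
  }
  structure(list(run_id = run_id, scan_times = as.numeric(scan_times),
                 peaks = peaks), class = "ms_run")
}

#' Total MS1 intensity of a run
#'
#' The normalization denominator: the summed intensity of every centroid in
#' every MS1 scan of the run ("total chromatogram intensity").
#'
#' @param run An `ms_run`.
#' @return A single non-negative number.
#' @export
total_ms1_intensity <- function(run) {
  sum(vapply(run$peaks, function(p) sum(p[, 2]), 0))
}

#' @export
print.ms_run <- function(x, ...) {
  cat(sprintf("<ms_run> %s: %d MS1 scans, %.2f-%.2f min, TIC %.4g\n",
              x$run_id, length(x$scan_times),
              if (length(x$scan_times)) min(x$scan_times) else NA,
              if (length(x$scan_times)) max(x$scan_times) else NA,
              total_ms1_intensity(x)))
  invisible(x)
}

#' Read MS1 spectra from an mzML file
#'
#' Loads the centroided MS1 scans of an mzML file into an [ms_run()].
#' MS2 (and higher) spectra are skipped and counted. Scan times are converted
#' to minutes (mzML stores them in seconds).
#'
#' @param path Path to an mzML file.
#' @param run_id Run identifier; defaults to the file name without extension.
#' @return An `ms_run`. The number of skipped non-MS1 spectra is attached as
#'   attribute `skipped_msn`.
#' @export
read_mzml <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  if (is.null(run_id)) run_id <- sub("\\.[^.]*$", "", basename(path))
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f), add = TRUE)
  hdr <- mzR::header(f)
  ms1 <- which(hdr$msLevel == 1L)
  if (!length(ms1)) stop("no MS1 spectra in ", path)
  if (!is.null(hdr$centroided) &&
      any(!is.na(hdr$centroided[ms1]) & !hdr$centroided[ms1]))
    stop("profile-mode MS1 spectra in ", path,
         ": centroid the data before quantification")
  pk <- mzR::peaks(f)
  if (is.matrix(pk)) pk <- list(pk)
  peaks <- lapply(pk[ms1], function(p) {
    p <- p[order(p[, 1]), , drop = FALSE]
    colnames(p) <- c("mz", "intensity")
    p
  })
  ord <- order(hdr$retentionTime[ms1])
  run <- ms_run(run_id, hdr$retentionTime[ms1][ord] / 60, peaks[ord])
  attr(run, "skipped_msn") <- length(hdr$msLevel) - length(ms1)
  run
}

#' Write an MS1 run to mzML
#'
#' @param run An `ms_run`.
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  n <- length(run$scan_times)
  peaks <- lapply(run$peaks, function(p) {
    colnames(p) <- c("mz", "intensity")
    p
  })
  npk <- vapply(peaks, nrow, 0L)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = npk,
    totIonCurrent = vapply(peaks, function(p) sum(p[, 2]), 0),
    retentionTime = run$scan_times * 60,
    basePeakMZ = vapply(peaks, function(p)
      if (nrow(p)) p[which.max(p[, 2]), 1] else 0, 0),
    basePeakIntensity = vapply(peaks, function(p)
      if (nrow(p)) max(p[, 2]) else 0, 0),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(peaks, function(p) if (nrow(p)) min(p[, 1]) else 0, 0),
    highMZ = vapply(peaks, function(p) if (nrow(p)) max(p[, 1]) else 0, 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(peaks, file = path, header = hdr)
  invisible(path)
}

#' Read a peptide database table
#'
#' The peptide database lists the identified peptide ions to be quantified
#' in every run: id, sequence, modification string, charge and reference
#' retention time (minutes), with optional declared monoisotopic mass and
#' Mascot-style first/second hit scores for site localization. When a
#' declared mass disagrees with the mass computed from the sequence and
#' modifications by more than `mass_tol` Da the record is flagged
#' (`mass_flag = TRUE`), not silently accepted.
#'
#' @param path TSV with header columns `id`, `sequence`, `modifications`,
#'   `charge`, `tR_min`, and optionally `mass`, `score_first`,
#'   `score_second`.
#' @param registry Modification registry.
#' @param mass_tol Tolerance (Da) for the declared-vs-computed mass check.
#' @return A data.frame of validated peptide records with derived columns
#'   `mass` (computed), `mz` and `mass_flag`.
#' @export
read_peptide_db <- function(path, registry = modification_registry(),
                            mass_tol = 0.01) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "sequence", "modifications", "charge", "tR_min")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("peptide database missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(tab))
    return(data.frame(id = character(0), sequence = character(0),
                      modifications = character(0), charge = integer(0),
                      tR_min = numeric(0), mass = numeric(0), mz = numeric(0),
                      mass_flag = logical(0), stringsAsFactors = FALSE))
  if (anyDuplicated(tab$id))
    stop("duplicate peptide id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  charge <- suppressWarnings(as.integer(tab$charge))
  if (any(is.na(charge)) || any(charge < 1))
    stop("charge must be a positive integer for every record")
  tR <- suppressWarnings(as.numeric(tab$tR_min))
  if (any(is.na(tR))) stop("non-numeric tR_min in peptide database")
  out <- data.frame(id = tab$id, sequence = tab$sequence,
                    modifications = tab$modifications, charge = charge,
                    tR_min = tR, stringsAsFactors = FALSE)
  comp_mass <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    comp <- composition_of(out$sequence[i], out$modifications[i], registry)
    comp_mass[i] <- monoisotopic_mass(comp)
  }
  out$mass <- comp_mass
  out$mz <- ion_mz(comp_mass, out$charge)
  out$mass_flag <- FALSE
  if ("mass" %in% names(tab)) {
    declared <- suppressWarnings(as.numeric(tab$mass))
    bad <- !is.na(declared) & abs(declared - comp_mass) > mass_tol
    out$mass_flag <- bad
    if (any(bad))
      warning(sum(bad), " record(s) flagged: declared mass differs from ",
              "computed mass by > ", mass_tol, " Da")
  }
  for (col in c("score_first", "score_second"))
    if (col %in% names(tab)) out[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  out
}

#' Write a peptide database table
#' @param db Peptide data.frame (as from [read_peptide_db()] or the
#'   simulator).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_db <- function(db, path) {
  cols <- intersect(c("id", "sequence", "modifications", "charge", "tR_min",
                      "mass", "score_first", "score_second"), names(db))
  utils::write.table(db[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an experimental design table
#'
#' Maps run ids to replicate groups and/or mixing proportions (percent of
#' the treated extract in the mixture, 0-100).
#'
#' @param path TSV with columns `run_id` and at least one of `group`,
#'   `proportion`.
#' @return A data.frame design table.
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"run_id" %in% names(tab)) stop("design table needs a run_id column")
  if (!any(c("group", "proportion") %in% names(tab)))
    stop("design table needs a group or proportion column")
  if (anyDuplicated(tab$run_id))
    stop("duplicate run_id(s) in design table: ",
         paste(unique(tab$run_id[duplicated(tab$run_id)]), collapse = ", "))
  if ("proportion" %in% names(tab)) {
    p <- tab$proportion
    if (any(!is.na(p) & (p < 0 | p > 100)))
      stop("mixing proportions must lie in [0, 100]")
  }
  tab
}

#' Intensity matrix constructor
#'
#' A peptides-by-runs matrix of peak heights or areas. Missing
#' quantifications are `NA` and are distinct from zero (the pipeline never
#' fabricates zeros). The normalization state is an append-only trail
#' (`raw` -> `total_normalized` -> `percent_of_max`).
#'
#' @param mat Numeric matrix with peptide-id rownames and run-id colnames.
#' @param readout `"height"` or `"area"`.
#' @param state Character vector of normalization states applied so far.
#' @return An `intensity_matrix`.
#' @export
intensity_matrix <- function(mat, readout = c("height", "area"),
                             state = "raw") {
  readout <- match.arg(readout)
  if (!is.matrix(mat) || !is.numeric(mat)) stop("mat must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("mat needs peptide-id rownames and run-id colnames")
  if (state[1] != "raw") stop("state trail must start at 'raw'")
  structure(mat, readout = readout, state = state, class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity matrix> %d peptides x %d runs, readout=%s, state=%s, %d NA\n",
              nrow(x), ncol(x), attr(x, "readout"),
              paste(attr(x, "state"), collapse = ">"), sum(is.na(x))))
  invisible(x)
}

.im_state <- function(m) attr(m, "state")

# Subset an intensity matrix while keeping its metadata.
.im_subset <- function(m, rows = NULL, cols = NULL) {
  mm <- unclass(m)
  if (!is.null(rows)) mm <- mm[rows, , drop = FALSE]
  if (!is.null(cols)) mm <- mm[, cols, drop = FALSE]
  structure(mm, readout = attr(m, "readout"), state = attr(m, "state"),
            class = "intensity_matrix")
}

#' Write / read an intensity matrix as TSV
#'
#' The TSV carries the readout and normalization-state metadata in `#`
#' header lines and encodes missing cells as `NA`; the round trip is
#' lossless.
#'
#' @param m An `intensity_matrix`.
#' @param path TSV path.
#' @param extra_header Optional named character vector written as additional
#'   `# key: value` lines (e.g. a parameter echo).
#' @return `path` (write) or an `intensity_matrix` (read).
#' @export
write_matrix <- function(m, path, extra_header = NULL) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("# readout: ", attr(m, "readout")), con)
  writeLines(paste0("# state: ", paste(attr(m, "state"), collapse = ",")), con)
  if (length(extra_header))
    writeLines(paste0("# ", names(extra_header), ": ", extra_header), con)
  df <- data.frame(peptide_id = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(hit)) stop("matrix file lacks '# ", key, ":' metadata header")
    sub(paste0("^# ", key, ": "), "", hit[1])
  }
  readout <- get_meta("readout")
  state <- strsplit(get_meta("state"), ",", fixed = TRUE)[[1]]
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df$peptide_id))
    stop("duplicate (peptide, run) entries in matrix file")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$peptide_id
  structure(mat, readout = readout, state = state, class = "intensity_matrix")
}
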