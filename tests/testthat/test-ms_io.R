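# Readers and writers: mzML, peptide database, design, intensity matrices.

test_that("ms_run validates structural invariants", {
  pk <- list(cbind(mz = c(400, 500), intensity = c(1, 2)))
  expect_s3_class(ms_run("r", 1.0, pk), "ms_run")
  expect_error(ms_run("r", c(2, 1), c(pk, pk)), "strictly increasing")
  expect_error(ms_run("r", 1.0, list(cbind(c(500, 400), c(1, 2)))),
               "ascending")
  expect_error(ms_run("r", 1.0, list(cbind(400, -1))), "negative intensity")
  run <- ms_run("r", c(1, 2), list(pk[[1]], pk[[1]]))
  expect_equal(total_ms1_intensity(run), 6)
})

test_that("mzML write-then-read round-trips an MS1 run", {
  env <- theoretical_envelope(composition_of("GGSK", "3:Phospho"), 2)
  run <- manual_gaussian_run(env, tR = 5, span_min = 10)
  path <- tempfile(fileext = ".mzML")
  write_mzml(run, path)
  back <- read_mzml(path)
  expect_equal(back$scan_times, run$scan_times, tolerance = 1e-9)
  expect_equal(unlist(lapply(back$peaks, function(p) p[, 1])),
               unlist(lapply(run$peaks, function(p) p[, 1])),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(total_ms1_intensity(back), total_ms1_intensity(run),
               tolerance = 1e-6)
  # mzML stores seconds; scan at 60 s must come back as 1.0 min
  expect_equal(back$scan_times[back$scan_times == 1.0], 1.0)
  unlink(path)
})

test_that("profile-mode and MS1-free files are rejected with clear errors", {
  env <- theoretical_envelope(composition_of("GGK"), 1)
  run <- manual_gaussian_run(env, tR = 2, span_min = 4)
  path <- tempfile(fileext = ".mzML")
  write_mzml(run, path)
  expect_error(read_mzml(tempfile(fileext = ".mzML")), "not found")
  # patch the header to claim profile mode via a low-level rewrite
  txt <- readLines(path)
  txt <- gsub("MS:1000127", "MS:1000128", txt, fixed = TRUE)  # centroid->profile
  txt <- gsub("centroid spectrum", "profile spectrum", txt, fixed = TRUE)
  path2 <- tempfile(fileext = ".mzML")
  writeLines(txt, path2)
  expect_error(read_mzml(path2), "centroid")
  unlink(c(path, path2))
})

test_that("peptide database reading validates against the chemistry module", {
  db <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsequence\tmodifications\tcharge\ttR_min",
               "p1\tGG\t\t1\t10.0"), db)
  rec <- read_peptide_db(db)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$mass, 132.05349, tolerance = 1e-5)
  expect_equal(rec$mz, ion_mz(rec$mass, 1))
  expect_false(rec$mass_flag)
  unlink(db)
})

test_that("declared masses disagreeing with computed masses are flagged, not accepted", {
  db <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsequence\tmodifications\tcharge\ttR_min\tmass",
               "p1\tGG\t\t1\t10.0\t132.5534",
               "p2\tGG\t\t2\t11.0\t132.05349"), db)
  expect_warning(rec <- read_peptide_db(db), "flagged")
  expect_equal(rec$mass_flag, c(TRUE, FALSE))
  # the stored mass stays the computed one
  expect_equal(rec$mass, rep(132.05349, 2), tolerance = 1e-5)
  unlink(db)
})

test_that("peptide database edge cases: empty file, bad charge, bad tR, bad mods", {
  db <- tempfile(fileext = ".tsv")
  writeLines("id\tsequence\tmodifications\tcharge\ttR_min", db)
  expect_equal(nrow(read_peptide_db(db)), 0)
  writeLines(c("id\tsequence\tmodifications\tcharge\ttR_min",
               "p1\tGG\t\t0\t10.0"), db)
  expect_error(read_peptide_db(db), "charge")
  writeLines(c("id\tsequence\tmodifications\tcharge\ttR_min",
               "p1\tGG\t\t1\tabc"), db)
  expect_error(read_peptide_db(db), "tR")
  writeLines(c("id\tsequence\tmodifications\tcharge\ttR_min",
               "p1\tGSK\tPhospho@2\t1\t10"), db)
  expect_error(read_peptide_db(db), "malformed modification")
  writeLines(c("id\tsequence\tmodifications\tcharge\ttR_min",
               "p1\tGG\t\t1\t10", "p1\tGG\t\t1\t11"), db)
  expect_error(read_peptide_db(db), "duplicate")
  unlink(db)
})

test_that("design tables enforce uniqueness and proportion bounds", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("run_id\tproportion", "a\t0", "b\t50", "c\t100"), f)
  expect_equal(read_design(f)$proportion, c(0, 50, 100))
  writeLines(c("run_id\tproportion", "a\t0", "a\t50"), f)
  expect_error(read_design(f), "duplicate")
  writeLines(c("run_id\tproportion", "a\t-5"), f)
  expect_error(read_design(f), "\\[0, 100\\]")
  writeLines(c("run_id\tother", "a\t1"), f)
  expect_error(read_design(f), "group or proportion")
  unlink(f)
})

test_that("intensity matrices round-trip losslessly with metadata and NA", {
  m <- matrix(c(1.5, NA, 3, 4e6), 2, 2,
              dimnames = list(c("p1", "p2"), c("r1", "r2")))
  im <- intensity_matrix(m, "area")
  path <- tempfile(fileext = ".tsv")
  write_matrix(im, path)
  txt <- readLines(path)
  expect_true(any(grepl("\tNA", txt)))
  expect_false(any(grepl("\t0\t", txt[-(1:3)])))
  back <- read_matrix(path)
  expect_equal(unclass(back), unclass(im))
  expect_equal(attr(back, "readout"), "area")
  expect_equal(attr(back, "state"), "raw")
  unlink(path)
})

test_that("matrix reading rejects missing metadata and duplicate rows", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("peptide_id\tr1", "p1\t5"), path)
  expect_error(read_matrix(path), "metadata")
  writeLines(c("# readout: height", "# state: raw",
               "peptide_id\tr1", "p1\t5", "p1\t6"), path)
  expect_error(read_matrix(path), "duplicate")
  unlink(path)
})

test_that("normalization state survives the TSV round trip", {
  m <- intensity_matrix(matrix(c(1, 2, 3, 4), 2, 2,
                               dimnames = list(c("p1", "p2"), c("r1", "r2"))),
                        "height")
  norm <- normalize_total(m, c(r1 = 10, r2 = 10))
  path <- tempfile(fileext = ".tsv")
  write_matrix(norm, path)
  back <- read_matrix(path)
  expect_equal(attr(back, "state"), c("raw", "total_normalized"))
  expect_error(normalize_total(back, c(r1 = 10, r2 = 10)),
               "already normalized")
  unlink(path)
})

test_that("files with only MS2 spectra are refused", {
  hdr <- data.frame(seqNum = 1L, acquisitionNum = 1L, msLevel = 2L,
    polarity = 1L, peaksCount = 2L, totIonCurrent = 3, retentionTime = 60,
    basePeakMZ = 500, basePeakIntensity = 2, collisionEnergy = 35,
    ionisationEnergy = 0, lowMZ = 400, highMZ = 500, precursorScanNum = 0L,
    precursorMZ = 600, precursorCharge = 2L, precursorIntensity = 100,
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_, spectrumId = "scan=1", centroided = TRUE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  path <- tempfile(fileext = ".mzML")
  mzR::writeMSData(list(cbind(mz = c(400, 500), intensity = c(1, 2))), path,
                   header = hdr)
  expect_error(read_mzml(path), "no MS1 spectra")
  unlink(path)
})
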