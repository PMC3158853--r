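## Peptide chemistry: elemental compositions, monoisotopic masses, charge-state
## m/z and aggregated (unit-mass) theoretical isotope envelopes.

# Mass of a proton (Da); charge carrier for positive-mode peptide ions.
PROTON_MASS <- 1.00727646
# Average spacing between adjacent aggregated isotope peaks of a peptide
# (dominated by 13C - 12C).
ISOTOPE_SPACING <- 1.0033548378

.chem_cache <- new.env(parent = emptyenv())

# Residue compositions of the 20 standard amino acids (residue = amino acid
# minus water, i.e. what a residue contributes inside a peptide chain).
AMINO_ACID_FORMULAS <- c(
  G = "C2 H3 N1 O1",  A = "C3 H5 N1 O1",  S = "C3 H5 N1 O2",
  P = "C5 H7 N1 O1",  V = "C5 H9 N1 O1",  T = "C4 H7 N1 O2",
  C = "C3 H5 N1 O1 S1", L = "C6 H11 N1 O1", I = "C6 H11 N1 O1",
  N = "C4 H6 N2 O2",  D = "C4 H5 N1 O3",  Q = "C5 H8 N2 O2",
  K = "C6 H12 N2 O1", E = "C5 H7 N1 O3",  M = "C5 H9 N1 O1 S1",
  H = "C6 H7 N3 O1",  F = "C9 H9 N1 O1",  R = "C6 H12 N4 O1",
  Y = "C9 H9 N1 O2",  W = "C11 H10 N2 O1")

#' Element isotope constants
#'
#' The frozen table of isotope masses and natural abundances used throughout
#' the package, shipped as a plain-text resource so that masses and envelopes
#' are reproducible across installations.
#'
#' @param path Optional path to an alternative constants table (TSV with
#'   columns `element`, `isotope_mass`, `abundance`).
#' @return A data.frame with one row per isotope, ordered by mass within each
#'   element.
#' @export
element_isotopes <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.chem_cache$isotopes)) return(.chem_cache$isotopes)
    path <- system.file("extdata", "element_isotopes.tsv", package = "xicquant")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "isotope_mass", "abundance") %in% names(tab)))
  tab <- tab[order(tab$element, tab$isotope_mass), ]
  .chem_cache$isotopes <- tab
  tab
}

.element_mono_masses <- function() {
  if (!is.null(.chem_cache$mono)) return(.chem_cache$mono)
  tab <- element_isotopes()
  mono <- vapply(split(tab, tab$element),
                 function(d) d$isotope_mass[which.min(d$isotope_mass)], 0)
  .chem_cache$mono <- mono
  mono
}

# Per-element abundance vector indexed by nominal neutron offset 0, 1, 2, ...
.element_abundance_vectors <- function() {
  if (!is.null(.chem_cache$abund)) return(.chem_cache$abund)
  tab <- element_isotopes()
  out <- lapply(split(tab, tab$element), function(d) {
    off <- round(d$isotope_mass - min(d$isotope_mass))
    v <- numeric(max(off) + 1)
    v[off + 1] <- d$abundance
    v / sum(v)
  })
  .chem_cache$abund <- out
  out
}

#' Parse a molecular formula string
#'
#' @param formula A string such as `"C4 H8 N2 O3"`. Negative counts (losses,
#'   e.g. `"H-3 N-1"` for pyroglutamate formation from Gln) are allowed.
#' @return An `elemental_composition` object (named numeric vector of element
#'   counts).
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(trimws(formula))) return(composition())
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?-?[0-9]*", formula))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = " ")) <
      nchar(gsub("\\s+", "", formula)))
    stop("malformed formula string: ", formula)
  el <- sub("(-?[0-9]*)$", "", toks)
  n <- sub("^[A-Z][a-z]?", "", toks)
  n <- ifelse(n == "", "1", n)
  composition(stats::setNames(as.numeric(n), el))
}

#' Elemental composition constructor
#'
#' @param counts Named numeric vector of element counts (elements must appear
#'   in the constants table). Counts may be negative for modification deltas.
#' @return An `elemental_composition` object.
#' @export
composition <- function(counts = numeric(0)) {
  known <- names(.element_mono_masses())
  if (length(counts)) {
    bad <- setdiff(names(counts), known)
    if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  full <- stats::setNames(numeric(length(known)), known)
  full[names(counts)] <- full[names(counts)] + counts
  structure(full, class = "elemental_composition")
}

#' @export
`+.elemental_composition` <- function(e1, e2) {
  composition(unclass(e1) + unclass(e2))
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<composition>", format_formula(x), "\n")
  invisible(x)
}

#' Format a composition back to a formula string
#' @param x An `elemental_composition`.
#' @return A string such as `"C4 H8 N2 O3"`.
#' @export
format_formula <- function(x) {
  x <- x[x != 0]
  if (!length(x)) return("(empty)")
  paste(paste0(names(x), as.integer(x)), collapse = " ")
}

.parse_mod_positions <- function(mod_string) {
  # Dialect: semicolon-separated "pos:name"; "nt"/"ct" denote the termini.
  if (is.null(mod_string) || is.na(mod_string) || !nzchar(trimws(mod_string)))
    return(data.frame(position = character(0), name = character(0),
                      stringsAsFactors = FALSE))
  parts <- trimws(strsplit(mod_string, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([0-9]+|nt|ct):(.+)$", parts))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad))
    stop("malformed modification token(s): ", paste(parts[bad], collapse = ", "))
  data.frame(position = vapply(m, `[`, "", 2L),
             name = trimws(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Modification registry
#'
#' Reads the registry of supported modifications (name, target residues or
#' terminus, compositional delta). The default registry covers the fixed and
#' variable modifications used in phosphoproteomics searches:
#' carbamidomethyl (C), oxidation (M), phospho (S/T/Y) and pyroglutamate
#' formation at the N terminus (loss of NH3 from Gln by default; the Glu
#' variant, loss of H2O, is registered as `Pyro-glu-E`).
#'
#' @param path Optional path to an alternative registry TSV with columns
#'   `name`, `target`, `delta`.
#' @return A data.frame registry.
#' @export
modification_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.chem_cache$mods)) return(.chem_cache$mods)
    path <- system.file("extdata", "modifications.tsv", package = "xicquant")
  }
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "target", "delta") %in% names(reg)))
  .chem_cache$mods <- reg
  reg
}

.mod_lookup <- function(name, registry) {
  i <- match(name, registry$name)
  if (is.na(i)) stop("unknown modification: ", name)
  registry[i, ]
}

.check_mod_target <- function(mod, position, sequence) {
  n <- nchar(sequence)
  tgt <- mod$target
  if (startsWith(tgt, "nterm:")) {
    if (!(position %in% c("nt", "1")))
      stop("modification ", mod$name, " is N-terminal; given position ", position)
    res <- substr(sequence, 1L, 1L)
    want <- sub("^nterm:", "", tgt)
    if (!grepl(res, want, fixed = TRUE))
      stop("modification ", mod$name, " requires N-terminal [", want,
           "], found ", res)
  } else if (startsWith(tgt, "cterm:")) {
    if (!(position %in% c("ct", as.character(n))))
      stop("modification ", mod$name, " is C-terminal; given position ", position)
  } else {
    p <- suppressWarnings(as.integer(position))
    if (is.na(p) || p < 1L || p > n)
      stop("modification position out of range: ", position)
    res <- substr(sequence, p, p)
    if (!grepl(res, tgt, fixed = TRUE))
      stop("modification ", mod$name, " targets [", tgt, "], found ", res,
           " at position ", p)
  }
  invisible(TRUE)
}

#' Elemental composition of a (modified) peptide
#'
#' Sums the residue compositions of the sequence, adds one water for the
#' peptide termini, and applies the compositional deltas of the listed
#' modifications.
#'
#' @param sequence Peptide sequence over the 20 standard one-letter codes.
#' @param modifications Modification string in the `"pos:name"` dialect
#'   (semicolon-separated; `nt`/`ct` for the termini), e.g.
#'   `"1:Phospho;nt:Pyro-glu"`, or a data.frame with columns `position` and
#'   `name`.
#' @param registry Modification registry (see [modification_registry()]).
#' @return An `elemental_composition`.
#' @export
composition_of <- function(sequence, modifications = "",
                           registry = modification_registry()) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!(aa %in% names(AMINO_ACID_FORMULAS)))
  if (length(bad))
    stop("unknown residue '", aa[bad[1]], "' at position ", bad[1])
  comp <- composition(c(H = 2, O = 1))  # terminal water
  for (r in aa) comp <- comp + parse_formula(AMINO_ACID_FORMULAS[[r]])
  mods <- if (is.data.frame(modifications)) modifications
          else .parse_mod_positions(modifications)
  if (nrow(mods)) {
    for (i in seq_len(nrow(mods))) {
      mod <- .mod_lookup(mods$name[i], registry)
      .check_mod_target(mod, mods$position[i], sequence)
      comp <- comp + parse_formula(mod$delta)
    }
  }
  if (any(comp < 0))
    stop("modification deltas drive element counts negative")
  comp
}

#' Monoisotopic mass of a composition
#'
#' @param comp An `elemental_composition` (negative counts allowed, so the
#'   mass of a modification delta can be computed directly).
#' @return Mass in Da, using the lightest isotope of each element.
#' @export
monoisotopic_mass <- function(comp) {
  mono <- .element_mono_masses()
  sum(unclass(comp)[names(mono)] * mono)
}

#' m/z of a positively charged ion
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param z Charge state (positive integer).
#' @return m/z in Th: `(mass + z * 1.00727646) / z`.
#' @export
ion_mz <- function(mass, z) {
  if (any(z < 1) || any(z != round(z))) stop("charge z must be a positive integer")
  (mass + z * PROTON_MASS) / z
}

# Truncated linear convolution: first k terms of conv(a, b).
.conv_trunc <- function(a, b, k) {
  la <- min(length(a), k); lb <- min(length(b), k)
  out <- numeric(k)
  for (i in seq_len(la)) {
    jmax <- min(lb, k - i + 1L)
    if (jmax >= 1L)
      out[i:(i + jmax - 1L)] <- out[i:(i + jmax - 1L)] + a[i] * b[seq_len(jmax)]
  }
  out
}

# n-fold self-convolution by binary exponentiation, truncated to k terms.
.conv_power <- function(v, n, k) {
  out <- c(1, numeric(k - 1L))
  base <- v
  while (n > 0) {
    if (n %% 2 == 1) out <- .conv_trunc(out, base, k)
    base <- .conv_trunc(base, base, k)
    n <- n %/% 2
  }
  out
}

#' Theoretical isotope envelope of a peptide ion
#'
#' Computes the aggregated (unit-mass-binned) isotopic distribution of a
#' composition by convolving the per-element natural isotope abundance
#' vectors, truncates it to the first `n_isotopes` peaks (A, A+1, A+2 by
#' default) and rescales so the most abundant retained peak equals 1. The
#' m/z values are spaced by `1.0033548/z` from the monoisotopic m/z.
#'
#' @param comp An `elemental_composition` with non-negative counts.
#' @param z Charge state.
#' @param n_isotopes Number of isotope peaks to retain (default 3).
#' @return An `isotope_envelope`: list with `mz`, `abundance` (max = 1) and
#'   `z`.
#' @export
theoretical_envelope <- function(comp, z, n_isotopes = 3L) {
  if (any(comp < 0)) stop("composition must be non-negative for an envelope")
  if (n_isotopes < 1L) stop("n_isotopes must be >= 1")
  abund <- .element_abundance_vectors()
  dist <- c(1, numeric(n_isotopes - 1L))
  counts <- unclass(comp)
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n > 0) dist <- .conv_trunc(dist, .conv_power(abund[[el]], n, n_isotopes),
                                   n_isotopes)
  }
  mono_mz <- ion_mz(monoisotopic_mass(comp), z)
  structure(list(
    mz = mono_mz + (seq_len(n_isotopes) - 1L) * ISOTOPE_SPACING / z,
    abundance = dist / max(dist),
    z = as.integer(z)), class = "isotope_envelope")
}

#' @export
print.isotope_envelope <- function(x, ...) {
  cat("<isotope envelope> z =", x$z, "\n")
  print(data.frame(mz = x$mz, abundance = x$abundance))
  invisible(x)
}

#' Construct a peptide ion
#'
#' An identified, modified peptide at a given charge state with a reference
#' retention time: the quantification target of the pipeline. Monoisotopic
#' mass and m/z are derived from the sequence and modifications.
#'
#' @param sequence Peptide sequence (20 standard one-letter codes).
#' @param modifications Modification string (`"pos:name"` dialect) or
#'   data.frame.
#' @param charge Charge state (positive integer).
#' @param tR Reference retention time in minutes.
#' @param id Optional identifier.
#' @param registry Modification registry.
#' @return A `peptide_ion` object with fields `id`, `sequence`,
#'   `modifications`, `charge`, `tR`, `composition`, `mass`, `mz`.
#' @export
peptide_ion <- function(sequence, modifications = "", charge, tR = NA_real_,
                        id = NULL, registry = modification_registry()) {
  comp <- composition_of(sequence, modifications, registry)
  mass <- monoisotopic_mass(comp)
  structure(list(
    id = if (is.null(id)) paste0(sequence, "/", charge) else id,
    sequence = sequence,
    modifications = if (is.data.frame(modifications)) modifications
                    else .parse_mod_positions(modifications),
    charge = as.integer(charge),
    tR = tR,
    composition = comp,
    mass = mass,
    mz = ion_mz(mass, charge)), class = "peptide_ion")
}

#' @export
print.peptide_ion <- function(x, ...) {
  mods <- if (nrow(x$modifications))
    paste(paste0(x$modifications$position, ":", x$modifications$name),
          collapse = ";") else "none"
  cat(sprintf("<peptide ion> %s  z=%d  m/z %.5f  tR %.2f min  mods: %s\n",
              x$sequence, x$charge, x$mz, x$tR, mods))
  invisible(x)
}
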