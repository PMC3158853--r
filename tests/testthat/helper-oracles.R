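# Independent oracles used across test files.

# Exhaustive isotopologue enumeration of the aggregated isotope distribution.
# Per element, all ways of distributing n atoms over its isotopes are
# enumerated with multinomial probabilities; per-element offset distributions
# are then combined by enumerating offset combinations. Independent of the
# package's truncated-convolution implementation.
oracle_envelope <- function(counts, k = 3L) {
  iso <- element_isotopes()
  elem_dist <- list()
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0) next
    d <- iso[iso$element == el, ]
    off <- round(d$isotope_mass - min(d$isotope_mass))
    p <- d$abundance / sum(d$abundance)
    m <- length(p)
    grids <- rep(list(0:n), m)
    combos <- as.matrix(do.call(expand.grid, grids))
    combos <- combos[rowSums(combos) == n, , drop = FALSE]
    prob <- apply(combos, 1, function(ks)
      exp(lfactorial(n) - sum(lfactorial(ks)) + sum(ks * log(p + (p == 0)))) *
        prod((p > 0 | ks == 0)))
    offs <- as.vector(combos %*% off)
    agg <- tapply(prob, offs, sum)
    elem_dist[[el]] <- stats::setNames(as.numeric(agg),
                                       names(agg))
  }
  if (!length(elem_dist)) return(c(1, numeric(k - 1L)))
  total <- c(`0` = 1)
  for (d in elem_dist) {
    grid <- expand.grid(a = as.numeric(names(total)),
                        b = as.numeric(names(d)))
    p <- as.vector(outer(unname(total), unname(d)))
    agg <- tapply(p, grid$a + grid$b, sum)
    total <- stats::setNames(as.numeric(agg), names(agg))
  }
  out <- numeric(k)
  for (j in seq_len(k)) {
    hit <- which(as.numeric(names(total)) == j - 1)
    if (length(hit)) out[j] <- total[hit]
  }
  out
}

# A tiny deterministic one-peptide run built directly from a Gaussian,
# bypassing the simulator, for quant unit tests.
manual_gaussian_run <- function(envelope, tR = 10, height = 1000,
                                sigma_s = 7.5, interval_s = 2.5,
                                span_min = 20, run_id = "manual") {
  scan_t <- seq(0, span_min, by = interval_s / 60)
  amps <- height * envelope$abundance / sum(envelope$abundance)
  peaks <- lapply(scan_t, function(t) {
    g <- exp(-((t - tR) * 60)^2 / (2 * sigma_s^2))
    if (g < 1e-12)
      return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("mz", "intensity"))))
    cbind(mz = envelope$mz, intensity = amps * g)
  })
  ms_run(run_id, scan_t, peaks)
}

random_composition <- function(max_atoms = 15) {
  els <- c("C", "H", "N", "O", "S", "P")
  repeat {
    n <- sample(0:5, 6, replace = TRUE)
    if (sum(n) > 0 && sum(n) <= max_atoms) break
  }
  composition(stats::setNames(n, els))
}
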