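# Independent oracles used to freeze expected values.  Deliberately written
# along a different derivation route from the package: full 5'-nucleoside
# monophosphates condensed with water loss, molecular formulas as strings,
# and a private copy of the atomic-mass table.

oracle_atomic <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, P = 30.97376163,
                   Na = 22.9897692809, K = 38.96370668)

oracle_parse_formula <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  counts <- stats::setNames(numeric(length(oracle_atomic)), names(oracle_atomic))
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[A-Za-z]", "", p)
    counts[el] <- counts[el] + if (nzchar(n)) as.numeric(n) else 1
  }
  counts
}

# full 5'-nucleoside monophosphates (free acids)
oracle_nmp <- list(A = "C10H14N5O7P", C = "C9H14N3O8P",
                   G = "C10H14N5O8P", U = "C9H13N2O9P")
oracle_h2o <- oracle_parse_formula("H2O")
oracle_hpo3 <- oracle_parse_formula("HPO3")
oracle_ch2 <- oracle_parse_formula("CH2")

# chain = sum of NMPs minus (n-1) waters => 5'-phosphate / 3'-OH oligo
oracle_oligo_counts <- function(seq, five_prime = "phosphate",
                                three_prime = "hydroxyl", n_methyl = 0) {
  bases <- strsplit(seq, "")[[1]]
  counts <- Reduce(`+`, lapply(bases, function(b) {
    oracle_parse_formula(oracle_nmp[[b]])
  }))
  counts <- counts - (length(bases) - 1) * oracle_h2o
  if (five_prime == "hydroxyl") counts <- counts - oracle_hpo3
  if (three_prime == "phosphate") counts <- counts + oracle_hpo3
  if (three_prime == "cyclic_phosphate") {
    counts <- counts + oracle_hpo3 - oracle_h2o
  }
  counts + n_methyl * oracle_ch2
}

oracle_oligo_mass <- function(seq, five_prime = "phosphate",
                              three_prime = "hydroxyl", n_methyl = 0) {
  sum(oracle_oligo_counts(seq, five_prime, three_prime, n_methyl) *
        oracle_atomic)
}

# exhaustive isotopologue enumeration (feasible for small atom counts),
# aggregated by nucleon count like the package's unit-mass binning
oracle_isotopes <- list(
  C = data.frame(dn = 0:1, mass = c(12, 13.0033548378),
                 p = c(0.9893, 0.0107)),
  H = data.frame(dn = 0:1, mass = c(1.00782503207, 2.01410177785),
                 p = c(0.999885, 0.000115)),
  N = data.frame(dn = 0:1, mass = c(14.0030740048, 15.0001088989),
                 p = c(0.99636, 0.00364)),
  O = data.frame(dn = 0:2,
                 mass = c(15.9949146196, 16.9991317012, 17.9991610041),
                 p = c(0.99757, 0.00038, 0.00205)),
  P = data.frame(dn = 0, mass = 30.97376163, p = 1),
  Na = data.frame(dn = 0, mass = 22.9897692809, p = 1),
  K = data.frame(dn = 0:2, mass = c(38.96370668, 39.96399848, 40.96182576),
                 p = c(0.932581, 0.000117, 0.067302))
)

oracle_envelope <- function(counts) {
  atoms <- rep(names(counts), counts)
  stopifnot(length(atoms) <= 8)
  choices <- lapply(atoms, function(el) seq_len(nrow(oracle_isotopes[[el]])))
  grid <- do.call(expand.grid, choices)
  res <- data.frame(dn = integer(nrow(grid)), mass = 0, p = 1)
  for (j in seq_along(atoms)) {
    iso <- oracle_isotopes[[atoms[j]]]
    res$dn <- res$dn + iso$dn[grid[[j]]]
    res$mass <- res$mass + iso$mass[grid[[j]]]
    res$p <- res$p * iso$p[grid[[j]]]
  }
  agg_p <- tapply(res$p, res$dn, sum)
  agg_m <- tapply(res$p * res$mass, res$dn, sum) / agg_p
  data.frame(dn = as.integer(names(agg_p)), mass = as.numeric(agg_m),
             abundance = as.numeric(agg_p))
}

# brute-force pairwise AUC (ties count one half)
oracle_auc <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls) {
    s <- s + (x > y) + 0.5 * (x == y)
  }
  s / (length(cases) * length(controls))
}

random_oligo_seq <- function(n, min_ac = 0) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
    if (sum(strsplit(s, "")[[1]] %in% c("A", "C")) >= min_ac) return(s)
  }
}
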