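# Single source of truth for atomic masses and isotope abundances.
# Monoisotopic masses and isotopic compositions: IUPAC/CIAAW 2013 tables
# (as tabulated in the AME2012-derived CIAAW compilation); average masses:
# IUPAC 2021 standard atomic weights (conventional values).

.ELEMENTS <- c("C", "H", "N", "O", "P", "Na", "K")

.MONO_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  Na = 22.9897692809,
  K  = 38.96370668
)

.AVG_MASS <- c(
  C  = 12.011,
  H  = 1.008,
  N  = 14.007,
  O  = 15.999,
  P  = 30.973761998,
  Na = 22.98976928,
  K  = 39.0983
)

# Isotope tables keyed by element; `dn` is the neutron excess over the
# lightest isotope (the unit-mass bin offset used by isotope_envelope()).
.ISOTOPES <- list(
  C  = data.frame(dn = 0:1, mass = c(12.0, 13.0033548378),
                  abundance = c(0.9893, 0.0107)),
  H  = data.frame(dn = 0:1, mass = c(1.00782503207, 2.01410177785),
                  abundance = c(0.999885, 0.000115)),
  N  = data.frame(dn = 0:1, mass = c(14.0030740048, 15.0001088989),
                  abundance = c(0.99636, 0.00364)),
  O  = data.frame(dn = 0:2, mass = c(15.9949146196, 16.9991317012, 17.9991610041),
                  abundance = c(0.99757, 0.00038, 0.00205)),
  P  = data.frame(dn = 0, mass = 30.97376163, abundance = 1.0),
  Na = data.frame(dn = 0, mass = 22.9897692809, abundance = 1.0),
  K  = data.frame(dn = 0:2, mass = c(38.96370668, 39.96399848, 40.96182576),
                  abundance = c(0.932581, 0.000117, 0.067302))
)

# CODATA mass of the proton (Da); used for negative-mode [M - zH]^z- m/z.
.PROTON_MASS <- 1.007276466621

# Residue = nucleoside-3'-monophosphate minus water.  Summing residues and
# adding one water yields the 5'-phosphate / 3'-hydroxyl oligonucleotide.
.RESIDUE_COMP <- list(
  A = c(C = 10, H = 12, N = 5, O = 6, P = 1),
  C = c(C = 9,  H = 12, N = 3, O = 7, P = 1),
  G = c(C = 10, H = 12, N = 5, O = 7, P = 1),
  U = c(C = 9,  H = 11, N = 2, O = 8, P = 1)
)

# Free nucleobases (neutral BH), lost by a-B ions and hydrazine chemistry.
.BASE_COMP <- list(
  A = c(C = 5, H = 5, N = 5),
  C = c(C = 4, H = 5, N = 3, O = 1),
  G = c(C = 5, H = 5, N = 5, O = 1),
  U = c(C = 4, H = 4, N = 2, O = 2)
)

.H2O  <- c(H = 2, O = 1)
.HPO3 <- c(H = 1, P = 1, O = 3)
.CH2  <- c(C = 1, H = 2)

# Methyl modifications on mature miRNAs.  All four are base methyls with a
# +CH2 elemental delta.  `blocks_n1` marks m1A (its adenine N1 carries the
# methyl and is unreactive to dimethyl sulfate); `hydrazine_protective`
# marks m5C (resistant to hydrazine-mediated cleavage).
.MODIFICATIONS <- list(
  m6A = list(id = "m6A", parent = "A", delta = c(C = 1, H = 2),
             blocks_n1 = FALSE, hydrazine_protective = FALSE),
  m1A = list(id = "m1A", parent = "A", delta = c(C = 1, H = 2),
             blocks_n1 = TRUE, hydrazine_protective = FALSE),
  m5C = list(id = "m5C", parent = "C", delta = c(C = 1, H = 2),
             blocks_n1 = FALSE, hydrazine_protective = TRUE),
  m3C = list(id = "m3C", parent = "C", delta = c(C = 1, H = 2),
             blocks_n1 = FALSE, hydrazine_protective = FALSE)
)

#' Monoisotopic mass of a methyl group increment (CH2)
#'
#' The nominal "+14 Da" spacing between consecutive methylated species of an
#' intact miRNA: 14.01565 Da monoisotopic.
#'
#' @return Monoisotopic mass of CH2 in daltons.
#' @export
#' @examples
#' methyl_delta_mass()
methyl_delta_mass <- function() {
  unname(.MONO_MASS["C"] + 2 * .MONO_MASS["H"])
}

#' Modification registry lookup
#'
#' @param id One of `"m6A"`, `"m1A"`, `"m5C"`, `"m3C"`.
#' @return A list with fields `id`, `parent` (parent base), `delta`
#'   (elemental composition of the methyl increment), `blocks_n1`,
#'   `hydrazine_protective`.
#' @export
modification <- function(id) {
  mod <- .MODIFICATIONS[[match.arg(id, names(.MODIFICATIONS))]]
  mod
}
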