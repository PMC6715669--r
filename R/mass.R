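#' Elemental composition of an RNA oligonucleotide
#'
#' Each residue is modeled as a nucleoside-3'-monophosphate minus water; the
#' residue sum plus one water gives the 5'-phosphate / 3'-hydroxyl chain.
#' Terminal chemistry then adjusts: a 5'-hydroxyl removes HPO3, a
#' 3'-phosphate adds HPO3, a 2',3'-cyclic phosphate adds HPO3 - H2O.
#' Every base-methyl modification contributes +CH2.
#'
#' @param x An [oligo()].
#' @return An [elem_comp()].
#' @export
#' @examples
#' oligo_composition(oligo("A"))  # pA == C10H14N5O7P
oligo_composition <- function(x) {
  stopifnot(inherits(x, "oligo"))
  counts <- table(factor(x$seq, levels = c("A", "C", "G", "U")))
  total <- stats::setNames(numeric(length(.ELEMENTS)), .ELEMENTS)
  for (b in names(counts)) {
    if (counts[[b]] > 0) {
      r <- .as_comp_vec(.RESIDUE_COMP[[b]])
      total <- total + counts[[b]] * r
    }
  }
  total <- total + .as_comp_vec(.H2O)
  if (x$five_prime == "hydroxyl") total <- total - .as_comp_vec(.HPO3)
  if (x$three_prime == "phosphate") total <- total + .as_comp_vec(.HPO3)
  if (x$three_prime == "cyclic_phosphate") {
    total <- total + .as_comp_vec(.HPO3) - .as_comp_vec(.H2O)
  }
  if (nrow(x$mods)) {
    for (id in x$mods$id) {
      total <- total + .as_comp_vec(.MODIFICATIONS[[id]]$delta)
    }
  }
  elem_comp(stats::setNames(as.integer(total), names(total)))
}

#' Neutral mass of an RNA oligonucleotide
#'
#' @param x An [oligo()], or anything [oligo()] accepts as `seq` (convenience:
#'   a plain string builds a default 5'-phosphate/3'-hydroxyl oligo).
#' @param kind `"monoisotopic"` (default) or `"average"`.
#' @return Neutral mass in daltons.  Adding any single methyl modification
#'   increases the monoisotopic mass by 14.01565 Da — the nominal "+14 Da"
#'   spacing used to detect methylated species.
#' @export
#' @examples
#' oligo_mass(oligo("A"))                      # 347.06308
#' oligo_mass(oligo("A", mods = "1:m6A")) - oligo_mass(oligo("A"))
oligo_mass <- function(x, kind = c("monoisotopic", "average")) {
  if (is.character(x)) x <- oligo(x)
  comp_mass(oligo_composition(x), kind = match.arg(kind))
}

#' m/z of a neutral mass in negative-ion mode
#'
#' MALDI-TOF here runs in negative-ion reflectron mode; observed ions are
#' `[M - zH]^z-`, so m/z = (M - z * m_proton) / z.  Positive polarity is
#' deliberately unsupported.
#'
#' @param neutral_mass Neutral mass in Da.
#' @param charge Positive integer charge count (number of protons removed).
#' @param polarity Must be `"negative"`.
#' @return m/z value.
#' @export
#' @examples
#' mz_from_mass(347.06308, 1)
mz_from_mass <- function(neutral_mass, charge = 1L, polarity = "negative") {
  if (!identical(polarity, "negative")) {
    stop("only negative-ion mode is supported (MALDI of nucleic acids is ",
         "acquired as [M - zH]^z-)", call. = FALSE)
  }
  if (any(charge < 1) || any(charge != round(charge))) {
    stop("`charge` must be a positive integer", call. = FALSE)
  }
  (neutral_mass - charge * .PROTON_MASS) / charge
}

#' Invert [mz_from_mass()]
#'
#' @param mz Observed m/z.
#' @param charge Positive integer charge count.
#' @param polarity Must be `"negative"`.
#' @return Neutral mass in Da.
#' @export
neutral_from_mz <- function(mz, charge = 1L, polarity = "negative") {
  if (!identical(polarity, "negative")) {
    stop("only negative-ion mode is supported", call. = FALSE)
  }
  if (any(charge < 1) || any(charge != round(charge))) {
    stop("`charge` must be a positive integer", call. = FALSE)
  }
  mz * charge + charge * .PROTON_MASS
}

# Convolve two unit-mass-binned distributions.  Each is a list with
# `p` (probability per extra-neutron bin, starting at 0) and `m`
# (probability-weighted mass moment per bin).
.conv_dist <- function(a, b, prune = 1e-15) {
  la <- length(a$p); lb <- length(b$p)
  p <- numeric(la + lb - 1L)
  m <- numeric(la + lb - 1L)
  for (i in seq_len(la)) {
    if (a$p[i] == 0) next
    j <- seq_len(lb)
    k <- i + j - 1L
    pij <- a$p[i] * b$p
    p[k] <- p[k] + pij
    # mass moment of a sum: E[p * (ma + mb)] accumulated per bin
    m[k] <- m[k] + a$m[i] * b$p + a$p[i] * b$m
  }
  keep <- which(p > prune)
  if (!length(keep)) keep <- which.max(p)
  hi <- max(keep)
  list(p = p[seq_len(hi)], m = m[seq_len(hi)])
}

.dist_pow <- function(d, n) {
  out <- list(p = 1, m = 0)   # identity (zero atoms)
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) out <- .conv_dist(out, base)
    n <- n %/% 2
    if (n > 0) base <- .conv_dist(base, base)
  }
  out
}

#' Isotope envelope of an elemental composition
#'
#' Aggregated isotope distribution computed by per-element convolution of
#' isotopologue probabilities, binned by nucleon count (unit-mass binning —
#' sufficient at MALDI-TOF resolution).  Each reported mass is the
#' probability-weighted mean mass of its bin.
#'
#' @param comp An [elem_comp()] (or an [oligo()], whose composition is used).
#' @param truncation Total abundance allowed to be dropped from the tail;
#'   must lie in (0, 0.01].  The retained abundances sum to at least
#'   `1 - truncation`.
#' @return Data frame with columns `mass` (Da, strictly increasing) and
#'   `abundance` (probabilities in (0, 1]); attribute `truncation`.
#' @export
#' @examples
#' isotope_envelope(elem_comp(C = 1))
isotope_envelope <- function(comp, truncation = 1e-4) {
  if (inherits(comp, "oligo")) comp <- oligo_composition(comp)
  stopifnot(inherits(comp, "elem_comp"))
  if (!(truncation > 0 && truncation <= 0.01)) {
    stop("`truncation` must lie in (0, 0.01]", call. = FALSE)
  }
  v <- .as_comp_vec(unclass(comp))
  if (sum(v) == 0) stop("empty composition has no isotope envelope",
                        call. = FALSE)
  acc <- list(p = 1, m = 0)
  for (el in names(v)) {
    if (v[[el]] == 0) next
    iso <- .ISOTOPES[[el]]
    p <- numeric(max(iso$dn) + 1L)
    m <- numeric(max(iso$dn) + 1L)
    p[iso$dn + 1L] <- iso$abundance
    m[iso$dn + 1L] <- iso$abundance * iso$mass
    acc <- .conv_dist(acc, .dist_pow(list(p = p, m = m), v[[el]]))
  }
  mass <- ifelse(acc$p > 0, acc$m / acc$p, NA_real_)
  ord <- order(acc$p, decreasing = TRUE)
  keep_n <- which(cumsum(acc$p[ord]) >= 1 - truncation)[1]
  keep <- sort(ord[seq_len(keep_n)])
  keep <- keep[acc$p[keep] > 0]
  out <- data.frame(mass = mass[keep], abundance = acc$p[keep])
  out <- out[order(out$mass), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truncation") <- truncation
  out
}
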