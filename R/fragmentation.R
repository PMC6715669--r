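#' Theoretical MS/MS fragment ladder for an RNA oligonucleotide
#'
#' Generates the nucleic-acid backbone ion series in McLuckey nomenclature:
#' 5'-anchored a/b/c/d ions (plus a-B, the a ion after neutral loss of its
#' 3'-terminal nucleobase) and 3'-anchored w/x/y/z ions.  For a chain of
#' length n there are n - 1 cleavage positions, hence n - 1 ions per series.
#' Complementary pairs (a_i, w_{n-i}), (b_i, x_{n-i}), (c_i, y_{n-i}),
#' (d_i, z_{n-i}) sum to the precursor neutral mass.
#'
#' Neutral masses relative to the 5' prefix (prefix_i = positions 1..i with
#' the parent's 5' terminus and a 3'-OH) and the 3' suffix (suffix_j = the
#' last j positions with a 5'-OH and the parent's 3' terminus):
#' a = prefix - H2O, b = prefix, c = prefix + HPO3 - H2O, d = prefix + HPO3,
#' w = suffix + HPO3, x = suffix + HPO3 - H2O, y = suffix, z = suffix - H2O.
#'
#' A base methyl shifts every ion whose span contains the modified position;
#' the one exception is a-B at the modified base itself, where the methyl
#' departs with the lost base.
#'
#' @param x An [oligo()] of length >= 2.
#' @param series Character vector, subset of
#'   `c("a", "a-B", "b", "c", "d", "w", "x", "y", "z")`.  Default
#'   `c("c", "y", "w", "a-B")`, the series commonly dominant for RNA in
#'   negative mode.
#' @param charges Integer vector of charge states (negative mode); default 1,
#'   MALDI being predominantly singly charged.
#' @return Data frame with columns `series`, `index`, `charge`,
#'   `neutral_mass`, `mz`, `contains_from`, `contains_to`, ordered by
#'   requested series, then index, then charge.
#' @export
#' @examples
#' fragment_ladder(oligo("UGAGG"), series = c("c", "w", "y"))
fragment_ladder <- function(x,
                            series = c("c", "y", "w", "a-B"),
                            charges = 1L) {
  stopifnot(inherits(x, "oligo"))
  n <- length(x$seq)
  if (n < 2) stop("fragmentation requires an oligo of length >= 2",
                  call. = FALSE)
  all_series <- c("a", "a-B", "b", "c", "d", "w", "x", "y", "z")
  bad <- setdiff(series, all_series)
  if (length(bad)) stop("unknown ion series: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  charges <- as.integer(charges)
  if (any(charges < 1)) stop("charges must be positive integers", call. = FALSE)

  h2o <- comp_mass(elem_comp(.H2O))
  hpo3 <- comp_mass(elem_comp(.HPO3))
  ch2 <- methyl_delta_mass()

  mod_at <- stats::setNames(rep(NA_character_, n), NULL)
  if (nrow(x$mods)) mod_at[x$mods$position] <- x$mods$id

  # residue + modification masses per position, then prefix/suffix sums
  res_mass <- vapply(x$seq, function(b) comp_mass(elem_comp(.RESIDUE_COMP[[b]])),
                     numeric(1))
  res_mass <- res_mass + ifelse(is.na(mod_at), 0, ch2)
  five_adj <- if (x$five_prime == "hydroxyl") -hpo3 else 0
  three_adj <- switch(x$three_prime,
                      hydroxyl = 0, phosphate = hpo3,
                      cyclic_phosphate = hpo3 - h2o)
  prefix <- cumsum(res_mass)[seq_len(n - 1L)] + h2o + five_adj
  # tail_sum[p] = residue masses over positions p..n; a suffix starting at p
  # carries a 5'-OH (hence - HPO3) and the parent's 3' terminus
  tail_sum <- rev(cumsum(rev(res_mass)))
  suffix_mass <- tail_sum + h2o - hpo3 + three_adj

  base_mass <- vapply(seq_len(n), function(p) {
    bm <- comp_mass(elem_comp(.BASE_COMP[[x$seq[p]]]))
    if (!is.na(mod_at[p])) bm <- bm + ch2
    bm
  }, numeric(1))

  idx <- seq_len(n - 1L)
  rows <- list()
  for (s in series) {
    if (s %in% c("a", "a-B", "b", "c", "d")) {
      nm <- switch(s,
                   "a" = prefix - h2o,
                   "a-B" = prefix - h2o - base_mass[idx],
                   "b" = prefix,
                   "c" = prefix + hpo3 - h2o,
                   "d" = prefix + hpo3)
      rows[[s]] <- data.frame(series = s, index = idx, neutral_mass = nm,
                              contains_from = 1L, contains_to = idx,
                              stringsAsFactors = FALSE)
    } else {
      span_from <- n - idx + 1L
      nm_suffix <- suffix_mass[span_from]
      nm <- switch(s,
                   "w" = nm_suffix + hpo3,
                   "x" = nm_suffix + hpo3 - h2o,
                   "y" = nm_suffix,
                   "z" = nm_suffix - h2o)
      rows[[s]] <- data.frame(series = s, index = idx, neutral_mass = nm,
                              contains_from = span_from, contains_to = n,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- merge(out, data.frame(charge = charges), by = NULL)
  out$mz <- mz_from_mass(out$neutral_mass, out$charge)
  out <- out[order(match(out$series, series), out$index, out$charge), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("series", "index", "charge", "neutral_mass", "mz",
          "contains_from", "contains_to")]
}
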