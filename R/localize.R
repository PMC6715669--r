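# Site localization from MS/MS ladders and modification typing via
# derivatization mass-shift logic (hydrazine for m5C, dimethyl sulfate for
# m6A vs m1A).

#' Localize a methyl modification from an MS/MS spectrum
#'
#' For every legal candidate position p (residues matching the
#' modification's parent base), the methyl is placed at p, the theoretical
#' fragment ladder generated, and observed peaks matched within `tol_ppm`.
#' A matched fragment *supports* p when it matches only under placement p,
#' and *contradicts* p when it fails under p but matches under some other
#' placement; the score is supporting minus contradicting fragment counts.
#' Positions are ranked by score; the positions tied at the top score form
#' the ambiguity set.
#'
#' @param msms A [peaklist()] of the fragment spectrum.
#' @param x An [oligo()] (without the methyl being localized; any fixed
#'   modifications it already carries are kept on every hypothesis).
#' @param mod Modification id (`"m6A"`, `"m1A"`, `"m5C"`, `"m3C"`) or a
#'   [modification()] object.
#' @param tol_ppm Fragment match tolerance in ppm (default 100; MS/MS
#'   accuracy is poorer than intact MS).
#' @param series Ion series used (default `c("c", "y", "w", "a-B")`).
#' @return Data frame of class `site_assignment`, one row per candidate
#'   position, ranked by descending score: `position`, `mod`, `score`,
#'   `n_supporting`, `n_contradicting`, `n_matched`, `top` (logical);
#'   attribute `ambiguity` is the integer vector of top-tied positions.
#' @export
localize <- function(msms, x, mod, tol_ppm = 100,
                     series = c("c", "y", "w", "a-B")) {
  stopifnot(inherits(msms, "peaklist"), inherits(x, "oligo"))
  if (is.character(mod)) mod <- modification(mod)
  candidates <- setdiff(which(x$seq == mod$parent), x$mods$position)
  if (!length(candidates)) {
    stop("no candidate positions: sequence has no unmodified ", mod$parent,
         " residue", call. = FALSE)
  }
  ladders <- lapply(candidates, function(p) {
    mods_p <- rbind(x$mods,
                    data.frame(position = p, id = mod$id,
                               stringsAsFactors = FALSE))
    fragment_ladder(oligo(paste(x$seq, collapse = ""),
                          five_prime = x$five_prime,
                          three_prime = x$three_prime, mods = mods_p),
                    series = series)
  })
  # matched[h, f]: does hypothesis h's fragment f hit an observed peak?
  nf <- nrow(ladders[[1]])
  matched <- matrix(FALSE, length(candidates), nf)
  if (nrow(msms)) {
    for (h in seq_along(ladders)) {
      mzs <- ladders[[h]]$mz
      for (f in seq_len(nf)) {
        matched[h, f] <-
          any(abs(msms$mz - mzs[f]) / mzs[f] * 1e6 <= tol_ppm)
      }
    }
  }
  n_hyp <- length(candidates)
  support <- contradict <- integer(n_hyp)
  for (h in seq_len(n_hyp)) {
    others <- matched[-h, , drop = FALSE]
    any_other <- if (n_hyp > 1) apply(others, 2, any) else rep(FALSE, nf)
    support[h] <- sum(matched[h, ] & !any_other)
    contradict[h] <- sum(!matched[h, ] & any_other)
  }
  score <- support - contradict
  ord <- order(score, candidates, decreasing = c(TRUE, FALSE),
               method = "radix")
  out <- data.frame(position = candidates[ord], mod = mod$id,
                    score = score[ord], n_supporting = support[ord],
                    n_contradicting = contradict[ord],
                    n_matched = rowSums(matched)[ord],
                    stringsAsFactors = FALSE)
  out$top <- out$score == out$score[1]
  rownames(out) <- NULL
  attr(out, "ambiguity") <- out$position[out$top]
  class(out) <- c("site_assignment", "data.frame")
  out
}

#' Expected hydrazine cleavage products
#'
#' Hydrazine (followed by aniline scission) cleaves RNA at cytosines;
#' 5-methylcytosine is resistant.  The model cleaves at every unprotected
#' C, excising that nucleotide; each resulting segment keeps the parent
#' terminus on an original end and gains a phosphate on a cut end.
#' Comparing observed against predicted product masses over candidate
#' protected sets identifies m5C positions.
#'
#' @param x An [oligo()]; its m5C modifications are protected by default.
#' @param protected_positions Positions treated as m5C-protected.  Must be
#'   cytosines.  Default: positions of the oligo's m5C modifications.
#' @return Data frame with columns `from`, `to` (1-based segment span) and
#'   `neutral_mass`; zero rows if the whole sequence is cleaved away.
#'   With no unprotected C, the single row is the intact oligo.
#' @export
hydrazine_cleavage_pattern <- function(x, protected_positions = NULL) {
  stopifnot(inherits(x, "oligo"))
  if (is.null(protected_positions)) {
    protected_positions <- x$mods$position[x$mods$id == "m5C"]
  }
  protected_positions <- as.integer(protected_positions)
  if (any(protected_positions < 1 | protected_positions > length(x$seq))) {
    stop("protected position outside the sequence", call. = FALSE)
  }
  if (any(x$seq[protected_positions] != "C")) {
    stop("protected positions must be cytosines", call. = FALSE)
  }
  n <- length(x$seq)
  cut <- setdiff(which(x$seq == "C"), protected_positions)
  bounds <- c(0L, cut, n + 1L)
  segs <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    from <- bounds[i] + 1L
    to <- bounds[i + 1L] - 1L
    if (from > to) next
    seg_seq <- paste(x$seq[from:to], collapse = "")
    seg_mods <- x$mods[x$mods$position >= from & x$mods$position <= to, ,
                       drop = FALSE]
    if (nrow(seg_mods)) seg_mods$position <- seg_mods$position - from + 1L
    seg <- oligo(seg_seq,
                 five_prime = if (from == 1L) x$five_prime else "phosphate",
                 three_prime = if (to == n) x$three_prime else "phosphate",
                 mods = seg_mods)
    segs[[length(segs) + 1L]] <- data.frame(from = from, to = to,
                                            neutral_mass = oligo_mass(seg))
  }
  if (!length(segs)) {
    return(data.frame(from = integer(), to = integer(),
                      neutral_mass = numeric()))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Type an adenine methyl as m6A or m1A from a DMS mass shift
#'
#' Dimethyl sulfate preferentially alkylates adenine N1 in RNA and the
#' reaction is modeled as complete: every adenine with a free N1 gains one
#' methyl (+14.01565 Da).  If the unknown methyl is m6A its N1 is still
#' free, so all `nA` adenines react (shift `nA * 14.01565`); if it is m1A
#' its N1 is blocked and only `nA - 1` react.  The observed post-DMS mass
#' shift picks the hypothesis within `tol`.
#'
#' @param x An [oligo()] carrying exactly one adenine methyl of unknown
#'   type, or a plain sequence string; only the adenine count matters.
#' @param observed_shift Observed mass increase after DMS treatment (Da).
#' @param tol Tolerance in Da (default 0.5).
#' @return `"m6A"`, `"m1A"`, or `"undetermined"`; attributes
#'   `predicted_m6A` and `predicted_m1A` give the two hypothesis shifts.
#' @export
classify_adenine_methylation <- function(x, observed_shift, tol = 0.5) {
  if (is.character(x)) x <- oligo(x)
  stopifnot(inherits(x, "oligo"))
  n_a <- sum(x$seq == "A")
  if (n_a < 1) stop("sequence contains no adenine", call. = FALSE)
  ch2 <- methyl_delta_mass()
  pred <- c(m6A = n_a * ch2, m1A = (n_a - 1) * ch2)
  hit <- names(pred)[abs(pred - observed_shift) <= tol]
  out <- if (length(hit) == 1L) hit else "undetermined"
  structure(out, predicted_m6A = unname(pred["m6A"]),
            predicted_m1A = unname(pred["m1A"]))
}
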