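# Intact-species detection and methylation stoichiometry.
#
# Methylated forms of an intact miRNA appear +14.01565 Da (per methyl) above
# the unmethylated predicted mass; the methylated fraction is estimated from
# the intensity shares of the 0..k-methyl species, optionally corrected with
# a synthetic-standard calibration curve.

.ADDUCT_DELTA <- function() c(
  none = 0,
  Na = unname(.MONO_MASS["Na"] - .MONO_MASS["H"]),  # +21.98194 (Na - H)
  K  = unname(.MONO_MASS["K"] - .MONO_MASS["H"])    # +37.95588 (K - H)
)

#' Predict intact methylated species of a miRNA
#'
#' Enumerates the 0..`kmax`-methyl forms of an oligo (and their Na/K
#' adducts), each k adding exactly one CH2 (14.01565 Da monoisotopic) —
#' the mono-/di-/tri-methylated peak pattern seen in intact MALDI spectra.
#'
#' @param x An [oligo()] (its own modification list is ignored here; k
#'   counts methyls generically without fixing their positions).
#' @param kmax Maximum methyl count; must not exceed the number of A + C
#'   residues (the methyl-accepting bases).
#' @param adducts Character subset of `c("Na", "K")`; default none.
#' @param mirna_id Label carried through to matches.
#' @return Data frame (`species_prediction`) with columns `mirna_id`, `k`,
#'   `adduct`, `neutral_mass`, `mz` (charge 1, negative mode).
#' @export
predict_species <- function(x, kmax = 3L, adducts = character(),
                            mirna_id = "miRNA") {
  stopifnot(inherits(x, "oligo"))
  kmax <- as.integer(kmax)
  if (kmax < 0) stop("`kmax` must be >= 0", call. = FALSE)
  n_ac <- sum(x$seq %in% c("A", "C"))
  if (kmax > n_ac) {
    stop(sprintf(paste0("kmax = %d exceeds the %d methyl-accepting (A/C) ",
                        "residues of the sequence"), kmax, n_ac),
         call. = FALSE)
  }
  bad <- setdiff(adducts, c("Na", "K"))
  if (length(bad)) stop("unknown adduct(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  base <- oligo_mass(x)
  deltas <- .ADDUCT_DELTA()[c("none", adducts)]
  grid <- expand.grid(k = 0:kmax, adduct = names(deltas),
                      stringsAsFactors = FALSE)
  grid$mirna_id <- mirna_id
  grid$neutral_mass <- base + grid$k * methyl_delta_mass() +
    deltas[grid$adduct]
  grid$mz <- mz_from_mass(grid$neutral_mass, 1L)
  out <- grid[order(grid$neutral_mass),
              c("mirna_id", "k", "adduct", "neutral_mass", "mz")]
  rownames(out) <- NULL
  class(out) <- c("species_prediction", "data.frame")
  out
}

#' Match observed peaks to predicted intact species
#'
#' Each prediction is assigned the nearest observed peak within `tol_ppm`;
#' a peak may satisfy only one prediction.  Conflicts are resolved
#' globally: candidate (prediction, peak) pairs are ranked by |ppm error|,
#' ties broken toward lower methyl count k, and assigned greedily.
#' Unmatched predictions are kept with `accepted = FALSE`.
#'
#' @param pl A [peaklist()].
#' @param preds A [predict_species()] result (non-empty).
#' @param tol_ppm Match tolerance in ppm (default 50, suitable for
#'   externally calibrated MALDI-TOF).
#' @return Data frame (`species_match`): prediction columns plus
#'   `obs_mz`, `intensity`, `snr`, `ppm_error`, `accepted`.
#' @export
match_species <- function(pl, preds, tol_ppm = 50) {
  stopifnot(inherits(pl, "peaklist"))
  if (!nrow(preds)) stop("empty prediction list", call. = FALSE)
  if (tol_ppm <= 0) stop("`tol_ppm` must be > 0", call. = FALSE)
  np <- nrow(preds)
  out <- preds
  out$obs_mz <- NA_real_
  out$intensity <- NA_real_
  out$snr <- NA_real_
  out$ppm_error <- NA_real_
  out$accepted <- FALSE
  if (nrow(pl)) {
    cand <- do.call(rbind, lapply(seq_len(np), function(i) {
      ppm <- (pl$mz - preds$mz[i]) / preds$mz[i] * 1e6
      j <- which(abs(ppm) <= tol_ppm)
      if (!length(j)) return(NULL)
      data.frame(pred = i, peak = j, ppm = ppm[j])
    }))
    if (!is.null(cand) && nrow(cand)) {
      # |ppm| ranks candidates; differences below 1e-6 ppm are ties
      # (floating-point guard) resolved toward lower methyl count
      cand <- cand[order(round(abs(cand$ppm), 6), preds$k[cand$pred]), ,
                   drop = FALSE]
      used_peak <- logical(nrow(pl))
      used_pred <- logical(np)
      for (r in seq_len(nrow(cand))) {
        i <- cand$pred[r]; j <- cand$peak[r]
        if (used_peak[j] || used_pred[i]) next
        used_peak[j] <- TRUE; used_pred[i] <- TRUE
        out$obs_mz[i] <- pl$mz[j]
        out$intensity[i] <- pl$intensity[j]
        out$snr[i] <- if ("snr" %in% names(pl)) pl$snr[j] else NA_real_
        out$ppm_error[i] <- cand$ppm[r]
        out$accepted[i] <- TRUE
      }
    }
  }
  class(out) <- c("species_match", "data.frame")
  out
}

#' Methylated fraction of a miRNA from species matches
#'
#' The stoichiometry estimate: fraction = sum of accepted intensities over
#' k >= 1 divided by the total over all k (summing adduct forms into their
#' parent species).  When no methylated species reaches `snr_floor` the
#' below-detection flag is set and the fraction reported as 0 — mirroring
#' the convention that expression below the detection limit is shown as
#' zero.  If the unmethylated species is absent but methylated ones are
#' present, the fraction is 1.
#'
#' @param matches A [match_species()] result.
#' @param snr_floor Detection floor applied to methylated species: compared
#'   against the peak `snr` when available, otherwise against raw intensity.
#'   Default 3.
#' @return List of class `methylation_fraction`: `mirna_id`, `fraction`,
#'   `below_detection`, `shares` (per-k intensity shares), `intensities`
#'   (per-k summed intensities).
#' @export
methylation_fraction <- function(matches, snr_floor = 3) {
  acc <- matches[matches$accepted, , drop = FALSE]
  if (!nrow(acc)) {
    stop("no accepted species matches; methylation fraction undefined",
         call. = FALSE)
  }
  ik <- tapply(acc$intensity, acc$k, sum)
  k <- as.integer(names(ik))
  det <- acc[acc$k >= 1, , drop = FALSE]
  det_val <- ifelse(is.na(det$snr), det$intensity, det$snr)
  methyl_detected <- nrow(det) > 0 && any(det_val >= snr_floor)
  total <- sum(ik)
  if (!methyl_detected) {
    fraction <- 0
    below <- TRUE
  } else {
    fraction <- sum(ik[k >= 1]) / total
    below <- FALSE
  }
  shares <- as.numeric(ik) / total
  names(shares) <- names(ik)
  structure(list(mirna_id = matches$mirna_id[1], fraction = fraction,
                 below_detection = below, shares = shares,
                 intensities = stats::setNames(as.numeric(ik), names(ik))),
            class = "methylation_fraction")
}

#' @export
print.methylation_fraction <- function(x, ...) {
  cat(sprintf("<methylation_fraction> %s: %.4f%s\n", x$mirna_id, x$fraction,
              if (x$below_detection) " (below detection)" else ""))
  invisible(x)
}

#' Fit a calibration curve from synthetic-standard mixtures
#'
#' Mixtures of synthetic methylated and non-methylated oligos at known
#' molar fractions give measured intensity ratios I_methyl / I_unmethyl.
#' Because that ratio is proportional to the molar *odds* f/(1-f) — with
#' the proportionality constant being the relative ionization response
#' factor of the methylated species — the least-squares line is fitted on
#' the odds scale: ratio ~ slope * odds + intercept.  The slope is the
#' response factor; the fitted fraction-to-ratio mapping is monotone
#' non-decreasing on [0, 1) whenever the slope is positive (enforced).
#'
#' @param points Data frame with columns `fraction` (known molar fraction in
#'   \[0, 1)) and `ratio` (measured I_methyl / I_unmethyl); at least two
#'   distinct fractions.
#' @return List of class `calibration_curve`: `slope` (response factor),
#'   `intercept`, `points`, `residuals`.
#' @export
fit_calibration <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("fraction", "ratio") %in% names(points))) {
    stop("`points` needs columns 'fraction' and 'ratio'", call. = FALSE)
  }
  if (nrow(points) < 2) stop("calibration needs >= 2 points", call. = FALSE)
  if (length(unique(points$fraction)) < 2) {
    stop("calibration needs >= 2 distinct known fractions", call. = FALSE)
  }
  if (any(points$fraction < 0 | points$fraction >= 1)) {
    stop("known fractions must lie in [0, 1)", call. = FALSE)
  }
  odds <- points$fraction / (1 - points$fraction)
  fit <- stats::lm(points$ratio ~ odds)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive (monotone response)",
         call. = FALSE)
  }
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 points = points,
                 residuals = unname(stats::residuals(fit))),
            class = "calibration_curve")
}

#' Correct a raw methylated fraction with a calibration curve
#'
#' Inverts [fit_calibration()]: the raw fraction is converted to an
#' intensity odds ratio, the fitted line inverted, and the corrected odds
#' mapped back to a fraction, clamped to \[0, 1\].
#'
#' @param curve A [fit_calibration()] result.
#' @param raw_fraction Raw methylated fraction(s) from
#'   [methylation_fraction()].
#' @return Corrected fraction(s) in \[0, 1\].
#' @export
apply_calibration <- function(curve, raw_fraction) {
  stopifnot(inherits(curve, "calibration_curve"))
  raw_fraction <- pmin(pmax(raw_fraction, 0), 1)
  out <- numeric(length(raw_fraction))
  for (i in seq_along(raw_fraction)) {
    f <- raw_fraction[i]
    if (f >= 1) { out[i] <- 1; next }
    ratio <- f / (1 - f)
    odds <- (ratio - curve$intercept) / curve$slope
    out[i] <- if (odds <= 0) 0 else min(1, odds / (1 + odds))
  }
  out
}

#' Correct matched intensities for isotope-envelope overlap
#'
#' When envelopes are broad enough that species k's tail reaches the
#' monoisotopic position of species k+1 (not the case at the 14 Da methyl
#' spacing under default truncation, where this is a no-op), the predicted
#' contribution of k's envelope at k+1's matched m/z is subtracted.
#' Corrected intensities are clamped at zero.
#'
#' @param matches A [match_species()] result.
#' @param envelopes Named list of isotope envelopes (from
#'   [isotope_envelope()]), one per methyl count, names `"0"`, `"1"`, ...
#' @param window_da Half-width (Da) within which an envelope line is taken
#'   to land on a matched peak (default 0.2).
#' @return `matches` with an added `intensity_corrected` column.
#' @export
isotope_overlap_correction <- function(matches, envelopes, window_da = 0.2) {
  out <- matches
  out$intensity_corrected <- out$intensity
  for (ad in unique(out$adduct)) {
    sel <- which(out$adduct == ad & out$accepted)
    sel <- sel[order(out$k[sel])]
    if (length(sel) < 2) next
    for (j in seq_along(sel)[-1]) {
      lo <- sel[j - 1]; hi <- sel[j]
      env <- envelopes[[as.character(out$k[lo])]]
      if (is.null(env)) next
      # envelope masses are neutral; compare spacing between species
      shift_da <- (out$mz[hi] - out$mz[lo])
      rel <- env$mass - env$mass[1]
      contrib_ab <- sum(env$abundance[abs(rel - shift_da) <= window_da])
      mono_ab <- env$abundance[1]
      if (contrib_ab <= 0 || mono_ab <= 0) next
      contrib <- out$intensity_corrected[lo] * contrib_ab / mono_ab
      out$intensity_corrected[hi] <-
        max(0, out$intensity_corrected[hi] - contrib)
    }
  }
  out
}
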