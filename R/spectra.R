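#' Centroided peak list
#'
#' The observational unit: (m/z, intensity) pairs, strictly increasing in
#' m/z, with polarity and MS-level metadata and an optional per-peak
#' signal-to-noise column.
#'
#' @param mz Numeric m/z values.
#' @param intensity Positive intensities (peak heights).
#' @param snr Optional signal-to-noise ratios, same length.
#' @param polarity `"negative"` (default) or `"positive"`.
#' @param ms_level 1 (intact) or 2 (fragment spectrum).
#' @param precursor_mz Precursor m/z, required context for `ms_level = 2`
#'   (may be `NA`).
#' @param provenance Free-text origin tag.
#' @return A `peaklist`: data frame with columns `mz`, `intensity` (and
#'   `snr` when given) plus metadata attributes.
#' @export
peaklist <- function(mz, intensity, snr = NULL,
                     polarity = c("negative", "positive"),
                     ms_level = 1L, precursor_mz = NA_real_,
                     provenance = "") {
  polarity <- match.arg(polarity)
  stopifnot(length(mz) == length(intensity))
  if (length(mz)) {
    if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
      stop("m/z and intensity must be finite", call. = FALSE)
    }
    if (any(intensity <= 0)) stop("intensities must be > 0", call. = FALSE)
    ord <- order(mz)
    mz <- mz[ord]; intensity <- intensity[ord]
    if (!is.null(snr)) snr <- snr[ord]
    if (any(diff(mz) <= 0)) {
      stop("m/z values must be strictly increasing (duplicate peak?)",
           call. = FALSE)
    }
  }
  df <- data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity))
  if (!is.null(snr)) df$snr <- as.numeric(snr)
  structure(df, class = c("peaklist", "data.frame"),
            polarity = polarity, ms_level = as.integer(ms_level),
            precursor_mz = precursor_mz, provenance = provenance)
}

#' Profile-mode spectrum
#'
#' @param mz Strictly increasing m/z grid.
#' @param intensity Non-negative intensities, same length.
#' @inheritParams peaklist
#' @return A `spectrum_profile` object.
#' @export
spectrum_profile <- function(mz, intensity,
                             polarity = c("negative", "positive"),
                             ms_level = 1L, precursor_mz = NA_real_) {
  polarity <- match.arg(polarity)
  stopifnot(length(mz) == length(intensity))
  if (length(mz) && any(diff(mz) <= 0)) {
    stop("profile m/z grid must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0)) stop("profile intensities must be >= 0",
                               call. = FALSE)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "spectrum_profile", polarity = polarity,
            ms_level = as.integer(ms_level), precursor_mz = precursor_mz)
}

#' Read a peak list (TSV) or spectra (mzML)
#'
#' The TSV dialect is fixed: tab-separated, dot decimal, UTF-8, with a
#' header line `mz<TAB>intensity` (an optional third `snr` column is
#' accepted).  An empty file or a header-only file yields an empty peak
#' list, not an error; a malformed row (non-numeric field, negative
#' intensity) is an error naming the offending line.  mzML files may hold
#' several spectra: centroided ones map to [peaklist()], profile ones to
#' [spectrum_profile()].
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"mzml"`.
#' @return For TSV, a [peaklist()].  For mzML, a single object when the
#'   file holds one spectrum, otherwise a list of objects.
#' @export
read_peaklist <- function(path, format = c("auto", "tsv", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "mzml") "mzml" else "tsv"
  }
  if (format == "mzml") return(read_mzml(path))

  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    return(peaklist(numeric(), numeric(), provenance = path))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "mz" || header[2] != "intensity") {
    stop("TSV peak list must start with header 'mz\tintensity': ", path,
         call. = FALSE)
  }
  has_snr <- length(header) >= 3 && header[3] == "snr"
  body <- lines[-1]
  body_no <- which(nzchar(trimws(body)))
  mzv <- intv <- snrv <- numeric(length(body_no))
  for (k in seq_along(body_no)) {
    i <- body_no[k]
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    want <- if (has_snr) 3L else 2L
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) < 2L || any(is.na(vals[seq_len(min(want, length(fields)))]))) {
      stop(sprintf("malformed peak-list row at line %d of %s: '%s'",
                   i + 1L, path, body[i]), call. = FALSE)
    }
    if (vals[2] < 0) {
      stop(sprintf("negative intensity at line %d of %s", i + 1L, path),
           call. = FALSE)
    }
    mzv[k] <- vals[1]; intv[k] <- vals[2]
    snrv[k] <- if (has_snr && length(vals) >= 3) vals[3] else NA_real_
  }
  keep <- intv > 0
  peaklist(mzv[keep], intv[keep],
           snr = if (has_snr) snrv[keep] else NULL,
           provenance = path)
}

#' Write a peak list as TSV
#'
#' Values are printed with six decimal places, making a write-read round
#' trip lossless at that precision.
#'
#' @param pl A [peaklist()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path) {
  stopifnot(inherits(pl, "peaklist"))
  has_snr <- "snr" %in% names(pl)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("mz", "intensity", if (has_snr) "snr"), collapse = "\t"),
             con)
  if (nrow(pl)) {
    rows <- sprintf("%.6f\t%.6f", pl$mz, pl$intensity)
    if (has_snr) rows <- sprintf("%s\t%.6f", rows, pl$snr)
    writeLines(rows, con)
  }
  invisible(path)
}

# -- mzML ---------------------------------------------------------------

.decode_binary <- function(node, defaults) {
  ns <- "d1"
  cv <- xml2::xml_find_all(node, sprintf(".//%s:cvParam", ns))
  acc <- xml2::xml_attr(cv, "accession")
  precision <- if ("MS:1000521" %in% acc) 4L else 8L   # 32- vs 64-bit float
  zlib <- "MS:1000574" %in% acc
  kind <- if ("MS:1000514" %in% acc) "mz"
          else if ("MS:1000515" %in% acc) "intensity" else "other"
  b64 <- xml2::xml_text(xml2::xml_find_first(node, sprintf(".//%s:binary", ns)))
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if (zlib && length(raw)) raw <- memDecompress(raw, type = "gzip")
  vals <- readBin(raw, what = "double", size = precision,
                  n = length(raw) %/% precision, endian = "little")
  list(kind = kind, values = vals)
}

#' Read spectra from an mzML file
#'
#' Minimal mzML reader covering the subset this package needs: 32/64-bit
#' little-endian float arrays, optionally zlib-compressed; polarity,
#' centroid/profile mode, MS level and precursor m/z from the standard
#' cvParam accessions.
#'
#' @param path mzML file.
#' @return A [peaklist()] or [spectrum_profile()] when the file holds one
#'   spectrum, else a list of them.
#' @export
read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  spectra <- xml2::xml_find_all(doc, ".//d1:spectrum")
  if (!length(spectra)) stop("no spectra found in ", path, call. = FALSE)
  out <- lapply(spectra, function(sp) {
    cv <- xml2::xml_find_all(sp, "./d1:cvParam")
    acc <- xml2::xml_attr(cv, "accession")
    polarity <- if ("MS:1000129" %in% acc) "negative"
                else if ("MS:1000130" %in% acc) "positive" else "negative"
    centroided <- "MS:1000127" %in% acc
    lev_node <- cv[acc == "MS:1000511"]
    ms_level <- if (length(lev_node)) {
      as.integer(xml2::xml_attr(lev_node[[1]], "value"))
    } else 1L
    prec <- xml2::xml_find_first(
      sp, ".//d1:selectedIon/d1:cvParam[@accession='MS:1000744']")
    precursor_mz <- if (inherits(prec, "xml_missing")) NA_real_
                    else as.numeric(xml2::xml_attr(prec, "value"))
    arrays <- lapply(xml2::xml_find_all(sp, ".//d1:binaryDataArray"),
                     .decode_binary)
    kinds <- vapply(arrays, `[[`, "", "kind")
    mzv <- arrays[[match("mz", kinds)]]$values
    intv <- arrays[[match("intensity", kinds)]]$values
    if (centroided) {
      keep <- intv > 0
      peaklist(mzv[keep], intv[keep], polarity = polarity,
               ms_level = ms_level, precursor_mz = precursor_mz,
               provenance = path)
    } else {
      spectrum_profile(mzv, intv, polarity = polarity, ms_level = ms_level,
                       precursor_mz = precursor_mz)
    }
  })
  if (length(out) == 1L) out[[1]] else out
}

# -- centroiding and recalibration --------------------------------------

#' Centroid a profile spectrum
#'
#' Local maxima whose height reaches `snr_threshold` times the local noise
#' become centroids.  Noise is the robust MAD estimate (median absolute
#' deviation scaled by 1.4826, i.e. `stats::mad`) of the profile within a
#' sliding `noise_window` around the candidate.  The centroid m/z is the
#' intensity-weighted mean over the contiguous region above half the apex
#' height.
#'
#' @param spec A [spectrum_profile()].
#' @param snr_threshold Positive signal-to-noise cutoff (default 3).
#' @param noise_window Width in Da of the local-noise window (default 20).
#' @return A [peaklist()] with an `snr` column.
#' @export
centroid <- function(spec, snr_threshold = 3, noise_window = 20) {
  stopifnot(inherits(spec, "spectrum_profile"))
  if (!length(spec$mz)) stop("profile spectrum is empty", call. = FALSE)
  if (snr_threshold <= 0) stop("`snr_threshold` must be > 0", call. = FALSE)
  mz <- spec$mz; y <- spec$intensity
  n <- length(y)
  if (n < 3) return(peaklist(numeric(), numeric(),
                             polarity = attr(spec, "polarity"),
                             ms_level = attr(spec, "ms_level")))
  apex <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  cm <- ci <- cs <- numeric(0)
  for (i in apex) {
    win <- which(mz >= mz[i] - noise_window / 2 & mz <= mz[i] + noise_window / 2)
    noise <- stats::mad(y[win])
    if (noise <= 0) noise <- stats::mad(y[win][y[win] > 0])
    if (!is.finite(noise) || noise <= 0) noise <- .Machine$double.eps
    snr <- y[i] / noise
    if (snr < snr_threshold || y[i] <= 0) next
    half <- y[i] / 2
    lo <- i; while (lo > 1 && y[lo - 1] >= half && y[lo - 1] <= y[lo]) lo <- lo - 1
    hi <- i; while (hi < n && y[hi + 1] >= half && y[hi + 1] <= y[hi]) hi <- hi + 1
    reg <- lo:hi
    cm <- c(cm, sum(mz[reg] * y[reg]) / sum(y[reg]))
    ci <- c(ci, y[i])
    cs <- c(cs, snr)
  }
  peaklist(cm, ci, snr = cs, polarity = attr(spec, "polarity"),
           ms_level = attr(spec, "ms_level"),
           precursor_mz = attr(spec, "precursor_mz"))
}

#' Linear m/z recalibration from reference masses
#'
#' External calibration typical of MALDI-TOF: a least-squares straight line
#' mapping observed to true m/z, fitted on reference pairs and applied to
#' the whole peak list.
#'
#' @param pl A [peaklist()].
#' @param references Data frame with columns `observed` and `true` (m/z);
#'   at least two rows with distinct `observed` values.
#' @return The recalibrated [peaklist()]; attribute `calibration` holds the
#'   fitted coefficients and per-reference residuals.
#' @export
recalibrate <- function(pl, references) {
  stopifnot(inherits(pl, "peaklist"))
  if (!is.data.frame(references) ||
      !all(c("observed", "true") %in% names(references))) {
    stop("`references` needs columns 'observed' and 'true'", call. = FALSE)
  }
  if (nrow(references) < 2) {
    stop("linear recalibration needs at least 2 references", call. = FALSE)
  }
  if (length(unique(references$observed)) < 2) {
    stop("degenerate references: observed m/z values are identical",
         call. = FALSE)
  }
  fit <- stats::lm(true ~ observed, data = references)
  newmz <- unname(stats::predict(fit, data.frame(observed = pl$mz)))
  out <- peaklist(newmz, pl$intensity,
                  snr = if ("snr" %in% names(pl)) pl$snr else NULL,
                  polarity = attr(pl, "polarity"),
                  ms_level = attr(pl, "ms_level"),
                  precursor_mz = attr(pl, "precursor_mz"),
                  provenance = attr(pl, "provenance"))
  attr(out, "calibration") <- list(
    coefficients = stats::coef(fit),
    residuals = data.frame(references, residual = stats::residuals(fit)))
  out
}
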