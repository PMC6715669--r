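# Build a minimal-but-valid mzML file in code (text + base64 payload), so
# mzML reading is tested without shipping binary fixtures.

encode_array <- function(values, compression = c("none", "zlib")) {
  compression <- match.arg(compression)
  raw <- writeBin(as.double(values), raw(), size = 8, endian = "little")
  if (compression == "zlib") raw <- memCompress(raw, type = "gzip")
  jsonlite::base64_enc(raw)
}

make_mzml <- function(path, mz, intensity, centroided = TRUE,
                      polarity = "negative", ms_level = 1,
                      precursor_mz = NULL,
                      compression = c("none", "zlib")) {
  compression <- match.arg(compression)
  comp_cv <- if (compression == "zlib") {
    '<cvParam cvRef="MS" accession="MS:1000574" name="zlib compression"/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>'
  }
  pol_cv <- if (polarity == "negative") {
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan"/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>'
  }
  mode_cv <- if (centroided) {
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum"/>'
  }
  prec <- if (!is.null(precursor_mz)) sprintf('
    <precursorList count="1"><precursor><selectedIonList count="1">
      <selectedIon>
        <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f"/>
      </selectedIon>
    </selectedIonList></precursor></precursorList>', precursor_mz) else ""
  array_xml <- function(values, kind_acc, kind_name) sprintf('
      <binaryDataArray encodedLength="0">
        <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
        %s
        <cvParam cvRef="MS" accession="%s" name="%s"/>
        <binary>%s</binary>
      </binaryDataArray>', comp_cv, kind_acc, kind_name,
      encode_array(values, compression))
  xml <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <run id="run1">
    <spectrumList count="1">
      <spectrum index="0" id="scan=1" defaultArrayLength="%d">
        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>
        %s
        %s%s
        <binaryDataArrayList count="2">%s%s
        </binaryDataArrayList>
      </spectrum>
    </spectrumList>
  </run>
</mzML>', length(mz), ms_level, pol_cv, mode_cv, prec,
          array_xml(mz, "MS:1000514", "m/z array"),
          array_xml(intensity, "MS:1000515", "intensity array"))
  writeLines(xml, path)
  invisible(path)
}

# Gaussian profile simulator for centroiding tests
make_profile <- function(centers, heights, sigma = 0.05,
                         from = min(centers) - 5, to = max(centers) + 5,
                         step = 0.01, baseline = 0, noise_sd = 0) {
  grid <- seq(from, to, by = step)
  y <- rep(baseline, length(grid))
  for (i in seq_along(centers)) {
    y <- y + heights[i] * exp(-(grid - centers[i])^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) y <- pmax(0, y + rnorm(length(grid), 0, noise_sd))
  spectrum_profile(grid, y)
}
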