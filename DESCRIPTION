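Package: mirmeth
Title: Detection, Site Localization and Quantification of Methyl Marks on
    Mature miRNAs by MALDI-TOF Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational toolkit for assaying methyl modifications (m6A,
    m1A, m5C, m3C) on mature microRNAs with negative-mode MALDI-TOF-MS/MS.
    Computes elemental compositions, monoisotopic and average masses, m/z
    values and isotope envelopes of modified RNA oligonucleotides; generates
    theoretical MS/MS fragment ladders (McLuckey a/b/c/d and w/x/y/z series);
    matches observed peaks to predicted intact species carrying 0..k methyl
    groups and sodium/potassium adducts; estimates per-miRNA methylation
    stoichiometry with synthetic-standard calibration; localizes methylated
    positions from fragment ladders and types the modification via hydrazine
    and dimethyl-sulfate derivatization logic; and provides a seeded simulator
    plus downstream RIP-Seq consensus, paired-comparison and biomarker ROC
    stages for end-to-end validation on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
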