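# mirmeth

Detection, site localization and quantification of methyl marks on
mature miRNAs from negative-mode MALDI-TOF-MS/MS data.

## Why

Mature miRNAs such as miR-17-5p, let-7a-5p, miR-200c-3p and miR-21-3p
can carry base methyls (m6A, m1A, m5C, m3C), and the *fraction* of
methylated molecules — rather than miRNA abundance — is elevated in
gastrointestinal cancer tissue and serum, making it a candidate
early-diagnosis biomarker. Intact mass spectrometry sees each methyl as
a mass increment of one CH2:

```
Δm = m(CH2) = 14.01565 Da  (monoisotopic; the nominal "+14 Da")
```

so a captured miRNA's methylated forms appear as satellite peaks at
+14.01565·k Da from the predicted unmethylated mass, and the
methylation stoichiometry is

```
f = Σ_{k≥1} I_k / Σ_{k≥0} I_k
```

over the intensities of the k-methyl species (optionally corrected with
a synthetic-standard calibration curve: the measured intensity ratio
I1/I0 equals r·f/(1−f) with r the relative ionization response factor).
Site assignment compares observed MS/MS fragments against the
theoretical McLuckey ladders (a/b/c/d, w/x/y/z, a-B) of every candidate
placement; hydrazine resistance identifies m5C and the dimethyl-sulfate
mass shift separates m6A (nA·14.01565) from m1A ((nA−1)·14.01565).

The package is aimed at mass-spectrometry informaticians building or
validating this assay: it covers oligonucleotide mass/composition/
isotope-envelope computation, peak-list and mzML I/O with centroiding
and recalibration, species matching and stoichiometry, MS/MS site
localization, derivatization typing, a fully seeded simulator, and the
downstream RIP-Seq consensus / paired-comparison / ROC stages — all
exercised end to end on synthetic data.

## Worked example

```r
library(mirmeth)

fa    <- system.file("extdata", "mirna_mature.fa", package = "mirmeth")
mir17 <- read_mirna_fasta(fa, id = "hsa-miR-17-5p")
ol    <- oligo(mir17)                     # 5'-phosphate, 3'-OH defaults

predict_species(ol, kmax = 2, adducts = "Na")
#>   mirna_id k adduct neutral_mass         mz
#> 1    miRNA 0   none   7487.00190 7485.99462
#> 2    miRNA 1   none   7501.01755 7500.01027
#> 3    miRNA 0     Na   7508.98384 7507.97657
#> 4    miRNA 2   none   7515.03320 7514.02592
#> ...
```

The unmethylated miR-17-5p anion is predicted at m/z 7485.99; the mono-
and di-methylated species sit +14.016 and +28.031 above it, the sodium
adduct +21.982. Simulate an acquisition at 20 ppm mass error and 5%
intensity noise with a true stoichiometry of 25% (20% mono-, 5%
di-methylated), then quantify:

```r
cfg <- sim_config(ol, fractions = c("0" = 0.75, "1" = 0.2, "2" = 0.05),
                  mass_error_ppm = 20, intensity_cv = 0.05, seed = 42)
pl  <- simulate_intact(cfg)
mm  <- match_species(pl, predict_species(ol, kmax = 2), tol_ppm = 100)
methylation_fraction(mm, snr_floor = 0)
#> <methylation_fraction> miRNA: 0.2529
```

The estimate (0.2529) recovers the planted 0.25 within the simulated
noise; per-species intensity shares come back as 0.747/0.202/0.051.
Localize a methyl planted at position 2 from a 70%-coverage MS/MS
spectrum:

```r
olm  <- oligo(mir17, mods = "2:m6A")
cfgm <- sim_config(olm, fractions = c("1" = 1), mass_error_ppm = 50,
                   intensity_cv = 0.1, coverage = 0.7, seed = 42)
localize(simulate_msms(cfgm), ol, "m6A", tol_ppm = 100)
#>   position mod score n_supporting n_contradicting n_matched   top
#> 1        2 m6A     3            3               0        56  TRUE
#> 2        3 m6A    -3            0               3        53 FALSE
#> ...
```

Position 2 ranks first: three fragments match only under that
placement and none contradict it. Type the adenine methyl from a
post-DMS shift of 98.11 Da (miR-17-5p has 7 adenines; 7 × 14.01565 =
98.11 predicts m6A, 6 × 14.01565 = 84.09 would predict m1A):

```r
classify_adenine_methylation(mir17, observed_shift = 98.11)
#> [1] "m6A"
```

## Command line

`exec/mirmeth` (installed with the package) exposes the same pipeline:

```sh
mirmeth mass --seq UGAGGUAGUAGGUUGUAUAGUU --mods 10:m6A
mirmeth fragments --seq UGAGG --series c,y,w --out ladder.tsv
mirmeth detect --peaks peaks.tsv --fasta mirna_mature.fa \
        --id hsa-miR-17-5p --kmax 3 --tol-ppm 50 --out matches.tsv
mirmeth simulate cohort --n-case 20 --n-control 20 --markers --seed 7
```

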