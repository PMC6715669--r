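# detect_quant: species prediction, peak matching, stoichiometry,
# calibration, envelope-overlap guard

mir17 <- "CAAAGUGCUUACAGUGCAGGUAG"

test_that("predicted species are spaced exactly one methyl apart", {
  preds <- predict_species(oligo(mir17), kmax = 3)
  expect_equal(nrow(preds), 4)
  expect_equal(diff(preds$neutral_mass), rep(14.01565, 3), tolerance = 1e-6)
  expect_equal(diff(preds$mz), rep(14.01565, 3), tolerance = 1e-6)
  p0 <- predict_species(oligo(mir17), kmax = 0)
  expect_equal(nrow(p0), 1)
  expect_equal(p0$k, 0)
})

test_that("adduct species sit at +21.98194 (Na-H) and +37.95588 (K-H)", {
  preds <- predict_species(oligo(mir17), kmax = 1, adducts = c("Na", "K"))
  expect_equal(nrow(preds), 6)   # (kmax+1) x (1 + |adducts|)
  base <- preds$neutral_mass[preds$k == 0 & preds$adduct == "none"]
  expect_equal(preds$neutral_mass[preds$k == 0 & preds$adduct == "Na"] - base,
               21.98194, tolerance = 1e-5)
  expect_equal(preds$neutral_mass[preds$k == 0 & preds$adduct == "K"] - base,
               37.95588, tolerance = 1e-5)
})

test_that("kmax above the A+C residue count is rejected", {
  expect_error(predict_species(oligo("GGUU"), kmax = 1), "methyl-accepting")
  expect_error(predict_species(oligo("GAUU"), kmax = 2), "methyl-accepting")
  expect_silent(predict_species(oligo("GAUU"), kmax = 1))
})

test_that("peak matching honors tolerance, uniqueness and tie-breaks", {
  preds <- predict_species(oligo(mir17), kmax = 2)
  # exact peaks: all matched with ppm 0
  pl <- peaklist(preds$mz, c(100, 50, 25))
  mm <- match_species(pl, preds, tol_ppm = 50)
  expect_true(all(mm$accepted))
  expect_equal(mm$ppm_error, rep(0, 3), tolerance = 1e-9)
  # 100 ppm displacement at 50 ppm tolerance: unmatched
  pl_off <- peaklist(preds$mz * (1 + 100e-6), c(100, 50, 25))
  mm_off <- match_species(pl_off, preds, tol_ppm = 50)
  expect_false(any(mm_off$accepted))
  # two peaks inside tolerance: nearest ppm wins
  pl2 <- peaklist(preds$mz[1] * (1 + c(-30e-6, 10e-6)), c(10, 20))
  mm2 <- match_species(pl2, preds[1, ], tol_ppm = 50)
  expect_equal(mm2$intensity, 20)
  expect_equal(mm2$ppm_error, 10, tolerance = 1e-6)
  # one peak at equal |ppm| distance from the k=0 and k=1 predictions
  # (harmonic mean of the two m/z): the documented tie-break favors lower k
  mid <- 2 * preds$mz[1] * preds$mz[2] / (preds$mz[1] + preds$mz[2])
  pl3 <- peaklist(mid, 10)
  mm3 <- match_species(pl3, preds[1:2, ], tol_ppm = 4000)
  expect_true(mm3$accepted[mm3$k == 0])
  expect_false(mm3$accepted[mm3$k == 1])
  expect_error(match_species(pl, preds[0, ]), "empty prediction")
})

test_that("methylation fraction follows the intensity-share definition", {
  preds <- predict_species(oligo(mir17), kmax = 1)
  mm <- match_species(peaklist(preds$mz, c(100, 100)), preds)
  mf <- methylation_fraction(mm, snr_floor = 0)
  expect_equal(mf$fraction, 0.5)
  expect_false(mf$below_detection)
  # k=0 absent, k>=1 present -> 1
  mm1 <- match_species(peaklist(preds$mz[2], 80), preds)
  expect_equal(methylation_fraction(mm1, snr_floor = 0)$fraction, 1)
  # no methylated peak detected -> 0 with below-detection flag
  mm0 <- match_species(peaklist(preds$mz[1], 80), preds)
  mf0 <- methylation_fraction(mm0)
  expect_equal(mf0$fraction, 0)
  expect_true(mf0$below_detection)
  # methylated peak present but under the snr floor -> below detection
  mm_low <- match_species(peaklist(preds$mz, c(1000, 1),
                                   snr = c(1000, 1)), preds)
  expect_true(methylation_fraction(mm_low, snr_floor = 3)$below_detection)
  # nothing accepted at all -> error
  mm_none <- match_species(peaklist(numeric(), numeric()), preds)
  expect_error(methylation_fraction(mm_none), "no accepted")
})

test_that("calibration fit recovers a known response factor", {
  # perfect identity: slope 1, intercept 0, apply is the identity
  f <- seq(0.1, 0.9, by = 0.1)
  pts <- data.frame(fraction = f, ratio = f / (1 - f))
  cal <- fit_calibration(pts)
  expect_equal(cal$slope, 1, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(apply_calibration(cal, f), f, tolerance = 1e-9)
  # response factor 0.8: slope 0.8, apply inverts the bias
  pts8 <- data.frame(fraction = f, ratio = 0.8 * f / (1 - f))
  cal8 <- fit_calibration(pts8)
  expect_equal(cal8$slope, 0.8, tolerance = 1e-9)
  raw <- 0.8 * f / (1 - f) / (1 + 0.8 * f / (1 - f))   # measured fraction
  expect_equal(apply_calibration(cal8, raw), f, tolerance = 1e-9)
  # clamping
  expect_equal(apply_calibration(cal8, 1), 1)
  expect_equal(apply_calibration(cal8, 0), 0)
  expect_error(fit_calibration(pts[1, ]), ">= 2")
  expect_error(fit_calibration(data.frame(fraction = c(0.5, 0.5),
                                          ratio = c(1, 1.1))), "distinct")
})

test_that("simulator-based calibration recovers slope 0.8 within 0.05", {
  ol <- oligo(mir17)
  cfg <- sim_config(ol, mass_error_ppm = 20, intensity_cv = 0.05,
                    response_factor = 0.8, seed = 20260910)
  series <- simulate_calibration_series(seq(0.1, 0.9, 0.1),
                                        replicates = 5, cfg)
  preds <- predict_species(ol, kmax = 1)
  ratio <- vapply(series$peaklist, function(pl) {
    mm <- match_species(pl, preds)
    ik <- mm$intensity[mm$k == 1] / mm$intensity[mm$k == 0]
    ik
  }, numeric(1))
  cal <- fit_calibration(data.frame(fraction = series$fraction,
                                    ratio = ratio))
  expect_equal(cal$slope, 0.8, tolerance = 0.05 / 0.8)
})

test_that("isotope overlap correction is a guarded no-op at 14 Da spacing", {
  ol <- oligo(mir17)
  preds <- predict_species(ol, kmax = 1)
  mm <- match_species(peaklist(preds$mz, c(100, 50)), preds)
  envs <- list("0" = isotope_envelope(oligo_composition(ol),
                                      truncation = 1e-4))
  out <- isotope_overlap_correction(mm, envs)
  # envelope mass range stays far below 14 Da at this truncation
  expect_lt(max(envs[["0"]]$mass) - min(envs[["0"]]$mass), 14)
  expect_equal(out$intensity_corrected, out$intensity, tolerance = 1e-12)
  # artificially broadened envelope overlapping the next species
  fake <- data.frame(mass = envs[["0"]]$mass[1] + c(0, 14.0157),
                     abundance = c(0.8, 0.2))
  out2 <- isotope_overlap_correction(mm, list("0" = fake))
  expect_lt(out2$intensity_corrected[out2$k == 1],
            out2$intensity[out2$k == 1])
  expect_gte(out2$intensity_corrected[out2$k == 1], 0)
})
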