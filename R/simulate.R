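# Seeded synthetic-data generator.  Emulates: intact negative-mode MALDI
# spectra of 20-25 nt miRNAs carrying 0-3 methyls at configurable
# stoichiometry, mass error, intensity noise and Na/K adducts; MS/MS
# ladders with configurable coverage; calibration dilution series of
# synthetic methylated/non-methylated standards; and two-group cohorts
# with elevated methylation fractions in cancer.
#
# A single global seed fans out to fixed per-component substreams so that
# adding a simulation stage never perturbs earlier draws.

.SIM_STREAM <- c(intact = 101L, msms = 211L, calibration = 307L,
                 cohort = 401L, noise = 503L)

.substream_seed <- function(seed, component, index = 0L) {
  # deterministic 31-bit mix; keeps derived seeds valid R integers
  s <- (as.numeric(seed) * 48271 + .SIM_STREAM[[component]] * 7919 +
          as.numeric(index)) %% 2147483647
  as.integer(s)
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' @param x An [oligo()] (or sequence string) the spectra are generated for.
#' @param fractions Named numeric vector of true molar fractions per methyl
#'   count, names `"0"`, `"1"`, ... (e.g. `c("0" = 0.7, "1" = 0.3)`);
#'   must sum to 1.
#' @param mass_error_ppm Gaussian m/z jitter (sd, ppm).  Default 20.
#' @param intensity_cv Lognormal intensity coefficient of variation.
#'   Default 0.05.
#' @param adduct_rates Named rates in \[0, 1\] for `Na` and `K` adducts
#'   (fraction of each species' signal diverted to the adduct peak).
#' @param response_factor Relative ionization efficiency of methylated
#'   (k >= 1) species; 1 = no bias, 0.8 emulates a methylated standard
#'   ionizing at 80% efficiency.
#' @param baseline_noise Mean intensity of chemical-noise peaks; 0 disables
#'   them.
#' @param n_noise_peaks Number of noise peaks when `baseline_noise > 0`.
#' @param coverage Per-fragment observation probability for MS/MS ladders.
#' @param total_intensity Total signal intensity budget.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(x, fractions = c("0" = 0.5, "1" = 0.5),
                       mass_error_ppm = 20, intensity_cv = 0.05,
                       adduct_rates = c(Na = 0, K = 0),
                       response_factor = 1,
                       baseline_noise = 0, n_noise_peaks = 50L,
                       coverage = 1, total_intensity = 1000,
                       seed = 1L) {
  if (is.character(x)) x <- oligo(x)
  stopifnot(inherits(x, "oligo"))
  fractions <- fractions[fractions > 0]
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must sum to 1", call. = FALSE)
  }
  if (is.null(names(fractions)) ||
      any(is.na(suppressWarnings(as.integer(names(fractions)))))) {
    stop("`fractions` must be named by methyl count ('0', '1', ...)",
         call. = FALSE)
  }
  adduct_rates <- adduct_rates[c("Na", "K")]
  adduct_rates[is.na(adduct_rates)] <- 0
  names(adduct_rates) <- c("Na", "K")
  rates <- c(adduct_rates, coverage)
  if (any(rates < 0 | rates > 1)) {
    stop("adduct rates and coverage must lie in [0, 1]", call. = FALSE)
  }
  if (sum(adduct_rates) > 1) stop("adduct rates sum above 1", call. = FALSE)
  stopifnot(mass_error_ppm >= 0, intensity_cv >= 0, response_factor > 0,
            baseline_noise >= 0, total_intensity > 0)
  structure(list(oligo = x, fractions = fractions,
                 mass_error_ppm = mass_error_ppm,
                 intensity_cv = intensity_cv,
                 adduct_rates = adduct_rates,
                 response_factor = response_factor,
                 baseline_noise = baseline_noise,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 coverage = coverage, total_intensity = total_intensity,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))   # unit mean
}

#' Simulate an intact MALDI spectrum
#'
#' One peak per (methyl count k, adduct) species.  Expected intensity is
#' `total_intensity * fraction_k * rate_adduct`, times the response factor
#' for methylated species, times unit-mean lognormal noise at the
#' configured CV; m/z is jittered by Gaussian ppm error.  Reproducible for
#' a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A [peaklist()] with `snr` (intensity over baseline noise, or
#'   over 1 when baseline noise is disabled).
#' @export
simulate_intact <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.substream_seed(config$seed, "intact"), {
    ks <- as.integer(names(config$fractions))
    adducts <- names(config$adduct_rates)[config$adduct_rates > 0]
    preds <- predict_species(config$oligo, kmax = max(ks), adducts = adducts)
    preds <- preds[preds$k %in% ks, , drop = FALSE]
    main_rate <- 1 - sum(config$adduct_rates)
    rate <- ifelse(preds$adduct == "none", main_rate,
                   config$adduct_rates[preds$adduct])
    frac <- config$fractions[as.character(preds$k)]
    rf <- ifelse(preds$k >= 1, config$response_factor, 1)
    inten <- config$total_intensity * frac * rate * rf *
      .lognorm_mult(nrow(preds), config$intensity_cv)
    mz <- preds$mz *
      (1 + stats::rnorm(nrow(preds), 0, config$mass_error_ppm * 1e-6))
    keep <- inten > 0
    mz <- mz[keep]; inten <- inten[keep]
    noise_level <- 1
    if (config$baseline_noise > 0 && config$n_noise_peaks > 0) {
      noise_level <- config$baseline_noise
      span <- range(preds$mz)
      nmz <- stats::runif(config$n_noise_peaks,
                          span[1] - 100, span[2] + 100)
      nint <- stats::rexp(config$n_noise_peaks, 1 / config$baseline_noise)
      mz <- c(mz, nmz); inten <- c(inten, nint)
      keep <- inten > 0
      mz <- mz[keep]; inten <- inten[keep]
    }
    pl <- peaklist(mz, inten, provenance = "simulate_intact")
    pl$snr <- pl$intensity / noise_level
    pl
  })
}

#' Simulate an MS/MS fragment spectrum
#'
#' Each theoretical ladder fragment of the configured oligo (with its
#' modifications) is observed with probability `coverage`; observed
#' fragments get lognormal intensities and ppm-jittered m/z.  At coverage
#' 1 and zero noise the peak set equals the theoretical ladder exactly.
#'
#' @param config A [sim_config()]; the oligo's own modification list
#'   defines the true site(s).
#' @param series Ion series (default `c("c", "y", "w", "a-B")`).
#' @return A [peaklist()] with `ms_level = 2`.
#' @export
simulate_msms <- function(config, series = c("c", "y", "w", "a-B")) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.substream_seed(config$seed, "msms"), {
    ladder <- fragment_ladder(config$oligo, series = series)
    keep <- stats::runif(nrow(ladder)) <= config$coverage
    ladder <- ladder[keep, , drop = FALSE]
    if (!nrow(ladder)) {
      return(peaklist(numeric(), numeric(), ms_level = 2L,
                      precursor_mz = mz_from_mass(oligo_mass(config$oligo)),
                      provenance = "simulate_msms"))
    }
    inten <- 100 * .lognorm_mult(nrow(ladder), config$intensity_cv)
    mz <- ladder$mz *
      (1 + stats::rnorm(nrow(ladder), 0, config$mass_error_ppm * 1e-6))
    # two fragments can collide on the m/z axis after jitter; merge
    ord <- order(mz)
    mz <- mz[ord]; inten <- inten[ord]
    while (any(diff(mz) <= 0)) {
      i <- which(diff(mz) <= 0)[1]
      inten[i] <- inten[i] + inten[i + 1]
      mz <- mz[-(i + 1)]; inten <- inten[-(i + 1)]
    }
    peaklist(mz, inten, ms_level = 2L,
             precursor_mz = mz_from_mass(oligo_mass(config$oligo)),
             provenance = "simulate_msms")
  })
}

#' Simulate a calibration dilution series
#'
#' Emulates mixing synthetic methylated and non-methylated standards at
#' known molar fractions, each measured in replicate — the dynamic-range
#' design behind the calibration curve.
#'
#' @param fractions Known molar fractions of the methylated standard
#'   (non-empty, values in \[0, 1)).
#' @param replicates Replicate spectra per level.
#' @param config A [sim_config()]; its `fractions` field is overridden per
#'   level, its seed fans out per (level, replicate).
#' @return Data frame with columns `fraction`, `replicate` and a list
#'   column `peaklist`.
#' @export
simulate_calibration_series <- function(fractions, replicates = 3L, config) {
  if (!length(fractions)) stop("`fractions` must be non-empty", call. = FALSE)
  if (any(fractions < 0 | fractions >= 1)) {
    stop("calibration fractions must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(inherits(config, "sim_config"))
  grid <- expand.grid(replicate = seq_len(replicates),
                      fraction = fractions)[, 2:1]
  pls <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- grid$fraction[i]
    cfg <- config
    cfg$fractions <- c("0" = 1 - f, "1" = f)
    cfg$fractions <- cfg$fractions[cfg$fractions > 0]
    cfg$seed <- .substream_seed(config$seed, "calibration", i)
    pls[[i]] <- simulate_intact(cfg)
  }
  grid$peaklist <- pls
  grid
}

.rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd <= 0) return(pmin(hi, pmax(lo, rep(mean, n))))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a two-group methylation cohort
#'
#' Per-sample methylation fractions are drawn from Gaussians truncated to
#' \[0, 1\]; in paired mode case and control values of a pair share a
#' latent subject effect (correlation `rho`).  Optional serum tumor-marker
#' columns (CA19-9, CEA) are drawn lognormally with group-dependent
#' location, giving the configurable case/control overlap used for ROC
#' comparison.
#'
#' @param n_case,n_control Group sizes (equal when `paired = TRUE`).
#' @param case_fraction_mean,control_fraction_mean Truncated-Gaussian means.
#' @param sd Truncated-Gaussian sd (both groups).
#' @param paired Draw correlated pairs sharing a `pair_id`.
#' @param rho Latent correlation of paired draws (default 0.5).
#' @param markers Add CA19-9 / CEA columns.
#' @param marker_meanlog Named list of lognormal meanlogs per marker and
#'   group.
#' @param marker_sdlog Named lognormal sdlogs per marker.
#' @param seed Integer seed.
#' @return Data frame (`cohort_table`): `sample_id`, `group`, `pair_id`
#'   (paired mode), `fraction`, and marker columns when requested.
#' @export
simulate_cohort <- function(n_case, n_control,
                            case_fraction_mean = 0.3,
                            control_fraction_mean = 0.05,
                            sd = 0.1, paired = FALSE, rho = 0.5,
                            markers = FALSE,
                            marker_meanlog = list(
                              CA19_9 = c(case = log(100), control = log(20)),
                              CEA = c(case = log(5), control = log(2))),
                            marker_sdlog = c(CA19_9 = 1, CEA = 0.6),
                            seed = 1L) {
  if (paired && n_case != n_control) {
    stop("paired cohorts need n_case == n_control", call. = FALSE)
  }
  .with_seed(.substream_seed(seed, "cohort"), {
    if (paired) {
      n <- n_case
      # shared + independent standard-normal components, then per-group
      # location/scale and truncation by clamped inverse-CDF resampling
      z_shared <- stats::rnorm(n)
      z_case <- sqrt(rho) * z_shared + sqrt(1 - rho) * stats::rnorm(n)
      z_ctrl <- sqrt(rho) * z_shared + sqrt(1 - rho) * stats::rnorm(n)
      to_frac <- function(z, mean) {
        p <- stats::pnorm(z)
        plo <- stats::pnorm(0, mean, sd); phi <- stats::pnorm(1, mean, sd)
        stats::qnorm(plo + p * (phi - plo), mean, sd)
      }
      case_f <- to_frac(z_case, case_fraction_mean)
      ctrl_f <- to_frac(z_ctrl, control_fraction_mean)
      out <- data.frame(
        sample_id = c(sprintf("case_%02d", seq_len(n)),
                      sprintf("control_%02d", seq_len(n))),
        group = rep(c("case", "control"), each = n),
        pair_id = rep(sprintf("pair_%02d", seq_len(n)), 2),
        fraction = c(case_f, ctrl_f),
        stringsAsFactors = FALSE)
    } else {
      case_f <- .rtrunc_norm(n_case, case_fraction_mean, sd)
      ctrl_f <- .rtrunc_norm(n_control, control_fraction_mean, sd)
      out <- data.frame(
        sample_id = c(sprintf("case_%02d", seq_len(n_case)),
                      sprintf("control_%02d", seq_len(n_control))),
        group = rep(c("case", "control"), c(n_case, n_control)),
        fraction = c(case_f, ctrl_f),
        stringsAsFactors = FALSE)
    }
    if (markers) {
      for (m in names(marker_meanlog)) {
        ml <- marker_meanlog[[m]][out$group]
        out[[m]] <- stats::rlnorm(nrow(out), ml, marker_sdlog[[m]])
      }
    }
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
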