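#' Characteristic Raman bands of crude palm oil
#'
#' Band positions cover the lipid skeleton (C-C stretches, CH2 deformation
#' and scissoring, cis C=C, ester C=O) plus the three carotenoid bands at
#' 1006, 1156 and 1533 cm^-1 whose height scales with beta-carotene
#' concentration. For carotene-linked bands `amplitude` is the intensity
#' per unit of `carotene_gain * conc` (the carotene-free oil contributes
#' nothing at these positions); for lipid bands it is the fixed peak
#' height. FWHM values are typical widths for condensed-phase Raman bands.
#'
#' @return Data frame with columns `center`, `fwhm`, `amplitude`,
#'   `carotene_linked`, `assignment`.
#' @export
palm_oil_bands <- function() {
  data.frame(
    center = c(848, 868, 1006, 1079, 1156, 1304, 1445, 1533, 1663, 1754),
    fwhm   = c(14, 14, 12, 18, 14, 20, 22, 18, 20, 16),
    amplitude = c(0.15, 0.12, 0.45, 0.25, 1.00, 0.35, 1.00, 0.90, 0.45, 0.30),
    carotene_linked = c(FALSE, FALSE, TRUE, FALSE, TRUE,
                        FALSE, FALSE, TRUE, FALSE, FALSE),
    assignment = c(
      "C-C stretching",
      "C-C stretching",
      "C-CH3 in-plane rocking (carotenoid)",
      "C-C stretching of (CH2)n",
      "C-C stretching (carotenoid)",
      "C-H bending twist of CH2",
      "C-H scissoring of CH2",
      "C=C stretching (carotenoid)",
      "C=C / cis C-H of unsaturated fatty acids",
      "C=O ester stretching"
    ),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for palm-oil Raman spectra
#'
#' Defines the axis, band list, carotene response, fluorescence-like
#' baseline, noise and replicate-variation model used by all simulators.
#' The default axis (400-2300 cm^-1, 1 cm^-1 step) matches a handheld
#' 1064 nm instrument's acquisition range.
#'
#' @param axis_start,axis_end,axis_step Axis limits and spacing (cm^-1).
#' @param bands Band table as returned by [palm_oil_bands()]; columns
#'   `center`, `fwhm`, `amplitude`, `carotene_linked`.
#' @param carotene_conc Beta-carotene concentration (mM).
#' @param carotene_gain Peak intensity per mM multiplying carotene-band
#'   amplitudes.
#' @param baseline_coeffs Polynomial coefficients (ascending degree) in the
#'   rescaled coordinate u = (x - axis_start)/(axis_end - axis_start); the
#'   default cubic rises gently, emulating fluorescence background.
#' @param noise_sd Additive Gaussian noise standard deviation as a fraction
#'   of the noise-free spectrum maximum (0.01 = 1 percent).
#' @param replicate_jitter Relative standard deviation of the multiplicative
#'   amplitude factor applied to the band sum of each measured replicate
#'   (day-to-day intensity variation); baseline unaffected.
#' @param seed Integer seed or NULL.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(axis_start = 400, axis_end = 2300, axis_step = 1,
                       bands = palm_oil_bands(),
                       carotene_conc = 0, carotene_gain = 1,
                       baseline_coeffs = c(0.5, 0.8, 0.6, 0.2),
                       noise_sd = 0.01, replicate_jitter = 0.02,
                       seed = NULL) {
  if (axis_step <= 0) stop("axis_step must be positive")
  if (axis_start >= axis_end) stop("axis_start must be below axis_end")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (carotene_conc < 0) stop("carotene_conc must be non-negative")
  if (replicate_jitter < 0) stop("replicate_jitter must be non-negative")
  bands <- as.data.frame(bands)
  if (any(bands$fwhm <= 0)) stop("band fwhm must be positive")
  if (any(bands$amplitude < 0)) stop("band amplitudes must be non-negative")
  structure(list(axis_start = axis_start, axis_end = axis_end,
                 axis_step = axis_step, bands = bands,
                 carotene_conc = carotene_conc,
                 carotene_gain = carotene_gain,
                 baseline_coeffs = baseline_coeffs,
                 noise_sd = noise_sd,
                 replicate_jitter = replicate_jitter,
                 seed = seed),
            class = "sim_config")
}

sim_axis <- function(config) {
  seq(config$axis_start, config$axis_end, by = config$axis_step)
}

# Lorentzian line shape: height `amp` at `center`, full width `fwhm` at
# half that height.
lorentzian <- function(x, center, fwhm, amp) {
  amp / (1 + ((x - center) / (fwhm / 2))^2)
}

#' Evaluate the polynomial baseline of a configuration
#' @param config A `sim_config`.
#' @param axis Optional axis; defaults to the config's axis.
#' @return Baseline intensity vector.
#' @export
sim_baseline <- function(config, axis = sim_axis(config)) {
  u <- (axis - config$axis_start) / (config$axis_end - config$axis_start)
  drop(outer(u, seq_along(config$baseline_coeffs) - 1, `^`) %*%
         config$baseline_coeffs)
}

#' Noise-free band sum for a given carotene concentration
#'
#' Lipid bands contribute their fixed amplitude; carotene-linked bands
#' contribute `amplitude * carotene_gain * conc`, so the carotene signal
#' is additive with height linear in concentration and absent at 0 mM.
#'
#' @param config A `sim_config`.
#' @param conc Carotene concentration (mM); defaults to the config's.
#' @param axis Optional axis.
#' @return Band-sum intensity vector (no baseline, no noise).
#' @export
sim_band_sum <- function(config, conc = config$carotene_conc,
                         axis = sim_axis(config)) {
  b <- config$bands
  y <- numeric(length(axis))
  for (k in seq_len(nrow(b))) {
    amp <- if (b$carotene_linked[k]) {
      b$amplitude[k] * config$carotene_gain * conc
    } else {
      b$amplitude[k]
    }
    if (amp > 0) y <- y + lorentzian(axis, b$center[k], b$fwhm[k], amp)
  }
  y
}

#' Simulate one Raman spectrum
#'
#' Intensity = band sum + polynomial baseline + additive Gaussian noise
#' whose sd is `noise_sd` times the noise-free maximum. Identical
#' configuration and seed give bit-identical output.
#'
#' @param config A `sim_config`.
#' @return A `spectrum` with `true_conc_mM` in its metadata.
#' @export
simulate_spectrum <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  axis <- sim_axis(config)
  check_band_coverage(config, axis)
  clean <- sim_band_sum(config) + sim_baseline(config)
  y <- with_seed(config$seed, {
    if (config$noise_sd > 0) {
      clean + stats::rnorm(length(clean), sd = config$noise_sd * max(clean))
    } else clean
  })
  spectrum(axis, y, meta = list(true_conc_mM = config$carotene_conc))
}

check_band_coverage <- function(config, axis = sim_axis(config)) {
  outside <- config$bands$center < min(axis) | config$bands$center > max(axis)
  if (any(outside)) {
    warning(sprintf("band center(s) %s lie outside the simulated axis",
                    paste(config$bands$center[outside], collapse = ", ")))
  }
  invisible(NULL)
}

# One noisy realisation drawn inside an existing RNG stream (no re-seeding):
# used by the set-level simulators so a single seed covers the whole set.
sim_draw <- function(config, conc, jitter_factor = 1) {
  clean <- jitter_factor * sim_band_sum(config, conc) + sim_baseline(config)
  if (config$noise_sd > 0) {
    clean + stats::rnorm(length(clean), sd = config$noise_sd * max(clean))
  } else clean
}

#' Simulate a spiked-standard calibration set
#'
#' Emulates the calibration design for beta-carotene quantification:
#' carotene spiked into a carotene-free base oil at a ladder of
#' concentrations, several independently prepared replicates per level,
#' one spectrum per preparation. The default design of the quantitative
#' model is 0 to 2 mM in 0.1 mM steps with 3 replicates (63 spectra).
#'
#' @param conc_start,conc_end,conc_step Concentration ladder (mM).
#' @param replicates Preparations per level.
#' @param config A `sim_config`; its `seed` drives the whole set.
#' @return A `spectrum_set`; metadata has `sample_id`, `origin`
#'   ("standard"), `replicate` and `true_conc_mM`.
#' @export
simulate_calibration_set <- function(conc_start = 0, conc_end = 2,
                                     conc_step = 0.1, replicates = 3,
                                     config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (conc_step <= 0) stop("conc_step must be positive")
  if (replicates < 1) stop("replicates must be at least 1")
  if (conc_end < conc_start) stop("conc_end must not be below conc_start")
  levels <- seq(conc_start, conc_end, by = conc_step)
  axis <- sim_axis(config)
  check_band_coverage(config, axis)
  design <- expand.grid(replicate = seq_len(replicates), conc = levels)
  design <- design[order(design$conc, design$replicate), ]
  ids <- sprintf("std_%05.2fmM_r%d", design$conc, design$replicate)
  Y <- with_seed(config$seed, {
    vapply(seq_len(nrow(design)), function(i) {
      jit <- if (config$replicate_jitter > 0) {
        1 + stats::rnorm(1, sd = config$replicate_jitter)
      } else 1
      sim_draw(config, design$conc[i], jit)
    }, numeric(length(axis)))
  })
  colnames(Y) <- ids
  spectrum_set(axis, Y, data.frame(
    spectrum_id = ids,
    sample_id = ids,  # each preparation is an independent sample
    origin = "standard",
    replicate = design$replicate,
    true_conc_mM = design$conc,
    stringsAsFactors = FALSE
  ))
}

#' Define an origin profile for panel simulation
#'
#' @param name Origin label (e.g. a country or mill).
#' @param carotene_mean,carotene_sd Mean and sd (mM) of the per-sample
#'   carotene concentration, drawn from a normal truncated at zero.
#' @param n_samples Oils from this origin.
#' @param replicates Measured spectra per oil (defaults to triplicate).
#' @return A list of class `origin_profile`.
#' @export
origin_profile <- function(name, carotene_mean, carotene_sd = 0,
                           n_samples = 1, replicates = 3) {
  if (carotene_mean < 0) stop("carotene_mean must be non-negative")
  if (carotene_sd < 0) stop("carotene_sd must be non-negative")
  if (n_samples < 1) stop("n_samples must be at least 1")
  structure(list(name = name, carotene_mean = carotene_mean,
                 carotene_sd = carotene_sd, n_samples = n_samples,
                 replicates = replicates),
            class = "origin_profile")
}

# Truncated-at-zero normal draw by rejection; sd = 0 returns the mean.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= 0) break
    }
    out[i] <- x
  }
  out
}

#' Simulate a multi-origin panel of oils
#'
#' Each oil's true carotene concentration is drawn from its origin's
#' truncated normal; each oil is then measured `replicates` times with
#' per-measurement amplitude jitter and fresh noise, mimicking repeat
#' acquisition on separate days. Ground truth is kept in the metadata.
#'
#' @param profiles List of [origin_profile()] objects.
#' @param config A `sim_config`; its `seed` drives the whole panel.
#' @return A `spectrum_set` with metadata columns `sample_id`, `origin`,
#'   `replicate`, `true_conc_mM`.
#' @export
simulate_origin_panel <- function(profiles, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(profiles, "origin_profile")) profiles <- list(profiles)
  if (length(profiles) == 0) stop("at least one origin profile is required")
  axis <- sim_axis(config)
  check_band_coverage(config, axis)
  with_seed(config$seed, {
    cols <- list(); meta <- list()
    for (pr in profiles) {
      stopifnot(inherits(pr, "origin_profile"))
      concs <- rtruncnorm0(pr$n_samples, pr$carotene_mean, pr$carotene_sd)
      for (s in seq_len(pr$n_samples)) {
        sid <- sprintf("%s_%02d", pr$name, s)
        for (r in seq_len(pr$replicates)) {
          jit <- if (config$replicate_jitter > 0) {
            1 + stats::rnorm(1, sd = config$replicate_jitter)
          } else 1
          cols[[length(cols) + 1L]] <- sim_draw(config, concs[s], jit)
          meta[[length(meta) + 1L]] <- data.frame(
            spectrum_id = sprintf("%s_r%d", sid, r),
            sample_id = sid, origin = pr$name, replicate = r,
            true_conc_mM = concs[s], stringsAsFactors = FALSE)
        }
      }
    }
    Y <- do.call(cbind, cols)
    md <- do.call(rbind, meta)
    colnames(Y) <- md$spectrum_id
    spectrum_set(axis, Y, md)
  })
}

#' Simulate 1H-NMR fatty-acid integrals from a known composition
#'
#' Forward proton-counting model for the three diagnostic lipid signals:
#' per chain, the terminal CH3 carries 3 protons (signal iii, all chains),
#' the bis-allylic CH2 of linoleic carries 2 protons (signal ii), and the
#' olefinic protons number 2 for oleic and 4 for linoleic (signal i).
#' With chain counts N_x = total_chains * pct_x / 100:
#' I_iii = 3 N_total, I_ii = 2 N_linoleic,
#' I_i = 2 N_oleic + 4 N_linoleic.
#'
#' @param composition A [fatty_acid_composition()] (percentages summing
#'   to 100).
#' @param total_chains Total chain count setting the integral scale.
#' @param noise_rel Relative sd of multiplicative noise per integral.
#' @param seed Integer seed or NULL.
#' @return A list of class `nmr_integrals` with elements `i_olefinic`,
#'   `i_bis_allylic`, `i_ch3`.
#' @export
simulate_nmr_integrals <- function(composition, total_chains = 1,
                                   noise_rel = 0, seed = NULL) {
  comp <- as_fatty_acid_composition(composition)
  n_tot <- total_chains
  n_ole <- total_chains * comp$oleic_pct / 100
  n_lin <- total_chains * comp$linoleic_pct / 100
  ints <- c(i_olefinic = 2 * n_ole + 4 * n_lin,
            i_bis_allylic = 2 * n_lin,
            i_ch3 = 3 * n_tot)
  if (noise_rel > 0) {
    ints <- with_seed(seed,
      ints * (1 + stats::rnorm(3, sd = noise_rel)))
    ints <- pmax(ints, 0)
  }
  nmr_integrals(ints[["i_olefinic"]], ints[["i_bis_allylic"]],
                ints[["i_ch3"]])
}
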