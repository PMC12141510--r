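test_that("zero-noise spectra equal the analytic band-sum plus baseline", {
  cfg <- sim_config(noise_sd = 0, carotene_conc = 0.7)
  sp <- simulate_spectrum(cfg)
  expect_equal(sp$intensity, analytic_spectrum(cfg), tolerance = 1e-12)
  # zero concentration: carotene bands contribute nothing anywhere
  cfg0 <- sim_config(noise_sd = 0, carotene_conc = 0)
  no_car <- cfg0
  no_car$bands <- cfg0$bands[!cfg0$bands$carotene_linked, ]
  expect_equal(simulate_spectrum(cfg0)$intensity, analytic_spectrum(no_car),
               tolerance = 1e-12)
})

test_that("carotene band height above baseline is linear in concentration", {
  at <- function(conc) {
    cfg <- sim_config(noise_sd = 0, carotene_conc = conc)
    sp <- simulate_spectrum(cfg)
    sp$intensity[sp$axis == 1156] - sim_baseline(cfg)[sp$axis == 1156]
  }
  h0 <- at(0); h05 <- at(0.5); h1 <- at(1)
  expect_equal(h1 - h0, 2 * (h05 - h0), tolerance = 1e-12)
  # slope equals carotene_gain * band amplitude at the band centre
  # (plus fixed lipid tails, removed by the h0 offset; small carotene
  # cross-band tails make the pointwise slope slightly exceed the
  # centre-band amplitude)
  bands <- palm_oil_bands()
  amp_1156 <- bands$amplitude[bands$center == 1156]
  expect_gte(h1 - h0, amp_1156)
  expect_lt(h1 - h0, amp_1156 * 1.05)
})

test_that("simulation is seed-deterministic and validates its inputs", {
  cfg <- sim_config(seed = 7)
  expect_identical(simulate_spectrum(cfg)$intensity,
                   simulate_spectrum(cfg)$intensity)
  expect_error(sim_config(axis_step = 0), "axis_step")
  expect_warning(
    simulate_spectrum(sim_config(axis_start = 1200, axis_end = 2300,
                                 noise_sd = 0)),
    "outside the simulated axis")
  # simulation must not disturb the caller's RNG stream
  set.seed(42); before <- stats::rnorm(1)
  set.seed(42); invisible(simulate_spectrum(cfg)); after <- stats::rnorm(1)
  expect_identical(before, after)
})

test_that("calibration designs produce the expected spectra and levels", {
  cfg <- sim_config(seed = 3)
  full <- simulate_calibration_set(0, 2, 0.1, 3, cfg)
  expect_equal(n_spectra(full), 63)
  expect_equal(length(unique(full$metadata$true_conc_mM)), 21)
  restricted <- simulate_calibration_set(0.1, 0.5, 0.1, 3, cfg)
  expect_equal(n_spectra(restricted), 15)
  blank <- simulate_calibration_set(0, 0, 0.1, 1, cfg)
  expect_equal(n_spectra(blank), 1)
  expect_equal(blank$metadata$true_conc_mM, 0)
  expect_error(simulate_calibration_set(1, 0.5, 0.1, 3, cfg), "conc_end")
})

test_that("origin panels have per-sample ground truth and replicates", {
  cfg <- sim_config(seed = 11)
  panel <- simulate_origin_panel(
    list(origin_profile("X", 0.5, 0.2, n_samples = 5, replicates = 3)), cfg)
  expect_equal(n_spectra(panel), 15)
  expect_equal(length(unique(panel$metadata$sample_id)), 5)
  expect_true(all(panel$metadata$true_conc_mM >= 0))
  # replicates of one sample share the drawn concentration
  expect_true(all(tapply(panel$metadata$true_conc_mM,
                         panel$metadata$sample_id,
                         function(v) diff(range(v))) == 0))
  # no randomness at all: within-profile spectra identical
  det <- simulate_origin_panel(
    list(origin_profile("Y", 0.8, 0, n_samples = 3, replicates = 2)),
    sim_config(noise_sd = 0, replicate_jitter = 0))
  expect_true(all(apply(det$intensities, 1,
                        function(r) diff(range(r)) == 0)))
  expect_error(simulate_origin_panel(list(), cfg), "at least one")
})

test_that("NMR integral simulation follows proton stoichiometry", {
  sat <- simulate_nmr_integrals(fatty_acid_composition(0, 0, 100))
  expect_equal(unlist(sat[c("i_olefinic", "i_bis_allylic", "i_ch3")]),
               c(i_olefinic = 0, i_bis_allylic = 0, i_ch3 = 3))
  ole <- simulate_nmr_integrals(fatty_acid_composition(100, 0, 0))
  expect_equal(unlist(ole[c("i_olefinic", "i_bis_allylic", "i_ch3")]),
               c(i_olefinic = 2, i_bis_allylic = 0, i_ch3 = 3))
  expect_error(fatty_acid_composition(-5, 55, 50), "non-negative")
  # integral scale follows total_chains
  big <- simulate_nmr_integrals(fatty_acid_composition(50, 25, 25),
                                total_chains = 10)
  expect_equal(big$i_ch3, 30)
})
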