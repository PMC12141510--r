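# palmspec

Chemometrics for tracing edible oils — in particular crude palm oil —
from vibrational spectra. Crude palm oil is red-orange because of
beta-carotene, and carotene content varies with the oil's source; a
handheld Raman spectrometer sees this as three carotenoid bands (1006,
1156 and 1533 cm⁻¹) superimposed on the lipid fingerprint. `palmspec`
implements the analysis chain that exploits this for authentication:

* a **seeded simulator** for palm-oil Raman spectra (Lorentzian bands on
  a fluorescence-like baseline, carotene bands linear in concentration,
  replicate jitter, additive noise) and for lipid ¹H-NMR integrals, with
  known ground truth;
* **preprocessing**: asymmetric-least-squares (Whittaker-type) baseline
  correction, Savitzky–Golay smoothing (2nd-order, 11-point), and vector
  normalization — with the regression path using vector normalization
  only;
* **PCA** (mean-centred SVD) for origin discrimination, sign-aligned so
  carotene-rich oils score positive on PC-1;
* a from-scratch **NIPALS PLS regression** for carotene quantification
  with grouped leave-one-preparation-out cross-validation, training R²,
  Q², RMSECV, RMSEP, and a restricted-range limit of detection
  LoD = 3.3·s/slope;
* **ranking** of oils by predicted carotene with Spearman correlation
  against PC-1 position;
* **NMR fatty-acid stoichiometry**: oleic/linoleic/saturated chain
  percentages from three proton integrals
  (N_tot = I_CH₃/3, N_lin = I_bis-allylic/2,
  N_ole = (I_olefinic − 2·I_bis-allylic)/2), and nearest-reference
  classification of palm vs palm-kernel oil.

It is written for analytical chemists and food-authenticity researchers
who want a tested, reproducible reference implementation of this
workflow; the methods vignette (`vignettes/oil-chemometrics.Rmd`)
explains every model, default and numerical choice.

## Worked example

Calibrate on a simulated spiked-standard series reproducing the
canonical design — carotene spiked into a carotene-free base oil at 0–2
mM in 0.1 mM steps, three preparations per level, 1% noise — then rank
a three-origin oil panel:

```r
library(palmspec)

cal   <- simulate_calibration_set(0, 2, 0.1, 3, sim_config(seed = 1))
cal_v <- preprocess_set(cal, "plsr_path")          # vector normalize only
tst_v <- preprocess_set(simulate_calibration_set(0, 2, 0.1, 3,
                                                 sim_config(seed = 2)),
                        "plsr_path")

model <- calibration_metrics(
  spectra_matrix(cal_v), cal_v$metadata$true_conc_mM,
  X_test = spectra_matrix(tst_v), y_test = tst_v$metadata$true_conc_mM,
  groups = cal_v$metadata$sample_id)
model
#> <plsr_model> 3 latent variable(s), 1901 variables
#>   r2 = 1, q2 = 0.9989, rmsecv = 0.02017, rmsep = 0.01727, n_lv = 3

compute_lod(cal_v)   # sub-model restricted to 0.1-0.5 mM
#> <lod_result> LoD = 0.03001 mM (slope 0.8568, residual sd 0.007792 mM, n = 15)
```

The cross-validated error (RMSECV, in mM) doubles as the threshold
below which a predicted concentration is flagged "effectively zero".
Now a panel of oils from three simulated origins, discriminated by PCA
and ranked by predicted carotene:

```r
panel <- simulate_origin_panel(list(
  origin_profile("Sodipalm", 0.15, 0.05, n_samples = 4),
  origin_profile("Saykro",   0.80, 0.10, n_samples = 4),
  origin_profile("Volta",    1.50, 0.15, n_samples = 4)),
  sim_config(seed = 3))

pca <- fit_pca(preprocess_set(panel, "pca_path"), 2)
pca
#> <pca_model> 2 components, 36 samples
#>   explained variance: 93.73%, 1.63%
loading_peaks(pca)        # PC-1 is carried by the carotenoid bands
#>   axis    loading
#> 1 1006 0.07550127
#> 2 1156 0.17664565
#> 3 1533 0.16057161

preds <- predict(model, spectra_matrix(preprocess_set(panel, "plsr_path")))
rk <- rank_by_carotene(panel$metadata$sample_id, preds, pca$scores[, 1])
head(rk, 5)
#>   sample_id predicted_mM  pc1_score rank
#> 1  Volta_03    1.8803595 0.42648203    1
#> 2  Volta_02    1.6251153 0.37240653    2
#> 3  Volta_04    1.4982857 0.34272110    3
#> 4  Volta_01    1.1472614 0.22945129    4
#> 5 Saykro_04    0.8136301 0.06963234    5
attr(rk, "spearman_rho")
#> [1] 0.993007
```

The ranking by predicted carotene mirrors the oils' PC-1 positions
(ρ = 0.99 at the default noise level; exactly 1 in the noise-free
limit). Finally, the NMR side — chain composition from three integrals
and palm vs palm-kernel classification:

```r
comp <- composition_from_integrals(c(1.320, 0.266, 3))
unlist(unclass(comp))
#>     oleic_pct  linoleic_pct saturated_pct
#>          39.4          13.3          47.3
classify_oil_type(comp)$label
#> [1] "palm_oil"
```

`run_full_analysis(run_config(seed = 1), "out_dir")` chains all stages
and writes CSV/JSON artefacts plus the exact configuration used.

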