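# myowater

Muscle water T2 (T2w) mapping from multi-echo spin-echo (MESE) MRI, for
researchers who quantify muscle health: T2w of the myocytic water pool is a
biomarker of disease activity (inflammation, edema) that — unlike fat
fraction — reflects processes that can still respond to therapy.  A naive
monoexponential fit of a MESE decay is corrupted both by fat infiltration
and by stimulated echoes from imperfect slice-selective refocusing;
`myowater` removes both confounds.

## The model

Each voxel's echo train is modeled with a two-component extended phase
graph (EPG) simulation with slice-profile-resolved summation:

    S(t) = FF * EPG(T1f, T2f, B1; TE, ETL, profiles)
         + (1 - FF) * EPG(T1w, T2w, B1; TE, ETL, profiles)

with T1f = 365 ms and T1w = 1400 ms fixed, and T2f calibrated per subject
in subcutaneous fat.  Three interchangeable voxel-wise estimators share
this forward model and one parameter space (FF in [0,1], muscle T2w in
[10,80] ms, B1 in [0.4,1.2], T2f in [50,250] ms):

* **`fit_nlsq()`** — bounded Levenberg–Marquardt least squares with a free
  amplitude (the classical reference method);
* **`dict_match()`** — exhaustive dictionary matching by normalized dot
  product on the published parameter grids, with optional SVD compression
  (`compress_svd()` / `match_compressed()`);
* **`predict_muscle()` / `predict_fat()`** — fully connected neural
  regressors trained on synthetic EPG signals with Rician noise
  augmentation (`train_regressor()`), which map a whole subject in seconds
  on a plain CPU.

Around them sits the full subject pipeline — subcutaneous fat segmentation
(`segment_subcutaneous_fat()`), subject-specific fat-T2 calibration
(`calibrate_t2f()`), voxel-wise mapping (`map_subject()`), Dixon
fat-fraction reference maps (`dixon_ff()`), ROI statistics (`roi_stats()`)
— plus method-agreement statistics (`bland_altman()`, `lin_ccc()`,
`pearson_corr()`), Shinnar–Le Roux pulse design and Bloch slice-profile
simulation (`design_slr_pulse()`, `compute_slice_profile()`), and a
digital thigh phantom with known ground truth (`default_thigh_phantom()`,
`make_phantom()`) so every stage is testable without scanner data.
See the methods vignette (`vignettes/muscle-water-t2-methods.Rmd`) for the
science and the design decisions.

## A worked example

Generate a synthetic thigh subject at first-echo SNR 100, calibrate the
fat T2 in the subcutaneous ring, and map two muscle compartments:

```r
library(myowater)

seq <- sequence_preset("siemens")          # TE 7.5 ms, ETL 17, generic profiles

phantom <- make_phantom(default_thigh_phantom(snr = 100), seq, seed = 7)
#> <mese_phantom> 160 x 160 x 1 x 17 stack, 5472 foreground voxels, sigma = 0.00624

cal <- calibrate_t2f(phantom$stack, phantom$masks$ring, seq, method = "dict")
#> <t2f_calibration> T2f = 148.0 ms (dict, 400 valid voxels)

mask <- phantom$masks$muscle_3 | phantom$masks$muscle_7
maps <- map_subject(phantom$stack, cal, seq, method = "dict",
                    muscle_mask = array(mask, c(dim(mask), 1)))
glance(maps)
#> # A tibble: 1 x 7
#>   method t2f_ms n_voxels n_flagged t2w_mean t2w_sd ff_mean
#> 1 dict      148      320         0     42.1   3.98   0.302

roi_stats(maps$t2w, list(muscle_3 = phantom$masks$muscle_3,
                         muscle_7 = phantom$masks$muscle_7), maps$quality)
#> # A tibble: 2 x 4
#>   roi       mean    sd n_voxels
#> 1 muscle_3  43.1  2.51      159
#> 2 muscle_7  41.0  4.81      161
```

The true values are T2w = 43 ms (FF 0.10) for `muscle_3` and 41 ms
(FF 0.50) for `muscle_7`: the per-muscle means land within about 0.1 ms of
truth despite 10% and 50% fat infiltration — the point of the two-component
model.  The calibrated T2f of 148 ms sits 2 ms below the phantom's 150 ms
(the Rician noise floor at SNR 100 pulls the fat decay slightly down).
`autoplot(maps)` shows the T2w/FF/B1 panels; `tidy(maps)` returns the
voxel table.

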