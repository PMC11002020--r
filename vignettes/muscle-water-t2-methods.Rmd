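---
title: "Muscle water T2 mapping: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle water T2 mapping: models, estimators, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myowater)
```

## The problem

In skeletal muscle, the transverse relaxation time of the *water* (myocytic)
component, T2w, is a biomarker of disease activity: it responds to
inflammation and edema, processes that precede irreversible fatty
replacement.  A plain monoexponential fit of a multi-echo spin-echo (MESE)
decay conflates two effects that corrupt T2w:

* **fat infiltration** — intramuscular fat (T2 around 150 ms) mixes into the
  voxel signal and lengthens the apparent T2;
* **stimulated echoes** — the slice-selective refocusing pulses of a 2-D
  MESE sequence do not achieve 180 degrees across the slice, so part of the
  transverse magnetization is stored longitudinally and re-emerges at later
  echoes, again lengthening and modulating the decay.

`myowater` models both effects.  The voxel signal is a two-component
extended-phase-graph (EPG) simulation,

$$S(t) = \mathrm{FF}\cdot\mathrm{EPG}(T_{1f}, T_{2f}, B_1; \mathrm{TE},
\mathrm{ETL}, \mathrm{profiles}) + (1-\mathrm{FF})\cdot
\mathrm{EPG}(T_{1w}, T_{2w}, B_1; \mathrm{TE}, \mathrm{ETL},
\mathrm{profiles}),$$

with T1 fixed at 365 ms (fat) and 1400 ms (water), and the acquisition
described by the echo spacing TE, the echo-train length ETL, and the
excitation/refocusing slice profiles.  Estimation is voxel-wise over
(FF, T2w, B1) with the fat T2 fixed at a subject-specific value calibrated
in subcutaneous fat (FF = 0.9, estimating T2f, T2w, B1 there).

Three interchangeable estimators share this forward model and one parameter
space (FF in [0, 1]; T2w in [10, 80] ms for muscle, [10, 110] ms for fat
calibration; T2f in [50, 250] ms; B1 in [0.4, 1.2]):

1. bounded nonlinear least squares (`fit_nlsq()`),
2. dictionary matching by normalized dot product (`dict_match()`),
   optionally SVD-compressed (`compress_svd()`, `match_compressed()`),
3. fully connected neural regressors trained on synthetic EPG signals
   (`train_regressor()`, `predict_fat()`, `predict_muscle()`).

## EPG simulation

The recursion tracks configuration states F(+k), F(-k), Z(k) up to order
ETL + 1, which is exact for a train of ETL refocusing pulses.  One CPMG
cycle is: relaxation over TE/2 with a unit crusher shift, refocusing pulse
at phase +90 degrees relative to the excitation, relaxation/shift over
TE/2, echo readout of F0.  Three implementation details matter:

* **Real-sector recursion.**  With excitation at phase 0 and refocusing at
  phase +90 degrees, the signal-carrying sector of the state evolves with
  purely real matrix coefficients, and the T1 *regrowth* term feeds only the
  orthogonal sector, whose pathways cancel at the echo times.  The compiled
  kernel therefore uses real arithmetic (about 4x fewer operations); the
  tests verify it to machine precision against the complex textbook
  operators (`epg_rf_rotation()`, `epg_relax_shift()`) and against an
  independent isochromat Bloch simulation.  T1 *decay* of stored
  longitudinal states — the mechanism of stimulated-echo amplitudes — is in
  the signal sector and fully modeled.  Steady-state saturation across
  repetitions is not modeled: clinical MESE protocols use TR of 2.9-5.6 s
  against a 1400 ms water T1, so T1-weighting of the echo train is
  negligible.
* **Slice-profile summation.**  Echo amplitudes are computed per sub-slice
  position and summed as complex values with quadrature weights.  The
  presets use Gauss-Legendre nodes restricted to the support where either
  pulse still tips at least 0.5 degrees; outside it the contribution is
  negligible while the filter stopband ripple (whose zero crossings make
  the integrand non-smooth) would spoil quadrature convergence.  With 64
  nodes, doubling the node count changes any echo by well under 0.1%.
* **Normalization.**  The slice-summed echo is divided by the excited
  transverse magnetization mass (the profile-weighted sine of the
  excitation flips).  This keeps amplitudes in [0, 1], reduces exactly to
  the single-bin ideal case, and — importantly — pins the *absolute* scale
  of simulated signals near that of an ideal acquisition, so that absolute
  noise variances used in training and phantoms mean what they say.
  Without it, the wide-support profile average silently shrinks all
  amplitudes by roughly 4x and makes every stated noise level 4x harsher
  relative to signal.

B1 multiplies the refocusing flips only; the excitation is assumed
calibrated (the convention of standard stimulated-echo T2 fitting).  A
`scale_excitation` flag extends B1 scaling to the excitation for users who
want it.

## Slice profiles

`design_slr_pulse()` implements the Shinnar-Le Roux parameterization: the
beta polynomial is designed as a linear-phase FIR filter, the minimum-phase
alpha polynomial is recovered by cepstral spectral factorization, and the
inverse SLR recursion yields the RF samples.  Refocusing pulses use the
spin-echo (beta-squared) ripple convention.  Two filter designs are
offered: windowed frequency sampling (`fir2`, default — smooth stopband,
well suited to profile summation) and Parks-McClellan equiripple
(`remez`).  On resonance all hard-pulse rotations share one axis, so the
sample-sum normalization anchors the slice-center flip exactly at the
nominal angle.

`compute_slice_profile()` Bloch-simulates a waveform (Cayley-Klein spinor
form) across the slice and reports the effective flip angle
`2 asin(|beta|)` per position — for refocusing pulses exactly the angle
whose EPG refocusing efficiency matches the simulated beta magnitude.
Near 180 degrees this representation visually magnifies tiny beta ripple
(a 0.7% beta dip reads as a 10-degree flip dip) while the physically
relevant efficiency `sin^2(flip/2)` stays at essentially 1; tests assert
the efficiency, not the cosmetic flip value.

The vendors' product pulse shapes are proprietary.  The shipped presets
(`"generic-siemens-like"`, `"generic-philips-like"`) are SLR stand-ins with
documented time-bandwidth products (excitation 4.0/3.5, refocusing
3.0/2.5) and a refocusing slice 25% wider than the excitation slice — a
common product-sequence choice that gives the excited magnetization
near-uniform refocusing.  They are *not* vendor-exact: fitting real scanner
data with wrong profiles biases T2w, so users should supply measured
waveforms via `load_waveform()` whenever available.

## Dictionary matching

`build_grid()` reproduces the published grids: fat calibration spans T2f
[50, 250] ms (step 0.25), T2w [10, 110] ms (step 0.5), B1 [0.4, 1.2] (step
0.025, dimensionless) with FF fixed at 0.9; muscle processing spans FF
[0, 1] (step 0.015), T2w [10, 80] ms (step 0.2), B1 (same) with T2f fixed
at the calibrated value.  Atoms are unit-norm echo trains in lexicographic
grid order (ties break to the lowest atom index); matching maximizes the
dot product of unit-norm vectors.  Building exploits the linearity of the
model in FF, so only the unique single-component trains are simulated.

Two quantitative findings from the validation suite are worth knowing:

* **Quantization is not one step.**  On noiseless off-grid signals the
  matched T2w absorbs the rounding of the coupled FF and B1 axes, so its
  error is typically a few grid steps (median near 0.5-1 ms), not half a
  step — even at full grid resolution, and even though nonlinear least
  squares recovers the same signals to machine precision.  Within a
  physiological box (FF below 0.6, B1 0.8-1.1, T2w 25-45 ms) 95% of
  phantom voxels match within 1 ms.
* **Rank-3 compression preserves variance, not ranking.**  Three singular
  components retain more than 99.9% of the (uncentered) atom variance, and
  compressed matching is exactly lossless at full rank.  But echo-train
  atoms are so strongly correlated that at k = 3 the argmax over projected
  dot products can disagree with full matching; a well-separated toy grid
  self-matches at about 89% (100% from k = 4).  Compression buys speed;
  its estimation impact should be checked against the uncompressed match
  before use — the package makes both routes available precisely for that
  comparison.  Uncentered variance ratios are used (matching operates on
  raw dot products); centered ratios are also reported for diagnostics.

## Nonlinear least squares

`fit_muscle_voxel()` / `fit_fat_voxel()` minimize the residual between the
measured train and `scale * model` with a bounded Levenberg-Marquardt
solver (cost and step tolerances 1e-8, at most 200 iterations).  A free
amplitude is estimated because magnitude images are unscaled.  The muscle
fit multi-starts over T2w (15, 35, 60 ms) crossed with B1 (0.8, 1.1): the
refocusing response is nearly symmetric about B1 = 1, and a single start
can strand at the wrong B1 bound.  Failures and degenerate inputs are
flagged rows, never exceptions, so a slice never aborts.  Voxels fitted
with FF above 0.95 carry a `high_ff` flag — with almost no water signal,
T2w there tends to a fitting bound and is not interpretable, whichever
estimator is used.

## Neural regressors

Fat-Net maps a unit-norm echo train to (T2f, T2w, B1); Muscle-Net maps the
train plus the calibrated T2f (scaled to [0, 1] over [50, 250] ms) to
(FF, T2w, B1).  Both are six weighted layers: five ReLU hidden layers in a
bottleneck and a three-unit linear output.  Targets are scaled to [0, 1]
over their ranges so the mean-absolute-error loss weighs the three
parameters comparably.  Training simulates a pool of noiseless signals
(100,000 at full scale), and every Adam step draws a fresh mini-batch
corrupted with freshly drawn noise: channel variance uniform in
[1e-7, 5e-5] for Muscle-Net; for Fat-Net an SNR uniform in [1e3, 1e4]
relative to the first echo, since subcutaneous fat is bright.  Noise is
applied as two-channel complex Gaussian followed by the magnitude
(Rician), matching acquired magnitude data; the network input is the
magnitude train scaled to unit norm, identically at training and
prediction time, which makes predictions exactly invariant to positive
rescaling of the input.

Choices the architecture sketch leaves open, fixed here as documented
defaults:

* **Hidden widths** default to 512-256-128-64-32.  At short training
  schedules the noise-augmented signal-to-parameter mapping needs this
  capacity; narrower bottlenecks plateau at a visibly higher muscle T2w
  error under the desk-scale budget while saving little time.
* **Input standardization.**  Unit-norm echo trains occupy a narrow,
  strongly anisotropic manifold; each input feature is centered and scaled
  by its training-pool statistics (stored in the bundle and applied at
  prediction).  This conditions the first layer and is worth more than any
  learning-rate tweak.
* **Learning rate** follows a cosine decay from a peak of 3e-3 to zero;
  the late low-rate phase is what lets the network sharpen around the
  noiseless manifold after the noisy bulk training.
* **Seeding.**  One seed controls parameter sampling, batch draws and
  noise; weight initialization has its own seed in `build_model()`.

The validation suite trains at desk scale — 20,000 pool signals, 30 epochs
of 200 steps at batch 256 (6,000 gradient steps, a couple of minutes on one
CPU) versus 500 x 1,000 steps at full scale.  What this shows, and does not
show: noiseless held-out muscle T2w MAE reaches about 2 ms (FF up to 0.8)
and fat T2f MAE sits far inside its 5 ms bound; but a shrinkage-toward-the-prior bias remains
that grows with FF — on noisy phantom voxels at FF = 0.8 the compartment
mean T2w is biased by about +4 ms where dictionary and NLSQ stay within
1.4 ms.  That bias is a property of the abbreviated training, not of the
architecture: the reference estimators prove the information is in the
signal.  Full-scale training is the published operating point and is
expected to close this gap; scaled-down networks should be treated as
demonstrators for FF up to about 0.6.

## Subject pipeline

`segment_subcutaneous_fat()` clusters first-echo intensities with Lloyd's
k-means (k = 3: background, muscle, fat), takes the brightest cluster and
keeps its largest connected component — the subcutaneous ring.
`calibrate_t2f()` applies any estimator in the ring (FF fixed at 0.9) and
aggregates per-voxel T2f by the median (robust to mask impurities;
configurable).  Poor fits are excluded before aggregation: dictionary
score below 0.999, NLSQ relative residual above 5%, or clipped regressor
outputs.  Fewer than 50 surviving voxels raises a low-coverage flag.
`map_subject()` then estimates (FF, T2w, B1) per voxel at the calibrated
T2f; out-of-range outputs are clipped and flagged rather than discarded so
maps stay dense, and flagged voxels (including FF above 0.95, low score,
or high residual) are excluded by `roi_stats()`.  Models and dictionaries
carry the acquisition fingerprint (`seq_hash()`) and mapping refuses a
mismatched sequence instead of resampling or guessing.  Registration and
muscle segmentation are upstream concerns: masks must share the MESE grid
exactly.

`t2f_sensitivity()` re-maps with the calibrated T2f biased by set offsets
and reports the induced shift in mean T2w; the validation suite asserts
the shift is nonzero and monotone in the assumed fat T2 — the reason
subject-specific calibration exists at all.

## The digital phantom

`default_thigh_phantom()` emulates a mid-thigh slice at the published
acquisition geometry: a 160 x 160 grid, an elliptical thigh with a
subcutaneous fat ring (FF 0.9, shared T2f 150 ms), and ten elliptical
muscle compartments with FF 0 to 0.8 and T2w spread over 25-45 ms in an
order deliberately uncorrelated with FF, so a regression of estimated T2w
on true FF tests fat suppression rather than the layout.  B1 drifts
linearly from 0.8 to 1.1 across the image, within the smooth, low-order
spatial behavior of measured transmit fields.  Noise is Rician: two
Gaussian channels at sigma = (mean noiseless first echo) / SNR, then the
magnitude; the default first-echo SNR of 100 is typical of 3 T muscle
protocols.  Everything is reproducible from one seed, and the ground-truth
maps and masks are emitted alongside the stack.

What the phantom does *not* emulate: partial-volume mixing at compartment
boundaries, chemical-shift displacement of the fat slice profile, a
multi-peak fat spectrum, motion, and receive-coil shading.  Passing the
end-to-end tests therefore demonstrates correctness of the estimation
chain under the package's own signal model, not robustness to every
artifact of real acquisitions.

## Agreement statistics

`bland_altman()` reports the mean difference, its two-sided one-sample
t-test (alpha 0.05 by convention), and limits of agreement
`bias +/- 1.96 sd` with the sample (n - 1) standard deviation; half-widths
are reported since that is how limits are usually quoted.  `lin_ccc()`
uses population (1/n) moments as in the original definition — the
sample/population choice visibly changes small-n values, so it is fixed
and documented.  `pearson_corr()` is the standard product-moment
correlation with a t-based p-value.  `agreement_stats()` bundles all three
for comparing per-muscle T2w values between estimators.

## Numerical and testing choices

Validation problem sizes are chosen so the whole suite runs in minutes on
one CPU: slice profiles at 32-64 quadrature nodes (convergence is verified
by node doubling), dictionaries at full or 2-4x-coarsened steps depending
on what a test asserts, 200-400 voxel samples for recovery statistics, and
the scaled-down training schedule above.  The independent oracles are a
2,000-isochromat time-domain Bloch simulation (agreement within 1e-3
relative, typically far better), closed-form CPMG decays (1e-6), the
Rician mean via the half-order Laguerre function, and hand-computed
statistics examples.  Degenerate inputs (all-zero voxels, empty masks,
constant images, mismatched geometries) are exercised explicitly; they
flag or refuse, never crash mid-slice.

## Known limitations

* Preset pulse profiles are generic; vendor-exact profiles must be
  supplied for unbiased in vivo T2w.
* B1 above 1 is weakly identifiable (the refocusing response is nearly
  symmetric about B1 = 1); estimators agree with each other but B1 maps
  saturate near the upper bound.
* The scaled-down neural estimator carries an FF-dependent T2w bias (see
  above); use full-scale training for quantitative work.
* Single-peak fat model; no chemical-shift or diffusion effects.
* T2w in voxels with FF near 1 (bone marrow, subcutaneous fat itself) is
  not interpretable by any estimator and is flagged, not fixed.
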