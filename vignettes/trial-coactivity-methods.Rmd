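---
title: "Trial-by-trial whole-brain co-activity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-by-trial whole-brain co-activity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

`trialfc` quantifies how a brain's task-evoked activity varies from one task
trial to the next, and how much of it is shared across people. The analysis
unit is a single task trial of a block/event paradigm: here, a 6 s task
period followed by 24 s of rest, sampled at TR = 2.5 s, i.e. 12 volumes per
trial, with three task types (word-reading, pattern-viewing and
finger-tapping analogues, labelled WR/PV/FT) interleaved eight times each in
a 12-minute run.

The steps are:

1. **Ideal response.** The task on/off boxcar is convolved with a canonical
   double-gamma haemodynamic response function (HRF) and sampled at the
   volume times, giving the template time signal $s(t)$ a task-driven voxel
   should follow (`ideal_response()`).
2. **FC map.** For each trial, the Pearson temporal correlation (TC) $r$
   between each in-mask voxel's 12-volume time course and the trial's
   template segment yields a whole-brain *functional co-activity* map
   (`temporal_correlation_map()`). Eight FC maps per task category per
   subject result.
3. **Similarity.** For any two trials, the Pearson spatial correlation (SC)
   $R$ of their FC maps over the brain mask quantifies how similar the two
   whole-brain activations were (`spatial_correlation()`). All pairs are
   summarized in within-category blocks ($\binom{8}{2} = 28$ pairs per task)
   and between-category blocks ($8 \times 8 = 64$ pairs per task pair)
   (`pairwise_blocks()`).
4. **Task identification.** Choosing one FC map per category as *markers*
   and predicting each remaining trial's task as the marker with the largest
   SC $R$ gives a nearest-prototype decoder. All $8^3 = 512$ marker
   combinations are enumerated, each classifying the other 21 trials —
   10,752 tests per subject (`run_identification()`). The per-category
   correct rate, compared with the 33.3% chance level, measures how
   distinctive and reproducible that task's whole-brain activity is.
5. **Commonality.** Averaging the 8 trial maps per task gives a task-mean FC
   map per subject; SC blocks and nearest-prototype identification across
   subjects' task-mean maps quantify what is shared across the cohort
   (`cross_subject_blocks()`, `cross_subject_identification()`).

```{r}
library(trialfc)
rep <- run_pipeline(pipeline_config(seed = 1), out_dir = "trialfc_demo")
rep$rates                 # per subject x task: correct rate and mean within-R
rep$association           # Pearson r between the two, over 27 points
```

## Assumptions

* The BOLD response is linear and time-invariant: trial responses superpose,
  and every trial shares one template shape. The per-trial template is the
  segment of the full-run regressor at the trial's onset, so any residual
  carryover from the preceding trial is part of the template; a property
  test verifies that all 24 segments correlate above 0.99 with the canonical
  single-trial response under the 6 s/24 s design.
* The trial window starts at the onset volume with no extra lag: the
  haemodynamic delay is inside the 30 s window and is carried by the
  convolved template, so no shift is applied. This is a documented default,
  not an estimated quantity.
* Pearson correlation is used both temporally and spatially. Correlation is
  invariant to per-voxel affine rescaling, which is also why percent signal
  change does not alter any FC value (verified numerically in the tests); it
  fixes interpretable units for maps and amplitudes.

## Preprocessing

The in-scope chain is `preprocess_run()`: isotropic Gaussian spatial
smoothing (default FWHM 4 mm, converted per axis by voxel size,
nearest-edge replication at boundaries), temporal bandpass to 0.009–0.08 Hz,
and percent signal change relative to each voxel's mean raw intensity.
Despiking, slice-timing and motion correction are out of scope and assumed
pre-applied for real data.

The bandpass is a brick-wall projection in the discrete Fourier domain:
bins outside the passband are zeroed. This makes the filter exactly
idempotent and linear (both are tested properties) at the cost of some
ringing relative to smooth filters; it matches the semantics of common
fMRI bandpassing tools. The high edge must stay below the Nyquist frequency
$1/(2 \cdot \mathrm{TR}) = 0.2$ Hz.

Whether the ideal template should itself be bandpassed like the data is an
open methodological choice; `ideal_response(band =)` exposes it, default
off, because the template's energy is concentrated at the 1/30 Hz trial
frequency and its harmonics, which the default band mostly retains.

The brain mask (`make_brain_mask()`) thresholds the mean volume at a
fraction (default 0.3) of its robust maximum and keeps the largest
6-connected component. It is a deliberately simple stand-in for
anatomically informed masking; on real data users can supply their own mask.
Voxels with non-positive baseline or zero within-window variance are removed
from a subject-level intersection mask so that every SC for a subject is
computed over identical voxel sets.

## The significance threshold

`critical_r(n, alpha)` inverts the t distribution:
$r^* = t^*/\sqrt{t^{*2} + n - 2}$ with $t^*$ the $1-\alpha/2$ quantile on
$n-2$ degrees of freedom. For $n = 12$, $\alpha = 0.05$ this gives 0.576
(0.58 at two decimals), the display threshold for single-trial maps. Like
any such threshold applied to fMRI time courses it ignores temporal
autocorrelation; it is used for display and calibration, never in the
similarity computations, which always use unthresholded signed maps.

## The synthetic-data generator

Real runs of this design are not redistributable, so `make_subject_run()` /
`make_cohort()` generate 4D runs with the statistical structure the method
assumes, plus ground truth. The signal model per voxel $v$ and volume $t$ is

$$ I(v,t) = B(v)\,\Big(1 + \tfrac{1}{100}\big[\textstyle\sum_k a_k\, p_k(v)\, h_k(t) + d(t) + \varepsilon(v,t)\big]\Big) $$

with baseline $B$ (1000 inside an elliptical brain, 50 outside), per-trial
amplitude $a_k \sim N(1, 0.25^2)$ in percent-signal units, per-trial pattern
$p_k = c \cdot \mathrm{core} + (1-c)\cdot \mathrm{jitter}_k$, the trial's
HRF-convolved regressor $h_k$ (peak 1), a slow cosine drift $d$ (0.5%
amplitude, one cycle per run, i.e. ~0.0014 Hz — below the passband, so the
bandpass provably removes it, which doubles as a filter test), and
stationary AR(1) Gaussian noise $\varepsilon$ (sd 2.5%, lag-1 coefficient
0.3).

Key choices:

* **Consistency.** $c \in [0,1]$ is the fraction of pattern "identity"
  stable across trials; per-task defaults WR 0.4, PV 0.6, FT 0.9 encode the
  finding that finger-tapping evokes the most reproducible whole-brain
  activity and word-reading the least. A single knob per task suffices to
  reproduce the within-category similarity ordering, the correct-rate
  ordering, and the positive association between the two.
* **Task overlap.** Core patterns are built as
  $\sqrt{1-w}\,u_l + \sqrt{w}\,g$ with a shared field $g$ and task-unique
  fields $u_l$ ($w = 0.3$). Different tasks genuinely co-activate common
  systems, so their maps are correlated rather than orthogonal; without this
  the decoder saturates at 100% and between-category similarity collapses to
  zero, neither of which resembles observed data.
* **Amplitude calibration.** Noise and amplitude defaults were chosen so
  that within-category mean SC $R$ falls in the 0.05–0.45 range reported
  for real subjects of this paradigm, with identification well above chance
  but not saturated.
* **Cohorts.** Each subject's core patterns are the shared cohort patterns
  plus an independent per-subject deviation field (sd 0.5), giving
  cross-subject commonality with individual variation; per-subject seeds
  derive deterministically from the master seed.
* **Grid.** Default 24 × 24 × 18 voxels at 3.5 mm (~4,000 brain voxels).
  Small enough that a full 9-subject cohort analysis runs in seconds, large
  enough that the null SC sd ($\approx 1/\sqrt{n_{voxels}}$) is a few
  hundredths. Unit tests use a still smaller 14 × 14 × 10 grid.

What the simulator does **not** model: biophysical BOLD nonlinearity,
physiological (cardiac/respiratory) noise, motion, spatial noise
correlations beyond smoothing, anatomical structure, or distance-dependent
pattern topology. Passing tests on synthetic data therefore validate the
*computational pipeline* and its statistical calibration, not the
neuroscientific claims on real data.

## Statistical calibration and null behaviour

On zero-pattern data with white noise, the fraction of in-mask voxels with
$|r| > 0.576$ should be 5% — the acceptance suite verifies 0.05 ± 0.01
pooled over 24 trials × 3 seeds — and marker identification should sit at
the 33.3% chance rate (verified within 3 points over 20 subjects). Both
checks run on unfiltered noise, because the threshold's t inversion assumes
temporally independent samples; after a 0.009–0.08 Hz bandpass a 12-volume
window has far fewer effective degrees of freedom and the nominal threshold
no longer applies. The same caveat extends to the original threshold's use
on filtered data — it is a display device, not an inference procedure.

## Group statistics

* The per-subject correct rate is a micro-average over all 512 × 21 tests;
  under this balanced design (each combination tests 7 trials per category)
  it coincides with the per-combination macro-average.
* The test of rates against chance is a one-sample, one-sided t test of
  (rate − 33.3) > 0 across subjects; pairing with a constant degenerates to
  the one-sample form.
* The similarity/correct-rate association is a two-sided Pearson test over
  subjects × categories points (27 for 9 subjects).
* Cross-subject between-category blocks pair task-mean maps of two different
  categories across **all** subject pairs, including a subject with itself
  (the two maps are distinct objects), mirroring the 8 × 8 structure of the
  within-subject between-category blocks.
* Cross-subject identification classifies task-mean maps (8 subjects × 3
  maps = 24 tests per reference subject), the reading under which the
  counts of the original design come out exactly; classifying individual
  trials instead would be a straightforward variant.

## Numerical choices

* HRF: difference of two gamma densities, shapes chosen so the lobe modes
  fall exactly at the peak (6 s) and undershoot (16 s) delays, dispersions
  1 s, undershoot weight 1/6, 32 s support, sampled at dt = 0.1 s and
  decimated to TR after convolution (a 6 s boxcar is not an integer number
  of TRs, so convolving at TR resolution would alias). The kernel and the
  sampled template are peak-normalized — correlation is scale-invariant, so
  this only fixes a canonical serialized form.
* SC matrices are built by centring and norm-scaling the map matrix once
  and taking a single cross-product, so they are exactly symmetric with unit
  diagonal.
* Classifier ties are broken by canonical label order (WR < PV < FT) and
  flagged; with continuous data they are measure-zero but the rule keeps
  runs bit-reproducible.
* Map flattening uses the array's linear order (x fastest), recorded
  implicitly by the fixed grid; all tables are written with fixed `%.10g`
  formatting so reruns are byte-identical.
* Block summaries use the sample (n − 1) standard deviation; a single-pair
  block reports sd 0 with a `degenerate` flag.

## Limitations

* The mask builder is intensity-based only; no registration, atlas or
  surface support is provided, and group analysis requires maps already on
  one grid.
* The similarity measure ignores spatial autocorrelation; its null
  distribution is narrower than map smoothness warrants, so empirical SC
  values should be compared between conditions, not against a parametric
  null (a spatial-autocorrelation-aware null model is future work).
* The decoder is a nearest-prototype rule by design — the point is to
  measure map distinctiveness, not to maximize decoding accuracy.
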