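---
title: "Methods: paired-limb thermographic asymmetry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-limb thermographic asymmetry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermolimp)
```

## The measurement model

A radiometric thermal camera renders each video frame as a matrix of skin
surface temperatures in °C.  In a child with an acute *unilateral* limp,
the contralateral leg is an internal control: focal inflammation (fracture
haematoma, soft tissue injury, joint effusion) perfuses the overlying skin
and raises its temperature relative to the same site on the healthy leg.
The pipeline quantifies that asymmetry in four stages, mirroring how a
clinical thermography protocol is actually run:

1. **Acquisition** — per subject, a short video (protocol default 20 s at
   30 Hz, 600 frames, 640 × 480 px) in each of up to four standardised
   positions (anterior sitting/standing, left/right lateral standing; the
   hip is imaged laterally because underwear confounds the frontal view).
2. **Frame selection** — of the `n` frames, keep the `k = 20` in which the
   child held the imaged pose best (children move).
3. **Paired-ROI measurement** — for each anatomical ROI (hip, upper knee,
   knee, lower knee, ankle) drawn as a rectangle on the affected leg, an
   identically sized rectangle is mirrored onto the healthy leg.  Pixel
   temperatures are averaged within the ROI per frame, then across the
   selected frames, giving one temperature pair
   `(T_affected, T_healthy)`; the asymmetry statistic is
   `pct_diff = (T_affected − T_healthy) / T_affected × 100`.
4. **Cohort summary** — after exclusions, subjects are stratified by
   diagnosis group and presenting-complaint region; each group cell reports
   `n`, the medians and IQRs of the two temperatures across subjects, and
   the percentage difference *of the medians*.

### Assumptions

* The limp is unilateral (bilateral involvement is an exclusion: no
  reference leg exists).
* Emissivity and reflected-temperature corrections have been applied by
  the camera; frames arrive as calibrated temperatures.
* The child is roughly centred and square to the camera, so the healthy-leg
  counterpart of an ROI is its reflection about a vertical axis.
* Skin temperature declines naturally from hip to ankle, so segments are
  never compared *across* levels — each complaint region is analysed only
  through its overlying ROIs (`relevant_rois()`).

## Design choices where the design was open

**Deterministic frame selection.**  Manual "pick the best frames by eye"
is not reproducible, so the package scores each frame by its centred
(Pearson) correlation with the *pixelwise median frame* of the recording.
The median reference is robust to a minority of moved frames, which is
exactly the failure mode being screened out; centring makes the score
insensitive to a global temperature drift, so geometry alone drives it.
Ties break towards the earlier frame, and one selection per recording is
shared by all five ROIs (re-selecting per ROI would let different ROIs of
one subject be measured on different poses).  Scores in degenerate cases
are fixed by convention: a single-frame recording scores 1, a zero-variance
frame (or any frame against a zero-variance reference) scores 0.

**Mirroring rule.**  The healthy-leg ROI is the reflection of the affected
ROI about the image's vertical midline by default, with an optional
explicit axis column for off-centre subjects.  Rows are untouched, so
dimensions are preserved and mirroring is an involution.

**Coordinate convention.**  ROIs are 1-based, inclusive rectangles
(`top:bottom` × `left:right`), i.e. ordinary R matrix indexing — the
convention every R user already holds — rather than 0-based half-open
bounds.  The two conventions describe identical pixel sets; widths,
mirroring and the involution property are exact in both.  Frame indices
are likewise 1-based.

**Group percentage convention.**  The group-level `pct_diff` is computed
from the group medians, *not* as the median of per-subject percentages.
Recomputing every published group cell from its printed median pair
reproduces the printed percentage column exactly (12/12 rows at 2 decimal
places — a regression test), which pins down this otherwise ambiguous
convention.

**Quartile method.**  IQRs use linear interpolation between order
statistics (`quantile` type 7, R's default).  Per-subject source data for
the published tables are unavailable, so no published number constrains
this choice; nothing downstream depends on it.

**Reporting precision.**  Temperatures and percentages are carried at full
precision internally and rounded to 2 decimal places only at the reporting
boundary (`format_group_summary()`), with `"n/a"` for the IQR of
single-subject cells.

**Exclusion rules.**  `apply_exclusions()` drops subjects with onset more
than 48 h before imaging, age ≥ 15 years, bilateral involvement, or no
definitive diagnosis, each with a machine-readable reason code.  Subjects
diagnosed "other" are *retained* — they belong in the descriptive summary —
but fall outside the three named groups of the group table.

## The synthetic phantom

`phantom_params()` defines the simulated subject:

| parameter | default | meaning |
|---|---|---|
| `image_shape` | 480 × 640 | camera resolution (rows × cols) |
| `proximal_temp` | 33.5 °C | skin temperature at the top of the leg |
| `distal_temp` | 30.5 °C | at the bottom (linear gradient between) |
| `background_temp` | 23 °C | room surfaces |
| `noise_sd` | 0.04 °C | per-pixel Gaussian sensor noise (camera NETD < 40 mK) |
| `hotspot` | none | additive isotropic Gaussian: leg, centre, `sigma` px, `amplitude` °C |
| `corrupt_frac` | 0 | fraction of frames motion-corrupted |
| `corrupt_shift_frac`, `corrupt_bias_c` | 0.15, 1.5 °C | the corruption: sideways silhouette shift + global bias |

The two silhouettes are symmetric about the vertical midline by
construction, and leg temperature depends on row only, so with
`noise_sd = 0` and no hotspot *every* mirrored ROI pair has `pct_diff`
exactly 0 — the null-symmetry property the tests assert without tolerance.
The hotspot is an additive isotropic Gaussian because it is the simplest
localised warm lesion with an analytically integrable footprint: its mean
elevation over any ROI can be computed by direct summation of the formula
and used as an independent oracle.  Motion corruption is a geometric shift
plus a bias (rather than, say, blur) because that is what a child shifting
their stance does to a fixed-mount recording, and because a centred
correlation score separates it cleanly: the bias alone is invisible to the
score, the shift is what gets caught.

Default temperatures sit in the published range of group medians
(~29–34 °C skin, warmer proximally).  Synthetic cohort hotspot magnitudes
(`default_cohort_groups()`: fracture 1.5 °C > soft tissue 0.45 °C >
irritable hip 0.25 °C, between-subject SD 0.15 °C, truncated at zero) are
artifact choices fixed once: with a hotspot `sigma` twice the ROI size the
ROI-mean elevation is ≈ 0.9 × amplitude, so at ~32 °C skin these
amplitudes put group asymmetries in the ~0.7–5% band that the clinical
tables report, ordered fracture > soft tissue > irritable hip.  They are
**not** estimates of patient effect sizes.

With sensor noise σ per pixel, an `N`-pixel ROI averaged over `F` frames
has mean-temperature noise σ/√(NF) per leg, so a null mirrored pair
satisfies `|pct_diff| ≤ 3·(σ√2/√(NF))/T̄ × 100` in ≈99.7% of trials; the
acceptance suite checks ≥99% over 500 seeded trials.

### What the phantom does *not* model

Biophysical heat diffusion and perfusion, clothing/underwear artefacts,
camera calibration drift, pose variation beyond rigid shifts, and the
anatomical shape of real legs.  Passing tests therefore demonstrate that
the *pipeline arithmetic and decision rules* behave as specified under the
assumed noise model — not that the method has any particular sensitivity
or specificity on real patients, which only a larger clinical study can
establish.

## Numerical and degenerate-input rules

* Temperatures outside the camera's radiometric range (−40 to 650 °C)
  are rejected at frame construction.
* The 16-bit TIFF format stores counts `round((T − offset)/scale)` with a
  default step of 0.01 K/count — finer than the sensor noise floor, so
  quantisation (≤ 0.005 K round-trip error) never dominates; counts
  outside 0..65535 are an error, not a clamp.
* `percentage_difference()` requires a positive affected-leg mean (its
  denominator); skin in °C is always positive, so a violation flags a
  unit or decoding error.
* An empty frame-index list, an empty group, an out-of-bounds ROI and a
  mirrored ROI leaving the image are all hard errors.
* `select_best_frames(k)` with fewer than `k` frames returns all frames
  with a warning — real recordings of young children are sometimes short,
  and silently changing `k` would hide it.
* All randomness flows through explicitly passed seeds
  (`withr::with_seed`), never global state; a seeded recording, cohort or
  pipeline run is bit-reproducible.

## Problem sizes used in the test and acceptance suites

Simulation checks run at reduced sizes chosen to exercise the full
geometry while keeping the suite quick on a laptop: phantoms of 96 × 128
(or smaller) pixels instead of 480 × 640; the frame-count check (600
frames from 20 s × 30 Hz) at 96 × 128; the null-symmetry noise bound over
500 seeded trials of 3-frame recordings; corrupted-frame exclusion over
100 trials of 30-frame recordings at 48 × 64; and the group-ordering
recovery over 100 replicate 25-subject cohorts (13 soft tissue injury /
9 irritable hip / 3 fracture, the published cohort's proportions) of
6-frame, 60 × 80 recordings in one position with `k = 4`.  All statistics
under test are size-free (means, medians, correlations), so the reduced
sizes change runtime, not the properties being verified.

## Known limitations

* The mirroring rule presumes an approximately centred, symmetric pose;
  real images may need the explicit-axis override, and grossly rotated
  subjects are out of scope (no pose estimation or leg tracking).
* ROI placement is user-supplied (as in the manual protocol, where larger
  legs get larger ROIs); the package validates but does not auto-size or
  auto-localise lesions.
* Group tables with `n` of 1–9 per cell support no significance testing,
  and none is offered; the summaries are descriptive by design.
* Proprietary radiometric container formats are not decoded; frames enter
  as CSV rasters or scaled 16-bit TIFFs with a documented sidecar/manifest.
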