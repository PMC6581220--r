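---
title: "Awake-animal PET with point-source tracking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Awake-animal PET with point-source tracking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(awakepet)
```

# The problem

Brain PET in mice is normally acquired under anesthesia, but anesthetics
alter cerebral blood flow, glucose consumption and tracer kinetics, so the
reading they immobilise the animal for is itself confounded. An alternative
is to let the mouse move freely on a platform inside the scanner, measure
the rigid motion of its head continuously, and undo that motion event by
event before reconstruction. `awakepet` implements this pipeline end to
end, together with a list-mode simulator that stands in for the scanner, so
every stage can be exercised and validated without animal data.

The tracking signal comes from four ~1 mm radioactive point sources
(296–370 kBq each) glued to the head: one under each ear, one on the nasal
bridge, one raised on a lightweight spacer so it clears the brain and
limits spill-in. The head pose is estimated in every 32-ms window of the
list-mode stream, and poses failing a 2-mm rigidity check are discarded.

# Pipeline overview

1. **Simulation** (`simulate_listmode`): decays are a Poisson process;
   emission sites are drawn from a digital mouse-head phantom (body,
   five-region brain) plus Gaussian marker blobs, mapped through the pose
   at the decay time; annihilation directions are isotropic; a coincidence
   is kept when both photons hit distinct crystals of the cylindrical
   scanner. Attenuation can thin events by `exp(-∫μ dl)` through the moving
   body. Scatter, randoms, positron range and depth of interaction are not
   modelled.
2. **Short-frame reconstruction** (`short_frame_images`): the stream is cut
   into half-open 32-ms frames, each reconstructed by a fast list-mode MLEM
   on a coarse grid.
3. **Tracking** (`track_events`): local maxima above a fraction of the
   frame maximum are candidate sources; the four candidates whose six
   pairwise distances best match the marker model (exhaustive search over
   all subsets and orderings, a purely geometric similarity score) are
   matched; a Kabsch fit gives the rigid pose; frames with any marker
   residual above 2 mm (inclusive boundary) are rejected.
4. **Motion-corrected reconstruction** (`motion_corrected_recon`): each
   event's line of response is transformed by the inverse of the pose
   interpolated at the event time (translation linear, rotation slerp);
   events in pose gaps longer than five frames are dropped; list-mode OSEM
   (16 subsets, 8 iterations by default, image-space Gaussian resolution
   model) runs in the head frame with an exposure-weighted sensitivity.
5. **Quantification and statistics** (`regional_means`, `suv`,
   `tac_extract`, `icc`, `bland_altman_percent`, `cov_percent`,
   `memantine_percent_change`, `estimate_blur_sigma`) and behavioural
   readouts (`head_track`, `speed_and_distance`, `position_heatmap`).

# The forward model and its scale

The default **desk** scanner is deliberately small so that a full
simulate–track–reconstruct cycle runs in minutes on one CPU: a single
cylinder of 288 crystals × 12 rings, radius 80 mm, axial extent 18 mm. Two
choices here deserve comment.

*Orientation.* The scanner axis is vertical, i.e. the detector ring lies
parallel to the 10 × 9 cm platform, so the (x, y) translations of the mouse
stay in the transaxial plane. The ring radius (80 mm) then has to enclose
the platform diagonal **plus** the marker offsets on the head (r up to
~77 mm); with a smaller ring the corners of the platform would be outside
the field of view and tracking there would be impossible.

*Crystal pitch.* Sub-millimetre marker localisation needs detector pitches
comparable to real small-animal scanners (~1.6 mm crystals). Early desk
geometries with 4 rings at 4.5 mm axial pitch limited axial resolution to
~3 mm and rotation errors to ~5°; the final 1.5 mm axial and ~1.75 mm
transaxial pitches bring median pose errors to ~0.16 mm and ~1.4°.

The paper-scale preset (`scanner_preset("inveon-like")`,
`grid_preset("inveon-like")` with its 128 × 128 × 159 matrix of
0.776 × 0.776 × 0.796 mm voxels) exists for realistic geometry work but is
not the test default.

# The phantom and the trajectory generator

`make_head_phantom` builds a rigid digital phantom in the head frame: an
ellipsoidal body (uniform 400 kBq/cm³, the soft-tissue attenuation constant
0.097 cm⁻¹ inside) enclosing an ellipsoidal brain partitioned into cortex,
caudate putamen, thalamus, hippocampus and cerebellum. Default region
activities (750–1050 kBq/cm³) follow the relative regional FDG uptake
pattern of the mouse brain at roughly twice the body background —
physiological for a fasted FDG mouse. The whole phantom moves rigidly with
the head; a real animal's body of course does not, which mostly affects
the body-outline attenuation map, not the brain.

The four markers sit fully **outside** the brain ellipsoid (spill-in from a
330 kBq point source into an adjacent 30-voxel region would otherwise
dominate its mean), with all six pairwise distances distinct by >1 mm so
the distance matching has a unique ordering.

`sample_trajectory` emulates a mouse exploring the platform: planar
velocity is an Ornstein–Uhlenbeck process (relaxation ~0.5 s), alternating
rest/move bouts (mean rest ~2 s; the resting fraction is 0.4 at baseline,
0.05 under a locomotor challenge), positions reflect at the platform
limits, z bobs smoothly within ±1 mm, and rotation is yaw-dominant
(~30°/s scale) with small pitch/roll. Velocities are rescaled so the
time-averaged speed equals the requested `mean_speed` — 2 cm/s for the
baseline regime and 4 cm/s for the challenge regime, the two regimes the
method must handle. The generator does **not** reproduce grooming (marker
slippage), non-rigid skin motion, or any correlation between pose and
platform position; passing tests therefore demonstrate correctness of the
algorithms under rigid motion, not robustness to marker slippage.

Counts are the simulator's free parameter (real acquisitions do not print
their coincidence rates in a way that transfers to this geometry): the
defaults used in tests are 6×10⁵ emitted decays per second, of which ~9%
are detected, i.e. ~10⁶ events in a 20-s scan with the markers carrying
roughly 20% of the activity.

# Numerical choices

**Projector.** Siddon/Amanatides–Woo traversal with exact chord lengths;
the sum of per-voxel lengths reproduces the clipped chord to 10⁻⁹ mm.

**OSEM.** Subsets are formed by event index modulo the subset count
(deterministic and balanced in time); the per-event forward model is the
Siddon trace convolved in image space with an isotropic Gaussian (default
sigma = half the transaxial crystal pitch); updates are multiplicative.
With one subset and no resolution model, `sum(image × sensitivity)` equals
the event count after every full iteration, and the implementation matches
a dense-matrix MLEM to 10⁻⁶ on a small two-dimensional instance.

**Sensitivity.** Backprojection over all crystal pairs, normalised to a
per-mm³ density so images computed on different voxel sizes agree
pointwise. Two variants exist deliberately. Centre-to-centre backprojection
is self-consistent for *static* reconstruction — events arrive on exactly
those discrete lines — but is aliased (it oscillates voxel-to-voxel, and
spikes where many diameters cross, e.g. the exact ring centre).
Interpolating that aliased image under motion produced regional biases up
to 40%, so motion correction instead resamples a *finite-aperture*
sensitivity (each endpoint offset within the crystal pitch by a
deterministic Weyl sequence), evaluated on an FOV-wide grid (2 mm in-plane,
1 mm axially — the axial profile is strongly curved on an 18 mm scanner)
and averaged over up to 64 accepted poses weighted by exposure.

**Short-frame reconstruction for tracking** uses a flat sensitivity: point
detection only needs local maxima, and dividing a 32-ms frame by the true
sensitivity amplifies noise at the FOV edge enough that the frame maximum
is occasionally a noise spike.

**Detection threshold.** Candidates are local maxima above
`detect_threshold_frac` × frame maximum (default 0.15), refined by a
3³-voxel intensity-weighted centroid. The threshold is deliberately low:
the dimmest marker (the spacer, at an unfavourable axial position) often
sits below 0.3× the sharpest peak, particularly when the animal is at rest
and the brightest marker is sharpest; the exhaustive geometric matcher
absorbs the extra decoy candidates a low threshold admits. `score_cap`
(default 4 × (2 mm)²) rejects frames whose best match is still poor.

**Pose interpolation.** Translation linear, rotation slerp between
bracketing *accepted* poses; times in gaps longer than `max_gap_frames`
(default 5) × 32 ms are dropped rather than extrapolated; events inside an
accepted frame adjacent to a long gap snap to their own frame's pose.

**Iteration count at desk-scale counts.** The production protocol
(16 subsets × 8 iterations) is the package default, matching how
full-count acquisitions are reconstructed. At desk-scale statistics
(~10⁵ brain counts) those 128 multiplicative updates sit deep in the MLEM
noise-amplification regime: replicate regional means of identical static
scans vary by 10–18%. Quantitative *comparisons* in the tests and the
acceptance script therefore use early-stopped OSEM (4 subsets ×
2 iterations, regional replicate noise ~1%) — the standard practice of
matching iteration number to count level — while everything structural
(subset handling, PSF, motion correction) is identical.

**Blur equivalence.** `estimate_blur_sigma` minimises the mean squared
difference between the Gaussian-blurred reference and the degraded image
by golden-section search on σ ∈ [0, 2] mm; on reference/degraded pairs
constructed with a known σ it recovers it to ±0.01 mm. Motion-corrected
desk images come out ~0.1–0.2 mm blurrier than matched static ones —
the same direction, though smaller in magnitude, as the ~0.6 mm
equivalent loss reported for real awake-mouse images, whose additional
blur sources (marker slippage from grooming, parallax off-centre) the
simulator intentionally omits.

# Statistics

- `cov_percent`: 100·SD/mean with the sample (n−1) SD.
- `icc`: computed from two-way ANOVA mean squares; the default variant is
  ICC(A,1) — two-way, absolute agreement, single measurement — the usual
  choice for test–retest agreement of a quantitative reading. Variants
  differ enough that the variant used should always be reported;
  `variant = "consistency"` gives ICC(C,1).
- `bland_altman_percent`: per-subject differences as a percentage of the
  pair mean; the sign convention (test − retest) makes retest readings
  that exceed test readings produce a *negative* bias.
- `variability_percent`: the mean absolute percent difference — one common
  concretisation of "test–retest variability"; it always bounds |bias|
  from above.
- `tac_slope_test`: ordinary least squares of regional uptake on frame
  midpoint time with a two-sided t-test on the slope (n−2 df). Its type-I
  error is calibrated at the nominal 5% over 1000 null simulations in the
  acceptance tests.
- `memantine_percent_change`: per-region percent change of the challenge
  SUV against the mean of test and retest as baseline, averaged unweighted
  over the five regions. With the test/retest mean as baseline the bundled
  group-mean table yields +63.7% (awake) and +24.0% (anesthetized), ratio
  2.65; a test-only baseline does not reproduce that contrast, which is
  why the symmetric baseline is the default.

# Problem sizes used by the tests

Unit tests run on a tiny one-ring scanner (32 crystals, 8 × 8 × 1 grid)
where dense-matrix oracles are exact, plus short desk-scale scans. The
end-to-end checks use 20-s scans (~10⁶ events) for tracking at each regime
and a 40-s matched pair (~2×10⁶ events each) for the motion-correction
comparison — sizes chosen so the whole suite completes in minutes on one
CPU while leaving the desk-scale noise floor (~1–2% per region) well below
the quantitative bands being checked.

# Known limitations

- Rigid-body assumption throughout: no grooming, skin slip, or body/head
  differential motion; accepted-frame fractions on real animals will be
  lower than simulated ones.
- No scatter, randoms, positron range, or parallax modelling; the
  simulator's resolution loss under motion is therefore milder than
  reality's.
- The body-outline attenuation map assumes FDG-like whole-body uptake;
  tracers without body background would need the CT-based route that is
  out of scope here.
- Regional means at desk-scale counts are noisy under the full production
  iteration schedule; quantitative comparisons should use the
  early-stopped configuration or larger simulated count budgets.
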