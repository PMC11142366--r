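---
title: "Models and methods behind kymotor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kymotor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymotor)
```

kymotor quantifies the movement of single fluorescently labelled molecules
-- unconventional myosins and similar cargo -- along stereocilia and other
thin actin protrusions, from single-plane time-lapse movies such as those
produced by light-sheet microscopy of hair cells. This vignette is the
package's own account of its models: what each stage assumes, which knobs
matter, and where the edges are.

## The imaging model

A movie is a stack of single-plane frames at 0.1--1 s intervals with
~100 ms exposures. The synthetic generator (`simulate_movie()`) emulates
that acquisition with an explicit physical model:

* **Geometry.** Emitters live on a straight axis (`stereocilium_geometry()`)
  from base to tip; the axial coordinate `s` is 0 at the base and increases
  tip-ward, so tip-directed velocities are positive and retrograde ones
  negative. A nonzero confinement radius adds uniform lateral jitter; the
  default radius of 0 reflects that a stereocilium's diameter is well below
  the diffraction limit.
* **Optics.** Each fluorophore contributes `quantal_yield` expected photons
  per frame through an isotropic Gaussian PSF integrated exactly over each
  pixel. Defaults: pixel size 162.5 nm (a 40x objective in front of a
  6.5 um sCMOS pixel) and PSF sigma 152 nm (0.21 lambda/NA at lambda =
  580 nm, NA = 0.8). Neither value is a measurement; both are configurable
  and only ratios of intensities are treated as meaningful.
* **Camera.** `counts = offset + gain * Poisson(signal + background) +
  N(0, read_noise)`. The default quantal yield of 400 photons per
  fluorophore per frame over a background of 10 photons/pixel gives a peak
  SNR of roughly 8, typical of bright rhodamine-class dyes on this camera
  class.
* **Motility.** Five modes: static; diffusive (reflected Brownian motion,
  increments `N(0, 2 D dt)`); processive (constant tip-ward speed, absorbed
  at the tip -- accumulation at tips); step-wise (exponential waiting times,
  jumps of fixed size toward the tip); intermittent (two-state switching
  between paused and moving). Motion, blinking and bleaching are updated
  once per frame: at the speeds of interest (~100 nm/s) a molecule moves
  ~10 nm during a 100 ms exposure, far below the localization scale, so
  intra-exposure blur is ignored.
* **Photophysics.** Per-fluorophore exponential photobleaching (absorbing)
  and optional bright/dark blinking. A two-fluorophore emitter is simply
  twice as bright while both survive -- the quantal logic used throughout.
* **Reproducibility.** One master seed; all per-emitter, drift and camera
  substreams are derived from it deterministically, so a configuration
  reproduces its movie bit for bit.

What the generator does *not* emulate: out-of-focus light and axial (z)
drift, optical aberrations, dual-view fusion, uneven illumination, and --
most importantly -- loss of molecules by diffusion out of the imaging
plane. Passing tests on synthetic movies therefore demonstrates the
correctness of the estimators under the stated model, not robustness to
every artifact of real acquisitions.

## Drift correction

Lateral stage drift is estimated per frame pair by a three-stage cascade
(`estimate_shift()`):

1. **Phase-only correlation.** The normalized cross-power spectrum
   `R = F_b conj(F_a) / |F_b conj(F_a)|` is inverse-transformed; its peak
   is the integer displacement and its height (~1 for identical frames,
   near 0 for unrelated ones) a match diagnostic. Frames are mean-
   subtracted and, in the movie driver, apodized with a raised-cosine
   window to suppress edge ringing.
2. **Closed-form subpixel refinement.** On the 3x3 neighbourhood of the
   peak, the side-lobe ratio `delta = r1 / (r0 + r1)` per axis -- exact for
   the ideal periodic-sinc peak of a pure translation -- clamped to the
   physically meaningful (-0.5, 0.5] range. This is an approximation used
   only to initialize stage 3.
3. **Least-squares image matching.** Gauss-Newton minimization of the
   summed squared difference between frame A and frame B resampled at the
   candidate shift. Three numerical choices matter and were made after
   measuring their effect on drift recovery:
   * *Fourier-domain resampling.* Bilinear interpolation carries a phase
     distortion that biased recovered fractional shifts by ~7% of the
     step; chained over 100 frames this grew to ~0.17 px RMS. Resampling
     via a Fourier phase ramp (exact for band-limited content, with the
     wrap-contaminated border masked) reduced it to ~0.03 px RMS.
   * *Symmetric gradients.* Using the mean of both frames' gradients
     cancels the first-order correlation between image noise and the
     Jacobian that biases one-sided Gauss-Newton updates.
   * *Optional robustness.* With sparse single-molecule content, a few
     moving molecules otherwise drag the estimate off the static majority.
     The movie driver uses Tukey-biweight reweighting with the robust
     scale taken from high-gradient pixels (a background-dominated scale
     would reject well-aligned spots too).
   Convergence: update norm below 1e-3 px, at most 50 iterations.

`correct_movie()` chains neighbour-to-neighbour estimates by default
(robust to slow photobleaching of the reference content) and re-anchors
the accumulated shifts to the reference frame; all-to-reference
registration is available via `chained = FALSE`. Corrected frames are
bilinearly resampled, out-of-field pixels filled with the frame's median
background and masked. Degenerate frames inherit the previous step's
shift and are flagged in the `DriftTrace`.

Two practical limits are worth stating. Registration needs static
structure: a movie in which *all* content moves coherently (e.g. every
molecule processive at the same speed) is unregistrable in principle,
because the common motion is indistinguishable from drift. The package's
parameter-recovery studies therefore run on drift-free movies with
registration disabled, while drift recovery is validated on static-rich
scenes -- the situation that, in real recordings, corresponds to
registering on the structural channel or on the static majority of
labelled molecules. Second, evenly spaced point content is ambiguous (a
shift of one spacing aliases); validation scenes use irregular spacing.

## Punctum detection and quantal intensities

Detection (`detect_puncta()`) band-passes each frame with a difference of
Gaussians at the PSF scale, takes 3x3 local maxima above
`median + 5 * MAD` of the band-passed image, merges detections closer
than `min_separation` keeping the brighter, and refines positions by
background-subtracted intensity-weighted centroid.

The summed intensity (`sum_intensity()`) adds all pixel values in a
square window (default half-size 3 px, ~3 PSF sigma at the default
calibration) and subtracts `area x` the median of a surrounding annulus
(half-sizes 5--7 px). The median tolerates a neighbouring punctum
intruding into the annulus. `S` saturates once the window exceeds ~3
sigma, so absolute values depend only weakly on the window; ratios of
`S` -- the quantity the analysis actually uses -- are robust to it.

`classify_populations()` fits an equal-variance two-component Gaussian
mixture to the summed intensities by EM with deterministic moment-based
initialization (quartile means, half the pooled SD). Pop1's mean is the
quantal intensity -- the brightness of one fluorophore -- and the
Pop2/Pop1 mean ratio should be ~2 when Pop2 molecules carry two
fluorophores. A bimodality flag compares the mixture to a single
Gaussian by BIC; puncta above `mean(Pop2) + 3 SD` are flagged as likely
carrying more than two fluorophores. Line-scan profiles
(`line_scan()`, `average_line_scan()`) and `compare_to_psf()` check the
point-source hypothesis: a punctum whose fitted width matches the PSF
(ratio within 0.8--1.25 by default) is consistent with a point emitter,
while an extended source is wider.

## Kymographs and tracking

`build_kymograph()` samples the movie along an `organelle_path()` at
pixel pitch, reducing across the perpendicular half-width by the
*maximum* -- on a thin organelle the mean would dilute a faint single
molecule with background rows. Columns are frames, rows run base to
tip.

`link_tracks()` replaces interactive manual tracking: frame-to-frame
assignment minimizing total displacement (exact enumeration up to 7
detections per frame, greedy nearest-neighbour beyond), a search radius
of `max_jump` nm (default 500) scaled proportionally across gaps up to
`max_gap` frames (default 2). Any automatic linker substitutes for
expert judgement; the parameters are exposed and exported with each
result. `project_to_axis()` assigns each detection the arc length of
its *foot point* on the path polyline -- a continuous coordinate.
(Projecting to the nearest path sample, the more literal reading of a
line-scan path, quantizes `s` to the 162.5 nm pixel pitch; that
quantization imitates clean steps and is exactly what a step detector
must not be fed.)

## Kinetics

* **Velocity** (`velocity_of_track()`): OLS slope of `s(t)`, tip-positive.
  The slope uses the whole track; endpoint differencing is available
  implicitly through the summaries but the slope has lower variance.
  `summarize_velocities()` applies the directed-run filters (minimum
  duration, minimum R^2, direction) that substitute for an expert's
  manual selection of directionally moving molecules.
* **Steps** (`detect_steps()`): binary segmentation of a piecewise-
  constant model; a change point is accepted while it reduces the
  residual sum of squares by more than `penalty * log(n) * sigma^2`
  (default penalty 3, the modified-BIC regime used in change-point
  practice), then steps below `min_size` (default `2 sigma`) are merged
  away smallest-first. With `sigma = 0` (noise-free input) the threshold
  collapses to numerical precision and exact staircases are recovered
  exactly.
* **MSD** (`msd_curve()`): time-averaged MSD to a quarter of the track
  length. The anomalous exponent alpha is fit on the shortest decade of
  lags only: long lags of a single-track time-averaged MSD are strongly
  correlated and inflate the variance of the exponent (measured on
  simulated diffusion, restricting the fit raised the fraction of tracks
  with alpha in [0.7, 1.3] from ~0.8 to ~0.95). `D` comes from a linear
  fit over the first four lags with a free intercept absorbing the
  2 sigma_loc^2 localization-noise offset.
* **Classification** (`classify_motility()`): deterministic rules, in
  order: static if the net displacement is below `3 sigma_loc` *and* the
  excursion below `7 sigma_loc` (the wider excursion factor covers the
  expected extremes of pure localization noise over ~100 frames);
  stepwise if the step fit finds >= 2 steps with dwells >= 2 frames,
  beats the straight line by BIC, *and* leaves within-plateau residual
  RMS <= `2 sigma_loc` -- the last condition is what separates a genuine
  staircase from a random walk, which wanders within its plateaus;
  processive if R^2 >= 0.8, |v| >= 20 nm/s and alpha >= 1.5 (the
  exponent gate removes the ~15% of random walks that achieve a high
  R^2 by chance); diffusive if alpha lands in [0.7, 1.3]; otherwise
  unclassified. All thresholds are arguments.
* **Photobleaching** (`bleaching_survival()`): the censored-exponential
  maximum-likelihood rate, `events / total observed time`, with tracks
  alive at the movie end right-censored, plus a product-limit survival
  curve.

## Validation studies and problem sizes

The `evaluate_*()` family rebuilds every validation quantity from
scratch at a given seed; `scripts/acceptance.R` runs all of them and
writes a JSON summary. The study sizes are chosen so each estimate's
Monte-Carlo error sits well inside the tolerance being checked while the
whole suite stays interactive (~1 minute): 60 puncta for the quantal
ratio; three 100-frame movies for drift recovery; 100 processive tracks
(five movies of twenty emitters, 20 frames); ~270 true steps across four
staircase movies; 36 diffusive tracks; ~100 bleaching lifetimes; 400
benchmark tracks (100 per mode, 100 frames, sigma_loc 30 nm) for the
classifier. The benchmark's kinetic parameters are the regimes the
imaging distinguishes: 100 nm/s processive runs, 100--200 nm steps,
2e4 nm^2/s constrained diffusion -- and 2.5e7 nm^2/s (a small cytosolic
protein) for the free-diffusion control, which is what makes unfused
tag molecules vanish between 1 s frames.

## Known limitations

* Registration is translational only; rotation, scale and z-drift are out
  of scope.
* The linker is nearest-neighbour with gap closing, not multiple-
  hypothesis tracking; dense scenes with crossing molecules will swap
  identities, and molecules passing within a PSF width of each other
  merge into one detection while they overlap.
* The quantal classifier assumes two dominant populations with equal
  variances; >2-fluorophore puncta are only flagged, not modelled.
* MSD-based quantities on single short tracks are intrinsically noisy;
  the classifier's accuracy figures are stated for 100-frame tracks.
* Absolute intensities are in camera counts; without a photon
  calibration only ratios are interpretable.
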