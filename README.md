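# kymotor

Single-molecule motility analysis for stereocilia time-lapse imaging.

Stereocilia are the actin-cored mechanosensory protrusions of inner-ear
hair cells; the myosins that build and maintain them can now be watched
one molecule at a time by light-sheet microscopy with sparse HaloTag
labelling. The raw data are single-plane time-lapse movies: a handful of
diffraction-limited puncta, each one or two fluorophores, moving (or not)
along a thin, nearly straight organelle, on top of camera noise, slow
stage drift, photobleaching and blinking. kymotor turns such movies --
real or simulated -- into calibrated kinetics.

The pipeline:

1. **Drift correction** — phase-only correlation (normalized cross-power
   spectrum `R = F_b conj(F_a)/|F_b conj(F_a)|`), closed-form subpixel
   refinement of the correlation peak, then Gauss–Newton least-squares
   image matching, chained across frames and re-anchored to a reference.
2. **Punctum detection & quantal intensities** — difference-of-Gaussians
   detection with subpixel centroids; background-subtracted summed
   intensities `S = sum(window) − b·area`; an equal-variance two-component
   Gaussian mixture (EM) that separates one- from two-fluorophore puncta,
   whose mean ratio is ~2 (the quantal intensity logic of fluorophore
   counting); line-scan comparison against the PSF.
3. **Kymographs & tracking** — line scans along a base-to-tip path
   stacked over time; nearest-neighbour track linking with gap closing;
   projection of each detection onto the axis as a continuous arc-length
   coordinate `s(t)` (nm, tip-positive).
4. **Kinetics** — per-track velocity (OLS slope of `s(t)`), change-point
   step detection (binary segmentation with a modified-BIC stopping rule;
   staircase steps in the 100–200 nm regime), time-averaged MSD with
   anomalous exponent and diffusion coefficient, motility-mode
   classification (static / diffusive / processive / stepwise), and
   censored-exponential photobleaching survival.
5. **Simulator** — a fully ground-truthed synthetic movie generator
   (Gaussian PSF, Poisson + read noise camera, five motility modes,
   per-fluorophore bleaching/blinking, linear + random-walk drift) so
   every stage is testable end to end.

## Worked example

Simulate a stereocilium carrying one processive myosin (100 nm/s), one
diffusing molecule, static single-fluorophore molecules and a few bright
static protein accumulations, under stage drift — then run the whole
pipeline on it:

```r
library(kymotor)
cfg <- system.file("extdata", "demo_config.yaml", package = "kymotor")
bundle <- run_pipeline(cfg, write = FALSE)
bundle$kinetics[bundle$kinetics$n >= 8,
                c("track_id", "mode", "v", "se", "r2", "n")]
#>   track_id       mode      v     se    r2  n
#> 1        1     static -0.447 0.0278 0.871 40
#> 2        2     static -0.472 0.0251 0.903 40
#> 3        3     static -0.471 0.0292 0.872 40
#> 4        4  diffusive 19.793 4.1867 0.419 33
#> 5        5     static -0.337 0.0875 0.281 40
#> 6        6 processive 99.578 0.1053 1.000 40
#> 7        7     static -0.590 0.1114 0.425 40
#> 8        8     static -0.295 0.1199 0.137 40
```

Track 6 is the processive mover, recovered at 99.6 nm/s (truth: 100) with
R² ≈ 1 after drift correction; the static molecules sit within ±0.6 nm/s
of zero — their kymograph traces are parallel to the time axis — and the
diffusing molecule is called diffusive. `v` is in nm/s (tip-positive),
`n` the number of frames in the track.

Quantal intensity classification works on any vector of summed punctum
intensities; with two populations at means 34 and 76 counts (SD 10):

```r
set.seed(1)
S <- c(rnorm(16, 34, 10), rnorm(12, 76, 10))
classify_populations(S)
#> Quantal fit (n = 28): Pop1 36.1, Pop2 78.4 (SD 9.5), ratio 2.17, bimodal
```

Pop1's mean is the quantal (single-fluorophore) intensity; a ratio near 2
says Pop2 puncta carry two fluorophores.

A thin command-line front end wraps the same functions
(`inst/cli/kymotor.R`, subcommands `run`, `simulate`, `register`,
`detect`, `track`, `kymo`, `kinetics`).

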