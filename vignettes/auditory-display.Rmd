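---
title: "Methods: sonifying NIRF hyperspectral data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sonifying NIRF hyperspectral data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonifluor)
```

## The model

A hyperspectral fluorescence cube assigns each pixel an intensity spectrum
over narrow wavelength channels (by default 18 channels, 640–810 nm in 10 nm
steps; the channel grid is carried as data, so 17-channel acquisitions work
identically). The auditory display reduces an ROI's mean spectrum to a single
number in two steps:

1. **Target value.** The mean intensity over the *mid* bins (710, 720, 730,
   740 nm — where a cy5.5-like NIRF probe emits) minus the mean over the
   *low* bins (640, 650, 660, 670 nm). Because this is a contrast between
   band averages, any spectrally flat contribution cancels exactly: a pixel
   twice as bright but flat still scores zero. This linear functional is the
   autofluorescence suppressor at the core of the method.
2. **Normalization.** The probe ROI's target value is divided by that of a
   designated background ROI (the skull), giving the probe-to-background
   ratio. The ratio is invariant under global rescaling of the cube
   (exposure, gain), and the background probes itself to exactly 1.

The ratio then becomes the **modulation index** of two-oscillator FM
synthesis. With carrier $f_c$, modulator $f_m$ and index $I$, the spectrum of
$\sin(2\pi f_c t + I\sin(2\pi f_m t))$ consists of sidebands at $f_c + k f_m$
with amplitudes $J_k(I)$; the number of audible sidebands grows roughly like
$I$ (Carson's rule). Index 0 is a pure tone; index 20 is a rich, buzzy
timbre. The mapping from data to sound is thus monotone and physically
interpretable, and the Bessel law gives the module an exact numerical oracle,
which the test suite checks to 1% across indices 0.5–4 and sideband orders
$|k| \le 8$.

Assumptions worth stating: the probe's emission must overlap the mid bins and
not the low bins (both sets are configurable per fluorophore); the background
ROI must have a *positive* target value — a background with no spectral slope
makes the ratio undefined, and the package treats a background target below
`eps` as an error rather than silently inflating it.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `low_nm`, `mid_nm` | 640–670, 710–740 | nm | cy5.5-style mapping; wavelength-keyed so other probes remap |
| `eps` | 1e-9 | intensity | guard against degenerate backgrounds |
| `carrier_hz` | 220 | Hz | musical register, harmonic 2:1 with modulator |
| `modulator_hz` | 110 | Hz | harmonic timbres are easier to compare by ear |
| `index_scale` | 1 | — | the ratio maps directly to the index |
| `duration_s` | 1 | s | discrete, file-testable notes |
| `fade_ms` | 10 | ms | raised-cosine fades prevent clicks; 0 for measurements |
| `peak_amplitude` | 0.8 | — | normalization applies only when exceeded, so quiet tones keep their level ordering |

Negative ratios (probe target below zero) are preserved in all numeric
outputs and tables but clamp to index 0 at synthesis: the numbers stay
faithful while the synthesizer stays well-defined. Spectral measurements in
tests use $f_c = 2000$, $f_m = 100$ Hz so that every sideband of interest
falls on an exact DFT bin of a 1 s buffer at 44100 Hz.

## The phantom

No raw animal data are available, so a synthetic phantom stands in for the
acquisition. It emulates, per channel $w$:

* a spatially uniform autofluorescence background
  $B\,e^{-\lambda_{bg}(810 - w)}$ with $B = 100$, $\lambda_{bg} = 0.002$/nm —
  rising across the window so the background target value is positive, which
  the ratio method itself requires (see above). The decay constant was fixed
  by the weak-signal construction below;
* an elliptical tumor (default semi-axes 12 × 9 px at (64, 80) in a 128 × 128
  image) adding a Gaussian emission bump
  $A\,e^{-(w - 720)^2 / (2\cdot 25^2)}$, peaked inside the mid bins because
  the bins define what "signal" means for this method;
* optionally a small high-amplitude region (amplitude ×5) emulating an
  extravasated-injection positive control at the tail;
* additive zero-mean Gaussian noise (sd 5), clipped at zero. Gaussian noise
  keeps the closed-form expected ratio exact in expectation; a Poisson mode
  exists for robustness testing. All randomness is seeded and the global RNG
  stream is left untouched.

With background band difference $d$ and unit-bump band difference $g$, the
noise-free ratio is exactly $1 + A g / d$ (23.8 at the defaults); the suite
verifies this to 1e-9 relative and verifies 5% recovery of the mean over 50
noisy phantoms. Rectangular probe ROIs are inscribed in the ellipses so every
probed pixel carries the bump, keeping the closed form exact.

**The weak-signal regime.** `masked_tumor_config()` models a tumor invisible
to single-band inspection: semi-axes shrink to (3, 2) and the amplitude is
solved from $A = (r - 1)\,d/g$ for a target ratio $r = 1.7$. At the default
noise this gives a best-channel contrast of $A/\sigma \approx 1.8$ — below
the ~2 usually needed to see a structure — while the ROI-averaged
sonification ratio stays near 1.7 with a standard error of ~0.1 per
measurement. Measurements of this regime follow the three-replicate averaging
protocol used for the statistics. The defaults $\lambda_{bg}$ and $r$ were
chosen once from this algebra (both constraints must hold simultaneously,
which forces $B d/g \approx 11$) and are not tuned thereafter.

What the phantom does **not** emulate: photon transport (depth-dependent
scattering/absorption), spatially textured autofluorescence (fur, food
particles), detector nonlinearity, or probe pharmacokinetics. Passing tests
therefore demonstrate the correctness and calibration of the *pipeline*, not
in vivo performance.

## Parametric images

Per-pixel target values normalized by the background target form the
parameter map. Rendering rescales min–max to 0–1 (an optional 1st–99th
percentile clip exists for noisy maps, off by default, since plain min–max is
the literal protocol) and maps value $v$ to HSV hue $240°(1 - v)$ at full
saturation — blue for cold, red for hot — using an explicit sextant formula
with round-half-up 8-bit quantization so the colors are bit-reproducible. A
constant map renders all-blue rather than erroring. Overlap with the
ground-truth mask is scored by Dice after Otsu thresholding (256 levels).

## Statistics

The group comparison is the two-sided Wilcoxon rank-sum test, exact by
enumeration when the combined sample is ≤ 12 without ties, and the
tie-corrected normal approximation otherwise (the threshold is configurable).
Replicate measurements are averaged within subject before testing, so each
animal contributes one value per region and pseudo-replication is avoided. A
paired signed-rank mode is available behind a flag, since per-animal pairing
of tumor versus own skull is an equally defensible protocol; unpaired is the
default. Degenerate input (all values identical) returns p = 1 with a
warning rather than an error. The suite checks the exact p-values against
exhaustive enumeration of all labelings for every group-size combination up
to a combined n of 10, the empirical type-I error at n = 10 per group over
2000 seeded null replicates, and power against a 3-sd shift.

## Numerical and I/O choices

* Cubes: multi-page TIFF + JSON wavelength sidecar. The TIFF writer stores
  integer samples, so integer-valued cubes round-trip exactly as uint16 while
  floating cubes are stored as scaled 32-bit integers with the scale recorded
  in the sidecar (read-back error ≤ scale·2⁻³²). Uncompressed pages make
  repeated seeded writes byte-identical.
* Audio: mono 16-bit PCM WAV; quantization error ≤ 1/32767, deterministic.
* Rasterization conventions (the interactive GUI this replaces left them
  implicit): 0-based row-major coordinates; rectangles half-open; polygon
  membership by pixel-center with the even-odd rule; circle membership by
  pixel-index distance. Property tests compare against exhaustive
  pixel-center containment.
* ROI-mean-then-target equals mean-of-per-pixel-targets by linearity; the
  package computes the former and the suite property-tests the equality, so
  the choice is immaterial.

## Known limitations

* **Per-pixel detection floor.** When the best single-band contrast is held
  below $2\sigma$, the per-pixel ratio-map z-score is bounded near
  $2\sqrt{2}\,g \approx 2.4$ regardless of every other parameter (noise,
  background level and slope all cancel). A 7 × 5-pixel tumor at that
  separation occupies ~0.1% of the image, and a global Otsu threshold then
  splits the background noise rather than isolating the tumor, so mask
  recovery by Dice fails in the masked regime even though the ROI-averaged
  ratio detects the tumor cleanly. This is a real limit of per-pixel
  histogram thresholding, not of the ROI-level display; the corresponding
  acceptance check is left failing by design and the acceptance script
  reports the measured `masked_dice` honestly.
* FM index changes timbre, not pitch; perceptual reports of "high-pitched"
  tumors conflate the two. No psychoacoustic (loudness/pitch) scaling is
  implemented.
* Real-time interactive probing and vendor file formats are out of scope;
  the CLI probes named ROIs in batch.

## Problem sizes

Default analyses use 128 × 128 × 18 cubes; the calibration checks use 50
noisy phantoms, 60 background-stability seeds, 2000 null replicates for test
size and 200 for power; synthesis oracles use 1 s buffers at 44100 Hz. The
full suite and the acceptance script each run in well under a minute on one
CPU.
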