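# sonifluor

Auditory display of in vivo near-infrared fluorescence (NIRF) hyperspectral
imaging data.

## The problem

Hyperspectral fluorescence imaging of living animals records, at every pixel,
intensities across many narrow wavelength bands (here 18 channels spanning
640–810 nm). A NIRF probe such as cy5.5-glucose accumulates in tumors and
emits in a characteristic band, but the signal competes with broadband tissue
autofluorescence — skin, fur, food particles — which can swamp small or deep
lesions in any single-band or visually unmixed image. This package implements
a complementary channel of perception: it converts the spectral signature of
a region of interest (ROI) into *sound*, so that a probe-bearing region is
heard as a bright, complex timbre against a plain background tone. It is
aimed at researchers working with small-animal fluorescence imaging or with
auditory display methods, and it ships a synthetic tumor phantom so the whole
pipeline runs and is tested without animal data.

## The method

For an ROI with mean spectrum $S(\lambda)$, the **target value** is the band
difference

$$T = \frac{1}{4}\sum_{\lambda \in \{710,720,730,740\}} S(\lambda)
    - \frac{1}{4}\sum_{\lambda \in \{640,650,660,670\}} S(\lambda),$$

which is zero for spectrally flat emission of any brightness — this is what
suppresses autofluorescence. The target value of the probed ROI is divided by
that of a background ROI (the skull) to give the **probe-to-background
ratio** $R = T_\text{probe} / T_\text{background}$. That ratio drives a
two-oscillator FM synthesizer as its **modulation index**
$I = \max(R, 0)$:

$$s[n] = A \sin\!\big(2\pi f_c n / sr + I \sin(2\pi f_m n / sr)\big),$$

with sideband amplitudes at $f_c + k f_m$ proportional to Bessel functions
$|J_k(I)|$. Larger ratios spread energy into more sidebands: tumors sound
"high-timbred". Per ROI the package returns the four outputs of the display —
the sound, its audio spectrum, its waveform, and the ratio as a number.
Per-pixel ratios are rescaled to 0–1 and rendered as a rainbow-scale
parametric image (blue = low, red = high), optionally overlaid on a
grayscale photograph. Cohort-level ROI ratios are compared with the
two-sided Wilcoxon rank-sum test after averaging replicate measurements
within subject.

## Worked example

```r
library(sonifluor)

ph <- generate_phantom(phantom_config(seed = 1))
ph$cube
#> <spectral_cube 'phantom-seed1'> 128 x 128 pixels, 18 channels (640-810 nm)
ph$truth$expected_ratio
#> [1] 23.82472

son_t <- sonify_roi(ph$cube, ph$rois$tumor, ph$rois$skull)
son_b <- sonify_roi(ph$cube, ph$rois$flank, ph$rois$skull)
son_t
#> <sonification> ratio=24.0014, 44100 samples @ 44100 Hz, centroid 1595.8 Hz
son_b
#> <sonification> ratio=1.0204, 44100 samples @ 44100 Hz, centroid 244.3 Hz
```

The tumor ROI measures a ratio of 24.0 against the closed-form expectation of
23.8 from the phantom's spectral model, and its sound carries far more
high-frequency energy (spectral centroid 1596 Hz vs 244 Hz for the flank):
the tumor is *audible*. Reconverting per-pixel ratios into an image and
thresholding recovers the ground-truth tumor mask:

```r
pm <- parameter_map(ph$cube, ph$rois$skull)
om <- otsu_mask(rescale01(pm))
dice_coefficient(om$mask, ph$truth$mask)
#> [1] 1

tab <- phantom_ratio_table(n_subjects = 6, replicates = 3, seed = 1)
cmp <- compare_groups(tab)
cmp$test
#> Wilcoxon rank-sum, exact: statistic=36, p=0.002165 (n1=6, n2=6)
```

Across a six-phantom cohort with three measurements per region, the tumor
ratios (median 24.04, range 23.32–24.75) separate cleanly from the skull
background (median 1.02, range 0.98–1.04).

A command-line pipeline wrapping these functions is installed at
`inst/cli/sonifluor`:

```sh
sonifluor phantom --seed 1 --out out/
sonifluor probe --cube out/cube.tif --rois out/rois.json \
    --probe tumor --background skull --out out/tumor/
sonifluor map --cube out/cube.tif --rois out/rois.json --background skull --out out/
sonifluor stats --cube out/cube.tif --rois out/rois.json --out out/
```

`probe` writes the four per-ROI outputs (`sound.wav`, `spectrum.png`,
`waveform.png`, `value.json`); `map` writes `map.csv`, the rainbow `map.png`
and `overlay.png`.

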