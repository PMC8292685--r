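---
title: "Measuring CT image quality on synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring CT image quality on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomiq)
```

`phantomiq` implements the standard quantitative image-quality chain for
reconstructed CT — line-ROI CT numbers and attenuation profiles, noise
magnitude, the radial-frequency noise power spectrum, the circular-edge
MTF, a model-observer detectability surrogate, and Cohen's kappa — together
with a synthetic phantom generator whose ground truth is known exactly.
This vignette explains the models behind each stage, the parameters that
matter, the numerical choices that were genuinely open, and what the
passing tests do and do not demonstrate about real scanner data.

## The synthetic phantom and what it emulates

A phantom specification (`phantom_spec()`) describes a uniform circular
body (default 200 mm, matching the body of a Catphan-style module) on an
air background of −1000 HU, with circular inserts given by centre,
diameter, and CT-number contrast. The presets (`catphan_presets()`) mirror
the three modules a phantom protocol uses:

* *sensitometry*: 12-mm disks at 340, 120 and −35 HU (aorta-like,
  tumour-like and adipose-like contrasts) at the 9, 11 and 1 o'clock
  positions of a 58.5-mm insert circle, plus a 990-HU disk for the MTF;
* *uniformity*: no inserts (noise and NPS measurements);
* *low contrast*: nine disks of 15, 9, 8, 7, 6, 5, 4, 3, 2 mm diameter at
  the 1.0% contrast level.

"1.0% contrast" has no universal HU meaning; the preset interprets it as
10 HU per 1% (a 100-HU scale, i.e. 10 HU above the local background) and
exposes the convention as `hu_per_percent`.

Two ground-truth channels make the generator useful for validation:

**Edge blur.** The reconstruction kernel's point spread is modelled as an
isotropic Gaussian of width `blur_sigma_mm` (default 0.3 mm, a typical
body-kernel scale). Rather than rasterizing a sharp disk and convolving
the *sampled* image — which aliases the edge spectrum and silently changes
the effective MTF — the blur is applied to the *continuous* scene in
closed form: the Gaussian-blurred indicator of a disk of radius $R$ at
distance $d$ from its centre is a noncentral $\chi^2_2$ probability,
$P\!\left[\chi^2_2\!\left(\mathrm{ncp} = d^2/\sigma^2\right) \le
R^2/\sigma^2\right]$ (the Rice distribution's CDF), evaluated per subpixel
sample and averaged over the pixel aperture. For $R/\sigma > 50$ the
normal limit with the curvature shift $\sigma^2/2d$ is used. The rendered
scene's true MTF is therefore *exactly*
$\exp(-2\pi^2\sigma^2 f^2)\,\mathrm{sinc}(\pi f \Delta x)$, which is what
every MTF recovery test asserts against.

**Noise.** Per-slice noise is white Gaussian (default), low-pass
correlated (`gaussian_lowpass`), or shaped to an arbitrary radial target
spectrum (`target_nps`): white noise is filtered in the frequency domain
by the square root of the target and rescaled deterministically by
$\sigma / \sqrt{\overline{H^2}}$ so the per-pixel SD equals `sigma_hu` in
expectation. The default noise level of 15.4 HU and the default 50 slices
per stack reproduce the measurement conditions of an abdominal
ultrahigh-resolution protocol (256² ROI, 50 sequential images). Noise is
added after the blur — it models reconstruction-domain noise, not scene
noise.

The generator does **not** simulate projections, reconstruction
algorithms, beam hardening, or the attenuation of an oval annulus. Passing
recovery tests therefore demonstrate that the *measurement chain* is
correct, not that any scanner behaves like the phantom; on real data the
noise is nonstationary, the PSF non-Gaussian, and the measured MTF is an
object-specific effective MTF.

## Line-ROI measurements

CT numbers are measured the way phantom protocols do it with an image
viewer: a 1 × 27 pixel line (≈ ±5 mm at 0.390625 mm/px) centred on the
insert, rotated through 360° in 1° steps on every slice, sampled by
bilinear interpolation. The attenuation profile curve uses a 1 × 51 line
(≈ ±10 mm) so the disk appears as a plateau flanked by background.

Two conventions were open and are worth stating:

* **Dispersion.** The reported `sd_hu` pools every sample (grand SD),
  whose magnitude is comparable to the image noise; the SD of per-angle
  means is also computed (`sd_angle_means`). Note that bilinear
  interpolation averages up to four pixels, so the grand SD of white noise
  is attenuated by a closed-form factor
  $\sqrt{\mathbb{E}[((1-f_r)^2+f_r^2)((1-f_c)^2+f_c^2)]}\approx 0.67$;
  with `method = "nearest"` samples are raw pixels and the grand SD equals
  the image noise. The tests assert both behaviours.
* **Interpolation.** Bilinear by default (matches common line-profile
  tools); nearest-neighbour available for exactness checks.

## Noise magnitude and the noise power spectrum

Noise is the per-slice SD inside a centred square ROI (256² by default),
averaged across slices; its SE is the SD of per-slice SDs over
$\sqrt{n}$, reported as `NA` (not 0) for a single slice.

The NPS uses the radial frequency method: per slice,

$$\mathrm{NPS}(f_x, f_y) = \frac{\Delta x^2}{N^2}\,
\left|\mathrm{DFT}\left[\,\mathrm{ROI} - \text{trend}\,\right]\right|^2
\quad [\mathrm{HU^2\,mm^2}],$$

averaged over slices and collapsed onto a radial axis with bin width equal
to the DFT spacing $1/(N\Delta x)$; the zero-frequency sample is excluded
and empty bins dropped. The normalized NPS divides by the trapezoidal area
under the curve, characterizing texture independent of amplitude. Open
choices, made and documented here: detrending is per-ROI mean subtraction
(default) with a first-order plane fit available against synthetic
shading; no windowing is applied; one whole-ROI periodogram per slice
(the protocol's stated ROI usage) rather than overlapping sub-ROIs.

Verification levels: the white-noise spectrum must be flat at
$\sigma^2 \Delta x^2$, its 2-D integral must match the ROI variance
(Parseval), radial binning must conserve total off-DC power to machine
precision, and a shaped texture must round-trip through
generator → estimator within 10% per well-occupied bin. Because the lowest
radial bin pools only ~8 Hermitian-paired periodogram samples per slice,
the per-bin Monte Carlo error is $\approx 1/\sqrt{4n_\text{slices}}$; the
flatness test therefore uses 1024 slices (error ≈ 1.6% against the 5%
band), while Parseval is checked at the protocol's own 50 slices.

## Circular-edge MTF

The chain is: pixel-wise signal average over the stack (noise falls as
$1/\sqrt{n}$) → optional centroid refinement of the disk centre → radial
edge-spread function (ESF) → central-difference line-spread function (LSF)
→ tapered, zero-padded DFT → normalization to 1 at zero frequency → f50 and
f10 at the first downward crossings, linearly interpolated. The nominal
radius is refined once at the half-amplitude crossing of a provisional
ESF, so the user's nominal value only needs to be roughly right.

The numerically delicate choices, each of which was validated against the
Gaussian closed form $f_p = \sqrt{\ln(1/p)/(2\pi^2\sigma^2)}$:

* **ESF binning.** Pixels in a ±5-mm annulus are binned by signed distance
  from the edge at 0.1-pixel width. Each bin is summarized by the
  *centroid* (mean distance, mean value) and the centroid scatter is
  interpolated onto the regular grid. Assigning bin-centre positions
  instead turns the steep edge slope into high-frequency ripple whose
  amplification by the aperture correction moved f10 by several percent at
  unfavourable sub-pixel disk positions; with centroid positions the
  worst-case closed-form recovery error across disk centres — including
  pathological lattice-aligned ones — is below 1%.
* **Taper.** A Tukey window with α = 0.5 (flat central half). A full Hann
  taper multiplies the LSF core by its envelope and inflates f50/f10 by
  2–10% for blurs of 0.2–0.5 mm; the regression test
  `test-mtf.R` ("the Hann taper option…") demonstrates the effect, and
  Hann remains available for comparison.
* **Transfer corrections.** The central-difference derivative contributes
  $\mathrm{sinc}(2\pi f h)$ and the renderer's pixel aperture
  $\mathrm{sinc}(\pi f \Delta x)$; both are divided out (the aperture
  correction only when `aperture_mm` is supplied, as the estimator cannot
  know the aperture of arbitrary input data). The reported curve is capped
  where the aperture correction approaches its zero
  ($f = 0.9/\Delta x$), beyond which corrected values are numerically
  meaningless.
* **Baseline.** The mean of the outer 10% LSF tails is subtracted before
  tapering.

The replicate runner emulates repeated signal-averaged reconstructions as
independent replicate stacks of the same scene and reports the mean curve
with across-replicate SEs of f50/f10 (absent, not zero, for a single
replicate).

## Detectability surrogate and reader agreement

Human low-contrast readings cannot be reproduced computationally. The
package provides a clearly-labelled surrogate: the non-prewhitening
matched-filter SNR of a disk template,
$\mathrm{SNR} = (C/\sigma)\sqrt{\pi d^2/4}/\Delta x$ under white noise,
or NPS-weighted ($\mathrm{SNR}^2 = [\int |\tilde W|^2 \mathrm{d}^2f]^2 /
\int |\tilde W|^2\,\mathrm{NPS}\,\mathrm{d}^2f$ with the disk's Airy
spectrum) when a measured spectrum is supplied. The minimum detectable
diameter is the smallest ladder entry whose SNR reaches a Rose-type
threshold (default 5). The surrogate is monotone in contrast, diameter and
inverse noise — properties the tests assert — but its absolute scale is a
modelling convention, not a prediction of human performance.

Cohen's kappa is unweighted by default (the convention matching the usual
interpretation scale: 0.01–0.20 slight, 0.21–0.40 fair, 0.41–0.60
moderate, 0.61–0.80 substantial, 0.81–1.00 almost perfect, applied to the
kappa rounded to two decimals); linear and quadratic weights are available
for the ordered diameter categories.

## Protocol runner, sizes, determinism

`run_protocol()` binds named conditions (each a noise level, blur, grid
and slice count, or pre-existing stacks on disk) to the three phantom
modules, runs every configured measurement, and writes CSV tables — CT
number (mean ± SD), noise (HU (SE)), noise ratio vs a reference condition
(integer percent, half-up rounding), f50/f10 (cycles/mm (SE)), the
detectability surrogate — plus NPS/APC/MTF curve exports and a markdown
summary whose provenance block records every analysis default in effect.
The noise/NPS ROI is automatically capped to the square inscribed in the
phantom body (3-mm margin per side) so it never touches the blurred body
edge. Any failing stage is recorded as an explicit skip without aborting
other conditions; a zero-noise reference makes the ratio table itself a
skip record.

All randomness flows from explicit seeds: a stack is a deterministic
function of (spec, seed), the protocol derives per-condition, per-module
seeds from its master seed, and reruns write byte-identical CSVs. The test
suite and the acceptance script run at reduced problem sizes — 256–512 px
grids at the standard 0.390625 mm pixel spacing, 80–200 mm bodies, 50-slice
stacks (more only where a Monte Carlo error budget demands it, as in the
NPS flatness check) — chosen so each check's sampling error is several
times smaller than the tolerance it asserts.

## Known limitations

* No projection/sinogram simulation or reconstruction-algorithm emulation;
  conditions are opaque labels, not models of FBP/HIR/MBIR/DLR.
* DICOM I/O is not included; stacks travel as raw float64 arrays with a
  YAML sidecar (`write_stack()` / `load_stack()`).
* The ESF assumes a circular edge and a radially symmetric PSF; strongly
  anisotropic reconstruction kernels would bias the azimuthally pooled
  estimate.
* The detectability surrogate ignores observer internal noise and
  psychophysical effects; it ranks conditions, it does not predict reader
  scores.
* Human-reader tables from physical-phantom studies are not an acceptance
  surface for the surrogate and are not reproduced.
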