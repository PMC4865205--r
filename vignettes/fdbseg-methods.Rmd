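---
title: "Factorized directional bandpass segmentation: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorized directional bandpass segmentation: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdbseg)
```

## The signal model

A fingerprint scan is modelled as an oriented oscillation — locally a plane
wave $\tfrac12 + \tfrac{A}{2}\cos(2\pi\,\phi(x)/\lambda)$ with interridge
distance $\lambda$ — inside the region of interest, over a background that is
either homogeneous (spectral content below the ridge band) or small-scale
noise (above it). Segmentation therefore reduces to isolating the spectral
band and the orientations that carry the ridge energy, reconstructing a
texture-only image, and converting it into a single convex foreground region.

## The DHBB filter bank

The oriented bandpass is a product of two factors on the 2D frequency grid.

**Radial factor.** The Butterworth bandpass
$$\hat b(\omega) = \frac{(\omega\Delta)^{2\gamma}}
  {(\omega\Delta)^{2\gamma} + (\omega^2-p^2)^{2\gamma}},\qquad
  \Delta = \omega_H-\omega_L,\; p^2 = \omega_H\,\omega_L,$$
is 1 exactly at $p$, decays to 0 at DC and at infinity, and tends to the
ideal indicator of $[\omega_L, \omega_H]$ as $\gamma \to \infty$
(`butterworth1d`, `butterworthIdeal1d`). Unlike a Gaussian (Gabor) profile it
treats all in-band frequencies almost alike at moderate $\gamma$, while
avoiding the Gibbs ringing of the ideal filter. Numerically we evaluate
$1/(1 + r^{2\gamma})$ with $r = (\omega^2-p^2)/(\omega\Delta)$, which is
algebraically identical, overflow-safe for large $\gamma$, and removes the
removable singularity at $\omega = 0$ (set to its limit 0).

For discrete frequencies the analog prototype is factorized over the roots
$t_k = e^{\pi j(\gamma+2k-1)/2\gamma}$ (`butterworthRoots`) and mapped
through the bilinear transform $j\omega \approx 2(e^{j\omega}-1)/(e^{j\omega}+1)$,
giving the rational product form of `butterworthBilinear1d`. The bilinear
form narrows the passband slightly; both variants are implemented and
selectable (`variant` in `fdbParams`), with the bilinear form — the one the
derivation of the method actually uses — as the default.

The 2D extension tiles the frequency plane with the Cartesian indicator pair
$\chi_h = 1\{b|\omega_1| \ge a|\omega_2|\}$, $\chi_v = 1 - \chi_h$, applying
the 1D response to the dominant axis frequency. Ties on the diagonal
$b|\omega_1| = a|\omega_2|$ are assigned to the horizontal sector so that the
two indicators form a partition — otherwise diagonal frequencies would be
double-weighted. $a$ and $b$ are the half-widths of the padded image
(columns/2, rows/2), so square images reduce to comparing
$|\omega_1|$ with $|\omega_2|$.

**Angular factor.** The $n$-th order directional Hilbert spectrum
$(-j)^n\cos^n(\angle\omega - \theta_l)$, $\theta_l = \pi l/L$, concentrates
around its orientation as $n$ grows, with magnitude at most 1 and exactly 0
perpendicular to the orientation. At DC the direction cosine is undefined;
we set the spectrum to 0 there, which changes nothing because the radial
factor already vanishes at DC. The constant $(-j)^n$ is taken exactly
(period-4 cycle), so even orders give exactly real spectra; for the default
$n = 20$ it equals $+1$.

With $L = 16$ orientations and $n = 20$ the worst-case orientation (midway
between two $\theta_l$) still receives $\cos^{20}(\pi/32) \approx 0.91$ of
the bandpass envelope, so no ridge orientation falls through the bank.

## The factorized transform

`fdbFeatureImage` composes: mirror-pad (15 px, reflection without repeating
the edge sample) → analysis → adaptive soft-threshold → synthesis → crop.

All filtering is circular via the DFT on the padded image; the pad absorbs
the wrap-around. Analysis correlates with each subband filter — i.e. filters
by the argument-reversed spectrum $\hat\phi_l(-\omega)$, implemented as an
index reversal on the DFT grid — and synthesis applies the non-reversed
filter to the thresholded coefficients and sums over subbands. The reversal
in analysis and non-reversal in synthesis make the composite filter
$\sum_l \hat\phi_l(-\omega)\hat\phi_l(\omega)$ symmetric, compensating the
phase of the odd Hilbert component; with a zero threshold the transform
reduces to exactly that composite filter (a property the tests verify to
1e−10 in the spectrum).

The shrinkage level adapts to the image: $\beta = C\max_{l,m}|c_l[m]|$. The
maximum is taken over coefficient *magnitudes*: coefficients may be negative
(or numerically complex), and a signed maximum would make the threshold
depend on pattern polarity. Since analysis is linear, $\beta$ scales with
the image, making the whole pipeline invariant to positive intensity
rescaling — only the dimensionless $C$ is trained. Soft-thresholding
$T(x,\beta) = \tfrac{x}{|x|}\max\{|x|-\beta, 0\}$ is the proximal operator
of $\beta\|\cdot\|_1$; hard, semi-soft and garrote comparators are provided
(`comparisonThreshold`) for the synthesis comparison study only. The
synthesis output takes the real part; the imaginary residue is rounding
noise for even $n$.

## From feature image to ROI

Binarization marks pixels with $\tilde f \ge C\max\tilde f$ (the same
trained $C$). Because $\tilde f$ oscillates, the binarized texture is a
striped version of the ridge pattern; the two-scale morphology turns it into
a solid region: a pixel is kept when at least $b = 6$ of the 9 cells of size
$s\times s$ centred at offsets $\{-s, 0, s\}^2$ around it contain at least
$s^2/t$ white pixels. Working at two scales (pixel cells, then a 3×3 block
of cells) fills inter-stripe gaps without bridging to detached noise blobs
the way a plain closing would — a blob separated by more than about $2s$
cannot contribute the required votes.

Three reading decisions, each forced by internal consistency: the cell
threshold is $s^2/t$ (the trained range $t \in \{4,\dots,7\}$ makes a
product $s^2 t$ an unreachable count); the 9 offsets are the full
$\{-s,0,s\}^2$ grid (the operator is described with 8 neighbouring blocks);
and pixels outside the image count as black, so cells keep their clipped
in-image counts wherever their centre falls. A consequence of the black
border is that even an all-white mask is slightly eroded within $\sim 2s$ of
the border (corner pixels see only 4 non-empty cells); the operator is
deliberately conservative near margins.

Foreground components are labelled with 8-connectivity (matching the visual
continuity of ridge masks), the largest kept, and its convex hull — filled
by a half-plane rasterization over the pixel grid — returned as the ROI.
Holes are inside the hull by convexity, so no separate filling step exists.
Degenerate inputs short-circuit: a blank image leaves only rounding noise in
the feature image (its maximum below $10^{-10}$ of the input scale, a
relative floor to preserve scale invariance), and returns an empty ROI
rather than letting the $\ge$ binarization rule mark everything.

## Parameters

| parameter | default | role |
|---|---|---|
| $C$ | 0.05 (trained 0.03–0.09) | relative level of $\beta$ and of binarization |
| $n$ | 20 | angular sharpness of the directional Hilbert factor |
| $L$ | 16 | number of orientations |
| $\gamma$ | 2 (trained 1–4) | Butterworth order (band edge sharpness) |
| $\omega_L, \omega_H$ | 0.3, 1 | passband, radians/sample |
| $s$ | 9 px | morphology cell size |
| $t$ | 5 (trained 4–7) | cell occupancy divisor ($\ge s^2/t$ white to vote) |
| $b$ | 6 | votes required of the 9 cells |
| pad | 15 px | mirror pad width |

$C$, $\gamma$ and $t$ are sensor-dependent and trained by exhaustive grid
search (`gridSearchParams`) minimizing the mean per-image error
$\mathrm{Err} = (M_f + M_b)/(N_1 N_2)$ on a training split, ties broken
toward the lexicographically smallest $(C, \gamma, t)$; the package defaults
are mid-range values of the per-sensor trained sets shipped in
`inst/extdata/configs/`. The mean over a dataset is the unweighted mean of
per-image errors (each image counts equally whatever its size).

## The synthetic generator

`makeFingerprint` renders the signal model directly: a cosine ridge pattern
of wavelength $\lambda \in [3, 25]$ px inside a known ellipse (three
geometries: parallel ridges, concentric arcs, parabolically bending ridges),
flat 0.5 background, optional white noise and artifact models — a 60 %
attenuated ghost print outside the ROI, dry-contact breaks (blank discs),
and smooth large-scale structure noise. Ground truth is the ellipse raster,
exact by construction, so measured errors are attributable to the algorithm
alone. All randomness flows from a single integer seed; output is
bit-reproducible.

`makeSuite` builds evaluation suites of 256×256 images cycling
$\lambda \in \{4, 8, 12, 20\}$ and the three geometries, in three nested
difficulty tiers: *clean* (noise σ = 0.03), *noisy* (σ = 0.15), and
*artifacts* (σ = 0.15 plus all three artifact models) — nesting makes the
difficulty ordering monotone by construction. Amplitude is 0.7 throughout;
these sizes keep a full three-tier evaluation plus training within a few
minutes on one CPU, and the acceptance tests state the suite sizes they use
(20 images per tier, 8 training images).

What the generator does *not* emulate: minutiae-level structure, pore
detail, local wavelength and amplitude modulation, sensor-specific
nonlinearities, or annotation noise in the ground truth. Passing the
synthetic tiers therefore demonstrates correct spectral selection, shrinkage
and morphology behaviour — not performance parity on real sensor data.

## Known limitations

* **Morphology scale bound.** With the fixed $s = 9$, $b = 6$, binarized
  stripe patterns with trough width $\ge s$ — i.e. $\lambda \gtrsim 2s$ —
  can be cut at stripe centres: the $\pm s$ cells of a stripe-centre pixel
  then sit wholly inside troughs, leaving only 3 of 9 votes. For ridges
  nearly aligned with an image axis these cuts sever the mask, the largest
  component collapses to one band, and the error jumps to 0.2–0.37; diagonal
  orientations are unaffected. In the synthetic suites this makes the
  $\lambda = 20$ px images the dominant error source (the clean tier
  averages ≈ 0.06 with trained parameters versus ≈ 0.015 for
  $\lambda \le 12$), and no setting of the trained $(C, \gamma, t)$ removes
  it. In the intended acquisition setting images are rescaled so that
  effective interridge distances stay near the lower half of the valid
  range, where the operator is sound.
* **Convex ROI only.** True ROIs of partial or rolled prints can be
  non-convex; the hull then over-covers.
* **Dilation bias.** The voting operator extends the mask a few pixels
  beyond the texture edge; the resulting ring (≈ 2–4 px) is the main error
  term on clean fixtures and weighs more on small images.
* **Single-print assumption.** The largest-component rule keeps exactly one
  region; two genuine prints in one frame would lose the smaller.

## Numerical notes

Frequency grids use the unshifted DFT layout mapped to $[-\pi, \pi)$, so
filters are built directly in the layout `fft` produces and no spectrum
shifting ever occurs. Argument reversal is an exact index reversal
(`(n - k) mod n`), not conjugation, so it is correct for complex spectra
too. The bilinear product form checks each factor's denominator and reports
the offending frequency on an exact pole hit (none occurs for the trained
parameter ranges). Box sums in the morphology use an integral image
(exact integer counts); the cell threshold $s^2/t$ is compared unrounded
with $\ge$, as is the binarization threshold. Hull rasterization includes
boundary pixels via a $10^{-9}$ half-plane tolerance; components of fewer
than three distinct points fall back to the pixels themselves.
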