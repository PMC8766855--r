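---
title: "Single-image vignetting correction: model, estimation and validation"
author: "vigncorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-image vignetting correction: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigncorr)
```

## The problem

In functional 2-photon microscopy the local image intensity is read as a
quantitative proxy of neural activity — for immediate-early-gene reporters,
the center-pixel brightness of a segmented soma. Vignetting, the radial
falloff of brightness *and* contrast from the optical axis toward the frame
periphery, breaks the presumed intensity–activity relationship in a
spatially structured way: central neurons appear systematically brighter
and more variable than peripheral ones, and any statistic compared across
positions inherits a center-periphery bias. Because the falloff varies
day-by-day (vessel dilation, brain-position shifts, optical drift),
reference-image and multi-image corrections are unattractive — they also
impose identical corrections at a given position across images, inducing
artificial correlations between the very signals whose correlation is the
scientific question. This package therefore corrects each slice from its
own content alone.

## Model

The observed slice $I_0(x,y)$ is modelled as an affine distortion of the
true scene $I(x,y)$ with a spatially varying additive background
$M_B(x,y)$ and multiplicative gain $M_C(x,y)$, corrected by

$$I(x,y) = C_T \, \frac{I_0(x,y) - M_B(x,y)}{M_C(x,y)} + B_T ,$$

where the constants $B_T$ and $C_T > 0$ only fix the output value range
and are held identical across all slices of a stack so background
statistics are unified in depth. Brightness-only
($I = I_0 - M_B + B_T$) and contrast-only
($I = C_T (I_0 - M_B)/M_C + M_B$) variants isolate the two effects.

Both fields are modelled as wide, axis-aligned 2D Gaussian surfaces with a
constant offset,
$A \exp\{-[(x-x_0)^2/2\sigma_x^2 + (y-y_0)^2/2\sigma_y^2]\} + b$ —
six parameters per field. The offset absorbs the camera baseline; a
rotation term is omitted because vignetting is approximately
axis-symmetric, and adding it would spend a seventh parameter on a degree
of freedom the data rarely constrain.

## Estimation

**Support points.** The slice is tiled with non-overlapping square
patches (default 32 px for a 512 px frame: 256 patches of ~1000 px). The
patch size is a trade-off: patches must hold enough background pixels for
a stable normality test, yet be numerous enough to constrain the surface
fit. 16-px patches leave ~250 pixels after foreground removal and fail
the normality gate routinely; 128-px patches leave only 16 support points.

Within each patch the background brightness $B$ and contrast $C$ are the
mean and ML standard deviation of the pixel intensities after two robust
cleaning stages:

1. *Power-law tail cutoff.* Bright foreground (active somata, whose
   point-spread-blurred profiles produce a long, slowly decaying
   intensity tail) is removed above a cutoff found by scanning candidate
   tail starts $x_{\min}$ over the sample values, fitting a continuous
   power law by maximum likelihood to each tail, and taking the *smallest*
   $x_{\min}$ whose tail passes a Kolmogorov–Smirnov acceptance band
   ($\sqrt{m}\,D \le 1$) with exponent $\alpha \le 8$. The more common
   global-minimum-$D$ rule is deliberately not used: on tails that are
   not genuinely power-law it drifts into the background bulk (large
   smooth tails have small absolute $D$) or deep into a true tail (small
   tails have small $D$ by chance), and either way truncates the
   background sample the next stage needs intact. When no candidate is
   acceptable — pure noise with no separable foreground — the cutoff
   falls back to the rightmost candidate and removes at most 7 points.
2. *Value-symmetric trimming to normality.* The remaining sample is
   restricted to a window $\mathrm{median} \pm c \cdot \mathrm{MAD}$,
   with $c$ shrinking from 3.5 by 0.25 per iteration until the
   Shapiro–Wilk statistic reaches 0.98 (computed on at most 4000 evenly
   spaced order statistics), the window would remove more than half the
   sample, or $c$ reaches 1.75. Trimming symmetric in *value* around the
   robust center excises residual one-sided bright contamination without
   biasing the background mean; count-symmetric quantile trimming, by
   contrast, converts a right-side contaminant into a left truncation of
   the background, which the Shapiro–Wilk gate then rightly rejects.

A patch is a valid support point only if the gate converged and $C > 0$
(a zero contrast cannot be divided by). On phantom slices at the default
density essentially all 256 patches validate; the fits remain
well-conditioned down to the enforced minimum of 15 valid points
(2.5 × the 6 free parameters).

**Surface fits.** The valid $(x^{(i)}, y^{(i)}, B)$ and $(\cdot, C)$
triples are fitted by bounded Levenberg–Marquardt least squares.
Initialization: $b_0 = \min$, $A_0 = \max - \min$, center at the
value-above-baseline weighted centroid, $\sigma_0$ = half the point-cloud
side. Bounds keep $\sigma$ within $[\mathrm{side}/16,\, 10\,
\mathrm{side}]$ and the center within one side length of the frame —
vignetting surfaces are wide and near-centered, so these bounds only
exclude needle-shaped or runaway solutions. $R^2$ is reported over the
support points; fits are per slice and per day, which is exactly what
makes the method single-image.

**Constants.** $B_T$ and $C_T$ default to the means of the valid
support-point $B$ and $C$ pooled over the processed slices; a median
policy is available, and any fixed pair can be supplied. The choice only
sets the output value range.

Corrected intensities are kept in floating point; the contrast field is
refused (with the offending pixel named) wherever it falls below
$10^{-3} C_T$ rather than silently amplifying noise.

## Plausibility evaluation

With no ground truth for real tissue, bias statistics substitute: each
slice is split 4×4 into 4 center (C), 8 edge (E) and 4 corner (A) cells.
Per-neuron measures — activity $X_l$ (center-pixel intensity), its
across-day absolute change $\Delta X_l$ and relative change
$\delta X_l = \Delta X_l / [X_l(d_1)+X_l(d_0)]$ — are compared between
all 120 region pairs by Welch *t*-tests with Bonferroni correction
(family = 120; Welch because vignetting induces heteroscedasticity by
construction), alongside the relative dispersion difference
$\delta_{STD} = |s_a - s_b| / \bar{s}$. Summaries per type pair:
$c_p$ (fraction non-significant at corrected $p \ge 0.01$),
$\Delta C = c_p / \langle c_p\rangle_{same}$ and
$\Delta STD = \bar\delta_{STD} / \langle\bar\delta_{STD}\rangle_{same}$,
normalized by the unweighted mean over the within-type pairs (C-C, E-E,
A-A). Values near 1 mean no center-periphery structure; vignetting drives
$\Delta C$(C-A) toward 0 and $\Delta STD$(C-A) above 1. Highly active
cells are those with $\delta X_l$ above the layer mean plus three
standard deviations; sets from different processing variants are compared
by the asymmetric overlap rate $|H_i \cap H_j| / |H_i|$.

## The phantom generator

Because no stacks are distributed with the package, validation runs on
synthetic phantoms that invert the correction model exactly: a true scene
of Gaussian background noise $N(100, 10)$ plus non-overlapping neuron
disks (radius 3 px, additive constant amplitude, center pixel stamped to
mean + amplitude so the activity readout is exact), observed through
$I_0 = (I - 100)/10 \cdot M_C + M_B$ with known Gaussian fields.
Correcting with the true fields and $B_T = 100$, $C_T = 10$ therefore
reproduces the true scene to floating-point accuracy — the generative
inverse every downstream test leans on.

Default conditions (chosen once for plausibility — real stacks publish
no quantitative SNR to match): 512×512 frames; brightness field
offset 50, peak +100, $\sigma = 0.75\times$ side; contrast field offset
4, peak +8, $\sigma = 0.55\times$ side (the gain falls off more steeply
than the brightness; center-to-corner gain ratio ≈ 1.6); 150 neurons per
slice with amplitudes Uniform(40, 120) — at least 4 background SDs, so
somata are cleanly brighter than noise, with a spread broad enough that
activity dispersion dominates region variance. The wide brightness field
keeps the within-cell brightness gradient small relative to that spread;
with a narrower field the gradient inflates corner-region variance enough
to cancel the gain-driven dispersion bias, and the phantom would no
longer show the dispersion signature expected of vignetted data. Day-1
amplitudes use the mean-preserving correlated-pair construction
$a_1 = \mu + \rho (a_0 - \mu) + \sqrt{1-\rho^2}(\varepsilon - \mu)$ with
$\rho = 0.6$ and $\varepsilon$ a fresh draw — the textbook construction,
since no across-day model is prescribed; the naive
$\rho a_0 + \sqrt{1-\rho^2}\varepsilon$ form would inflate the day-1 mean
by ~40% for a non-centered amplitude distribution. One seed drives fixed
per-slice/per-day sub-streams, so regeneration is bit-reproducible.

What the phantom does *not* emulate: axon/dendrite background texture,
blood-vessel shadows, motion, day-to-day field changes (both days share
the ground-truth fields) and any systematic day effect on mean activity.
Consequently $\Delta X$ and $\delta X$ carry no mean bias on phantoms
(their region means are ~0 everywhere), and passing the bias tests shows
the pipeline removes the distortions the generative model contains — not
that it reproduces real-tissue effect sizes.

```{r phantom, eval = FALSE}
ph <- generatePhantom(phantomSpec(nSlices = 1, seed = 1))
fields <- estimateFields(observedStack(ph), patchSize = 32)
kons <- chooseConstants(fields[[1]]$supportPoints)
corrected <- correctStack(observedStack(ph), fields, kons, "full")
```

## Numerical choices and degenerate inputs

* Shapiro–Wilk on more than 4000 values uses 4000 evenly spaced order
  statistics (deterministic; the test implementation degrades for very
  large n and `stats::shapiro.test` caps at 5000).
* A constant patch has MAD 0: the trim returns the tied value, the gate
  reports non-convergence, and the support point is invalid with $C = 0$.
* A flat support-value set ($SS_{tot} = 0$) has no Gaussian fit and
  errors; slices with fewer than 15 valid points are flagged
  uncorrectable and passed through unchanged with a warning.
* $\delta X$ is NA where $X(d_0) + X(d_1) = 0$; region pairs with fewer
  than 2 neurons are untestable, not errors; an empty reference set makes
  the overlap rate NA with a warning.
* The tail cutoff is computed per patch (it is part of the patch
  analysis); a per-slice variant is not offered.
* Coordinates in all tables and files are 0-based with x = column,
  y = row, pixel centers at integer positions; patch centers are the
  arithmetic mean of the domain corners (e.g. 15.5 for a 32-px patch at
  the origin).

## Validation scale and what the tests show

The test suite and the acceptance script run entirely on phantoms at
sizes chosen to exercise the method faithfully while staying quick:
field-recovery runs use twenty 512×512 single-slice phantoms with 32×32
patches (the fitted brightness surface matches truth at $r^2 > 0.99$ on a
16×16 lattice and the recovered center lands within a fraction of a
percent of the frame width); bias-pattern runs use ten 256×256 × 4-slice
phantoms pooled into one laminar compartment, ~600 neurons each, with the
field widths scaled to the frame. On these, the raw stacks show the
center-periphery signature ($\Delta C$(C-A) ≪ $\Delta C$(E-E),
$\Delta STD$(C-A) > $\Delta STD$(E-E), aggregated over the three measures
as in the evaluation protocol), full correction closes both gaps by well
over half, brightness-only correction leaves the dispersion gap, and
contrast-only correction leaves the $\Delta C$ gap — the qualitative
pattern expected from the model, at desk scale. Unvignetted phantoms are
calibrated: no Bonferroni-corrected pair reaches $p < 0.01$ and every
$\Delta C$ equals 1 within noise.

## Known limitations

* The Gaussian-surface assumption is the method's load-bearing prior;
  strongly asymmetric or multi-modal shading (vessel shadows) violates it
  and is out of scope, as are polynomial/spline shading models and
  multi-image (reference or retrospective) correction.
* The estimator needs a majority-background patch; fields of view packed
  with somata starve the normality gate.
* Absolute corrected intensities should not be compared across laminar
  compartments: tissue composition varies with depth, and unifying
  $B_T/C_T$ across slices makes backgrounds, not biology, comparable.
* The highly-active-cell rule (mean + 3 SD) is sensitive to the
  $\delta X$ distribution's tail; at phantom scale (hundreds of neurons)
  the expected set size is near zero, so overlap rates are validated on
  constructed sets rather than phantom runs.
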