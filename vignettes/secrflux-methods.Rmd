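---
title: "Methods: models and numerical choices in secrflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and numerical choices in secrflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the quantitative model behind each readout, the
synthetic generator that validates it, and the numerical choices that are
easy to get silently wrong.

## The transport index

A synchronized-release experiment images a cargo channel and a Golgi
marker channel at timepoints $t_0 = 0 < t_1 < \dots$ after release. With
the Golgi region $G$ segmented from the marker and the cell ROI $C$, the
raw ratio and the transport index are

$$ r(t) = \frac{\sum_{G} I_{\mathrm{cargo}}}{\sum_{C \setminus G}
I_{\mathrm{cargo}}}, \qquad \mathrm{TI}(t) = \frac{r(t)}{r(t_0)}. $$

Normalizing by $r(t_0)$ removes the per-cell baseline (resting Golgi
content, expression level), so $\mathrm{TI}(t_0) = 1$ identically.

If a fraction $f(t)$ of a conserved cargo pool resides in the Golgi then
$r(t) = f(t)/(1 - f(t))$ and

$$ \mathrm{TI}(t) = \frac{f(t)\,\bigl(1 - f_0\bigr)}{f_0\,\bigl(1 -
f(t)\bigr)}, $$

which is the closed form that `predict_ti()` evaluates and that the
generator plants (baseline $f_0 = 0.02$). The acceptance tests demand the
measured TI to match this closed form within 2% on noise-free scenes
across Golgi fractions 0.05–0.9.

### Golgi segmentation recipe

`compute_golgi_mask()` is deliberately simple and fixed: rolling-ball
background subtraction of the marker frame, Otsu thresholding restricted
to the ROI pixels, intersection with the ROI, then two erosions with a
3×3 cross. The erosions trim the soft edge of the marker blob (the
generator renders it with a ~1.7 px Gaussian edge, matching the optics of
a diffraction-limited rim) so the mask sits strictly inside the true
compartment; the planted-mask IoU stays above 0.9 for all planted
fractions.

### Shot noise and the background pedestal

Morphological (rolling-ball) background estimation takes a local
*minimum* before the smoothing step, so under Poisson noise the estimated
background sits systematically *below* the mean background (roughly 13
counts at a background of 20 with the default radii). After subtraction
every pixel keeps a small positive pedestal. The non-Golgi sum absorbs
~10⁴ pixels of pedestal while the small $t_0$ Golgi numerator (a few
hundred pixels at $f_0 = 0.02$) is inflated by ~50%, which attenuates
late TI values (e.g. a planted TI of 14 reads as ~8). The fix is classic
background-ROI referencing: `compute_transport_index(...,
background_mask = background_region(roi))` measures the median residual
in a cell-free region and subtracts it from both region sums,
per timepoint. On noise-free images this is an exact no-op. The cargo
channel's own rolling-ball radius (default 90 px) is intentionally larger
than the cell footprint so that flat-field shading is removed without
eating the cell-scale cargo signal itself.

### Classification

`classify_transport()` applies half-open intervals $[\ell, u)$ to the TI
at the decision timepoint (30 min for soluble cargo: thresholds 2/5/10;
15 min for transmembrane cargo: thresholds 4/7/10), so a cell exactly on
a boundary goes to the higher class. The generator's `kinetics_preset()`
TI targets sit well inside the class intervals, so the cohort-recovery
acceptance test measures the pipeline noise, not boundary luck.

## Vesicle motility

The movie pipeline is rolling-ball subtraction, optional bleach
correction, global Otsu per frame, connected components filtered by area,
intensity-weighted (sub-pixel) centroids, and greedy nearest-neighbour
linking with a gating radius and single-frame gap closing. MeanSpeed is
the mean per-step speed over all steps of all accepted tracks;
MeanDisplacement is the mean net start-to-end distance. The two
statistics separate motion models at equal step length: directed motion
accumulates displacement linearly in time, a random walk only as
$\sqrt{t}$.

The generator moves each spot by an *exact* planted step per frame.
Border handling reflects the heading *before* the step and retakes the
full step from the current position; folding the position across the wall
instead would preserve path length but shorten the chord between
consecutive recorded centres, corrupting the planted speed.

## Photobleaching correction

Frame means are modelled as $m(t) = A e^{-kt} + b$ (t in frames,
0-based). A joint 3-parameter nonlinear fit is numerically
rank-deficient for slow decays: for $kT \lesssim 1$,
$e^{-kt} \approx 1 - kt$ makes $\partial m/\partial A$ a linear
combination of the offset and rate gradients, and standard NLS reports a
singular gradient even on noise-free data. `bleach_correct()` therefore
uses variable projection: the rate is found by a one-dimensional profile
search (`optimize` over $k$), and $A, b$ are solved linearly for each
candidate rate. The exponential is accepted only if it beats the constant
model in an F test at the 1% level; otherwise a noisy, non-bleaching
movie would receive a spurious correction. Frames are rescaled by
$\hat m(0)/\hat m(t)$, so the first frame is untouched.

## Thresholding

`otsu_threshold()` maximizes the between-class variance over the
*observed unique values* of the image (no fixed bin grid), so it is exact
for integer camera data of any bit depth and agrees with an exhaustive
search by construction; ties resolve to the lowest threshold. The mask is
`image > threshold`. `local_otsu_threshold()` applies the same criterion
in overlapping tiles with a per-tile bimodality guard, recovering dim
structures next to bright ones at the cost of a window-size parameter.

## Morphology

Form factor is $4\pi A / P^2$ with $A$ the pixel count and $P$ a
Crofton-style perimeter estimator. Discretization matters: pixel-edge
counting overestimates the perimeter of smooth shapes by up to
$4/\pi$, pushing disc form factors far below 1. The Crofton estimator is
accurate for smooth boundaries (discs of radius ≥ 20 px reach form
factors above 0.95) but *underestimates* long straight axis-aligned
edges, so thin rectangles read ~20% above the continuous closed form;
this bias is documented and asserted rather than hidden. For
disaggregation series the Golgi footprint is blanked before labelling so
Golgi-resident cargo never contaminates the structure statistics.

## Bandpass filtering

The filament pipeline's band-pass is computed entirely in the frequency
domain: the difference-of-Gaussians transfer function
$e^{-2\pi^2\sigma_s^2 f^2} - e^{-2\pi^2\sigma_l^2 f^2}$ (with $\sigma =
\mathrm{size}/2$) applied to the FFT of the frame. A truncated spatial
kernel would be invalid whenever $\sigma$ approaches the image size; the
frequency-domain form is exact for any cutoff. A hard annulus on spatial
periods is available as `method = "fft"`.

## Scope of the generator

The generator is a *verification* instrument, not a cell model. It
plants: conserved two-compartment cargo kinetics with elliptical cells
and disc Golgi; ER cargo split between diffuse signal and elliptical
puncta of controllable aspect ratio; vesicles as Gaussian spots with
exact step lengths; frame-wide exponential bleaching; Poisson or Gaussian
noise. It does not attempt cell-to-cell variability in shape, organelle
texture, focus drift, or camera artefacts beyond shot noise. Conclusions
about robustness to those effects require real data.

## Limitations

- Golgi segmentation assumes a single compact marker-positive region per
  cell; fragmented Golgi (e.g. after nocodazole) would need the local
  Otsu variant and a multi-component mask.
- Tracking is greedy nearest-neighbour; it is adequate up to moderate
  densities (tested at 20 vesicles / 128² px) but will mislink dense or
  crossing traffic that a global assignment method would resolve.
- The bleach model is mono-exponential with offset; two-population
  bleaching will bias the rate toward the dominant component.
- The TI closed form assumes conservation of the cargo pool; degradation
  or late secretion from the Golgi breaks the mapping from TI back to
  Golgi fraction, though the TI itself remains a valid ratio.
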