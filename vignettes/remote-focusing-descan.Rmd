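---
title: "Models and methods behind rflsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rflsm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflsm)
```

rflsm is the computational side of a polarization-split remote-focusing
(axially de-scanned) light-sheet microscope: the detection path splits the
fluorescence into S- and P-polarized copies, routes both through a
pupil-matched remote objective onto a small scanning mirror, and recombines
them on the camera, so a voice-coil mirror translation -- rather than sample
or objective motion -- scans the focal plane.  The package provides the
paraxial model of that detection path, the sub-pixel S/P overlay
registration, bead-based resolution and light-sheet characterization,
magnification calibration, the dual-color live-cell processing chain, and
mean-square-displacement analysis of tracked granules, together with seeded
synthetic-data generators that carry full ground truth.  This vignette
records the models, the tunable parameters, and the design decisions taken
where the methods left genuine freedom.

## Paraxial ray tracing of the folded detection path

A ray is the column vector $[n\alpha, y]^T$ -- reduced angle (index times
paraxial angle, radians) over transverse height (mm) -- and propagates by
left multiplication with $2\times 2$ elements: a gap $d$ in index $n$ is
$\begin{bmatrix}1 & 0\\ d/n & 1\end{bmatrix}$ and a thin lens of focal
length $f$ is $\begin{bmatrix}1 & -n/f\\ 0 & 1\end{bmatrix}$.  Water
($n = 1.33$) applies up to and including the detection objective, air
afterwards.  Fold mirrors (the polarizing beam splitter and the remote
mirror) rotate the working axis but leave $(n\alpha, y)$ unchanged, so the
algebra runs along a single unrolled axis and folds are pure bookkeeping
for the plotted polylines.  Two invariants anchor the implementation: every
element and every composed system matrix has determinant 1, and for a
composed matrix $S$ from an object plane the image lies where
$S_{21} + (t/n)S_{11} = 0$, with lateral magnification $1/S_{11}$ -- which
is how `trace_field()` and `magnification_vs_scan()` locate images without
ray search.

The detection objective's effective focal length comes from
$f_{obj} = f_{tube}\, n / M_{obj}$ (6.65 mm for the 40x/1.33 design used
throughout); the remote objective is 10 mm.  The remote mirror is not
modeled as a moving part: the gap between the forward and backward copies
of the remote objective is the free parameter (`mirror_gap`), and the scan
surrogate solves, in closed form, the gap that keeps the final image on the
fixed camera plane -- equivalent to holding the image distance after the
second remote-objective pass constant, which is what the physical focus
actuator does.

Two magnification scales coexist.  The camera magnification is the full
relay product (order 40x); the *remote-space* magnification -- image size at
the scanning mirror over object size -- is the quantity that perfect
remote focusing pins at $n_{water}/n_{air} = 1.33$, because aberration-free
refocusing requires unit angular magnification between the two objectives.
`magnification_vs_scan()` therefore reports the camera magnification
divided by the fixed remote-to-camera relay factor $f_{L6}/f_{obj2}$, the
scale on which the perfect-imaging value is 1.33.  With the literal lens
set (relay lens $f_{L5} = 300$ mm) the exact-4f limit evaluates to
$M_{obj} f_{obj2} / f_{L5} = 4/3 \approx 1.333$; the perfect-imaging
(pupil-matched) limit requires $f_{L5} = M_{obj} f_{obj2}/n_{water}
\approx 300.75$ mm, and `detection_model(pupil_matched = TRUE)` solves for
that value.  The package treats the pupil-matched configuration as the
ideal limit and the 300 mm lens as the as-built choice.

The as-built geometry deliberately breaks the 4f conditions (tube lens
about 100 mm from the objective, remote objective about 500 mm from the
beam splitter) to keep the S/P launch angle small; the S/P image
separation at the mirror is $\Delta L = f_{obj2}\,\theta$, 1.396 mm at the
8-degree working angle.  Only a few of the as-built gaps are documented
numbers (S1 = 6.695 mm, 45 um beyond the design focal plane); the rest
ship as 4f-nominal defaults flagged `estimated` in
`detection_model_preset()`.  Consequently the preset's magnification curve
(about 1.28-1.33 with a ~4% change over the 80-um scan) is qualitatively,
not digit-for-digit, comparable with the instrument's; the oracle-checked
properties (thin-lens equivalence, unimodularity, smooth monotone curve)
are what the tests pin down.  `choose_theta()` implements the stated
selection criterion -- the smallest grid angle whose mirror-plane image
separation clears a mirror-size floor, since the traced pupil footprint
grows monotonically with the angle -- and `calibrate_d1()` /
`calibrate_s1()` fit the undocumented gaps to measured magnification
curves by scalar least squares.

Collection efficiency uses a deliberately simple unfolded geometry: the
bundle converging to an off-axis remote image point fills the aperture
disc of radius $f_{obj2}\cdot NA$; unfolding the flat mirror displaced by
$\delta$ from the focal plane maps that disc to a scaled, shifted disc at
the aperture plane, and the efficiency is the fractional disc overlap
(closed-form circle intersection, cross-checked against a Monte-Carlo ray
fan).  The model is asymmetric in the displacement sign: outward
displacement loses rays monotonically, while inward displacement first
*shrinks* the returning footprint (efficiency recovers toward 1 before
degrading), which is a real feature of the geometry, not an artifact.

## Sub-pixel S/P registration

`scaled_crosscorr()` computes the mean-subtracted, variance-normalized
circular cross-correlation by FFT, so identical images peak at exactly 1
at zero lag; `find_offset_subpixel()` takes the integer argmax (ties
broken deterministically toward the smallest absolute lag) and refines
each axis with a second-order polynomial through the peak.  Conventions:
offsets are reported in array order ((row, col) or (z, y, x)), positive
when the second image is displaced toward increasing indices; the
convention is round-trip tested.  The fit window half-width defaults to 1
(a 3-point parabola): a quadratic is only locally valid at the peak, and
on sharply peaked surfaces (axial correlation peaks are about one voxel
wide) wider windows bias the fractional shift toward zero by amounts that
matter at the 0.05-0.2 voxel tolerances used here.  The window stays
configurable for broad, noisy surfaces.  `alignment_monitor()` replays the
interactive overlay procedure: per-frame offsets against a reference with
a convergence flag once the magnitude stays under a threshold for k
consecutive frames.

## Bead-based resolution characterization

`measure_fwhm()` fits amplitude, center, width and a constant baseline of
a Gaussian to a 1-d profile (Levenberg-Marquardt, moment-based starts) and
reports $2\sqrt{2\ln 2}\,\sigma$ in nm; non-convergent fits are flagged
and excluded rather than propagated.  The protocol mirrors the bead
measurements: lateral profiles are taken on a maximum-intensity projection
of 10 slices spaced 500 nm around the bead (`mode = "mip"`); because the
maximum of a separable Gaussian over an interior slab preserves the
lateral profile shape exactly, this introduces no width bias while
improving SNR.  The axial profile projects only a ~0.3-um lateral
neighbourhood, which keeps a neighbouring bead from leaking its own axial
profile into the measurement -- with 1-um windows this leakage was the
dominant failure mode on dense fields.  `detect_beads()` correlates the
stack's Z-MIP with the PSF model's Z-MIP (local normalized correlation),
keeps local maxima above a correlation threshold that are brighter than
the robust background by 5 sigma (configurable), and rejects outright
*every* member of any pair closer than the separation floor -- isolated
beads only, by construction.  The PSF model itself is parametric (a 3-d
Gaussian from per-axis FWHM) or any measured stack via `psf_model()`;
inverse PSF modeling from bead data is out of scope.

## Light-sheet dimension quantification

The light sheet translates in Y while scanning in Z, so bead coordinates
are first corrected to the sheet frame, $y' = y - a z$.  The tilt $a$ is
estimated by profiled least squares: the value minimizing the residual of
the beam-width fit in the corrected coordinate (a 1-d `optimize` with the
polynomial fit nested inside).  The width fit itself defaults to a full
quadratic in $y'$ fitted to the *squared* axial width, because the
Gaussian-beam profile $W(y') = W_0\sqrt{1 + (y'/y_R)^2}$ is exactly
quadratic in squared space -- the fit recovers waist and field of view
without approximation bias, whereas an even quartic on $W$ itself is
biased at the few-percent level over realistic sampling ranges (and
restricting to even terms wrongly pins the waist at the sampling center).
The direct polynomial fit remains available (`fit_space = "direct"`).
Gross width outliers (a contaminated profile can fit tens of times too
wide) are trimmed by robust residuals before the final fit.  The waist is
the fitted minimum -- refusing to extrapolate beyond the sampled $y'$
range -- and the FOV is the width over which the fitted width stays below
twice the waist; for an exact Gaussian beam that width is
$2\sqrt{3}\,y_R$, the closed form the tests compare against.
`crop_lightsheet_region()` applies the same geometry to raw stacks:
per-slice integer crop windows tracking the tilted waist line, with the
fractional remainder carried forward so the mean window center follows
the line exactly (a flat line yields one identical window).

## Magnification calibration

`absolute_magnification()` follows the line-target recipe: average over
the line direction, smooth with a centered 30-px running average
(reflected edges), find peaks with a prominence floor of 10% of the
profile's dynamic range, refine each to sub-pixel with a local parabola,
and convert the mean spacing $\Delta d$ into the sample-plane pixel size
(spacing$/\Delta d$) and magnification (camera pixel over sample pixel).
The peak finder is reliable when the line spacing is at least about twice
the smoothing window.  `relative_zoom()` estimates the isotropic scale of
the best similarity map between two images by maximizing the peak
cross-correlation of the center-cropped, rescaled image over a scale grid
(0.25% steps) followed by golden-section refinement; the grid matters
because periodic targets produce correlation ripples in scale that can
trap a pure line search.  `magnification_curve()` anchors the absolute
value at the reference position (defaulting to the scan center) and
propagates it by the zoom factors.

## Dual-color live-cell pipeline

`run_pipeline()` executes, deterministically: optional user crop ->
per-channel drift estimation against a reference time point (default the
first) -> correction by the channel-averaged shift -> inter-channel
registration (channels time-averaged first, single rigid shift applied to
channel 2) -> Richardson-Lucy deconvolution -> linear interpolation of
the scan axis to isotropic voxels -> background subtraction, zero
clamping, and division by the per-frame, per-channel 99.95% quantile
(pinning that quantile of the output at exactly 1, which also removes
photobleaching trends).  Drift per volume pair is estimated from the
three MIP-pair 2-d registrations, each axis averaged over the two
projections that observe it; degenerate (constant) projections fall back
to the remaining observer.  Shifts are applied by separable linear
interpolation with edge fill -- no Fourier wrap-around on clamped data.
The Richardson-Lucy update is the standard multiplicative form with FFT
(circular) convolution and a unit-sum PSF; the iteration count is not a
documented number, so the default is 20 with the per-iteration update
norm logged.  The background default is the intensity-histogram mode of
the first frame, config-overridable.  Dual-color field splitting is
handled at the crop stage; wavelength-dependent distortion beyond one
rigid shift is out of scope.

## Granule MSD analysis

Trajectories come from `link_detections()`, a greedy mutual-nearest-
neighbour linker with a displacement gate -- deliberately minimal plumbing
(no gap closing, merging or splitting) standing in for full cost-matrix
tracking, which external software provides.  `compute_msd()` is the
time-averaged 3-d MSD over all ordered pairs per lag, computed to 1/4 of
the track length.  The motion model is
$$\mathrm{MSD}(t) = 6 D t + v^2 t^2 + o,$$
the standard 3-d diffusion-plus-transport form with an offset absorbing
localization and tracking uncertainty; $D, v \ge 0$ are enforced by an
exact active-set least squares, the offset is unconstrained.  A
`strict_form` mode fits the variant in which the diffusive term shares
the quadratic power ($ (6D + v^2)t^2 + o$); the two parameters are then
not separately identifiable, and the mode exists only to demonstrate
that degeneracy.

Two estimator decisions matter.  First, the fit uses the leading 5 lags
by default (`max_fit_lags`): time-averaged MSD values at long lags are
strongly correlated and noise-dominated, and including them biases the
diffusion estimate low while adding variance.  Second, classification
(brownian vs directed) is a Hotelling $T^2$ test of zero mean
*single-step* displacement at level 0.05: steps are independent under the
model, so the test holds its nominal level, whereas a nested-model F-test
on the correlated MSD residuals is badly anticonservative; that F-test
remains only as a fallback for bare curves without step statistics, with
its level caveat documented.  The reported $D$ comes from the selected
model -- the pure-diffusion refit when classified brownian -- because the
non-negative $v^2 t^2$ term otherwise absorbs upward curvature noise and
systematically depresses $D$.  `summarize_population()` applies the
$D > 0.001\ \mu m^2/s$ floor before histograms, the empirical CDF, and
the between-condition fold change (ratio of mean $D$).

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their seed (the session RNG stream
is saved and restored).  Defaults match the characterized imaging
conditions: 104 nm lateral pixels, 500 nm axial steps, bead FWHM
(570, 666, 924) nm in (X, Y, Z), light-sheet waist 850 nm with
Rayleigh-like length 2.3 um and Y-per-Z tilt 0.14, granule imaging at 8.3
volumes/s for 80 volumes with 30 nm localization noise.  The noise model
is Poisson photons plus Gaussian read noise on a 100-count camera offset.
Beads are ideal Gaussians whose axial width follows the beam envelope at
their sheet coordinate; granule movies render a membrane-like shell plus
the granule signal into the second channel (real dual-label channels
share gross structure; with none, an inter-channel offset would be
unobservable), with accumulated linear drift and the configured offset.
The Rayleigh-like length is a free parameter rather than being derived
from an illumination NA.

What passing tests therefore show is that the *measurement chains recover
known ground truth under realistic sampling and shot noise*.  They do not
show robustness to everything real data adds: aberrated, depth-dependent
PSFs; structured background and autofluorescence; detection and linking
errors feeding the MSD analysis; polarization-dependent differences
between the S and P images beyond an intensity ratio; or magnification
distortion beyond an isotropic zoom.

## Problem sizes and numerical conventions

The tests and the acceptance analysis run deliberately modest problem
sizes chosen as representative rather than exhaustive: 20 beads for
resolution recovery (matching the reported measurement count), ~100 beads
for the light-sheet fit, 200-1000 tracks of 80 frames for the motion
analyses, 16-48 voxel movies for pipeline closure.  Axis order is
(Z, Y, X) with Z the scan axis and Y the sheet propagation axis; lengths
are mm inside the ray tracer and um at image/track interfaces; FWHM
values are nm.  Degenerate inputs error early and descriptively (constant
images in correlation, zero normalizers, borders peaks in the fit window,
extrapolated beam minima), rather than returning silently wrong numbers.
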