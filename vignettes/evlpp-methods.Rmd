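---
title: "Methods: single-particle analytics for EV-lipoprotein mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-particle analytics for EV-lipoprotein mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evlpp)
```

## Scope and rationale

Blood plasma and other biofluids contain extracellular vesicles (EVs,
bilayer-enclosed, roughly 50-200 nm) alongside a vast excess of
lipoprotein particles (LPPs: chylomicrons, VLDL, LDL, HDL), which overlap
with EVs in size, density and molecular makeup and can physically
associate with them. `evlpp` implements the computational side of four
orthogonal single-particle measurements used to characterize such
mixtures:

1. **Optical-trapping Rayleigh/Raman segmentation** - detecting individual
   trapping events as steps on the elastic-scatter trace and extracting
   one background-subtracted Raman spectrum per trapped particle;
2. **PCA of event spectra** - classing particles chemically and
   annotating loading peaks with lipid/protein band assignments;
3. **AFM spherical-cap morphometry** - converting adsorbed-particle cap
   measurements into contact angle and equivalent solution diameter and
   classifying particles as LDL-like or EV-like;
4. **Calibrated flow-cytometry quantification** - ERF/MESF calibration,
   time-based concentrations, density-window pooling, spike-in and
   detergent comparisons.

Because the original instruments and biological samples are not
reproducible at a desk, every stage is validated against a ground-truthed
synthetic-data generator whose population parameters are the published
single-particle statistics for these particle classes.

## The synthetic-data generator

### Component spectra and particle classes

Raman component spectra are sums of Gaussian band profiles parameterized
by center, full-width-at-half-maximum (default 16 cm^-1) and relative
amplitude, evaluated on a wavenumber grid (default 600-3100 cm^-1 at
2 cm^-1) and normalized to unit maximum. A Lorentzian line shape is
available via `shape = "lorentzian"`; the published spectra do not state a
line shape, and the analysis results depend only on band positions.
Cholesterol carries the anchored lines at 698 and 1438 cm^-1 plus the
high-frequency cluster 2850/2866/2888/2932 cm^-1; triglyceride
(1302, 1445, 1747 cm^-1), protein (1003, 1656 cm^-1) and phospholipid
(718, 1094 cm^-1) use literature-standard positions, all configurable.

Particle classes (`default_particle_classes()`) bundle a Raman
composition, a solution-diameter distribution (TEM statistics: LDL
25.3 +/- 3.4 nm, VLDL 63.5 +/- 24 nm, CM 148.2 +/- 91 nm; EV 50-200 nm), a
buoyant density (LPPs in/below the 1.06-1.10 g/cm^3 window, EVs around
1.14 g/cm^3), adsorbed-cap morphometry (LDL 17 +/- 3 nm at 71 +/- 8
degrees; EV 97 +/- 12 degrees over dispersed diameters), a Rayleigh step
height and a fluorescence yield. EVs are cholesterol- and protein-rich;
LDL is triglyceride-rich - the contrast that drives their PCA separation.

**The EV-LDL complex class.** Imaging of mixed preparations shows
complexes as an EV carrying a corona of several adsorbed LDL particles.
Since Raman signals of co-trapped structures add, the complex class's
composition is the additive combination of one EV with an LDL corona
whose summed weight is twice the EV contribution, i.e.
`(1*EV + 2*LDL)/3`. A plain 50:50 average places the complex marginally
on the EV side of the EV-LDL contrast axis after row-wise normalization
(normalization pulls a convex mixture toward the higher-variance parent
spectrum), which contradicts the observed placement of complexes on the
triglyceride (LDL-like) side with a separate second-component offset; the
corona-weighted composition reproduces that placement without touching
any analysis parameter.

### Trapping campaigns

`simulate_campaign()` emulates the acquisition protocol: 256 synchronous
Rayleigh/Raman spectra per 9.7 s cycle at 38 ms per spectrum, 100 cycles
per sample, a 1 s laser-blocked release between cycles. Arrivals are
Poisson per cycle; the first arrival occupies the trap and is held until
the deliberate cycle-end release (step-and-hold), so at most one particle
is trapped at a time, matching the dilution used experimentally to
prevent simultaneous trapping. Arrivals are placed from the second
spectrum onward - an arrival inside the very first 38 ms bin is not
resolvable as a step and would leave no pre-event baseline.

The published traces come with no step-height or noise statistics.
Defaults are class step heights of 8-14 a.u. over a baseline of 100 with
additive Gaussian noise of sd 1 - a trace signal-to-noise ratio of about
10, which is the regime the detection-accuracy guarantees are stated for.
A Poisson shot-noise mode is available for the Raman channel. Synthetic
campaigns at the full protocol size (256 x 100 x 21 = 537,600 spectra)
are exercised on a coarse wavenumber grid; analysis-grade simulations use
the fingerprint grid at 2-8 cm^-1 spacing and tens to hundreds of cycles,
which keeps the whole validation suite in seconds to minutes on one CPU.

### What the generator does not emulate

No optical physics (trap stiffness, polarizability, size-dependent
trapping efficiency), no cosmic rays or detector drift beyond white
noise, no multi-particle occupancy, no AFM raster images or tip
convolution, and no fluorescence spillover/compensation. Passing tests
therefore demonstrate the correctness of the computations under the
stated population models - not robustness to every instrumental artifact
of real acquisitions.

## Trace segmentation

The Rayleigh trace of a cycle is either the stored elastic channel or the
per-spectrum mean over an elastic-scatter wavenumber window. Step
detection uses a two-window mean-difference statistic at every boundary
(window 5 spectra, shrunk adaptively at the trace edges so early and late
steps remain localizable). Up-steps are local maxima of the statistic
above `max(min_step, k * sigma)` with `k = 5` and `sigma` the robust
noise scale of the differenced trace (median absolute deviation /
sqrt(2)); down-steps mirror this. An event runs from an up-step to the
next down-step or to the cycle end (truncated events are kept and
flagged, since cycles end with deliberate release). Candidate events
closer than 3 spectra are merged; events must exceed the threshold over
their preceding baseline and last at least `min_duration = 5` spectra -
the published analysis does not state a minimum duration, and 5 spectra
(190 ms) rejects single-spectrum glitches while costing under 2% of
uniformly arriving events.

The event spectrum is the mean Raman spectrum over the event minus the
mean over the nearest-in-time background: the last 20 pre-event baseline
spectra by default, falling back to post-release spectra when an event
starts the cycle. Subtraction is linear, so constant offsets cancel
exactly; on noise-free synthetic events the injected particle spectrum is
recovered to machine precision, and boundaries equal the ground truth.

## Spectral analysis

Spectra are analysed on the fingerprint region 600-1800 cm^-1 by default
(the high-frequency region 2800-3050 cm^-1 is analysable separately, as
in the supplementary treatment of the cholesterol CH-stretch lines).
Normalization is `"snv"` (row mean 0, sd 1) by default, with `"area"`
(unit trapezoidal integral) and `"none"` available; the source analysis
does not state its normalization, and SNV makes the separation statistics
invariant to global intensity scaling, which the suite asserts.

PCA is column-centred, unscaled, via singular value decomposition.
Loading signs are arbitrary; they are canonicalized so each loading's
largest-magnitude element is positive, and `orient_pca()` can flip
components so a named class's centroid is positive - the orientation used
when presenting the EV/LDL contrast with LDL on the positive first
component. Loading annotation reports local extrema with magnitude at
least 30% of the loading maximum and matches them to the nearest band
within 6 cm^-1 (three grid steps); both thresholds are package defaults,
stated nowhere in the source material. Cluster separation reports
pairwise centroid distances and silhouettes on the first two components
(matching the two-dimensional presentation convention) plus per-class
sign-quadrant occupancies; classification is nearest-centroid with a
softmin confidence and a lexicographic tie-break.

## AFM morphometry

An adsorbed particle is a spherical cap of height `h` and contact radius
`a`:

* contact angle `CA = 2 atan(h/a)` (degrees; `a = 0` is the free-sphere
  limit, 180 degrees);
* membrane area `A = pi (h^2 + a^2) + pi a^2` (curved cap plus adhered
  disc), giving the equivalent solution diameter
  `D_eq = sqrt(A/pi) = sqrt(h^2 + 2 a^2)`.

Area conservation - not volume - defines `D_eq`, reflecting the
near-inextensible lipid envelope of vesicles; it is applied uniformly to
LDL-like particles as well so that all particles share one coordinate
system, which is an acknowledged approximation for non-vesicular
particles. `forward_project()` is the exact inverse
(`a = D_eq / sqrt(2 + tan^2(CA/2))`, `h = a tan(CA/2)`); round trips are
exact to 1e-9 relative, which the generator relies on.

Classification uses a two-component responsibility model on
`(CA, log D_eq)`: Gaussian in CA, lognormal in `D_eq` (moment-matched),
class weights from the priors (equal by default), hard labels by maximum
responsibility, exact ties left unassigned, and an input `cluster_flag`
overriding to "cluster" - proximity flagging itself is an upstream image
analysis step and is accepted as a column, not computed. With the
published priors (71 +/- 8 degrees at 17 +/- 3 nm vs 97 +/- 12 degrees
over 30-130 nm) the populations are far apart in both coordinates and
per-class accuracy exceeds 0.99 at n = 10^4, so the recovered EV share of
an 86:14 field lands within one percentage point of 14%.

For broadly dispersed size populations truncated at zero (chylomicrons:
sd 91 nm against mean 148.2 nm), the naive sample mean is biased upward
by ~10 nm; `fit_truncnorm()` recovers the parent mean by maximum
likelihood of the zero-truncated normal, with an asymptotic standard
error from the Hessian.

## Flow-cytometry quantification

Calibration is ordinary least squares of `log10(assigned ERF/MESF)` on
`log10(median bead intensity)` (a unit-slope option exists); application
is `fl_erf = 10^(slope * log10(fl_au) + intercept)`, zero mapping to zero
by convention, with an inclusive threshold (default 100 ERF, the typical
trigger level for generic membrane staining of submicron particles).
Time-based concentration is `n / (flow_rate * time) * dilution` - the
protocol's 50 uL into 950 uL gives dilution 20; the instrument flow rate
is a required measured input, never a constant. Density windows (EV-rich
1.12-1.16, LPP-rich 1.06-1.10, total 1.06-1.16 g/cm^3) are inclusive on
both ends, with densities rounded to two decimals first because gradient
fractions are discrete; counts in the named windows plus "other" conserve
the total. Spike-in comparisons report per-window fold changes (zero
references flagged infinite) and differences; detergent sensitivity is
`100 (1 - post/pre)` per gate, clipped at zero with an anomaly flag, and
undefined for empty pre-gates. An event-rate check warns above a
configurable swarm-risk limit; no coincidence correction is attempted.

The synthetic event generator draws per-particle fluorescence as a
lognormal whose mean is proportional to particle surface area (a
membrane dye stains the envelope; default 0.04 ERF/nm^2, putting a
100 nm EV near 1,250 ERF and a 25 nm LDL near 80 ERF, i.e. mostly below a
100 ERF trigger), scatter increasing steeply with diameter, and density
from the class's truncated Gaussian. Instrument-scale intensities are
obtained by inverting the bead calibration so that re-applying the
calibration reproduces the truth - making the calibrated pipeline
self-consistent by construction, which the tests assert.

## Numerical and reproducibility choices

* All generators consume one integer seed; internal stages derive bounded
  substream seeds from it (multiplicative hash), so campaigns, AFM fields
  and FC tables are independently reproducible and bit-identical under a
  fixed seed.
* Truncated-Gaussian sampling is by rejection with a guard against
  essentially-empty truncation regions.
* Intervals are 1-based and closed, the native R convention, applied
  uniformly across detection, extraction and scoring.
* Degenerate inputs are defined, not accidental: zero-variance PCA input
  gives zero scores and ratios; all-zero rows fail normalization naming
  the row; empty morphometry tables give empty summaries; a trace shorter
  than the minimum duration yields an empty detection table.

## Known limitations

Segmentation assumes step-and-hold occupancy; overlapping or transient
multi-particle events are out of scope. Band annotation is nearest-match
within a fixed tolerance and does not deconvolve blended bands (the
cholesterol 1438 and triglyceride 1445 cm^-1 lines overlap at the default
width; the sign pattern is carried by the well-separated 698 and
1747 cm^-1 lines). Chemical quantification is relative throughout. The
morphometry classifier is a fixed two-component model, not a general
mixture fit; fields dominated by classes outside its priors require new
priors.
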