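---
title: "Multicontrast OCT analysis of the mouse retina: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicontrast OCT analysis of the mouse retina: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retoct)
```

## Scope

`retoct` implements a quantitative analysis pipeline for multicontrast
spectral-domain OCT of the rodent retina: volumes acquired with two
polarization detection channels (co- and cross-polarized) and repeated
B-scans at each slow-axis location. Three contrasts are derived from the
same raw data:

* **reflectivity** — layer segmentation and peripapillary thickness
  morphometry, plus hyper-reflective focus (HRF) screening;
* **motion (angiography)** — decorrelation between repeated B-scans,
  vessel binarization, vessel density and Weber contrast;
* **polarization** — per-voxel phase retardation and screening for
  depolarizing deposits outside the melanin-bearing anatomy.

A synthetic phantom generator produces dual-channel complex volumes with
complete ground truth, a cohort generator emulates thickness-versus-age
study tables, and a brightfield histomorphometry module counts
immunostained plaques per mm². Because no public OCT volumes exist for
this kind of acquisition, every algorithm is validated against the
phantom's ground truth.

## The reference acquisition

The protocol constants mirror a small-animal system: 83 kHz A-scan rate,
512 A-scans per B-scan, 5 repeats at each of 400 locations over a
1 mm × 1 mm field, 840 nm center wavelength, 1.5 ms flyback. Derived
quantities are pure functions:

```{r}
protocol_report()
```

The lateral resolution is modelled as the Gaussian 1/e² focal-spot
diameter `4·λ·f_eye/(π·d)` with the pupil beam diameter `d` given by the
refocusing telescope's demagnification. The refocusing diopter range is
*not* modelled: it would require the inter-lens spacings, which are not
part of the protocol description. Likewise no axial-resolution model is
attempted; the axial pixel pitch is a metadata field (default 2 µm).

## The phantom: what it emulates, and what it does not

`generate_phantom()` realises fully developed speckle as one independent
circular complex Gaussian per voxel, scaled by a piecewise-constant layer
reflectivity (RNFL bright, INL dim, a hyper-reflective OPL band, dark ONL,
a triangular melanin band at the RPE/choroid, dim sclera). Key modelling
decisions:

* **Static tissue is identical across repeats** up to a global per-B-scan
  phase and integer axial motion. This is the physical premise of
  decorrelation angiography, and it has a corollary that shapes two
  algorithms below: repeat averaging reduces detector noise but *cannot*
  reduce speckle.
* **Flow** is modelled as a per-repeat redraw of vessel voxels with
  probability equal to the vessel's decorrelation fraction — sufficient
  for a magnitude-of-complex-difference pipeline; no Doppler phase ramps.
* **Polarization**: preserving voxels put all amplitude in the co
  channel; melanin voxels draw a retardation angle δ uniform on [0°, 90°]
  and split amplitude as cos δ / sin δ with a fixed random cross-channel
  phase, so `arctan(A_cross/A_co)` recovers δ exactly. No birefringent
  retarders are modelled (the retina model needs only preserving versus
  depolarizing tissue).
* **No lateral point-spread correlation**: speckle is white. Real OCT
  speckle is correlated over the focal spot; algorithms that average
  laterally are therefore somewhat *better* on the phantom than on real
  data, and passing tests bound algorithmic correctness, not clinical
  performance.
* The ONH is a layerless depression with a depolarizing remnant column,
  so annulus masking, segmentation-validity flagging and the
  expected-depolarization cylinder are all exercised.

Default conditions: 5 × 100 × 128 × 256 voxels (desk scale; the full
5 × 400 × 512 × 1024 acquisition geometry is supported), retina 220 µm
thick (inner 130, outer 90), boundary undulation 8 µm, noise floor 0.04,
per-B-scan axial motion as an integer random walk (σ = 1 px), three HRF
in the outer nuclear layer, six radial superficial vessels
(decorrelation 1.0) and a deep capillary grid (decorrelation 0.5, the
condition under which the Weber-contrast ordering between plexuses is
defined). Vessel calibres (SVP radius 16 µm, DCP 15 µm) are set by the
desk-scale sampling: a vessel must span at least 3 pixels laterally to
survive a radius-1 morphological opening, which at 7.8–10 µm lateral
pitch means ≥ 24 µm diameter. At the full 512 × 400 sampling (≈ 2 µm
pitch) true capillary calibres satisfy the same constraint.

## Preprocessing

Axial bulk motion is estimated per B-scan by maximising the 1-D
cross-correlation of adjacent depth-intensity profiles and accumulating
the integer lags. The RPE/choroid surface is then detected from the
**cross-polarized** channel — melanin dominates it — as the
boxcar-smoothed amplitude peak per A-scan, restricted to the posterior
portion of the depth range (the hyaloid-remnant column near the ONH
would otherwise capture the peak), refined to sub-pixel precision by the
intensity-weighted centroid of the band above half maximum, and
regularised by a lateral median filter. Flattening rolls every A-scan by
an integer shift so the detected surface sits at a common target depth
(default 75% of the axial extent).

Only integer shifts are used, deliberately: sub-pixel interpolation would
mix neighbouring speckle realisations and alter the complex-difference
statistics that the angiography stage depends on. Complex values are
moved, never modified. A volume whose RPE cannot be detected (poor SNR,
no depolarizing band) raises a typed exclusion error rather than
degrading silently.

## Layer segmentation and thickness

On the repeat-averaged co-channel amplitude of the flattened volume:

* **ILM** — first depth exceeding a noise-adaptive threshold (mean + 4 SD
  of the anterior noise-floor region, zero-padding excluded);
* **posterior OPL** — the strongest, most posterior falling edge inside a
  fractional inner-retina window (default [0.30, 0.70] of the ILM→RPE
  span). The profile is smoothed laterally (5 × 5) first: the boundary is
  laterally smooth whereas speckle in bright foci or vessels is not, and
  without this step a bright HRF near the boundary can capture the edge;
* **posterior RPE** — the falling edge of the *combined*
  (polarization-independent) intensity, searched posterior to the
  cross-channel RPE peak. Inside the depolarizing band the co-channel
  amplitude alone is randomized by the polarization split, which makes a
  co-only edge unstable.

Boundaries are integer depths of the first voxel of the posterior side,
so inner + outer = total thickness holds exactly. Maps are 5 × 5
median-filtered; pixels violating ILM < OPL < RPE (e.g. the ONH) are
flagged invalid and filled by lateral interpolation, and a volume with
more than 30% invalid pixels raises an exclusion error.

Thickness metrics are means over the valid pixels of a peripapillary
annulus (inner/outer diameter 500/900 µm, physical coordinates, split
transversely into superior and inferior halves through the ONH centre;
the split orientation is configurable within ± 30°).

## Cohort statistics

For each of the nine metrics ({total, inner, outer} × {whole, superior,
inferior}), each group is first pretested by OLS regression of thickness
on age. If **both** groups show a significant age dependence
(p < 0.05) the groups are compared by analysis of covariance and the
reported p-value is the F-test of the age × group interaction — a
difference in thinning *trend*; the additive model's age-adjusted group
effect is also reported secondarily, since a covariance analysis could
defensibly test either. If either pretest fails, a one-way ANOVA on the
group means is used. The "both groups" rule reflects how the branch must
have operated in practice: a trend comparison is meaningful only when
both groups actually exhibit a trend. No multiple-testing correction is
applied across the nine metrics by default (a Bonferroni flag exists).

The cohort generator draws ages uniformly per group and builds each
compartment–half combination as `baseline − slope·age + noise`, with the
whole-annulus value the mean of the halves and totals the sum of
compartments, so the structural identity total = inner + outer holds by
construction. Defaults emulate the study conditions: 44 transgenic and
28 wild-type eyes aged 45–104 weeks, total thinning 0.37 and 0.26
µm/week, inner/outer slope split 0.35/0.65, residual SD 5 µm.

## Angiography

Per B-scan location, repeats are bulk-phase aligned (the global phase of
each adjacent pair is the argument of their complex inner product);
repeats whose normalised complex difference against the pixel-wise median
repeat exceeds 0.6 are excluded — the quantitative stand-in for manual
screening of uncorrectable motion. The decorrelation image is the mean
magnitude of complex differences between consecutive retained repeats.
Maximum-intensity en-face projections are taken over the SVP slab (ILM to
ILM + 20 µm) and DCP slab (posterior OPL − 15 µm to posterior OPL);
projection, equalization (CLAHE, 8 × 8 tiles), global Otsu threshold,
morphological opening and closing with a radius-1 disc, Zhang–Suen
skeletonization, and a 5-pixel square averaging filter whose positive
support is the final binary vessel map (equivalently, dilation of the
skeleton by a 5 × 5 square). Vessel density is the vessel-pixel
percentage in the whole/superior/inferior annulus; the modified Weber
contrast `(Iv − Ib)/Ib` is computed on the **raw** (pre-equalization)
en-face intensities, because equalization would distort the very
signal-to-background ratio the metric audits. The CLAHE clip limit uses
the equalization library's own convention (default 2).

## Polarization

Phase retardation is `δ = arctan(A_cross / A_co)` in degrees on
repeat-averaged amplitudes, masked below 6 × the noise floor — a
deliberately strict gate: static speckle survives repeat averaging, so at
a looser 3 × gate the dim tail of preserving tissue carries noise-driven
retardation well above 10°. The
printed formula in the source description assigns the cross amplitude to
the numerator's *co* label, which would give δ = 90° for
polarization-preserving tissue — contradicting its own physics text; the
implementation uses the physically consistent ratio and offers
`swap_channels` for the literal reading. High retardation is expected
only in the RPE/choroid complex and near the ONH; the expected mask
spans from `rpe_band_um + rpe_margin_um` (32 + 10 µm) above the detected
posterior RPE downwards, plus a cylinder of ONH radius + 75 µm. Both
margins are sized to exceed the boundary-detection uncertainty (which is
largest in the ring around the ONH) — with tighter margins, millimetre-
scale sheets of band-top melanin voxels leak past the mask wherever the
boundary estimate is a couple of pixels late. Candidates above 30° are
grouped by 26-connectivity and reported if ≥ 27 voxels. At desk-scale
sampling (voxel ≈ 156 µm³) that minimum corresponds to a ≈ 16 µm-radius
deposit; at full sampling (voxel ≈ 10 µm³) to the ≈ 10 µm scale of real
pigment clusters.

## Hyper-reflective foci

HRF are screened in the outer retina only (posterior OPL to posterior
RPE), exactly because bright vessels confound the plexiform layers. Since
static speckle survives repeat averaging, a raw "+6 dB over the per-depth
median" rule would sit near the Rayleigh 94th percentile and flood the
detector with speckle clusters; the amplitude is therefore boxcar-smoothed
along depth (5 px) first, which suppresses speckle without inflating the
lateral footprint of small foci. Components within size bounds
(8–4000 voxels) are refined to their half-level support — the linear
midpoint between the robust (median) component level and the local
background crosses at the true object edge under a symmetric kernel —
which keeps centroids and volumes unbiased (within ±15% on phantom
spheres). Components touching the RPE band are excluded, and an 8 µm
guard band below the posterior OPL avoids boundary speckle. The detected
slab therefore covers normalized outer-retina depths ≈ 0.1–0.6; deposits
abutting the RPE are intentionally out of reach of the automated
surrogate (they are indistinguishable from the band itself), and
externally supplied manual segmentations can be summarised with
`summarize_hrf()` instead.

## Histomorphometry

Brown immunoreaction product is segmented by an HSV window (hue 10–40°,
saturation > 0.2, value < 0.9 — defaults tuned on the synthetic
DAB-brown/eosin-pink palette), components ≥ 20 µm² inside the supplied
region mask are counted, and the load is count per mm². Touching
deposits merge into one particle — a documented property of
connected-component counting. The load-versus-age trend is an OLS fit
reporting slope, R², and the slope p-value. The cortex mask is always
supplied externally; no automatic cortex detection is attempted.

## Numerical choices and degenerate inputs

* All depths are 1-based voxel indices; voxel z is centred at
  `(z − 0.5) · pitch` µm, and a boundary at depth *b* µm has continuous
  coordinate `b/pitch + 0.5`.
* Flattening and motion correction use integer shifts with zero fill;
  energy outside the padded margins is conserved exactly.
* Constant images raise "no contrast" errors in binarization; empty
  annulus regions, all-zero B-scans, and melanin-free cross channels all
  raise typed errors rather than returning defaults.
* Determinism: every generator takes a seed and restores the caller's RNG
  state; identical seeds give bit-identical outputs.
* The volume container stores float64 NIfTI per channel (real/imaginary
  stacked on a fifth dimension) plus a JSON sidecar, making the
  read–write round trip bit-exact and the byte layout deterministic.

## Problem sizes used in the tests

The validation suite runs phantoms at 5 × 100 × 128 × 256 (the desk-scale
default) for end-to-end parameter recovery and false-positive screening,
smaller constructed volumes for exact-recovery and oracle tests, and
500/300-replicate simulations for the type-I error and slope-recovery
characteristics of the cohort statistics. These sizes were chosen so the
whole suite exercises every pipeline stage at full fidelity while staying
comfortably runnable on a laptop.

## Known limitations

* The phantom's white speckle and layer-homogeneous reflectivity make
  segmentation easier than in vivo data; the recovery rates reported by
  the tests are upper bounds.
* The automated HRF detector and deposit screener replace what was a
  manual expert procedure; their thresholds are validated only against
  phantoms.
* Lateral (x/y) motion between B-scans is not corrected, and
  birefringence (fibrous-tissue retardance) is neither simulated nor
  estimated — only preserving-versus-depolarizing contrast is modelled.
* The segmentation surrogate assumes the flattened geometry; it is not a
  general-purpose curved-retina segmenter.
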