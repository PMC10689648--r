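---
title: "Simulation and reconstruction methods behind wtpet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation and reconstruction methods behind wtpet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A walk-through total-body PET scanner replaces the conventional crystal
ring with two flat panels of monolithic, depth-of-interaction (DOI)
capable BGO detectors, 50 cm apart, between which the patient stands.
The open geometry buys throughput and cost (0.0224 m^3 of scintillator
and 1.40 m^2 of SiPM area, roughly half of what a 106 cm cylindrical
scanner of the Biograph Vision Quadra class uses) at the price of
missing projection angles along the panel normal. `wtpet` implements a
desk-scale Monte Carlo model of this scanner and of a Quadra-like
cylindrical comparator, a time-of-flight (TOF) list-mode MLEM
reconstruction, and the NEMA NU-2 performance metrics, so that the
published system characteristics of both designs can be recomputed end
to end on a laptop.

# Scanner models

Both geometries are idealized but dimensionally faithful:

* **Flat-panel scanner** (`buildFlatPanelScanner()`): two mirror-image
  panels at y = +-25 cm, each 14 x 20 monolithic BGO blocks of
  50 x 50 x 16 mm. Blocks tile the 70 cm width contiguously; along the
  scanner axis they are placed with a uniform pitch chosen so that the
  outer block edges span the stated 106 cm axial FOV, which leaves a
  3.16 mm inter-block gap (20 blocks of 50 mm cover only 100 cm). This
  placement matches the stated axial FOV and the extent of the axial
  sensitivity profile; note that it puts the central transverse plane
  (z = 0) inside a gap. The published "longest LOR through the centre"
  of 138.61 cm is not reproducible from any block placement consistent
  with the other printed dimensions (the box diagonal gives 136.5 cm);
  the package reports the geometric value and does not treat the
  printed one as a constraint.
* **Cylindrical scanner** (`buildCylindricalScanner()`): an idealized
  gapless ring of 3.2 x 3.2 x 20 mm LSO crystals, 82 cm front-face
  diameter, 322 rings over 106 cm (axial pitch 3.29 mm). Crystals per
  ring are `floor(pi * D / pitch)` = 782 with the tangential pitch
  defaulting to the axial pitch. No block or module gaps are modelled.

Digitizer parameters (energy resolution 15 %/11 % FWHM at 511 keV,
windows 434-645/455-645 keV, coincidence windows 5/4.7 ns, CTR 327/228
ps, dead time 370/320 ns) are carried on the scanner objects and are
the published values for the two systems.

# Photon transport

Decays are sampled uniformly inside each active primitive with weights
(activity concentration x overlap-corrected volume); acquisition
duration is tied to the decay count through the scene's total activity,
so count-rate-dependent effects (randoms, dead time) are physical.
Each decay emits an exactly back-to-back 511 keV photon pair with an
isotropic direction. Annihilation acollinearity is off by default (a
simplified half-Gaussian toggle exists) and positron range is not
modelled: the centre-row reconstructed resolution (~1.2 mm FWHM)
matches the reference values without them, indicating the reference
simulation used a back-to-back source.

Free paths follow the exponential attenuation law with
piecewise-constant coefficients along the ray (analytic primitive
intersections, painter's-order material resolution). At an interaction,
Compton scattering versus photoelectric absorption is chosen by the
energy-dependent branching fraction; Compton angles are drawn with
Kahn's rejection method for the Klein-Nishina distribution and the
scattered energy follows the Compton formula. Each material is anchored
by its incoherent and photoelectric linear attenuation at 511 keV
(XCOM-derived; coherent scattering is not modelled). Energy dependence
uses the total Klein-Nishina cross-section ratio for the incoherent
part and a power law `(511/E)^n` for the photoelectric part, with n = 3
for the low-Z materials and n = 2.5 for BGO/LSO (the XCOM slope for
Bi/Lu compounds over 150-511 keV). Photons falling below 300 keV are
terminated: both energy windows open at 434/455 keV and the blur sigma
near the window edge is ~30 keV, so such photons can never be accepted,
and dead time is modelled after windowing.

In the crystals, the interaction depth is drawn from the truncated
exponential along the in-crystal ray segments. A photoelectric
interaction deposits the remaining energy; a Compton interaction
deposits the transfer and the scattered photon is followed further, up
to three interactions, with sub-100 keV residuals absorbed locally
(their mean free path in BGO/LSO is below ~0.5 mm). Deposits are merged
into one single at their energy-weighted position — the behaviour of an
adder-plus-readout digitizer and of monolithic light-spread positioning
— but only within one readout region: the monolithic block for the
flat-panel scanner and the detector block (10 x 10 crystals, ~33 mm)
for the pixelated one. A chain that leaves the readout region is
truncated there; the escaping residual would form a separate,
sub-window single. The readout scope of the reference simulation is not
published; mini-block (16 mm) and module (~50 mm) scopes bracket the
published sensitivities by -12 %/+9 %, and the detector-block scope —
the standard energy-summing level of this detector family — reproduces
all three published sensitivity values within 3-5 %.

# Digitizer and coincidence processing

Deposited energies are blurred with a Gaussian of sigma
`resolution x 511/2.3548 x sqrt(E/511)` and windowed. Dead time is
non-paralyzable per monolithic block (flat panel) or per emulated
5 x 5 cm detector region (cylindrical), applied to the time-sorted
singles after windowing. Timestamps are blurred per single with
`sigma = CTR/(2.3548 sqrt(2))` so that the difference of two stamps has
the stated coincidence time resolution.

Pairing uses an event-driven open window: the first single opens one
coincidence time window, all singles inside form a cluster, and every
pair passing the geometric validity rule is emitted ("takeAllGoods").
Validity means opposite panels for the flat-panel scanner and a
tangential index separation of at least one sixth of the ring for the
cylindrical one (both configurable; neither is published). Coincidences
are classified purely from ground-truth tags carried through the chain:
different decay ids give a random, a phantom-Compton flag on either
single gives a scatter, otherwise a true. The maximum ring difference
cut (85 or none) applies to cylindrical events only.

The detector response positions the accepted endpoints after
classification, keeping the tags pristine: monolithic points are
smeared per block-local axis (sigma 0.55 mm in-plane, 0.85 mm along the
DOI axis, i.e. ~1.3 mm and ~2 mm FWHM detector resolution) with
per-coordinate clamping to the block surface, which avoids non-physical
LORs; pixelated points are moved to the crystal mid-depth plane and
randomized uniformly over the 3.2 x 3.2 mm face.

# Reconstruction

`mlemReconstruct()` is a standard TOF list-mode MLEM: exact
(Siddon-type) ray tracing through the voxel grid, a Gaussian TOF kernel
of sigma `c x CTR/(2 x 2.3548)` centred at the annihilation estimate
`-c dt/2` from the LOR midpoint (truncated at 3 sigma; <0.3 % of the
kernel mass, a large speedup), exactly the requested number of full
iterations, no subsets, no regularization, no post-filter, uniform
initialization on the sensitivity support. Reconstructions use true
coincidences only, as the reference study does, so scatter and random
corrections are out of scope. Attenuation is corrected by building the
sensitivity image with the analytic attenuation factor of the
ground-truth scene; the per-event attenuation then cancels inside each
event's update term.

The sensitivity image is the geometric coincidence acceptance of an
emission at each point: at every control point of a coarse lattice
(default 9 per axis) spanning the grid, a shared set of isotropic
directions (default 20 000) is tested for detection by a valid crystal
pair, weighted by the scene attenuation factor when requested, and the
control values are interpolated trilinearly onto the grid. The shared
direction set keeps neighbouring control estimates correlated, so the
interpolated image is smooth — essential, because MLEM divides by it.
Crystal stopping power is treated as direction-independent; it varies
slowly over any local grid. (Uniform sampling of crystal-face pairs,
the obvious alternative, is catastrophically inefficient for small
grids: almost no sampled LOR crosses a 3 cm box, and the resulting
voxel noise destroys the reconstruction.)

# NEMA metrics

* **Spatial resolution**: point sources (0.5 mm diameter, 15.28 MBq/ml)
  at the NEMA positions, reconstructed with 0.5 mm voxels and 10
  iterations on a local 64^3 grid centred on the source. Widths are
  measured on the NU-2 *summed response function* — the image summed
  over the two orthogonal axes within two line-cut FWHM of the peak —
  with linear interpolation at half and tenth maximum, a tail-estimated
  baseline (the warm-background pedestal) subtracted, and the peak
  located near the nominal source position. The line-cut alternative
  (`profileWidth(..., method = "cut")`) underestimates the widths of
  the limited-angle point spread.
* **Sensitivity**: the 1 MBq line source (70 or 106 cm) inside the five
  NU-2 aluminum sleeves; total sensitivity is accepted coincidences per
  decay x 1000 (cps/kBq), the axial profile bins each event's
  single-slice-rebinned mid-plane into slices of the cylindrical axial
  crystal pitch. Values are reported with all five sleeves, without the
  NU-2 zero-sleeve extrapolation, matching how the reference values are
  quoted.
* **Count rates / NECR**: the 70 cm line at 4.5 cm offset in the
  20.3 cm polyethylene cylinder, swept over activity concentrations;
  after the full chain and single-slice rebinning (central 65 cm,
  12 cm transaxial mask), `NECR = T^2/(T+S+R)`. Absolute NECR values
  are not reproduction targets: they depend on the unpublished dead-time
  scope and on system-bandwidth effects outside the model. The
  structural properties hold instead: the NECR column equals the
  defining formula exactly, randoms grow quadratically at low activity,
  and the flat-panel curve is non-monotone over the ladder once dead
  time is enabled.
* **Scatter fraction**: same phantom at the bottom of the activity
  ladder (0.045 kBq/ml), where randoms are below 1 % of trues;
  `SF = 100 S/(S+T)` from the ground-truth tags after rebinning. A
  NEMA profile-tail estimator is not implemented — the tags make it
  unnecessary.
* **Image quality**: the NEMA IQ body (modelled as a 30 x 22 cm
  elliptical water cylinder, 18 cm long; the lung insert is omitted)
  with six hot spheres (10-37 mm) at 4:1 over 5.3 kBq/cc, optionally
  two extra 10 mm surface lesions, reconstructed at 2 mm voxels with
  sensitivity and ground-truth attenuation correction. CRC uses
  sphere-sized circular ROIs in the sphere plane and twelve
  deterministic background ROIs placed away from the spheres and the
  body edge.

# The warm background and its consequences

The reference protocol reconstructs the NEMA point sources "in a warm
background" that is never quantified, and the iteration-10 FWHM of an
unregularized MLEM point is very sensitive to it — particularly along
the panel normal at the worst-case corner position, where the limited
projection angles leave the solution poorly constrained. The package's
desk-scale surrogate is a warm water cylinder of 15 mm radius and
30 mm length centred on the source — the largest cylinder that fits the
local reconstruction grid, so that all simulated activity lies inside
the reconstructed volume — at the default source-to-background
concentration ratio of 1000:1. Under this protocol the corner row of
the published resolution table is reproduced (panel-normal FWHM ~3.4 mm
vs 3.36 mm) while the centre row over-widens by ~15-20 % (1.4 mm vs
1.20 mm): the compact pedestal is relatively hotter at the centre than
the reference background evidently was. A cold acquisition reproduces
the centre row on all six numbers (FWHM 1.29/1.85/1.31, FWTM
3.05/4.20/3.07 vs 1.20/1.62/1.30 and 2.87/4.14/3.06) but converges to
2.3 mm at the corner. No single desk-scale background matches both
rows; the warm protocol is the package default for the NEMA table
because it is the stated procedure. Resolution measurements average the
reconstructions of three replicate acquisitions before measuring the
widths, which suppresses the speckle of a single short acquisition
without changing the expected point spread.

# Problem sizes and numerical choices

The shipped studies use desk-scale statistics: 10^6 decays for each
sensitivity value (Monte Carlo error ~0.5 %), 2 x 10^6 for the scatter
fraction, 3 x (4-7) x 10^6 for the resolution rows, 1.5-2 x 10^5 decays
per count-rate ladder point, and ~10^6 for the image-quality
reconstruction. Each study runs in seconds to a few minutes on one
core. Numerical conventions worth noting: half-open `[low, high)`
crystal boundaries (a boundary point belongs to the block whose lower
edge it is); all randomness flows through R's RNG so `set.seed()` (or
the `seed` field of a recipe) makes every run bit-reproducible, with
stages consuming the stream in a fixed order; ray tracing guards
grazing rays with relative epsilons; MLEM skips (and counts) events
whose LOR misses the grid and excludes zero-sensitivity voxels from
updates; attenuation factors are floored at 1e-6 with a warning.

# What the model does not capture

Full electromagnetic shower physics, Rayleigh scattering, inter-crystal
optical cross-talk, pile-up energy summation, positron range,
position-dependent monolith resolution near edges and the SiPM face
(the smearing sigmas are whole-detector averages), block/module gaps of
the cylindrical scanner, the patient bed (which is why the cylindrical
scatter fraction is not a reproduction target), system-level bandwidth
limits on count rates, and the lung insert of the IQ phantom. Passing
tests therefore demonstrate agreement with the reference simulation's
idealized conditions, not with measurements on physical scanners.
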