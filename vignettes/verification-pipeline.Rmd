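---
title: "Monte Carlo treatment verification with rtmc: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo treatment verification with rtmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtmc)
```

## The problem

Monte Carlo (MC) dose calculation is the reference standard for verifying
radiotherapy treatment plans: instead of an analytic dose kernel, individual
particle histories are transported through a voxelized model of the patient,
and the dose estimate converges as the number of histories grows.  The cost
is computational -- clinically useful uncertainties (a 2-sigma statistical
uncertainty of 2--4% in the target volume) require 10^8--10^9 histories --
so practical systems split a verification into many independent worker runs
(the *map* phase) and statistically combine their outputs (the *reduce*
phase).

`rtmc` implements that pipeline at desk scale.  Everything between the
clinical file formats and the statistics is real: DICOM RT plan parsing and
discretization, CT-to-phantom conversion, parametrized MC input binding,
worker distribution and seed management, binary/phase-space reduction with
uncertainty propagation, RTDOSE export, and DVH evaluation.  The one
deliberately simplified component is the transport engine itself (see
below): the package verifies the pipeline's statistics and plumbing, not
linac dosimetry.

## Plan discretization

Treatment plans arrive as DICOM RTPLAN control-point sequences.  The parser
carries machine state (gantry, collimator and table angles, isocenter, jaws,
MLC banks) forward across control points, because DICOM only stores changed
attributes.  A *deliverable segment* is defined as a maximal run of
consecutive control points joined by nonzero cumulative-meterset-weight
increments; zero-increment control points encode beam-off travel.  This
contract covers the three supported techniques:

* **Static**: one segment per beam, gantry fixed.
* **Step-and-shoot IMRT**: several segments per beam at a fixed gantry, the
  MLC changing only while the beam is off.
* **mArc (burst-mode arc)**: the gantry rotates continuously and the beam
  pulses on over short *arclets* -- in the bundled head-and-neck fixture,
  4-degree arclets whose central angles are 8 degrees apart.  Each arclet
  becomes a static beam at the arclet's central gantry angle (circular
  midpoint, so an arclet spanning 358--2 degrees maps to 0 degrees) carrying
  the arclet's monitor units (MU).

A segment's MU is `BeamMeterset x (cumulative weight at segment end - at
start)`.  The plan's `total_mu` is *defined* as the left-to-right sum of
segment MUs, and is cross-checked against the fraction-group metersets at
parse time (warning beyond 1e-6 relative).  With this definition MU
conservation under discretization is exact in floating point -- the
discretized beams carry the identical summands -- which is what the MU
conservation tests assert.  Deliveries in which the aperture moves while the
beam is on (sliding-window IMRT, conformal arcs) are rejected with an
explicit unsupported-technique error rather than silently approximated.

## CT to voxel phantom

CT slices are sorted by patient z, converted to Hounsfield units (HU)
through the DICOM rescale tags, and checked for uniform slice spacing (1%
tolerance).  Resampling happens *before* material conversion, on HU:
coarsening an axis takes a volume-weighted mean (each source voxel
contributes in proportion to the overlap volume), refining replicates the
nearest source voxel, per axis.  The order (average HU, then convert)
matters only through the nonlinearity of the conversion table; the
mass-conservation test bounds that effect at 0.5% on smooth volumes.

Material and density come from a user table: contiguous HU bins for
materials and piecewise-linear density breakpoints, clamped outside the
tabulated range; HU outside every bin is an error that names the offending
value.  A 4-material default (air / lung / soft tissue / bone, conventional
breakpoints) ships with the package (`default_hu_table()`,
`inst/extdata/hu_table_default.yaml`).

Two phantom file formats are written and read back: the standard `egsphant`
text layout (boundaries in cm, one character per voxel for the material map
-- media are renumbered 1..N, the format's single-character code space
allows 89 media) and a documented ASCII "PenVox" dialect (dims / spacing /
origin header, then one `material density` record per voxel, x-fastest)
that preserves original material indices exactly.  Round trips are exact
for materials and below 1e-6 relative for density.

## Map phase: parametrized models, distribution, seeds

An MC model is a directory of text input files plus a manifest declaring
*where* each tunable parameter lives: file, line, whitespace-token index,
parameter kind, and a printf format.  Binding a work item validates every
locator first and only then writes a copy of the template with the values
substituted in place -- every byte outside descriptor locations is
preserved, which the binding-purity test checks line by line.  MLC bank
parameters are vectors and replace tokens from their index to the end of
the line.

Beams are distributed over worker nodes in two modes.  `EQUAL` gives each
beam `floor(n_nodes / n_beams)` nodes, remainder to the earliest beams.
`MU_WEIGHTED` apportions nodes by largest remainder (Hamilton) on quotas
`n_nodes x mu_b / sum(mu)` with a floor of one node per beam; ties break to
the lowest index, and floor enforcement takes nodes from the largest
allocation (highest index on ties).  Tie-breaks are part of the documented
contract and are pinned by a brute-force oracle over random instances.
Histories are apportioned the same way (so the total is conserved exactly)
and divide evenly within a beam, remainder on its first node; in
`MU_WEIGHTED` mode histories follow MU so per-node workload stays balanced.

Seed pairs derive from the master seed by a bijective mixing (odd-multiplier
and xor-shift steps, both invertible on the 31-bit integers) of consecutive
counters.  Injectivity guarantees all seed values of a simulation are
pairwise distinct -- no state, no retry loop -- and the same master seed
always reproduces the same list.

Workers run as local forked processes in a sliding window of at most
`max_parallel`; outputs stream into the results directory in finish order.
The simulation object tracks the five-state machine (inactive, downloading
files, simulating, uploading results, finished), where the transfer states
correspond to staging files into and out of the results directory.  Any
nonzero worker exit fails the simulation fast (no retry policy) and keeps
partial outputs for diagnosis.

## Reduce phase: statistics

Independent runs with history counts $h_i$ are combined with weights
$w_i = h_i / \sum h$:

$$\bar d = \sum_i w_i d_i, \qquad
  \sigma = \sqrt{\textstyle\sum_i w_i^2 \sigma_i^2},$$

per voxel (and identically for column-format text tallies).  Stored
uncertainties are absolute 1-sigma throughout; the coverage factor $k$ is
applied only at reporting time (`region_uncertainty()`, which averages
$100\,k\,\sigma/d$ over masked voxels above 50% of the in-mask maximum dose
-- the region convention used for "uncertainty in the PTV" figures).
Binary dose files are an opaque header (copied verbatim from the first
input), the dose array, then the uncertainty array, single or double
precision little endian.  Phase-space files concatenate; their headers add.

The merge formula is pinned by a *ledger oracle*: the toy engine can dump
every history's per-voxel deposit, and an independent accumulation path
recomputes each worker's mean and history-by-history variance
$s^2 = (\sum d^2 - (\sum d)^2/n)/(n(n-1))$ from the raw ledger, then
propagates.  Merged dose agrees with the pooled-ledger mean to 1e-10
relative and merged sigma with the ledger-propagated sigma to 1e-6
relative.  One subtlety is worth recording: the propagated sigma and the
single-sample estimator applied to the pooled ledger are *different
estimators* of the same quantity -- they differ by terms of order
$\sqrt{K}/n$ (between-worker spread of means, Bessel factors) -- so exact
agreement between them is not a meaningful requirement; the package asserts
their consistency at the 1% level it can actually guarantee, and byte-level
fidelity against the ledger through the propagation formula.

## The toy dose engine

The bundled engine honors the same template contract as a production code
(histories/time/seeds in `engine.in`, geometry in `beam.in`) and writes
reducer-compatible outputs, but its physics is deliberately minimal: each
history samples a ray uniformly over the open jaw/MLC aperture from a point
source a source-axis distance (default 1000 mm) from the isocenter, rotated
by the gantry and table angles; the ray is traversed through the density
grid with a 3-D DDA, depositing $E\,(1 - e^{-\mu\rho L})$ per crossed voxel
with a single effective mass attenuation coefficient (default 0.05 cm^2/g,
a megavoltage-like value in water).  No scatter, no electron transport, no
spectrum.  Consequences to keep in mind:

* Central-axis depth dose is a pure attenuated exponential times the
  inverse-square fluence factor -- `analytic_depth_dose()` is its closed
  form and the convergence oracle.
* The statistics are *real*: per-voxel history-by-history variance, correct
  1/sqrt(N) scaling, genuinely independent workers.  Tests passing here
  validate the statistical pipeline, not dosimetric accuracy on real
  anatomy.
* The RNG is counter-based (a splitmix64 finalizer keyed on seed pair and
  history index), so outputs are bit-reproducible regardless of execution
  order or parallelism, which is what makes the whole-chain reproducibility
  test possible.

Voxels along one ray receive correlated deposits from the same history.
The split-invariance check (8 workers vs 1 at equal total histories)
therefore compares z-scores on a sparse lattice of beam columns -- one voxel
per column, every second column -- so the Kolmogorov-Smirnov test's
independence assumption approximately holds.

## Evaluation

Merged dose exports as DICOM RTDOSE with 32-bit unsigned pixels and
`DoseGridScaling = max(dose) / (2^32 - 1)` (configurable positive floor for
all-zero grids): quantization error is at most one scaling step per voxel,
negligible against MC noise (16-bit pixels would not be).  The reader
accepts both the full per-frame `GridFrameOffsetVector` and the two-element
uniform-offset shorthand.  Absolute-dose calibration (per-history dose to
Gy via delivered MU) is a single multiplicative constant left to the user.

Structures rasterize by voxel-center point-in-polygon with the even-odd
parity rule -- nested contours punch holes; no partial-volume weighting
(deterministic and oracle-checkable; partial volume is a noted extension).
Contours attach to the nearest grid slice within half a slice spacing, so
DVH grids should use a z spacing matching the contour planes.  Cumulative
DVHs use fixed-width bins (default 0.01 Gy): `volume_pct(d)` is the
percentage of masked voxels at or above `d`.  `Dxx` is read as the largest
bin edge still covering xx% of the volume (no interpolation, matching the
step-function definition); `V_x` interpolates linearly and clamps with a
flag outside the curve.  The DVH-derived mean dose agrees with the voxel
mean to within half a bin by construction.

## Fixtures and study conditions

The fixture generator emulates the three verification cases at toy
resolution: a head-and-neck mArc plan (45 arclets of 4 degrees, 8 degrees
apart, full circle), a step-and-shoot prostate plan (25 segments over 7
gantry incidences) and a lung SBRT plan (9 static conformal beams), on a
32x32x16 CT (4x4x5 mm voxels) of a water cylinder in air with a bone insert
(plus a low-density insert for the lung case) and a cylindrical PTV of
known analytic volume.  Geometry is synthetic by design -- cylinders, not
anthropomorphic anatomy -- so no test depends on realistic tissue
distributions.  All randomness (per-segment weights, total MU in 150--350)
flows through a private RNG stream seeded from the fixture spec, and DICOM
UIDs derive from the same seed, so a spec reproduces its files byte for
byte.

Problem sizes used by the test-suite and the acceptance script -- 16^3
water phantoms, 10^4--10^5 histories, 4--48 workers -- were chosen as the
smallest sizes at which the statistical assertions have comfortable margins
(e.g. the mArc end-to-end run reaches ~9% 2-sigma region uncertainty at
10^5 histories, against a 10% bound).

## Known limitations

* Only explicit-VR little-endian DICOM is read and written; the codec
  covers the RT tags this pipeline needs, not the full standard.
* No VMAT with continuously moving MLC; no electron or proton plans.
* The phase-space dialect is simplified (text header + packed records);
  real IAEA files with extra-long variables need an adapter.
* Worker execution is local fork-based; there is deliberately no
  provisioning, persistence or cost-model layer.
* Partial-volume rasterization and DVH interpolation beyond the documented
  conventions are extension points, not options.
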