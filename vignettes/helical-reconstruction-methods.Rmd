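---
title: "Methods: helical reconstruction, flexible fitting, and actomyosin state comparison at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: helical reconstruction, flexible fitting, and actomyosin state comparison at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`helicalem` implements, at sizes that run in minutes on one core, the
computational chain used to solve actin filaments decorated with myosin
motor domains by cryo-EM: synthetic specimen generation, iterative helical
real-space reconstruction (IHRSR) with gold-standard half-datasets and
helical-parameter search, Fourier-shell-correlation (FSC) resolution
estimation with B-factor sharpening, simplified multi-resolution flexible
fitting of atomic models into maps, and the quantitative comparison of
actomyosin conformational states. This vignette explains the models and
procedures, the parameters that matter, what the synthetic data do and do
not emulate, and the numerical choices behind the defaults.

## The helical model

A 1-start helical filament is described by two numbers: the axial **rise**
per subunit (Angstrom) and the azimuthal **twist** per subunit (degrees)
about the helix axis, which is the +z axis of every grid and model in this
package. Actin-like filaments have rise ~28.1 A and twist ~ -166.7 deg; the
negative sign records the left-handed 1-start genetic helix (clockwise
rotation per subunit viewed from +z). Twist angles are normalized to
(-180, 180]. The paper's own twist sign convention is not stated explicitly
anywhere in its text; this package's reading (negative = left-handed
1-start) reproduces the printed values without reinterpretation and is
recorded here as an assumption.

The symmetry operator for subunit k rotates by `k * twist` about z and
translates `k * rise` along z. Everything downstream — filament
construction, map symmetrization, symmetry restraints in fitting — uses
this single operator family.

## Synthetic specimens

`simulate_segments()` is first-class, tested code, not a fixture: it defines
the study conditions for every reconstruction experiment.

* **Subunit.** A pseudo-atomic protomer of ~8 Gaussian blobs (sigma 4-6 A)
  whose centroid sits ~12 A off-axis, plus (for decorated filaments) a
  motor-domain arm reaching ~45 A from the axis. The motor arm slants
  axially as it extends — the arrowhead pattern of myosin-decorated actin.
  This matters: with an axially symmetric decoration, projections are
  nearly polarity-ambiguous and at SNR 5 roughly a third of segments align
  with flipped polarity, which dilutes the recovered twist. The slant is a
  realism choice (decorated filaments are strongly polar), not a tuning
  knob.
* **Imaging model.** Filaments are projected analytically (each 3D Gaussian
  integrates to a 2D Gaussian) at random azimuth, out-of-plane angle
  uniform in [84, 96] deg (filaments lie near the ice plane), random
  in-plane angle, and Gaussian sub-pixel jitter (sd 1 A). The contrast
  transfer function (200 kV, Cs 2 mm, amplitude contrast 0.07, defocus
  drawn uniformly from 1.5-3.0 um underfocus) is applied by Fourier
  multiplication; white Gaussian noise is added to a target SNR defined as
  signal variance over noise variance within the filament support.
  Segments are windowed every `step` A (81 A by default, the 3-protomer
  windowing convention; note 3 x 28.06 = 84.2 A, so step is kept as an
  independent parameter and both are recorded).
* **Ground truth.** Each segment's orientation is stored relative to a
  one-box helical reference: moving one rise along the filament equals one
  twist of azimuth, so the axial position folds into the reference frame
  and the sub-rise remainder appears as an in-plane shift. Reprojecting the
  reference at the recorded truth reproduces each noise-free segment to
  correlation > 0.99 in the filament core.
* **Desk scale.** Default boxes are 40-64 px at 2.5-3.4 A/px — about 4-6
  protomers per box, versus ~23 in a 512-px box at 1.27 A/px. This is the
  single most consequential scale reduction (see "Recovery envelope").

What the generator does **not** emulate: beam-induced motion, ice
gradients, structural heterogeneity, dose-dependent damage, and the
non-independence of overlapping segments' noise. Passing tests therefore
show the machinery is correct and self-consistent, not that it would reach
any particular resolution on real micrographs.

## The reconstruction engine

`ihrsr()` runs the hybrid protocol: segments are split into two random
half-datasets (per-segment by default; per-filament behind a flag, since
overlapping segments make per-segment halves not strictly independent);
each half is aligned by exhaustive projection matching against its own
reference and reconstructed independently; the two asymmetric
reconstructions are summed; new helical parameters are searched on the sum;
the updated symmetry is applied to each half; the half-map FSC at the 0.143
criterion sets both the reported resolution and the low-pass filter of the
next round's references. After a configured round (the second, by default)
segments whose cross-correlation falls below `mean - 1.5 sd` of the raw CC
scores are excluded once. An optional polishing pass re-aligns the
recombined full dataset against a strictly 10 A-filtered reference with the
symmetry held fixed. CTF handling is phase flipping only.

Numerical choices that proved load-bearing:

* **View weighting in backprojection.** Filaments lying in the ice plane
  give single-tilt-axis geometry, so each segment is ramp-filtered along
  the in-plane direction perpendicular to its projected axis before
  real-space smearing. With *random* azimuths, uniform view weights
  systematically distort the reconstruction (clustered views are
  over-counted); views are therefore weighted by their azimuthal Voronoi
  gap (modulo 180 deg), capped at 4x the mean.
* **Half-operator symmetry search.** The search objective is the Pearson
  correlation, inside a cylindrical mask (80% of the half-box radius,
  central 60% of z), between the volume displaced by +1/2 and by -1/2 of
  the candidate screw operator. Using half-operators interpolates both
  fields with the same fractional voxel offsets; the naive
  volume-vs-moved-copy objective smooths only one side, which measurably
  attracts the rise to integer-voxel values. A coarse grid (0.1 A /
  0.25 deg) on a 2x-binned copy is refined by a joint Nelder-Mead simplex
  (rise and twist are correlated along a ridge; axis-alternating line
  searches stall on it), clamped to the requested bounds.
* **Search on a filtered sum.** Voxel-scale reconstruction noise biases the
  self-correlation optimum through the same interpolation-smoothing
  mechanism, so the parameter search runs on the sum low-passed at 0.4x
  the current rise (~11 A for actin) — coarse enough to kill voxel noise,
  fine enough to keep inter-subunit detail.
* **Initial reference filter.** The classic 35 A initial filter presumes
  650 A boxes whose long helical lever retains azimuthal contrast at 35 A.
  A 5-subunit desk-scale box retains almost none, and first-round
  alignments then scramble the twist; desk-scale runs use an 18 A initial
  filter instead. The 35 A default remains in `refinement_config()`.
* **Symmetrization** is a projection onto the helically symmetric subspace
  through the canonical asymmetric unit (each voxel folded into the
  central rise interval by the nearest integer operator, then averaged
  over mates, with a soft in-grid weight keeping the average continuous at
  grid edges). Re-symmetrization reproduces the output to trilinear
  interpolation accuracy — a few percent in max norm, correlation
  > 0.999. Exact idempotence is not attainable with trilinear resampling;
  tests assert it at interpolation accuracy.

### Recovery envelope

On noise-free data the loop's fixed point is the ground truth: aligning
segments against the true reference and searching the reconstruction
recovers (28.06 A, -166.73 deg) to within (0.01 A, 0.02 deg), and the
noise-free loop converges there from perturbed starts. At the study-like
noisy condition used in the tests (SNR 5, CTF, 300 segments of 48 px at
3.2 A/px, three iterations, start perturbed by +0.24 A / +0.53 deg) the
measured envelope across seeds is roughly +/-0.2 A in rise and +/-1 deg in
twist; the suite asserts a fixed-seed run at |rise error| < 0.2 A and
|twist error| < 0.6 deg. The dominant limit is the box length: twist
precision scales with the number of subunits a segment spans, and a
desk-scale box spans ~5.5 against the original ~23. High-SNR runs at the
same geometry recover to about +/-0.05 A / +/-0.15 deg.

## Resolution estimation and post-processing

FSC is the per-shell normalized complex correlation with one-Fourier-voxel
shells; resolution is the reciprocal of the first linearly interpolated
crossing below the threshold (0.143 by default), with a Nyquist-limited
flag when the curve never crosses. Sharpening scales amplitudes by
`exp(-B s^2 / 4)` (B = -150 A^2 is the typical value for a ~4.6 A map)
followed by a cosine-edge low-pass at the nominal resolution, so the
amplification peaks there. The local-resolution proxy for helical maps is
the cylindrical-mask series: identical soft cylinder masks (5-voxel cosine
edge, to avoid correlation inflation from hard edges) of decreasing radius
applied to both halves, one FSC resolution per radius — full filament,
motor-excluded, interface-only.

## Flexible fitting

`flexfit()` biases a model toward density with the energy
`-g * sum(w_i * rho(x_i))` over map-coupled atoms (trilinear density and
analytic gradient; atom weights are element masses) on top of a simplified
mechanics: harmonic bonds and angles from the starting topology, an
elastic network over all heavy atoms within 10 A (a Calpha-only network
leaves the side-chain torsions degenerate and was rejected), soft-core
repulsion excluding 1-2/1-3 pairs and rest-state contacts, and helical
symmetry restraints tying operator-mapped equivalent actin Calpha to their
group mean. Explicit solvent and electrostatics are intentionally absent:
the scientifically load-bearing choices — per-atom coupling regimes, fixed
ligands, symmetry restraints, the three-phase schedule — are all kept.

Coupling regimes are per-atom: FULL (all atoms feel the map — actin
residues with large side chains: Phe, Tyr, Trp, His, Arg, Gln, Lys, Met —
in the high-resolution variant), BACKBONE (N/CA/C/O only), DECOUPLED
(conformationally variable loops with no density: the bundled myosin VI
preset decouples loop 2, residues 622-636, and the HCM-loop tip, residues
397-405; the loop-2 range is also quoted as 621-642 elsewhere and the
preset uses the narrower figure-caption range), and FIXED (nucleotide and
ions, immobile). The LPF preset couples backbone only everywhere, matching
fitting into 7.5 A-filtered maps.

Schedules follow the canonical three phases — short minimization to relieve
clashes, stochastic dynamics at low map weight, long minimization at high
weight — with two desk-scale adaptations: minimization phases use chunked
L-BFGS-B on the mobile coordinates (damped steepest descent stalls in the
narrow valleys of this energy; the chunking preserves checkpoint logging
and the energy is asserted non-increasing per checkpoint), and phases may
carry a per-phase map low-pass, giving multi-resolution annealing (default
12 A, then 8 A, then full resolution) that funnels a far-off start into the
correct register before full-resolution refinement. A literal "250 ns" of
dynamics is meaningless in a simplified integrator; the dynamics phase is a
step count (400 by default).

The weighting factor g is selected by `select_weight()`: one fit per
candidate, then the best geometry score (clash count + bond/angle RMS
deviation against rest) among fits whose model-map correlation is within
2% of the best.

The recovery experiment behind the fitting tests perturbs a ~200-atom
synthetic chain by a *smooth* random deformation — small rigid rotation and
translation plus a low-frequency bend, rescaled to exactly 2.0 A RMSD — and
requires refitting into the map rasterized from the unperturbed model to
below 0.5 A median over ten seeds. Smoothness is the realistic displacement
class: starting models differ from their targets by conformational
changes, not by iid per-atom scrambling, which destroys local geometry no
real starting model lacks and leaves mirror-state traps no fitting
protocol claims to escape.

For low-resolution comparison, `backbone_average()` averages backbone
positions over symmetry-equivalent subunits or replicate models (optionally
after Calpha superposition) and truncates side chains beyond Cbeta.

## State comparison

Superposition is Kabsch (SVD with the determinant corrected to +1, so
mirror images never superpose to zero). Correspondence between models is
strictly by chain and author residue number; there is no sequence-alignment
fallback, because all compared models descend from common parents. On top
of that sit Calpha RMSD over named domain selections (U50: residues
180-206, 229-397, 405-441; L50: 467-597, 638-661; H-plug: 263-273; D-loop
default 40-50, configurable since only its anchor residues are named in
print; cleft loop in both quoted variants 670-681 and 670-684), unweighted
Calpha domain centroids and their displacements, per-residue deviation
profiles, displacement-vector fields (scaled by 1.5 for display, the raw
vectors kept alongside), and axis-angle decomposition of any superposition
rotation. Density maps of helical specimens are aligned over the
specimen's natural parameterization — azimuthal rotation, axial shift,
small in-plane offsets — by masked correlation, and the resulting
transform re-docks the corresponding models ("filament reference frame").
When maps are unavailable the filament frame falls back to superposition
on all shared actin Calpha.

Conservation is the identity fraction: for each ungapped reference column,
the fraction of alignment sequences (reference included) carrying the
reference residue, gaps counting as mismatches. The scoring function is
pluggable; identity was chosen because it is the simplest reproducible
reading of a printed "conservation" coloring. Scores land in the b-factor
column for structure coloring.

## Degenerate inputs and edge behavior

Flat volumes are rejected by the symmetry search and map alignment (no
unique optimum); a zero-variance background annulus is rejected by
normalization; an empty half-set or a half emptied by the exclusion cutoff
aborts refinement; collinear point sets are rejected by superposition and
by the subunit constructor; ties in projection matching resolve to the
lowest grid index, making alignment fully deterministic; atoms outside the
map are clamped with a warning during fitting.

## Problem sizes

The test suite runs entirely on synthetic data: reconstruction tests use
up to 300 segments of 48 px, fitting tests a 180-atom chain in a 64^3 map,
and the headline parameter-recovery experiment a 12-subunit filament in a
96^3 box at 2.5 A/px. These sizes were chosen so that each experiment
carries enough signal for its assertion while the full suite completes in
minutes.

## Known limitations

Twist precision at desk scale is box-length limited (above); the FSC of
the first refinement iteration is inflated by the shared initial
reference, as in any gold-standard scheme seeded from one model; the
simplified force field has no dihedral or electrostatic terms, so fitted
side-chain rotamers are only map- and sterics-driven; mmCIF, STAR and
compressed micrograph formats are out of scope; and the printed
actomyosin state-comparison numbers can only be reproduced when the
deposited coordinate sets are present locally — the comparison machinery
is fully implemented and tested on synthetic models either way.
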