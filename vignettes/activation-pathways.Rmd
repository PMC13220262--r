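---
title: "Coarse-grained activation pathways: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained activation pathways: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgpathway)
```

## What the package computes

Activation of a membrane receptor — the motivating case is a chemokine
GPCR switching from an antagonist-bound inactive conformation to a
G-protein-coupled active one — can be summarised as a one-dimensional
free-energy profile along a conformational progress coordinate. The profile's
local minima are metastable intermediates (`Int1`, `Int2`, ...), its local
maxima are transition states (`TS1`, `TS2`, ...), each transition state
carries an activation barrier relative to the preceding intermediate, and the
largest barrier marks the rate-limiting step. `cgpathway` builds that picture
from two endpoint structures:

1. **Coarse-graining** (`read_structure()`): each residue becomes a C-alpha
   bead plus a side-chain centroid bead (the unweighted mean of the resolved
   side-chain heavy atoms). Two beads per residue is the minimal resolution
   that still distinguishes a backbone hinge motion from a side-chain rotamer
   switch, which are exactly the two motion classes the perturbation tools
   probe. Ligand or sterol atoms can ride along as rigid hetero beads.
2. **Pathway generation** (`targeted_morph()`): a steered-relaxation
   surrogate for targeted molecular dynamics. A harmonic restraint on the
   RMSD to the target, whose center decreases linearly from the initial
   endpoint separation to zero, is added to the coarse-grained energy, and
   the structure performs steepest-descent moves at each restraint step.
3. **Scoring** (`evaluate_energy()`, `build_profile()`): each frame is scored
   with a transparent coarse-grained membrane energy function and reported
   relative to the first (inactive) frame.
4. **Analysis** (`find_stationary_points()`): discrete extrema with a
   prominence rule give the `Int`/`TS` decomposition, per-TS barriers and the
   rate-limiting step.
5. **Perturbation** (`ddg_scan()`, `set_sidechain_from_reference()`):
   alanine scanning and rotamer switches re-run the whole pipeline on
   perturbed endpoints and report per-TS barrier changes
   `ddG = dG_mutant - dG_wild_type`, with the standard sign convention:
   positive inhibits activation, negative facilitates it.

## The energy model and its assumptions

The published free-energy profiles this pipeline emulates were produced with
a coarse-grained membrane model whose parametrization is not publicly
printed. The analyses themselves — profile assembly, stationary-point
extraction, barrier differences — are defined over *any* conformational
energy function, so this package ships its own fully documented surrogate.
Every constant lives in `energy_params()`; nothing is hidden. The total is a
sum of five terms (kcal/mol):

* **Membrane burial.** Each residue contributes `h(res) * f(z)` where `h` is
  a per-residue transfer free energy and `f(z)` is 1 inside the membrane
  slab (`membrane_z_min`..`membrane_z_max` along z, default ±15 Å), decaying
  smoothly to 0 over 6 Å outside it (cubic smoothstep). The default `h` is
  the Wimley–White interface scale (water to phospholipid-interface transfer,
  negative = membrane-seeking). The membrane normal is assumed along +z of
  the input frame, i.e. structures are expected pre-oriented (OPM-style).
* **Screened electrostatics.** Formal charges at neutral pH (Asp/Glu −1,
  Lys/Arg +1, His 0) on side-chain centroids interact by
  `332.0637 q_i q_j / (eps(r) r)` with a distance-dependent dielectric
  `eps(r) = eps0 + slope * r` (defaults 4 + 1/Å).
* **8-6 contact term.** `contact_epsilon * ((R/r)^8 - 2 (R/r)^6)` between
  side-chain centroids: an attractive well that is non-positive for
  `r >= contact_radius` and a steep repulsive core below it. The default
  `contact_radius` of 5.0 Å was chosen so that the natural i, i±3/i±4
  centroid spacing of an ideal helix sits on the attractive shoulder rather
  than in the core.
* **Excluded volume.** Harmonic penalty `k (R_rep - r)^2` between C-alpha
  beads closer than `repulsion_radius` (4 Å).
* **Ligand interaction.** Electrostatic plus contact terms between rigid
  hetero beads and residue centroids; hetero beads never move, mirroring
  positional restraints on a bound ligand.

Pairs on the same chain closer than `min_seq_separation = 3` in residue
numbering are skipped (bonded geometry is not modelled); electrostatic and
contact terms are switched smoothly to zero over the last 2 Å before
`pair_cutoff` (12 Å), so the energy is continuous in all coordinates.

Assumptions worth stating plainly: protonation is fixed (no titration),
there are no explicit lipids or waters, and "free energy" here is the
potential of a single relaxed frame — no entropy estimator, no ensemble
averaging per intermediate. Whether the original study averaged over MD
ensembles per intermediate is not stated in its text; single-frame scoring is
the simpler, reproducible choice, and is documented as such.

## The morphing protocol

`morph_config()` defaults: 120 restraint steps, restraint constant
2000 kcal/mol/Å², 5 descent moves of at most 0.05 Å per bead per step. Those
values were chosen so that (i) the per-step relaxation budget
(`relax_iters * step_size`) comfortably exceeds the per-step schedule
decrement for toy-scale endpoint separations of a few Å, keeping the
restraint tracked tightly, and (ii) the progress coordinate of consecutive
frames advances in increments well below 1/29, so the default extraction of
30 uniformly spaced intermediates never has to collapse duplicate frames.
At the final step (restraint center 0) extra descent rounds with a
geometrically stiffened restraint close the residual gap; failure to reach
`convergence_tol` (0.05 Å) is a hard error carrying the achieved RMSD.

The morph never re-orients its inputs. A rigid re-fit of the target onto the
start would silently change every bead's membrane depth, which is meaningful
in a z-slab membrane model — so a shared coordinate frame is a precondition
(the run-layer can superpose endpoints once, on request, via
`run_config(align = TRUE)`, which is the pragmatic default for endpoint
files from different depositions). A warning fires when the direct
coordinate deviation between endpoints grossly exceeds their best-fit RMSD,
the classic symptom of un-superposed inputs.

The progress coordinate is `s = d0 / (d0 + d1)` with `d0`, `d1` the
best-fit C-alpha RMSDs of a frame to the two endpoints: dimensionless,
anchored at 0 and 1, and monotone along well-steered pathways. Noise
(`noise_sd`) is i.i.d. Gaussian on coordinates, seeded from a single master
seed, making every run bit-reproducible; with `noise_sd = 0` the morph is
deterministic regardless of seed.

## Stationary points, smoothing, and the prominence rule

`find_stationary_points()` works on the discrete series (the smoothed one if
`smooth_profile()` was applied): sign changes of finite differences give
candidate extrema, exact plateaus collapse to their midpoint, and the profile
endpoints are candidate minima. A maximum whose barrier over the preceding
minimum falls below `prominence_threshold` is merged away together with the
shallower of its two flanking minima, so minima and maxima strictly
alternate. The default threshold of 0.5 kcal/mol suppresses sampling jitter
while sitting well below the ~2.7 kcal/mol scale of the smallest barriers the
method is meant to resolve; both the threshold and the smoothing window are
exposed because the right setting depends on the noise level of the energy
backend. Barriers are always measured against the *preceding* minimum, ties
for the rate-limiting label go to the earliest transition state, and TS
positions are reported at sample resolution (no spline interpolation).

The smoothing/threshold defaults for noisy profiles were calibrated on the
analytic triple-well landscape: at 301 samples with 0.1 kcal/mol Gaussian
noise, a window-7 moving average plus the 0.5 kcal/mol threshold recovers
all three transition states with barrier errors under 0.3 kcal/mol in at
least 95 of 100 seeds (this calibration is re-run in the test suite and the
acceptance script).

## What the synthetic fixtures emulate — and what they do not

`make_toy_two_state()` builds an ideal two-helix hairpin (rise 1.5 Å/residue,
100°/residue, centroids displaced radially) whose active state differs by a
rigid hinge rotation of the second helix and a discrete flip of one
tryptophan "switch" centroid — the smallest system exhibiting both a
collective motion (TS1-like) and a local rotamer switch (W94-like). The
generator records exactly which residues move, so tests can assert the
bookkeeping rather than trust it. `analytic_landscape()` provides
closed-form Gaussian multi-well profiles whose stationary points come from a
dense-grid-plus-refinement oracle accurate to better than 1e-4 in `s`; the
default triple-well shape mirrors the three-barrier topology of the
motivating receptor system, with the first barrier rate-limiting.

Passing tests on these fixtures demonstrate that the machinery — morphing,
scoring, extraction, stationary-point logic, scan bookkeeping — is correct
and reproducible. They do not demonstrate that the surrogate energy function
reproduces any particular receptor's absolute barrier heights: the published
reference values for CXCR4 activation (for example a 12.46 kcal/mol
rate-limiting barrier) came from all-atom targeted MD plus an unpublished CG
parametrization, and no attempt is made to match them numerically. The
deliverable is the pipeline's logic, not a fitted force field.

## Numerical choices and degenerate inputs

* Energies are evaluated with vectorised pair matrices; an independent
  scalar double-loop oracle in the test suite pins the implementation to
  1e-9 relative agreement on random structures.
* Kabsch superposition uses base SVD with the determinant correction, so the
  rotation is always proper; fewer than 3 pairs or a collinear point set is
  a geometry error.
* Identical endpoints yield a single-frame pathway with a logged notice
  rather than an error; the progress coordinate is undefined (error) only
  when the *endpoints* coincide.
* Glycine (and residues with no resolved side-chain heavy atoms) carries no
  centroid bead: it is skipped by centroid-based terms, rejected as an
  alanine-scan site, and reported with a warning at read time.
* Mutating an alanine to alanine is a warning no-op; the ALA centroid is
  placed 1.52 Å (the C-beta distance) from the C-alpha along the original
  side-chain direction.
* Transition states of wild-type and mutant profiles are matched by rank
  order along `s`; count mismatches are flagged per row
  (`ts_count_match = FALSE`) and unmatched TS are reported as `NA`, never
  imputed.
* All randomness flows from one master seed; derived stream seeds stay below
  2^31.

## Problem sizes used in validation

The test suite and the acceptance script run on 40–60-residue toys, 100-seed
oracle sweeps, and 301-point landscape samples; a full profile run on the
default toy takes a few seconds and an alanine-scan site a few seconds more.
These sizes were chosen because every contract being checked (oracle
equivalence, restraint tracking, barrier recovery, planted-perturbation
recovery) is already fully exercised at this scale; nothing in the
implementation is specific to small systems, but wall-time grows roughly
with `n_steps * relax_iters * n_residues^2`.

## Known limitations

* The energy surrogate has no explicit lipids, water, polarizability, or
  grid-based membrane self-energy; absolute barrier heights are not
  comparable to published all-atom values.
* Single-frame scoring ignores conformational entropy along the pathway.
* The morph is a steepest-descent surrogate: no thermostat, no momentum, no
  replica exchange; pathways are representative, not Boltzmann-weighted.
* TS positions are reported at the resolution of the extracted frames.
* Chain selection is left to the user: which chains of a complex (G protein,
  agonist peptide) belong in the model is a modelling decision the tool does
  not guess.
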