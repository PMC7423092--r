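---
title: "Interpreting crystallographic density maps in electron units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting crystallographic density maps in electron units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edmapr)
```

## The problem

Sigma-scaled electron density maps distributed for x-ray crystallographic
PDB entries are expressed in arbitrary units: the zero-frequency structure
factor (F000) is omitted when the map is synthesized, so the map is
zero-meaned and its scale carries no physicochemical meaning, and the scale
differs between entries. That makes local model-vs-data discrepancies hard
to interpret — a difference-map blob has no natural size. `edmapr`
implements a method that derives, from the 2Fo-Fc map and the model alone,
a per-structure conversion factor from map units to electrons, and uses it
to express Fo-Fc discrepancies as absolute electron counts.

## The density-ratio chain

For every heavy atom $i$ of the 20 standard amino acids (hydrogens are not
resolvable; their electrons are folded into the bonded heavy atom), the
significant map voxels — value above $1.5\sigma$ of all voxels, $\sigma$
being the population standard deviation of the whole grid — whose centers
lie within a per-atom-type radius are collected, and the density ratio is

$$ r_i = \frac{\sum \rho_m}{Z_i \cdot q_i}, $$

with $Z_i$ the folded electron count and $q_i$ the occupancy (occupancy is
implemented as effective electrons so the raw density sum stays auditable;
for the ratio the two readings are equivalent). Atom clouds are aggregated
into residue clouds (at least 4 atoms) and chain clouds (at least 50
atoms), counting voxels shared between atoms once. The median chain ratio
$\mathrm{median}(r_c)$ is the structure's **conversion factor**.

Two corrections make the atom-level ratio comparable within and across
structures:

* **Volume normalization** — the all-or-none inclusion of voxels makes
  $r_i$ depend on how the atom happens to sit on the grid;
  $r_{i,\mathrm{norm}} = r_i \cdot \mathrm{median}(V_t)/V_i$ rescales each
  cloud to its type's median volume (in voxels, per structure).
* **B-factor correction** — thermal smearing spreads density beyond the
  fixed radius, and the chain deviation fraction
  $f_i = (r_{i,\mathrm{norm}} - \mathrm{median}(r_c))/\mathrm{median}(r_c)$
  falls approximately linearly with $\log b_i$. A per-type,
  per-structure slope $s_t$ (ordinary least squares of $f$ on $\log b$;
  types with fewer than three atoms take a shipped fallback table) is used
  to extrapolate every atom to a common B level:
  $f_{i,\mathrm{corr}} = f_i - (\log b_i - M)\, s_t$ and
  $r_{i,\mathrm{corr}} = f_{i,\mathrm{corr}}\,\mathrm{median}(r_c) +
  \mathrm{median}(r_c)$.

Two choices here deserve a note, because the verbal definition of the
correction admits several readings:

* *Sign.* With $s_t$ defined as the fitted slope of $f$ on $\log b$
  (negative in practice: hotter atoms capture less density), adding
  $(\log b_i - M)\,s_t$ would double the trend rather than remove it — we
  verified numerically that the spread of $f_\mathrm{corr}$ then exceeds
  the spread of $f$. The correction therefore subtracts the fitted trend,
  which is what makes the corrected distributions tighter.
* *Anchor $M$.* Anchoring each type to its own median $\log b$ makes the
  type's median $f_\mathrm{corr}$ track the B-factor sampling noise of
  that type's few atoms (a per-structure shift of order
  $|s_t| \cdot \mathrm{SE}(\mathrm{median}\,\log b_t)$ — for a type with
  ten or twenty atoms, comparable to the effect being corrected).
  `edmapr` anchors to the structure-wide median $\log b$, which cancels
  each type's own B draws to first order while removing the same trend;
  per-type medians then reflect the radii, not the B sampling.

All even-count medians are the mean of the middle pair, everywhere.

## Radius optimization

The per-type radii are free parameters. They are optimized exactly as the
method prescribes: evaluate the pooled per-type medians of
$f_\mathrm{corr}$ over a sample of structures; pick the type with the
largest |median|; scan candidate radii within ±0.3 Å of the incumbent in
0.01 Å steps (clamped to (0.3, 1.5) Å); adopt the radius whose |median| is
closest to zero; refit the slope tables; repeat until every |median| is
below 0.05. Ties in type selection break by a fixed alphabetical type
order; a type whose scan cannot improve its |median| by at least $10^{-4}$
is frozen for one round (anti-cycling); an iteration cap (100) guarantees
termination with a flagged best-effort result. During a scan the incumbent
per-structure slopes are held fixed and refit only on adoption, matching
the stated protocol ("at the end of each optimization").

The shipped `default_radii()` is the published optimized set (with the
published literature set as `default_radii("literature")`); both are
per-0.01 Å values for the 13 atom types (backbone types carry the `_bb`
suffix).

## The synthetic forward model

Everything above is testable offline against a generator
(`fixture_spec()`, `synth_structure()`, `synth_density_map()`,
`synth_difference_map()`) that emulates what the real inputs look like:

* **Structures** are extended-chain toy proteins with idealized bond
  lengths (geometry realism beyond interatomic distances does not enter
  the density math). The default entry has two 46-residue chains
  containing all twenty amino acids, with the residues carrying rare atom
  types repeated so each of the 13 types has at least ten atoms per entry
  (which also makes every per-structure slope fittable). A seeded Gaussian
  coordinate jitter (0.12 Å per coordinate) makes entries differ in
  geometry and grid alignment, not only in B-factors — without it, the
  voxel-shell discretization of every entry is synchronized and pooled
  medians jump coarsely with radius.
* **Density** is a sum of isotropic Gaussians: atom $i$ contributes
  $q_i Z_i (4\pi/B')^{3/2} \exp(-4\pi^2 d^2/B')$ with $B' = b_i +
  B_\mathrm{grid}$, which integrates to $q_i Z_i$ electrons. B-factors are
  log-normal (median 20 Å², log-sd 0.25 — a plausible within-structure
  spread for a mid-resolution entry); the grid-softening constant
  $B_\mathrm{grid} = 10$ Å² keeps even cold atoms several voxels wide at
  the 0.4 Å default spacing. The grid is scaled by an arbitrary factor
  $k$ and zero-meaned, reproducing the sigma-scaled map convention; values
  are snapped to 32-bit float so in-memory grids equal their CCP4 round
  trip.
* **Difference maps** are independent per-voxel Gaussian noise (0.02 e/Å³
  before scaling) plus injected signed Gaussian blobs of known integrated
  electron content; the truncated-Gaussian mass above any threshold is
  available in closed form (`blob_truncated_fraction()`) for oracle use.

What the generator does **not** emulate: Fourier-space synthesis and
resolution cutoff ripple, bulk solvent, correlated noise, anisotropic
displacement, alternate conformations, or real fold geometry. Passing
tests therefore demonstrate the correctness of the pipeline's arithmetic
and its self-consistency under the stated forward model — not performance
on real PDBe maps.

### Ground-truth radii for the generator

The forward model has no per-type radius, so "the radii used to render the
data" are only well-defined as the **self-consistent fixed point**: the
radii at which the per-type median corrected chain deviation fractions
vanish for maps drawn from the generator — precisely how the method itself
defines optimal radii. The shipped `synthetic_true_radii()` and the
fallback slope table were frozen from one seeded calibration
(`calibrate_synthetic_defaults()`: six 2-chain entries with the default
cassette repeated three times per chain, optimized from a uniform 0.8 Å
start to a pooled tolerance of 0.025 — tighter than the 0.05 analysis
criterion, and at the floor the 0.01 Å scan granularity permits). Single-entry consistency checks use the same
three-repeat entry size, because the fixed point shifts slightly with
chain length (chain-end atoms see fewer neighbors); at matched size the
worst per-type |median| on fresh seeds stays within the 0.05 criterion.

### What does the Eq-1 sum run over?

The ratio definition admits two readings: sum the *significant* voxels
(above 1.5σ) within the radius, or sum *all* voxels within the radius.
`edmapr` defaults to the unthresholded sum (`threshold_sum = FALSE`), and
the radius optimization is the reason. On a zero-meaned map the background
sits below zero, so an unthresholded sum penalizes an oversized radius;
with the significant-voxel restriction, inflating **all** radii at once is
nearly free — each atom captures a little more density, but the chain
ratios (and hence the conversion factor) grow along with it, and the
deviation fractions barely move. That leaves the uniform all-radii
direction of the optimization weakly identified: the response of a type's
median to a uniform shift of all radii is an order of magnitude weaker
than its response to its own radius. The
unthresholded sum improves the conditioning and follows the literal
procedure ("the sum of all densities within the corresponding radius");
the thresholded variant remains available as a switch.

Even unthresholded, a soft mode remains: the residual error of a radius
optimization along the uniform direction is bounded by the stopping
tolerance divided by the (small) common-mode sensitivity. Recovery
experiments that compare optimized radii against a known ground truth
therefore run the optimizer to an internal tolerance of 0.025 (the floor
the 0.01 Å scan granularity permits — convergence under the published
0.05 criterion follows a fortiori), and some perturbation draws still
drift along the soft mode by more than the per-type errors. This is an
identifiability property of the method itself, not of the synthetic data:
the conversion factor is defined relative to the same clouds it
normalizes, so only the *relative* radii are strongly determined. The
absolute level is inherited from the starting point of the optimization —
in the original protocol, from the literature radii.

## Numerical choices and degenerate inputs

* Voxel significance is defined about zero (the maps are zero-meaned by
  construction), 1.5σ for model maps and 3σ for difference maps; σ is
  recomputed from the data block, never taken from the header. The
  significance threshold always drives difference-map blob detection;
  whether it also restricts the Eq-1 cloud sums is the `threshold_sum`
  switch discussed above.
* A voxel belongs to the grid cell it indexes; its **center** is the
  reference point for every distance. Periodic wrapping applies along axes
  where the stored extent covers a full cell; otherwise out-of-extent
  candidates are skipped and the cloud is flagged partial and excluded
  from the statistics.
* Atoms with zero occupancy or non-positive B are excluded from the ratio
  statistics (the occupancy adjustment is undefined at 0) but kept for
  F000; empty clouds likewise carry no ratio but still contribute their
  electrons to residue/chain totals.
* Alternate locations keep the highest-occupancy conformer (ties: altloc
  letter order) with its stated occupancy.
* Blob connectivity is 26-neighbor by default (corner contact joins), with
  6-neighbor available; components are found by flood fill with periodic
  neighbor wrapping, and centroids are density-weighted with unwrapped
  coordinates so a blob crossing the boundary is not torn apart.
* F000 folds hydrogens into typed protein atoms and waters (10 electrons)
  and uses element-only counts for other hetero atoms; the estimate is
  reported but never used for the conversion factor, which is anchored by
  the chain median (the F000 route misses the bulk-solvent contribution).
* Natural logarithms throughout the B-factor correction; slopes are
  shipped alongside so the choice is self-consistent.
* OXT is typed as a carboxylate oxygen (`O_intermediate`) and included;
  protonation is the standard pH-7 assignment (Arg/Lys protonated,
  Asp/Glu deprotonated, His neutral with the ring proton on ND1), which
  fixes every folded electron count deterministically.

## Problem sizes used by the test suite

Unit tests run on small grids (up to $16^3$) and short chains; the
consistency and recovery checks use the default two-chain entries (92
residues, ~740 heavy atoms, ~1M voxels at 0.4 Å) and a three-repeat entry
(276 residues) for single-entry statistics; radius recovery optimizes a
20-entry default-size sample from a ±0.1 Å perturbed start. These sizes
were chosen so each statistic is estimated with enough atoms per type for
its tolerance while the whole suite stays desk-scale.

## Known limitations

* Atom typing covers the 20 standard amino acids; ligands, nucleic acids
  and ions enter only the F000 estimate.
* Radii are resolution-independent, as in the original optimization; the
  correlation between chain ratios and resolution suggests
  resolution-stratified radii as an extension.
* The conversion factor presumes a significant, reasonably ordered
  peptide component (at least one 50-atom chain).
* Partial-coverage maps are handled by flagging affected atoms rather
  than by symmetry-completing the density; for maps that cover less than
  a unit cell the affected border atoms simply drop out of the
  statistics.

## Reproducing the shipped calibration

```{r, eval = FALSE}
opt <- calibrate_synthetic_defaults()   # ~10 min on one core
opt$radii    # compare synthetic_true_radii()
opt$slopes   # compare default_slopes()
```
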