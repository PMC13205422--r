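---
title: "Mesh sieving and affinity switching: the methods behind gelmesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh sieving and affinity switching: the methods behind gelmesh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelmesh)
```

## The scientific problem

pH/temperature dual-responsive P(NIPAM-co-AAc) nanogels retain or release a
hydrophobic drug (ibuprofen, IBU) depending on two coupled mechanisms:

* **mesh steric sieving** — whether the hydrated polymer network's pore
  bottlenecks are wide enough for the drug to pass, and
* **affinity switching** — whether protonation-dependent polymer-drug
  hydrogen bonding anchors the drug to the carrier.

`gelmesh` implements the computational side of that analysis as a reusable,
tested pipeline: explicit cross-linked network construction, periodic pore
descriptors, trajectory statistics for the embedded drug, release-kinetics
fitting, and rank correlation of simulation descriptors with experimental
release. Because the underlying molecular-dynamics trajectories and raw
release measurements of such studies are rarely deposited, the package also
ships seeded synthetic-data generators with analytic ground truth for every
input class, so each stage is validated end to end without any download.

## Network construction

Chains are built at united-atom resolution: backbone carbons plus labelled
pendant heavy atoms per monomer (amide group for NIPAM, carboxyl for AAc).
This is deliberate — the downstream analyses need topology and geometry,
not force-field energetics, and force-field parametrization is out of scope.
Each chain has a configurable degree of polymerization (default 20) and AAc
count (0, 1, 3 or 4 units give the 0/5/15/20 mol% compositions), with AAc
positions drawn by a seeded uniform choice. Two limiting protonation models
represent the media: acidic (pH 2.75, all carboxyls -COOH) and basic
(pH 7.4, all -COO^-). The Henderson-Hasselbalch estimate
$100/(1+10^{pK_a-pH})$ with $pK_a = 4.75$ gives 0.99% deprotonation in the
acidic medium and 99.8% in the basic one, which is why two limiting states
are a reasonable approximation.

Packing emulates random rigid-body insertion with rejection: a cubic box
sized from total mass over density (default 0.8 g cm^-3), seeded random
rotations and translations, and a 2.0 Å minimum-image tolerance between
molecules. Cross-linking then runs the iterative distance-plus-template
scheme: the reaction cutoff ladder grows from 3.5 to 5.0 Å in 0.5 Å steps
with three searches per cutoff; candidate pairs must be reactive, unreacted,
intermolecular and within the cutoff; each endpoint's depth-1 bonded
neighbourhood must match its residue's pre-reaction template (all
neighbours unreacted, element multiset as configured); matched pairs bond
greedily by ascending distance, one reaction per site per cycle, ties broken
by lowest atom id. BIS-BIS and chain-chain pairings are forbidden by the
default templates (both configurable) — the chemistry cross-links chain
pendant sites through the bifunctional BIS bridge. Conversion counts *all*
flagged reactive sites (chain pendant plus both BIS vinyls) in the
denominator.

After every search the structure relaxes on a surrogate energy surface:
harmonic bonds at covalent-radii rest lengths plus a purely repulsive
soft-sphere term, minimized by steepest descent with a bounded per-step
displacement and a backtracking step so the energy never increases. Two
consequences are worth stating plainly. First, freshly formed long bonds
contract toward their rest length, which is what draws molecules together
between search cycles. Second, the relaxer is deterministic strain relief,
not thermal motion: it cannot recruit distant sites the way interleaved MD
equilibration does, so desk-scale builds typically terminate
ladder-exhausted well below the 80% conversion target. The report records
that outcome explicitly (`ladder_exhausted`), which the protocol's stopping
rule treats as valid; all downstream analyses are independent of the
terminal conversion. Unreacted BIS molecules are pruned after the loop.

## Pore descriptors

The box is discretized into a cubic lattice (default spacing 0.4 Å,
convergence-tested on phantoms below); each node stores the minimum-image
distance to the nearest atom van der Waals surface (Bondi radii by default,
configurable). Two descriptors follow:

* **MPD** (maximum pore diameter): twice the largest node value — the
  largest spherical probe that fits anywhere.
* **PLD** (pore limiting diameter): the largest probe diameter whose
  accessible nodes (value ≥ d/2) still contain a cluster that *winds
  around* a periodic dimension. Clusters are labelled by union-find
  connected components (the Hoshen-Kopelman construction) with face
  (6-neighbour) connectivity; a cluster percolates a dimension when it
  joins a wrap-adjacent node pair across that boundary while wrap bonds in
  that dimension are withheld from the labelling — that closes a loop
  crossing the boundary exactly once, i.e. an infinite pathway. Percolation
  across any one dimension suffices by default (configurable to all three).

The percolation threshold is always attained at a node value, so the search
is a discrete binary search over the sorted values and terminates exactly;
a brute-force downward sweep over all thresholds reproduces it on small
grids (a unit test). Probes are capped at the shortest box edge, and an
empty box returns the cap. Phantom generators with closed-form answers — a
cylindrical channel (PLD = MPD = 2r), a sealed cavity (PLD = 0, MPD = 2R),
and a simple-cubic sphere lattice (PLD = a√2 − 2r through face windows,
MPD = a√3 − 2r at cell centres) — recover their analytic values within one
grid spacing at the default resolution, and halving the spacing changes the
answers by less than the coarse spacing.

Steric accessibility compares PLD and MPD against the drug's
principal-axis extents X ≤ Y ≤ Z (for IBU the package carries
6.78/7.47/12.03 Å as constants; these derive from a quantum-chemical
electron-density surface that this package does not recompute). The three
qualitative scenarios overlap in the original narrative — a system can be
bottleneck-confined yet releasable from large local pockets — so the
package resolves them into four disjoint labels, applied in this order:
MPD > Z with PLD < Y is `bottleneck_with_free_pockets`, MPD > Z with
PLD ≥ Y is `free`, Y < MPD ≤ Z with PLD ≥ Y is `transition`, and everything
else is `bottleneck_limited`. This rule order is this package's own
resolution of the overlap and is deliberately conservative about calling a
system `free`.

Per-trajectory aggregation samples 20 frames uniformly (first and last
inclusive) from the final 10 ns by default and reports mean ± unbiased SD.

## Trajectory statistics

**Dissociated fraction.** For each drug molecule the minimum atom-atom
minimum-image distance to the polymer is averaged over the analysis window
(final 10 ns by default, frames weighted uniformly); a molecule is
dissociated when that average strictly exceeds 5 Å — a molecule sitting
exactly at the cutoff is retained. With N molecules every attainable value
is a multiple of 100/N, so the 50-molecule default reproduces the 2%
granularity of published values; the contact criterion is atomic minimum
distance, not centre of mass, because the notion being captured is loss of
short-range contact.

**Diffusion.** The centre-of-mass mean-squared displacement is averaged
over molecules and all sliding time origins (an FFT correlation identity
makes origin stride 1 affordable); the Einstein relation gives
D = slope/6, converted from Å²/ps to the conventional 10^-7 cm² s^-1
(1 Å²/ps = 10³ × 10^-7 cm²/s — this constant is defined once and
round-trip tested, since getting it wrong silently corrupts every D). Two
defaults matter: `max_lag` is one tenth of the trajectory span, the
customary cap that keeps every lag backed by many origins (at half the
span, the final-window slope of a 50-molecule, 10 ns ensemble has a
10-seed-mean sampling SD of ~6%, measured over 100 seeds — useless against
a 5% recovery check; at one tenth it is ~1.5% and unbiased); and the fit
window is the final 10% of lags, the late linear regime. A negative fitted
slope is reported as-is with a warning.

**Hydrogen bonds.** Geometric criteria: donor-acceptor distance ≤ 3.5 Å
and H-D···A angle ≤ 35°, both inclusive (a nanometre of numerical slack
keeps constructed boundary geometries countable). The angle convention is
the common reading of the 35° criterion — the angle at the donor between
the D→H and D→A vectors; the D-H···A ≥ 145° dialect can be expressed by
passing a different cutoff. When both partners of a pair can donate, each
donor direction counts once. Counts are categorized by the unordered
(donor-group, acceptor-group) pair: polymer-polymer bonds act as reversible
physical cross-links that regulate pore structure, polymer-drug bonds
anchor the drug.

**Radial density.** Drug-molecule COM distances to the polymer COM,
histogrammed per frame and averaged over the window; per-bin counts
conserve the number of molecules exactly each frame, and shell-volume
normalization (4πr²Δr) is an optional flag.

## Release kinetics and correlation

Cumulative release supports both the literal summation
Σ C_t · V / M · 100% and (default) the standard sample-withdrawal
correction that adds back drug removed in earlier 1 mL samples — published
procedures withdraw and replenish, while printed formulas often omit the
correction, so both modes are selectable and the mode is recorded.

Four kinetic models are fitted on fractional release (cumulative %/100,
with the loaded mass as M∞ — no M∞ re-estimation): zero order k₀t (linear
through the origin — which is why its R² can be negative, as published fits
of this form show), first order 1−e^(−k₁t), Higuchi k_H√t, and
Korsmeyer-Peppas k_KP·t^n. The power law is fitted by Levenberg-Marquardt
on the untransformed form, started from a log-log regression (the log-log
fit itself is available as a flag); all points are used unless the
classical 60%-release validity cap is requested. The release exponent
classifies transport: n < 0.5 Fickian diffusion, n = 0.5 the Higuchi
boundary, 0.5 < n ≤ 1 anomalous. Noiseless round trips recover generating
parameters to solver tolerance for all sixteen bundled parameter sets; the
generation grid for such sweeps stays below each system's 100% ceiling
(the bundled power-law parameters overshoot 100% beyond ~16 h for four
systems, where the generator clips and warns).

Release performance is summarized as the trapezoidal AUC of the mean
cumulative release over 1-24 h, with endpoints interpolated linearly when
not sampled (exact for piecewise-linear profiles). Before correlation,
every variable is centred within material (per polymer composition), which
removes composition baseline differences; centring is idempotent and leaves
exact zero group means. Association is then measured by Spearman rank
correlation — Pearson correlation of mid-ranks, ties averaged — with a
two-sided p-value from the t approximation on n−2 degrees of freedom (the
method is recorded in the result; an exact permutation p-value is available
for n ≤ 10). No multiple-testing correction is applied, matching the
exploratory reporting convention of the source analyses.

## What the synthetic generators emulate — and what they do not

Every generator is seed-deterministic and attaches machine-readable ground
truth; statistical generators expose the analytic variances their test
tolerances are computed from, so no tolerance in the suite is a magic
number.

* `gen_brownian`: independent Gaussian increments with per-step variance
  2·D·dt per dimension around a static polymer decoy — the exact
  discretization of isotropic diffusion, so the ensemble MSD slope is 6D
  by construction. Defaults mirror the study conditions (50 molecules,
  10 ns at 1 ps).
* `gen_dissociation_scenario`: molecules placed statically at
  cutoff ± margin; the margin → 0 case places them exactly at the cutoff
  (axis-aligned so the distance is exact in floating point) and documents
  the tie rule.
* `gen_release_curve`: replicate mean ± SD of a model curve with additive
  Gaussian noise, truncated to [0, 100]% with a warning.
* `gen_pore_phantom` and `gen_hbond_triplet`: geometry with closed-form
  descriptors, as above.

None of these emulate real polymer dynamics: no solvent, no chain
relaxation coupled to drug motion, no correlated noise between release
time points, no anomalous diffusion. Passing tests therefore demonstrate
that the *estimators* are correct and correctly calibrated on data obeying
their model assumptions — not that the models describe any particular real
system.

## Numerical choices and degenerate inputs

* Distance grids refuse spacings coarser than a quarter of the box edge;
  per-axis spacing is adjusted so the grid tiles the box periodically.
* The empty box returns PLD = MPD = the box-edge cap; a fully occupied box
  returns 0; an isolated cavity returns PLD = 0 with MPD > 0.
* Equality at classification boundaries: exactly 5 Å is retained (strict
  >); exactly 3.5 Å / 35° is a hydrogen bond (inclusive ≤); n = 0.5 gets
  its own boundary label.
* Cross-linking ties (equal pair distances) break by lowest atom id;
  identical seeds and inputs reproduce bond lists exactly.
* Relaxation caps per-step displacement (0.2 Å) and backtracks on any
  energy increase; a non-finite surrogate energy aborts with an error.
* Packing gives up after a configurable number of attempts (default 10^5)
  with a packing-infeasible error suggesting a lower density.
* Zero rank variance (a constant descriptor) is an error in the
  correlation, not a silent NA.

## Problem sizes used by the test suite

The suite exercises the full study scale where the statistic demands it
(50-molecule, 10 000-frame Brownian ensembles across 10 seeds for the
diffusion-recovery checks; all 16 bundled parameter sets for the kinetics
sweep) and reduced-scale builds elsewhere (2 chains of DP 10 with 8 BIS
for cross-linking properties; 12 Å phantom boxes at 0.4 Å spacing for pore
checks), sizes chosen so each property is tested at the smallest scale
that still distinguishes a correct implementation from a broken one.

## Known limitations

* The network builder produces a representative local cross-linked domain,
  not a whole nanogel particle, and without thermal motion its terminal
  conversion undershoots targets reachable with MD-interleaved protocols.
* Pore descriptors use the centre-accessible distance-transform
  convention; surface-accessible conventions would shift PLD/MPD by an
  amount comparable to the probe-atom radius convention difference.
* Only orthorhombic periodic boxes are supported.
* The Spearman p-value's t approximation is asymptotic; for n = 16 it is
  adequate for exploratory screening but not a substitute for exact
  inference.
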