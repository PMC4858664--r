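---
title: "Structure-corrected aggregation propensity over conformational ensembles"
author: "aggscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-corrected aggregation propensity over conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggscape)
```

## The problem

Many folded proteins are only kinetically protected against aggregation:
their sequences contain short hydrophobic, β-prone stretches
("hot spots") that would drive amyloid formation if they were exposed to
solvent.  In the native state such stretches are usually buried, flanked
by charged "gatekeeper" residues, or kept in well-formed β-structure.
Whether a given variant aggregates therefore depends on two separable
ingredients: the *intrinsic*, sequence-encoded propensity of each
residue, and the degree to which the native-state *dynamics* keeps the
dangerous residues protected on average.  A classic example is an
immunoglobulin-fold amyloidogenic protein whose stabilized point mutants
aggregate far more slowly although their sequences are nearly identical —
the difference lives in the average solvent protection of the hot spots
across the conformational ensemble.

`aggscape` implements this analysis as a reusable pipeline:

1. a per-residue **intrinsic aggregation profile** computed from sequence
   alone,
2. a **structurally corrected profile** that modulates the intrinsic
   score by per-conformation relative solvent exposure,
3. **ensemble averaging** of the corrected profiles and of their scalar
   totals over a multi-conformation ensemble (multi-MODEL PDB),
4. ensemble structure analytics — Kabsch–Sander β-bridges and per-strand
   β populations, backbone/χ1 dihedrals, AlphaBeta and β-content
   collective variables, weighted-histogram free-energy surfaces,
   Kabsch-superposition RMSF,
5. a **rational design stage** that selects candidate sites and scans all
   single substitutions, and
6. a **synthetic-data generator** that produces inputs with known ground
   truth so every stage can be validated end to end.

## The intrinsic profile

Each residue type carries four tabulated properties: Kyte–Doolittle
hydropathy, Chou–Fasman β-sheet and α-helix propensities, and net side
chain charge at pH 7.4 (His = +0.1).  Each scale (the charge enters as
its absolute value) is z-normalised over the 20-letter alphabet, and the
raw score of residue *i* is the linear combination

$$ r_i = w_{hyd}\,\tilde h(a_i) + w_\beta\,\tilde\beta(a_i)
       - w_\alpha\,\tilde\alpha(a_i) - w_{chg}\,\widetilde{|q|}(a_i), $$

with defaults $w = (1.0,\,0.4,\,0.2,\,0.8)$.  Raw scores are smoothed
with a centred 7-residue moving average (truncated and renormalised at
the termini), because aggregation is a property of contiguous stretches
rather than single residues.  A gatekeeper term then subtracts
$g \times (\text{number of D/E/K/R within } \pm r_g)$ from each residue
($g = 0.15$, $r_g = 3$): charged flanks disrupt the zipper interactions
that elongate aggregates, an effect not captured by the per-residue
charge term.  Note that with a 7-residue window the *centre* of a wide
hot spot lies beyond $r_g$ of its flanks, so gatekeepers lower the edges
and the regional mean rather than the peak value.

The **total score** of a profile is the arithmetic mean over residues.
Using the mean (not the sum) keeps totals comparable between sequences
of different lengths; for fixed-length variant comparisons the two only
differ by a constant factor.  Profile values above 1 mark
aggregation-prone regions, and `aggregation_prone_regions()` reports the
maximal runs above that threshold.

The weights, window, gatekeeper constants and threshold were chosen once
so that hydrophobic stretches planted in a polar background score above
+1 while the background stays well below it, and are all exposed through
`profile_params()`.  They are a documented re-parameterisation of the
familiar solubility-profile architecture, with the sign convention that
*higher means more aggregation-prone*; they are not fitted to any
external data set, so absolute values should only be compared within
analyses run with one parameter set.

## The structural correction

Burial protects.  For one conformation the corrected profile is

$$ c_i = e_i\,
   \frac{\sum_j K(d_{ij})\, r_j\, e_j}{\sum_j K(d_{ij})\, e_j}, $$

where $e_i \in [0,1]$ is the relative solvent exposure (residue SASA
divided by its Gly-X-Gly theoretical maximum, clamped), $K$ is a
Gaussian of width $\sigma_d = 5$ Å over Cα–Cα distances truncated at
8 Å, and $j$ runs over residues within the cutoff including $i$.  The
leading factor gates the score by the residue's own exposure (a fully
buried residue scores exactly 0); the ratio replaces the intrinsic value
by an exposure-weighted local average, so that a hot spot whose
neighbourhood is buried is also discounted.  Two limits anchor the
definition: with all $e_i = 1$ and $\sigma_d \to 0$ the corrected
profile equals the intrinsic one, and the corrected values can never
exceed the largest intrinsic magnitude in the neighbourhood (the ratio
is a convex combination scaled by $e_i \le 1$).  Note the bound is a
neighbourhood bound, not a per-residue one: a low-scoring residue
surrounded by a hot spot can be pulled up toward its neighbours.

SASA itself is computed with a Shrake–Rupley algorithm on a
deterministic golden-spiral lattice (default 192 points per atom,
probe 1.4 Å, Bondi-type radii C 1.70 / N 1.55 / O 1.52 / S 1.80 /
H 1.20 Å; hydrogens excluded by default since crystal structures lack
them).  Determinism was preferred over randomised lattices so that
identical inputs give byte-identical outputs; the price is that rotation
invariance is only approximate (at 960 points, per-residue areas move by
up to ~2 Å² under rigid rotation while the total moves by ~0.01%).

## Ensembles

An ensemble is an ordered set of conformations of one sequence with
normalized non-negative weights (uniform by default; externally computed
weights, e.g. from enhanced-sampling reweighting, can be supplied as a
one-per-line file).  The ensemble-average profile is the weighted
per-residue mean of the per-conformation corrected profiles, and because
the total is a mean over residues, the ensemble mean of the totals
equals the total of the ensemble-mean profile exactly.  The reported
uncertainty is the weighted standard deviation of the per-conformation
totals divided by $\sqrt{N}$; no autocorrelation correction is applied,
so for genuinely correlated trajectory frames it underestimates the
error.

## Structure analytics

**β-bridges.**  Backbone hydrogen bonds use the Kabsch–Sander
electrostatic criterion $E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} -
1/r_{OH} - 1/r_{CN})$ kcal/mol with a −0.5 kcal/mol cutoff; the amide
proton, absent from crystal structures, is reconstructed 1.0 Å from N
opposite the bisector of the C$_{i-1}$–N–Cα angle.  Antiparallel and
parallel bridges follow the standard two-H-bond patterns, residues with
at least one bridge carry the β indicator, and per-strand β populations
are weighted means of that indicator over conformations and strand
residues.  Residue-level β attribution uses bridges (which are defined
per residue pair) rather than the segment-based collective variables
(which are not attributable to single residues).

**Collective variables.**  The side-chain AlphaBeta CV is
$\sum_k \frac12[1+\cos(\chi_{1,k}-\chi_{1,k}^{ref})]$ over the
χ1-bearing hydrophobic residues (V, L, I, M, F, W, C); the backbone
variant uses all defined φ/ψ.  Reference angles default to the first
conformation of an ensemble.  The antiparallel (and parallel) β-content
CVs sum a rational switching function
$S(r) = (1-(r/r_0)^8)/(1-(r/r_0)^{12})$, $r_0 = 1$ Å, of the RMSD of
every pair of non-adjacent 3-residue segments (backbone N, Cα, C, O)
to an ideal two-strand template after optimal superposition.

The templates are built internally: a 3-residue strand at
$(\phi,\psi) = (-139^\circ, 135^\circ)$ paired with a rigid copy of
itself.  The pairing transform matters: a β-strand at these dihedrals is
a helix with ~171° twist per residue, so an arbitrarily optimized rigid
placement holds hydrogen-bond registry only at its anchor rungs and
drifts by >1 Å per residue away from them.  The transform is therefore
constrained to the *sheet dyad family* — a 180° rotation about an axis
perpendicular to the strand's two-residue repeat vector — which
propagates registry along strands of any length with only ~0.05 Å per
residue of residual drift, and its four free parameters were optimized
once against canonical H-bond geometry (N···O 2.95 Å, H···O 1.95 Å,
across-strand Cα–Cα 5.0 Å, no clashes) and frozen as package constants.
`build_hairpin()` reuses the same transform, screw-shifted so residue
$k$ of one strand pairs with residue $n+1-k$ of the other, which is why
an $n$-residue hairpin yields a complete ladder of $n-1$ antiparallel
bridges.  Absolute CV values depend on these internal templates and are
not comparable to numbers produced with other template conventions.

**Free-energy surfaces.**  CV samples are histogrammed on a homogeneous
grid with their weights, $F_k = -k_B T \ln p_k$ ($k_B = 0.0083145$
kJ/mol/K, default $T = 310$ K), shifted so the occupied minimum is zero;
empty bins are $+\infty$.  Marginalization sums probabilities over the
dropped axes and re-shifts, which reproduces a directly computed
lower-dimensional surface to numerical precision.  The surface is
invariant under uniform weight rescaling.

**RMSF.**  Conformations are superposed onto their weighted mean
(Kabsch rotation with reflection guard, iterated until the mean is
stable) and the per-residue Cα fluctuation is the weighted RMS deviation
from the converged mean.

## Rational design

Candidate sites are residues with intrinsic value > 1 *and* an absolute
difference > 0.2 between the two variants' ensemble-averaged corrected
profiles — residues that are both dangerous in sequence and differently
protected by dynamics.  At each site all 19 substitutions are scored by
re-running the *entire intrinsic pipeline* on the mutated sequence and
reporting Δtotal (mutant − reference); the corrected profiles enter only
site selection, because substitution changes the sequence but the
available structures belong to the reference protein.  Protective
rankings sort ascending in Δ, promoting ones descending, with a
deterministic tie-break (site index, then residue letter), so reports
are bit-reproducible.  Distribution summaries (median, quartiles,
5th/95th percentiles — whiskers of the usual box plot) use type-7
linear-interpolation quantiles, and are emitted both pooled over sites
and per site, since both views are informative and the choice is a
presentation matter.

## The synthetic benchmark

`make_sequence()` draws a polar background (S, T, N, Q, G), fills a
designated window from the hydrophobic set (V, I, L, F), and optionally
places charged gatekeepers at the window flanks.
`make_ensemble_pair()` builds an extended chain of that sequence,
perturbs all coordinates with Gaussian noise (default 0.3 Å), and packs
the chain's own terminal flanking segments around the hot spot — above,
below and on both sides — at a packing distance calibrated per
conformation by bisection until the mean relative exposure of the
hot-spot residues matches the variant's target (defaults 0.50 for the
exposed variant, 0.30 for the protected one; achieved values are
reported as ground truth and reachable targets span roughly 0.05–0.55
for the default geometry).  Burial is thus achieved *geometrically*, so
scoring a synthetic ensemble exercises the real SASA → exposure →
correction → averaging code path, not a shortcut.

The generator emulates the features the pipeline is sensitive to — a
localized hot spot, a controlled between-variant protection shift, and
conformational noise — and deliberately not the features it is not:
chains are backbone + Cβ only, occluder packing breaks covalent
continuity at two junctions, there are no side-chain rotamers, no
realistic turn ensembles, and no correlation structure between
conformations.  Passing the planted-protection benchmark therefore
demonstrates that the pipeline recovers exposure differences of the
stated size from geometry, not that its absolute scores are calibrated
against experimental aggregation rates.

## Numerical choices and problem sizes

* Smoothing windows must be odd and no longer than the sequence;
  termini use truncated renormalised windows.
* The switching function's removable singularity at $r = r_0$ evaluates
  to $n/m$; segments with coincident atoms are excluded.
* Exposure bisection runs on $h \in [4, 40]$ Å to a tolerance of 0.015
  in mean exposure (at most 18 iterations); unreachable targets raise an
  error that reports the achieved exposure.
* Quantiles are type 7; ranking ties break by site then residue.
* All randomness flows through explicit seeds; generator output is
  byte-identical across runs, and the end-to-end driver writes no
  timestamps so identical config + seed reproduces reports byte for
  byte.
* The validation suite runs the planted-protection benchmark at
  40 residues, 10–12 conformations per ensemble and 40 seeds per
  condition, and the free-energy recovery at 10,000 samples × 30 seeds —
  sizes at which the stochastic acceptance properties are stable while
  the whole suite completes on a laptop-class single core.

## Limitations

* The intrinsic scale combination is a transparent stand-in with the
  standard architecture, not a fit to solubility data; only relative
  comparisons under a fixed parameter set are meaningful.
* The structural correction treats exposure as the only protection
  mechanism; hydrogen-bond saturation of edge strands, for example, is
  visible to the β-population analytics but not to the score.
* Ensemble weights are taken as given; no reweighting of biased
  simulations is performed.
* Multi-chain complexes are out of scope; PDB reading keeps one chain
  (the first, by default).
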