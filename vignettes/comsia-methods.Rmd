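---
title: "Similarity-index fields, PLS and contour maps: the methods behind comsia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-index fields, PLS and contour maps: the methods behind comsia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

comsia implements grid-based 3D-QSAR in the CoMSIA tradition: molecular
similarity indices evaluated on a shared lattice, partial least squares
regression against activity, and coefficient contour maps for rational
design. This vignette explains the model, the parameters that matter, the
numerical conventions, and the design decisions taken where the method
leaves room — together with what the synthetic test bed does and does not
establish about real data.

## The model

All molecules of a series are assumed to share one alignment (either given
in the input SDF or produced by the package's MCS alignment). On a common
Cartesian lattice with spacing $s$, the similarity index of molecule $m$
for property $p$ at lattice point $q$ is a Gaussian-attenuated sum over
property-weighted sources:

$$A_{p,m}(q) \;=\; \sum_{i \in m} w_{p,i}\, e^{-\alpha\, r_{iq}^2},$$

where $r_{iq}$ is the distance from source $i$ to the point and $\alpha$
is the attenuation factor (default 0.3 per squared Angstrom). Five
properties are computed:

* **Steric (S)** — one source per atom, weight $r_\mathrm{vdW}^3$ (cube of
  the van der Waals radius, from a fixed Bondi-style element table shipped
  with the package so results do not depend on an external library
  version).
* **Electrostatic (E)** — weight = Gasteiger–Marsili partial charge
  (assigned through OpenBabel), signed.
* **Hydrophobic (H)** — weight = the atom's contribution in the package's
  fixed Wildman–Crippen-type atomic logP table, signed. The table assigns
  each atom one of ~25 coarse classes from its element and bonded
  environment; the molecular logP of the scheme is the sum of its atomic
  contributions by construction.
* **Hydrogen-bond donor (D)** and **acceptor (A)** — unit-weight
  *pseudoatoms* placed along idealized hydrogen-bond directions (below),
  one Gaussian each.

The fields are reported as raw similarity sums with an implicit +1 probe
for every property; no sign flip is applied. PLS is indifferent to an
overall sign (the coefficients absorb it), but the convention matters when
reading contour maps: a positive coefficient × std region means *more of
that field value there predicts higher activity*.

Because the kernel is smooth, there are no cutoffs, no singularities at
atom positions, and small alignment changes move field values
proportionally — the properties that historically motivated similarity
indices over probe-energy fields.

## Grid geometry

Atom coordinates are snapped to the lattice (`round(c / s) * s`, ties at
half-grid away from zero) before the extent is computed; per axis the grid
spans `[min − padding, max + padding]` of the snapped coordinates of *all*
molecules (training, test and prediction sets jointly), with
`ceiling(range / s) + 1` points so both padded extremes are lattice points.
Defaults: spacing 1 Å, padding 4 Å.

By default field distances are also measured from the snapped coordinates,
so every molecule is represented consistently on the lattice;
`field_config(snap = FALSE)` keeps raw coordinates for sensitivity
analysis. Snapping at 1 Å deliberately coarsens geometry — an O–H bond
(~0.96 Å) can become collinear with its heavy-atom neighbor after
snapping. The pseudoatom builders detect such degenerate neighborhoods and
fall back to a single perpendicular/anti-bond direction with a warning
(collected into `warnings.yaml` in pipeline runs); this is expected
behavior at coarse spacings, not data corruption.

Lattice points are enumerated x-fastest; the ordering is a pure labelling
convention (any consistent reordering permutes feature columns and leaves
every PLS statistic unchanged) and is fixed so that `grid_index` in column
metadata, coefficient maps and exported volumes agree.

## Hydrogen-bond pseudoatom geometry

Donor and acceptor capacity is modelled at the position a complementary
partner would occupy, not at the heavy atom:

* **Donors** (N–H, O–H, S–H by the default rules): one pseudoatom per
  polar hydrogen, on the heavy-atom→H ray at 1.9 Å from the heavy atom.
  `donor_placement = "beyond_h"` instead places it 1.9 Å beyond the
  hydrogen; the default follows the fixed-distance-from-heavy-atom
  convention and the alternative is provided because the two readings are
  both defensible.
* **Acceptors** (N/O, not positively charged, excluding pyrrole-type
  aromatic N–H, amide N and aromatic O by the default rules): pseudoatoms
  at 1.9 Å along idealized VSEPR lone-pair directions — two in-plane
  trigonal directions for a carbonyl-type sp2 oxygen, the in-plane
  anti-bisector for pyridine-type nitrogen, two tetrahedral directions for
  ether/hydroxyl-type sp3 oxygen, the anti-bond direction for sp3 nitrogen,
  and a single anti-bond direction for sp/other or degenerate geometry.

A pseudoatom closer than `clash_factor × r_vdW` (default 0.7) to any atom
other than its parent (and the parent's own hydrogens) is discarded as
sterically implausible. Donor and acceptor layers are kept separate and
both use weight +1, so the two never cancel numerically.

The default donor/acceptor classification is implemented as documented
graph rules (equivalent to the usual SMARTS set; the rules are printed in
`?annotate_atoms`); custom classifiers can be passed as functions. A
SMARTS-text override file is not supported because no installed R SMARTS
engine reports per-atom matches.

## Alignment

For unaligned input (SMILES), the package finds the maximum common
connected substructure of the set by backtracking search (strict element
and bond-order matching by default), takes the first molecule as template,
and rigidly superposes every molecule's core atoms onto the template core
by Kabsch rotation. 3D conformers are built with OpenBabel's structure
generator at its deterministic level ("fast": rule-based placement plus
force-field minimization). The stochastic rotor-search levels are *not*
used, because reproducibility of a QSAR model from identical inputs is
worth more here than a marginally lower conformer energy. No constrained
re-minimization is performed after superposition: an unconstrained
minimizer would undo the alignment, and a coordinate-constrained embedder
is not available in this toolchain. The per-molecule residual core RMSD is
reported so poor core fits are visible rather than silent.

The MCS search is exponential in the worst case and intended for the small
congeneric series this workflow targets (tens of heavy atoms); pre-aligned
SDF input bypasses it entirely.

## Preprocessing: filtering, block scaling, centering

Training and prediction tensors are stacked before any statistic is
computed, so all rows share one descriptor space. Column filtering (off by
default) drops grid points whose value *range* across molecules falls
below a threshold.

Scaling is per **field block**: one mean and one population variance,
pooled over all of a field's columns and all molecules, scale the whole
block. This equalizes the gross magnitude of the five fields (steric sums
of $r^3$ versus partial charges differ by orders of magnitude) while
preserving the spatial contrast *within* a field — per-column
autoscaling, available as `per_column = TRUE` for comparison, would give
every grid point identical variance and flatten the maps. The per-column
standard deviation of the scaled data is stored; it is the $s_j$ used by
contour maps and field contributions.

The feature matrix is then mean-centered with **training-row** column
means, and activities centered by the **training** mean, which is retained
to express predictions in original units. Test rows never influence the
centering.

## PLS, cross-validation and the reported statistics

The regression engine is single-response PLS (NIPALS), fitted in the
centered, block-scaled column space. Statistics follow the conventions of
classic CoMSIA reports:

* $PRESS(k) = \sum_i (y_i - \hat y_{(-i)})^2$ from leave-one-out
  cross-validation with $k$ components;
* $q^2(k) = 1 - PRESS(k)/\sum_i (y_i - \bar y)^2$;
* $S_{PRESS}(k) = \sqrt{PRESS(k)/(n - k - 1)}$, and analogously
  $S = \sqrt{SSE/(n - k - 1)}$ for the fitted model;
* the component count is the $q^2$ argmax, ties broken toward fewer
  components;
* $r^2_{pred} = 1 - \sum (y - \hat y)^2 / \sum (y - \bar y_{train})^2$ on
  the test set — the predictive-$r^2$ convention that benchmarks against
  the training-mean predictor;
* field contribution of field $f$:
  $\sum_{j \in f} |b_j s_j| \,/\, \sum_j |b_j s_j|$.

Centering and scaling statistics are *not* refit inside LOOCV folds: the
preprocessing is performed once, then cross-validated, which mirrors the
usual CoMSIA workflow; `loocv(refit_center = TRUE)` provides the strict
variant for comparison. The implementation is verified in the test suite
against two independent routes — a Krylov-subspace closed form of PLS
(per-fold, to 1e-10) and the mixOmics PLS implementation (full fit).

With mean-centered $y$ and centered columns, training residuals sum to
zero analytically; the "0.00" residual means in conventional result tables
are a property of the estimator, not an empirical finding.

## Contour maps

Each kept column's $b_j s_j$ is scattered back to its lattice point
(filtered columns contribute 0), one map per field. Thresholds are
percentile-based on the **nonzero** map values — the structural zeros of
dropped columns and empty space would otherwise drag both quantiles to
zero — with the default 0.05 per tail (the "top 5%" convention, read as
5% per tail; the fraction is configurable). Isosurfaces are extracted by
marching tetrahedra (each cell split into six tetrahedra, crossings
linearly interpolated along edges) — operationally equivalent to marching
cubes and free of that algorithm's ambiguous cases — and exported as OBJ
and/or legacy VTK polydata meshes in Angstrom coordinates, with Gaussian
cube export for volumes. The sphere-recovery test (half-max level set of
$e^{-\alpha r^2}$ has radius $\sqrt{\ln 2/\alpha}$) pins the geometry to
its closed form within one grid spacing.

## The synthetic fixture generator

`generate_fixture()` builds a deterministic congeneric series entirely in
code: a benzene scaffold in exact geometry, substituents (H, CH3, OH, NH2,
F, Cl, OCH3) attached at idealized bond lengths and angles, varied at a
small set of ring positions (default: the two para positions, as in a
classic para-disubstituted series). Keeping the variable sites few keeps
the series' latent dimensionality well below the training size; letting
all six positions vary independently produces a series no n≈20 QSAR model
could learn, which is a statement about the design, not the method.
Activities are

$$y = 6 + \mathrm{signal} + \mathcal N(0, \sigma),$$

where the signal is a fixed one-signed linear combination of the three
highest-variance columns of one chosen field (default: electrostatic),
standardized to unit spread over the training rows. One-signed
coefficients make the signal the dominant variance direction of that field
at the variable site, recoverable with few latent variables. The
electrostatic default reflects both identifiability (the steric field's
informative columns carry little scaled variance after block scaling, so a
steric truth is systematically under-attributed by the $|b_j s_j|$
convention — an intrinsic property of that convention worth knowing when
reading real contribution tables) and the empirical pattern of classic
steroid-benchmark analyses, where electrostatics dominates the
contributions.

What the fixture emulates: a rigid, perfectly aligned series with smooth
field differences localized at substitution sites and activities linear in
one field. What it does not: conformational flexibility, alignment error,
tautomers/protonation states, activity cliffs, nonlinear
structure–activity relations, experimental heteroscedasticity. Green
tests on the fixture therefore certify the *machinery* — geometry,
scaling, cross-validation bookkeeping, attribution — not predictive
performance on real chemistry.

Default study conditions used by the tests and the acceptance script: 21
training + 10 test molecules (mirroring the classic steroid benchmark
split), noise sd 0.1 activity-log units, spacing 1 Å, padding 4 Å, α=0.3;
smaller problem sizes (n = 8–20, spacing 1.5 Å) are used for the
brute-force oracle comparisons and the 50–200-replicate noise controls,
chosen so each such check completes in seconds.

## Numerical conventions

* Snapping rounds half away from zero (documented, tested); base R's
  banker's rounding is deliberately not used.
* Population variance (n) for field scaling; sample variance (n − 1) for
  reported activity summaries, matching how benchmark tables print
  activity statistics.
* Quantiles are linear-interpolation (R type 7).
* PLS stops early (with a warning) when the residual covariance collapses,
  so requesting components beyond the effective rank truncates rather than
  fabricates.
* Tie-breaks: component selection prefers fewer components; MCS search
  explores atoms in index order, making results deterministic.
* All randomness (fixture substituent sampling, activity noise) flows from
  a single integer seed; identical config + seed reproduces every artifact
  byte for byte.

## Reproducing published steroid-benchmark statistics

The canonical external validation of any CoMSIA implementation is the
corticosteroid-binding-globulin steroid set (Coats' compilation): 21
training and 10 test steroids whose pKi activities ship with this package
(`steroid_activities()`; train mean 6.15, SD 1.17; test mean 6.89, SD
0.65). The pre-aligned 3D structures are distributed with the original
benchmarking literature and are not redistributed here; reproducing the
full model requires downloading them.

With those structures saved as `steroids_train.sdf` / `steroids_test.sdf`
(activity tag `pKi`), the published protocol is:

```{r steroid, eval = FALSE}
run <- run_comsia(run_config(
  train = "steroids_train.sdf", test = "steroids_test.sdf",
  activity_tag = "pKi", fields = "SEH",
  spacing = 1, padding = 4, alpha = 0.3
))
metrics_table(run)
```

Published Sybyl-era analyses of this set report $q^2 \approx 0.66$ with 4
components and $r^2 \approx 0.94$; open reimplementations report
$q^2 \approx 0.61$ with 3 components and $r^2 \approx 0.92$ on the same
activities. Cross-implementation agreement closer than about
$|\Delta q^2| \le 0.1$ should not be expected, because the surviving
copies of the dataset differ in alignment detail and the statistics are
alignment-sensitive; component counts within ±1 are likewise normal. This
comparison is an optional offline exercise, not part of the test suite,
because it depends on externally hosted data.

## Known limitations

* Gasteiger charges come from OpenBabel; another charge implementation
  will shift the electrostatic field and, downstream, the contribution
  split (the steroid-benchmark literature shows the same sensitivity).
* The atomic hydrophobicity table is a coarse-grained class scheme; it
  preserves the signs and rough magnitudes that drive the hydrophobic
  field but is not a fitted logP predictor.
* Formal charges are read from V2000 atom-block charge codes; `M CHG`
  property lines are not parsed.
* The MCS aligner assumes a congeneric series with a genuinely common
  core; it is not a flexible- or field-based alignment tool.
* Very coarse grids (spacing ≳ bond lengths) degrade pseudoatom geometry,
  as discussed above; spacing 1 Å with α=0.3 is the tested regime.
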