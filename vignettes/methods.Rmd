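---
title: "Methods: descriptors, model selection and validation for the coumarin LOX data set"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, model selection and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
the code, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the
design choices that were genuinely open.

## The modelling problem

Thirty-seven substituted coumarins were assayed for soybean lipoxygenase
inhibition at 100 µM; the response modelled is the base-10 logarithm of
the percent inhibition (range roughly 0.85–1.98). The published model is
an ordinary least-squares regression on three computed descriptors,

log(% inhibition) = 0.67 + 0.42·C-026 + 0.07·RDF035p − 1.85·HATS8p,

fitted on 28 training compounds (29 minus one response outlier) and
evaluated on an 8-compound external set. The package freezes this
equation as a predictor (`published_model()`) and separately re-derives
models from scratch (`ga_select()`), keeping the two routes distinct: the
frozen equation is never refitted, and the refit is never presented as
the published one.

With n = 28 and p = 3 this is small-data QSAR. Everything downstream —
leave-one-out validation, Y-scrambling, the leverage-based applicability
domain — exists because ordinary fit statistics are untrustworthy at this
size.

## Structures and their provenance

Compounds are defined by substituent specifications on the coumarin
scaffold (standard numbering: O1, C2=O, C3, C4, C4a, C5–C8, C8a) and
turned into SMILES by template. 3D conformers come from OpenBabel's
rule-based builder followed by classical force-field minimization. The
original study used force-field preoptimization followed by semiempirical
PM3 refinement; this package deliberately stays with the force-field
conformer, trading bit-level agreement with the published descriptor
values for a dependency-free, deterministic pipeline. The 3D descriptors
are rotation- and translation-invariant, so the arbitrary global
orientation of a conformer never matters; what does matter is torsional
geometry, and for flexible compounds (benzyloxy, ethoxycarbonyl) a
force-field conformer can legitimately differ from a PM3 one. This is why
descriptor agreement with the printed worked values is asserted as a
±20 % relative band in the tests rather than as equality, while all
structural properties (pair-sum oracles, invariances) are asserted
exactly.

One substituent name required a decision: "6-dihydroxyamino" (compounds
36, 37) is chemically unusual and the original work gives no structure
for it. It is encoded literally as N(OH)₂ attached at C6, without
claiming this matches the authors' intent; both compounds sit in the
middle of the activity range and neither is a worked example, so the
choice has no effect on any asserted value.

## Aromaticity and fragment typing

The atom-centered fragment C-026 counts aromatic R–CX–R carbons: an
aromatic carbon flanked by two aromatic carbons whose remaining heavy
substituent is a heteroatom. The package's aromaticity rule is
deliberately narrow: only six-membered all-carbon rings with an
alternating Kekulé pattern are aromatic. Under this rule the pyranone
ring of the coumarin scaffold is *not* aromatic, so the ring-fusion
carbon C8a — flanked by two benzo-ring carbons and bearing the lactone
oxygen — counts as exactly one C-026 per scaffold. This reproduces both
published worked counts (one for compound 5, two for compound 7). The
original narrative attributes compound 7's two C-026 atoms to its
3-benzoyl and 7-benzyloxy groups; under the standard definition of the
fragment the two atoms are the ring carbons C8a and C7, and the package
follows the definition, which reproduces the printed counts, rather than
the narrative attribution. A carbon at the fusion of two aromatic rings
(three aromatic neighbours) is never C-026; this tie rule keeps fused
polycyclics well-defined, although no compound in this set exercises it.

The heteroatom set for X is {N, O, S, F, Cl, Br, I}; only N, O and Br
occur on aromatic positions in this chemistry.

## The 3D descriptors

**RDF.** RDF(r) = Σ_{i<j} w_i w_j exp(−β (r − r_ij)²) over all atom
pairs, hydrogens included. The smoothing constant β is not stated in the
source study; the package uses the descriptor literature's conventional
β = 100 Å⁻², exposed as a parameter. Weights are atomic properties scaled
so carbon equals 1 (polarizability divides by 1.76 Å³); the raw tables
(H 0.667, C 1.76, N 1.10, O 0.802, Cl 2.18, Br 3.05 Å³ for
polarizability, plus mass, van der Waals volume and Sanderson
electronegativity schemes) are the standard handbook constants. At
β = 100 the Gaussian kernel is ~0.07 Å wide, much narrower than the 0.5 Å
descriptor grid — a property the tests exploit by integrating the RDF on
a fine quadrature grid to recover the pair count (Gaussian mass
conservation).

**GETAWAY HATS.** Atomic leverages are the diagonal of
H = M(MᵀM)⁻¹Mᵀ for the row-centered coordinate matrix M, computed through
the singular value decomposition so planar (rank 2) and linear (rank 1)
geometries fall back to the pseudo-inverse automatically; the leverages
then sum to the coordinate rank. HATS_k(w) sums (h_i w_i)(h_j w_j) over
unordered atom pairs at topological distance k (lag 0 sums (h_i w_i)²).
The source text's remark that the relevant atom pairs sit "at topological
distance 2" is inconsistent with the descriptor's own name (lag 8); the
package implements lag 8, as the name says. All-coincident geometries
raise an error rather than returning a value.

## Descriptor filtering and the test set

The three elimination tests run in a fixed order: missing values, then
the zero test (drop columns with a non-zero fraction below 0.1, boundary
kept), then greedy pairwise-correlation pruning at R² > 0.7 in fixed
column order (the later column of an offending pair is dropped, so the
result is deterministic and scale-free). "Multiple correlations" in the
original tool is not defined anywhere recoverable; the package implements
the pairwise test and leaves multiple-R² pruning out of the default path.

The published external set {16, 19, 22, 24, 25, 28, 35, 37} is shipped as
a fixture and honoured by default — reproducibility of the published
model takes precedence over re-derivation. The clustering route is
nevertheless implemented (`select_test_set()`): z-score the descriptor
block plus activity, single-linkage clustering on Euclidean distance, cut
at n_test clusters, take each cluster's medoid (lowest row index on
ties). How the original authors extracted eight compounds from their tree
is not stated; the medoid-per-cluster rule is this package's declared
convention, and exact identity of the re-derived set with the published
one is not asserted anywhere.

## GA-MLR model selection

Chromosomes are descriptor subsets of fixed size 3 (the published cap).
Fitness is leave-one-out Q², not R²: at n ≈ 28 the difference matters,
and cross-validated fitness penalizes the overfit subsets a descriptive
criterion would reward. Whether the original selection tool used Q² or a
composite is not recoverable; this choice is declared, not inferred.
Selection is 2-tournament; crossover samples the child from the union of
two parents; mutation replaces genes uniformly; the elite is copied
unchanged, making the best-fitness trajectory non-decreasing. Defaults
(population 200, 300 generations, crossover 0.8, mutation 0.05, elitism
5) are robust for a few hundred candidate columns; every evaluated subset
is cached, so the effective cost is bounded by the number of *unique*
subsets visited and the final ranking draws on the entire search history
with duplicates collapsed (ties: fewer descriptors, then lexicographic).
The seed is mandatory; a run is exactly reproducible.

## Validation statistics

All closed forms are implemented once and reused everywhere:
Q²_LOO = 1 − PRESS/TSS with PRESS = Σ(e_i/(1−h_ii))², which the tests
verify against explicit n-refit leave-one-out on random problems at
1e−10; Q²F1/Q²F2/Q²F3 differ only in the reference variance (training
mean, external mean, training variance per observation — hence Q²F1 ≥
Q²F2 identically); CCC is Lin's concordance with population moments; r²m
uses the through-origin convention (slope-through-origin fit of one
vector on the other, ordinary TSS denominator) computed in both
directions and reported as mean and absolute difference; K is the
eigenvalue-dispersion index of the correlation matrix, 0 for mutual
orthogonality and 1 for total collinearity. Y-scrambling permutes the
response (500 draws by default, seeded) and reports mean R² and Q²; under
a pure-noise null the expected scrambled R² is ≈ p/(n−1), about 0.11 at
n = 28, p = 3, which the tests check directly.

Standardized residuals use e/s with s the residual standard deviation of
the regression — matching the way the original study quotes its outlier
("standard residual of −2.65") — rather than the leverage-corrected
studentized form. The applicability domain flags |e/s| > 2 as a response
outlier and leverage h > h* = 3p′/n as out of domain; for the final
training configuration h* = 12/28 = 0.429.

## The synthetic-data generator

`gen_descriptors()` draws multivariate-normal columns in correlated
blocks (default: blocks of 5 at ρ = 0.5 — the moderate redundancy typical
of descriptor grids where one property is sampled at neighbouring radii);
`gen_response()` adds a sparse linear signal (defaults: coefficients 3,
−2, 1 on columns 5, 12, 21) plus Gaussian noise. This emulates exactly
what the linear-model machinery sees: a response that is a sparse linear
combination of a redundant descriptor pool. It does *not* emulate the
skewed, integer-valued, heteroscedastic marginals of real descriptor
grids (a count-column option exists for fragment-like variables), nor any
nonlinearity in real structure-activity relations — so passing recovery
tests demonstrate the selector and the statistics, not descriptor quality
on real molecules.

The planted-signal recovery experiment runs the GA on 20 seeded draws at
n = 28, p = 50 and asks for exact recovery of the true triple in ≥ 90 %
of runs. The default noise (σ = 0.5, population R² ≈ 0.98) reflects the
regime in which exact support recovery is a fair demand: a design study
with exhaustive best-subset search showed that at population R² ≈ 0.7
and n = 28 *no* selector — the global Q² optimum included — recovers the
exact triple much more often than ~10 % of the time, because the
smallest coefficient is statistically indistinguishable from correlated
decoys at that noise level. The R² ≈ 0.7 regime is therefore used where
it is meaningful (calibration of the fitted R² of the true-subset model)
and the low-noise regime where recovery itself is the property under
test. Coefficient accuracy on recovered runs is asserted as marginal
2-standard-error coverage (nominal ≈ 94 % per coefficient); joint
all-coefficients coverage has a nominal rate near 0.81 and would be the
wrong check.

## Numerical choices and degenerate inputs

- Rank-deficient design matrices are an error naming the collinear
  columns, not a silent drop.
- Leverage 1 makes leave-one-out undefined; it is an explicit error.
- Constant columns are rejected by K and pruned (with reason) before
  correlation filtering; constant responses are an error for
  standardized coefficients and r²m.
- The correlation prune keeps the earlier column of a correlated pair;
  column order is the matrix's, so results are reproducible.
- `embed_3d()` caches per SMILES within a session; repeated calls are
  bitwise-identical. A rebuild reproduces the geometry up to global
  orientation (every descriptor here is invariant to that).
- Exported tables round percentages and predictions to the 1–2 decimals
  of the source tables only at write time; everything internal is full
  precision.

## Problem sizes in the test suite

The suite exercises: all 39 fixture compounds (embedding plus the full
descriptor grid, computed once and shared), 50-replicate random-problem
oracles for leave-one-out equivalence, 500-permutation scrambling nulls,
20-seed GA recovery at n = 28, p = 50, and exhaustive 3-subset
enumeration (220–19 600 subsets) as the GA's optimality oracle on 12- and
50-column problems. These sizes were chosen to keep each statistical
assertion's sampling error far below its asserted tolerance while the
whole suite stays in the minutes range on one core.

## Known limitations

- Descriptor values are conformer-dependent; agreement with values
  computed on semiempirically optimized geometries is approximate by
  construction (the tests bound it at ±20 % relative on the published
  worked examples).
- The atom-centered fragment typing implements the carbon classes
  distinguishable on this chemistry, not the full published 120-type
  table.
- The aromaticity rule is scoped to carbocycles; heteroaromatic rings
  (furan, pyridine) are deliberately non-aromatic under it, which is
  correct for this compound set but not a general perception model.
- Only single-linkage (and complete-linkage, as an option) Euclidean
  clustering is provided for test-set design.
- No regularized regression, PLS or nonlinear models: the package scopes
  to what the original analysis used, OLS on GA-selected triples.
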