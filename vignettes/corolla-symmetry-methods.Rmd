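---
title: "Decomposing biradial corolla shape symmetry: models and methods"
author: "florasym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing biradial corolla shape symmetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Actinomorphic flowers with four petals are, ideally, invariant under two
perpendicular reflections: the corolla seen face-on has biradial (four-fold)
symmetry. Real corollas deviate from that ideal, and the *structure* of the
deviation is biologically informative: coordinated shape change of all four
petals (flowers differing from each other while staying internally
symmetric) is a different phenomenon from asymmetry *within* a flower, and
within-flower asymmetry itself splits into contrasts between adjacent petal
pairs (lateral) and between opposite petal pairs (transversal). In
gynodioecious species — where purely pistillate (female) and hermaphrodite
flowers occur on different individuals — comparing these components between
the sexual groups asks whether sexual differentiation affects only corolla
size or also shape and developmental precision.

`florasym` implements the full analysis chain for this question on 2D
outline landmarks: 4 petals x 50 outline points per corolla, with two
photographs per flower and two digitisations per photograph nested inside a
sex / tree / flower sampling design.

## Symmetry group and expansion

The analysis treats the corolla as an object with two nominal symmetry
axes. Its symmetry group is the Klein four-group: identity, reflection
across each axis, and reflection across both (a half-turn). A reflection of
a landmark configuration must be accompanied by a re-labelling that
restores homology: with petals P1..P4 counterclockwise from the (+x, +y)
quadrant, the vertical-axis reflection swaps P1/P2 and P3/P4 and reverses
the within-petal point order; the horizontal one swaps P1/P4 and P2/P3
(also reversing); the double reflection swaps P1/P3 and P2/P4 with point
order preserved. Reflections act about each configuration's own centroid —
no symmetry axis is ever estimated, because the subsequent Procrustes
superimposition removes all orientation differences.

Every configuration is joined by its three transformed copies
(`expand_symmetry_group()`), quadrupling the dataset; a 676-configuration
study becomes 2,704 rows. Averaging the four aligned copies of an object
(`symmetrise()`) yields its ideally symmetric consensus, used for the size
and shape ANOVA and for the sex regression.

A result worth stating explicitly: any *uniform* re-labelling of the whole
dataset — renumbering which petal is "P1", reversing the petal order, or
reversing the within-petal point direction — conjugates the symmetry group
onto itself and provably changes no downstream statistic (the variance
fractions, asymmetry scores and tests are all invariant; the package's
tests verify this numerically to 1e-10). The labelling convention therefore
only matters *within* a dataset: a record digitised against the convention
of the others (e.g. traced in the opposite direction and not re-labelled)
breaks homology. `validate_labeling()` screens for exactly this by fitting
each configuration to a reference under all 16 candidate re-labellings;
direction and point-order errors are parity errors that the rotation-only
Procrustes fit cannot absorb and stand out by an order of magnitude, and
`reverse_digitisation()` repairs the standard case of a reversed tracing.

## Superimposition

Generalized Procrustes analysis centers every configuration, scales it to
unit centroid size (CS, the square root of the summed squared landmark
distances from the centroid; CS is recorded from the raw digitised
coordinates first, since size is analysed in original units), and
iteratively rotates all configurations onto their consensus. Reflection is
never allowed in the fit — the reflected copies are explicit data points,
and allowing reflection would collapse the asymmetric subspaces.

The two basal corner points of each petal are fixed landmarks; the 48
interior outline points are semilandmarks whose exact along-curve position
is not homologous. After each converged alignment round they slide along
their tangent direction (the chord between their outline neighbours) to
the position minimizing the thin-plate-spline bending energy of the
configuration against the grand consensus; the joint optimum over all 192
sliders is one linear solve per configuration. The bending-energy kernel is
the standard 2D `U(r) = r^2 log r` construction, whose quadratic form
vanishes exactly on affine deformations. Sliding targets the grand
consensus of the expanded dataset (the mean shape of the entire dataset),
not per-group means.

Defaults: 5 outer align-slide rounds, convergence tolerance 1e-6 on the
consensus RMS change, tangent-line (not curve) projection. The final
orientation is canonicalized (first petal centroid on the 45-degree
bisector), which makes the output invariant to input ordering, orientation,
position and scale; this matters because a four-fold-symmetric consensus
has an isotropic inertia tensor, so principal-axis alignment would be
undefined.

## Decomposition of shape space

PCA of the aligned, expanded dataset (covariance of the flattened
coordinates, divisor n - 1) yields components that fall into orthogonal
symmetry subspaces. The reason is structural: because the dataset is closed
under the symmetry group and the group acts orthogonally, the sample
covariance commutes with every transform, so each eigenvector with a
non-degenerate eigenvalue satisfies `T(v) = +v` or `T(v) = -v` for both
reflections. The package computes the characters `s_V = v . T_V(v)` and
`s_H = v . T_H(v)` and labels a component:

* **symmetric** — both characters above +0.9: the four copies of an object
  have identical scores; variation among flowers with petals staying
  mutually identical;
* **lateral** — characters of opposite sign: adjacent petal pairs
  contrast. The two lateral patterns cannot be attributed to left–right
  versus adaxial–abaxial axes (the two axes are anatomically
  indistinguishable), so both are pooled into one lateral subspace;
* **transversal** — both characters below -0.9: opposite petal pairs
  contrast; copies form mirror pairs;
* **ambiguous** — anything else. This can only arise inside
  (near-)degenerate eigenvalue blocks, where the eigenbasis is arbitrary
  within the block; such blocks are re-rotated to diagonalize the
  transforms before labelling, and anything still mixed is reported as an
  unassigned variance remainder with a warning.

The copy-score criterion (equal scores of the four copies versus mirror
pairs) is retained in the test suite as an independent oracle for the
character-based classification.

Variance fractions are eigenvalue sums per label as a percentage of total
shape variance. Per-object asymmetry is the Euclidean distance of the
object's scores, restricted to one asymmetric subspace, from the subspace
origin (the ideally symmetric consensus); the four symmetry copies share
this distance by construction. The phrase "sum of distances on the
subspace's PCs" admits a per-PC absolute-value reading as well; the
Euclidean norm is the default because it is the distance "from the
midpoint" that a distance-to-centroid dispersion test consumes, and the
absolute-value sum is available behind `method = "abs_sum"`. This
decomposition quantifies total asymmetry; it cannot separate directional
from fluctuating asymmetry.

## Inference

**Nested permutation ANOVA** (`nested_anova()`): type-I sequential sums of
squares over sex / tree(sex) / flower(tree) / imaging / digitisation, for
CS (univariate) and for the symmetrised shape coordinates (summed over
coordinates). Each F uses the mean square of the immediately nested effect
as denominator. P-values come from restricted permutation of the
exchangeable units of that nested level — whole trees across sexes, whole
flowers across trees within sex, whole photographs across flowers within
tree, digitisations across photographs within flower — with 999
permutations by default and the observed statistic included in the
reference distribution. For the study design (16 trees, 169 flowers, 2 x 2
replicates) the df column is (1, 14, 153, 169, 338; total 675).

**Sex regression** (`goodall_regression()`): Goodall's F for a binary
predictor, `(SS_between / 1) / (SS_within / (n - 2))` on Procrustes
distances, permutation p on F. The pipeline regresses per-flower mean
symmetrised shapes (n = 169) rather than all 676 symmetrised rows; the
published F-to-percent arithmetic is only consistent with flower-level
units, and replicates of one flower are not independent evidence about
sex. Row-level regression remains available through the exported function.

**Dispersion test** (`dispersion_test()`): the Levene analogue for
multivariate scores — each point's Euclidean distance to its group centroid
(centroid, not spatial median, matching the "average distance to centroid"
summary being tested), one-way ANOVA F on the distances, and a permutation
p (9,999 by default). The default exchangeable unit is the *flower*: the
four symmetry copies and four replicate digitisations of a flower travel
together, because copies of one flower are not exchangeable between sexes;
row-level permutation is available to mimic classical row-wise analyses.
The confidence interval of the difference in mean distances is a
two-sample Welch t interval on the distances (the exact construction
behind published symmetric bounds is not fixed by any of our sources; the
t interval is the conventional default).

**NMDS** (`nmds()`): two-dimensional non-metric MDS of the subspace
scores, Kruskal stress-1 via `vegan::monoMDS`, with a metric
(principal-coordinates) start plus random starts, keeping the best
solution. NMDS is a standard delegated step, not a contribution of this
package.

## The synthetic corolla generator

`generate_population()` draws complete nested datasets so that every stage
above is testable without any digitised images. A petal is two mirrored
cubic arcs from the basal corners over the tip, parameterized by length,
width, tip pointedness, basal width fraction, skew and attachment radius;
the outline is resampled to 50 equidistant points by arc length. Latent
effects enter as template perturbations:

* coordinated (all-petal) flower-level and tree-level shape modes, drawn
  as near size-neutral elongation contrasts (length +d with width -0.55 d),
  plus tip-shape variation — these span the symmetric subspace;
* two adjacent-pair contrast amplitudes (`sigma_lat`, patterns + + - - and
  + - - +) and one opposite-pair amplitude (`sigma_trans`, + - + -) on
  petal length and width — the lateral and transversal subspaces;
* independent per-petal noise (`sigma_petal`), which spreads over all
  subspaces;
* measurement error: per-photograph rigid motion plus isotropic point
  jitter (`sigma_imaging`, shared by both digitisations of a photograph)
  and per-digitisation jitter along the outline tangent (`sigma_digit`),
  most of which the sliding semilandmarks legitimately absorb — which is
  why digitising error is the smallest variance component, as it should
  be;
* pure size variability as log-normal scale factors per tree, flower and
  photograph (`size_cv_*`): template draws are rescaled to a fixed
  centroid size first, so shape variance and size variance are controlled
  independently;
* sex effects: female flowers scaled by `female_size_factor = 0.845`
  (15.5% smaller), their asymmetry SDs multiplied by
  `female_asym_factor = 1.22`, and their petal bases thickened by
  `female_base_factor = 1.19` (a subtle deterministic mean-shape
  difference).

Petal residual noise is modelled as independent across petals; the
within-flower covariance beyond the subspace structure is a modelling
choice, not an observed quantity.

### How the defaults were chosen

The defaults are the validated study conditions, set once and frozen: the
nested design (8 + 8 trees with unbalanced per-tree flower counts summing
to 169, 2 photographs x 2 digitisations = 676 configurations) and the
female size factor are taken directly from the study system; the noise SDs
were calibrated in a handful of simulation runs so that the synthetic
population reproduces the reported variance *structure* — roughly 45 / 43 /
12 percent of shape variance in the symmetric / lateral / transversal
subspaces, tree and flower effects dominating shape variation with
measurement error far below them, size error ordered imaging >
digitisation, and a female asymmetric-dispersion excess of roughly a
quarter. Calibration targeted these structural features, not any test
outcome, and the parameters were not revisited afterwards.

### What the generator does and does not emulate

It emulates the design, the subspace structure, realistic magnitudes of
the variance components, and measurement error. It does **not** emulate
the high-dimensional "noise floor" of real outline data: synthetic shape
variation is low-rank (a handful of template modes per subspace), so
ordinations of synthetic scores reach much lower NMDS stress than real
datasets, and classification of noise-floor components is cleaner than it
would be on real digitisations. Passing tests on synthetic data therefore
validate the algebra, the estimators and the calibration of the tests —
not the biological realism of any particular outline model. Two
study-level quantities are intrinsically seed-variable under the study's
own design and should be read as one realization each: the sex difference
in mean shape (the sex contrast rests on 8 trees per group, so tree-level
sampling noise dominates its magnitude) and, to a lesser degree, the
asymmetric-dispersion excess. One calibration target is only partially
attainable: with the single `female_asym_factor` scaling both asymmetric
channels, the lateral dispersion excess realizes near its ~24% target and
is detected by the flower-level permutation test in ~90% of seeds, but the
transversal excess realizes at roughly half that — nonlinear interaction
between the transversal channel and the large symmetric template modes
dilutes it — so transversal significance is a weaker, seed-dependent
outcome in synthetic runs than the lateral one.

## Numerical choices and degenerate inputs

* Rotation fits use the 2x2 SVD with the determinant constrained to +1;
  the test suite cross-checks against a rotation-grid search and an
  independent closed-form implementation.
* GPA convergence: tolerance 1e-6 (RMS consensus change), 100 iterations
  per round; non-convergence warns and reports the final delta rather than
  failing.
* Singular TPS or sliding systems fall back to a ridge-regularized solve
  with a warning; the ridge solution still cannot increase bending energy.
* Zero-length curves, zero-CS configurations, degenerate templates and
  mixed landmark counts raise informative errors; an all-coincident
  configuration returns CS 0 with a warning.
* Eigenvalues below 1e-12 of the leading eigenvalue are "negligible" and
  excluded from classification; near-degenerate ambiguous blocks are
  re-rotated as described above.
* Permutation p-values are `(exceedances + 1) / (n_perm + 1)`, so they lie
  in `[1/(n_perm+1), 1]` and are reproducible under a fixed seed; every
  randomized function takes an explicit seed and restores the caller's RNG
  state.
* Problem sizes in the test suite are chosen to exercise every code path
  at small n (12–676 configurations, 199–999 permutations, 1,000 null
  replicates for the type-I error check); the full study-sized run
  (2,704 configurations, 999 / 9,999 permutations) is exercised by the
  acceptance script.

## Known limitations

* Only the Klein four-group is implemented; no cyclic (rotational)
  symmetry treatment, and only 4-petal corollas are tested although the
  petal count is not hard-coded.
* No directional-versus-fluctuating asymmetry decomposition.
* No image processing: the package consumes already-digitised outline
  points.
* The dispersion test's confidence interval is a t interval on distances;
  bootstrap alternatives are not provided.
* Thin-plate-spline deformation grids are not drawn; the decomposition
  table and score exports are the visualization interface, plus a simple
  stacked bar chart of variance fractions.
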