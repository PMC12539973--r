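---
title: "Models and methods behind shaperate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shaperate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(shaperate)
```

`shaperate` measures the tempo and mode of shape evolution from landmark
data: it asks, branch by branch of a time-calibrated phylogeny, whether a
lineage accumulated more or less shape change than neutral constant-rate
evolution predicts. This vignette is the package's own account of the
models, the tunable parameters, the numerical choices, and what the test
suite does and does not demonstrate.

## The generative model assumed by the analysis

Shape is a point configuration of `k` landmarks in 3D, reduced to
Procrustes shape space (translation, scale and orientation removed).
Between species, shape is assumed to evolve by Brownian motion: along a
branch spanning `n_b` generations, each retained principal component `j`
of the species-consensus shape space receives an independent Gaussian
increment with variance `sigma2_j * n_b`. Time is converted to generations
because drift accumulates per generation, not per year: a branch of `t_b`
Ma spanned by a species with generation time `g` years covers
`n_b = t_b * 1e6 / g` generations. Selection enters only as a deviation
from this null: a branch under directional selection accumulates more
change than the neutral expectation, a branch under stabilizing selection
less.

## The excess-change rate

For each branch, the observed change `D_obs(b)` is the Procrustes distance
between the (estimated) ancestor shape and the descendant shape, both
expressed in landmark coordinates via the full PC basis (the basis is
orthonormal, so distances in PC space and landmark space agree to
`1e-10`). The expectation `D_exp(b)` is the mean ancestor-descendant
distance for that branch over `n_sims` simulations of the neutral model
above, started at the observed root estimate, using per-PC per-generation
variances estimated from the data by phylogenetically independent
contrasts on the generation-scaled tree. The branch rate is
`R(b) = D_obs(b) / D_exp(b)`, unsigned by construction.

Two expectation modes exist, and the difference matters:

* `true_node` (default) uses the *true* simulated ancestor values. This
  is the literal reading of "simulate, then measure ancestor-descendant
  distances", but it compares estimated observed ancestors against true
  simulated ancestors. GLS ancestral estimates are conditional means and
  therefore less variable than the truth, so `D_obs` is systematically
  smaller than a matched `D_exp`, biasing `R` downward (about 20-25% on
  the 16-tip fixture).
* `reestimated` re-runs the ancestral estimator on the simulated tip data
  of every simulation, so estimation shrinkage cancels between numerator
  and denominator. This is the apples-to-apples mode, and the one the
  self-consistency acceptance check uses: under matched generative
  conditions with the exact GLS estimator on both sides, the grand-mean
  `R` over 50 replicates of the 16-tip fixture is within a few percent
  of 1.

Both modes are exposed and tested; ranked comparisons (which branch is
fastest, clade contrasts) are essentially unaffected by the choice because
the bias is shared across branches.

## Ancestral states: exact GLS and the gated mvBM

Plain BM ancestral states are exact generalized least squares: the root is
`(1'C^-1 1)^-1 1'C^-1 Y` with `C` the matrix of shared root-to-MRCA path
lengths, and each internal node is its conditional expectation given the
tips. The test suite verifies this against a brute-force full-covariance
oracle on all trees up to 6 tips at `1e-8`, and against an independent
implementation.

The multiple-variance BM estimator gives each branch a variance scalar
`s_b` (normalized to mean 1) multiplying its length, so lineages that
genuinely evolved faster pull their ancestral estimates less strongly
toward their neighbours. The scheme iterates: estimate states under
current effective lengths `t_b * s_b`; compute each branch's local rate
(mean squared per-trait change over effective length) against the global
mean rate; update `s_b <- s_b * (local/global)^0.5` — but *only* for
branches whose standardized local rate `p * local/global` leaves the
central 98% chi-square band expected under rate homogeneity
(`band_alpha = 0.02`). The gate is essential: an unconditional update has
its fixed point where every branch's realized rate equals the global rate,
i.e. it fits the sampling noise of per-branch changes completely, and
under constant-rate data its states drifted ~10% of trait SD away from
the exact GLS states. With the gate, homogeneous data leave all scalars
at 1 and the estimator *is* the constant-rate GLS estimator — the
convergence behaviour that defines this estimator family — while a
strongly deviant branch (e.g. a tip displaced far beyond its expected
variance) still captures the maximum scalar. This gated rescaling is this
package's own concrete definition of mvBM; it is not guaranteed to match
other variable-rate implementations, and plain `bm_ancestral_states()` is
the fallback whenever that matters.

## Disparity and rate statistics

* **Procrustes variance** of a group is `(1/n) sum ||x_i - xbar||^2`
  (the divisor-`n` trace of the group covariance). Clades are compared by
  the variance ratio; significance by permuting taxa across clades with
  the statistic `|PV_A - PV_B|` and the `(b+1)/(m+1)` p-value convention
  (no zero p-values).
* **Pairwise Procrustes distances** within each clade are compared with
  an exact Wilcoxon rank-sum test (exact null distribution when
  `n_x + n_y <= 25` without ties; mid-ranks and a continuity-corrected
  normal approximation otherwise, flagged in the output). The printed
  clade ratio is the ratio of distribution means; the median-based ratio
  is reported alongside because the choice is a convention, not a result.
* **`sigma^2_mult`** is the net multivariate Brownian rate: rows centered
  on the GLS root, whitened by `C^-1/2`, summed squared norms divided by
  `n`. On a star tree with unit branches this reduces exactly to the
  divisor-`n` variance. Group rates restrict the whitened rows to each
  group; regional comparisons use the max/min ratio with a null that
  simulates all regions at the common (mean) rate while preserving each
  region's dimensionality and within-region evolutionary covariance.
* **Rate correlations** between regions are Pearson correlations of
  per-branch `R` values, over all branches and within each clade (a stem
  branch belongs to its crown clade), with two-sided t-based p-values and
  0.05/0.01/0.001 stars.
* **Allometry** is a lambda-fixed phylogenetic regression of shape on
  centered log centroid size: Pagel's lambda multiplies the off-diagonal
  of `C` (the standard construction), the fit is GLS via the inverse
  square root of `C_lambda` (on an ultrametric tree, `lambda = 0` is
  ordinary least squares), and significance comes from residual
  randomization under the intercept-only reduced model. Residual shapes
  are re-centered on the fitted mean shape so they remain valid
  Procrustes-space coordinates and can be fed back through the whole
  battery.

### Attenuation of whitening-based rate ratios

The group-rate ratio estimator is attenuated under strong heterogeneity:
because the whitening matrix and GLS root are those of a single-rate
model, the root estimate couples the whitened rows of the two clades, and
part of the fast clade's variance is charged to the slow clade. An exact
expectation computation on the default two-clade fixture tree shows a
planted 4x variance ratio measured as ~3.4 even from noise-free species
means. Within-species specimen noise attenuates further, and selectively:
whitening amplifies iid tip noise in inverse proportion to terminal branch
length, so a reference clade with short terminal branches (a recent
radiation) absorbs proportionally more noise, inflating its apparent rate.
With the generator's default noise this lowers the measured median ratio
to just below 3. Both effects are properties of the estimator and the
sampling design, not implementation artifacts; the acceptance suite
reports them honestly (one recovery band check sits marginally outside
its target for exactly this reason) and the power of both significance
tests on the same data is essentially 1.

## The synthetic-data generator

`simulate_shape_evolution()` produces landmark datasets with the exact
statistical structure the analysis assumes, plus full ground truth, so
every stage is testable without external data:

* A deterministic template (`make_template()`): a spherical Fibonacci
  lattice deformed into a vault-plus-face surface, partitioned
  contiguously into the four named cranial regions; default 1475 points,
  matching high-density practice, while fixtures use `k = 60` to keep
  test runtimes in seconds.
* A 16-tip, two-clade ultrametric tree (7 + 9 tips, root depth 20 Ma by
  default): the focal clade's crown spans 80% of root depth, the
  reference clade's 35%, emulating a diverse old clade against a young
  compact radiation.
* Species mean shapes evolve by BM along `n_basis = 40` orthonormal
  directions constructed orthogonal to the template's similarity
  transformations (translations, rotations, scaling), so superimposition
  cannot remove or distort the simulated signal. Per-branch variance is
  `sigma2_base * kappa_b * n_gen(b)`; `kappa` multipliers plant rate
  structure (9 on one terminal branch, 4 on a whole clade in the shipped
  fixtures).
* Defaults chosen as realistic for interspecific craniofacial data at
  unit centroid size: `sigma2_base = 3e-10` per generation per dimension
  (typical between-species Procrustes distances ~0.1),
  `noise_sd = 0.002` per coordinate (~7% within- to among-species
  variance), log centroid size BM with `size_sigma2 = 3e-8` (tip SD
  ~0.15 around a 100-unit baseline), dimorphism offset 0.03, 4 specimens
  per species (2 per sex).
* Fixture scenarios use a uniform 25-year generation time for both
  clades. This is deliberate: the planted `kappa` are per-generation
  multipliers while clade rate comparisons are made on the time tree, so
  clade-specific generation times would confound the planted contrast
  with generation-time differences. The generator itself accepts
  arbitrary per-tip generation times and the rescaling rules (terminal
  branch: tip value; internal branch: mean of descendant tips, with a
  tree-wide-mean switch) are unit-tested separately.

What the generator does **not** emulate: realistic cranial surface
geometry, integration/modularity covariance among regions (the simulated
basis spreads variance isotropically), non-Gaussian within-species
variation, missing landmarks, and sliding-semilandmark placement error.
Passing tests therefore demonstrate the statistical machinery is correct
and calibrated under its own assumptions — not that those assumptions hold
for any particular empirical dataset.

## Numerical choices and degenerate inputs

* GPA: full Procrustes (every configuration kept at unit centroid size),
  proper rotations only (no reflections), iteration to mean change
  `< 1e-10` with a 100-iteration cap; the iteration starts from the
  arithmetic mean of the centered, scaled configurations (falling back to
  the first configuration if that mean is degenerate), which makes
  alignment idempotent on already-aligned data. Configurations with
  coincident points or fewer than 3 landmarks are rejected.
* Distances are computed directly on aligned coordinates (no tangent
  projection): the distance definition used throughout is the plain
  coordinate-wise Euclidean norm.
* Per-region analyses re-superimpose each region independently by
  default (the shape of a part is not the restriction of the whole's
  alignment); `region_realign = FALSE` reuses the whole-configuration
  alignment for sensitivity analysis.
* PCA is on the covariance (not correlation) of Procrustes coordinates —
  the coordinates share units; eigenvalues use divisor `n` so they sum to
  the mean squared distance from the mean; component signs are fixed by
  making each component's largest-magnitude loading positive.
* Per-sex analyses are fully separate pipelines sharing code, not a
  pooled model.
* All Monte-Carlo stages take explicit integer seeds; the pipeline
  derives decoupled substreams per stage and per region-sex cell from one
  master seed, so results are independent of stage order and two runs
  with the same configuration are byte-identical (verified at the JSON
  level in the test suite).
* Test and acceptance problem sizes: 16 taxa, 60-point templates,
  40-dimensional bases, 100 neutral simulations, 99-999 permutations,
  and 50-200 replicates per calibration — sizes chosen so the entire
  statistical validation runs in about a minute while keeping every
  assertion at its stated tolerance.

## Known limitations

* The mvBM gate uses a chi-square band that treats per-branch trait
  changes as independent given the current scalars; estimation-induced
  correlation between sibling branches makes the band slightly
  conservative.
* Generation counts are real-valued; simulation adds Gaussian increments
  with variance `sigma2 * n_b` rather than stepping generation by
  generation (exact for BM, an approximation for any non-Gaussian
  per-generation process).
* `sigma^2_mult` is reported in the tree's native branch-length units;
  absolute values depend on unit conventions, so only ratios are
  compared across analyses.
* Exact Wilcoxon p-values require tie-free data; distances from
  continuous coordinates are tie-free in practice, but heavily rounded
  input would silently switch the test to its approximate form (the
  `exact` flag in the output records which branch was taken).
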