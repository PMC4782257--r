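---
title: "Shape diversity, evolutionary rate, and lability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape diversity, evolutionary rate, and lability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the estimation strategy

Different parts of a skull occupy very different amounts of morphospace.
That observation alone does not tell us *why*: a region can be diverse
because its structural organization makes it responsive to selection
(labile), because it has simply evolved at a higher rate, or it can be
kept uniform by stabilizing selection. `morpholab` implements the three
measurements needed to separate these explanations for 2D landmark data on
a phylogeny:

1. **Disparity** — the mean squared Procrustes distance to the mean shape,
   $P^2 = \tfrac{1}{N}\sum_i d_T^2(x_i, \bar{x})$, computed in the tangent
   space of a region-specific Procrustes fit.
2. **Evolutionary rate and mode** — maximum-likelihood fits of Brownian
   motion (BM), Ornstein–Uhlenbeck (OU), early burst (EB), a node-depth
   power transform (delta), and a combined delta+OU model, compared by AIC,
   plus the pooled multivariate rate $\sigma^2_{mult}$.
3. **Lability** — respondability $\bar r$, evolvability $\bar e$ and
   flexibility $\bar f$ of the mean-standardized covariance matrix of
   reconstructed ancestral shapes, estimated by random skewers: random unit
   selection gradients $\beta$ and responses $\Delta z = P\beta$ in Lande's
   $\Delta z = G\beta$ framework, with the phenotypic $P$ standing in for
   $G$.

Because real comparative datasets of this kind are built from undeposited
museum photographs, the package ships a synthetic-data generator with full
ground truth; every stage of the pipeline is validated against either
closed-form oracles or parameter-recovery simulations.

# Morphometrics

**Superimposition.** `gpa_align()` performs Generalized Procrustes
Analysis: every configuration is centered, scaled to unit centroid size,
and rotated to the evolving consensus until the consensus stops changing
(tolerance $10^{-10}$ on its root-sum-of-squares change). GPA leaves a
global rotation free, so the consensus orientation is fixed
deterministically: principal axes of the mean shape aligned to the
coordinate axes, largest spread along $+x$, landmark 1 at negative $y$
(resolved by a proper 180° rotation, never a reflection). Unit-size
scaling of every specimen (rather than variable scaling) keeps tangent
distances comparable across specimens.

**Regions.** Each skull region (face, braincase, whole cranium, mandible)
is analyzed with its own independent Procrustes fit of the region's raw
landmark subset — subsetting happens *before* alignment, so a region's
shape space is never contaminated by landmarks outside it. When a
semi-landmark's curve neighbors are not both retained in a subset it is
demoted to a fixed landmark (its sliding direction would be undefined).

**Semi-landmark sliding.** Semi-landmarks are allowed to slide along their
curve to minimize thin-plate-spline bending energy relative to a
reference. The bending-energy matrix is the upper-left $k \times k$ block
of the inverted TPS system built on the reference; it annihilates affine
displacements, so sliding penalizes only non-affine deformation. Each
sliding pass solves the exact quadratic program for the displacement of
every semi-landmark along its tangent (the chord between curve
neighbors), so energy relative to the current reference never increases.
The reference is the sample Procrustes mean, updated over (by default) 5
outer slide/re-align iterations with tolerance $10^{-6}$ on the energy
change. Two known properties of sliding-to-the-sample-mean are worth
stating: (i) the alternation has a nearly neutral direction in which all
specimens and the mean drift together along the curves, so the default
iteration count is deliberately small — running it to numerical
convergence is neither necessary nor meaningful; and (ii) a sample of
identical shapes is an exact fixed point. Whether one should slide against
the sample mean or an external template is not settled usage; the sample
mean is the default here.

**Tangent space.** Aligned shapes are projected orthogonally onto the
plane tangent to the unit sphere at the mean shape
($t_i = m + (I - mm^\top) z_i$); the projection is idempotent and agrees
with full Procrustes distance to well under 1% at the disparity levels of
mammalian skulls (verified in the tests at $d < 0.05$). Stereographic
projection would differ only at far larger distances.

# Phylogenetic machinery

Trees are handled by `ape`; polytomies are resolved to zero-length
bifurcations (`resolve_polytomies()`, seeded), which leaves patristic
distances untouched. Inside contrast and reconstruction code, zero-length
branches are floored at $10^{-8}$ times tree depth, preserving distances
to numerical precision while avoiding division by zero.

Independent contrasts use Felsenstein's pruning with the standard
branch-length inflation. Ancestral states minimize the
branch-length-weighted sum of squared changes — the squared-change
parsimony solution, which coincides with the BM maximum-likelihood/GLS
estimate. The implementation is the dense GLS form (root
$\hat a = (1^\top C^{-1}x)/(1^\top C^{-1}1)$; other nodes the conditional
expectation given the tips), which is exact and fast at the few hundred
species this package targets; an unweighted (equal-branch) mode is
available because mapping software traditionally defaults to unweighted
squared-change parsimony while ML reconstruction weights by branch
length. Tip/trait matching is always by species label; order is never
trusted.

# Allometry

Shape may covary with size; the package follows the two-step
contrast-based procedure. Shape and log centroid size are reduced to
independent contrasts, and shape contrasts are regressed on size contrasts
*through the origin* (contrasts have no intercept). The fraction of shape
variance explained is pooled over all tangent dimensions. Significance
comes from permuting the size contrasts against the shape rows (default
10,000 permutations) with the $+1$ correction,
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n+1)$, so $p$ is never
exactly zero. Where the test is significant at 0.05 (the default policy;
`always`/`never` are available), species-level data are corrected with the
contrast-estimated slopes, $y_i - b\,(s_i - \bar s)$, which preserves the
mean shape. The permutation test is exact under exchangeability; its
empirical size is checked in the acceptance tests (nominal 5%, accepted
band 3–8% over 200 null replicates).

# Evolutionary models

All models are covariance transformations of the BM matrix $C$ of shared
root-to-MRCA path lengths (tree depth $T$):

| model | covariance | parameter |
|---|---|---|
| BM | $C$ | — |
| delta | $C^{\delta}\,T^{1-\delta}$ (element-wise) | $\delta > 0$ |
| EB | $(e^{rs}-1)/r$, $s$ = shared path | $r$ |
| OU | $e^{-2\alpha(T-s)}(1-e^{-2\alpha s})/(2\alpha)$ | $\alpha \ge 0$ |
| delta+OU | delta first, then OU | $\delta,\ \alpha$ |

The delta transform is rescaled by $T^{1-\delta}$ so total depth — and
hence the units of $\sigma^2$ — is preserved across models; the OU form
above likewise tends to $C$ as $\alpha \to 0$. The combined model applies
the depth-power transform to the shared times first and the OU constraint
second ("rate shift in time, then attraction"); the opposite composition
would be a different model, and plugging in single-model best estimates
instead of jointly re-optimizing is a third — the package fits the joint
2-D problem because sequential plug-in is not maximum likelihood.

**Likelihood.** Traits are treated as independent with one pooled rate:
per trait the root is the GLS estimate, and
$\hat\sigma^2 = \sum_j (x_j-\hat a_j 1)^\top V^{-1}(x_j-\hat a_j 1)/(Np)$
is profiled out. This is the pooled-rate ($\sigma^2_{mult}$-style)
formulation; a full $p \times p$ rate matrix is deliberately out of scope
(it would change the parameter count and is rarely estimable at
morphometric dimensionalities). Parameter counts: BM 2, OU/EB/delta 3,
delta+OU 4 (the per-trait root states are profiled, counted once). AIC —
not AICc — is used for selection, with ties broken toward fewer
parameters.

**Optimization.** Single-parameter models use Brent's bounded search
(OU: $\alpha \in [10^{-8}, 50/T]$; delta: $[0.01, 3]$; EB:
$r \in [-10/T, 10/T]$). The combined model is optimized with a
box-constrained quasi-Newton search from a fixed five-point start grid —
deterministic, no randomness anywhere in fitting. One empirical caveat the
simulations make visible: the combined model's $(\delta, \alpha)$ pair
sits on a pronounced likelihood ridge (tip-concentrated change and strong
attraction to the optimum shrink deep covariance in similar ways), so the
two estimates trade off against each other between replicates even at 200
tips, and non-phylogenetic digitization noise pushes $\hat\alpha$ up.
Model *selection* and the rate $\sigma^2_{mult}$ are robust to this;
individual combined-model parameter values should be read with the ridge
in mind. Single-model parameters are well identified (the tests require
median $\hat\delta \in [1.5, 2.5]$ at true $\delta = 2$, and
$\sigma^2_{mult}$ within 25%).

**Dimension reduction.** Procrustes tangent data are rank-deficient (four
similarity dimensions are lost). When $2k > N/2$ the model fits run on the
leading principal components capturing ≥ 95% of variance, keeping the
model covariance well conditioned; $P^2$ and $\sigma^2_{mult}$ are always
computed on the full tangent data (a GLS quadratic form is well defined on
rank-deficient responses — zero-variance directions contribute zero).

# Lability

The P-matrix is, by default, the covariance across all reconstructed
internal-node shape vectors ("the ancestral reconstruction"), with the
reconstructed root as the trait-mean vector; the covariance of independent
contrasts (an evolutionary rate matrix) is available as the alternative
source, because the literature phrase does not pin down which sample is
meant, and we do not assert either as canonical.

Mean standardization divides $P_{ij}$ by $\bar z_i \bar z_j$. The method
was designed for positive linear measurements; Procrustes tangent
coordinates can pass arbitrarily close to zero, which would blow the
quotient up. Means smaller in magnitude than $10^{-3}$ of the norm of the
mean vector are therefore floored at that bound (keeping their sign); an
unstandardized mode is available.

Random skewers draws selection gradients uniformly on the unit sphere
(normalized Gaussians; 1000 by default), responses $\Delta z = P\beta$,
and reports $\bar r = \mathbb{E}\lVert\Delta z\rVert$,
$\bar e = \mathbb{E}[\beta^\top P \beta]$ (analytically
$\mathrm{tr}(P)/p$), and $\bar f$ = mean cosine between $\Delta z$ and
$\beta$ — the cosine of the raw vectors, not a centered correlation, per
the standard convention. Monte-Carlo standard errors accompany each
index. Useful exact laws used in the tests: for $P = cI$,
$\bar r = \bar e = c$ and $\bar f = 1$; $\bar e$ is linear in $P$;
$\bar f$ is scale-invariant and decreases with eigenvalue dispersion.

# The synthetic-data generator

The generator is the package's stand-in for digitized museum photographs,
and its defaults define the study conditions used in the tests and in
`scripts/acceptance.R`:

- **Tree**: pure birth, rate 1, 100 tips by default (depth ≈ ln N). Any
  ultrametric tree works; pure birth is the simplest generator with
  controllable depth.
- **Trait signal**: p = 20 independent dimensions by default (capped at a
  template's shape-space dimension 2k−4), rate 5 × 10⁻⁴ per dimension per
  unit time. Distributing signal over many tangent directions reflects
  how real skull variation spreads over the whole configuration and gives
  every region comparable signal density; with these values total cranial
  disparity lands at $P^2 \approx 0.02$–0.06, the magnitude seen across
  mammals. Traits are mapped through an orthonormal basis of the tangent
  space at the template, so injected signal lives exactly in shape space
  and is recoverable by GPA; for OU-type models the optimum is the
  template shape itself (trait value 0).
- **Size**: log centroid sizes evolve by BM on the same tree with
  tip-level standard deviation 0.6 (mammals span orders of magnitude in
  skull size, and size is strongly phylogenetic). An earlier iid-size
  variant made the allometry permutation test anticonservative for a
  subtle reason worth recording: iid size produces heteroscedastic size
  contrasts whose variance pattern across nodes matches that of the
  digitization-noise part of the shape contrasts, coupling the two under
  the null. Phylogenetic size is both more realistic and restores the
  nominal test size.
- **Allometry**: a fraction (default 3%, the order reported for mammalian
  skulls) of shape variance is injected along a basis direction orthogonal
  to the trait signal, proportional to centered log size.
- **Nuisance**: iid Gaussian coordinate noise (default 0.002 of unit
  centroid size, i.e. small digitization error), then a random rotation,
  translation and digitizer scale per specimen; the TPS writer stores raw
  "pixel" coordinates with a `SCALE=` line, as digitizing software does.

What the generator does **not** emulate: landmarking bias that covaries
with taxon, missing landmarks, object symmetry, 3D structure viewed in
projection, and model heterogeneity across clades. Passing tests therefore
demonstrate correctness of the estimators under the stated models, not
robustness of the biology to those real-data complications.

# Problem sizes and determinism

Every random stage (tree, traits, sizes, noise, permutations, skewers,
polytomy resolution) is seeded, and the pipeline is deterministic given
its config — identical runs produce byte-identical result files. The test
suite and acceptance script use problem sizes chosen to make the
statistical claims sharp but cheap: oracle comparisons on 6–12 tip trees;
parameter recovery at 200 tips, 10 traits, 20 replicates; permutation
calibration at 200 null datasets × 2000 permutations; end-to-end ratio
recovery at 100 tips × 10 replicates. These are the package's validation
conditions, reported as such in the acceptance output.

# Known limitations

- 2D landmarks only; no missing-data estimation; no object symmetry.
- The pooled-rate likelihood assumes independent, equal-rate trait
  dimensions; correlated-rate extensions are out of scope.
- The combined delta+OU parameters are ridge-correlated (above); report
  them together, never in isolation.
- Mean standardization of near-zero Procrustes coordinates is guarded but
  remains a convention transplanted from positive-measurement traits; the
  unstandardized indexes are also reported by the pipeline's details for
  comparison.
- Squared-change parsimony mapping and ML root reconstruction are the same
  estimator here (branch-length-weighted); the unweighted variant is
  provided for comparison with mapping-software defaults.
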