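---
title: "The geometry of community responses: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The geometry of community responses: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commgeom)
```

## The model

A community of $S$ species is a point $\mathbf{N} \in \mathbb{R}_{>0}^S$ in
*state space*, whose axes are the biomasses of the constituent species. A
perturbation moves the community from a control state $\mathbf{N}^c$ to a
perturbed state $\mathbf{N}^p$; everything the framework needs is the
displacement $\Delta\mathbf{N} = \mathbf{N}^p - \mathbf{N}^c$.

A linear ecosystem function $f(\mathbf{N}) = f_0 + \langle \boldsymbol\varphi,
\mathbf{N} \rangle$ is represented by the *direction* of its per-capita
contribution vector $\boldsymbol\varphi \ge 0$ (the constant $f_0$ and the
overall scale of $\boldsymbol\varphi$ play no role: only relative
contributions matter, and every operation in the package is invariant to
positive rescaling). The observed response is the projection
$\Delta f = \langle \boldsymbol\varphi, \Delta\mathbf{N} \rangle$
(`function_response()`).

Two functions $f, g$ *mismatch* under a perturbation when their responses
have opposite signs. Drawing the two hyperplanes orthogonal to
$\boldsymbol\varphi$ and $\boldsymbol\phi$ splits state space into cones of
agreement and disagreement, and for isotropic, unbiased displacements the
disagreement cones occupy a fraction

$$\mathbb{P}(\text{mismatch}) = \theta / \pi, \qquad
\cos\theta = \frac{\langle\boldsymbol\varphi, \boldsymbol\phi\rangle}
{\lVert\boldsymbol\varphi\rVert \lVert\boldsymbol\phi\rVert}$$

(`angle_between()`, `mismatch_probability()`). For nonnegative directions
$\theta \le \pi/2$, so mismatch probabilities between positive functions
cannot exceed one half.

Diversity metrics enter through their state-dependent gradients. For the
Hill family $^qD(\mathbf{p}) = (\sum_i p_i^q)^{1/(1-q)}$
(`hill_diversity()`), the gradient with respect to absolute biomasses has
entries proportional to $\frac{q}{1-q}(p_i^{q-1} - \sum_j p_j^q)$
(`diversity_gradient()`). Entries for abundant species are negative, so
the gradient is *not* a positive direction and its angle with a function
can exceed $\pi/2$ — the geometric root of the systematic opposition
between diversity and biomass under biomass-scaled perturbations.

Two derived quantities close the loop between geometry and data:

* **Broadness** $b(f) = {}^2D(\hat{\boldsymbol\varphi})/S \in [1/S, 1]$
  (`broadness()`), the Hill-Simpson evenness of the contribution vector.
  For *random* positive functions $\cos\theta \approx \sqrt{b(f) b(g)}$
  (`cos_from_broadness()`), and against total biomass (broadness 1),
  $b(f) = \cos^2(P\pi)$ (`broadness_from_mismatch()`), which turns an
  observable mismatch proportion into an estimate of how evenly species
  contribute to a function. Both are approximations whose stated validity
  assumptions (random positive functions; random, unbiased perturbations)
  are part of the operation contracts.
* **The biomass-scaled angle** $\theta_\alpha$ (`scaled_angle()`), with
  $\cos\theta_\alpha = \langle\boldsymbol\varphi, \Lambda^{2\alpha}
  \boldsymbol\phi\rangle / (\lVert\Lambda^\alpha\boldsymbol\varphi\rVert
  \lVert\Lambda^\alpha\boldsymbol\phi\rVert)$ and $\Lambda =
  \mathrm{diag}(\mathbf{N})$, which is the relevant predictor when
  displacements take the form $\Delta\mathbf{N} = \Lambda^\alpha
  \boldsymbol\Delta$. It reduces exactly to the plain angle at
  $\alpha = 0$ or for even communities.

## The simulation protocol

The simulator generates the study conditions under which all quantitative
claims are tested, and its defaults *are* those conditions:

* richness $S$ uniform on $[20, 100]$; log-biomasses Normal$(0, \sigma)$
  with $\sigma$ uniform on $[1/2, 2]$ per community (`generate_community()`);
* displacements $\Delta N_i = \text{intensity} \times y_i \times
  N_i^\alpha$ with $x_i \sim$ Normal$(\mu, 1)$, $y_i = x_i /
  \sqrt{\tfrac1S\sum_j x_j^2}$, intensity uniform on $[0, 0.1]$ per
  perturbation, $\mu$ uniform on $[-0.3, 0.3]$ per community and $\alpha$
  uniform on $[0, 1]$ per perturbation when not fixed by the caller
  (`generate_perturbation()`, `run_mismatch_experiment()`);
* per-capita contributions lognormal with sd uniform on $[0, 1.3]$
  (`generate_function()`): sd 0 is total biomass, larger sd means narrower
  functions.

The bias parameter $\mu$ controls response diversity through the expected
negative-response fraction $\Phi(-\mu)$ (`expected_negative_fraction()`);
the realized summary is $\text{bias} = |\tfrac12 - \#\{i : \Delta N_i <
0\}/S|$ (`response_bias()`).

Numerical conventions worth stating:

* Linear responses are exact projections of the *unclipped* displacement;
  diversity responses are exact before/after differences of $^qD$ on the
  perturbed state clipped at zero. Clipping events are counted
  (`perturbed_state()`); at intensity $\le 0.1$ they are rare, and this
  split keeps linear projections exactly linear while keeping perturbed
  states valid community states. Diversity responses never use the
  gradient linearization — the gradient is used only for *predictions*,
  so the simulations genuinely test it.
* Exactly-zero responses are tri-state (`observed_sign()`) and excluded
  from mismatch tallies. With continuous data ties are rare; with richness
  columns under weak perturbations they are the norm (richness only moves
  when a species is driven extinct), and silently coercing them to one
  sign would bias proportions.
* Angles live in $[0, \pi]$ radians and every arccos argument is clamped
  to $[-1, 1]$; the $q = 1$ Hill diversity and gradient use the analytic
  Shannon limits rather than a numerical $q \to 1$ excursion, which
  removes a tolerance knob. The gradient at an even community (any
  $q > 0$) is the zero vector and is flagged degenerate instead of being
  normalized into a direction; richness ($q = 0$) is rejected because it
  has no informative gradient at interior states.

A small demonstration of the central law:

```{r theta-pi}
set.seed(1)
N <- generate_community(c(40, 40), c(1, 1))
f <- generate_function(40, 1)
g <- generate_function(40, 1)
ex <- run_mismatch_experiment(N, list(f = f, g = g),
                              n_perturbations = 5000, mu = 0, alpha = 0)
ex$pairs[, c("proportion", "predicted")]
```

## Estimators and calibration curves

`estimate_broadness()` inverts $b = \cos^2(P\pi)$ at the observed
proportion and transforms a 95% Wilson score interval for $P$ through the
same map (Wilson rather than Wald for its small-sample behaviour; the
interval is the only uncertainty statement the data support, since effect
sizes carry no usable replication structure here). An observed $P > 0.5$
violates the positive-direction assumption; the estimate is reported as
the boundary value 0 with an explicit flag rather than following the
re-rising branch of $\cos^2$, which would silently misread the geometry.

The bias and scaling estimators invert simulation-built *calibration
curves* (`build_calibration_curve()`): mean mismatch signal on a parameter
grid, regularized to be nondecreasing by isotonic regression so that
piecewise-linear inversion is well defined (raw Monte-Carlo means jitter).
The curves are simulation-generated rather than closed-form because only
their monotonicity and endpoints are theoretically pinned down; they are
fully seeded and serialize to JSON with their simulator settings as
provenance (`write_calibration()`). Values outside a curve's fitted range
return the boundary with an `extrapolated` flag.

* `estimate_response_consistency()` converts an observed proportion into
  the relative deviation $(P_{\text{pred}} - P_{\text{obs}}) /
  P_{\text{pred}}$ from the $\theta/\pi$ baseline
  (`relative_deviation()`) and maps it to $\hat\mu$, also reported on the
  expected-bias scale $|\tfrac12 - \Phi(-\hat\mu)|$. The baseline
  $\theta$ must be supplied — from known contributions or from broadness
  via $\sqrt{b_f b_g}$.
* `estimate_biomass_scaling()` maps the raw biomass-vs-diversity mismatch
  proportion to $\hat\alpha$; proportions above one half already certify
  $\alpha > 0$, since only biomass scaling pushes a positive function and
  a diversity metric into systematic opposition.

Both report, alongside the point estimates, the assumption-free *relative
ranking* of perturbation classes (`rank_classes()`): at a fixed property
pair, a lower mismatch proportion means lower response diversity (or
weaker scaling). The rankings are invariant to any monotone recalibration
of the curves, which is why they are the primary empirical claim the
package makes on real data.

## The empirical pipeline

The pipeline ingests long-format effect-size tables — one row per (study,
perturbation, property) with $\mathrm{RR} = \ln(X_t/X_c)$
(`log_response_ratio()`) — and never filters on statistical significance:
a variance column is parsed and ignored, because there is no reason to
expect mismatch proportions to differ between significant and
non-significant effects.

`build_mismatch_matrix()` applies the tri-state sign rule pairwise and
masks pairs with fewer than `min_pairs` (default 10) valid shared
perturbations; masked means absent, never zero. All other filters
(broadness report: at least 20 shared perturbations spanning at least 5
factor types, with nutrient-matched factors excluded per the configurable
`default_nutrient_exclusions()` map; class reports: at least 5 shared
observations) are pure row selections, so weakening them only adds rows
and never changes a retained proportion.

`validation_test()` asks whether the matrix is consistent with *any*
arrangement of directions in a common phase space: each unmasked pair is
held out in turn, the remaining cosines $G_{ij} = \cos(\pi P_{ij})$ are
completed by alternating projections onto rank-$r$ positive-semidefinite
matrices with unit diagonal (truncated eigen-embedding, multi-start
because the rank constraint is nonconvex), and the held-out proportion is
predicted as $\arccos(\hat G_{ij})/\pi$. The rank defaults to
$\min(P - 1, 5)$ since the true phase-space dimension is unknown;
`validation_rank_sweep()` emits the sensitivity check. A strong
predicted-vs-observed correlation licenses the phase-space reading; a weak
one does not refute it, because the completion itself can introduce
artefacts (it is reliable when properties genuinely occupy a
low-dimensional cone and the matrix is well filled, and degrades when the
held-out entry is barely determined by the rest). Grouping by biome is the
recommended default: pooling heterogeneous systems mixes incompatible
phase spaces, and the synthetic experiments reproduce exactly that
degradation.

`similarity_network()` lays the properties out with the Kamada-Kawai
cost using mismatch proportions as target distances (deterministic: the
optimizer starts from a fixed circular arrangement), and masked pairs are
reached through shortest paths.

## The synthetic-data generator

`default_design()` / `generate_dataset()` emulate the statistical
structure of a global-change research synthesis: biomes with their own
planted contribution directions shared across studies within the biome,
factor classes with their own $(\mu, \alpha)$, intensities on $[0, 0.1]$,
and missing-at-random dropout (20% at the `paper_like` scale) so the
observation-count filters are actually exercised. The `paper_like` scale
(2 biomes × 2 studies, 6 factor classes × 80 perturbations per study, 13
properties) mirrors the magnitudes of the soil synthesis the pipeline
targets; `smoke` is a seconds-scale miniature. The factor defaults encode
the qualitative pattern reported for such experiments — land-use
conversion consistent and strongly biomass-scaled ($\mu = -0.3, \alpha =
0.9$), warming and enrichment diverse and weakly scaled — and were fixed
once as the generator's study conditions.

What the generator does *not* emulate: within-study variance structure,
correlated dropout (real sparsity is study-driven, not independent per
cell), temporal dynamics, state-dependent contributions, or biotic
interactions. Passing recovery tests on this generator therefore shows
that the estimators invert the stated generative model at realistic
sample sizes — not that real effect-size tables satisfy that model; the
validation test exists precisely to check the latter on a given dataset.

Ground truth (true broadness, pairwise angles, factor parameters,
per-perturbation realized bias) is emitted alongside the table, and the
planted broadness is exactly `broadness()` of the planted directions, so
every pipeline stage has an end-to-end recovery test with no external
data.

## Problem sizes and test design

The quantitative checks run at: 10,000 perturbations per fixed angle for
the $\theta/\pi$ law (three binomial standard errors); 5,000 for
broadness round trips (±0.05); 50 replicate communities for the bias
suppression and $\alpha$-monotonicity claims; calibration grids of 9-11
points × 20 communities × 800 perturbations with 100 synthetic datasets
per recovery Spearman; and 9 properties in rank-3 cones × 2,000
perturbations per biome for the validation contrast. These sizes were
chosen so each Monte-Carlo claim is resolved with an order of magnitude
of headroom while the whole suite stays desk-scale.

## Known limitations

* Equation-level approximations: $\sqrt{b_f b_g}$ is an average-case
  statement over random positive functions, not a pairwise identity;
  $\theta/\pi$ assumes isotropic unbiased displacements, and every
  departure from that assumption is information the estimators consume —
  but bias ($\mu$) and scaling ($\alpha$) acting together are not
  separable from a single pair's proportion.
* The Gram completion can be inconclusive on sparse or high-rank
  matrices even when the phase-space picture holds.
* Mismatch-based estimates need moderate observation counts: below ~20
  shared observations the Wilson intervals are wide, which is why the
  reports carry `n` and eligibility flags instead of bare point
  estimates.
* Richness responses are ties under weak perturbations, so richness
  participates in the pipeline only where perturbations actually remove
  species.
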