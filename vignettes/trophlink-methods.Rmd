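---
title: "Methods: models, parameters and design choices in trophlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in trophlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`trophlink` analyses species assemblages observed at two linked trophic
levels over a common set of sites, asking how much of each community's
structure is attributable to abiotic filtering, to the other trophic level,
and to their interplay. This vignette documents the statistical machinery,
the tunable parameters, the synthetic-data generator that backs the test
suite, and the places where the design was genuinely open — together with
the choices made and why.

## The multiblock model

### Formulation

Let $Y$ ($n$ sites $\times$ $q$ species, centred) be the response community
and $X_1, \dots, X_K$ the predictor blocks (centred, unit-scaled per
variable). Writing $P_k$ for the orthogonal projector onto the current
column span of block $k$, each model dimension $h$ extracts:

1. the response weights $v(h)$, the dominant eigenvector of
   $\sum_k Y' P_k Y$, and the response component $u(h) = Y v(h)$;
2. block components $t_k(h) \propto P_k\, u(h)$, normalised to unit length
   within each block's span;
3. the global component $t(h) = \sum_k a_k(h)\, t_k(h)$ with
   $a_k(h) \propto u(h)' t_k(h)$ and $\sum_k a_k(h)^2 = 1$.

After each dimension every block is replaced by its residual on $t(h)$; the
response is never deflated. Because $u' P_k u \ge 0$, the weights $a_k$ are
nonnegative, and because later components live in the deflated spans, the
global components are mutually orthogonal.

Two exact reductions anchor the implementation and are enforced by the test
suite at tolerance $10^{-8}$:

* **Single block.** For $K = 1$ the per-dimension explained variances
  $\lambda(h)$ equal the eigenvalue proportions of the RDA of $Y$ on $X$ —
  the method is a multiblock generalisation of redundancy analysis, and the
  block-component normalisation (unit norm within the span, via projector)
  is precisely what makes this hold. Normalising the weight vector instead
  breaks it.
* **Saturation.** With $h$ equal to the rank of the concatenated blocks,
  $\sum_h \lambda(h)$ equals the RDA $R^2$ of $Y$ on all predictors at once.
  This is why the response is never deflated; deflating $Y$ sacrifices the
  property.

### Importance indices

With $\lambda(h)$ the additional proportion of response variance explained
by $t(h)$:

$$\mathrm{BlockImp}_k = \frac{\sum_h \lambda(h)\, a_k(h)^2}{\sum_h \lambda(h)},
\qquad
\mathrm{VarImp}_j = \frac{\sum_h \lambda(h)\, \big(a_k(h)\, w_{kj}(h)\big)^2}{\sum_h \lambda(h)},$$

where $w_k(h)$ are the unit-norm coefficients expressing $t_k(h)$ on the
(deflated) block variables. Both index families sum to one by construction,
so the natural significance references are the equal shares $1/K$ and
$1/P$. The $\lambda$-weighted cumulation is the one form we found that
simultaneously (i) sums to one, (ii) is invariant to block and variable
ordering, and (iii) degenerates correctly (a single-predictor model has
VarImp $= 1$); the exact weighting used by earlier multiblock software is
not published, so equivalence with it cannot be asserted — the properties
above are what the test suite pins.

### Dimensionality and uncertainty

`select_ncomp_cv()` uses repeated twofold cross-validation (default 100
random splits; the pipeline default is 20): the model fitted on one half
predicts the held-out community through the original-variable expression of
the global components, and the pooled RMSEP is averaged. The chosen $h$ is
the smallest within a relative tolerance ($10^{-6}$) of the minimum, with an
absolute floor of $10^{-9}$ times the response scale so that
machine-precision differences among exactly-zero errors (noiseless
responses) count as ties.

`mbra_bootstrap()` resamples sites with replacement (default $B = 1000$;
the pipeline default is 200, which keeps the full profile under half a
minute without visibly changing the intervals), refits, aligns dimension
signs by the correlation of global components, and reports percentile
intervals at the 95% level for every importance value. Replicates whose
refit fails (rank-deficient resamples) are dropped and counted.

### Forward selection

Each abiotic block is screened by forward selection under the
double-stopping rule: the model with all candidates must itself pass a
permutation test at $\alpha$ (otherwise nothing is selected), and selection
stops as soon as the best remaining candidate's permutation p-value exceeds
$\alpha$ (9,999 permutations by default) or the cumulative adjusted $R^2$
would exceed that of the all-candidate model. Permutation schemes: rows of
$Y$ for marginal tests, reduced-model residuals for the step tests. One
behavioural note: when the candidate pool is one true driver plus pure
noise, the all-candidate adjusted $R^2$ falls below the single-variable one
about half the time — the ceiling then (correctly, per the rule) blocks
selection. This is a property of the double-stopping rule itself, not of
this implementation.

The biotic block is never subjected to selection: it is always the first
two partial least-squares components (NIPALS, predictors unit-scaled,
responses centred; both deflated) of the focal response regressed on the
other community, entering the multiblock model as two ordinary variables.
If selection empties an abiotic block, the block is dropped, $K$ shrinks
and the $1/K$ threshold moves accordingly, with a warning. If selection
empties *every* abiotic block, Step 2 falls back to the full abiotic
variable set (again with a warning): selection is a parsimony device, and
the abiotic/biotic variance partition is still well defined without it.

## Variation partitioning

With adjusted $R^2$ (Ezekiel: $1 - (1 - R^2)(n-1)/(n-m-1)$, $m$ = predictor
rank) the fractions are
$[a] = R^2_{adj}(ab) - R^2_{adj}(b)$,
$[b] = R^2_{adj}(ab) - R^2_{adj}(a)$,
$[c] = R^2_{adj}(a) + R^2_{adj}(b) - R^2_{adj}(ab)$,
$[d] = 1 - R^2_{adj}(ab)$.
Negative adjusted fractions are reported as computed, never truncated, so
the additive identities hold to $10^{-10}$ on all inputs. Only $[a]$, $[b]$
and the full model are testable by permutation (999 by default; partial
tests permute reduced-model residuals); the shared fraction has no
permutation test and is reported untested. When one predictor set adds no
column span beyond the other (e.g. duplicated sets), the corresponding pure
fraction is exactly zero and untestable, and its p-value is `NA`.

## Co-occurrence analysis

The pair C-score $(R_a - S)(R_b - S)$ is compared against a fixed–fixed
null model: a sequential chain that proposes a uniformly random
$2 \times 2$ submatrix and swaps it when it is a checkerboard. Because the
proposal is symmetric, the stationary distribution is uniform over the
class of matrices with the given margins; the test suite verifies this by
exhaustive enumeration on a small matrix. We drive the chain with vegan's
compiled trial-swap sampler (`"tswap"`), noting that the plain sequential
swap variant (which hunts for a swappable unit at every step) is *not*
uniform on classes whose members contain different numbers of checkerboard
units — enumeration shows it missing half the class on a $3\times3$
example. Chain defaults: 1000 null matrices, 30,000 burn-in attempts, 1,000
attempts between samples; all configurable.

The CL criterion flags a pair when its observed score falls outside the
central 95% mass of its null distribution, with ties counted into the tail:
flag when $P(\text{null} \ge c_{obs}) \le 0.025$ or
$P(\text{null} \le c_{obs}) \le 0.025$. For the heavily tied discrete
C-score distributions this is the conservative reading of
confidence-limit screening; comparing against inclusive empirical quantiles
instead flags entire probability atoms and measurably inflates the Type I
rate (to roughly 13% in our calibration), while the tail rule keeps it at or
below the nominal 5%. Pairs with zero null spread are classified random,
flagged degenerate, and never significant.

The mean-Bayes filter addresses the multiplicity of screening thousands of
pairs: pooled null pair scores define 20 equal-width bins (top bin closed);
the expected count per bin is the mean number of pairs falling in it across
null matrices; and in every bin whose observed count exceeds expectation,
the excess — rounded to the nearest integer — most-extreme CL-flagged
pairs by $|SES|$ are retained. Rounding matters: truncating the excess
suppresses genuine single extreme pairs (excess 0.99 would keep none),
while always rounding up inflates the set on random data. The mean-Bayes
set is a subset of the CL set by construction, and simulations confirm it
is strictly smaller on average whenever the CL set is nonempty.

Pairwise screening is run on two stacked submatrices: `gc` (all generalist
consumers plus the most widespread producers — ranked by occupancy, ties by
total abundance, top $N$, default 88) and `sh` (all specialist consumers
plus the union of their matched hosts, exact species first, else any
congeneric producer present; specialists with no match are reported and
excluded). The "most widespread and abundant" criterion has no published
operationalisation; occupancy-then-abundance ranking is our stand-in and is
configurable.

## The synthetic generator

The generator emulates the structure of a vineyard survey at desk cost: 68
sites; six abiotic blocks of 5/5/9/5/6/6 variables; 120 producer and 80
consumer species (30 specialists) before filtering; bottom-up coupling 0.7;
one latent standard-normal gradient per block, with block variables
`loading * gradient + N(0, 0.5)`; per-block effect shares (default:
topography-dominant, 0.7) weighting the gradients into the composite
gradient that drives the producer community.

Producers follow Gaussian niches: expected percent cover
$\mu_{is} = A \exp(-(g_i - o_s)^2 / 2\sigma^2)$ with optima spread
uniformly along the composite gradient, multiplicative log-normal noise
(sd 0.6 on the log scale), covers capped at 100 and recorded as absent
below a detection floor of 1% — this yields realistic occupancy patterns
and gradient turnover (hence matrix-level segregation). Consumers are
Poisson counts around a mixture: `coupling` times a biotic driver
(specialists: their host plant's abundance; generalists: a random-weighted
plant composite) plus `1 - coupling` times a Gaussian niche on a
*consumer-specific* latent axis. Running the consumers' abiotic term on its
own axis (rather than the shared composite) is deliberate: it makes the
coupling parameter a clean switch, so that at `coupling = 0` the two
communities are statistically independent — a property the test suite
asserts at $n = 2000$ sites — while at high coupling the consumers inherit
the producers' abiotic structure, which is exactly what routes variance
into the shared fraction $[c]$ in the partition.

Cover values are continuous percentages; ordinal cover-scale semantics
(e.g. decimal scales used in field botany) are not modelled. Neither are
spatially explicit landscapes, multi-season phenology, or
sampling-technique effects: passing recovery tests on these data shows the
machinery recovers planted structure of this generative kind, not that any
field dataset satisfies the generator's assumptions.

Planted co-occurrence pairs (`generate_binary_cooccurrence()`) overwrite
the two species' rows after background Bernoulli fill — segregated pairs
get complementary occupancy (zero shared sites, C-score $R_a R_b$),
aggregated pairs identical occupancy (C-score 0) — guaranteeing exact
checkerboard/nesting for the oracle tests.

## Numerical choices

* Rank decisions use QR with relative tolerance $10^{-10}$; within-block
  rank deficiency is absorbed by the projector, which is the sense in which
  the multiblock model "restricts the problem of multicollinearity".
* Constant predictor columns abort `rda_fit()` (naming the column) but are
  dropped with a warning by `forward_select()`; exact duplicates abort
  `rda_fit()` and are harmless to selection and to `varpart2()`, whose
  global test runs on the orthonormal span basis.
* Permutation p-values use the add-one estimator
  $(1 + \#\{F^* \ge F\}) / (n_{perm} + 1)$ and therefore live in
  $[1/(n_{perm}+1),\, 1]$.
* Every stochastic step derives a named child seed from the master seed
  (`derive_seed()`, a 31-bit string hash), so pipeline reruns are
  bit-identical and individual steps can be re-executed in isolation.
* Degenerate null ensembles (no swappable checkerboard) warn and return
  copies of the input; the matrix-level test then reports p = 1 with a
  degeneracy flag rather than a spurious significance.

## Problem sizes used in the tests

The test suite exercises the framework at sizes chosen to make the
statistical properties measurable at desk cost: oracle equivalences on
$30 \times 10$ predictor and $30 \times 4$ response matrices; Type I
calibration of the matrix-level test on 200 random $15 \times 20$ matrices
with 1000 nulls each; planted-pair recovery on 50 fixtures of 14 species
by 68 sites with 1000 nulls; block-importance recovery on 50 replicates of
the 68-site profile with a 0.7 effect share on one block; and mean-Bayes
restrictiveness on 100 random matrices. The end-to-end pipeline smoke test
runs a reduced profile (40 sites, 20 + 14 species) with a permissive
selection level, since at that size almost no abiotic variable passes a
5% permutation test — the full profile in `scripts/acceptance.R` uses the
study-shaped sizes and defaults.

## Known limitations

* The mbRA importance weighting reproduces the printed constraints of the
  method it follows (indices sum to one, thresholds $1/K$ and $1/P$) but
  cannot be verified against the original software's unpublished weighting.
* The CL criterion's original "standard contour length" computation has no
  published formula; the tail-proportion reading implemented here is pinned
  by its measurable properties (nominal Type I, planted-pair recovery), not
  by equivalence with the original program. The same holds for the
  mean-Bayes bin count (20) and excess-allocation rule, which the original
  program does not document.
* Adjusted-R² fractions can be (correctly) negative; users comparing
  fractions across responses should keep the differing $[d]$ in mind.
* The framework is correlational throughout: aggregation or segregation
  surviving both screens is evidence of nonrandom association, not of a
  mechanism.
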