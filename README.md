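# trophlink

Disentangling abiotic and biotic drivers of species assemblages observed at
two linked trophic levels — for example plant communities and the
phytophagous leafhoppers feeding on them, surveyed over the same set of
sites. `trophlink` implements a three-step statistical framework for
community ecologists who have, per site, (i) abundance tables for both
communities, (ii) environmental predictors organised in thematic blocks
(management, topography, soil, vegetation structure, landscape composition at
several radii, ...), and (iii) species metadata on diet specialisation
(generalist/specialist guilds and host-plant associations).

## The three steps

**Step 1 — multiblock redundancy analysis (mbRA).** Classical RDA cannot
handle many, possibly collinear predictors spread over K thematic blocks.
mbRA extracts model dimensions h = 1, 2, ...: on each dimension the response
weight vector v(h) is the dominant eigenvector of Σₖ Y′PₖY (Pₖ the projector
onto the current span of block k), giving a response component u(h) = Y v(h);
each block contributes a unit-norm block component tₖ(h), the projection of
u(h) onto the block's span; and the global component

    t(h) = Σₖ aₖ(h) · tₖ(h),   aₖ(h) ∝ cov(u(h), tₖ(h)),  Σₖ aₖ(h)² = 1

summarises all blocks at once. Blocks (never the response) are deflated on
t(h) before the next dimension, so the global components are mutually
orthogonal; with a single block the method reduces exactly to RDA, and at
full predictor rank its cumulative explained variance equals the RDA R² of
the concatenated predictors. λ(h) is the additional proportion of response
variance explained by t(h). Two indices summarise the fit, each summing to 1:

    BlockImp_k = Σ_h λ(h) aₖ(h)² / Σ_h λ(h)        (threshold 1/K)
    VarImp_j   = Σ_h λ(h) (aₖ(h) w_kj(h))² / Σ_h λ(h)   (threshold 1/P)

with w_k(h) the unit-norm block weights. Dimensionality is chosen by repeated
twofold cross-validation; bootstrap resampling of sites gives tolerance
intervals for both indices. Before fitting, each abiotic block is screened by
permutation-based forward selection with the double-stopping rule (a global
test of all candidates plus an adjusted-R² ceiling), and the *other*
community enters as a biotic block: the first two partial least-squares
components of the focal response regressed on the other community.

**Step 2 — variation partitioning.** The community variance splits into four
additive fractions of adjusted R² via partial RDA: pure abiotic `[a]`, pure
biotic `[b]`, shared `[c] = adjR²(abiotic) + adjR²(biotic) − adjR²(both)`,
and unexplained `[d]`. `[a]` and `[b]` are testable by permutation; a large
`[c]` indicates biotic structure that is itself shaped by the environment.

**Step 3 — co-occurrence screening.** On presence–absence matrices, the
C-score of a species pair with row totals R_a, R_b and S shared sites is
(R_a − S)(R_b − S); high values mean segregation, low values aggregation.
Observed scores are compared against a fixed–fixed null model (sequential
trial-swap chain preserving every row and column total; uniform over the
fixed-margin class). Matrix-level tests describe whole-community structure;
pairwise screening flags individual pairs by confidence limits (CL) and then
tightens the set with the empirical mean-Bayes criterion, which keeps only
the per-bin excess of observed pairs over the null expectation. Flagged
pairs are classified aggregated/segregated and cross-tabulated as
plant–plant, leafhopper–leafhopper, or plant–leafhopper.

A synthetic-data generator (`simulate_vineyard()` and friends) produces
study-shaped data — 68 sites, six abiotic blocks of 5/5/9/5/6/6 variables,
coupled producer/consumer communities with Gaussian niches, guild structure,
bottom-up coupling, and planted aggregated/segregated pairs — with the
ground truth recorded, so every recovery claim in the test suite is checked
against known structure.

## Worked example

```r
library(trophlink)

sim <- simulate_vineyard(seed = 11, n_sites = 68, n_plants = 40,
                         n_hoppers = 25, n_specialists = 8)
plants  <- hellinger_transform(occupancy_filter(log_transform_cover(sim$plants), 5))
hoppers <- hellinger_transform(occupancy_filter(sim$hoppers, 5))
ids   <- c(setdiff(names(plants), "site_id"), setdiff(names(hoppers), "site_id"))
meta  <- sim$meta[sim$meta$species_id %in% ids, ]
hosts <- sim$hosts[sim$hosts$leafhopper_id %in% ids, ]

cfg <- trophlink_config(seed = 11, n_perm_select = 999, bootstrap_b = 0,
                        n_null = 500)
report <- run_all(plants, hoppers, sim$blocks, meta, hosts, cfg)
print(report)
#> Three-step assemblage analysis
#>
#> [plants] multiblock model: h = 1, explained variance 61.6%
#>    Explained variation: 61.2% ([a] 5.8%, [b] 12.5%, [c] 42.9%, [d] 38.8%);
#>    ordering among fractions: shared > pure biotic > pure abiotic.
#>
#> [leafhoppers] multiblock model: h = 1, explained variance 38.6%
#>    Explained variation: 45.7% ([a] 5.8%, [b] 11.4%, [c] 28.5%, [d] 54.3%);
#>    ordering among fractions: shared > pure biotic > pure abiotic.
#>
#> Matrix-level C-score: plants SES 35.26 (p_upper 0.001996); leafhoppers SES 0.18 (p_upper 0.521)
#> GC pairs: 204 CL-flagged, 92 mean-Bayes-flagged of 1596
#> SH pairs: 7 CL-flagged, 7 mean-Bayes-flagged of 120
```

Reading this output: the multiblock model explains 61.6% of plant community
variance on one cross-validated dimension; the variance partition attributes
most of the explained variation to the shared abiotic–biotic fraction `[c]`
(42.9%), i.e. biotic structure aligned with the environmental gradient, as
expected for a generator with bottom-up coupling 0.7. The plant community is
strongly segregated at the matrix level (SES 35.3, upper-tail p ≈ 0.002) —
species turn over along the gradient — while the leafhopper matrix is
indistinguishable from the null. Of the 1596 generalist–common-plant (GC)
pairs, 204 pass the CL screen and 92 survive the stricter mean-Bayes filter.

Fitted objects follow broom conventions:

```r
head(tidy(report$step1$plants$model), 6)
#> # A tibble: 6 × 6
#>   level    term        block  importance threshold flag
#>   <chr>    <chr>       <chr>       <dbl>     <dbl> <lgl>
#> 1 block    Top         Top        0.469       0.5  FALSE
#> 2 block    Biotic      Biotic     0.531       0.5  TRUE
#> 3 variable Top_v4      Top        0.273       0.25 TRUE
#> 4 variable Top_v1      Top        0.195       0.25 FALSE
#> 5 variable Biotic_pls1 Biotic     0.448       0.25 TRUE
#> 6 variable Biotic_pls2 Biotic     0.0834      0.25 FALSE
```

(at this seed only the topography and biotic blocks survive forward
selection, hence K = 2 and thresholds 1/2 and 1/4). `autoplot()` methods
draw importance bars with thresholds and tolerance intervals, variation
fractions, and SES/C-score screens; `glance()` gives one-row summaries.

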