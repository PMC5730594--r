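---
title: "Functional redundancy and sensitivity under extinction scenarios: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional redundancy and sensitivity under extinction scenarios: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdextinct)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what the synthetic tests do and do
not demonstrate about real data.

## The model

### Functional space and dendrogram

An assemblage's functional structure is summarized on a dendrogram built
once over the whole species pool. Species are coded on five coarse
categorical traits (`fish_trait_schema()`): body size (six ordered length
classes, 0–8 cm up to > 80 cm), vertical position (benthic / non-benthic),
trophic group (seven classes), spawning habitat (six classes), swimming
mode (eight classes). Pairwise dissimilarity is the classical Gower index
for mixed types: the unweighted mean over traits of a 0/1 mismatch for
nominal traits and a range-scaled rank difference |rᵃ − rᵇ|/(L − 1) for an
ordered trait with L declared levels. Ordered levels are treated as equally
spaced ranks — the standard coding when no quantitative spacing is
declared. All dissimilarities are therefore in [0, 1], and two species are
at distance 0 exactly when their trait vectors coincide.

The dendrogram is UPGMA (average linkage): the merge height of two
clusters is the mean of all between-cluster dissimilarities, which yields
an ultrametric tree with leaves at height 0. Fidelity is checked with the
cophenetic correlation between tree-implied and original distances
(`cophenetic_correlation()`); 1 means the input was already ultrametric.

### Functional richness

FD of a species subset is the total branch length of the minimal subtree
spanning the subset, connected *up to the subset's most recent common
ancestor* — not the global root. This convention was genuinely open (the
branch-length index is sometimes rooted); we adopt the MRCA form because
the extinction simulation must run FD down to a single remaining species,
and only the MRCA convention makes FD(singleton) = 0 so that every loss
curve terminates exactly at zero. `functional_richness(..., from =
"root")` exposes the rooted alternative. A dendrogram-based FD is used
(rather than convex-hull volumes) precisely because it stays defined for
assemblages with fewer species than trait dimensions, which a
species-subtraction simulation inevitably reaches.

### Loss curves and AUC

A trajectory removes species one at a time (or in Red-List clusters); after
each step the residual FD proportion y is recorded against the proportion
of species lost x. The abscissa was another open point, since the area
under the curve has no universal normalization. The default divides the
removal count by S − 1, so the terminal *observable* state — one species
left, FD = 0 — sits at x = 1; a two-species assemblage then has AUC
exactly 1/2, which we take as the natural reference. The alternative
(divide by S, append a terminal point at (1, 0)) is available via
`axis = "s"` everywhere; both conventions agree that curves start at (0, 1)
and end at (1, 0).

### Scenarios and the null

Six scenarios per assemblage (`run_scenarios()`):

* **random** — 999 uniform removal orders; their mean AUC is the
  *redundancy index* of the assemblage;
* **best / worst** — greedy per-step extremes: remove the species whose
  loss decreases FD least / most (not globally optimal orders; the greedy
  form is the operational definition here);
* **abundance** — rarest first (ascending standardized density);
* **trait** — most vulnerable first (descending 0–100 intrinsic
  vulnerability score);
* **IUCN** — whole Red-List categories removed in decreasing threat order.

Directional scenarios are standardized against the null:
SES = (Obs − Mean_r)/sd_r with the *sample* SD of the replicate AUCs. The
abundance- and trait-based scenarios share the assemblage's single
999-replicate sequential null (one null per assemblage, rather than fresh
draws per scenario: the comparisons are then mutually consistent and the
cost is halved); the IUCN scenario is compared to random partitions with
the same cluster sizes, removed in the same order. The Red-List severity
order is fixed as CR > EN > VU > NT > LC, with data-deficient and
not-evaluated species folded into LC (removed last).

## Numerical choices

* **Tie-breaking.** UPGMA merges and greedy removals break ties
  lexicographically by species identifier (clusters ordered by their
  smallest member), making trees and trajectories bit-reproducible.
  Floating-point noise is absorbed by a 1e-12 relative tolerance when
  detecting tied merge distances and a 1e-9 tolerance on tied FD values in
  the greedy step; true Gower-derived differences are orders of magnitude
  larger.
* **Per-assemblage computation.** All trajectory work runs on the
  assemblage's induced sub-dendrogram (UPGMA of the cophenetic submatrix,
  which reconstructs the induced tree exactly; equal-height tie resolutions
  do not affect branch-length sums). The 999-replicate null uses a
  closed-form batched AUC — for a removal order with positions pos, the
  edge above node v survives until the last removal among its leaves, so
  Σₖ FD_root(k) = Σᵥ lenᵥ·tᵥ with tᵥ the nodewise maximum of pos, plus an
  MRCA-height correction read off the ancestor path of the last-removed
  leaf. Property tests pin this against the step-by-step curve evaluation
  to 1e-12.
* **Degenerate assemblages.** If all species of an assemblage share one
  trait vector, FD = 0 and loss curves are undefined; such assemblages
  raise a typed condition, are skipped, and are counted in the study's
  `skipped` table. A zero-variance null (e.g. a single IUCN cluster) makes
  SES undefined; it is flagged `NA` and excluded from the sign tests.
* **Seeds.** One master seed; each assemblage gets a child seed derived
  from the master and its site id by multiplicative (Lehmer-style) hashing,
  so results do not depend on processing order and near-identical site ids
  do not produce correlated random streams.

## Statistics

The FD–richness relationship is tested by OLS of FD on SR and SR²; the
quadratic term's partial t test (equivalently the one-df partial F test)
gives its p-value. A point that required a decision: a *significant*
quadratic term alone does not indicate saturation — the parabola must also
be concave. The sign convention is ambiguous in parts of the applied
literature, so `saturation_regression()` reports the raw quadratic
coefficient, a concavity flag, and declares "saturated" only when the term
is significant *and* negative. Redundancy–richness association uses
Spearman rank correlation; cross-system comparisons use Kruskal–Wallis with
pairwise Wilcoxon post hoc tests under Bonferroni correction (exact
distributions where sample sizes allow, normal approximation with
continuity correction otherwise) and a compact letter display; SES values
are tested against zero with one-sided (less) Wilcoxon signed-rank tests.
All of these call the corresponding base-R implementations.

## The synthetic generator

`generator_config()` defaults emulate the monitoring conditions the
pipeline targets: a 271-species pool; 302 lakes, 869 river reaches and 49
estuaries; per-system richness ranges 3–19, 3–31 and 4–57 with right-skewed
draws calibrated to mean richness 8.9, 7.9 and 26.7 (discretized lognormal,
sdlog 0.55, clipped to the range); lognormal abundances (sdlog 1.5) giving
a few dominants and a long rare tail; region and category labels drawn with
realistic proportions.

Trait categories are sampled independently per trait with strongly
dominant frequencies (top category roughly 40–50% per trait — small-to-mid
sized sub-carangiform insectivores/omnivores and lithophilic spawners
dominate, with thin tails over rare categories such as parasitic feeders
or rajiform swimmers). The dominance structure matters: it clumps most of
the pool into a few heavily occupied functional groups, so a species in a
rare trait region is functionally distinct both in the pool *and* within a
small subsampled assemblage. With weakly skewed frequencies, pairwise
Gower distances concentrate and pool-level distinctiveness is destroyed by
subsampling — the coupling below would then be undetectable at assemblage
scale by construction, not because the method fails.

Extinction drivers: each species' functional *distinctiveness* is its
leave-one-out FD loss on the pool dendrogram (exactly the quantity the
worst-case scenario exploits). Intrinsic vulnerability (0–100) is generated
by a Gaussian copula on normal scores so its rank correlation with
distinctiveness approximates the configured `coupling`; Red-List categories
are assigned by vulnerability quantiles with configurable pool proportions
(default 72% LC, 10% NT, 9% VU, 6% EN, 3% CR — a deliberately
threat-enriched pool, chosen once as plausible for a fauna with a
substantial threatened fraction).

### What the generator does and does not emulate

It reproduces: richness ranges and means per system, heavy-tailed
abundance, a tunable vulnerability–distinctiveness coupling, and Red-List
composition. It does **not** reproduce: environmental filtering or nested
assembly (species are sampled uniformly, so synthetic redundancy does not
*increase* with richness the way real communities' redundancy can),
spatial structure, co-occurrence of ecologically similar species, or
non-native introduction history. Consequently, passing the end-to-end
tests shows the *pipeline* recovers a coupling that is present and stays
calibrated when it is absent; it does not validate ecological conclusions
about any particular real system. Two corollaries seen in synthetic runs:
redundancy–richness correlations are near zero or negative (uniform
sampling), and with very many assemblages the SES sign test can detect the
small skew of the null AUC distribution itself — the SES *mean* is
centered at zero under no coupling (verified), but its median need not be,
which is worth remembering when interpreting signed-rank p-values at large
n.

## Problem sizes used in the tests

The test suite exercises the exact 3-species worked fixture; random
fixtures of 10–25 species; 50 small assemblages (S ≤ 6) for
Monte-Carlo-versus-enumeration and greedy-versus-brute-force checks; 200
river-like assemblages for null-SES calibration and for coupling recovery
at 0.8 versus 0 (999-replicate nulls throughout); and 100–500 simulation
replicates for the regression power and type-I checks. These sizes were
chosen to make the checks statistically meaningful while keeping a full
test run in a few minutes on one CPU; `scripts/acceptance.R` additionally
runs the complete default-scale study (1220 assemblages).

## Known limitations

* Missing trait values are rejected, not imputed: the trait table must be
  complete.
* Greedy best/worst are per-step extremes; globally optimal orders are out
  of scope.
* The generator's uniform species sampling is the main realism gap (see
  above); richness-dependent redundancy patterns should not be read off
  synthetic runs.
* Catchability corrections and seasonal weighting of surveys are out of
  scope; abundance standardization is a plain counts-per-effort ratio with
  system-specific units (estuaries per 1000 m², rivers per m², lakes per
  m² per night), and repeated samplings of a site are pooled as total
  counts over total effort (effort-weighted, invariant to splitting a
  sampling into proportional parts).
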