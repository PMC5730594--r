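# fdextinct

Functional redundancy and sensitivity of ecological assemblages under
species-extinction scenarios.

## The problem

When species are lost from a community, how fast does its *functional*
diversity erode? That depends on two things: how much trait redundancy the
assemblage carries (how many species back each other up functionally), and
the *order* in which species disappear — extinctions are rarely random, and
if the most vulnerable species carry singular trait combinations, function
collapses much faster than chance would suggest. `fdextinct` implements a
complete simulation pipeline to quantify this for assemblages described by
mixed categorical/ordered traits (its defaults are tuned to European
continental fish communities of lakes, rivers and estuaries, but nothing is
fish-specific).

## The method

1. **Functional space.** Species are described by five coarse traits (body
   size in six ordered classes; vertical position; trophic group; spawning
   habitat; swimming mode). Pairwise dissimilarity is the Gower index: the
   unweighted mean over traits of per-trait contributions, 0/1 mismatch for
   nominal traits and |rᵃ − rᵇ|/(L − 1) for an ordered trait with L ranked
   levels.
2. **Functional dendrogram.** UPGMA (average linkage) clustering of the
   Gower matrix, validated by the cophenetic correlation *c* between
   tree-implied and original distances. The functional richness FD of any
   species subset is the total branch length of the minimal subtree spanning
   it up to its most recent common ancestor — so FD(one species) = 0 and FD
   can never increase when a species is removed.
3. **Extinction scenarios.** For each assemblage, species are removed
   sequentially (or in Red-List clusters) and FD is recomputed after every
   step, giving a loss curve of residual FD proportion against the
   proportion of species lost. The area under that curve (AUC) summarizes
   sensitivity: low AUC = function lost early. Six scenarios: random
   (999 trajectories, mean AUC = the redundancy index), greedy best- and
   worst-case, abundance-based (rarest first), trait-based (most vulnerable
   first, intrinsic vulnerability 0–100), and IUCN-based (clusters removed
   CR → EN → VU → NT → LC).
4. **Inference.** Directional scenarios are compared to the random null by
   the standardized effect size, SES = (Obs − Mean_r)/sd_r; negative SES
   means function erodes faster than random extinction. One-sided Wilcoxon
   signed-rank tests ask whether SES < 0 across assemblages;
   Kruskal–Wallis/Wilcoxon-Bonferroni compare systems; a quadratic
   regression of FD on species richness flags saturation (redundancy
   accumulating in species-rich assemblages).

A synthetic-data module generates species pools, assemblages (realistic
richness ranges and heavy-tailed abundances per system) and
extinction-driver covariates with a *tunable* rank coupling between
species' vulnerability and their functional distinctiveness, so the whole
pipeline is testable end-to-end without any survey download.

## Worked example

The three-species toy assemblage with d(A,B) = 0.2, d(A,C) = d(B,C) = 0.6:

```r
library(fdextinct)
toy <- matrix(c(0, 0.2, 0.6,
                0.2, 0, 0.6,
                0.6, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
tree <- build_upgma_dendrogram(toy)
print(tree)
#> Functional dendrogram (UPGMA): 3 species, root height 0.6
#> Total branch length: 1.4

functional_richness(tree, c("A", "B"))
#> [1] 0.4

worst <- greedy_trajectory(tree, c("A", "B", "C"), "worst")
cv <- loss_curve(tree, c("A", "B", "C"), worst)
cv
#>     x         y
#> 1 0.0 1.0000000
#> 2 0.5 0.2857143
#> 3 1.0 0.0000000
trapezoid_auc(cv)
#> [1] 0.3928571

redundancy_index(tree, c("A", "B", "C"), n = 999, seed = 1)
#> [1] 0.5844773
null <- null_auc_distribution(tree, c("A", "B", "C"), n = 999, seed = 1)
standardized_effect_size(trapezoid_auc(cv), null)
#> [1] -1.426336
```

Reading: removing C first (the worst case) wipes out 71% of functional
richness with the first of two removals (y drops to 0.286), giving
AUC ≈ 0.393 against a random-extinction expectation of ≈ 0.584 — an SES of
−1.43, i.e. this order erodes function about one and a half null standard
deviations faster than chance. The exact enumeration over all 3! = 6 orders
(`exhaustive_auc_oracle`) gives mean 7/12 ≈ 0.5833, which the 999-replicate
Monte-Carlo estimate approaches.

A full synthetic study (pool, dendrogram, all six scenarios over all
assemblages, statistics, CSV/Newick outputs):

```r
cfg <- run_config(generator = generator_config(coupling = 0.8),
                  n_random = 999, seed = 1)
study <- run_study(cfg, verbose = TRUE)
write_study_outputs(study, "study_out")
```

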