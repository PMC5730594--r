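toy_sp <- c("A", "B", "C")

test_that("loss curves reproduce the hand-computed toy points", {
  tr <- toy_tree()
  cv <- loss_curve(tr, toy_sp, extinction_trajectory(list("C", "A")))
  expect_equal(cv$x, c(0, 0.5, 1))
  expect_equal(cv$y, c(1, 0.4 / 1.4, 0), tolerance = 1e-12)

  cv2 <- loss_curve(tr, toy_sp, extinction_trajectory(list("A", "B")))
  expect_equal(cv2$y, c(1, 1.2 / 1.4, 0), tolerance = 1e-12)

  # any two-species assemblage drops straight from (0,1) to (1,0)
  cv3 <- loss_curve(tr, c("A", "C"), extinction_trajectory(list("A")))
  expect_equal(cv3$x, c(0, 1))
  expect_equal(cv3$y, c(1, 0))

  expect_error(extinction_trajectory(list("A", "A")), "twice")
  expect_error(loss_curve(tr, toy_sp, extinction_trajectory(list("Z"))),
               "absent")
})

test_that("trapezoid AUC matches hand integrals", {
  expect_equal(trapezoid_auc(data.frame(x = c(0, 1), y = c(1, 0))), 0.5)
  tr <- toy_tree()
  expect_equal(
    trapezoid_auc(loss_curve(tr, toy_sp, extinction_trajectory(list("C", "A")))),
    0.25 + 0.5 * (0.4 / 1.4), tolerance = 1e-9)
  expect_equal(
    trapezoid_auc(loss_curve(tr, toy_sp, extinction_trajectory(list("A", "B")))),
    0.25 + 0.5 * (1.2 / 1.4), tolerance = 1e-9)
})

test_that("degenerate assemblages (zero FD) raise a typed condition", {
  cfg <- small_config(pool_size = 10, seed = 3,
                      redundancy_blocks = list(n_blocks = 1, block_size = 10))
  pool <- generate_species_pool(cfg)
  d <- gower_dissimilarity(pool, cfg$schema)
  tr <- build_upgma_dendrogram(d)
  sp <- rownames(pool)[1:4]
  expect_error(loss_curve(tr, sp, extinction_trajectory(as.list(sp[1:3]))),
               class = "fdextinct_degenerate")
})

test_that("random trajectories are seed-reproducible and cover edge cases", {
  tr <- toy_tree()
  t1 <- random_trajectories(toy_sp, n = 5, seed = 42)
  t2 <- random_trajectories(toy_sp, n = 5, seed = 42)
  expect_identical(t1, t2)
  expect_error(random_trajectories(toy_sp, n = 1), "n >= 2")

  # two species: every trajectory is the same up to labeling, AUC = 1/2
  aucs <- null_auc_distribution(tr, c("A", "C"), n = 10, seed = 1)
  expect_equal(aucs, rep(0.5, 10), tolerance = 1e-12)
  expect_equal(redundancy_index(tr, c("A", "C"), n = 10, seed = 1), 0.5)
})

test_that("batched null AUCs equal the per-trajectory loss-curve path", {
  fix <- random_tree_fixture(14, seed = 8)
  sp <- sort(sample(fix$tree$labels, 9))
  for (ax in c("s_minus_1", "s")) {
    fast <- null_auc_distribution(fix$tree, sp, n = 30, seed = 5, axis = ax)
    slow <- vapply(random_trajectories(sp, n = 30, seed = 5), function(t)
      trapezoid_auc(loss_curve(fix$tree, sp, t, axis = ax)), numeric(1))
    expect_equal(fast, slow, tolerance = 1e-12)
  }
  sizes <- c(2, 4, 3)
  fastc <- cluster_null_aucs(fix$tree, sp, sizes, n = 30, seed = 5)
  slowc <- vapply(random_cluster_trajectories(sp, sizes, n = 30, seed = 5),
                  function(t) trapezoid_auc(loss_curve(fix$tree, sp, t)),
                  numeric(1))
  expect_equal(fastc, slowc, tolerance = 1e-12)
})

test_that("redundancy index converges to the exhaustive enumeration mean", {
  tr <- toy_tree()
  orc <- exhaustive_auc_oracle(tr, toy_sp)
  expect_equal(orc$mean, 3.5 / 6, tolerance = 1e-9)   # 6-order enumeration
  expect_equal(orc$n_orders, 6)
  ri <- redundancy_index(tr, toy_sp, n = 999, seed = 11)
  expect_lt(abs(ri - orc$mean), 3 * orc$sd / sqrt(999))

  # nearly-identical species plus one singular one: high redundancy
  cfg <- small_config(pool_size = 8, seed = 5,
                      redundancy_blocks = list(n_blocks = 1, block_size = 7))
  pool <- generate_species_pool(cfg)
  d <- gower_dissimilarity(pool, cfg$schema)
  t8 <- build_upgma_dendrogram(d)
  expect_gt(redundancy_index(t8, rownames(pool), n = 199, seed = 2), 0.5)
})

test_that("exhaustive oracle bounds and refusals hold", {
  tr <- toy_tree()
  orc2 <- exhaustive_auc_oracle(tr, c("A", "B"))
  expect_equal(c(orc2$mean, orc2$min, orc2$max), c(0.5, 0.5, 0.5))
  expect_equal(orc2$sd, 0)
  fix <- random_tree_fixture(10, seed = 4)
  expect_error(exhaustive_auc_oracle(fix$tree, fix$tree$labels[1:8]),
               "S > 7")
})

test_that("greedy trajectories match a per-step brute-force oracle", {
  tr <- toy_tree()
  best <- greedy_trajectory(tr, toy_sp, "best")
  worst <- greedy_trajectory(tr, toy_sp, "worst")
  expect_identical(unlist(best$steps), c("A", "B"))
  expect_identical(unlist(worst$steps)[1], "C")
  expect_equal(trapezoid_auc(loss_curve(tr, toy_sp, best)),
               0.25 + 0.5 * (1.2 / 1.4), tolerance = 1e-9)
  expect_equal(trapezoid_auc(loss_curve(tr, toy_sp, worst)),
               0.25 + 0.5 * (0.4 / 1.4), tolerance = 1e-9)

  # independent oracle: per-step arg-min/arg-max with ape-pruned FD
  greedy_oracle <- function(tree, sp, mode) {
    remaining <- sort(sp); out <- character(0)
    while (length(remaining) > 1L) {
      fd <- vapply(remaining, function(s)
        fd_oracle_ape(tree, setdiff(remaining, s)), numeric(1))
      extreme <- if (mode == "best") max(fd) else min(fd)
      k <- which(abs(fd - extreme) <= 1e-9)[1L]   # lexicographic tie-break
      out <- c(out, remaining[k]); remaining <- remaining[-k]
    }
    out
  }
  for (seed in 1:3) {
    fix <- random_tree_fixture(12, seed = seed)
    sp <- sort(sample(fix$tree$labels, 7))
    for (mode in c("best", "worst"))
      expect_identical(unlist(greedy_trajectory(fix$tree, sp, mode)$steps),
                       greedy_oracle(fix$tree, sp, mode))
  }
})

test_that("score-ranked trajectories sort with lexicographic tie-breaks", {
  ab <- c(A = 0.01, B = 0.5, C = 0.2)
  expect_identical(unlist(score_ranked_trajectory(toy_sp, ab,
                                                  "ascending")$steps),
                   c("A", "C"))
  vu <- c(A = 80, B = 20, C = 55)
  expect_identical(unlist(score_ranked_trajectory(toy_sp, vu,
                                                  "descending")$steps),
                   c("A", "C"))
  tied <- c(A = 1, B = 1, C = 1)
  expect_identical(unlist(score_ranked_trajectory(toy_sp, tied,
                                                  "ascending")$steps),
                   c("A", "B"))
  expect_error(score_ranked_trajectory(toy_sp, c(A = 1), "ascending"),
               "missing scores.*B", perl = TRUE)
})

test_that("IUCN clusters order by decreasing threat with folding to LC", {
  tr <- iucn_cluster_trajectory(toy_sp, c(A = "CR", B = "LC", C = "LC"))
  expect_identical(tr$steps, list("A", c("B", "C")))

  all_lc <- iucn_cluster_trajectory(toy_sp, c(A = "LC", B = "LC", C = "LC"))
  expect_identical(length(all_lc$steps), 1L)
  cv <- loss_curve(toy_tree(), toy_sp, all_lc)
  expect_equal(cv$x, c(0, 1)); expect_equal(cv$y, c(1, 0))

  ne <- iucn_cluster_trajectory(toy_sp, c(A = "NE", B = "EN", C = "LC"))
  expect_identical(ne$steps, list("B", c("A", "C")))
  expect_error(iucn_cluster_trajectory(toy_sp, c(A = "XX", B = "LC",
                                                 C = "LC")),
               "unknown IUCN")
})

test_that("random cluster nulls match enumeration and reproduce from seed", {
  tr <- toy_tree()
  # one big cluster: every replicate collapses to the one-cluster AUC
  one <- cluster_null_aucs(tr, toy_sp, 3, n = 20, seed = 2)
  expect_true(all(abs(one - 0.5) < 1e-12))

  # sizes [1, 2] on the toy: first pick A/B gives 0.6786, C gives 0.3929
  aucs <- cluster_null_aucs(tr, toy_sp, c(1, 2), n = 2000, seed = 3)
  hi <- 0.25 + 0.5 * (1.2 / 1.4); lo <- 0.25 + 0.5 * (0.4 / 1.4)
  expect_true(all(abs(aucs - hi) < 1e-9 | abs(aucs - lo) < 1e-9))
  expect_equal(mean(abs(aucs - lo) < 1e-9), 1 / 3, tolerance = 0.1)

  expect_identical(cluster_null_aucs(tr, toy_sp, c(1, 2), n = 9, seed = 7),
                   cluster_null_aucs(tr, toy_sp, c(1, 2), n = 9, seed = 7))
  expect_error(cluster_null_aucs(tr, toy_sp, c(1, 1), n = 9, seed = 1),
               "sum")
  expect_error(random_cluster_trajectories(toy_sp, c(2, 2)), "sum")
})

test_that("standardized effect sizes follow their defining identities", {
  null <- c(0.5, 0.6, 0.7, 0.4, 0.55)
  expect_equal(standardized_effect_size(mean(null), null), 0)
  expect_equal(standardized_effect_size(mean(null) - sd(null), null), -1)
  expect_error(standardized_effect_size(0.5, rep(0.5, 10)),
               class = "fdextinct_ses_undefined")
  expect_error(standardized_effect_size(0.5, 0.4), "at least two")

  # toy worst case against the exact 6-order null (population SD)
  orc <- exhaustive_auc_oracle(toy_tree(), toy_sp)
  lo <- 0.25 + 0.5 * (0.4 / 1.4)
  expect_equal((lo - orc$mean) / orc$sd, -sqrt(2), tolerance = 1e-9)
})

test_that("loss-curve invariants hold across random trajectories", {
  fix <- random_tree_fixture(16, seed = 10)
  set.seed(12)
  for (i in 1:6) {
    sp <- sort(sample(fix$tree$labels, sample(3:10, 1)))
    ord <- sample(sp)
    cv <- loss_curve(fix$tree, sp,
                     extinction_trajectory(as.list(ord[-length(ord)])))
    expect_equal(cv$x[1], 0); expect_equal(cv$y[1], 1)
    expect_equal(cv$x[nrow(cv)], 1); expect_equal(cv$y[nrow(cv)], 0)
    expect_true(all(diff(cv$x) > 0))
    expect_true(all(diff(cv$y) < 1e-12))      # FD monotone along removals
    expect_true(all(cv$y >= 0 & cv$y <= 1))
    auc <- trapezoid_auc(cv)
    expect_gte(auc, 0); expect_lte(auc, 1)
  }
})

test_that("greedy extremes bracket the random-null redundancy", {
  for (seed in c(21, 22)) {
    fix <- random_tree_fixture(14, seed = seed)
    sp <- sort(sample(fix$tree$labels, 8))
    best <- trapezoid_auc(loss_curve(fix$tree, sp,
                                     greedy_trajectory(fix$tree, sp, "best")))
    worst <- trapezoid_auc(loss_curve(fix$tree, sp,
                                      greedy_trajectory(fix$tree, sp,
                                                        "worst")))
    ri <- redundancy_index(fix$tree, sp, n = 299, seed = 3)
    expect_lte(worst, ri + 1e-9)
    expect_lte(ri, best + 1e-9)
    # greedy worst can do no better than the global enumerated minimum
    orc <- exhaustive_auc_oracle(fix$tree, sp[1:6])
    w6 <- trapezoid_auc(loss_curve(fix$tree, sp[1:6],
                                   greedy_trajectory(fix$tree, sp[1:6],
                                                     "worst")))
    expect_gte(w6, orc$min - 1e-9)
  }
})

test_that("scenario runner assembles per-assemblage results", {
  fix <- random_tree_fixture(25, seed = 13)
  sp <- sort(sample(fix$tree$labels, 10))
  ab <- stats::setNames(rlnorm(10), sp)
  vu <- stats::setNames(round(runif(25) * 100, 1), fix$tree$labels)
  iu <- stats::setNames(sample(c("LC", "VU", "EN"), 25, TRUE),
                        fix$tree$labels)
  asm <- assemblage("site_x", ab, "river", "Iberian", "MES")
  out <- run_scenarios(fix$tree, asm, vulnerability = vu, iucn = iu,
                       n_random = 99, seed = 17, keep_curves = TRUE)
  expect_s3_class(out, "scenario_result")
  expect_setequal(out$results$scenario,
                  c("random", "best", "worst", "abundance", "trait", "iucn"))
  expect_true(all(out$results$auc >= 0 & out$results$auc <= 1))
  expect_false(any(is.na(out$results$ses[out$results$scenario %in%
                                           c("abundance", "trait")])))
  expect_gte(out$results$auc[out$results$scenario == "best"],
             max(out$results$auc[out$results$scenario == "worst"]))
  # rerun identical
  out2 <- run_scenarios(fix$tree, asm, vulnerability = vu, iucn = iu,
                        n_random = 99, seed = 17)
  expect_equal(out$results, out2$results)
  expect_error(run_scenarios(fix$tree, asm, scenarios = "trait"),
               "requires vulnerability")
})
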