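schema <- fish_trait_schema()

make_species <- function(size = "0-8", vp = "benthic", tg = "omnivorous",
                         sh = "lithophilic", sm = "carangiform") {
  data.frame(size = size, vertical_position = vp, trophic_group = tg,
             spawning_habitat = sh, swimming_mode = sm,
             stringsAsFactors = FALSE)
}

test_that("schema validation rejects malformed tables and values", {
  tab <- rbind(make_species(), make_species(size = "8.1-15"))
  rownames(tab) <- c("sp1", "sp2")
  expect_silent(validate_trait_table(tab, schema))

  bad <- tab; bad$size[1] <- "huge"
  expect_error(gower_dissimilarity(bad, schema), "unknown categories")
  expect_error(validate_trait_table(tab[, -1], schema), "missing traits")
  na_tab <- tab; na_tab$size[2] <- NA
  expect_error(validate_trait_table(na_tab, schema), "missing values")
  expect_error(trait_schema(list(list(name = "t", kind = "ordered",
                                      levels = c("a", "a")))),
               "duplicate")
})

test_that("Gower dissimilarity matches hand-computed cases", {
  # identical trait vectors
  tab <- rbind(make_species(), make_species())
  rownames(tab) <- c("s1", "s2")
  expect_identical(gower_dissimilarity(tab, schema)["s1", "s2"], 0)

  # all five traits differ, size levels 1 vs 6: four nominal 1s + |1-6|/5
  tab <- rbind(make_species("0-8", "benthic", "omnivorous", "lithophilic",
                            "carangiform"),
               make_species(">80.1", "non-benthic", "piscivorous",
                            "pelagophilic", "rajiform"))
  rownames(tab) <- c("s1", "s2")
  expect_equal(gower_dissimilarity(tab, schema)["s1", "s2"], 1)

  # identical except size levels 2 vs 4: (|2-4|/5)/5
  tab <- rbind(make_species(size = "8.1-15"), make_species(size = "30.1-50"))
  rownames(tab) <- c("s1", "s2")
  expect_equal(gower_dissimilarity(tab, schema)["s1", "s2"], 0.08)

  # single species: 1x1 zero matrix
  one <- make_species(); rownames(one) <- "solo"
  expect_identical(gower_dissimilarity(one, schema),
                   matrix(0, 1, 1, dimnames = list("solo", "solo")))
})

test_that("Gower agrees with a brute-force oracle and with cluster::daisy", {
  for (seed in 1:3) {
    tab <- random_trait_table(sample(5:20, 1), seed = seed)
    d <- gower_dissimilarity(tab, schema)
    expect_lt(max(abs(d - gower_oracle(tab, schema))), 1e-12)
    expect_true(all(d >= 0 & d <= 1))
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0))
    # zero off-diagonal iff identical trait vectors
    ut <- which(upper.tri(d) & d == 0, arr.ind = TRUE)
    if (nrow(ut))
      for (r in seq_len(nrow(ut)))
        expect_identical(unlist(tab[ut[r, 1], ]), unlist(tab[ut[r, 2], ]))
  }
  skip_if_not_installed("cluster")
  tab <- random_trait_table(15, seed = 4)
  # daisy range-scales ordered traits by the observed rank range, so make
  # sure every size level is represented before comparing
  tab$size[1:6] <- schema$traits$size$levels
  df <- tab
  df$size <- factor(df$size, levels = schema$traits$size$levels,
                    ordered = TRUE)
  for (nm in setdiff(names(df), "size")) df[[nm]] <- factor(df[[nm]])
  dd <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_lt(max(abs(gower_dissimilarity(tab, schema) - dd)), 1e-10)
})

test_that("UPGMA reproduces hand-clustered examples", {
  tr <- toy_tree()
  expect_equal(tr$height, c(0.2, 0.6))
  # first merge joins A and B, then C comes in at the root
  expect_setequal(tr$merge[1, ], c(-1, -2))
  expect_equal(functional_richness(tr, c("A", "B", "C")), 1.4)

  d2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- build_upgma_dendrogram(d2)
  expect_equal(t2$height, 0.5)

  bad <- toy_dissimilarity(); bad[1, 2] <- 0.3
  expect_error(build_upgma_dendrogram(bad), "symmetric")
  neg <- toy_dissimilarity(); neg[1, 2] <- neg[2, 1] <- -0.1
  expect_error(build_upgma_dendrogram(neg), "negative")
})

test_that("ultrametric input is a fixed point of UPGMA", {
  fix <- random_tree_fixture(12, seed = 2)
  cm <- cophenetic_matrix(fix$tree)
  rebuilt <- build_upgma_dendrogram(cm)
  expect_lt(max(abs(cophenetic_matrix(rebuilt)[rownames(cm), rownames(cm)] -
                      cm)), 1e-10)
  expect_equal(cophenetic_correlation(rebuilt, cm), 1)
})

test_that("UPGMA agrees with hclust average linkage on tie-free matrices", {
  set.seed(31)
  for (i in 1:3) {
    n <- 10
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)   # continuous: ties a.s. absent
    m <- m + t(m)
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    mine <- build_upgma_dendrogram(m)
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    expect_lt(max(abs(cophenetic_matrix(mine) -
                        as.matrix(stats::cophenetic(hc))[mine$labels,
                                                         mine$labels])),
              1e-10)
  }
})

test_that("cophenetic correlation matches an independent computation", {
  # 4-species non-ultrametric matrix; oracle goes through hclust + cor
  m <- matrix(c(0, .1, .5, .7,
                .1, 0, .45, .8,
                .5, .45, 0, .3,
                .7, .8, .3, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- build_upgma_dendrogram(m)
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  oracle <- cor(as.numeric(stats::cophenetic(hc)),
                as.numeric(stats::as.dist(m)))
  expect_equal(cophenetic_correlation(tr, m), oracle, tolerance = 1e-12)
  expect_error(cophenetic_correlation(build_upgma_dendrogram(m[1:2, 1:2]),
                                      m[1:2, 1:2]),
               "at least 3")
})

test_that("functional richness reproduces the hand-summed toy subtrees", {
  tr <- toy_tree()
  expect_equal(functional_richness(tr, "A"), 0)
  expect_equal(functional_richness(tr, c("A", "B")), 0.4)
  expect_equal(functional_richness(tr, c("A", "C")), 1.2)
  expect_equal(functional_richness(tr, c("A", "B", "C")), 1.4)
  expect_equal(functional_richness(tr, character(0)), 0)
  # root convention adds the LCA-to-root path
  expect_equal(functional_richness(tr, c("A", "B"), from = "root"), 0.8)
  expect_error(functional_richness(tr, "Z"), "not in tree")
})

test_that("functional richness is monotone and matches the ape oracle", {
  fix <- random_tree_fixture(15, seed = 3)
  sp <- fix$tree$labels
  set.seed(99)
  for (i in 1:10) {
    big <- sample(sp, sample(3:12, 1))
    small <- sample(big, sample(seq_len(length(big)), 1))
    fd_big <- functional_richness(fix$tree, big)
    fd_small <- functional_richness(fix$tree, small)
    expect_lte(fd_small, fd_big + 1e-12)
    expect_equal(fd_big, fd_oracle_ape(fix$tree, big), tolerance = 1e-9)
  }
  expect_equal(functional_richness(fix$tree, sp),
               sum(fix$tree$edgelen, na.rm = TRUE))
})

test_that("induced dendrogram preserves subset branch lengths", {
  fix <- random_tree_fixture(20, seed = 5)
  set.seed(7)
  for (i in 1:5) {
    sub <- sort(sample(fix$tree$labels, sample(4:12, 1)))
    itree <- induced_dendrogram(fix$tree, sub)
    expect_identical(itree$labels[order(itree$labels)], sub)
    for (j in 1:4) {
      s <- sample(sub, sample(2:length(sub), 1))
      expect_equal(functional_richness(itree, s),
                   functional_richness(fix$tree, s), tolerance = 1e-10)
    }
  }
})

test_that("Newick export round-trips through ape", {
  fix <- random_tree_fixture(8, seed = 6)
  f <- tempfile(fileext = ".nwk")
  export_newick(fix$tree, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, fix$tree$labels)
  expect_equal(sum(phy$edge.length),
               sum(fix$tree$edgelen, na.rm = TRUE), tolerance = 1e-6)
  unlink(f)
})

test_that("trait tables and schemas round-trip through files", {
  tab <- random_trait_table(10, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_trait_table(tab, f)
  back <- read_trait_table(f, schema = schema)
  expect_identical(back[rownames(tab), ], tab)
  unlink(f)

  sf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(traits = lapply(schema$traits, function(tr)
    list(name = tr$name, kind = tr$kind, levels = tr$levels))), sf)
  s2 <- read_trait_schema(sf)
  expect_identical(names(s2$traits), names(schema$traits))
  expect_identical(s2$traits$size$levels, schema$traits$size$levels)
  unlink(sf)
})
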