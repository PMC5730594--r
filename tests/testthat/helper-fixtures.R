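# shared fixtures, built in code

# 3-species worked example: d(A,B) = 0.2, d(A,C) = d(B,C) = 0.6
toy_dissimilarity <- function() {
  matrix(c(0, 0.2, 0.6,
           0.2, 0, 0.6,
           0.6, 0.6, 0), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

toy_tree <- function() build_upgma_dendrogram(toy_dissimilarity())

# a generator config scaled to a small pool (richness ranges clipped)
small_config <- function(pool_size = 30, seed = 1, ...) {
  generator_config(pool_size = pool_size, seed = seed,
                   richness_ranges = list(lake = c(3, min(12, pool_size)),
                                          river = c(3, min(12, pool_size)),
                                          estuary = c(4, min(15, pool_size))),
                   ...)
}

# random valid trait table
random_trait_table <- function(n, seed = 1) {
  generate_species_pool(small_config(pool_size = n, seed = seed))
}

# random pool + tree fixture
random_tree_fixture <- function(n, seed = 1) {
  pool <- random_trait_table(n, seed)
  schema <- fish_trait_schema()
  d <- gower_dissimilarity(pool, schema)
  list(pool = pool, d = d, tree = build_upgma_dendrogram(d))
}

# independent functional-richness oracle through ape: prune the phylogeny
# to the subset (keep.tip roots the pruned tree at the subset's MRCA) and
# sum its edge lengths; as.phylo.hclust halves heights, so double back
fd_oracle_ape <- function(tree, species) {
  if (length(species) <= 1L) return(0)
  phy <- ape::as.phylo(as.hclust(tree))
  sub <- ape::keep.tip(phy, species)
  2 * sum(sub$edge.length)
}

# brute-force per-trait-loop Gower oracle
gower_oracle <- function(table, schema) {
  sp <- rownames(table)
  n <- length(sp)
  out <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (tr in schema$traits) {
      a <- table[i, tr$name]; b <- table[j, tr$name]
      if (tr$kind == "ordered") {
        L <- length(tr$levels)
        acc <- acc + abs(match(a, tr$levels) - match(b, tr$levels)) / (L - 1)
      } else {
        acc <- acc + as.numeric(a != b)
      }
    }
    out[i, j] <- acc / length(schema$traits)
  }
  out
}
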