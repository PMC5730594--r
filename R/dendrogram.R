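#' Build a UPGMA functional dendrogram
#'
#' Agglomerative average-linkage (UPGMA) clustering of a dissimilarity
#' matrix. The merge height of two clusters is the arithmetic mean of all
#' between-cluster pairwise dissimilarities, so the result is ultrametric
#' with leaves at height zero. Ties in the minimal between-cluster distance
#' are broken by merging the lexicographically smallest eligible pair of
#' clusters (clusters ordered by their smallest member label), which makes
#' trees bit-reproducible across platforms and input orderings.
#'
#' @param d a symmetric dissimilarity matrix (or `dist`) with zero diagonal
#'   and species labels; at least two species.
#' @return an object of class `fdendro`: a rooted binary merge tree with
#'   components `merge` and `height` (in `hclust` coding), `labels`, and
#'   cached node arrays used by the branch-length machinery.
#' @seealso [functional_richness()], [cophenetic_correlation()],
#'   [export_newick()]
#' @export
build_upgma_dendrogram <- function(d) {
  d <- check_dissimilarity(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two species to build a dendrogram")
  labels <- rownames(d)

  # active clusters: ids 1..n are leaves, n+k is the k-th merge
  ids <- seq_len(n)
  sizes <- rep(1L, n)
  reprs <- labels                     # smallest member label per cluster
  D <- d
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (k in seq_len(n - 1L)) {
    m <- min(D)
    # all tied pairs (within float tolerance), upper triangle only
    cand <- which(D <= m + 1e-12 & upper.tri(D), arr.ind = TRUE)
    lo <- pmin(reprs[cand[, 1L]], reprs[cand[, 2L]])
    hi <- pmax(reprs[cand[, 1L]], reprs[cand[, 2L]])
    pick <- order(lo, hi)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]

    merge[k, ] <- sort(ifelse(ids[c(i, j)] <= n,
                              -ids[c(i, j)], ids[c(i, j)] - n))
    height[k] <- D[i, j]

    # average-linkage update (Lance-Williams, size-weighted)
    newrow <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_along(ids), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], Inf))
    ids <- c(ids[keep], n + k)
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    reprs <- c(reprs[keep], min(reprs[i], reprs[j]))
  }
  new_fdendro(merge, height, labels)
}

# construct an fdendro from hclust-style merge/height, caching node arrays:
# nodes 1..n are leaves, n+k is the k-th merge; root is node 2n-1
new_fdendro <- function(merge, height, labels) {
  n <- length(labels)
  if (any(diff(height) < -1e-10))
    stop("merge heights decrease: tree is not ultrametric")
  children <- matrix(0L, n - 1L, 2L)
  children[] <- ifelse(merge < 0, -merge, merge + n)
  parent <- integer(2L * n - 1L)
  parent[children[, 1L]] <- parent[children[, 2L]] <- n + seq_len(n - 1L)
  parent[2L * n - 1L] <- NA_integer_
  nodeh <- c(rep(0, n), height)
  edgelen <- nodeh[parent] - nodeh
  structure(list(merge = merge, height = height, labels = labels, n = n,
                 children = children, parent = parent, nodeh = nodeh,
                 edgelen = edgelen, root = 2L * n - 1L,
                 cache = new.env(parent = emptyenv())),
            class = "fdendro")
}

#' @export
print.fdendro <- function(x, ...) {
  cat("Functional dendrogram (UPGMA):", x$n, "species, root height",
      format(max(x$nodeh), digits = 4), "\n")
  cat("Total branch length:", format(sum(x$edgelen, na.rm = TRUE),
                                     digits = 6), "\n")
  invisible(x)
}

#' @export
as.hclust.fdendro <- function(x, ...) {
  # leaf display order by depth-first traversal
  ord <- integer(0)
  stack <- x$root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= x$n) ord <- c(ord, v)
    else stack <- c(stack, x$children[v - x$n, 2L], x$children[v - x$n, 1L])
  }
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "gower"),
            class = "hclust")
}

#' Cophenetic distance matrix of a dendrogram
#'
#' The cophenetic distance between two leaves is the height of their lowest
#' common ancestor.
#'
#' @param tree an `fdendro`.
#' @return a symmetric numeric matrix with species dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "fdendro"))
  if (!is.null(tree$cache$coph)) return(tree$cache$coph)
  n <- tree$n
  cm <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  leafsets <- c(as.list(seq_len(n)), vector("list", n - 1L))
  for (k in seq_len(n - 1L)) {
    a <- leafsets[[tree$children[k, 1L]]]
    b <- leafsets[[tree$children[k, 2L]]]
    cm[a, b] <- cm[b, a] <- tree$height[k]
    leafsets[[n + k]] <- c(a, b)
  }
  tree$cache$coph <- cm
  cm
}

#' Cophenetic correlation between a dendrogram and its source matrix
#'
#' Pearson correlation between the upper triangles of the dendrogram's
#' cophenetic distance matrix and the original dissimilarity matrix: the
#' standard fidelity check for a clustering of a functional distance matrix.
#' Equals 1 exactly when the input was already ultrametric.
#'
#' @param tree an `fdendro` built from the species in `d`.
#' @param d the original dissimilarity matrix (or `dist`).
#' @return a correlation in [-1, 1].
#' @export
cophenetic_correlation <- function(tree, d) {
  d <- check_dissimilarity(d)
  if (nrow(d) < 3L) stop("cophenetic correlation needs at least 3 species")
  if (!setequal(rownames(d), tree$labels))
    stop("tree and matrix species sets differ")
  cm <- cophenetic_matrix(tree)[rownames(d), rownames(d)]
  ut <- upper.tri(d)
  stats::cor(cm[ut], d[ut])
}

#' Functional richness of a species subset
#'
#' Total branch length of the minimal subtree of `tree` spanning the given
#' species, connecting them up to their most recent common ancestor (not the
#' global root). A single species therefore has zero functional richness and
#' the full leaf set returns the tree's total branch length. The index is
#' monotone: it cannot increase when a species is removed.
#'
#' @param tree an `fdendro`.
#' @param species character vector of leaf labels (duplicates ignored); an
#'   empty set is defined as 0, the terminal point of a loss curve.
#' @param from `"lca"` (default) spans the subset up to its most recent
#'   common ancestor; `"root"` adds the path from that ancestor to the
#'   global root.
#' @return a non-negative branch length.
#' @export
functional_richness <- function(tree, species, from = c("lca", "root")) {
  stopifnot(inherits(tree, "fdendro"))
  from <- match.arg(from)
  species <- unique(species)
  if (length(species) == 0L) return(0)
  idx <- match(species, tree$labels)
  if (anyNA(idx))
    stop("species not in tree: ",
         paste(species[is.na(idx)], collapse = ", "))
  n <- tree$n
  cnt <- integer(2L * n - 1L)
  cnt[idx] <- 1L
  for (k in seq_len(n - 1L))
    cnt[n + k] <- cnt[tree$children[k, 1L]] + cnt[tree$children[k, 2L]]
  present <- cnt > 0L
  fd_root <- sum(tree$edgelen[present & !is.na(tree$edgelen)])
  if (from == "root") return(fd_root)
  # deepest node containing the whole subset = the LCA
  h_lca <- min(tree$nodeh[cnt == length(idx)])
  fd_root - (tree$nodeh[tree$root] - h_lca)
}

#' Induced sub-dendrogram for a species subset
#'
#' Prunes the dendrogram to a subset of leaves, preserving the heights of
#' all retained ancestors (pairwise cophenetic distances are unchanged).
#' Branch-length queries on the induced tree agree with queries on the full
#' tree restricted to the subset, which is what the extinction engine
#' exploits to work per assemblage.
#'
#' @param tree an `fdendro`.
#' @param species at least two leaf labels of `tree`.
#' @return an `fdendro` over `species`.
#' @export
induced_dendrogram <- function(tree, species) {
  stopifnot(inherits(tree, "fdendro"))
  species <- unique(species)
  if (length(species) < 2L) stop("need at least two species")
  if (!all(species %in% tree$labels))
    stop("species not in tree: ",
         paste(setdiff(species, tree$labels), collapse = ", "))
  cm <- cophenetic_matrix(tree)[species, species]
  # UPGMA of an ultrametric matrix reconstructs the induced tree exactly
  build_upgma_dendrogram(cm)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are merge-height differences, so every leaf sits at depth
#' equal to the root's merge height and the branch lengths sum to the
#' tree's total branch length (the functional richness of the full pool).
#'
#' @param tree an `fdendro`.
#' @param file path for the Newick file.
#' @return the file path, invisibly.
#' @export
export_newick <- function(tree, file) {
  phy <- ape::as.phylo(as.hclust.fdendro(tree))
  # as.phylo.hclust halves heights (distance convention); undo that so
  # depths equal merge heights
  phy$edge.length <- phy$edge.length * 2
  ape::write.tree(phy, file = file)
  invisible(file)
}

# per-leaf ancestor paths used by the trajectory engine:
# anc[[leaf]] = internal nodes from parent up to root,
# sib[[leaf]] = the off-path child of each of those nodes
leaf_paths <- function(tree) {
  n <- tree$n
  anc <- sib <- vector("list", n)
  for (lf in seq_len(n)) {
    a <- integer(0); s <- integer(0)
    v <- lf
    repeat {
      p <- tree$parent[v]
      if (is.na(p)) break
      ch <- tree$children[p - n, ]
      a <- c(a, p)
      s <- c(s, if (ch[1L] == v) ch[2L] else ch[1L])
      v <- p
    }
    anc[[lf]] <- a; sib[[lf]] <- s
  }
  list(anc = anc, sib = sib)
}
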