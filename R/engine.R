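# Batched AUC machinery for random-null trajectories.
#
# All functions here work on the induced dendrogram of one assemblage, whose
# leaves are exactly the assemblage's species in canonical (sorted label)
# order. The key identity: for a sequential removal order with positions
# pos[leaf] in 1..S, the edge above node v stays in the spanning subtree
# until step t_v = max(pos over leaves under v). Hence, with edge lengths
# len_v and tree root height H,
#   sum_{k=0}^{S-1} FD_root(k) = sum_v len_v * t_v
# and the LCA correction sum_k h_LCA(k) follows from the ancestor path of
# the last-removed leaf, giving the exact trapezoidal AUC of every
# trajectory without evaluating FD step by step.

# propagate per-leaf removal positions to internal nodes: t_v = max under v;
# posmat is S x n, returns (2S-1) x n
propagate_max <- function(tree, posmat) {
  S <- tree$n
  n <- ncol(posmat)
  M <- matrix(0, 2L * S - 1L, n)
  M[seq_len(S), ] <- posmat
  for (k in seq_len(S - 1L))
    M[S + k, ] <- pmax(M[tree$children[k, 1L], ], M[tree$children[k, 2L], ])
  M
}

# exact AUC of sequential trajectories given a permutation matrix
# perms: S x n, perms[i, r] = leaf index removed at step i of replicate r
auc_sequential_batch <- function(tree, perms, axis = "s_minus_1") {
  S <- tree$n
  n <- ncol(perms)
  el <- tree$edgelen
  el[tree$root] <- 0
  H <- tree$nodeh[tree$root]
  fd_full <- sum(el)
  if (fd_full <= 0)
    stop(errorCondition("degenerate assemblage: zero functional richness",
                        class = "fdextinct_degenerate"))
  posmat <- matrix(0L, S, n)
  for (r in seq_len(n)) posmat[perms[, r], r] <- seq_len(S)
  M <- propagate_max(tree, posmat)
  sum_fd_root <- as.numeric(el %*% M)

  # LCA-height correction, grouped by the last-remaining leaf
  paths <- leaf_paths(tree)
  last <- perms[S, ]
  sum_h <- numeric(n)
  for (lf in unique(last)) {
    reps <- which(last == lf)
    anc <- paths$anc[[lf]]; sib <- paths$sib[[lf]]
    m <- length(anc)
    SM <- M[sib, reps, drop = FALSE]          # m x |reps| sibling maxima
    if (m > 1L)                                # rc[i,] = max_{j>=i} SM[j,]
      for (i in (m - 1L):1L) SM[i, ] <- pmax(SM[i, ], SM[i + 1L, ])
    lower <- rbind(SM[-1L, , drop = FALSE], rep(0, length(reps)))
    sum_h[reps] <- as.numeric(tree$nodeh[anc] %*% (SM - lower))
  }
  denom <- if (axis == "s_minus_1") S - 1L else S
  ((sum_fd_root - S * H + sum_h) / fd_full - 0.5) / denom
}

# exact AUC of cluster trajectories; posmat[leaf, r] = cluster index (1..C)
# in removal order; sizes = cluster sizes (same for all replicates)
auc_cluster_batch <- function(tree, posmat, sizes, axis = "s_minus_1") {
  S <- tree$n
  n <- ncol(posmat)
  C <- length(sizes)
  el <- tree$edgelen
  el[tree$root] <- 0
  H <- tree$nodeh[tree$root]
  fd_full <- sum(el)
  if (fd_full <= 0)
    stop(errorCondition("degenerate assemblage: zero functional richness",
                        class = "fdextinct_degenerate"))
  denom <- if (axis == "s_minus_1") S - 1L else S
  xs <- pmin(c(0, cumsum(sizes)) / denom, 1)
  if (C == 1L)    # single cluster: straight drop from (0,1) to (1,0)
    return(rep(sum(diff(xs) * 0.5), n))
  M <- propagate_max(tree, posmat)
  # FD_root after removing clusters 1..k, k = 1..C-1
  fd_root_k <- vapply(seq_len(C - 1L),
                      function(k) as.numeric(el %*% (M > k)), numeric(n))
  paths <- leaf_paths(tree)
  # collapse duplicate capped points at x = 1 once; xs is shared by reps
  keep <- !duplicated(xs) | xs < 1
  dx <- diff(xs[keep])
  nk <- sum(keep)
  ks <- seq_len(C - 1L)
  auc <- numeric(n)
  for (r in seq_len(n)) {
    lf <- which(posmat[, r] == C)[1L]          # a leaf removed last
    anc <- paths$anc[[lf]]
    sibt <- M[paths$sib[[lf]], r]
    m <- length(anc)
    rc <- rev(cummax(rev(sibt)))               # rc[i] = o(a_{i-1})
    o <- c(rc[-1L], 0)                         # o[i] = o(a_i)
    hpath <- c(0, tree$nodeh[anc])             # heights of a_0..a_m
    # deepest ancestor with o(a_i) <= k; o is non-increasing in i
    i_star <- m + 1L - findInterval(ks, rev(o))
    h_lca <- ifelse(rc[1L] <= ks, 0, hpath[i_star + 1L])
    ys <- c(1, pmax((fd_root_k[r, ] - H + h_lca) / fd_full, 0), 0)
    yk <- ys[keep]
    auc[r] <- sum(dx * (yk[-nk] + yk[-1L]) / 2)
  }
  auc
}

#' Null distribution of AUC under random sequential extinction
#'
#' Draws `n` uniform-random removal orders for the assemblage and returns
#' their exact trapezoidal AUC values, computed by a closed-form batched
#' algorithm over the assemblage's induced dendrogram. With the same seed
#' this reproduces the AUCs of [random_trajectories()] evaluated through
#' [loss_curve()] + [trapezoid_auc()].
#'
#' @param tree an `fdendro` containing the assemblage's species (the global
#'   dendrogram or an induced one).
#' @param x an [assemblage()] or character vector of species (S >= 2).
#' @param n replicates (default 999).
#' @param seed integer seed.
#' @param axis abscissa convention, see [loss_curve()].
#' @return numeric vector of `n` AUC values.
#' @export
null_auc_distribution <- function(tree, x, n = 999, seed = 1,
                                  axis = c("s_minus_1", "s")) {
  axis <- match.arg(axis)
  sp <- canonical_species(x)
  if (length(sp) < 2L) stop("need at least two species")
  if (n < 2L) stop("need n >= 2 replicates")
  itree <- induced_for(tree, sp)
  S <- itree$n
  set.seed(seed)
  perms <- vapply(seq_len(n), function(i) sample.int(S), integer(S))
  auc_sequential_batch(itree, perms, axis)
}

#' Functional redundancy index of an assemblage
#'
#' Mean AUC over `n` random extinction trajectories: the overall
#' compensatory potential of the assemblage. Values near 1 indicate strong
#' redundancy (random losses barely dent functional richness early on);
#' values near the worst-case AUC indicate assemblages of functionally
#' singular species.
#'
#' @inheritParams null_auc_distribution
#' @return the mean null AUC.
#' @export
redundancy_index <- function(tree, x, n = 999, seed = 1,
                             axis = c("s_minus_1", "s")) {
  mean(null_auc_distribution(tree, x, n = n, seed = seed,
                             axis = match.arg(axis)))
}

#' Exhaustive AUC oracle over all removal orders
#'
#' Enumerates every one of the S! sequential removal orders of a small
#' assemblage and returns the exact distribution of AUC values: mean,
#' population standard deviation, min and max. Used to validate the
#' Monte-Carlo null and to bound the greedy extremes; refuses S > 7.
#'
#' @inheritParams null_auc_distribution
#' @return a list with `mean`, `sd` (population SD over all orders), `min`,
#'   `max`, `n_orders`, and the vector `aucs`.
#' @export
exhaustive_auc_oracle <- function(tree, x, axis = c("s_minus_1", "s")) {
  axis <- match.arg(axis)
  sp <- canonical_species(x)
  S <- length(sp)
  if (S < 2L) stop("need at least two species")
  if (S > 7L) stop("refusing exhaustive enumeration for S > 7")
  itree <- induced_for(tree, sp)
  perms <- t(all_permutations(S))
  aucs <- auc_sequential_batch(itree, perms, axis)
  m <- mean(aucs)
  list(mean = m, sd = sqrt(mean((aucs - m)^2)), min = min(aucs),
       max = max(aucs), n_orders = length(aucs), aucs = aucs)
}

# rows = all permutations of 1..n
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}

# return an induced tree whose leaves are exactly sp (in canonical order);
# reuse the tree itself when it already matches
induced_for <- function(tree, sp) {
  stopifnot(inherits(tree, "fdendro"))
  if (length(tree$labels) == length(sp) && all(tree$labels == sp)) tree
  else induced_dendrogram(tree, sp)
}
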