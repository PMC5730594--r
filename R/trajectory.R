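#' Extinction trajectories
#'
#' A trajectory is an ordered sequence of removal steps applied to an
#' assemblage. Sequential scenarios remove one species per step and stop
#' when a single species remains; cluster scenarios (IUCN-based and its
#' null) remove whole groups per step and may remove every species.
#'
#' @param steps list of character vectors; each element is the set of
#'   species removed at that step (singletons for sequential scenarios).
#' @param scenario scenario label.
#' @return an object of class `extinction_trajectory`.
#' @export
extinction_trajectory <- function(steps, scenario = "custom") {
  if (!is.list(steps) || length(steps) == 0L)
    stop("`steps` must be a non-empty list of species sets")
  all_sp <- unlist(steps)
  if (anyDuplicated(all_sp)) stop("a species is removed twice")
  if (any(lengths(steps) == 0L)) stop("empty removal step")
  structure(list(steps = lapply(steps, as.character),
                 scenario = as.character(scenario)),
            class = "extinction_trajectory")
}

#' @export
print.extinction_trajectory <- function(x, ...) {
  cat(sprintf("Extinction trajectory '%s': %d steps, %d species removed\n",
              x$scenario, length(x$steps), length(unlist(x$steps))))
  invisible(x)
}

# canonical species ordering used everywhere a random draw indexes species,
# so that results are independent of input ordering
canonical_species <- function(x) {
  sp <- if (inherits(x, "assemblage")) x$species else as.character(x)
  sort(unique(sp))
}

#' Random sequential extinction trajectories
#'
#' Draws `n` independent uniform-random removal orders (every species
#' equally likely to go extinct next), the null model against which the
#' directional scenarios are compared. Reproducible from `seed`; the same
#' seed yields the AUC distribution used by [redundancy_index()] and
#' [null_auc_distribution()].
#'
#' @param x an [assemblage()] or a character vector of species (S >= 2).
#' @param n number of trajectories (>= 2; the null SD is undefined below
#'   that). Default 999.
#' @param seed integer seed.
#' @return a list of `extinction_trajectory` objects, each with S - 1
#'   single-species steps.
#' @export
random_trajectories <- function(x, n = 999, seed = 1) {
  sp <- canonical_species(x)
  S <- length(sp)
  if (S < 2L) stop("need at least two species")
  if (n < 2L) stop("need n >= 2 random trajectories")
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ord <- sp[sample.int(S)]
    extinction_trajectory(as.list(ord[seq_len(S - 1L)]), "random")
  })
}

#' Greedy best-case / worst-case extinction trajectory
#'
#' At each step the functional-richness loss of removing every remaining
#' candidate is evaluated; the best-case trajectory removes the species
#' causing the smallest decline, the worst-case the largest. Ties are broken
#' lexicographically by species identifier. These are per-step (greedy)
#' extremes, not globally optimal orders.
#'
#' @param tree an `fdendro` containing the assemblage's species.
#' @param x an [assemblage()] or character vector of species (S >= 2).
#' @param mode `"best"` or `"worst"`.
#' @return an `extinction_trajectory` with S - 1 steps.
#' @export
greedy_trajectory <- function(tree, x, mode = c("best", "worst")) {
  mode <- match.arg(mode)
  remaining <- canonical_species(x)
  if (length(remaining) < 2L) stop("need at least two species")
  steps <- character(0)
  eps <- 1e-9   # FD values within eps count as tied (float-noise guard)
  while (length(remaining) > 1L) {
    fd_after <- vapply(remaining, function(s)
      functional_richness(tree, setdiff(remaining, s)), numeric(1))
    extreme <- if (mode == "best") max(fd_after) else min(fd_after)
    # remaining is sorted, so the first tied candidate is the
    # lexicographically smallest species id
    pick <- which(abs(fd_after - extreme) <= eps)[1L]
    steps <- c(steps, remaining[pick])
    remaining <- remaining[-pick]
  }
  extinction_trajectory(as.list(steps), paste0(mode, "-case"))
}

#' Score-ranked sequential trajectory (abundance- and trait-based scenarios)
#'
#' Orders species by a per-species score. The abundance-based scenario uses
#' `direction = "ascending"` on standardized abundances, so the rarest
#' species disappear first; the trait-based scenario uses
#' `direction = "descending"` on the intrinsic vulnerability score (0-100),
#' so the most vulnerable species disappear first. Score ties are broken
#' lexicographically by species identifier.
#'
#' @param x an [assemblage()] or character vector of species.
#' @param scores named numeric vector covering every species of `x`.
#' @param direction `"ascending"` (smallest score removed first) or
#'   `"descending"`.
#' @param scenario label stored on the trajectory.
#' @return an `extinction_trajectory` with S - 1 steps.
#' @export
score_ranked_trajectory <- function(x, scores,
                                    direction = c("ascending", "descending"),
                                    scenario = NULL) {
  direction <- match.arg(direction)
  sp <- canonical_species(x)
  if (length(sp) < 2L) stop("need at least two species")
  miss <- setdiff(sp, names(scores))
  if (length(miss))
    stop("missing scores for species: ", paste(miss, collapse = ", "))
  s <- as.numeric(scores[sp])
  ord <- if (direction == "ascending") order(s, sp) else order(-s, sp)
  if (is.null(scenario))
    scenario <- if (direction == "ascending") "abundance" else "trait"
  extinction_trajectory(as.list(sp[ord][seq_len(length(sp) - 1L)]), scenario)
}

# severity order of Red List categories, most threatened first; data
# deficient and not evaluated fold into least concern
.iucn_order <- c("CR", "EN", "VU", "NT", "LC")
.iucn_fold <- c(DD = "LC", NE = "LC", NA. = "LC")

normalize_iucn <- function(categories) {
  v <- toupper(as.character(categories))
  v[is.na(v) | v %in% c("DD", "NE", "NA")] <- "LC"
  bad <- setdiff(unique(v), .iucn_order)
  if (length(bad))
    stop("unknown IUCN categories: ", paste(bad, collapse = ", "))
  v
}

#' IUCN-based cluster trajectory
#'
#' Removes clusters of species in decreasing order of Red List threat:
#' CR, EN, VU, NT, LC. Species not assessed (NE) or data deficient (DD)
#' are folded into least concern, so they are removed last. Functional
#' richness is evaluated once per cluster removal; empty categories are
#' skipped.
#'
#' @param x an [assemblage()] or character vector of species.
#' @param iucn_categories named character vector of categories
#'   (`"CR"`, `"EN"`, `"VU"`, `"NT"`, `"LC"`, `"DD"`, `"NE"`) covering
#'   every species.
#' @return an `extinction_trajectory` whose steps partition all species.
#' @export
iucn_cluster_trajectory <- function(x, iucn_categories) {
  sp <- canonical_species(x)
  miss <- setdiff(sp, names(iucn_categories))
  if (length(miss))
    stop("missing IUCN categories for species: ",
         paste(miss, collapse = ", "))
  cat <- normalize_iucn(iucn_categories[sp])
  steps <- lapply(.iucn_order, function(cl) sp[cat == cl])
  steps <- steps[lengths(steps) > 0L]
  extinction_trajectory(steps, "iucn")
}

#' Random cluster trajectories (null for the IUCN-based scenario)
#'
#' Each replicate randomly partitions the species into clusters of the
#' given sizes and removes them in the given order, mirroring the cluster
#' structure of the IUCN-based trajectory while randomizing which species
#' fall in which cluster.
#'
#' @param x an [assemblage()] or character vector of species.
#' @param cluster_sizes integer vector summing to S.
#' @param n replicates (default 999).
#' @param seed integer seed.
#' @return a list of `extinction_trajectory` objects.
#' @export
random_cluster_trajectories <- function(x, cluster_sizes, n = 999, seed = 1) {
  sp <- canonical_species(x)
  S <- length(sp)
  cluster_sizes <- as.integer(cluster_sizes)
  if (any(cluster_sizes <= 0L) || sum(cluster_sizes) != S)
    stop("cluster sizes must be positive and sum to the number of species")
  if (n < 2L) stop("need n >= 2 replicates")
  idx <- rep(seq_along(cluster_sizes), cluster_sizes)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    shuffled <- sp[sample.int(S)]
    extinction_trajectory(split(shuffled, idx), "iucn-null")
  })
}
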