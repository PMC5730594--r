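#' Run the extinction scenarios for one assemblage
#'
#' Simulates the six scenarios — random (999 trajectories, averaged into
#' the redundancy index), greedy best-case and worst-case, abundance-based
#' (rarest first), trait-based (most vulnerable first, by the 0-100
#' intrinsic vulnerability score) and IUCN-based (clusters removed from CR
#' down to LC) — on one assemblage, and computes the standardized effect
#' size of each directional scenario against its random null. The
#' abundance- and trait-based scenarios share the sequential random null
#' (one null per assemblage); the IUCN-based scenario is compared to random
#' cluster removals with the same cluster sizes.
#'
#' @param tree the global `fdendro` (the assemblage is pruned to its induced
#'   subtree internally).
#' @param asm an [assemblage()] with at least two species.
#' @param vulnerability named numeric vector of intrinsic vulnerability
#'   scores (0-100); required for the trait-based scenario.
#' @param iucn named character vector of Red List categories; required for
#'   the IUCN-based scenario.
#' @param scenarios subset of
#'   `c("random", "best", "worst", "abundance", "trait", "iucn")`.
#' @param n_random null replicates (default 999).
#' @param seed integer seed for this assemblage's randomizations.
#' @param axis abscissa convention, see [loss_curve()].
#' @param keep_curves if TRUE, the loss curves of the directional scenarios
#'   are returned.
#' @return a list of class `scenario_result`: `results` (a data.frame with
#'   one row per scenario: `site`, `scenario`, `auc`, `ses`, `null_mean`,
#'   `null_sd`, `n_random`, `seed`), `null_aucs`, and optionally `curves`.
#'   Degenerate assemblages (zero functional richness) raise a condition of
#'   class `fdextinct_degenerate`.
#' @export
run_scenarios <- function(tree, asm, vulnerability = NULL, iucn = NULL,
                          scenarios = c("random", "best", "worst",
                                        "abundance", "trait", "iucn"),
                          n_random = 999, seed = 1,
                          axis = c("s_minus_1", "s"), keep_curves = FALSE) {
  axis <- match.arg(axis)
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  stopifnot(inherits(asm, "assemblage"))
  sp <- canonical_species(asm)
  if (length(sp) < 2L)
    stop(errorCondition("assemblage has fewer than two species",
                        class = "fdextinct_degenerate"))
  itree <- induced_for(tree, sp)
  fd_full <- functional_richness(itree, sp)
  if (fd_full <= 0)
    stop(errorCondition("degenerate assemblage: zero functional richness",
                        class = "fdextinct_degenerate"))
  S <- length(sp)

  need_null <- any(c("random", "abundance", "trait") %in% scenarios)
  null_aucs <- NULL
  if (need_null)
    null_aucs <- null_auc_distribution(itree, sp, n = n_random, seed = seed,
                                       axis = axis)
  ses_or_na <- function(obs, null) {
    tryCatch(standardized_effect_size(obs, null),
             fdextinct_ses_undefined = function(e) NA_real_)
  }
  curve_auc <- function(traj) trapezoid_auc(loss_curve(itree, sp, traj, axis))

  rows <- list()
  curves <- list()
  add <- function(scenario, auc, ses = NA_real_, nm = NA_real_,
                  nsd = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      site = asm$site_id, scenario = scenario, auc = auc, ses = ses,
      null_mean = nm, null_sd = nsd, n_random = n_random, seed = seed,
      stringsAsFactors = FALSE)
  }

  if ("random" %in% scenarios)
    add("random", mean(null_aucs), nm = mean(null_aucs),
        nsd = stats::sd(null_aucs))
  if ("best" %in% scenarios) {
    traj <- greedy_trajectory(itree, sp, "best")
    if (keep_curves) curves$best <- loss_curve(itree, sp, traj, axis)
    add("best", curve_auc(traj))
  }
  if ("worst" %in% scenarios) {
    traj <- greedy_trajectory(itree, sp, "worst")
    if (keep_curves) curves$worst <- loss_curve(itree, sp, traj, axis)
    add("worst", curve_auc(traj))
  }
  if ("abundance" %in% scenarios) {
    traj <- score_ranked_trajectory(sp, asm$abundance, "ascending",
                                    scenario = "abundance")
    if (keep_curves) curves$abundance <- loss_curve(itree, sp, traj, axis)
    a <- curve_auc(traj)
    add("abundance", a, ses_or_na(a, null_aucs), mean(null_aucs),
        stats::sd(null_aucs))
  }
  if ("trait" %in% scenarios) {
    if (is.null(vulnerability))
      stop("trait-based scenario requires vulnerability scores")
    traj <- score_ranked_trajectory(sp, vulnerability, "descending",
                                    scenario = "trait")
    if (keep_curves) curves$trait <- loss_curve(itree, sp, traj, axis)
    a <- curve_auc(traj)
    add("trait", a, ses_or_na(a, null_aucs), mean(null_aucs),
        stats::sd(null_aucs))
  }
  if ("iucn" %in% scenarios) {
    if (is.null(iucn))
      stop("IUCN-based scenario requires Red List categories")
    traj <- iucn_cluster_trajectory(sp, iucn)
    if (keep_curves) curves$iucn <- loss_curve(itree, sp, traj, axis)
    a <- curve_auc(traj)
    sizes <- lengths(traj$steps)
    cl_null <- cluster_null_aucs(itree, sp, sizes, n = n_random,
                                 seed = seed, axis = axis)
    add("iucn", a, ses_or_na(a, cl_null), mean(cl_null),
        stats::sd(cl_null))
  }

  structure(list(site_id = asm$site_id, n_species = S, fd = fd_full,
                 results = do.call(rbind, rows), null_aucs = null_aucs,
                 curves = if (keep_curves) curves),
            class = "scenario_result")
}

#' Null AUC distribution for cluster removals
#'
#' Random partitions of the assemblage into clusters of the given sizes,
#' removed in the given order: the null model for the IUCN-based scenario.
#'
#' @inheritParams null_auc_distribution
#' @param cluster_sizes integer vector summing to S.
#' @return numeric vector of `n` AUC values.
#' @export
cluster_null_aucs <- function(tree, x, cluster_sizes, n = 999, seed = 1,
                              axis = c("s_minus_1", "s")) {
  axis <- match.arg(axis)
  sp <- canonical_species(x)
  S <- length(sp)
  cluster_sizes <- as.integer(cluster_sizes)
  if (any(cluster_sizes <= 0L) || sum(cluster_sizes) != S)
    stop("cluster sizes must be positive and sum to the number of species")
  if (n < 2L) stop("need n >= 2 replicates")
  itree <- induced_for(tree, sp)
  idx <- rep(seq_along(cluster_sizes), cluster_sizes)
  set.seed(seed)
  posmat <- vapply(seq_len(n), function(i) {
    p <- integer(S); p[sample.int(S)] <- idx; p
  }, integer(S))
  auc_cluster_batch(itree, posmat, cluster_sizes, axis)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario results for '%s' (S = %d, FD = %.4f):\n",
              x$site_id, x$n_species, x$fd))
  print(x$results, row.names = FALSE)
  invisible(x)
}
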