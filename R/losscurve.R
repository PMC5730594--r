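#' Functional loss curve of an extinction trajectory
#'
#' Applies a trajectory to an assemblage and records, after each removal
#' step, the residual proportion of functional richness (y) against the
#' proportion of species lost (x). The curve starts at (0, 1) and ends at
#' (1, 0).
#'
#' Two abscissa conventions are supported. The default,
#' `axis = "s_minus_1"`, divides the cumulative number of removals by
#' S - 1, so the terminal observable state of a sequential trajectory (one
#' species left, zero functional richness) sits exactly at x = 1 and a
#' two-species assemblage has AUC 1/2. The alternative `axis = "s"` divides
#' by S and appends a terminal point at (1, 0). Cluster trajectories cap x
#' at 1 once at most one species remains.
#'
#' @param tree an `fdendro` containing the assemblage's species.
#' @param x an [assemblage()] or character vector of species (S >= 2).
#' @param trajectory an [extinction_trajectory()] over those species.
#' @param axis `"s_minus_1"` (default) or `"s"`.
#' @return an object of class `loss_curve`: a data.frame with columns `x`
#'   and `y`, with the scenario, assemblage size and axis convention as
#'   attributes.
#' @export
loss_curve <- function(tree, x, trajectory, axis = c("s_minus_1", "s")) {
  axis <- match.arg(axis)
  stopifnot(inherits(trajectory, "extinction_trajectory"))
  sp <- canonical_species(x)
  S <- length(sp)
  if (S < 2L) stop("need at least two species")
  removed_all <- unlist(trajectory$steps)
  if (!all(removed_all %in% sp))
    stop("trajectory removes species absent from the assemblage")
  fd0 <- functional_richness(tree, sp)
  if (fd0 <= 0)
    stop(errorCondition(paste0("degenerate assemblage: zero functional ",
                               "richness among ", S, " species"),
                        class = "fdextinct_degenerate"))
  denom <- if (axis == "s_minus_1") S - 1L else S
  xs <- 0; ys <- 1
  remaining <- sp
  lost <- 0L
  for (step in trajectory$steps) {
    remaining <- setdiff(remaining, step)
    lost <- lost + length(step)
    fd <- if (length(remaining) >= 2L)
      functional_richness(tree, remaining) else 0
    xs <- c(xs, min(lost / denom, 1))
    ys <- c(ys, fd / fd0)
  }
  if (xs[length(xs)] < 1) { xs <- c(xs, 1); ys <- c(ys, 0) }
  # cluster caps can stack several points at x = 1; keep the first
  at_end <- xs >= 1
  if (sum(at_end) > 1L) {
    keep <- !at_end | seq_along(xs) == which(at_end)[1L]
    xs <- xs[keep]; ys <- ys[keep]
  }
  structure(data.frame(x = xs, y = ys),
            class = c("loss_curve", "data.frame"),
            scenario = trajectory$scenario, n_species = S, axis = axis)
}

#' Area under a functional loss curve
#'
#' Trapezoidal integral of the residual functional-richness proportion over
#' the proportion of species lost, on [0, 1]. Low AUC means high functional
#' sensitivity (function is lost early along the trajectory); high AUC means
#' redundancy buffers the early removals.
#'
#' @param curve a [loss_curve()], or any data.frame with `x` and `y`.
#' @return the AUC, in [0, 1] for curves with y in [0, 1].
#' @export
trapezoid_auc <- function(curve) {
  xs <- curve$x; ys <- curve$y
  if (length(xs) < 2L || is.unsorted(xs))
    stop("curve must have >= 2 points with non-decreasing x")
  sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
}

#' Standardized effect size of a directional scenario
#'
#' `SES = (obs - mean_r) / sd_r`, where `mean_r` and `sd_r` are the mean
#' and (sample) standard deviation of the AUC values of the random
#' trajectories. Negative SES means the directional scenario erodes
#' functional richness faster than random extinction.
#'
#' @param obs_auc observed AUC of the directional trajectory.
#' @param random_aucs numeric vector (length >= 2) of null AUC values.
#' @return the SES.
#' @export
standardized_effect_size <- function(obs_auc, random_aucs) {
  if (length(random_aucs) < 2L) stop("need at least two random AUC values")
  s <- stats::sd(random_aucs)
  if (!is.finite(s) || s == 0)
    stop(errorCondition("null AUC standard deviation is zero; SES undefined",
                        class = "fdextinct_ses_undefined"))
  (obs_auc - mean(random_aucs)) / s
}
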