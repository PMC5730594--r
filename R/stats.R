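#' Saturation regression of functional on taxonomic richness
#'
#' Ordinary least squares of functional richness on species richness and
#' its square. A saturating (decelerating, concave) relationship — the
#' signature of functional redundancy accumulating in species-rich
#' assemblages — is flagged when the quadratic term is significant (partial
#' t test, equivalent to the partial F test with one degree of freedom) AND
#' the fitted parabola is concave (negative quadratic coefficient). Both
#' the raw coefficient and the concavity flag are reported, since a
#' significant quadratic term alone does not distinguish saturation from
#' acceleration.
#'
#' @param richness species richness values (length >= 4, not constant).
#' @param fd functional richness values, same length.
#' @param alpha significance level for the saturation flag (default 0.05).
#' @return an object of class `saturation_fit`: coefficients (intercept,
#'   linear, quadratic), `p_quadratic`, `r_squared`, `n`, `concave` and
#'   `saturated`.
#' @export
saturation_regression <- function(richness, fd, alpha = 0.05) {
  stopifnot(length(richness) == length(fd))
  ok <- is.finite(richness) & is.finite(fd)
  richness <- richness[ok]; fd <- fd[ok]
  n <- length(richness)
  if (n < 4L) stop("need at least 4 paired observations")
  if (length(unique(richness)) < 3L)
    stop("species richness is (nearly) constant: quadratic design singular")
  fit <- stats::lm(fd ~ richness + I(richness^2))
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("singular design in saturation regression")
  sm <- summary(fit)
  p_quad <- sm$coefficients["I(richness^2)", "Pr(>|t|)"]
  concave <- cf[["I(richness^2)"]] < 0
  structure(list(coefficients = c(intercept = cf[[1L]], linear = cf[[2L]],
                                  quadratic = cf[[3L]]),
                 p_quadratic = p_quad, r_squared = sm$r.squared, n = n,
                 concave = concave,
                 saturated = is.finite(p_quad) && p_quad < alpha && concave,
                 fit = fit),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf(paste0("Saturation regression (n = %d): FD = %.4g %+.4g*SR ",
                     "%+.4g*SR^2\n"), x$n, x$coefficients[1L],
              x$coefficients[2L], x$coefficients[3L]))
  cat(sprintf("  quadratic term p = %.4g, r^2 = %.3f, %s\n", x$p_quadratic,
              x$r_squared,
              if (x$saturated) "saturating (concave, significant)"
              else "no saturation flagged"))
  invisible(x)
}

#' Spearman rank association
#'
#' Rank correlation between two paired variables with a two-sided p-value;
#' used for the association between species richness and functional
#' redundancy.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @return a list with `rho`, `p_value` and `n`.
#' @export
spearman_association <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Non-parametric group comparison with post-hoc letters
#'
#' Kruskal-Wallis omnibus test across groups, followed by pairwise Wilcoxon
#' rank-sum tests with Bonferroni-adjusted p-values and a compact letter
#' display: groups sharing a letter were not significantly different at
#' `alpha`. Exact Wilcoxon distributions are used where sample sizes allow
#' (the `stats::wilcox.test` default), the normal approximation with
#' continuity correction otherwise.
#'
#' @param values numeric vector of index values.
#' @param groups factor (or coercible) of group labels; every group needs
#'   at least two values.
#' @param alpha significance level (default 0.05).
#' @return a list with `omnibus_p`, `kruskal_statistic`, `pairwise`
#'   (matrix of Bonferroni-adjusted p-values), `letters` (named character),
#'   and `n` per group.
#' @export
group_comparison <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L))
    stop("groups with fewer than 2 values: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  kw <- stats::kruskal.test(values, groups)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(values, groups,
                                p.adjust.method = "bonferroni"))$p.value
  g <- levels(groups)
  pm <- matrix(1, length(g), length(g), dimnames = list(g, g))
  for (i in rownames(pw)) for (j in colnames(pw))
    if (!is.na(pw[i, j])) pm[i, j] <- pm[j, i] <- pw[i, j]
  letters_out <- letter_display(pm, values, groups, alpha)
  list(omnibus_p = kw$p.value, kruskal_statistic = unname(kw$statistic),
       pairwise = pm, letters = letters_out, n = as.vector(tab),
       groups = g)
}

# compact letter display: order groups by median, sweep maximal runs of
# mutually non-significant groups, one letter per run
letter_display <- function(pmat, values, groups, alpha) {
  g <- rownames(pmat)
  med <- vapply(g, function(x) stats::median(values[groups == x]), numeric(1))
  ord <- g[order(med)]
  runs <- list()
  i <- 1L
  while (i <= length(ord)) {
    j <- i
    while (j < length(ord) &&
           all(pmat[ord[i:(j + 1L)], ord[i:(j + 1L)]][
             upper.tri(diag(j - i + 2L))] >= alpha))
      j <- j + 1L
    run <- ord[i:j]
    if (!length(runs) || !all(run %in% runs[[length(runs)]]))
      runs[[length(runs) + 1L]] <- run
    i <- i + 1L
  }
  lab <- stats::setNames(rep("", length(g)), g)
  for (k in seq_along(runs))
    lab[runs[[k]]] <- paste0(lab[runs[[k]]], letters[k])
  lab
}

#' One-sided Wilcoxon signed-rank test of SES values against zero
#'
#' Tests whether standardized effect sizes are significantly lower than
#' zero (the directional scenario erodes function faster than random
#' extinction), by a one-sided (less) Wilcoxon signed-rank test.
#'
#' @param ses numeric vector of SES values (>= 5 non-missing, not all zero).
#' @return a list with `p_value`, `statistic`, `n` and `mean_ses`.
#' @export
ses_sign_test <- function(ses) {
  ses <- ses[is.finite(ses)]
  if (length(ses) < 5L) stop("need at least 5 non-missing SES values")
  if (all(ses == 0)) stop("all SES values are zero: test undefined")
  wt <- suppressWarnings(stats::wilcox.test(ses, mu = 0,
                                            alternative = "less"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n = length(ses), mean_ses = mean(ses))
}
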