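#' Gower dissimilarity for mixed nominal / ordered traits
#'
#' Pairwise Gower dissimilarity between species: the unweighted mean over
#' traits of per-trait contributions. A nominal trait contributes 0 when the
#' two species share the category and 1 otherwise; an ordered trait with L
#' declared levels, ranked 1..L in schema order, contributes
#' `|rank_a - rank_b| / (L - 1)` (classical range-scaled ranks). All values
#' therefore lie in [0, 1], with 0 exactly for identical trait vectors.
#'
#' @param table species-by-trait data.frame (species as row names),
#'   conforming to `schema`.
#' @param schema a [trait_schema()].
#' @return a symmetric numeric matrix with zero diagonal and species
#'   dimnames; a 1x1 zero matrix for a single species.
#' @examples
#' tab <- data.frame(size = c("0-8", "8.1-15"),
#'                   vertical_position = c("benthic", "benthic"),
#'                   trophic_group = c("omnivorous", "omnivorous"),
#'                   spawning_habitat = c("lithophilic", "lithophilic"),
#'                   swimming_mode = c("carangiform", "carangiform"),
#'                   row.names = c("sp1", "sp2"))
#' gower_dissimilarity(tab, fish_trait_schema())
#' @export
gower_dissimilarity <- function(table, schema) {
  table <- validate_trait_table(table, schema)
  n <- nrow(table)
  sp <- rownames(table)
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  if (n < 2L) return(d)
  for (tr in schema$traits) {
    v <- table[[tr$name]]
    if (tr$kind == "ordered") {
      L <- length(tr$levels)
      r <- match(v, tr$levels)
      contrib <- abs(outer(r, r, "-")) / (L - 1)
    } else {
      contrib <- 1 - outer(v, v, "==")
    }
    d <- d + contrib
  }
  d <- d / length(schema$traits)
  diag(d) <- 0
  d
}

# validate a square dissimilarity matrix (symmetry, zero diagonal, range)
check_dissimilarity <- function(d, tol = 1e-10) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("dissimilarity must be a square matrix or 'dist'")
  if (any(d < -tol)) stop("negative dissimilarities")
  if (max(abs(d - t(d))) > tol) stop("dissimilarity matrix is not symmetric")
  if (any(abs(diag(d)) > tol)) stop("dissimilarity diagonal is not zero")
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("sp", seq_len(nrow(d))),
                        paste0("sp", seq_len(nrow(d))))
  d
}
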