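#' Construct an assemblage
#'
#' An assemblage is one site's species set with strictly positive
#' standardized abundances (densities) and site metadata: the aquatic
#' system (lake, river or estuary), the biogeographical region, and the
#' within-system category (small/large for lakes and estuaries; HWS, MGR,
#' LLR or MES for rivers).
#'
#' @param site_id character site identifier.
#' @param abundance named numeric vector of standardized densities, one
#'   entry per species, all > 0.
#' @param system one of `"lake"`, `"river"`, `"estuary"`.
#' @param region one of `"Danubian"`, `"Iberian"` (or NA).
#' @param category system category label (or NA).
#' @return an object of class `assemblage`.
#' @export
assemblage <- function(site_id, abundance, system,
                       region = NA_character_, category = NA_character_) {
  system <- match.arg(system, c("lake", "river", "estuary"))
  if (length(abundance) < 1L || is.null(names(abundance)) ||
      anyDuplicated(names(abundance)))
    stop("`abundance` must be a named vector with unique species names")
  if (any(!is.finite(abundance)) || any(abundance <= 0))
    stop("abundances must be strictly positive")
  structure(list(site_id = as.character(site_id), abundance = abundance,
                 species = names(abundance), system = system,
                 region = region, category = category),
            class = "assemblage")
}

#' @export
print.assemblage <- function(x, ...) {
  cat(sprintf("Assemblage '%s' (%s%s): %d species\n", x$site_id, x$system,
              if (!is.na(x$region)) paste0(", ", x$region) else "",
              length(x$species)))
  invisible(x)
}

#' Classify a lake or estuary into a size category
#'
#' Surface-area thresholds: 0.68 km2 for lakes and 25 km2 for estuaries.
#' Sites at or above the threshold are "large" (boundary goes to large by
#' convention).
#'
#' @param system `"lake"` or `"estuary"`; river categories are supplied by
#'   the survey typology, not derived, so rivers are an error here.
#' @param surface_area_km2 positive surface area.
#' @return `"small"` or `"large"`.
#' @export
classify_size_category <- function(system, surface_area_km2) {
  system <- match.arg(system, c("lake", "estuary", "river"))
  if (system == "river")
    stop("river categories (HWS/MGR/LLR/MES) are supplied, not derived")
  if (!is.finite(surface_area_km2) || surface_area_km2 <= 0)
    stop("surface area must be positive")
  thr <- c(lake = 0.68, estuary = 25)[[system]]
  if (surface_area_km2 >= thr) "large" else "small"
}

#' Filter river sites by sampling reliability
#'
#' Retains river records with fished area strictly greater than 100 m2 and
#' strictly more than 50 individuals caught in total, the inclusion rule
#' used to limit false absences in electrofishing surveys.
#'
#' @param records data.frame with columns `fished_area_m2` and
#'   `n_individuals` (one row per site).
#' @return the retained rows (possibly zero rows).
#' @export
filter_river_sites <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("fished_area_m2", "n_individuals") %in% colnames(records)))
  records[records$fished_area_m2 > 100 & records$n_individuals > 50, ,
          drop = FALSE]
}

#' Standardize raw counts to a per-system density
#'
#' Estuaries: individuals per 1000 m2 of trawled surface. Rivers:
#' individuals per m2 of fished area. Lakes: catch per unit effort,
#' individuals per m2 of net per night (`effort` = net area times nights).
#'
#' @param counts non-negative counts.
#' @param effort positive sampled effort in the system's unit (m2, or
#'   m2 x nights for lakes).
#' @param system `"lake"`, `"river"` or `"estuary"`.
#' @return densities on the system's conventional scale.
#' @export
standardize_abundance <- function(counts, effort, system) {
  system <- match.arg(system, c("lake", "river", "estuary"))
  if (any(!is.finite(effort)) || any(effort <= 0))
    stop("effort must be strictly positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  scale <- if (system == "estuary") 1000 else 1
  counts / effort * scale
}

#' Pool repeated samplings of one site into an assemblage
#'
#' Species occurrences are pooled over all samplings of a locality; the
#' pooled density of a species is its total count divided by total effort
#' (an effort-weighted ratio, invariant to splitting one sampling into two
#' with proportional effort), then rescaled by the system convention.
#'
#' @param samplings data.frame in long format with columns `sampling`
#'   (sampling identifier), `species`, `count`, and `effort` (the effort of
#'   the sampling, repeated on each of its rows and consistent within a
#'   sampling).
#' @param site_id site identifier for the assemblage.
#' @param system,region,category passed to [assemblage()].
#' @return an [assemblage()]; species never caught are absent.
#' @export
pool_samples <- function(samplings, site_id, system,
                         region = NA_character_, category = NA_character_) {
  stopifnot(is.data.frame(samplings),
            all(c("sampling", "species", "count", "effort") %in%
                  colnames(samplings)))
  if (nrow(samplings) == 0L) stop("no samplings for site ", site_id)
  eff <- tapply(samplings$effort, samplings$sampling, function(e) {
    if (length(unique(e)) != 1L) stop("inconsistent effort within a sampling")
    e[1L]
  })
  total_effort <- sum(eff)
  counts <- tapply(samplings$count, samplings$species, sum)
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("no individuals caught at site ", site_id)
  dens <- standardize_abundance(as.numeric(counts), total_effort, system)
  names(dens) <- names(counts)
  assemblage(site_id, dens, system, region, category)
}

#' Read a long-format abundance table
#'
#' Expected columns: `site`, `species`, `count`, `effort`, and optionally
#' `sampling` (defaults to one sampling per site). A wide site-by-species
#' matrix can be read with [read_wide_abundance()].
#'
#' @param file CSV/TSV path (separator inferred from extension).
#' @return a data.frame.
#' @export
read_abundance_long <- function(file) {
  sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  x <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("site", "species", "count", "effort")
  miss <- setdiff(need, colnames(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"sampling" %in% colnames(x)) x$sampling <- "s1"
  x
}

#' Read a wide site-by-species abundance matrix
#'
#' First column = site identifier; remaining columns are species densities
#' (already standardized). Zeros mean absence.
#'
#' @param file CSV/TSV path.
#' @return a numeric matrix with site row names and species columns.
#' @export
read_wide_abundance <- function(file) {
  sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  x <- utils::read.table(file, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  m
}
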