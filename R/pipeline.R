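#' Configuration for a full study run
#'
#' Bundles the synthetic-generator configuration (or pre-built inputs), the
#' scenario list, the null size, the abscissa convention and the master
#' seed. Every source of randomness in [run_study()] derives from the
#' master seed through per-assemblage child seeds, so results are
#' reproducible and independent of processing order.
#'
#' @param generator a [generator_config()]; ignored if `pool` and
#'   `assemblages` are supplied directly to [run_study()].
#' @param scenarios subset of the six scenario names.
#' @param n_random null replicates per assemblage (default 999, >= 2).
#' @param seed master seed (overrides the generator's seed).
#' @param axis abscissa convention, see [loss_curve()].
#' @return a list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       scenarios = c("random", "best", "worst",
                                     "abundance", "trait", "iucn"),
                       n_random = 999, seed = 1,
                       axis = c("s_minus_1", "s")) {
  axis <- match.arg(axis)
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  if (n_random < 2L) stop("n_random must be at least 2")
  generator$seed <- seed
  structure(list(generator = generator, scenarios = scenarios,
                 n_random = as.integer(n_random), seed = as.integer(seed),
                 axis = axis),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] and [generator_config()]:
#' `seed`, `n_random`, `axis`, `scenarios`, and a `generator` block with
#' `pool_size`, `n_sites`, `richness_ranges`, `coupling`, etc.
#'
#' @param file YAML path.
#' @return a `run_config`.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  gen_args <- y$generator
  if (!is.null(gen_args$richness_ranges))
    gen_args$richness_ranges <- lapply(gen_args$richness_ranges, unlist)
  if (!is.null(gen_args$n_sites)) gen_args$n_sites <- unlist(gen_args$n_sites)
  if (!is.null(gen_args$iucn_proportions))
    gen_args$iucn_proportions <- unlist(gen_args$iucn_proportions)
  gen <- do.call(generator_config, if (is.null(gen_args)) list() else gen_args)
  args <- list(generator = gen)
  for (k in c("scenarios", "n_random", "seed", "axis"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

#' Run the full functional-sensitivity study
#'
#' Orchestrates the whole pipeline: builds (or accepts) the species pool
#' and its functional dendrogram, assigns extinction-driver covariates,
#' generates (or accepts) the assemblages, runs the requested extinction
#' scenarios per assemblage with derived child seeds, and performs the
#' statistical stages — saturation regression of functional on species
#' richness per system, Spearman association of redundancy with richness,
#' Kruskal-Wallis comparisons across systems, and one-sided tests of the
#' directional SES values per system.
#'
#' @param config a [run_config()].
#' @param pool optional pre-built species-by-trait table (else synthetic).
#' @param assemblages optional list of [assemblage()] objects (else
#'   synthetic, for every system in the generator's `n_sites`).
#' @param drivers optional data.frame as from [assign_extinction_drivers()].
#' @param verbose print progress.
#' @return a list of class `fd_study` with elements `pool`, `tree`,
#'   `cophenetic_correlation`, `drivers`, `results` (long per-scenario
#'   data.frame), `sites` (one row per assemblage), `stats` (inference
#'   results per system), `skipped` (degenerate assemblages with reasons)
#'   and `config`.
#' @export
run_study <- function(config = run_config(), pool = NULL,
                      assemblages = NULL, drivers = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  gen <- config$generator
  say <- function(...) if (verbose) message(...)

  if (is.null(pool)) {
    say("generating species pool (", gen$pool_size, " species)")
    pool <- generate_species_pool(gen)
  } else {
    pool <- validate_trait_table(pool, gen$schema)
  }
  say("building Gower dissimilarities and UPGMA dendrogram")
  D <- gower_dissimilarity(pool, gen$schema)
  tree <- build_upgma_dendrogram(D)
  coph <- cophenetic_correlation(tree, D)

  if (is.null(drivers))
    drivers <- assign_extinction_drivers(pool, tree,
                                         coupling = gen$coupling,
                                         seed = config$seed,
                                         iucn_proportions =
                                           gen$iucn_proportions)
  vuln <- stats::setNames(drivers$vulnerability, drivers$species)
  iucn <- stats::setNames(drivers$iucn, drivers$species)

  if (is.null(assemblages)) {
    assemblages <- list()
    for (s in names(gen$n_sites)) {
      say("generating ", gen$n_sites[[s]], " ", s, " assemblages")
      assemblages <- c(assemblages, generate_assemblages(pool, gen, s))
    }
  }
  missing_tr <- setdiff(unique(unlist(lapply(assemblages, `[[`, "species"))),
                        rownames(pool))
  if (length(missing_tr))
    stop("assemblage species missing from the trait table: ",
         paste(missing_tr, collapse = ", "))

  say("running scenarios over ", length(assemblages), " assemblages")
  res_rows <- list(); site_rows <- list(); skipped <- list()
  for (asm in assemblages) {
    child <- derive_seed(config$seed, asm$site_id)
    sr <- tryCatch(
      run_scenarios(tree, asm, vulnerability = vuln, iucn = iucn,
                    scenarios = config$scenarios,
                    n_random = config$n_random, seed = child,
                    axis = config$axis),
      fdextinct_degenerate = function(e) e)
    if (inherits(sr, "condition")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(site = asm$site_id, reason = conditionMessage(sr),
                   stringsAsFactors = FALSE)
      next
    }
    meta <- data.frame(system = asm$system, region = asm$region,
                       category = asm$category,
                       richness = length(asm$species), fd = sr$fd,
                       stringsAsFactors = FALSE)
    res_rows[[length(res_rows) + 1L]] <- cbind(sr$results, meta)
    w <- sr$results
    site_rows[[length(site_rows) + 1L]] <- cbind(
      data.frame(site = asm$site_id, stringsAsFactors = FALSE), meta,
      data.frame(
        redundancy = if ("random" %in% w$scenario)
          w$auc[w$scenario == "random"] else NA_real_,
        auc_best = if ("best" %in% w$scenario)
          w$auc[w$scenario == "best"] else NA_real_,
        auc_worst = if ("worst" %in% w$scenario)
          w$auc[w$scenario == "worst"] else NA_real_,
        ses_abundance = if ("abundance" %in% w$scenario)
          w$ses[w$scenario == "abundance"] else NA_real_,
        ses_trait = if ("trait" %in% w$scenario)
          w$ses[w$scenario == "trait"] else NA_real_,
        ses_iucn = if ("iucn" %in% w$scenario)
          w$ses[w$scenario == "iucn"] else NA_real_))
  }
  results <- do.call(rbind, res_rows)
  sites <- do.call(rbind, site_rows)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(site = character(0), reason = character(0))

  say("running inference")
  stats_out <- study_inference(sites, config)

  structure(list(pool = pool, tree = tree,
                 cophenetic_correlation = coph, drivers = drivers,
                 results = results, sites = sites, stats = stats_out,
                 skipped = skipped, config = config),
            class = "fd_study")
}

# per-system saturation fits, redundancy~richness associations, cross-system
# comparisons, and one-sided SES tests
study_inference <- function(sites, config) {
  out <- list()
  systems <- unique(sites$system)
  out$saturation <- lapply(stats::setNames(systems, systems), function(s) {
    d <- sites[sites$system == s, ]
    tryCatch(saturation_regression(d$richness, d$fd),
             error = function(e) e)
  })
  if ("random" %in% config$scenarios)
    out$redundancy_vs_richness <-
      lapply(stats::setNames(systems, systems), function(s) {
        d <- sites[sites$system == s, ]
        tryCatch(spearman_association(d$richness, d$redundancy),
                 error = function(e) e)
      })
  if (length(systems) >= 2L) {
    out$richness_by_system <-
      tryCatch(group_comparison(sites$richness, sites$system),
               error = function(e) e)
    if ("random" %in% config$scenarios)
      out$redundancy_by_system <-
        tryCatch(group_comparison(sites$redundancy, sites$system),
                 error = function(e) e)
  }
  ses_cols <- c(abundance = "ses_abundance", trait = "ses_trait",
                iucn = "ses_iucn")
  ses_cols <- ses_cols[paste0("ses_", names(ses_cols)) %in% colnames(sites) &
                         names(ses_cols) %in% config$scenarios]
  ses_tests <- list()
  for (s in systems) for (sc in names(ses_cols)) {
    v <- sites[sites$system == s, ses_cols[[sc]]]
    ses_tests[[paste(s, sc, sep = ".")]] <-
      tryCatch(c(list(system = s, scenario = sc), ses_sign_test(v)),
               error = function(e) e)
  }
  out$ses_tests <- ses_tests
  out
}

#' @export
print.fd_study <- function(x, ...) {
  cat("Functional-sensitivity study:", nrow(x$sites), "assemblages,",
      nrow(x$pool), "pool species\n")
  cat("Cophenetic correlation of the pool dendrogram:",
      format(x$cophenetic_correlation, digits = 3), "\n")
  if (nrow(x$skipped))
    cat("Skipped (degenerate):", nrow(x$skipped), "assemblages\n")
  tab <- stats::aggregate(cbind(richness, fd) ~ system, data = x$sites, mean)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write the study's report tables
#'
#' Writes tidy CSVs (per-scenario results, per-site summary, SES tests,
#' saturation fits), the pool dendrogram as Newick, and a plain-text run
#' log recording the seed, counts and skipped assemblages.
#'
#' @param study an `fd_study` from [run_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study_outputs <- function(study, dir) {
  stopifnot(inherits(study, "fd_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$results, file.path(dir, "scenario_results.csv"),
                   row.names = FALSE)
  utils::write.csv(study$sites, file.path(dir, "site_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(study$skipped, file.path(dir, "skipped_sites.csv"),
                   row.names = FALSE)
  ses <- study$stats$ses_tests
  ok <- !vapply(ses, inherits, logical(1), "condition")
  if (any(ok)) {
    ses_df <- do.call(rbind, lapply(ses[ok], function(t)
      data.frame(system = t$system, scenario = t$scenario, n = t$n,
                 mean_ses = t$mean_ses, p_value = t$p_value)))
    utils::write.csv(ses_df, file.path(dir, "ses_tests.csv"),
                     row.names = FALSE)
  }
  sat <- study$stats$saturation
  ok <- !vapply(sat, inherits, logical(1), "condition")
  if (any(ok)) {
    sat_df <- do.call(rbind, lapply(names(sat)[ok], function(s) {
      f <- sat[[s]]
      data.frame(system = s, n = f$n, intercept = f$coefficients[1L],
                 linear = f$coefficients[2L],
                 quadratic = f$coefficients[3L],
                 p_quadratic = f$p_quadratic, r_squared = f$r_squared,
                 saturated = f$saturated)
    }))
    utils::write.csv(sat_df, file.path(dir, "saturation.csv"),
                     row.names = FALSE)
  }
  export_newick(study$tree, file.path(dir, "dendrogram.nwk"))
  log <- c(
    paste("master seed:", study$config$seed),
    paste("n_random:", study$config$n_random),
    paste("axis:", study$config$axis),
    paste("scenarios:", paste(study$config$scenarios, collapse = ", ")),
    paste("pool species:", nrow(study$pool)),
    paste("assemblages processed:", nrow(study$sites)),
    paste("assemblages skipped (degenerate):", nrow(study$skipped)),
    paste("cophenetic correlation:",
          format(study$cophenetic_correlation, digits = 6)))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
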