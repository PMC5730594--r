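#' Trait schema for a functional trait table
#'
#' A schema declares, for each trait, its name, whether it is nominal or
#' ordered, and its allowed categories (in rank order for ordered traits).
#' The Gower dissimilarity and all downstream validation are driven by the
#' schema, so trait coding is explicit rather than inferred from the data.
#'
#' @param traits a list; each element is a list with components `name`
#'   (character), `kind` (`"nominal"` or `"ordered"`) and `levels`
#'   (character vector of allowed categories, duplicate-free, in declared
#'   order).
#' @return an object of class `trait_schema`.
#' @seealso [fish_trait_schema()] for the default five-trait fish schema,
#'   [read_trait_schema()] to load a schema from a YAML file.
#' @export
trait_schema <- function(traits) {
  if (!is.list(traits) || length(traits) == 0L)
    stop("`traits` must be a non-empty list")
  for (tr in traits) {
    if (!all(c("name", "kind", "levels") %in% names(tr)))
      stop("each trait needs `name`, `kind` and `levels`")
    if (!tr$kind %in% c("nominal", "ordered"))
      stop("trait kind must be 'nominal' or 'ordered': ", tr$name)
    if (length(tr$levels) == 0L)
      stop("trait has no categories: ", tr$name)
    if (anyDuplicated(tr$levels))
      stop("duplicate categories in trait: ", tr$name)
  }
  nm <- vapply(traits, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate trait names")
  names(traits) <- nm
  structure(list(traits = traits), class = "trait_schema")
}

#' @export
print.trait_schema <- function(x, ...) {
  cat("Trait schema with", length(x$traits), "traits:\n")
  for (tr in x$traits)
    cat(sprintf("  %-18s %-8s %d levels: %s\n", tr$name, tr$kind,
                length(tr$levels), paste(tr$levels, collapse = ", ")))
  invisible(x)
}

#' Default five-trait fish functional schema
#'
#' The standard coarse trait coding used for European continental fish:
#' maximum body size in six ordered length classes, vertical position in the
#' water column (benthic vs non-benthic), trophic group (dominant diet
#' item), spawning habitat preference, and swimming mode (body-shape /
#' locomotion class).
#'
#' @return a `trait_schema` with five traits.
#' @export
fish_trait_schema <- function() {
  trait_schema(list(
    list(name = "size", kind = "ordered",
         levels = c("0-8", "8.1-15", "15.1-30", "30.1-50", "50.1-80", ">80.1")),
    list(name = "vertical_position", kind = "nominal",
         levels = c("benthic", "non-benthic")),
    list(name = "trophic_group", kind = "nominal",
         levels = c("piscivorous", "omnivorous", "planktivorous",
                    "insectivorous", "herbivorous", "detritivorous",
                    "parasitic")),
    list(name = "spawning_habitat", kind = "nominal",
         levels = c("lithophilic", "pelagophilic", "phytophilic",
                    "polyphilic", "nest builder", "internal brooder")),
    list(name = "swimming_mode", kind = "nominal",
         levels = c("carangiform", "sub-carangiform", "diodontiform",
                    "anguilliform", "labriform", "balistiform", "amiiform",
                    "rajiform"))
  ))
}

#' Validate a species-by-trait table against a schema
#'
#' Checks that the table has exactly the schema's traits as columns, unique
#' species row names, no missing values, and that every value is one of the
#' trait's allowed categories.
#'
#' @param table a data.frame with species identifiers as row names and one
#'   character column per trait.
#' @param schema a [trait_schema()].
#' @return the table, invisibly, with columns reordered to schema order.
#' @export
validate_trait_table <- function(table, schema) {
  stopifnot(inherits(schema, "trait_schema"), is.data.frame(table))
  sp <- rownames(table)
  if (is.null(sp) || anyDuplicated(sp))
    stop("trait table must have unique species row names")
  want <- names(schema$traits)
  miss <- setdiff(want, colnames(table))
  if (length(miss))
    stop("trait table is missing traits: ", paste(miss, collapse = ", "))
  table <- table[, want, drop = FALSE]
  for (nm in want) {
    v <- as.character(table[[nm]])
    if (anyNA(v)) stop("missing values in trait: ", nm)
    bad <- setdiff(unique(v), schema$traits[[nm]]$levels)
    if (length(bad))
      stop("unknown categories in trait '", nm, "': ",
           paste(bad, collapse = ", "))
    table[[nm]] <- v
  }
  invisible(table)
}

#' Read / write a trait table as CSV or TSV
#'
#' The file must have a header row; the first column holds species
#' identifiers. The separator is taken from the file extension (`.tsv` means
#' tab, anything else comma) unless `sep` is given.
#'
#' @param file path to a delimited text file.
#' @param schema optional [trait_schema()]; if supplied the table is
#'   validated against it.
#' @param sep field separator; default inferred from the extension.
#' @return a data.frame with species row names.
#' @export
read_trait_table <- function(file, schema = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  x <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  rownames(x) <- x[[1]]
  x <- x[, -1, drop = FALSE]
  if (!is.null(schema)) x <- validate_trait_table(x, schema)
  x
}

#' @rdname read_trait_table
#' @param table a species-by-trait data.frame with species row names.
#' @export
write_trait_table <- function(table, file, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  out <- cbind(species = rownames(table), table)
  utils::write.table(out, file, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Read a trait schema from a YAML file
#'
#' The file holds a list `traits:` of entries with `name`, `kind` and
#' `levels`, mirroring [trait_schema()].
#'
#' @param file path to a YAML schema file.
#' @return a `trait_schema`.
#' @export
read_trait_schema <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$traits)) y <- y$traits
  trait_schema(lapply(y, function(tr) {
    list(name = tr$name, kind = tr$kind, levels = as.character(tr$levels))
  }))
}
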