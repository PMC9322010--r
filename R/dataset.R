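#' Construct a CommunityDataset from its four tables
#'
#' Assembles and curates the unit of analysis: abundance, traits,
#' coordinates and environment tables with consistent labels. Species that
#' never occur and sites holding no species are dropped (curation), keeping
#' all four tables in step. Trait column types are guessed when not given:
#' numeric columns holding only 0/1 are \code{binary}, other numeric
#' columns \code{continuous}, everything else \code{categorical}; columns
#' named in \code{fuzzy_groups} are \code{fuzzy}.
#'
#' @param abundance sites x species numeric matrix (counts or cover),
#'   with site row names and species column names.
#' @param traits species x traits data.frame, row names = species.
#' @param coords sites x 2 matrix or data.frame of decimal-degree
#'   latitude and longitude (columns \code{lat}, \code{lon} or positional).
#' @param env sites x variables numeric matrix or data.frame.
#' @param trait_types optional named character vector typing each trait
#'   column (\code{continuous}, \code{binary}, \code{categorical},
#'   \code{fuzzy}).
#' @param fuzzy_groups named list mapping fuzzy group names to member
#'   trait columns; a whole group counts as a single trait.
#' @param meta list of dataset metadata: \code{realm}, \code{biotic_group},
#'   \code{body_size_log10_g}, \code{dispersal_mode},
#'   \code{occurrence_only}. Missing entries are filled with NA/FALSE.
#' @param drop_empty drop all-zero species/sites during curation
#'   (default TRUE).
#' @return a validated [CommunityDataset-class].
#' @examples
#' ds <- simulateDataset(simulationParams(seed = 1))
#' ds
#' @export
communityDataset <- function(abundance, traits, coords, env,
                             trait_types = NULL, fuzzy_groups = list(),
                             meta = list(), drop_empty = TRUE) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (any(abundance < 0, na.rm = TRUE))
    stop("negative abundances present")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(colnames(coords))) colnames(coords) <- c("lat", "lon")
  env <- as.data.frame(env)
  traits <- as.data.frame(traits)

  sites <- rownames(abundance)
  species <- colnames(abundance)
  .checkLabels(sites, rownames(coords), "abundance", "coords")
  .checkLabels(sites, rownames(env), "abundance", "env")
  .checkLabels(species, rownames(traits), "abundance (species)", "traits")
  coords <- coords[sites, , drop = FALSE]
  env <- env[sites, , drop = FALSE]
  traits <- traits[species, , drop = FALSE]

  if (drop_empty) {
    keep_sp <- colSums(abundance, na.rm = TRUE) > 0
    keep_si <- rowSums(abundance, na.rm = TRUE) > 0
    abundance <- abundance[keep_si, keep_sp, drop = FALSE]
    coords <- coords[keep_si, , drop = FALSE]
    env <- env[keep_si, , drop = FALSE]
    traits <- traits[keep_sp, , drop = FALSE]
  }

  env_m <- as.matrix(as.data.frame(lapply(env, function(x)
    if (is.numeric(x)) x else suppressWarnings(as.numeric(as.character(x))))))
  rownames(env_m) <- rownames(env)

  if (is.null(trait_types)) {
    trait_types <- vapply(traits, function(x) {
      if (is.numeric(x)) {
        v <- x[!is.na(x)]
        if (length(v) && all(v %in% c(0, 1))) "binary" else "continuous"
      } else "categorical"
    }, character(1))
  }
  for (g in names(fuzzy_groups)) trait_types[fuzzy_groups[[g]]] <- "fuzzy"
  trait_types <- trait_types[colnames(traits)]
  names(trait_types) <- colnames(traits)

  meta_full <- list(realm = NA_character_, biotic_group = NA_character_,
                    body_size_log10_g = NA_real_,
                    dispersal_mode = NA_character_, occurrence_only = FALSE)
  meta_full[names(meta)] <- meta

  new("CommunityDataset", abundance = abundance, traits = traits,
      coords = coords, env = env_m, traitTypes = trait_types,
      fuzzyGroups = fuzzy_groups, meta = meta_full)
}

.checkLabels <- function(a, b, name_a, name_b) {
  if (is.null(b)) stop(sprintf("%s table has no labels", name_b))
  if (!setequal(a, b)) {
    miss <- setdiff(a, b); extra <- setdiff(b, a)
    stop(sprintf(
      "label mismatch between %s and %s: missing from %s: %s; extra in %s: %s",
      name_a, name_b, name_b,
      if (length(miss)) paste(utils::head(miss, 5), collapse = ", ") else "none",
      name_b,
      if (length(extra)) paste(utils::head(extra, 5), collapse = ", ") else "none"))
  }
  invisible(TRUE)
}

#' @rdname dataset-accessors
setMethod("abundance", "CommunityDataset", function(x) x@abundance)
#' @rdname dataset-accessors
setMethod("speciesTraits", "CommunityDataset", function(x) x@traits)
#' @rdname dataset-accessors
setMethod("siteCoords", "CommunityDataset", function(x) x@coords)
#' @rdname dataset-accessors
setMethod("envData", "CommunityDataset", function(x) x@env)
#' @rdname dataset-accessors
setMethod("datasetMeta", "CommunityDataset", function(x) x@meta)
#' @rdname dataset-accessors
setMethod("traitTypes", "CommunityDataset", function(x) x@traitTypes)
#' @rdname dataset-accessors
setMethod("fuzzyGroups", "CommunityDataset", function(x) x@fuzzyGroups)
#' @rdname dataset-accessors
setMethod("nSites", "CommunityDataset", function(x) nrow(x@abundance))
#' @rdname dataset-accessors
setMethod("nSpecies", "CommunityDataset", function(x) ncol(x@abundance))

setMethod("show", "CommunityDataset", function(object) {
  cat("CommunityDataset:", nrow(object@abundance), "sites x",
      ncol(object@abundance), "species\n")
  cat("  traits:", ncol(object@traits), "columns (",
      .nTraitUnits(object@traitTypes, object@fuzzyGroups),
      "trait units )\n")
  cat("  env variables:", ncol(object@env), "\n")
  cat("  realm:", object@meta$realm, "| biotic group:",
      object@meta$biotic_group, "\n")
})

# Number of traits toward the inclusion rule: a fuzzy group of columns
# counts as ONE trait.
.nTraitUnits <- function(types, fuzzy_groups) {
  sum(types != "fuzzy") + length(fuzzy_groups)
}

#' Apply the dataset inclusion rules
#'
#' A dataset enters the analysis only if it has at least 10 sites, at
#' least two environmental variables and at least three traits or trait
#' categories (a fuzzy-coded group of columns counts as one trait).
#'
#' @param ds a [CommunityDataset-class].
#' @param min_sites,min_env,min_traits inclusion thresholds
#'   (defaults 10, 2, 3).
#' @return a \code{validation_report} list: \code{passed}, counts
#'   (\code{n_sites}, \code{n_species}, \code{n_traits}, \code{n_env}) and
#'   human-readable \code{messages} for each violated rule.
#' @examples
#' ds <- simulateDataset(simulationParams(n_sites = 12, seed = 1))
#' validateDataset(ds)$passed
#' @export
validateDataset <- function(ds, min_sites = 10L, min_env = 2L,
                            min_traits = 3L) {
  stopifnot(is(ds, "CommunityDataset"))
  n_sites <- nSites(ds)
  n_env <- ncol(envData(ds))
  n_traits <- .nTraitUnits(traitTypes(ds), fuzzyGroups(ds))
  msgs <- character(0)
  if (n_sites < min_sites)
    msgs <- c(msgs, sprintf("only %d sites (>= %d required)", n_sites, min_sites))
  if (n_env < min_env)
    msgs <- c(msgs, sprintf("only %d environmental variables (>= %d required)",
                            n_env, min_env))
  if (n_traits < min_traits)
    msgs <- c(msgs, sprintf("only %d traits or trait categories (>= %d required)",
                            n_traits, min_traits))
  structure(list(passed = length(msgs) == 0L, n_sites = n_sites,
                 n_species = nSpecies(ds), n_traits = n_traits,
                 n_env = n_env, messages = msgs),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Dataset validation:", if (x$passed) "PASSED" else "FAILED", "\n")
  cat(sprintf("  %d sites, %d species, %d traits, %d env variables\n",
              x$n_sites, x$n_species, x$n_traits, x$n_env))
  for (m in x$messages) cat("  -", m, "\n")
  invisible(x)
}

#' Curate the environmental table
#'
#' Keeps only continuous environmental variables whose fraction of missing
#' cells is strictly below \code{max_missing} (default 5\%); remaining
#' missing cells in retained variables are imputed by the column mean.
#' Abundance, traits and coordinates are untouched.
#'
#' @param ds a [CommunityDataset-class].
#' @param max_missing maximum tolerated missing fraction, strict
#'   (default 0.05).
#' @return a new [CommunityDataset-class] with the curated env table.
#' @export
filterEnvVariables <- function(ds, max_missing = 0.05) {
  stopifnot(is(ds, "CommunityDataset"))
  env <- envData(ds)
  frac_na <- colMeans(is.na(env))
  keep <- frac_na < max_missing & apply(env, 2, function(x) is.numeric(x))
  dropped <- colnames(env)[!keep]
  if (length(dropped))
    message("filterEnvVariables: dropped ", length(dropped), " variable(s): ",
            paste(dropped, collapse = ", "))
  env <- env[, keep, drop = FALSE]
  if (ncol(env) == 0)
    stop("no environmental variables survive curation")
  for (j in seq_len(ncol(env))) {
    na <- is.na(env[, j])
    if (any(na)) {
      env[na, j] <- mean(env[, j], na.rm = TRUE)
      message(sprintf("filterEnvVariables: imputed %d cell(s) of '%s' by column mean",
                      sum(na), colnames(env)[j]))
    }
  }
  initialize(ds, env = env)
}

#' Convert abundances to presence/absence
#'
#' Replaces the abundance matrix by a 0/1 presence matrix. Idempotent.
#'
#' @param ds a [CommunityDataset-class].
#' @return a new [CommunityDataset-class] in occurrence form.
#' @export
toOccurrence <- function(ds) {
  stopifnot(is(ds, "CommunityDataset"))
  ab <- abundance(ds)
  ab[] <- as.numeric(ab > 0)
  initialize(ds, abundance = ab)
}
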