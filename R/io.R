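#' Read a four-table dataset bundle from disk
#'
#' A bundle is a directory holding delimited tables \code{abundance},
#' \code{traits}, \code{coords} and \code{env} (CSV or TSV, autodetected by
#' extension; first column = row labels) plus an optional \code{schema.yml}
#' declaring trait column types, fuzzy groups and dataset metadata.
#'
#' @param path directory containing the bundle.
#' @return a validated [CommunityDataset-class].
#' @seealso [writeDatasetBundle()]
#' @export
readDatasetBundle <- function(path) {
  if (!dir.exists(path)) stop("bundle directory not found: ", path)
  tabs <- lapply(c(abundance = "abundance", traits = "traits",
                   coords = "coords", env = "env"), function(stem) {
    f <- list.files(path, pattern = paste0("^", stem, "\\.(csv|tsv)$"),
                    full.names = TRUE)
    if (length(f) == 0) stop("bundle is missing the '", stem, "' table")
    sep <- if (grepl("\\.tsv$", f[1])) "\t" else ","
    utils::read.table(f[1], header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8")
  })
  schema_file <- file.path(path, "schema.yml")
  schema <- if (file.exists(schema_file)) yaml::read_yaml(schema_file) else list()
  trait_types <- if (!is.null(schema$trait_types))
    unlist(schema$trait_types) else NULL
  fuzzy_groups <- if (!is.null(schema$fuzzy_groups))
    lapply(schema$fuzzy_groups, unlist) else list()
  meta <- if (!is.null(schema$meta)) schema$meta else list()
  communityDataset(tabs$abundance, tabs$traits, tabs$coords, tabs$env,
                   trait_types = trait_types, fuzzy_groups = fuzzy_groups,
                   meta = meta)
}

#' Write a CommunityDataset as a four-table bundle
#'
#' Inverse of [readDatasetBundle()]: writes \code{abundance.csv},
#' \code{traits.csv}, \code{coords.csv}, \code{env.csv} and a
#' \code{schema.yml} with trait types, fuzzy groups and metadata. The
#' round-trip load(write(ds)) reproduces all numeric cells.
#'
#' @param ds a [CommunityDataset-class].
#' @param path target directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
writeDatasetBundle <- function(ds, path) {
  stopifnot(is(ds, "CommunityDataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) {
    df <- data.frame(id = rownames(x), as.data.frame(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file.path(path, f), sep = ",", row.names = FALSE,
                       quote = TRUE, fileEncoding = "UTF-8")
  }
  wr(abundance(ds), "abundance.csv")
  wr(speciesTraits(ds), "traits.csv")
  wr(siteCoords(ds), "coords.csv")
  wr(envData(ds), "env.csv")
  schema <- list(trait_types = as.list(traitTypes(ds)),
                 fuzzy_groups = lapply(fuzzyGroups(ds), as.list),
                 meta = datasetMeta(ds))
  yaml::write_yaml(schema, file.path(path, "schema.yml"))
  invisible(path)
}

#' Write similarity or distance matrices in long format
#'
#' Writes one row per unordered site pair. For a
#' [PairwiseSimilarity-class]: site_i, site_j, facet, mode, S_total,
#' beta_total, beta_repl, beta_rich, a, b, c. For a \code{dist}: site_i,
#' site_j, kind, value.
#'
#' @param x a [PairwiseSimilarity-class] or a \code{dist} produced by
#'   [spatialDistanceMatrix()] / [environmentalDistanceMatrix()].
#' @param file output CSV path.
#' @param square write the square similarity/distance matrix instead of
#'   the long pair format (default FALSE).
#' @return \code{file}, invisibly.
#' @export
writePairsCSV <- function(x, file, square = FALSE) {
  if (square) {
    m <- if (is(x, "PairwiseSimilarity")) as.matrix(x) else as.matrix(x)
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file, sep = ",", row.names = FALSE, quote = TRUE)
    return(invisible(file))
  }
  if (is(x, "PairwiseSimilarity")) {
    df <- pairTable(x)
  } else if (inherits(x, "dist")) {
    labs <- attr(x, "Labels")
    pg <- .pairGrid(length(labs))
    df <- data.frame(site_i = labs[pg[, 1]], site_j = labs[pg[, 2]],
                     kind = attr(x, "kind") %||% "distance",
                     value = as.numeric(x))
  } else stop("unsupported object for writePairsCSV")
  utils::write.table(df, file, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
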