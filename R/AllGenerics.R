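#' @include AllClasses.R
NULL

#' Accessors for CommunityDataset slots
#'
#' @param x a [CommunityDataset-class].
#' @return \code{abundance} the sites x species matrix; \code{speciesTraits}
#'   the species x traits data.frame; \code{siteCoords} the sites x 2
#'   lat/lon matrix; \code{envData} the sites x variables matrix;
#'   \code{datasetMeta} the metadata list; \code{traitTypes} the per-column
#'   type vector; \code{fuzzyGroups} the fuzzy-group mapping.
#' @name dataset-accessors
#' @aliases abundance speciesTraits siteCoords envData datasetMeta
#'   traitTypes fuzzyGroups nSites nSpecies
NULL

#' @rdname dataset-accessors
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))
#' @rdname dataset-accessors
#' @export
setGeneric("speciesTraits", function(x) standardGeneric("speciesTraits"))
#' @rdname dataset-accessors
#' @export
setGeneric("siteCoords", function(x) standardGeneric("siteCoords"))
#' @rdname dataset-accessors
#' @export
setGeneric("envData", function(x) standardGeneric("envData"))
#' @rdname dataset-accessors
#' @export
setGeneric("datasetMeta", function(x) standardGeneric("datasetMeta"))
#' @rdname dataset-accessors
#' @export
setGeneric("traitTypes", function(x) standardGeneric("traitTypes"))
#' @rdname dataset-accessors
#' @export
setGeneric("fuzzyGroups", function(x) standardGeneric("fuzzyGroups"))
#' @rdname dataset-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname dataset-accessors
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' Volume of a hypervolume region
#'
#' @param x a [Hypervolume-class].
#' @return numeric volume in SD^3 units.
#' @export
setGeneric("volume", function(x) standardGeneric("volume"))

#' Similarity values of a PairwiseSimilarity object
#'
#' @param x a [PairwiseSimilarity-class].
#' @return condensed numeric vector of total similarities (dist order).
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))

#' Long-format pair table of a PairwiseSimilarity object
#'
#' One row per unordered site pair with columns site_i, site_j, facet,
#' mode, S_total, beta_total, beta_repl, beta_rich, a, b, c.
#'
#' @param x a [PairwiseSimilarity-class].
#' @return data.frame.
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
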