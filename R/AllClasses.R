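#' @import methods
NULL

#' CommunityDataset: the four linked tables of a distance-decay dataset
#'
#' An S4 container for the unit of analysis: a sites-by-species abundance
#' matrix, a species-by-traits table, a sites-by-coordinates table
#' (decimal-degree WGS84 latitude/longitude) and a sites-by-environment
#' table, plus dataset-level metadata (realm, biotic group, body size,
#' dispersal mode).
#'
#' Validity enforces label agreement across tables (abundance rows ==
#' coordinate rows == environment rows; abundance columns == trait rows),
#' non-negative abundances, coordinates within [-90, 90] x [-180, 180],
#' and (after curation) no empty sites or never-observed species.
#'
#' @slot abundance numeric matrix, sites x species, counts or cover.
#' @slot traits data.frame, species x traits; columns may be continuous,
#'   binary, categorical, or members of a fuzzy-coded group.
#' @slot coords numeric matrix, sites x 2, columns \code{lat}, \code{lon}.
#' @slot env numeric matrix, sites x environmental variables.
#' @slot traitTypes named character vector, one of \code{"continuous"},
#'   \code{"binary"}, \code{"categorical"}, \code{"fuzzy"} per trait column.
#' @slot fuzzyGroups named list mapping each fuzzy group name to its member
#'   trait columns; a whole group counts as one trait.
#' @slot meta list with elements \code{realm} (freshwater/marine/terrestrial),
#'   \code{biotic_group}, \code{body_size_log10_g}, \code{dispersal_mode}
#'   (active/passive/seed), \code{occurrence_only} flag.
#'
#' @seealso [communityDataset()], [validateDataset()], [readDatasetBundle()]
#' @export
setClass("CommunityDataset",
  representation(
    abundance  = "matrix",
    traits     = "data.frame",
    coords     = "matrix",
    env        = "matrix",
    traitTypes = "character",
    fuzzyGroups = "list",
    meta       = "list"
  )
)

.validCommunityDataset <- function(object) {
  msgs <- character(0)
  ab <- object@abundance
  if (is.null(rownames(ab)) || is.null(colnames(ab)))
    return("abundance matrix must have site row names and species column names")
  if (!identical(rownames(ab), rownames(object@coords)))
    msgs <- c(msgs, "site labels of abundance and coords differ")
  if (!identical(rownames(ab), rownames(object@env)))
    msgs <- c(msgs, "site labels of abundance and env differ")
  if (!identical(colnames(ab), rownames(object@traits)))
    msgs <- c(msgs, "species labels of abundance and traits differ")
  if (any(ab < 0, na.rm = TRUE))
    msgs <- c(msgs, "negative abundances present")
  if (ncol(object@coords) != 2L)
    msgs <- c(msgs, "coords must have exactly two columns (lat, lon)")
  else {
    lat <- object@coords[, 1]; lon <- object@coords[, 2]
    if (any(lat < -90 | lat > 90, na.rm = TRUE))
      msgs <- c(msgs, "latitude outside [-90, 90]")
    if (any(lon < -180 | lon > 180, na.rm = TRUE))
      msgs <- c(msgs, "longitude outside [-180, 180]")
  }
  if (nrow(ab) > 0 && any(rowSums(ab, na.rm = TRUE) == 0))
    msgs <- c(msgs, "site(s) with no species present")
  if (ncol(ab) > 0 && any(colSums(ab, na.rm = TRUE) == 0))
    msgs <- c(msgs, "species never observed at any site")
  if (length(object@traitTypes) != ncol(object@traits) ||
      !identical(names(object@traitTypes), colnames(object@traits)))
    msgs <- c(msgs, "traitTypes must be named for every trait column")
  bad <- setdiff(unique(object@traitTypes),
                 c("continuous", "binary", "categorical", "fuzzy"))
  if (length(bad))
    msgs <- c(msgs, paste0("unknown trait type(s): ", paste(bad, collapse = ", ")))
  realm <- object@meta$realm
  if (!is.null(realm) && !is.na(realm) &&
      !realm %in% c("freshwater", "marine", "terrestrial"))
    msgs <- c(msgs, "realm must be freshwater, marine or terrestrial")
  if (length(msgs)) msgs else TRUE
}
setValidity("CommunityDataset", .validCommunityDataset)

#' TraitSpace: a three-axis principal-coordinates embedding of species
#'
#' Species coordinates on the retained principal-coordinate axes of a
#' balanced Gower trait distance matrix, ordered by descending eigenvalue.
#' The \code{negativeEigenvalues} flag records whether the full spectrum
#' contained negative eigenvalues (no Cailliez/Lingoes correction is
#' applied; the retained axes are always positive-eigenvalue axes).
#'
#' @slot coordinates numeric matrix, species x k (default k = 3).
#' @slot eigenvalues numeric, full eigenvalue spectrum, descending.
#' @slot negativeEigenvalues logical flag.
#' @export
setClass("TraitSpace",
  representation(
    coordinates = "matrix",
    eigenvalues = "numeric",
    negativeEigenvalues = "logical"
  )
)

#' Hypervolume: a Gaussian-kernel density region for one community
#'
#' The trait space occupied by a community, represented as the region where
#' a Gaussian mixture (one kernel per member species, weights proportional
#' to relative abundance) exceeds the density threshold that encloses a
#' fixed quantile (default 0.95) of the mixture probability mass. Volumes
#' are in units of SD^3 (the trait axes are PCoA axes of a standardized
#' trait distance).
#'
#' @slot centers numeric matrix, member species x 3 kernel centres.
#' @slot weights numeric, non-negative mixture weights summing to 1.
#' @slot bandwidth numeric length-3, per-axis Silverman bandwidths.
#' @slot threshold numeric, mixture density threshold delimiting the region.
#' @slot points numeric matrix, uniform Monte-Carlo points retained inside
#'   the region (density >= threshold).
#' @slot box numeric 2 x 3 matrix, bounding box (rows: lower, upper).
#' @slot volume numeric, Monte-Carlo volume of the region, SD^3.
#' @slot seed integer seed used for all sampling.
#' @export
setClass("Hypervolume",
  representation(
    centers   = "matrix",
    weights   = "numeric",
    bandwidth = "numeric",
    threshold = "numeric",
    points    = "matrix",
    box       = "matrix",
    volume    = "numeric",
    seed      = "integer"
  )
)

setValidity("Hypervolume", function(object) {
  msgs <- character(0)
  if (length(object@weights) != nrow(object@centers))
    msgs <- c(msgs, "one weight per kernel centre required")
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-8)
    msgs <- c(msgs, "weights must be non-negative and sum to 1")
  if (any(object@bandwidth <= 0))
    msgs <- c(msgs, "bandwidths must be positive")
  if (nrow(object@centers) >= 1 && object@volume <= 0)
    msgs <- c(msgs, "volume must be positive for a non-empty hypervolume")
  if (length(msgs)) msgs else TRUE
})

#' PairwiseSimilarity: condensed site-pair similarity components
#'
#' All unordered site pairs of one dataset for one facet (taxonomic or
#' functional) and one mode (occurrence or abundance). Stores the Sorensen
#' similarity S = 1 - (b+c)/(2a+b+c), the total dissimilarity and its
#' replacement / richness-difference partition, and the raw (a, b, c)
#' components per pair. Pairs are stored condensed in \code{stats::dist}
#' order (lower triangle, column-wise); [as.matrix()] restores square form.
#' Pairs involving a site excluded from the functional analyses (too few
#' species for a hypervolume) are NA and the sites listed in
#' \code{excluded}.
#'
#' @slot labels character site ids.
#' @slot facet "taxonomic" or "functional".
#' @slot mode "occurrence" or "abundance".
#' @slot S_total numeric condensed similarity in [0, 1].
#' @slot beta_total,beta_repl,beta_rich numeric condensed dissimilarity
#'   components in [0, 1]; beta_repl + beta_rich == beta_total.
#' @slot components numeric matrix (pairs x 3) of a, b, c.
#' @slot excluded character, sites excluded from this facet.
#' @export
setClass("PairwiseSimilarity",
  representation(
    labels     = "character",
    facet      = "character",
    mode       = "character",
    S_total    = "numeric",
    beta_total = "numeric",
    beta_repl  = "numeric",
    beta_rich  = "numeric",
    components = "matrix",
    excluded   = "character"
  )
)

setValidity("PairwiseSimilarity", function(object) {
  msgs <- character(0)
  n <- length(object@labels)
  np <- n * (n - 1L) / 2L
  if (length(object@S_total) != np)
    msgs <- c(msgs, "condensed length must be n*(n-1)/2")
  ok <- !is.na(object@S_total)
  if (any(abs(object@S_total[ok] - (1 - object@beta_total[ok])) > 1e-9))
    msgs <- c(msgs, "S_total must equal 1 - beta_total")
  if (any(abs(object@beta_repl[ok] + object@beta_rich[ok] -
              object@beta_total[ok]) > 1e-9))
    msgs <- c(msgs, "beta_repl + beta_rich must equal beta_total")
  rng <- c(object@S_total[ok], object@beta_total[ok],
           object@beta_repl[ok], object@beta_rich[ok])
  if (length(rng) && (min(rng) < -1e-12 || max(rng) > 1 + 1e-12))
    msgs <- c(msgs, "similarities and dissimilarities must lie in [0, 1]")
  if (!object@facet %in% c("taxonomic", "functional"))
    msgs <- c(msgs, "facet must be taxonomic or functional")
  if (!object@mode %in% c("occurrence", "abundance"))
    msgs <- c(msgs, "mode must be occurrence or abundance")
  if (length(msgs)) msgs else TRUE
})
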