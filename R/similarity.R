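#' Sorensen similarity components for one site pair
#'
#' For occurrence data, \code{a} counts shared species, \code{b} and
#' \code{c} species unique to each community. For abundance data the
#' standard Sorensen (Bray-Curtis-family) generalization is used:
#' \code{a = sum(pmin(x_j, x_k))}, with \code{b} and \code{c} the
#' abundance remainders of each community. On 0/1 vectors the two
#' constructions coincide exactly.
#'
#' @param x_j,x_k non-negative numeric vectors over the same species
#'   universe (presence 0/1 for the occurrence variant).
#' @return named numeric vector \code{c(a, b, c)}.
#' @examples
#' sorensenComponentsOccurrence(c(1, 1, 0), c(0, 1, 1)) # a=1, b=1, c=1
#' sorensenComponentsAbundance(c(3, 0), c(1, 2))        # a=1, b=2, c=2
#' @export
sorensenComponentsOccurrence <- function(x_j, x_k) {
  stopifnot(length(x_j) == length(x_k))
  pj <- x_j > 0; pk <- x_k > 0
  if (!any(pj) && !any(pk)) stop("both communities are empty")
  c(a = sum(pj & pk), b = sum(pj & !pk), c = sum(!pj & pk))
}

#' @rdname sorensenComponentsOccurrence
#' @export
sorensenComponentsAbundance <- function(x_j, x_k) {
  stopifnot(length(x_j) == length(x_k))
  if (any(x_j < 0) || any(x_k < 0)) stop("negative abundance")
  if (sum(x_j) == 0 && sum(x_k) == 0) stop("both communities are empty")
  m <- pmin(x_j, x_k)
  c(a = sum(m), b = sum(x_j - m), c = sum(x_k - m))
}

#' Sorensen similarity from components
#'
#' \deqn{S = 1 - (b + c) / (2a + b + c)}
#'
#' @param comp numeric vector or 3-column matrix of components
#'   \code{(a, b, c)}, all non-negative, not all zero.
#' @return similarity in [0, 1] (vectorized over matrix rows).
#' @export
similarityFromComponents <- function(comp) {
  m <- if (is.matrix(comp)) comp else matrix(comp, nrow = 1)
  if (any(m < 0, na.rm = TRUE)) stop("components must be non-negative")
  tot <- 2 * m[, 1] + m[, 2] + m[, 3]
  if (any(tot == 0, na.rm = TRUE)) stop("a = b = c = 0: similarity undefined")
  unname(1 - (m[, 2] + m[, 3]) / tot)
}

#' Partition total dissimilarity into replacement and richness difference
#'
#' Using the Sorensen denominator, so the total matches
#' \code{1 - similarityFromComponents()}:
#' \deqn{\beta_{tot} = (b+c)/(2a+b+c)}
#' \deqn{\beta_{repl} = 2\min(b,c)/(2a+b+c)}
#' \deqn{\beta_{rich} = |b-c|/(2a+b+c)}
#' The identity \code{beta_repl + beta_rich == beta_total} holds exactly.
#'
#' @inheritParams similarityFromComponents
#' @return matrix with columns \code{beta_total}, \code{beta_repl},
#'   \code{beta_rich} (one row per component triple).
#' @export
partitionDissimilarity <- function(comp) {
  m <- if (is.matrix(comp)) comp else matrix(comp, nrow = 1)
  if (any(m < 0, na.rm = TRUE)) stop("components must be non-negative")
  tot <- 2 * m[, 1] + m[, 2] + m[, 3]
  if (any(tot == 0, na.rm = TRUE)) stop("a = b = c = 0: dissimilarity undefined")
  cbind(beta_total = (m[, 2] + m[, 3]) / tot,
        beta_repl = 2 * pmin(m[, 2], m[, 3]) / tot,
        beta_rich = abs(m[, 2] - m[, 3]) / tot)
}

.pairwiseSimilarityFromComponents <- function(comp, labels, facet, mode,
                                              excluded = character(0)) {
  ok <- !is.na(comp[, 1])
  S <- beta_t <- beta_re <- beta_ri <- rep(NA_real_, nrow(comp))
  if (any(ok)) {
    S[ok] <- similarityFromComponents(comp[ok, , drop = FALSE])
    part <- partitionDissimilarity(comp[ok, , drop = FALSE])
    beta_t[ok] <- part[, "beta_total"]
    beta_re[ok] <- part[, "beta_repl"]
    beta_ri[ok] <- part[, "beta_rich"]
  }
  new("PairwiseSimilarity", labels = labels, facet = facet, mode = mode,
      S_total = S, beta_total = beta_t, beta_repl = beta_re,
      beta_rich = beta_ri, components = comp, excluded = excluded)
}

#' Taxonomic similarity for all site pairs
#'
#' Sorensen similarity of species composition for every unordered pair of
#' sites, from occurrences or abundances.
#'
#' @param ds a [CommunityDataset-class].
#' @param mode \code{"occurrence"} (presence/absence) or
#'   \code{"abundance"}.
#' @return a [PairwiseSimilarity-class] with facet \code{"taxonomic"}.
#' @export
taxonomicSimilarityMatrix <- function(ds, mode = c("occurrence", "abundance")) {
  stopifnot(is(ds, "CommunityDataset"))
  mode <- match.arg(mode)
  ab <- abundance(ds)
  if (mode == "occurrence") ab[] <- as.numeric(ab > 0)
  n <- nrow(ab)
  pg <- .pairGrid(n)
  xi <- ab[pg[, 1], , drop = FALSE]
  xj <- ab[pg[, 2], , drop = FALSE]
  m <- pmin(xi, xj)
  comp <- cbind(a = rowSums(m), b = rowSums(xi - m), c = rowSums(xj - m))
  .pairwiseSimilarityFromComponents(comp, rownames(ab), "taxonomic", mode)
}

#' Functional similarity for all site pairs
#'
#' Builds the trait space (balanced Gower distances, three PCoA axes),
#' one hypervolume per community, and Sorensen similarity from the shared
#' and unique hypervolume fractions of every site pair. Sites with fewer
#' than \code{min_species} species are excluded (their pairs are NA).
#' The master seed fans out deterministically to one sub-seed per
#' community and per pair, so results are reproducible and independent of
#' evaluation order.
#'
#' @inheritParams taxonomicSimilarityMatrix
#' @param seed master integer seed.
#' @param space optional precomputed [TraitSpace-class] (skips
#'   Gower + PCoA).
#' @param q,n_samples,min_species,eps_bw hypervolume parameters, see
#'   [buildHypervolume()].
#' @return a [PairwiseSimilarity-class] with facet \code{"functional"}.
#' @export
functionalSimilarityMatrix <- function(ds, mode = c("occurrence", "abundance"),
                                       seed = 1L, space = NULL, q = 0.95,
                                       n_samples = 1000L, min_species = 4L,
                                       eps_bw = 1e-6) {
  stopifnot(is(ds, "CommunityDataset"))
  mode <- match.arg(mode)
  if (is.null(space))
    space <- pcoaEmbed(balancedGower(speciesTraits(ds), traitTypes(ds),
                                     fuzzyGroups(ds)), k = 3L)
  res <- .functionalComponents(abundance(ds), space@coordinates, mode, seed,
                               q, n_samples, min_species, eps_bw)
  if (length(res$excluded))
    warning("sites excluded from functional analyses (fewer than ",
            min_species, " species): ", paste(res$excluded, collapse = ", "))
  if (length(res$excluded) == nrow(abundance(ds)))
    stop("all sites excluded from functional analyses")
  .pairwiseSimilarityFromComponents(res$comp, rownames(abundance(ds)),
                                    "functional", mode, res$excluded)
}

# Fast core shared by the observed pipeline and the trait-shuffling null:
# takes raw species coordinates so null iterations can reassign them
# without re-running Gower + PCoA.
.functionalComponents <- function(ab, coords, mode, seed, q, n_samples,
                                  min_species, eps_bw) {
  n <- nrow(ab)
  pres <- ab > 0
  rich <- rowSums(pres)
  included <- rich >= min_species
  seeds <- .seedStream(seed, n + n * (n - 1L) / 2L)
  hv <- vector("list", n)
  for (i in which(included)) {
    members <- colnames(ab)[pres[i, ]]
    w <- if (mode == "abundance") ab[i, pres[i, ]] else NULL
    hv[[i]] <- .withSeed(seeds[i], .hvSpec(coords[members, , drop = FALSE],
                                           w, q, n_samples, eps_bw))
  }
  pg <- .pairGrid(n)
  comp <- matrix(NA_real_, nrow(pg), 3, dimnames = list(NULL, c("a", "b", "c")))
  for (p in seq_len(nrow(pg))) {
    i <- pg[p, 1]; j <- pg[p, 2]
    if (included[i] && included[j])
      comp[p, ] <- .withSeed(seeds[n + p],
                             .hvOverlapABC(hv[[i]], hv[[j]], n_samples))
  }
  list(comp = comp, excluded = rownames(ab)[!included])
}

#' @rdname similarityValues
setMethod("similarityValues", "PairwiseSimilarity", function(x) x@S_total)

#' @rdname pairTable
setMethod("pairTable", "PairwiseSimilarity", function(x) {
  pg <- .pairGrid(length(x@labels))
  data.frame(site_i = x@labels[pg[, 1]], site_j = x@labels[pg[, 2]],
             facet = x@facet, mode = x@mode, S_total = x@S_total,
             beta_total = x@beta_total, beta_repl = x@beta_repl,
             beta_rich = x@beta_rich, a = x@components[, 1],
             b = x@components[, 2], c = x@components[, 3],
             stringsAsFactors = FALSE)
})

#' @export
#' @describeIn PairwiseSimilarity-class square similarity matrix
setMethod("as.matrix", "PairwiseSimilarity", function(x, which = "S_total", ...) {
  vals <- slot(x, which)
  .squareForm(vals, x@labels, diag_value = if (which == "S_total") 1 else 0)
})

setMethod("show", "PairwiseSimilarity", function(object) {
  cat("PairwiseSimilarity:", length(object@labels), "sites,",
      object@facet, "facet,", object@mode, "mode\n")
  ok <- !is.na(object@S_total)
  cat("  mean similarity:", round(mean(object@S_total[ok]), 3), "over",
      sum(ok), "pairs\n")
  if (length(object@excluded))
    cat("  excluded sites:", paste(object@excluded, collapse = ", "), "\n")
})
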