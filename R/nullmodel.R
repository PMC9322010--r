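# Trait-randomization null model: shuffle species names across the trait
# table, re-derive functional decay, and standardize the observed rate
# against the null distribution.

#' Shuffle species names across the trait table
#'
#' Permutes which species carries which trait row, keeping every row
#' intact (whole-row shuffle preserves the trait covariance structure and
#' the multiset of trait profiles). Uniform over permutations;
#' reproducible given \code{seed}.
#'
#' @param traits species x traits data.frame.
#' @param seed integer seed.
#' @return a data.frame with the same row names but permuted rows.
#' @export
shuffleTraits <- function(traits, seed = 1L) {
  traits <- as.data.frame(traits)
  if (nrow(traits) < 2) stop("shuffleTraits needs at least 2 species")
  p <- .withSeed(seed, sample.int(nrow(traits)))
  out <- traits[p, , drop = FALSE]
  rownames(out) <- rownames(traits)
  out
}

#' Standardized effect size of functional decay against a trait-shuffling null
#'
#' The observed functional decay rate (rate = -slope of the truncated
#' quasi-binomial fit, so larger = faster decay) is compared with the
#' distribution of rates obtained by re-running the functional pipeline
#' under \code{n_iter} random reassignments of species names across the
#' trait table. SES = (observed - null mean) / null sd, per gradient;
#' SES > 1.96 means functional similarity decays faster than expected
#' given the taxonomic decay, SES < -1.96 slower.
#'
#' Because a whole-row shuffle of the trait table only permutes the rows
#' and columns of the species trait-distance matrix, the principal
#' coordinates of the shuffled table are the row-permuted coordinates of
#' the observed [TraitSpace-class]; null iterations therefore reassign
#' coordinates to species instead of re-running Gower + PCoA (the
#' equivalence is exercised in the test suite).
#'
#' @param ds a validated [CommunityDataset-class].
#' @param n_iter null iterations (default 999).
#' @param seed master integer seed.
#' @param mode \code{"occurrence"} or \code{"abundance"}.
#' @param q,n_samples,min_species,eps_bw hypervolume parameters.
#' @return list of class \code{ses_result} with one element per gradient
#'   (\code{spatial}, \code{environmental}), each holding
#'   \code{observed_rate}, \code{null_mean}, \code{null_sd}, \code{ses},
#'   \code{n_iter}, \code{seed}, \code{significant_faster},
#'   \code{significant_slower}, \code{degenerate}.
#' @export
sesFunctionalDecay <- function(ds, n_iter = 999L, seed = 1L,
                               mode = c("occurrence", "abundance"),
                               q = 0.95, n_samples = 1000L,
                               min_species = 4L, eps_bw = 1e-6) {
  stopifnot(is(ds, "CommunityDataset"))
  mode <- match.arg(mode)
  ab <- abundance(ds)
  if (mode == "occurrence") ab[] <- as.numeric(ab > 0)
  space <- pcoaEmbed(balancedGower(speciesTraits(ds), traitTypes(ds),
                                   fuzzyGroups(ds)), k = 3L)
  co <- space@coordinates
  d_sp <- spatialDistanceMatrix(ds)
  d_env <- environmentalDistanceMatrix(ds)
  seeds <- .seedStream(seed, 2L * (n_iter + 1L))
  mc_seeds <- seeds[seq_len(n_iter + 1L)]
  perm_seeds <- seeds[n_iter + 1L + seq_len(n_iter)]

  rates <- matrix(NA_real_, n_iter + 1L, 2,
                  dimnames = list(NULL, c("spatial", "environmental")))
  labs <- rownames(ab)
  for (it in seq_len(n_iter + 1L)) {
    co_it <- if (it == 1L) co else {
      p <- .withSeed(perm_seeds[it - 1L], sample.int(nrow(co)))
      ci <- co[p, , drop = FALSE]
      rownames(ci) <- rownames(co)
      ci
    }
    fc <- .functionalComponents(ab, co_it, mode, mc_seeds[it], q, n_samples,
                                min_species, eps_bw)
    sim <- .pairwiseSimilarityFromComponents(fc$comp, labs, "functional",
                                             mode, fc$excluded)
    rates[it, "spatial"] <-
      -truncatePositiveSlope(fitDecay(sim, d_sp))$slope
    rates[it, "environmental"] <-
      -truncatePositiveSlope(fitDecay(sim, d_env))$slope
  }
  out <- lapply(c(spatial = "spatial", environmental = "environmental"),
                function(g) {
    obs <- rates[1L, g]
    null <- rates[-1L, g]
    nm <- mean(null); nsd <- stats::sd(null)
    degenerate <- !is.finite(nsd) || nsd == 0
    ses <- if (degenerate) NA_real_ else (obs - nm) / nsd
    list(gradient = g, observed_rate = obs, null_mean = nm, null_sd = nsd,
         ses = ses, n_iter = as.integer(n_iter), seed = as.integer(seed),
         significant_faster = isTRUE(ses > 1.96),
         significant_slower = isTRUE(ses < -1.96),
         degenerate = degenerate)
  })
  structure(out, class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  for (g in names(x)) {
    e <- x[[g]]
    cat(sprintf(
      "SES (%s): observed rate %.5f, null %.5f +/- %.5f, SES = %s%s\n",
      g, e$observed_rate, e$null_mean, e$null_sd,
      if (e$degenerate) "degenerate" else sprintf("%.2f", e$ses),
      if (e$significant_faster) " [faster than null]"
      else if (e$significant_slower) " [slower than null]" else ""))
  }
  invisible(x)
}
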