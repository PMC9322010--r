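# Per-dataset distance decay: strength (ranked Mantel) and rate
# (quasi-binomial log-link GLM slope) for taxonomic/functional similarity
# along spatial/environmental distance.

# Extract condensed response + distance vectors (and square matrices for
# permutation) with any excluded sites removed.
.alignPair <- function(similarity, distance, values = NULL) {
  if (is(similarity, "PairwiseSimilarity")) {
    labs <- similarity@labels
    dl <- attr(distance, "Labels")
    if (!is.null(dl) && !identical(labs, dl))
      stop("site labels of similarity and distance matrices differ")
    v <- if (is.null(values)) similarity@S_total else values
    keep <- setdiff(labs, similarity@excluded)
    Ssq <- .squareForm(v, labs, diag_value = NA)[keep, keep, drop = FALSE]
    Dsq <- as.matrix(distance)[keep, keep, drop = FALSE]
  } else {
    v <- as.numeric(similarity)
    n <- length(attr(distance, "Labels") %||% seq_len(attr(distance, "Size")))
    labs <- attr(distance, "Labels") %||% as.character(seq_len(n))
    if (length(v) != n * (n - 1) / 2)
      stop("condensed similarity length does not match the distance matrix")
    Ssq <- .squareForm(v, labs, diag_value = NA)
    Dsq <- as.matrix(distance)
  }
  ut <- upper.tri(Ssq)
  list(S = Ssq[ut], d = Dsq[ut], Ssq = Ssq, Dsq = Dsq)
}

#' Ranked Mantel test of distance decay strength
#'
#' Spearman rank correlation between the condensed dissimilarity
#' \code{1 - S} and the condensed distance, so that a decay (similarity
#' falling with distance) gives a positive Mantel \emph{r}. Significance
#' comes from jointly permuting the rows and columns of the dissimilarity
#' matrix: \code{n_perm} random site relabelings by default, or the
#' exhaustive set of all \code{n!} relabelings when \code{exact = TRUE}
#' (small n only). The permutation p-value is
#' \code{(1 + #(perm >= observed)) / (n_perm + 1)} (exhaustive:
#' \code{#(perm >= observed) / n!}).
#'
#' @param similarity a [PairwiseSimilarity-class] (excluded sites are
#'   dropped) or a condensed numeric similarity vector.
#' @param distance a \code{dist} over the same sites.
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param exact exhaustive enumeration of all relabelings (n <= 8).
#' @param values optional condensed response overriding \code{S_total}
#'   (used for the replacement / richness-difference components).
#' @return list of class \code{mantel_result}: \code{r}, \code{p},
#'   \code{n_perm}, \code{seed}, \code{degenerate} (TRUE when either
#'   vector is constant; then \code{r = 0}).
#' @export
mantelStrength <- function(similarity, distance, n_perm = 999L, seed = 1L,
                           exact = FALSE, values = NULL) {
  ap <- .alignPair(similarity, distance, values)
  n <- nrow(ap$Ssq)
  if (n < 4) stop("mantelStrength needs at least 4 sites")
  dis <- 1 - ap$S
  if (stats::sd(dis) == 0 || stats::sd(ap$d) == 0) {
    warning("constant similarity or distance vector; Mantel r undefined, returned as 0")
    return(structure(list(r = 0, p = NA_real_, n_perm = 0L,
                          seed = as.integer(seed), degenerate = TRUE),
                     class = "mantel_result"))
  }
  ut <- upper.tri(ap$Ssq)
  rd <- rank(ap$d)
  Dis <- 1 - ap$Ssq            # square dissimilarity, NA diagonal
  r_obs <- stats::cor(rank(dis), rd)
  stat_perm <- function(p) {
    v <- Dis[p, p][ut]
    stats::cor(rank(v), rd)
  }
  if (exact) {
    if (n > 8) stop("exact enumeration limited to 8 sites")
    perms <- .allPermutations(n)
    stats_all <- vapply(perms, stat_perm, numeric(1))
    p_val <- mean(stats_all >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    stats_all <- .withSeed(seed, vapply(seq_len(n_perm), function(i)
      stat_perm(sample.int(n)), numeric(1)))
    p_val <- (1 + sum(stats_all >= r_obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p_val, n_perm = as.integer(n_used),
                 seed = as.integer(seed), degenerate = FALSE),
            class = "mantel_result")
}

.allPermutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (s in sub) for (pos in 0:(n - 1L)) {
    out[[k]] <- append(s, n, after = pos)
    k <- k + 1L
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %s (%d permutations)%s\n", x$r,
              format.pval(x$p), x$n_perm,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Negative-exponential decay fit (quasi-binomial, log link)
#'
#' Fits the mean model \eqn{E[S] = \exp(\beta_0 + \beta_1 d)} with
#' variance proportional to \eqn{\mu(1-\mu)} by iteratively reweighted
#' least squares; the quasi-binomial family affects only the dispersion
#' (Pearson chi-squared / df), so point estimates match a binomial-family
#' fit. Step-halving keeps the fitted mean inside (0, 1). Pairs are
#' treated as independent observations; only the point estimates are used
#' downstream.
#'
#' @inheritParams mantelStrength
#' @param tol convergence tolerance on the coefficient change
#'   (default 1e-8).
#' @param max_iter iteration cap (default 100); on non-convergence the
#'   last iterate is returned with a warning and \code{converged = FALSE}.
#' @return list of class \code{decay_fit}: \code{intercept} (log scale),
#'   \code{slope} (per unit distance), \code{dispersion},
#'   \code{converged}, \code{truncated} (always FALSE here, see
#'   [truncatePositiveSlope()]), \code{n_pairs}.
#' @export
fitDecay <- function(similarity, distance, values = NULL, tol = 1e-8,
                     max_iter = 100L) {
  if (is.numeric(similarity) && is.numeric(distance) &&
      !inherits(distance, "dist") &&
      length(similarity) == length(distance)) {
    # plain paired vectors (e.g. from simulateDecayPairs)
    ap <- list(S = similarity, d = distance)
  } else {
    ap <- .alignPair(similarity, distance, values)
  }
  ok <- !is.na(ap$S)
  y <- ap$S[ok]; d <- ap$d[ok]
  if (length(y) < 3) stop("too few pairs for a decay fit")
  if (any(y < 0 | y > 1)) stop("similarities must lie in [0, 1]")
  if (all(y == 0)) stop("all similarities are zero: no mean structure to fit")
  fit <- .irlsLogBinomial(y, d, tol = tol, max_iter = max_iter)
  structure(list(intercept = fit$beta[1], slope = fit$beta[2],
                 dispersion = fit$dispersion, converged = fit$converged,
                 truncated = FALSE, n_pairs = length(y)),
            class = "decay_fit")
}

# IRLS for the log-link binomial mean model with mu(1-mu) variance.
.irlsLogBinomial <- function(y, d, tol = 1e-8, max_iter = 100L) {
  X <- cbind(1, d)
  mu <- pmin(pmax((y + mean(y)) / 2, 1e-4), 1 - 1e-4)
  eta <- log(mu)
  beta <- stats::lm.fit(X, eta)$coefficients
  eta <- pmin(drop(X %*% beta), -1e-10)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- exp(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    w <- mu / (1 - mu)              # (dmu/deta)^2 / V = mu^2 / (mu(1-mu))
    z <- eta + (y - mu) / mu        # working response
    beta_new <- tryCatch(
      stats::lm.wfit(X, z, w)$coefficients,
      error = function(e) beta)
    # step-halving to keep eta (hence mu) below the boundary
    step <- 1
    repeat {
      cand <- beta + step * (beta_new - beta)
      eta_c <- drop(X %*% cand)
      if (max(eta_c) < 0 || step < 1e-8) break
      step <- step / 2
    }
    eta_c <- pmin(eta_c, -1e-10)
    delta <- max(abs(cand - beta))
    beta <- cand
    eta <- eta_c
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("decay fit did not converge in ", max_iter,
            " iterations; returning last iterate")
  mu <- pmin(pmax(exp(eta), 1e-10), 1 - 1e-10)
  df <- max(length(y) - 2, 1)
  dispersion <- sum((y - mu)^2 / (mu * (1 - mu))) / df
  list(beta = unname(beta), dispersion = dispersion, converged = converged)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Decay fit: E[S] = exp(%.4f %+.5f d); dispersion %.3f; %d pairs%s%s\n",
    x$intercept, x$slope, x$dispersion, x$n_pairs,
    if (!x$converged) " [not converged]" else "",
    if (x$truncated) " [slope truncated to 0]" else ""))
  invisible(x)
}

#' Truncate positive decay slopes to zero
#'
#' A distance decay must have a non-positive slope; positive fitted slopes
#' (periodic gradients or community-environment mismatch) are set to zero
#' and flagged. Idempotent.
#'
#' @param fit a \code{decay_fit} from [fitDecay()].
#' @return the fit, with \code{slope = 0} and \code{truncated = TRUE} if
#'   the raw slope was positive.
#' @export
truncatePositiveSlope <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  if (fit$slope > 0) {
    fit$slope <- 0
    fit$truncated <- TRUE
  }
  fit
}

#' All decay metrics of one dataset
#'
#' Computes, for each facet (taxonomic, functional) and gradient (spatial,
#' environmental), the ranked Mantel strength and the truncated
#' quasi-binomial decay slope -- for the total similarity and for the
#' replacement and richness-difference components (modelled on the
#' similarity scale, 1 - component). Four facet-by-gradient cells per
#' component.
#'
#' @param ds a validated, curated [CommunityDataset-class].
#' @param mode \code{"occurrence"} or \code{"abundance"}.
#' @param seed master seed (Mantel permutations and hypervolume sampling).
#' @param n_perm Mantel permutations (default 999).
#' @param components include replacement / richness rows (default TRUE).
#' @param q,n_samples,min_species,eps_bw hypervolume parameters.
#' @return data.frame of class \code{decay_metrics}: one row per
#'   facet x gradient x component with \code{mantel_r}, \code{mantel_p},
#'   \code{slope}, \code{intercept}, \code{dispersion}, \code{converged},
#'   \code{truncated}, \code{n_pairs}.
#' @export
decaySuite <- function(ds, mode = c("occurrence", "abundance"), seed = 1L,
                       n_perm = 999L, components = TRUE, q = 0.95,
                       n_samples = 1000L, min_species = 4L, eps_bw = 1e-6) {
  stopifnot(is(ds, "CommunityDataset"))
  mode <- match.arg(mode)
  seeds <- .seedStream(seed, 3L)
  sims <- list(
    taxonomic = taxonomicSimilarityMatrix(ds, mode),
    functional = functionalSimilarityMatrix(ds, mode, seed = seeds[1],
                                            q = q, n_samples = n_samples,
                                            min_species = min_species,
                                            eps_bw = eps_bw))
  dists <- list(spatial = spatialDistanceMatrix(ds),
                environmental = environmentalDistanceMatrix(ds))
  comps <- if (components) c("total", "replacement", "richness") else "total"
  out <- list()
  k <- 0L
  for (facet in names(sims)) for (gradient in names(dists)) {
    sim <- sims[[facet]]
    for (comp in comps) {
      vals <- switch(comp, total = NULL,
                     replacement = 1 - sim@beta_repl,
                     richness = 1 - sim@beta_rich)
      mt <- mantelStrength(sim, dists[[gradient]], n_perm = n_perm,
                           seed = seeds[2], values = vals)
      ft <- truncatePositiveSlope(fitDecay(sim, dists[[gradient]],
                                           values = vals))
      k <- k + 1L
      out[[k]] <- data.frame(facet = facet, gradient = gradient,
                             component = comp, mode = mode,
                             mantel_r = mt$r, mantel_p = mt$p,
                             slope = ft$slope, intercept = ft$intercept,
                             dispersion = ft$dispersion,
                             converged = ft$converged,
                             truncated = ft$truncated,
                             n_pairs = ft$n_pairs,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "seed") <- as.integer(seed)
  class(res) <- c("decay_metrics", "data.frame")
  res
}
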