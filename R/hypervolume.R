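# Gaussian-kernel hypervolumes: a community's occupied region of trait
# space is {x : mixture density(x) >= c}, with c chosen so the region
# encloses a fixed quantile q of mixture probability mass. All region
# geometry (threshold, volume, overlap) is estimated by Monte Carlo.

# Mixture density of a diagonal-bandwidth Gaussian mixture at `pts`.
# pts: n x d, centers: m x d, bw: length d, w: length m (sums to 1).
.mixtureDensity <- function(pts, centers, bw, w) {
  d <- ncol(centers)
  sq <- 0
  for (j in seq_len(d)) {
    z <- outer(pts[, j], centers[, j], "-") / bw[j]
    sq <- sq + z * z
  }
  drop(exp(-sq / 2) %*% w) / ((2 * pi)^(d / 2) * prod(bw))
}

# Per-axis Silverman bandwidth for m points in d dimensions, floored.
.silvermanBW <- function(coords, eps_bw) {
  m <- nrow(coords); d <- ncol(coords)
  s <- apply(coords, 2, stats::sd)
  s[!is.finite(s)] <- 0
  bw <- s * (4 / ((d + 2) * m))^(1 / (d + 4))
  pmax(bw, eps_bw)
}

# Core hypervolume geometry without the S4 wrapper; used in the hot
# similarity/null loops. Returns centers, weights, bandwidth, threshold
# and bounding box. RNG must already be seeded by the caller.
.hvSpec <- function(centers, weights = NULL, q = 0.95, n_samples = 1000L,
                    eps_bw = 1e-6, bandwidth = NULL) {
  m <- nrow(centers)
  w <- if (is.null(weights)) rep(1 / m, m) else weights / sum(weights)
  bw <- if (is.null(bandwidth)) .silvermanBW(centers, eps_bw)
        else pmax(bandwidth, eps_bw)
  idx <- if (m == 1L) rep(1L, n_samples)
         else sample.int(m, n_samples, replace = TRUE, prob = w)
  draws <- centers[idx, , drop = FALSE] +
    matrix(stats::rnorm(n_samples * ncol(centers)), n_samples) *
      rep(bw, each = n_samples)
  dens <- .mixtureDensity(draws, centers, bw, w)
  threshold <- unname(stats::quantile(dens, probs = 1 - q))
  lo <- apply(centers, 2, min) - 3 * bw
  hi <- apply(centers, 2, max) + 3 * bw
  list(centers = centers, w = w, bw = bw, threshold = threshold,
       box = rbind(lower = lo, upper = hi))
}

.boxVolume <- function(box) prod(box["upper", ] - box["lower", ])

.uniformInBox <- function(n, box) {
  d <- ncol(box)
  u <- matrix(stats::runif(n * d), n, d)
  sweep(sweep(u, 2, box["upper", ] - box["lower", ], "*"),
        2, box["lower", ], "+")
}

# Monte-Carlo (a, b, c) overlap volumes of two hypervolume specs over
# their union bounding box. RNG must already be seeded by the caller.
.hvOverlapABC <- function(h1, h2, n_samples = 1000L) {
  box <- rbind(lower = pmin(h1$box["lower", ], h2$box["lower", ]),
               upper = pmax(h1$box["upper", ], h2$box["upper", ]))
  u <- .uniformInBox(n_samples, box)
  in1 <- .mixtureDensity(u, h1$centers, h1$bw, h1$w) >= h1$threshold
  in2 <- .mixtureDensity(u, h2$centers, h2$bw, h2$w) >= h2$threshold
  bv <- .boxVolume(box)
  c(a = bv * mean(in1 & in2),
    b = bv * mean(in1 & !in2),
    c = bv * mean(!in1 & in2))
}

#' Build the Gaussian-kernel hypervolume of one community
#'
#' Places one Gaussian kernel per member species at its [TraitSpace-class]
#' coordinates, with mixture weights proportional to relative abundance
#' (uniform for occurrence data) and per-axis Silverman bandwidths over
#' the member coordinates. The occupied region is the density superlevel
#' set enclosing quantile \code{q} of mixture mass (threshold estimated
#' from \code{n_samples} mixture draws); its volume is estimated by
#' rejection sampling against the bounding box (member range +/- 3
#' bandwidths). Fully reproducible given \code{seed}.
#'
#' @param space a [TraitSpace-class].
#' @param members character vector of member species (rows of the space).
#' @param weights optional non-negative abundances for the members.
#' @param seed integer seed for all sampling.
#' @param q mass quantile enclosed by the region (default 0.95).
#' @param n_samples Monte-Carlo sample count (default 10000).
#' @param min_species minimum community size for a hypervolume
#'   (default 4 = dimensions + 1); smaller communities return NULL with a
#'   warning and are excluded from functional analyses.
#' @param eps_bw bandwidth floor on zero-variance axes (default 1e-6 SD).
#' @param bandwidth optional fixed per-axis bandwidth overriding Silverman
#'   (needed e.g. for single-kernel communities).
#' @return a [Hypervolume-class], or NULL if the community is too small.
#' @export
buildHypervolume <- function(space, members, weights = NULL, seed = 1L,
                             q = 0.95, n_samples = 10000L, min_species = 4L,
                             eps_bw = 1e-6, bandwidth = NULL) {
  stopifnot(is(space, "TraitSpace"))
  if (length(members) < min_species) {
    warning("community of ", length(members), " species below min_species = ",
            min_species, "; excluded from functional analyses")
    return(NULL)
  }
  missing_sp <- setdiff(members, rownames(space@coordinates))
  if (length(missing_sp))
    stop("members not in trait space: ", paste(missing_sp, collapse = ", "))
  if (!is.null(weights)) {
    if (any(weights < 0) || sum(weights) <= 0)
      stop("weights must be non-negative with positive sum")
  }
  centers <- space@coordinates[members, , drop = FALSE]
  .withSeed(seed, {
    h <- .hvSpec(centers, weights, q, n_samples, eps_bw, bandwidth)
    u <- .uniformInBox(n_samples, h$box)
    inside <- .mixtureDensity(u, h$centers, h$bw, h$w) >= h$threshold
    vol <- .boxVolume(h$box) * mean(inside)
    if (vol <= 0) vol <- .boxVolume(h$box) * 0.5 / n_samples
    new("Hypervolume", centers = centers, weights = h$w, bandwidth = h$bw,
        threshold = h$threshold, points = u[inside, , drop = FALSE],
        box = h$box, volume = vol, seed = as.integer(seed))
  })
}

#' @rdname volume
setMethod("volume", "Hypervolume", function(x) x@volume)

setMethod("show", "Hypervolume", function(object) {
  cat("Hypervolume:", nrow(object@centers), "kernels,",
      ncol(object@centers), "dimensions\n")
  cat("  volume:", signif(object@volume, 4), "SD^",
      ncol(object@centers), " (q-region threshold ",
      signif(object@threshold, 3), ")\n", sep = "")
})

.asSpec <- function(H) list(centers = H@centers, w = H@weights,
                            bw = H@bandwidth, threshold = H@threshold,
                            box = H@box)

#' Shared and unique volumes of two hypervolumes
#'
#' Monte-Carlo estimate, over the union bounding box, of the volume shared
#' by the two regions (\code{a}) and the volume unique to each
#' (\code{b}, \code{c}). These are the features entering the Sorensen
#' similarity of the functional facet.
#'
#' @param H1,H2 [Hypervolume-class] objects built in the same trait space.
#' @param seed integer seed.
#' @param n_samples Monte-Carlo sample count (default 10000).
#' @return named numeric vector \code{c(a, b, c)}.
#' @export
hypervolumeOverlap <- function(H1, H2, seed = 1L, n_samples = 10000L) {
  stopifnot(is(H1, "Hypervolume"), is(H2, "Hypervolume"))
  if (ncol(H1@centers) != ncol(H2@centers))
    stop("hypervolumes built in incompatible trait spaces")
  .withSeed(seed, .hvOverlapABC(.asSpec(H1), .asSpec(H2), n_samples))
}

#' Volume of the union of several hypervolumes
#'
#' Monte-Carlo volume of the union region over the joint bounding box;
#' this is the functional gamma-diversity of a dataset (in SD^3).
#'
#' @param hypervolumes non-empty list of [Hypervolume-class] objects.
#' @param seed integer seed.
#' @param n_samples Monte-Carlo sample count (default 10000).
#' @return numeric volume; at least the largest member volume and at most
#'   the sum of member volumes (up to Monte-Carlo error).
#' @export
unionVolume <- function(hypervolumes, seed = 1L, n_samples = 10000L) {
  hypervolumes <- Filter(Negate(is.null), hypervolumes)
  if (length(hypervolumes) == 0) stop("unionVolume needs at least one hypervolume")
  d <- unique(vapply(hypervolumes, function(h) ncol(h@centers), integer(1)))
  if (length(d) != 1) stop("hypervolumes built in incompatible trait spaces")
  lo <- Reduce(pmin, lapply(hypervolumes, function(h) h@box["lower", ]))
  hi <- Reduce(pmax, lapply(hypervolumes, function(h) h@box["upper", ]))
  box <- rbind(lower = lo, upper = hi)
  .withSeed(seed, {
    u <- .uniformInBox(n_samples, box)
    inside <- rep(FALSE, n_samples)
    for (h in hypervolumes) {
      todo <- !inside
      if (!any(todo)) break
      inside[todo] <- .mixtureDensity(u[todo, , drop = FALSE], h@centers,
                                      h@bandwidth, h@weights) >= h@threshold
    }
    .boxVolume(box) * mean(inside)
  })
}
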