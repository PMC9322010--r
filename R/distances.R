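#' Great-circle spatial distances between sites
#'
#' Haversine distance in kilometres between every pair of sites, using an
#' Earth mean radius of 6371.0 km.
#'
#' @param coords sites x 2 matrix of decimal-degree latitude and longitude
#'   (columns \code{lat}, \code{lon}), or a [CommunityDataset-class].
#' @return a \code{dist} in km, with attribute \code{kind = "spatial_km"}.
#' @examples
#' co <- cbind(lat = c(0, 0), lon = c(0, 90))
#' rownames(co) <- c("s1", "s2")
#' spatialDistanceMatrix(co) # pi * 6371 / 2 ~ 10007.5 km
#' @export
spatialDistanceMatrix <- function(coords) {
  if (is(coords, "CommunityDataset")) coords <- siteCoords(coords)
  coords <- as.matrix(coords)
  lat <- coords[, 1]; lon <- coords[, 2]
  bad <- which(lat < -90 | lat > 90 | lon < -180 | lon > 180 | is.na(lat) | is.na(lon))
  if (length(bad))
    stop("out-of-range coordinates for site(s): ",
         paste(rownames(coords)[bad], collapse = ", "))
  # geosphere expects (lon, lat) and radius in metres
  m <- geosphere::distm(coords[, c(2, 1)],
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371000))
  dimnames(m) <- list(rownames(coords), rownames(coords))
  d <- stats::as.dist(m / 1000)
  attr(d, "kind") <- "spatial_km"
  d
}

#' Standardized environmental distances between sites
#'
#' Z-scores every environmental variable (mean 0, sample sd with n-1
#' denominator), takes Euclidean distances between all site pairs, and
#' rescales the matrix to [0, 1] by dividing by its maximum, so the units
#' are comparable within a dataset. Zero-variance variables are dropped
#' with a warning.
#'
#' @param env sites x variables numeric matrix, or a
#'   [CommunityDataset-class].
#' @return a \code{dist} with maximum 1, attribute
#'   \code{kind = "environmental_unit"}.
#' @export
environmentalDistanceMatrix <- function(env) {
  if (is(env, "CommunityDataset")) env <- envData(env)
  env <- as.matrix(env)
  sds <- apply(env, 2, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    warning("dropping zero-variance environmental variable(s): ",
            paste(colnames(env)[zero], collapse = ", "))
    env <- env[, !zero, drop = FALSE]
  }
  if (ncol(env) == 0) stop("no environmental variables with variance")
  z <- scale(env)
  d <- stats::dist(z)
  mx <- max(d)
  if (mx == 0) stop("all site pairs environmentally identical (max distance 0)")
  d <- d / mx
  attr(d, "kind") <- "environmental_unit"
  d
}
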