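# Synthetic metacommunity generator: datasets with known, controllable
# spatial turnover, environmental filtering of traits, functional
# redundancy and noise, so every pipeline stage has a ground truth.

#' Parameters of the synthetic metacommunity generator
#'
#' @param n_sites number of sites (default 20).
#' @param n_species regional species pool size (default 40).
#' @param n_traits number of continuous traits (default 3).
#' @param n_env_vars number of environmental variables (default 3).
#' @param extent_km target largest pairwise distance; sites are placed
#'   uniformly in a square of side \code{extent_km / sqrt(2)}
#'   (default 300 km).
#' @param env_spatial_autocorr range (km) of the exponential covariance of
#'   the simulated environmental fields (default \code{extent_km / 3}).
#' @param niche_breadth Gaussian niche breadth of species along each
#'   standardized environmental axis (default 1.5 SD).
#' @param dispersal_range_km range of the exponential dispersal kernel
#'   around each species' home centre; small values relative to the
#'   extent create strong spatial turnover (default \code{extent_km / 3}).
#' @param trait_env_coupling in [0, 1]: 0 = traits random with respect to
#'   the species' environmental niches, 1 = traits fully determined by
#'   them (default 0.5).
#' @param functional_redundancy in [0, 1]: fraction of trait-profile
#'   collapse; 0 = every species its own profile, 1 = species share a
#'   minimal set of profiles (default 0).
#' @param noise_sd lognormal abundance noise sd (default 0.3).
#' @param trait_noise_sd sd of the jitter around each trait profile
#'   (default 0.05; keeps profiles distinct so the trait space is full
#'   rank even under complete redundancy).
#' @param individuals_per_site multinomial draw size per site
#'   (default 150).
#' @param centre_lat,centre_lon geographic placement of the simulated
#'   square (defaults 45, 10), so latitude descriptors are exercised.
#' @param realm,biotic_group,body_size_log10_g,dispersal_mode dataset
#'   metadata passed through to the bundle.
#' @param seed integer seed; the dataset is fully reproducible given it.
#' @return a list of class \code{simulation_params}.
#' @seealso [simulateDataset()]
#' @export
simulationParams <- function(n_sites = 20L, n_species = 40L, n_traits = 3L,
                             n_env_vars = 3L, extent_km = 300,
                             env_spatial_autocorr = extent_km / 3,
                             niche_breadth = 1.5,
                             dispersal_range_km = extent_km / 3,
                             trait_env_coupling = 0.5,
                             functional_redundancy = 0,
                             noise_sd = 0.3, trait_noise_sd = 0.05,
                             individuals_per_site = 150L,
                             centre_lat = 45, centre_lon = 10,
                             realm = "freshwater",
                             biotic_group = "synthetic",
                             body_size_log10_g = 0,
                             dispersal_mode = "passive", seed = 1L) {
  stopifnot(trait_env_coupling >= 0, trait_env_coupling <= 1,
            functional_redundancy >= 0, functional_redundancy <= 1,
            extent_km > 0, n_sites >= 2, n_species >= 2, n_traits >= 1)
  structure(as.list(environment()), class = "simulation_params")
}

#' Simulate one CommunityDataset with known decay structure
#'
#' Sites are placed uniformly in a square whose diagonal matches the
#' requested extent and mapped to latitude/longitude around the requested
#' centre. Environmental variables are spatially autocorrelated Gaussian
#' fields (low-rank kernel expansion with exponential covariance).
#' Each species gets a Gaussian niche optimum in standardized environment
#' space and an exponential dispersal kernel around a home centre;
#' expected abundance = niche response x dispersal kernel x lognormal
#' noise, converted to counts by a multinomial draw of
#' \code{individuals_per_site} individuals per site. Traits blend the
#' niche optima (coupling 1) with independent values (coupling 0);
#' functional redundancy assigns shared trait profiles to species groups.
#' Species never drawn anywhere are dropped during curation.
#'
#' @param params a [simulationParams()] list.
#' @return a [CommunityDataset-class] that passes [validateDataset()] at
#'   the default generator sizes.
#' @export
simulateDataset <- function(params = simulationParams()) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  .withSeed(p$seed, {
    for (attempt in 1:10) {
      ds <- try(.simulateOnce(p), silent = TRUE)
      if (!inherits(ds, "try-error")) return(ds)
      warning("simulateDataset: degenerate draw, resampling (attempt ",
              attempt, ")")
    }
    stop("simulateDataset failed after 10 attempts: ",
         attr(ds, "condition")$message)
  })
}

.simulateOnce <- function(p) {
  L <- p$extent_km / sqrt(2)
  xy <- cbind(x = stats::runif(p$n_sites, 0, L),
              y = stats::runif(p$n_sites, 0, L))
  site_ids <- sprintf("site%02d", seq_len(p$n_sites))
  rownames(xy) <- site_ids
  # planar km -> decimal degrees around the centre (small-extent approx)
  km_per_deg <- 111.32
  lat <- p$centre_lat + (xy[, "y"] - L / 2) / km_per_deg
  lon <- p$centre_lon + (xy[, "x"] - L / 2) /
    (km_per_deg * cos(p$centre_lat * pi / 180))
  coords <- cbind(lat = lat, lon = lon)

  dxy <- as.matrix(stats::dist(xy))
  # low-rank GP: weighted exponential kernels at random knots
  n_knots <- 25L
  knots <- cbind(stats::runif(n_knots, 0, L), stats::runif(n_knots, 0, L))
  kd <- sqrt(outer(xy[, 1], knots[, 1], "-")^2 +
             outer(xy[, 2], knots[, 2], "-")^2)
  env <- vapply(seq_len(p$n_env_vars), function(v) {
    f <- drop(exp(-kd / p$env_spatial_autocorr) %*% stats::rnorm(n_knots))
    as.numeric(scale(f))
  }, numeric(p$n_sites))
  colnames(env) <- sprintf("env%d", seq_len(p$n_env_vars))
  rownames(env) <- site_ids

  sp_ids <- sprintf("sp%03d", seq_len(p$n_species))
  optima <- matrix(stats::rnorm(p$n_species * p$n_env_vars), p$n_species,
                   dimnames = list(sp_ids, colnames(env)))
  centres <- cbind(stats::runif(p$n_species, 0, L),
                   stats::runif(p$n_species, 0, L))
  d_home <- sqrt(outer(xy[, 1], centres[, 1], "-")^2 +
                 outer(xy[, 2], centres[, 2], "-")^2)
  niche <- exp(-as.matrix(stats::dist(rbind(env, optima)))[
    seq_len(p$n_sites), p$n_sites + seq_len(p$n_species)]^2 /
      (2 * p$niche_breadth^2))
  disp <- exp(-d_home / p$dispersal_range_km)
  lambda <- niche * disp *
    matrix(stats::rlnorm(p$n_sites * p$n_species, 0, p$noise_sd), p$n_sites)
  if (any(rowSums(lambda) == 0)) stop("site with zero total intensity")
  ab <- t(vapply(seq_len(p$n_sites), function(i)
    as.numeric(stats::rmultinom(1, p$individuals_per_site,
                                lambda[i, ] / sum(lambda[i, ]))),
    numeric(p$n_species)))
  dimnames(ab) <- list(site_ids, sp_ids)

  # trait profiles: redundancy collapses species onto a reduced profile
  # set. Profiles are interleaved along the spatial arrangement of the
  # species' home centres (round-robin over the centre x-rank), so that
  # spatial turnover replaces species WITHIN trait groups -- local
  # communities then sample all profiles, the premise of functionally
  # redundant replacement.
  n_profiles <- max(2L, ceiling((1 - p$functional_redundancy) * p$n_species))
  prof_of <- if (n_profiles >= p$n_species) seq_len(p$n_species) else {
    pr <- integer(p$n_species)
    pr[order(centres[, 1])] <- rep_len(seq_len(n_profiles), p$n_species)
    pr
  }
  prof_random <- matrix(stats::rnorm(n_profiles * p$n_traits), n_profiles)
  cpl <- p$trait_env_coupling
  traits <- matrix(NA_real_, p$n_species, p$n_traits,
                   dimnames = list(sp_ids,
                                   sprintf("trait%d", seq_len(p$n_traits))))
  for (t in seq_len(p$n_traits)) {
    env_part <- if (t <= p$n_env_vars) optima[, t] else
      stats::rnorm(p$n_species)
    rand_part <- prof_random[prof_of, t]
    base <- cpl * env_part + (1 - cpl) * rand_part
    if (p$functional_redundancy > 0 && cpl > 0) {
      # redundancy also pools the coupled part within profile groups
      base <- cpl * stats::ave(env_part, prof_of) + (1 - cpl) * rand_part
    }
    traits[, t] <- base + stats::rnorm(p$n_species, 0, p$trait_noise_sd)
  }

  communityDataset(ab, as.data.frame(traits), coords, env,
                   meta = list(realm = p$realm, biotic_group = p$biotic_group,
                               body_size_log10_g = p$body_size_log10_g,
                               dispersal_mode = p$dispersal_mode,
                               occurrence_only = FALSE))
}

#' Simulate similarity/distance pairs from a known decay curve
#'
#' Direct test harness for the decay GLM: distances are uniform on
#' \code{[0, d_max]} and similarities are drawn with mean
#' \code{exp(intercept + slope * d)} and quasi-binomial-style variance
#' \code{dispersion * mu * (1 - mu)} (a beta draw with matching moments;
#' \code{dispersion = 0} returns the noiseless mean).
#'
#' @param intercept log-scale intercept; \code{exp(intercept)} must be
#'   <= 1.
#' @param slope decay slope per unit distance (non-positive for a decay).
#' @param n_pairs number of pairs.
#' @param dispersion variance inflation in [0, 1).
#' @param seed integer seed.
#' @param d_max upper end of the distance range (default 400).
#' @return list with numeric vectors \code{similarity} and
#'   \code{distance}.
#' @export
simulateDecayPairs <- function(intercept = 0, slope = -0.01, n_pairs = 100L,
                               dispersion = 0.05, seed = 1L, d_max = 400) {
  if (exp(intercept) > 1 + 1e-12) stop("exp(intercept) must be <= 1")
  stopifnot(dispersion >= 0, dispersion < 1)
  .withSeed(seed, {
    d <- stats::runif(n_pairs, 0, d_max)
    mu <- exp(intercept + slope * d)
    if (any(mu <= 0 | mu >= 1 + 1e-12))
      stop("mean similarity outside (0, 1] over the distance range")
    mu <- pmin(mu, 1 - 1e-9)
    if (dispersion == 0) {
      S <- mu
    } else {
      theta <- 1 / dispersion - 1
      S <- stats::rbeta(n_pairs, mu * theta, (1 - mu) * theta)
      S <- pmin(pmax(S, 0), 1)
    }
    list(similarity = S, distance = d)
  })
}

#' Simulate a cross-dataset meta-analysis table directly
#'
#' Draws the nine dataset descriptors over realistic ranges and builds a
#' response (decay rate) as \code{response_fun(descriptor row)} plus
#' Gaussian noise. This bypasses the community-level pipeline and is the
#' harness for testing the boosted-regression-tree stage in isolation
#' (e.g. a response driven by spatial extent only, or pure noise).
#'
#' @param n_datasets number of rows.
#' @param response_fun function(row of descriptors) -> numeric response;
#'   default 0 (pure noise once \code{noise_sd} > 0).
#' @param noise_sd sd of additive Gaussian noise on the response
#'   (default 0).
#' @param seed integer seed.
#' @return data.frame with the nine descriptors plus a \code{response}
#'   column.
#' @export
simulateMetaTable <- function(n_datasets = 50L, response_fun = NULL,
                              noise_sd = 0, seed = 1L) {
  if (is.null(response_fun)) response_fun <- function(row) 0
  .withSeed(seed, {
    tb <- data.frame(
      latitude_abs_deg = stats::runif(n_datasets, 0, 70),
      extent_km = exp(stats::runif(n_datasets, log(20), log(5000))),
      realm = sample(c("freshwater", "marine", "terrestrial"),
                     n_datasets, replace = TRUE),
      body_size_log10_g = stats::runif(n_datasets, -9, 3),
      dispersal_mode = sample(c("active", "passive", "seed"),
                              n_datasets, replace = TRUE),
      gamma_tax = sample(10:300, n_datasets, replace = TRUE),
      gamma_fun = exp(stats::runif(n_datasets, log(0.5), log(50))),
      n_sites = sample(10:100, n_datasets, replace = TRUE),
      n_env_vars = sample(2:12, n_datasets, replace = TRUE),
      stringsAsFactors = FALSE)
    tb$response <- vapply(seq_len(n_datasets),
                          function(i) response_fun(tb[i, ]), numeric(1)) +
      stats::rnorm(n_datasets, 0, noise_sd)
    tb
  })
}

#' Simulate a collection of datasets with a truth table
#'
#' Draws \code{n_datasets} parameter sets from \code{param_sampler}
#' (a function of the dataset index returning a
#' [simulationParams()] object; the default varies spatial extent,
#' dispersal range, latitude, realm, body size and dispersal mode over
#' realistic ranges), simulates each dataset, and returns the datasets
#' plus a truth table of the generating parameters.
#'
#' @param n_datasets number of datasets.
#' @param param_sampler function(i) -> \code{simulation_params}; when
#'   NULL the default sampler is used.
#' @param seed master integer seed (fans out one seed per dataset).
#' @return list with \code{datasets} (list of
#'   [CommunityDataset-class]) and \code{truth} (data.frame of the
#'   generating parameters, one row per dataset).
#' @export
simulateCollection <- function(n_datasets = 30L, param_sampler = NULL,
                               seed = 1L) {
  seeds <- .seedStream(seed, 2L * n_datasets)
  if (is.null(param_sampler)) {
    param_sampler <- function(i) .withSeed(seeds[n_datasets + i], {
      extent <- stats::runif(1, 50, 2000)
      simulationParams(
        n_sites = sample(12:25, 1),
        n_species = sample(25:50, 1),
        extent_km = extent,
        dispersal_range_km = extent * stats::runif(1, 0.1, 1),
        trait_env_coupling = stats::runif(1),
        functional_redundancy = stats::runif(1, 0, 0.8),
        centre_lat = stats::runif(1, -65, 65),
        realm = sample(c("freshwater", "marine", "terrestrial"), 1),
        body_size_log10_g = stats::runif(1, -9, 3),
        dispersal_mode = sample(c("active", "passive", "seed"), 1),
        seed = seeds[i])
    })
  }
  params <- lapply(seq_len(n_datasets), param_sampler)
  datasets <- lapply(params, simulateDataset)
  names(datasets) <- sprintf("dataset%03d", seq_len(n_datasets))
  truth <- do.call(rbind, lapply(seq_len(n_datasets), function(i) {
    p <- params[[i]]
    data.frame(dataset = names(datasets)[i], n_sites = p$n_sites,
               n_species = p$n_species, extent_km = p$extent_km,
               dispersal_range_km = p$dispersal_range_km,
               trait_env_coupling = p$trait_env_coupling,
               functional_redundancy = p$functional_redundancy,
               centre_lat = p$centre_lat, realm = p$realm,
               body_size_log10_g = p$body_size_log10_g,
               dispersal_mode = p$dispersal_mode, seed = p$seed,
               stringsAsFactors = FALSE)
  }))
  list(datasets = datasets, truth = truth)
}
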