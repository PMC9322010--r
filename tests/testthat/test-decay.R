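# Helpers building condensed similarity vectors paired with dist objects.
.mkDist <- function(m, labels) {
  d <- as.dist(m)
  attr(d, "Labels") <- labels
  d
}

test_that("perfect monotone decay gives Mantel r = 1", {
  set.seed(2)
  co <- cbind(lat = runif(8, 40, 41), lon = runif(8, 10, 11))
  rownames(co) <- sprintf("s%d", 1:8)
  d <- spatialDistanceMatrix(co)
  S <- exp(-0.01 * as.numeric(d))  # strictly decreasing in distance
  r <- mantelStrength(S, d, n_perm = 99, seed = 1)
  expect_equal(r$r, 1)
  expect_lte(r$p, 0.05)
  # rank-based: any strictly monotone transform of distance changes nothing
  d2 <- d; d2[] <- log1p(d[])^1.3
  expect_equal(mantelStrength(S, d2, n_perm = 99, seed = 1)$r, 1)
})

test_that("exact permutation p matches exhaustive enumeration on 4 sites", {
  set.seed(8)
  n <- 4
  Dm <- as.matrix(dist(cbind(runif(n), runif(n))))
  Sm <- matrix(runif(n * n), n); Sm <- (Sm + t(Sm)) / 2; diag(Sm) <- 1
  labels <- paste0("s", 1:n)
  dimnames(Dm) <- dimnames(Sm) <- list(labels, labels)
  dd <- .mkDist(Dm, labels)
  S <- as.numeric(as.dist(Sm))  # condensed similarity, dist order
  res <- mantelStrength(S, dd, exact = TRUE, seed = 1)

  # independent oracle: enumerate all 4! relabelings directly
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  ut <- upper.tri(Dm)
  rd <- rank(Dm[ut])
  dis <- 1 - Sm
  stats_all <- apply(perms, 1, function(p) {
    v <- dis[p, p][ut]
    cor(rank(v), rd)
  })
  r_obs <- cor(rank(dis[ut]), rd)
  expect_equal(res$r, r_obs, tolerance = 1e-12)
  expect_equal(res$p, mean(stats_all >= r_obs - 1e-12), tolerance = 1e-12)
  expect_equal(res$n_perm, 24L)
})

test_that("Mantel agrees with vegan and behaves under the null", {
  skip_if_not_installed("vegan")
  set.seed(10)
  co <- cbind(lat = runif(12, 40, 42), lon = runif(12, 10, 12))
  rownames(co) <- sprintf("s%02d", 1:12)
  d <- spatialDistanceMatrix(co)
  S <- runif(66)
  r <- mantelStrength(S, d, n_perm = 999, seed = 3)
  v <- vegan::mantel(as.dist(betadecay:::.squareForm(1 - S, rownames(co))),
                     d, method = "spearman", permutations = 99)
  expect_equal(r$r, unname(v$statistic), tolerance = 1e-10)
  # independence: |r| small, p not extreme for most seeds
  ps <- vapply(1:20, function(s) {
    Ss <- runif(66)
    mantelStrength(Ss, d, n_perm = 199, seed = s)$p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)
})

test_that("constant vectors yield a flagged zero Mantel r", {
  co <- cbind(lat = c(40, 40.5, 41, 41.5), lon = rep(10, 4))
  rownames(co) <- paste0("s", 1:4)
  d <- spatialDistanceMatrix(co)
  expect_warning(r <- mantelStrength(rep(0.4, 6), d, n_perm = 99, seed = 1),
                 "constant")
  expect_identical(r$r, 0)
  expect_true(r$degenerate)
})

test_that("noiseless exponential decay is inverted to machine precision", {
  sim <- simulateDecayPairs(intercept = log(0.9), slope = -0.01,
                            n_pairs = 300, dispersion = 0, seed = 2)
  fit <- fitDecay(sim$similarity, sim$distance)
  expect_equal(fit$slope, -0.01, tolerance = 1e-6)
  expect_equal(fit$intercept, log(0.9), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$dispersion, 1e-10)
})

test_that("slope recovery under quasi-binomial noise is unbiased within 10%", {
  slopes <- vapply(1:60, function(s) {
    sim <- simulateDecayPairs(intercept = log(0.95), slope = -1.0,
                              n_pairs = 200, dispersion = 0.05, seed = s,
                              d_max = 1)
    fitDecay(sim$similarity, sim$distance)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-1.0)) / 1.0, 0.1)

  # no decay: fitted slopes centred on zero and small
  null_sl <- vapply(1:60, function(s) {
    sim <- simulateDecayPairs(intercept = log(0.5), slope = 0,
                              n_pairs = 200, dispersion = 0.05,
                              seed = 1000 + s, d_max = 400)
    fitDecay(sim$similarity, sim$distance)$slope
  }, numeric(1))
  expect_lt(mean(abs(null_sl) * 400), 0.05 * 10)  # |slope * max d| small
  expect_lt(abs(mean(null_sl) * 400), 0.05)
})

test_that("decay fits match glm quasibinomial(log) point estimates", {
  sim <- simulateDecayPairs(intercept = log(0.8), slope = -0.005,
                            n_pairs = 150, dispersion = 0.02, seed = 9)
  fit <- fitDecay(sim$similarity, sim$distance)
  g <- suppressWarnings(glm(sim$similarity ~ sim$distance,
                            family = quasibinomial(link = "log")))
  expect_equal(fit$slope, unname(coef(g)[2]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(coef(g)[1]), tolerance = 1e-6)
  expect_equal(fit$dispersion, summary(g)$dispersion, tolerance = 1e-4)
})

test_that("positive slopes are truncated to zero, idempotently", {
  fit <- structure(list(intercept = -0.1, slope = 0.003, dispersion = 1,
                        converged = TRUE, truncated = FALSE, n_pairs = 10L),
                   class = "decay_fit")
  t1 <- truncatePositiveSlope(fit)
  expect_identical(t1$slope, 0)
  expect_true(t1$truncated)
  expect_identical(truncatePositiveSlope(t1), t1)
  neg <- fit; neg$slope <- -0.01
  expect_identical(truncatePositiveSlope(neg), neg)
  zero <- fit; zero$slope <- 0
  expect_false(truncatePositiveSlope(zero)$truncated)
})

test_that("decaySuite returns the full grid, reproducibly", {
  ds <- simulateDataset(simulationParams(n_sites = 12L, n_species = 25L,
                                         seed = 6L))
  m1 <- suppressWarnings(decaySuite(ds, seed = 4, n_perm = 49, n_samples = 300))
  m2 <- suppressWarnings(decaySuite(ds, seed = 4, n_perm = 49, n_samples = 300))
  expect_identical(m1, m2)
  expect_identical(nrow(m1), 12L)  # 2 facets x 2 gradients x 3 components
  expect_setequal(unique(m1$component), c("total", "replacement", "richness"))
  with(m1, expect_true(all(slope[truncated] == 0)))
  with(m1, expect_true(all(slope <= 0)))

  # construction validity: strong dispersal limitation, no env-trait link
  dsp <- simulateDataset(simulationParams(n_sites = 15L, n_species = 30L,
                                          extent_km = 600,
                                          dispersal_range_km = 60,
                                          trait_env_coupling = 0,
                                          niche_breadth = 50, seed = 8L))
  m <- suppressWarnings(decaySuite(dsp, seed = 2, n_perm = 49, n_samples = 300))
  tot <- m[m$component == "total" & m$facet == "taxonomic", ]
  expect_gt(tot$mantel_r[tot$gradient == "spatial"],
            tot$mantel_r[tot$gradient == "environmental"])
})

test_that("constant traits give functional similarity ~1 and zero functional slopes", {
  ds <- simulateDataset(simulationParams(n_sites = 10L, n_species = 20L,
                                         functional_redundancy = 1,
                                         trait_env_coupling = 0,
                                         trait_noise_sd = 1e-3, seed = 12L))
  m <- suppressWarnings(decaySuite(ds, seed = 3, n_perm = 49, n_samples = 500))
  fun <- m[m$facet == "functional" & m$component == "total", ]
  tax <- m[m$facet == "taxonomic" & m$component == "total", ]
  d_sp <- spatialDistanceMatrix(ds)
  # spatial turnover swaps functionally redundant species: taxonomic decay
  # persists while functional decay vanishes
  expect_lt(tax$slope[tax$gradient == "spatial"], 0)
  expect_true(all(abs(fun$slope[fun$gradient == "spatial"]) * max(d_sp) < 0.05))
  # and mean functional similarity stays high throughout
  fs <- suppressWarnings(functionalSimilarityMatrix(ds, "occurrence",
                                                    seed = 5, n_samples = 500))
  expect_gt(mean(similarityValues(fs), na.rm = TRUE), 0.8)
})
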