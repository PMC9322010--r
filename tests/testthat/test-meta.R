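test_that("dataset descriptors are computed as defined", {
  ds <- transectDataset(n_sites = 12L, total_km = 100)
  smry <- summarizeDataset(ds, seed = 1, n_samples = 300)
  expect_lt(abs(smry$extent_km - 100) / 100, 0.005)
  expect_identical(smry$gamma_tax, 20L)
  expect_identical(smry$n_sites, 12L)
  expect_identical(smry$n_env_vars, 2L)
  expect_gt(smry$gamma_fun, 0)

  # sites symmetric about the equator: |mean latitude| = 0
  ds2 <- transectDataset(n_sites = 10L, total_km = 100)
  co <- siteCoords(ds2)
  co[, "lat"] <- co[, "lat"] - mean(co[, "lat"])
  ds2 <- initialize(ds2, coords = co)
  expect_equal(summarizeDataset(ds2, seed = 1, n_samples = 200,
                                gamma_fun = 1)$latitude_abs_deg, 0)

  # gamma_tax counts only species with at least one occurrence
  expect_identical(summarizeDataset(toyDataset(), seed = 1, n_samples = 200,
                                    gamma_fun = 1)$gamma_tax, 5L)
})

test_that("paired t matches the closed form, antisymmetry and degeneracy", {
  x <- c(2, 3, 4); y <- c(1, 1, 1)   # d = (1, 2, 3)
  r <- pairedT(x, y)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_identical(r$df, 2)
  # independent closed-form check on random vectors
  set.seed(44)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    d <- a - b
    expect_equal(pairedT(a, b)$t, mean(d) / (sd(d) / sqrt(15)),
                 tolerance = 1e-10)
    expect_equal(pairedT(b, a)$t, -pairedT(a, b)$t, tolerance = 1e-10)
  }
  same <- pairedT(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_true(same$degenerate)
})

test_that("BRT ranks a single informative predictor first, deterministically", {
  tb <- simulateMetaTable(60L, response_fun = function(row)
    -0.02 * log(row$extent_km), noise_sd = 0.005, seed = 3L)
  m <- fitBRT(tb, "response", learning_rate = 0.05, max_trees = 1000,
              seed = 9)
  ri <- relativeInfluence(m)
  expect_equal(sum(ri), 100, tolerance = 1e-6)
  expect_identical(names(which.max(ri)), "extent_km")
  expect_gt(ri[["extent_km"]], 50)
  expect_gt(m$deviance_explained, 0.5)
  expect_gte(m$n_trees_selected, 1L)

  m2 <- fitBRT(tb, "response", learning_rate = 0.05, max_trees = 1000,
               seed = 9)
  expect_identical(m$n_trees_selected, m2$n_trees_selected)
  expect_identical(relativeInfluence(m2), ri)

  # pure-noise response: near-zero cross-validated deviance explained
  tb0 <- simulateMetaTable(60L, noise_sd = 1, seed = 5L)
  m0 <- fitBRT(tb0, "response", learning_rate = 0.05, max_trees = 1000,
               seed = 9)
  expect_lt(m0$deviance_explained, 0.1)

  expect_error(fitBRT(tb[1:10, ], "response"), "at least")
  tbc <- tb; tbc$response <- 1
  expect_error(fitBRT(tbc, "response"), "constant")
})

test_that("partial dependence is centred, flat for ignored predictors, monotone for monotone truth", {
  tb <- simulateMetaTable(80L, response_fun = function(row)
    0.01 * row$latitude_abs_deg, noise_sd = 1e-4, seed = 11L)
  m <- fitBRT(tb, "response", learning_rate = 0.05, max_trees = 2000,
              seed = 2)
  pd <- partialDependence(m, "latitude_abs_deg")
  expect_equal(mean(pd$centred_effect), 0, tolerance = 1e-9)
  expect_gt(cor(pd$grid, pd$centred_effect, method = "spearman"), 0.9)
  # a predictor the response ignores: flat profile
  pd0 <- partialDependence(m, "gamma_fun")
  expect_lt(diff(range(pd0$centred_effect)),
            diff(range(pd$centred_effect)) * 0.2)
  expect_warning(partialDependence(m, "latitude_abs_deg", grid = c(-10, 90)),
                 "outside")
})

test_that("interaction sizes flag constructed interactions and stay symmetric", {
  tb <- simulateMetaTable(90L, response_fun = function(row)
    0.001 * row$latitude_abs_deg * log(row$extent_km), noise_sd = 1e-4,
    seed = 21L)
  m <- fitBRT(tb, "response", learning_rate = 0.05, max_trees = 2000,
              tree_depth = 3, seed = 4)
  s_int <- interactionStrength(m, c("latitude_abs_deg", "extent_km"))
  s_rev <- interactionStrength(m, c("extent_km", "latitude_abs_deg"))
  expect_equal(s_int, s_rev, tolerance = 1e-8)
  s_other <- interactionStrength(m, c("gamma_tax", "n_sites"))
  expect_gt(s_int, s_other)

  # additive response: interaction at the noise floor
  tba <- simulateMetaTable(90L, response_fun = function(row)
    0.01 * row$latitude_abs_deg + 0.02 * log(row$extent_km),
    noise_sd = 1e-4, seed = 22L)
  ma <- fitBRT(tba, "response", learning_rate = 0.05, max_trees = 2000,
               tree_depth = 3, seed = 4)
  s_add <- interactionStrength(ma, c("latitude_abs_deg", "extent_km"))
  expect_lt(s_add, s_int)
})

test_that("subsampling keeps the top predictor stable for a strong signal", {
  tb <- simulateMetaTable(60L, response_fun = function(row)
    -0.02 * log(row$extent_km), noise_sd = 0.001, seed = 31L)
  sens <- sensitivitySubsample(tb, "response", fractions = c(1, 0.5),
                               n_reps = 5L, learning_rate = 0.05,
                               max_trees = 1500, seed = 6)
  expect_identical(sens$top_rank_stability[["1"]], 1)
  expect_gte(sens$top_rank_stability[["0.5"]], 0.8)
  expect_setequal(unique(sens$influences$fraction), c(1, 0.5))
})
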