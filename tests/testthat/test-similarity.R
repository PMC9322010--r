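test_that("Sorensen components count shared and unique features", {
  expect_equal(sorensenComponentsOccurrence(c(1, 1, 0), c(0, 1, 1)),
               c(a = 1, b = 1, c = 1))
  expect_equal(sorensenComponentsOccurrence(c(1, 1), c(1, 1))[c("b", "c")],
               c(b = 0, c = 0))
  expect_equal(sorensenComponentsOccurrence(c(1, 0), c(0, 1))[["a"]], 0)
  expect_error(sorensenComponentsOccurrence(c(0, 0), c(0, 0)), "empty")

  expect_equal(sorensenComponentsAbundance(c(3, 0), c(1, 2)),
               c(a = 1, b = 2, c = 2))
  expect_equal(sorensenComponentsAbundance(c(2, 5), c(2, 5))[c("b", "c")],
               c(b = 0, c = 0))
  expect_error(sorensenComponentsAbundance(c(-1, 2), c(1, 1)), "negative")
})

test_that("abundance components on 0/1 vectors equal occurrence components", {
  set.seed(21)
  for (i in 1:50) {
    x <- rbinom(12, 1, 0.5); y <- rbinom(12, 1, 0.5)
    if (sum(x) + sum(y) == 0) next
    expect_equal(sorensenComponentsAbundance(x, y),
                 sorensenComponentsOccurrence(x, y) * 1)
  }
})

test_that("similarity and partition follow the Sorensen forms and their identity", {
  expect_equal(similarityFromComponents(c(1, 1, 1)), 0.5)
  expect_equal(similarityFromComponents(c(7, 0, 0)), 1)
  expect_equal(similarityFromComponents(c(0, 3, 2)), 0)
  expect_error(similarityFromComponents(c(0, 0, 0)), "undefined")

  # independent decomposition oracle (Podani/Carvalho family with the
  # Sorensen denominator), written out directly
  oracle <- function(a, b, c) {
    den <- 2 * a + b + c
    c(total = (b + c) / den, repl = 2 * min(b, c) / den,
      rich = abs(b - c) / den)
  }
  o <- oracle(1, 1, 1)
  p <- partitionDissimilarity(c(1, 1, 1))
  expect_equal(unname(p[1, ]), unname(o), tolerance = 1e-15)
  expect_equal(unname(p[1, "beta_repl"]), 0.5)

  set.seed(4)
  comp <- cbind(runif(1e4, 0, 50), runif(1e4, 0, 50), runif(1e4, 0, 50))
  part <- partitionDissimilarity(comp)
  expect_lt(max(abs(part[, "beta_repl"] + part[, "beta_rich"] -
                    part[, "beta_total"])), 1e-12)
  expect_equal(1 - part[, "beta_total"], similarityFromComponents(comp),
               tolerance = 1e-12, ignore_attr = TRUE)
  # b == c kills the richness part; min(b, c) == 0 kills replacement
  expect_equal(partitionDissimilarity(c(2, 3, 3))[1, "beta_rich"], 0,
               ignore_attr = TRUE)
  expect_equal(partitionDissimilarity(c(2, 0, 3))[1, "beta_repl"], 0,
               ignore_attr = TRUE)
})

test_that("Eq. 1 is monotone: increasing in a, decreasing in b and c", {
  grid <- expand.grid(a = 1:5, b = 0:4, c = 0:4)
  S <- similarityFromComponents(as.matrix(grid))
  for (i in seq_len(nrow(grid))) {
    up_a <- similarityFromComponents(unlist(grid[i, ]) + c(1, 0, 0))
    up_b <- similarityFromComponents(unlist(grid[i, ]) + c(0, 1, 0))
    up_c <- similarityFromComponents(unlist(grid[i, ]) + c(0, 0, 1))
    if (grid$b[i] + grid$c[i] > 0) expect_gt(up_a, S[i])  # S = 1 is a fixed point
    expect_lt(up_b, S[i]); expect_lt(up_c, S[i])
  }
})

test_that("taxonomic similarity matrix matches brute-force set arithmetic", {
  ds <- toyDataset()
  ps <- taxonomicSimilarityMatrix(ds, "occurrence")
  m <- as.matrix(ps)
  # s1 = {sp1,sp2,sp5}, s2 = {sp2,sp3,sp5}, s3 = {sp3,sp4}
  expect_equal(m["s1", "s2"], 1 - (1 + 1) / (2 * 2 + 1 + 1))
  expect_equal(m["s1", "s3"], 0)                      # disjoint
  expect_equal(m["s2", "s3"], 1 - (2 + 1) / (2 * 1 + 2 + 1))
  expect_equal(diag(m), c(s1 = 1, s2 = 1, s3 = 1))

  # abundance facet, by direct min/remainder arithmetic
  pa <- taxonomicSimilarityMatrix(ds, "abundance")
  ab <- abundance(ds)
  cmp <- sorensenComponentsAbundance(ab["s1", ], ab["s2", ])
  expect_equal(as.matrix(pa)["s1", "s2"], similarityFromComponents(cmp))

  # duplicated site rows give similarity 1; binary data collapse the modes
  ds2 <- toyDataset()
  ab2 <- abundance(ds2); ab2["s2", ] <- ab2["s1", ]
  ds2 <- initialize(ds2, abundance = ab2)
  expect_equal(as.matrix(taxonomicSimilarityMatrix(ds2, "abundance"))["s1", "s2"], 1)
  dso <- toOccurrence(ds)
  expect_equal(similarityValues(taxonomicSimilarityMatrix(dso, "abundance")),
               similarityValues(taxonomicSimilarityMatrix(dso, "occurrence")))
})

test_that("disjoint species with shared trait values: functional S exceeds taxonomic S", {
  # two site groups with completely different species but identical trait
  # profiles pairwise (continuous traits included)
  n <- 6L
  sp <- sprintf("sp%02d", 1:12)
  ab <- matrix(0, n, 12, dimnames = list(sprintf("s%d", 1:n), sp))
  for (i in 1:n) {
    if (i <= 3) ab[i, 1:6] <- 1 else ab[i, 7:12] <- 1
  }
  base <- matrix(rnorm(18), 6, 3)
  tr <- as.data.frame(rbind(base, base + rnorm(18, 0, 1e-3)))
  rownames(tr) <- sp; colnames(tr) <- c("t1", "t2", "t3")
  co <- cbind(lat = seq(50, 50.5, length.out = n), lon = rep(10, n))
  rownames(co) <- rownames(ab)
  env <- matrix(rnorm(2 * n), n, 2, dimnames = list(rownames(ab), c("e1", "e2")))
  ds <- communityDataset(ab, tr, co, env)
  tax <- taxonomicSimilarityMatrix(ds, "occurrence")
  fun <- functionalSimilarityMatrix(ds, "occurrence", seed = 5,
                                    n_samples = 2000)
  cross <- as.matrix(tax)[1:3, 4:6]
  expect_true(all(cross == 0))
  fcross <- as.matrix(fun)[1:3, 4:6]
  expect_true(all(fcross > 0.5))
  expect_true(all(fcross > cross))  # functional beats taxonomic on every disjoint pair
})

test_that("functional similarity is seed-reproducible and MC-stable", {
  ds <- simulateDataset(simulationParams(n_sites = 8L, n_species = 20L,
                                         seed = 3L))
  f1 <- functionalSimilarityMatrix(ds, "occurrence", seed = 2, n_samples = 800)
  f2 <- functionalSimilarityMatrix(ds, "occurrence", seed = 2, n_samples = 800)
  expect_identical(similarityValues(f1), similarityValues(f2))
  f3 <- functionalSimilarityMatrix(ds, "occurrence", seed = 99, n_samples = 800)
  expect_lt(max(abs(similarityValues(f1) - similarityValues(f3)), na.rm = TRUE),
            0.1)
  # identical communities at two sites stay near self-similarity
  ab <- abundance(ds); ab[2, ] <- ab[1, ]
  dsx <- initialize(ds, abundance = ab)
  fx <- functionalSimilarityMatrix(dsx, "occurrence", seed = 4, n_samples = 2000)
  expect_gte(as.matrix(fx)[1, 2], 0.9)
})

test_that("pair tables and CSV writers round the data out in both layouts", {
  ds <- toyDataset()
  ps <- taxonomicSimilarityMatrix(ds, "occurrence")
  tab <- pairTable(ps)
  expect_identical(nrow(tab), 3L)
  expect_true(all(c("site_i", "site_j", "S_total", "beta_repl", "a") %in%
                    colnames(tab)))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writePairsCSV(ps, f1)
  writePairsCSV(ps, f2, square = TRUE)
  long <- read.csv(f1)
  expect_equal(long$S_total, ps@S_total)
  sq <- read.csv(f2, row.names = 1, check.names = FALSE)
  expect_equal(unname(as.matrix(sq)), unname(as.matrix(ps)), tolerance = 1e-12)
  f3 <- withr::local_tempfile(fileext = ".csv")
  writePairsCSV(spatialDistanceMatrix(ds), f3)
  expect_identical(read.csv(f3)$kind[1], "spatial_km")
})
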