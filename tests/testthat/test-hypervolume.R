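test_that("single-kernel volume approaches the analytic 95% Gaussian ellipsoid", {
  co <- matrix(0, 1, 3, dimnames = list("sp1", paste0("PCoA", 1:3)))
  sp <- spaceFromCoords(co)
  bw <- c(0.8, 1.0, 1.2)
  h <- buildHypervolume(sp, "sp1", seed = 7, n_samples = 40000,
                        min_species = 1, bandwidth = bw)
  expect_s4_class(h, "Hypervolume")
  analytic <- gaussianEllipsoidVolume(bw, q = 0.95)
  expect_lt(abs(volume(h) - analytic) / analytic, 0.15)
})

test_that("hypervolumes are deterministic given a seed", {
  set.seed(31)
  co <- matrix(rnorm(30), 10, 3,
               dimnames = list(sprintf("sp%02d", 1:10), paste0("PCoA", 1:3)))
  sp <- spaceFromCoords(co)
  h1 <- buildHypervolume(sp, rownames(co)[1:6], seed = 5, n_samples = 2000)
  h2 <- buildHypervolume(sp, rownames(co)[1:6], seed = 5, n_samples = 2000)
  expect_identical(volume(h1), volume(h2))
  expect_identical(h1@threshold, h2@threshold)
  o1 <- hypervolumeOverlap(h1, h2, seed = 9, n_samples = 2000)
  o2 <- hypervolumeOverlap(h1, h2, seed = 9, n_samples = 2000)
  expect_identical(o1, o2)
})

test_that("duplicating every member leaves the mixture (hence volume) unchanged", {
  set.seed(17)
  co <- matrix(rnorm(24), 8, 3,
               dimnames = list(sprintf("sp%d", 1:8), paste0("PCoA", 1:3)))
  co2 <- rbind(co, co)
  rownames(co2) <- c(rownames(co), paste0(rownames(co), "b"))
  h1 <- buildHypervolume(spaceFromCoords(co), rownames(co), seed = 3,
                         n_samples = 20000)
  # duplicated members double the kernel count; Silverman bandwidth depends
  # on m, so pin the bandwidth to isolate the mixture-invariance property
  h2 <- buildHypervolume(spaceFromCoords(co2), rownames(co2), seed = 4,
                         n_samples = 20000, bandwidth = h1@bandwidth)
  expect_lt(abs(volume(h2) - volume(h1)) / volume(h1), 0.05)
})

test_that("overlap behaves at the self and disjoint extremes", {
  set.seed(23)
  co <- matrix(rnorm(18), 6, 3,
               dimnames = list(sprintf("sp%d", 1:6), paste0("PCoA", 1:3)))
  sp <- spaceFromCoords(co)
  h <- buildHypervolume(sp, rownames(co), seed = 2, n_samples = 20000)
  o <- hypervolumeOverlap(h, h, seed = 11, n_samples = 20000)
  expect_equal(o[["b"]], 0)
  expect_equal(o[["c"]], 0)
  expect_lt(abs(o[["a"]] - volume(h)) / volume(h), 0.05)
  # Sorensen similarity of self-overlap stays near 1
  expect_gte(similarityFromComponents(o), 0.9)

  far <- co; far[, 1] <- far[, 1] + 100  # >> 10 bandwidths away
  rownames(far) <- paste0(rownames(co), "f")
  spf <- spaceFromCoords(rbind(co, far))
  h1 <- buildHypervolume(spf, rownames(co), seed = 2, n_samples = 5000)
  h2 <- buildHypervolume(spf, rownames(far), seed = 3, n_samples = 5000)
  od <- hypervolumeOverlap(h1, h2, seed = 7, n_samples = 20000)
  expect_equal(od[["a"]], 0)
})

test_that("two offset single kernels match the closed-form 1-D interval overlap", {
  # both regions are ellipsoids with identical radii; with an offset along
  # one axis the intersection is a lens whose volume has a closed form
  bw <- c(1, 1, 1)
  r <- sqrt(qchisq(0.95, 3))          # ellipsoid radius in bandwidth units
  delta <- 1                           # centre offset: one bandwidth
  co <- rbind(spA = c(0, 0, 0), spB = c(delta, 0, 0))
  colnames(co) <- paste0("PCoA", 1:3)
  sp <- spaceFromCoords(co)
  h1 <- buildHypervolume(sp, "spA", seed = 5, n_samples = 40000,
                         min_species = 1, bandwidth = bw)
  h2 <- buildHypervolume(sp, "spB", seed = 6, n_samples = 40000,
                         min_species = 1, bandwidth = bw)
  o <- hypervolumeOverlap(h1, h2, seed = 8, n_samples = 40000)
  # lens volume of two equal spheres of radius r with centres delta apart:
  # two spherical caps of height r - delta/2
  lens <- pi * (4 * r + delta) * (2 * r - delta)^2 / 12
  expect_lt(abs(o[["a"]] - lens) / lens, 0.1)
})

test_that("a + b is consistent with the first volume (stochastic identity)", {
  set.seed(41)
  co <- matrix(rnorm(36), 12, 3,
               dimnames = list(sprintf("sp%02d", 1:12), paste0("PCoA", 1:3)))
  sp <- spaceFromCoords(co)
  h1 <- buildHypervolume(sp, rownames(co)[1:7], seed = 1, n_samples = 20000)
  h2 <- buildHypervolume(sp, rownames(co)[5:12], seed = 2, n_samples = 20000)
  o <- hypervolumeOverlap(h1, h2, seed = 3, n_samples = 20000)
  expect_lt(abs(o[["a"]] + o[["b"]] - volume(h1)) / volume(h1), 0.1)
  expect_lt(abs(o[["a"]] + o[["c"]] - volume(h2)) / volume(h2), 0.1)
})

test_that("union volume: identity, idempotence and disjoint additivity", {
  set.seed(53)
  co <- matrix(rnorm(24), 8, 3,
               dimnames = list(sprintf("sp%d", 1:8), paste0("PCoA", 1:3)))
  far <- co; far[, 2] <- far[, 2] + 100
  rownames(far) <- paste0(rownames(co), "f")
  sp <- spaceFromCoords(rbind(co, far))
  h1 <- buildHypervolume(sp, rownames(co), seed = 2, n_samples = 20000)
  h2 <- buildHypervolume(sp, rownames(far), seed = 3, n_samples = 20000)
  expect_equal(unionVolume(list(h1), seed = 5, n_samples = 20000), volume(h1),
               tolerance = 0.05)
  expect_equal(unionVolume(list(h1, h1), seed = 5, n_samples = 40000),
               volume(h1), tolerance = 0.05)
  u <- unionVolume(list(h1, h2), seed = 7, n_samples = 60000)
  expect_lt(abs(u - (volume(h1) + volume(h2))) / (volume(h1) + volume(h2)),
            0.1)
  expect_error(unionVolume(list()), "at least one")
})

test_that("volume estimates converge: doubling samples shrinks the spread", {
  co <- matrix(c(0, 0, 0, 1, 1, 0, 0, 1, 1, -1, 0, 1, 2, -1, 0), 5, 3,
               byrow = TRUE,
               dimnames = list(sprintf("sp%d", 1:5), paste0("PCoA", 1:3)))
  sp <- spaceFromCoords(co)
  vols <- function(n) vapply(1:24, function(s)
    volume(buildHypervolume(sp, rownames(co), seed = s, n_samples = n)),
    numeric(1))
  expect_lt(sd(vols(4000)), sd(vols(1000)))
})

test_that("too-small communities are excluded, not fatal", {
  co <- matrix(rnorm(15), 5, 3,
               dimnames = list(sprintf("sp%d", 1:5), paste0("PCoA", 1:3)))
  sp <- spaceFromCoords(co)
  expect_warning(h <- buildHypervolume(sp, c("sp1", "sp2"), seed = 1),
                 "min_species")
  expect_null(h)
  expect_error(buildHypervolume(sp, c("sp1", "nope"), seed = 1,
                                min_species = 1), "nope")
})
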