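# Shared fixture builders; everything is generated in code.

# A small hand-specified dataset with known overlaps between sites.
toyDataset <- function(n_env = 2L) {
  set.seed(101)
  ab <- rbind(
    s1 = c(sp1 = 2, sp2 = 1, sp3 = 0, sp4 = 0, sp5 = 3),
    s2 = c(sp1 = 0, sp2 = 1, sp3 = 4, sp4 = 0, sp5 = 1),
    s3 = c(sp1 = 0, sp2 = 0, sp3 = 2, sp4 = 5, sp5 = 0))
  tr <- data.frame(size = c(1.2, 3.4, 2.2, 0.5, 4.1),
                   woody = c(0, 1, 1, 0, 1),
                   habit = c("a", "b", "a", "c", "b"),
                   row.names = colnames(ab))
  co <- cbind(lat = c(60.0, 60.1, 60.2), lon = c(24.0, 24.2, 24.4))
  rownames(co) <- rownames(ab)
  env <- matrix(rnorm(3 * n_env), 3, n_env,
                dimnames = list(rownames(ab), paste0("env", seq_len(n_env))))
  communityDataset(ab, tr, co, env,
                   meta = list(realm = "terrestrial", biotic_group = "toy",
                               body_size_log10_g = 1.5,
                               dispersal_mode = "seed"))
}

# Sites along a meridian spanning `total_km`, exercising the great-circle
# geometry with a closed-form expected extent.
transectDataset <- function(n_sites = 12L, total_km = 100, seed = 1L) {
  km_per_deg_lat <- pi * 6371 / 180
  set.seed(seed)
  lat <- 45 + seq(0, total_km, length.out = n_sites) / km_per_deg_lat
  co <- cbind(lat = lat, lon = rep(10, n_sites))
  rownames(co) <- sprintf("t%02d", seq_len(n_sites))
  n_sp <- 20L
  ab <- matrix(rpois(n_sites * n_sp, 3), n_sites, n_sp,
               dimnames = list(rownames(co), sprintf("sp%02d", seq_len(n_sp))))
  ab[ab == 0] <- 1  # keep every species present everywhere
  tr <- data.frame(t1 = rnorm(n_sp), t2 = rnorm(n_sp), t3 = rnorm(n_sp),
                   row.names = colnames(ab))
  env <- matrix(rnorm(n_sites * 2), n_sites, 2,
                dimnames = list(rownames(co), c("env1", "env2")))
  communityDataset(ab, tr, co, env)
}

# Trait space spanned by explicit coordinates (bypasses Gower/PCoA) so
# hypervolume geometry can be tested against closed forms.
spaceFromCoords <- function(co) {
  new("TraitSpace", coordinates = co,
      eigenvalues = rep(1, ncol(co)), negativeEigenvalues = FALSE)
}

# Analytic volume of the 95% mass ellipsoid of a diagonal Gaussian.
gaussianEllipsoidVolume <- function(bw, q = 0.95, d = 3) {
  r <- sqrt(qchisq(q, df = d))
  (4 / 3) * pi * r^3 * prod(bw)
}
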