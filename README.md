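# betadecay

**Taxonomic and functional distance decay of community similarity.**

Community ecologists measure β-diversity by how fast the similarity
between pairs of communities declines ("decays") with the spatial or
environmental distance separating them. `betadecay` computes that decay
in two facets and compares them:

* the **taxonomic** facet — similarity in which species two sites share;
* the **functional** facet — similarity in how much trait space two
  sites share, with communities represented as Gaussian-kernel
  hypervolumes on three principal-coordinate axes of a balanced Gower
  trait distance.

Both facets use the Sørensen similarity on shared and unique features,

    S = 1 − (b + c) / (2a + b + c),

where features are species (taxonomic) or hypervolume fractions
(functional), with the total dissimilarity partitioned into replacement
and richness-difference components. Per dataset the package reports the
**strength** of decay (ranked Mantel r: Spearman correlation of
dissimilarity against distance, permutation-tested) and its **rate**
(slope of a quasi-binomial log-link GLM, a negative exponential curve;
positive slopes truncated to zero) — four Mantel r values and four slopes
per dataset (taxonomic/functional × spatial/environmental). A
trait-shuffling null model (species names randomized across the trait
table, 999×) yields standardized effect sizes: SES > 1.96 means
functional similarity decays faster than expected given the taxonomic
turnover, SES < −1.96 slower. Across datasets, paired t-tests compare
facets and Laplace-loss boosted regression trees relate decay rates to
nine dataset descriptors (latitude, spatial extent, realm, body size,
dispersal mode, taxonomic and functional γ-diversity, site and variable
counts).

A synthetic metacommunity generator with controllable dispersal
limitation, environmental filtering of traits, functional redundancy and
noise provides ground-truth inputs for every stage, so the whole pipeline
runs and is tested without any external data.

## Worked example

```r
library(betadecay)

ds <- simulateDataset(simulationParams(
  n_sites = 15, n_species = 30, extent_km = 500,
  dispersal_range_km = 150, trait_env_coupling = 0.6, seed = 42))
ds
#> CommunityDataset: 15 sites x 30 species
#>   traits: 3 columns ( 3 trait units )
#>   env variables: 3
#>   realm: freshwater | biotic group: synthetic

metrics <- decaySuite(ds, seed = 1, n_perm = 199, n_samples = 1000)
subset(as.data.frame(metrics), component == "total",
       select = c(facet, gradient, mantel_r, mantel_p, slope, truncated))
#>       facet      gradient mantel_r mantel_p     slope truncated
#>   taxonomic       spatial    0.299    0.020 -2.59e-04     FALSE
#>   taxonomic environmental    0.515    0.005 -1.49e-01     FALSE
#>  functional       spatial    0.188    0.075 -9.59e-05     FALSE
#>  functional environmental    0.295    0.020 -6.56e-02     FALSE

sesFunctionalDecay(ds, n_iter = 99, seed = 2, n_samples = 300)
#> SES (spatial): observed rate 0.00012, null 0.00010 +/- 0.00006, SES = 0.23
#> SES (environmental): observed rate 0.06709, null 0.06494 +/- 0.03051, SES = 0.07
```

Reading the output: this metacommunity was simulated with moderate
dispersal limitation and a trait–environment link, and the decay metrics
recover exactly that — community similarity decays along both gradients
(negative slopes; Mantel r positive, significant for three of the four
cells), the taxonomic facet decays more strongly than the functional one,
and the SES values near zero say the functional decay is about what the
taxonomic turnover alone would produce, since traits here are only partly
filtered by the environment. Spatial slopes are per km (−2.6e-4/km means
similarity falls by a factor e every ~3,900 km), environmental slopes are
per unit of the [0, 1]-rescaled environmental distance.

The same machinery runs from files: `readDatasetBundle()` loads a
directory of `abundance.csv`, `traits.csv`, `coords.csv`, `env.csv` and a
`schema.yml`, `runDataset()` writes per-dataset artifacts (long-format
CSVs, decay metrics, JSON manifest with every seed and parameter), and
`runMeta()` assembles the cross-dataset table, paired t-tests, BRT models
and subsampling sensitivity.

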