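# End-to-end orchestration: per-dataset runs and the cross-dataset
# meta-analysis, with a JSON manifest recording seeds and parameters so
# identical configurations reproduce identical outputs.

#' Run the full per-dataset pipeline
#'
#' Validates and curates the dataset, computes taxonomic and functional
#' similarity matrices, spatial and environmental distances, the decay
#' metrics grid (Mantel strength + truncated slopes for total,
#' replacement and richness components) and, optionally, the
#' trait-shuffling SES. All artifacts are written under \code{out_dir}
#' (long-format CSVs, a decay-metrics CSV, a JSON result and a manifest);
#' with \code{out_dir = NULL} nothing is written and results are only
#' returned.
#'
#' @param ds a [CommunityDataset-class] or a bundle path for
#'   [readDatasetBundle()].
#' @param out_dir output directory, or NULL.
#' @param mode \code{"occurrence"} or \code{"abundance"}.
#' @param seed master integer seed.
#' @param n_perm Mantel permutations (default 999).
#' @param null_iters SES null iterations; 0 skips the null model.
#' @param q,n_samples,min_species,eps_bw hypervolume parameters.
#' @param dataset_id label used in file names and the manifest.
#' @return list with \code{validation}, \code{similarities},
#'   \code{distances}, \code{metrics} (the \code{decay_metrics} frame),
#'   \code{summary} (nine descriptors), \code{ses} (or NULL) and
#'   \code{manifest}.
#' @export
runDataset <- function(ds, out_dir = NULL, mode = c("occurrence", "abundance"),
                       seed = 1L, n_perm = 999L, null_iters = 0L, q = 0.95,
                       n_samples = 1000L, min_species = 4L, eps_bw = 1e-6,
                       dataset_id = "dataset") {
  mode <- match.arg(mode)
  if (is.character(ds)) ds <- readDatasetBundle(ds)
  rep <- validateDataset(ds)
  if (!rep$passed)
    stop("dataset '", dataset_id, "' fails validation: ",
         paste(rep$messages, collapse = "; "))
  ds <- filterEnvVariables(ds)
  seeds <- .seedStream(seed, 4L)
  metrics <- decaySuite(ds, mode = mode, seed = seeds[1], n_perm = n_perm,
                        q = q, n_samples = n_samples,
                        min_species = min_species, eps_bw = eps_bw)
  # same sub-seed decaySuite used internally, so the written functional
  # similarities are the ones the metrics were computed from
  fun_seed <- .seedStream(seeds[1], 3L)[1]
  sims <- list(
    taxonomic = taxonomicSimilarityMatrix(ds, mode),
    functional = suppressWarnings(
      functionalSimilarityMatrix(ds, mode, seed = fun_seed,
                                 q = q, n_samples = n_samples,
                                 min_species = min_species,
                                 eps_bw = eps_bw)))
  dists <- list(spatial = spatialDistanceMatrix(ds),
                environmental = environmentalDistanceMatrix(ds))
  summary_row <- summarizeDataset(ds, seed = seeds[2], q = q,
                                  n_samples = n_samples,
                                  min_species = min_species,
                                  eps_bw = eps_bw)
  ses <- NULL
  if (null_iters > 0)
    ses <- suppressWarnings(
      sesFunctionalDecay(ds, n_iter = null_iters, seed = seeds[3],
                         mode = mode, q = q, n_samples = n_samples,
                         min_species = min_species, eps_bw = eps_bw))
  manifest <- list(dataset = dataset_id, mode = mode, seed = as.integer(seed),
                   n_perm = as.integer(n_perm),
                   null_iters = as.integer(null_iters),
                   hypervolume = list(q = q, n_samples = as.integer(n_samples),
                                      min_species = as.integer(min_species),
                                      eps_bw = eps_bw),
                   n_sites = nSites(ds), n_species = nSpecies(ds),
                   package_version = as.character(utils::packageVersion("betadecay")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (f in names(sims))
      writePairsCSV(sims[[f]], file.path(out_dir,
                    sprintf("%s_similarity_%s.csv", dataset_id, f)))
    for (g in names(dists))
      writePairsCSV(dists[[g]], file.path(out_dir,
                    sprintf("%s_distance_%s.csv", dataset_id, g)))
    utils::write.table(metrics, file.path(out_dir,
                       sprintf("%s_decay_metrics.csv", dataset_id)),
                       sep = ",", row.names = FALSE, quote = TRUE)
    res_json <- list(manifest = manifest,
                     validation = unclass(rep),
                     summary = as.list(summary_row),
                     metrics = metrics)
    if (!is.null(ses)) res_json$ses <- lapply(unclass(ses), unclass)
    jsonlite::write_json(res_json, file.path(out_dir,
                         sprintf("%s_results.json", dataset_id)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(validation = rep, similarities = sims, distances = dists,
       metrics = metrics, summary = summary_row, ses = ses,
       manifest = manifest)
}

#' Assemble the meta-analysis table from per-dataset runs
#'
#' One row per dataset: the nine descriptors plus the four Mantel r and
#' four (truncated) slopes of the total component, and SES values when
#' present.
#'
#' @param runs named list of [runDataset()] results.
#' @return data.frame, one row per dataset.
#' @export
buildMetaTable <- function(runs) {
  stopifnot(length(runs) >= 1)
  ids <- names(runs) %||% sprintf("dataset%03d", seq_along(runs))
  do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    m <- r$metrics
    m <- m[m$component == "total", ]
    row <- r$summary
    row$dataset <- ids[i]
    for (j in seq_len(nrow(m))) {
      key <- paste0(substr(m$facet[j], 1, 3), "_",
                    ifelse(m$gradient[j] == "spatial", "spatial", "env"))
      row[[paste0("mantel_r_", key)]] <- m$mantel_r[j]
      row[[paste0("slope_", key)]] <- m$slope[j]
    }
    if (!is.null(r$ses)) {
      row$ses_spatial <- r$ses$spatial$ses
      row$ses_env <- r$ses$environmental$ses
    }
    row
  }))
}

#' Run the cross-dataset meta-analysis
#'
#' Builds the meta table, runs the paired t-tests comparing taxonomic and
#' functional Mantel r per gradient, and (when at least \code{min_rows}
#' datasets are available) fits the Laplace-loss BRT for each of the four
#' slope responses, with optional subsampling sensitivity.
#'
#' @param runs named list of [runDataset()] results (>= 2 for t-tests).
#' @param out_dir output directory for CSV/JSON artifacts, or NULL.
#' @param brt_params list of arguments forwarded to [fitBRT()].
#' @param sensitivity run [sensitivitySubsample()] per response
#'   (default FALSE).
#' @param min_rows minimum datasets for the BRT stage (default 20).
#' @param seed integer seed.
#' @return list with \code{table}, \code{t_tests}, \code{brt} (possibly
#'   empty), \code{sensitivity} (or NULL).
#' @export
runMeta <- function(runs, out_dir = NULL, brt_params = list(),
                    sensitivity = FALSE, min_rows = 20L, seed = 1L) {
  if (length(runs) < 2) stop("runMeta needs at least 2 dataset runs")
  tb <- buildMetaTable(runs)
  t_tests <- list(
    spatial = pairedT(tb$mantel_r_tax_spatial, tb$mantel_r_fun_spatial),
    environmental = pairedT(tb$mantel_r_tax_env, tb$mantel_r_fun_env))
  responses <- c("slope_tax_spatial", "slope_fun_spatial",
                 "slope_tax_env", "slope_fun_env")
  brt <- list(); sens <- NULL
  if (nrow(tb) >= min_rows) {
    for (resp in responses) {
      brt[[resp]] <- tryCatch(
        do.call(fitBRT, c(list(table = tb, response = resp, seed = seed),
                          brt_params)),
        error = function(e) {
          warning("BRT for ", resp, " failed: ", conditionMessage(e))
          NULL
        })
    }
    if (sensitivity)
      sens <- lapply(responses, function(resp)
        do.call(sensitivitySubsample,
                c(list(table = tb, response = resp, seed = seed),
                  brt_params)))
  } else {
    warning("only ", nrow(tb), " datasets: skipping the BRT stage ",
            "(needs >= ", min_rows, "); t-tests still computed")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tb, file.path(out_dir, "meta_table.csv"), sep = ",",
                       row.names = FALSE, quote = TRUE)
    jsonlite::write_json(t_tests, file.path(out_dir, "paired_t.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    brt_sum <- lapply(Filter(Negate(is.null), brt), function(m)
      list(response = m$response,
           n_trees_selected = m$n_trees_selected,
           deviance_explained = m$deviance_explained,
           relative_influence = as.list(m$relative_influence)))
    jsonlite::write_json(brt_sum, file.path(out_dir, "brt_models.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(table = tb, t_tests = t_tests, brt = brt, sensitivity = sens)
}
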