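# Cross-dataset synthesis: the nine dataset descriptors, paired t-tests
# on Mantel r, Laplace-loss boosted regression trees on decay slopes,
# relative influence, partial dependence, interactions and subsampling
# sensitivity.

.BRT_PREDICTORS <- c("latitude_abs_deg", "extent_km", "realm",
                     "body_size_log10_g", "dispersal_mode", "gamma_tax",
                     "gamma_fun", "n_sites", "n_env_vars")

#' The nine cross-dataset descriptors of one dataset
#'
#' (1) latitude as the absolute mean site latitude; (2) spatial extent as
#' the largest pairwise great-circle distance (km); (3) realm;
#' (4) body size as mean log10 fresh weight (g); (5) dispersal mode;
#' (6) taxonomic gamma-diversity (species count); (7) functional
#' gamma-diversity (union hypervolume volume, SD^3); (8) number of sites;
#' (9) number of environmental variables.
#'
#' @param ds a curated [CommunityDataset-class].
#' @param seed seed for the union-hypervolume Monte Carlo.
#' @param q,n_samples,min_species,eps_bw hypervolume parameters.
#' @param gamma_fun optionally supply a precomputed union volume and skip
#'   the hypervolume computation.
#' @return one-row data.frame with the nine descriptors.
#' @export
summarizeDataset <- function(ds, seed = 1L, q = 0.95, n_samples = 1000L,
                             min_species = 4L, eps_bw = 1e-6,
                             gamma_fun = NULL) {
  stopifnot(is(ds, "CommunityDataset"))
  d_sp <- spatialDistanceMatrix(ds)
  if (is.null(gamma_fun)) {
    space <- pcoaEmbed(balancedGower(speciesTraits(ds), traitTypes(ds),
                                     fuzzyGroups(ds)), k = 3L)
    ab <- abundance(ds)
    seeds <- .seedStream(seed, nrow(ab) + 1L)
    hvs <- lapply(seq_len(nrow(ab)), function(i) {
      members <- colnames(ab)[ab[i, ] > 0]
      if (length(members) < min_species) return(NULL)
      suppressWarnings(buildHypervolume(space, members, seed = seeds[i],
                                        q = q, n_samples = n_samples,
                                        min_species = min_species,
                                        eps_bw = eps_bw))
    })
    hvs <- Filter(Negate(is.null), hvs)
    gamma_fun <- if (length(hvs))
      unionVolume(hvs, seed = seeds[nrow(ab) + 1L], n_samples = n_samples)
    else NA_real_
  }
  meta <- datasetMeta(ds)
  data.frame(
    latitude_abs_deg = abs(mean(siteCoords(ds)[, 1])),
    extent_km = max(d_sp),
    realm = meta$realm %||% NA_character_,
    body_size_log10_g = meta$body_size_log10_g %||% NA_real_,
    dispersal_mode = meta$dispersal_mode %||% NA_character_,
    gamma_tax = sum(colSums(abundance(ds)) > 0),
    gamma_fun = gamma_fun,
    n_sites = nSites(ds),
    n_env_vars = ncol(envData(ds)),
    stringsAsFactors = FALSE)
}

#' Student's paired t-test
#'
#' Compares two per-dataset metrics (e.g. taxonomic vs functional Mantel
#' r) paired by dataset: t = mean(d) / (sd(d) / sqrt(n)), df = n - 1,
#' two-sided p.
#'
#' @param x,y numeric vectors of equal length n >= 3, paired by dataset.
#' @return list \code{t}, \code{df}, \code{p}, \code{mean_difference},
#'   \code{degenerate} (TRUE when the differences have zero variance).
#' @export
pairedT <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  if (stats::sd(d) == 0)
    return(list(t = if (mean(d) == 0) 0 else NA_real_,
                df = length(d) - 1L,
                p = if (mean(d) == 0) 1 else NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = mean(d), degenerate = FALSE)
}

# One-hot design matrix for the BRT, remembering which columns belong to
# which predictor so importances can be re-aggregated.
.brtDesign <- function(table, predictors) {
  cols <- list(); groups <- character(0)
  for (p in predictors) {
    x <- table[[p]]
    if (is.character(x) || is.factor(x)) {
      x <- factor(x)
      for (lev in levels(x)) {
        cols[[paste0(p, "=", lev)]] <- as.numeric(x == lev)
        groups <- c(groups, stats::setNames(p, paste0(p, "=", lev)))
      }
    } else {
      cols[[p]] <- as.numeric(x)
      groups <- c(groups, stats::setNames(p, p))
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  list(X = X, groups = groups)
}

#' Fit a Laplace-loss boosted regression tree model across datasets
#'
#' Stagewise gradient boosting of shallow regression trees under
#' absolute-error (Laplace) loss, with the number of trees selected by
#' 10-fold cross-validation (early stop at the CV-deviance minimum).
#' Categorical predictors enter one-hot. Reports
#' pseudo-deviance-explained = 1 - MAE(model) / MAE(median), the Laplace
#' analogue of deviance explained. Deterministic given \code{seed}.
#'
#' @param table a meta-analysis table (one row per dataset) holding the
#'   nine descriptors of [summarizeDataset()] plus the response column.
#' @param response name of the response column (a decay slope).
#' @param predictors predictor column names (default: the nine
#'   descriptors).
#' @param learning_rate boosting shrinkage (default 0.001).
#' @param tree_depth maximum tree depth (default 5).
#' @param bag_fraction subsampling fraction per tree (default 0.5).
#' @param min_node_obs minimum observations per terminal node (default 10,
#'   the classic gbm convention; under absolute-error loss the per-point
#'   hessian weight is 1, so this is an observation count).
#' @param max_trees cap on boosting rounds scanned by CV (default 10000).
#' @param n_folds CV folds (default 10).
#' @param min_rows minimum rows required (default 20).
#' @param seed integer seed.
#' @return list of class \code{brt_model}: the fitted booster,
#'   \code{n_trees_selected}, \code{deviance_explained} (cross-validated,
#'   1 - CV MAE / null MAE; \code{training_deviance_explained} is the
#'   in-sample analogue), \code{relative_influence} (percentages summing
#'   to 100), the design information and the hyperparameters.
#' @export
fitBRT <- function(table, response, predictors = .BRT_PREDICTORS,
                   learning_rate = 0.001, tree_depth = 5L,
                   bag_fraction = 0.5, min_node_obs = 10L,
                   max_trees = 10000L, n_folds = 10L,
                   min_rows = 20L, seed = 1L) {
  table <- as.data.frame(table)
  keep <- stats::complete.cases(table[, c(response, predictors)])
  table <- table[keep, , drop = FALSE]
  if (nrow(table) < min_rows)
    stop("fitBRT needs at least ", min_rows, " complete rows")
  y <- as.numeric(table[[response]])
  if (stats::sd(y) == 0) stop("constant response: nothing to model")
  des <- .brtDesign(table, predictors)
  dtrain <- xgboost::xgb.DMatrix(des$X, label = y)
  params <- list(objective = "reg:absoluteerror", eta = learning_rate,
                 max_depth = tree_depth, subsample = bag_fraction,
                 min_child_weight = min_node_obs, nthread = 1)
  cv <- .withSeed(seed, xgboost::xgb.cv(
    params = params, data = dtrain, nrounds = max_trees,
    nfold = n_folds, early_stopping_rounds = 50L, verbose = 0))
  best <- which.min(cv$evaluation_log$test_mae_mean)
  booster <- .withSeed(seed, xgboost::xgb.train(
    params = params, data = dtrain, nrounds = best, verbose = 0))
  pred <- stats::predict(booster, des$X)
  mae_model <- mean(abs(y - pred))
  mae_cv <- min(cv$evaluation_log$test_mae_mean)
  mae_null <- mean(abs(y - stats::median(y)))
  imp <- tryCatch(xgboost::xgb.importance(model = booster),
                  error = function(e) NULL)
  ri <- stats::setNames(rep(0, length(predictors)), predictors)
  if (!is.null(imp) && nrow(imp)) {
    gain <- stats::setNames(imp$Gain, imp$Feature)
    for (f in names(gain)) ri[des$groups[[f]]] <- ri[des$groups[[f]]] + gain[[f]]
    ri <- 100 * ri / sum(ri)
  }
  structure(list(booster = booster, response = response,
                 predictors = predictors, design = des, data = table,
                 y = y, n_trees_selected = as.integer(best),
                 deviance_explained = 1 - mae_cv / mae_null,
                 training_deviance_explained = 1 - mae_model / mae_null,
                 relative_influence = ri,
                 learning_rate = learning_rate, tree_depth = tree_depth,
                 bag_fraction = bag_fraction,
                 min_node_obs = as.integer(min_node_obs),
                 seed = as.integer(seed)),
            class = "brt_model")
}

#' @export
print.brt_model <- function(x, ...) {
  cat(sprintf("BRT (Laplace loss) on '%s': %d trees, deviance explained %.1f%%\n",
              x$response, x$n_trees_selected, 100 * x$deviance_explained))
  ri <- sort(x$relative_influence, decreasing = TRUE)
  cat("  relative influence (%):\n")
  for (p in names(ri)) cat(sprintf("    %-20s %5.1f\n", p, ri[p]))
  invisible(x)
}

#' Relative influence of each predictor
#'
#' Per-split loss-reduction (squared-improvement) sums aggregated per
#' predictor and normalized to 100 percent; one-hot columns of a
#' categorical predictor are pooled.
#'
#' @param model a \code{brt_model}.
#' @return named numeric percentages summing to 100.
#' @export
relativeInfluence <- function(model) {
  stopifnot(inherits(model, "brt_model"))
  model$relative_influence
}

#' Partial dependence of the BRT response on one predictor
#'
#' For each grid value g, the mean model prediction over the training
#' table with the predictor forced to g, centred to mean zero (positive
#' values = steeper-than-average decay rate).
#'
#' @param model a \code{brt_model}.
#' @param predictor predictor name.
#' @param grid grid values (default: 25 quantile points for continuous
#'   predictors, the observed levels for categorical ones).
#' @return data.frame \code{predictor}, \code{grid},
#'   \code{centred_effect}.
#' @export
partialDependence <- function(model, predictor, grid = NULL) {
  stopifnot(inherits(model, "brt_model"),
            predictor %in% model$predictors)
  x <- model$data[[predictor]]
  categorical <- is.character(x) || is.factor(x)
  if (is.null(grid)) {
    grid <- if (categorical) unique(as.character(x)) else
      unique(stats::quantile(x, probs = seq(0, 1, length.out = 25),
                             names = FALSE))
  } else if (!categorical &&
             (min(grid) < min(x) || max(grid) > max(x))) {
    warning("partial dependence grid extends outside the observed range")
  }
  eff <- vapply(grid, function(g) {
    tbl <- model$data
    tbl[[predictor]] <- if (categorical) as.character(g) else as.numeric(g)
    if (categorical) {
      # keep all observed levels so the one-hot design stays aligned
      tbl[[predictor]] <- factor(tbl[[predictor]],
                                 levels = levels(factor(model$data[[predictor]])))
    }
    Xg <- .brtDesign(tbl, model$predictors)$X
    Xg <- Xg[, colnames(model$design$X), drop = FALSE]
    mean(stats::predict(model$booster, Xg))
  }, numeric(1))
  data.frame(predictor = predictor, grid = grid,
             centred_effect = eff - mean(eff), stringsAsFactors = FALSE)
}

#' Pairwise interaction strength in a BRT
#'
#' gbm-style statistic: the model's partial-dependence surface on a 2-D
#' grid of the predictor pair is regressed on an additive model with
#' arbitrary main effects in the two grid margins; the interaction size is
#' 1000 times the variance of the non-additive remainder (the x1000
#' scaling is the conventional reporting scale). Symmetric in the pair.
#'
#' @param model a \code{brt_model}.
#' @param pair character vector of two predictor names.
#' @param grid_size grid points per continuous margin (default 10).
#' @return numeric interaction size.
#' @export
interactionStrength <- function(model, pair, grid_size = 10L) {
  stopifnot(inherits(model, "brt_model"), length(pair) == 2,
            all(pair %in% model$predictors))
  margin <- function(p) {
    x <- model$data[[p]]
    if (is.character(x) || is.factor(x)) unique(as.character(x)) else
      unique(stats::quantile(x, probs = seq(0.05, 0.95,
                                            length.out = grid_size),
                             names = FALSE))
  }
  g1 <- margin(pair[1]); g2 <- margin(pair[2])
  gg <- expand.grid(v1 = g1, v2 = g2, stringsAsFactors = FALSE)
  pd <- mapply(function(a, b) {
    tbl <- model$data
    tbl[[pair[1]]] <- .coerceLike(a, model$data[[pair[1]]])
    tbl[[pair[2]]] <- .coerceLike(b, model$data[[pair[2]]])
    Xg <- .brtDesign(tbl, model$predictors)$X
    Xg <- Xg[, colnames(model$design$X), drop = FALSE]
    mean(stats::predict(model$booster, Xg))
  }, gg$v1, gg$v2)
  fit <- stats::lm(pd ~ factor(gg$v1) + factor(gg$v2))
  1000 * stats::var(stats::residuals(fit))
}

.coerceLike <- function(value, template) {
  if (is.character(template) || is.factor(template))
    factor(as.character(value), levels = levels(factor(template)))
  else as.numeric(value)
}

#' Subsampling sensitivity of a BRT fit
#'
#' Refits the model on random subsets of 90, 70 and 50 percent of the
#' rows and summarizes how stable the relative influences (and the
#' top-ranked predictor) are per fraction.
#'
#' @param table,response,predictors,seed,... as in [fitBRT()].
#' @param fractions subsampling fractions (default 0.9, 0.7, 0.5).
#' @param n_reps replicates per fraction (default 10).
#' @return list with \code{influences} (long data.frame: fraction, rep,
#'   predictor, influence) and \code{top_rank_stability} (per fraction,
#'   the share of replicates whose top predictor matches the full fit).
#' @export
sensitivitySubsample <- function(table, response,
                                 predictors = .BRT_PREDICTORS,
                                 fractions = c(0.9, 0.7, 0.5),
                                 n_reps = 10L, seed = 1L, ...) {
  full <- fitBRT(table, response, predictors, seed = seed, ...)
  top_full <- names(which.max(full$relative_influence))
  seeds <- .seedStream(seed, length(fractions) * n_reps)
  rows <- list(); k <- 0L
  stability <- stats::setNames(numeric(length(fractions)),
                               as.character(fractions))
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    hits <- 0L
    for (r in seq_len(n_reps)) {
      s <- seeds[(fi - 1L) * n_reps + r]
      idx <- .withSeed(s, sample.int(nrow(table), ceiling(f * nrow(table))))
      m <- fitBRT(table[idx, , drop = FALSE], response, predictors,
                  seed = s, min_rows = 10L, ...)
      if (names(which.max(m$relative_influence)) == top_full)
        hits <- hits + 1L
      k <- k + 1L
      rows[[k]] <- data.frame(fraction = f, rep = r,
                              predictor = names(m$relative_influence),
                              influence = unname(m$relative_influence),
                              stringsAsFactors = FALSE)
    }
    stability[as.character(f)] <- hits / n_reps
  }
  list(full = full, influences = do.call(rbind, rows),
       top_rank_stability = stability)
}
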