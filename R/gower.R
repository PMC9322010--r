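#' Balanced Gower distance among species
#'
#' Pairwise trait distances in [0, 1] for mixed trait tables, with trait
#' weights balanced so every trait (counting a fuzzy-coded group as one
#' trait) contributes equally, on average, to the combined distance.
#'
#' Per-trait distances: continuous traits use the range-normalized absolute
#' difference; binary and categorical traits use 0/1 mismatch; a fuzzy
#' group uses the mean over its member columns of range-normalized
#' differences, the whole group acting as a single variable. Missing trait
#' values are handled by pairwise deletion: for each species pair the
#' combined distance renormalizes over the traits observed in both.
#'
#' The balancing weights are found by iterative proportional fitting:
#' starting from equal weights, each trait's weight is rescaled by the
#' ratio of the target (common) mean contribution to its current mean
#' pairwise contribution, until all mean contributions agree to
#' \code{tol} (default 1e-8) or \code{max_iter} iterations. With no
#' missing data this converges in one step to weights inversely
#' proportional to each trait's mean distance. Zero-variance traits
#' (all pairwise distances zero) cannot contribute and are dropped with a
#' warning.
#'
#' @param traits species x traits data.frame (row names = species).
#' @param trait_types named character vector per column (see
#'   [communityDataset()]); guessed if NULL.
#' @param fuzzy_groups named list of fuzzy group -> member columns.
#' @param tol convergence tolerance on the spread of mean contributions.
#' @param max_iter iteration cap (default 1000).
#' @return a \code{dist} object of balanced Gower distances in [0, 1],
#'   with attributes \code{weights} (the balanced trait weights) and
#'   \code{contributions} (each trait's mean pairwise contribution).
#' @examples
#' tr <- data.frame(size = c(1, 2, 4), woody = c(0, 1, 1),
#'                  row.names = paste0("sp", 1:3))
#' balancedGower(tr)
#' @export
balancedGower <- function(traits, trait_types = NULL, fuzzy_groups = list(),
                          tol = 1e-8, max_iter = 1000L) {
  traits <- as.data.frame(traits)
  n <- nrow(traits)
  if (n < 2) stop("balancedGower needs at least 2 species")
  if (is.null(trait_types)) {
    trait_types <- vapply(traits, function(x) {
      if (is.numeric(x)) {
        v <- x[!is.na(x)]
        if (length(v) && all(v %in% c(0, 1))) "binary" else "continuous"
      } else "categorical"
    }, character(1))
    names(trait_types) <- colnames(traits)
    for (g in names(fuzzy_groups)) trait_types[fuzzy_groups[[g]]] <- "fuzzy"
  }
  all_missing <- rownames(traits)[rowSums(!is.na(traits)) == 0]
  if (length(all_missing))
    stop("species missing all traits: ", paste(all_missing, collapse = ", "))

  # One distance matrix per trait *unit* (fuzzy group = one unit).
  units <- list()
  plain <- setdiff(colnames(traits), unlist(fuzzy_groups))
  for (cn in plain)
    units[[cn]] <- .traitUnitDist(traits[[cn]], trait_types[[cn]])
  for (g in names(fuzzy_groups)) {
    mats <- lapply(fuzzy_groups[[g]], function(cn)
      .traitUnitDist(traits[[cn]], "continuous"))
    arr <- simplify2array(mats)
    units[[g]] <- apply(arr, c(1, 2), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  }

  # Drop zero-variance units.
  zero <- vapply(units, function(m) {
    v <- m[upper.tri(m)]
    all(is.na(v)) || max(v, na.rm = TRUE) == 0
  }, logical(1))
  if (any(zero)) {
    warning("balancedGower: dropping zero-variance trait unit(s): ",
            paste(names(units)[zero], collapse = ", "))
    units <- units[!zero]
  }
  if (length(units) == 0) stop("no informative traits remain")
  p <- length(units)
  ut <- upper.tri(units[[1]])
  dmat <- vapply(units, function(m) m[ut], numeric(sum(ut)))  # pairs x units
  avail <- !is.na(dmat)
  if (any(rowSums(avail) == 0))
    stop("species pair(s) share no observed traits")

  w <- rep(1 / p, p)
  contrib <- numeric(p)
  for (iter in seq_len(max_iter)) {
    wm <- matrix(w, nrow(dmat), p, byrow = TRUE)
    wm[!avail] <- 0
    denom <- rowSums(wm)
    share <- wm / denom            # per-pair renormalized weights
    contr_pair <- share * ifelse(avail, dmat, 0)
    contrib <- colMeans(contr_pair)
    target <- mean(contrib)
    if (max(abs(contrib - target)) < tol) break
    adj <- ifelse(contrib > 0, target / contrib, 1)
    w <- w * adj
    w <- w / sum(w)
  }
  Dvals <- rowSums(share * ifelse(avail, dmat, 0))
  Dvals <- pmin(pmax(Dvals, 0), 1)
  m <- matrix(0, n, n, dimnames = list(rownames(traits), rownames(traits)))
  m[ut] <- Dvals
  m <- m + t(m)
  d <- stats::as.dist(m)
  attr(d, "weights") <- stats::setNames(w, names(units))
  attr(d, "contributions") <- stats::setNames(contrib, names(units))
  d
}

# Pairwise distance matrix for a single trait column.
.traitUnitDist <- function(x, type) {
  n <- length(x)
  if (type %in% c("continuous", "fuzzy")) {
    x <- as.numeric(x)
    rng <- diff(range(x, na.rm = TRUE))
    d <- abs(outer(x, x, "-"))
    if (rng > 0) d <- d / rng
  } else {
    # binary and categorical: 0/1 mismatch
    d <- outer(x, x, FUN = function(a, b) as.numeric(a != b))
  }
  d[is.na(d)] <- NA_real_
  # pairs with a missing value stay NA
  na_i <- is.na(x)
  d[na_i, ] <- NA_real_
  d[, na_i] <- NA_real_
  diag(d) <- 0
  d
}
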