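#' Principal coordinates embedding of a trait distance matrix
#'
#' Classical scaling: eigen-decomposition of the double-centred matrix
#' \eqn{-\frac{1}{2} J D^2 J}, retaining the top \code{k} axes by
#' eigenvalue, scaled by the square root of their eigenvalues. No
#' Cailliez/Lingoes correction is applied; negative eigenvalues elsewhere
#' in the spectrum only set \code{negativeEigenvalues}. The sign of each
#' axis is fixed so that its largest-magnitude loading is positive, making
#' the embedding reproducible across platforms.
#'
#' @param D a \code{dist} (e.g. from [balancedGower()]) or symmetric matrix.
#' @param k number of axes to retain (default 3). Fails if fewer than
#'   \code{k} eigenvalues are positive.
#' @return a [TraitSpace-class].
#' @examples
#' tr <- data.frame(a = rnorm(8), b = rnorm(8), row.names = paste0("s", 1:8))
#' sp <- pcoaEmbed(balancedGower(tr), k = 2)
#' head(sp@coordinates)
#' @export
pcoaEmbed <- function(D, k = 3L) {
  m <- as.matrix(D)
  n <- nrow(m)
  if (n < k + 1) stop("pcoaEmbed needs at least k + 1 = ", k + 1, " species")
  A <- -0.5 * m^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- sum(e$values > 1e-12)
  if (pos < k)
    stop("only ", pos, " positive eigenvalue(s); reduce k to at most ", pos)
  co <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  # sign convention: largest-magnitude loading positive per axis
  for (j in seq_len(k)) {
    i <- which.max(abs(co[, j]))
    if (co[i, j] < 0) co[, j] <- -co[, j]
  }
  rownames(co) <- rownames(m)
  colnames(co) <- paste0("PCoA", seq_len(k))
  new("TraitSpace", coordinates = co, eigenvalues = e$values,
      negativeEigenvalues = any(e$values < -1e-12))
}

setMethod("show", "TraitSpace", function(object) {
  k <- ncol(object@coordinates)
  ev <- object@eigenvalues
  rel <- round(100 * ev[seq_len(k)] / sum(ev[ev > 0]), 1)
  cat("TraitSpace:", nrow(object@coordinates), "species on", k, "axes\n")
  cat("  eigenvalue share (%):", paste(rel, collapse = ", "), "\n")
  if (object@negativeEigenvalues)
    cat("  note: negative eigenvalues present in the full spectrum\n")
})
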