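#' Principal component analysis of a genotype panel
#'
#' Works on the alternate-allele dosage matrix (0/1/2): missing entries
#' are mean-imputed per site, sites are centered and scaled by
#' `sqrt(2 p (1-p))` with `p` the sample alternate frequency (the
#' allele-frequency-variance scaling used by genotype-PCA tools), and the
#' sample covariance matrix is eigendecomposed. Monomorphic sites drop
#' out. Sample coordinates are eigenvectors scaled by the square root of
#' their eigenvalues.
#'
#' @param panel a [genotype_panel()].
#' @param k number of components (`k < n_samples`).
#' @param scale logical; divide by `sqrt(2p(1-p))` (centering always on).
#' @return list with `coords` (samples x k), `eigenvalues` (all),
#'   `var_frac` (fractions of total variance, first k).
#' @export
pca <- function(panel, k = 4, scale = TRUE) {
  ns <- n_samples(panel)
  if (k >= ns) stop("k must be smaller than the number of samples")
  D <- dosage_matrix(panel)
  mu <- rowMeans(D, na.rm = TRUE)
  imp <- which(is.na(D), arr.ind = TRUE)
  if (nrow(imp)) D[imp] <- mu[imp[, 1L]]
  p <- mu / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all sites monomorphic")
  X <- D[poly, , drop = FALSE] - mu[poly]
  if (scale) X <- X / sqrt(2 * p[poly] * (1 - p[poly]))
  C <- crossprod(X) / (nrow(X) - 1L)
  eig <- eigen(C, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(k)]), k)
  rownames(coords) <- panel$samples
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, eigenvalues = lam,
       var_frac = lam[seq_len(k)] / sum(lam))
}

#' Pairwise p-distance matrix between samples
#'
#' Per co-called site, identical genotypes contribute 0, heterozygote vs
#' homozygote 0.5, opposite homozygotes 1 (i.e. half the absolute dosage
#' difference); the distance is the mean over co-called sites, handled
#' pairwise.
#'
#' @param panel a [genotype_panel()].
#' @param on_empty `"error"` (default) or `"na"` for sample pairs with no
#'   co-called site.
#' @return symmetric numeric matrix with zero diagonal, labeled by sample.
#' @export
p_distance_matrix <- function(panel, on_empty = c("error", "na")) {
  on_empty <- match.arg(on_empty)
  D <- dosage_matrix(panel)
  ns <- ncol(D)
  out <- matrix(0, ns, ns, dimnames = list(panel$samples, panel$samples))
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    ok <- !is.na(D[, i]) & !is.na(D[, j])
    if (!any(ok)) {
      if (on_empty == "error")
        stop("samples ", panel$samples[i], " and ", panel$samples[j],
             " share no co-called site")
      out[i, j] <- out[j, i] <- NA_real_
    } else {
      out[i, j] <- out[j, i] <- mean(abs(D[ok, i] - D[ok, j])) / 2
    }
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the pairwise distances; negative branch
#' lengths (a known artifact of NJ on noisy matrices) are clamped to zero
#' with the deficit transferred to the sister branch, preserving path
#' lengths through the parent node.
#'
#' @param dm symmetric distance matrix with labels.
#' @return an `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(dm))
  for (iter in seq_len(nrow(tr$edge))) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1L]
    parent <- tr$edge[e, 1L]
    sibs <- which(tr$edge[, 1L] == parent & seq_len(nrow(tr$edge)) != e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs))
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + deficit
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
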