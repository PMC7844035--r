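#' Weir-Cockerham variance components from per-population summaries
#'
#' Two-population form of the 1984 analysis-of-variance estimator for a
#' biallelic locus, vectorized over loci. Inputs are per-locus sample
#' sizes (called diploid genotypes), alternate-allele sample frequencies
#' and observed heterozygote proportions for each population.
#'
#' @param nA,nB called genotype counts per locus.
#' @param pA,pB alternate-allele frequencies per locus.
#' @param hA,hB observed heterozygote proportions per locus.
#' @return data.frame with components `a` (among populations), `b` (among
#'   individuals within populations), `c` (within individuals) and `fst =
#'   a / (a + b + c)`; rows where either population has fewer than two
#'   called genotypes, or the locus is monomorphic across both
#'   populations, are `NA`.
#' @export
wc_components_counts <- function(nA, pA, hA, nB, pB, hB) {
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- nA < 2 | nB < 2 | is.na(pA) | is.na(pB) |
    (pbar %in% c(0, 1) & s2 == 0 & hbar == 0)
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  denom <- a + b + cc
  data.frame(a = a, b = b, c = cc,
             fst = ifelse(!is.na(denom) & denom > 0, a / denom, NA_real_))
}

#' Per-locus Weir-Cockerham components for two populations of a panel
#'
#' @param panel a [genotype_panel()].
#' @param popmap a [population_map()].
#' @param popA,popB population labels.
#' @return data.frame `chrom`, `pos`, `a`, `b`, `c`, `fst`.
#' @export
wc_components <- function(panel, popmap, popA, popB) {
  stat <- function(pop) {
    idx <- match(pop_samples(popmap, pop), panel$samples)
    a <- panel$geno[, 2L * idx - 1L, drop = FALSE]
    b <- panel$geno[, 2L * idx, drop = FALSE]
    ok <- a >= 0L & b >= 0L
    n <- rowSums(ok)
    alt <- rowSums((a == 1L) * ok) + rowSums((b == 1L) * ok)
    list(n = n, p = ifelse(n > 0, alt / (2 * n), NA_real_),
         h = ifelse(n > 0, rowSums((a != b) & ok) / n, NA_real_))
  }
  A <- stat(popA); B <- stat(popB)
  comp <- wc_components_counts(A$n, A$p, A$h, B$n, B$p, B$h)
  cbind(data.frame(chrom = panel$chrom, pos = panel$pos,
                   stringsAsFactors = FALSE), comp)
}

#' Windowed Weir-Cockerham FST
#'
#' Window value is the ratio of sums `sum(a) / sum(a + b + c)` over the
#' informative loci in the window (the "weighted" windowed estimator);
#' `method = "mean_of_ratios"` averages per-locus `a/(a+b+c)` instead.
#' Windows with fewer than `min_snps` informative loci carry no score.
#' Z-scores are computed across all scored windows of the comparison.
#'
#' @param components data.frame from [wc_components()].
#' @param windows data.frame from [make_windows()].
#' @param min_snps minimum informative loci per scored window.
#' @param method `"ratio_of_sums"` (default) or `"mean_of_ratios"`.
#' @return data.frame `chrom`, `start`, `end`, `n_snps`, `fst`, `z`.
#' @export
windowed_fst <- function(components, windows, min_snps = 10,
                         method = c("ratio_of_sums", "mean_of_ratios")) {
  method <- match.arg(method)
  if (nrow(components) == 0L) stop("empty component set")
  ok <- !is.na(components$a)
  comp <- components[ok, , drop = FALSE]
  denom <- comp$a + comp$b + comp$c
  vals <- if (method == "ratio_of_sums")
    cbind(num = comp$a, den = denom)
  else
    cbind(num = ifelse(denom > 0, comp$a / denom, NA_real_), den = 1)
  # drop ratio-undefined loci in mean_of_ratios mode
  keep <- !is.na(vals[, "num"])
  w <- .window_sums(comp$chrom[keep], comp$pos[keep],
                    vals[keep, , drop = FALSE], windows)
  fst <- ifelse(w[, "den"] != 0, w[, "num"] / w[, "den"], NA_real_)
  fst[w[, "n_snps"] < min_snps] <- NA_real_
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, n_snps = as.integer(w[, "n_snps"]),
             fst = fst, z = z_transform(fst), stringsAsFactors = FALSE)
}

#' Genome-wide ratio-of-sums FST
#'
#' @param components data.frame from [wc_components()].
#' @return single numeric value `sum(a) / sum(a + b + c)` over
#'   informative loci.
#' @export
global_fst <- function(components) {
  ok <- !is.na(components$a)
  sum(components$a[ok]) / sum(components$a[ok] + components$b[ok] +
                                components$c[ok])
}

#' Windows exceeding an FST Z-score cutoff
#'
#' @param scores data.frame from [windowed_fst()].
#' @param z_min cutoff; windows with `z > z_min` are returned.
#' @return the selected rows, sorted by decreasing Z.
#' @export
significant_fst_windows <- function(scores, z_min = 4) {
  out <- scores[!is.na(scores$z) & scores$z > z_min, , drop = FALSE]
  out[order(-out$z), , drop = FALSE]
}
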