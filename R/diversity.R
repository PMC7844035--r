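#' Per-variant allele counts for one population
#'
#' @param panel a [genotype_panel()].
#' @param popmap a [population_map()].
#' @param pop population label.
#' @return data.frame with `chrom`, `pos`, `ref_count`, `alt_count`,
#'   `n_called` (called diploid genotypes; counts run over non-missing
#'   alleles, so `ref_count + alt_count <= 2 * n_samples`).
#' @export
allele_counts <- function(panel, popmap, pop) {
  g <- panel$geno[, hap_columns(panel, pop_samples(popmap, pop)),
                  drop = FALSE]
  a <- g[, seq(1L, ncol(g), 2L), drop = FALSE]
  b <- g[, seq(2L, ncol(g), 2L), drop = FALSE]
  data.frame(chrom = panel$chrom, pos = panel$pos,
             ref_count = rowSums(g == 0L),
             alt_count = rowSums(g == 1L),
             n_called = rowSums(a >= 0L & b >= 0L),
             stringsAsFactors = FALSE)
}

#' Per-population diversity summary
#'
#' Per site: alternate frequency `p` over called alleles, expected
#' heterozygosity `He = 2p(1-p)`, observed heterozygote fraction `Ho`
#' among fully called genotypes, and `MAF = min(p, 1-p)`. The summary
#' averages each quantity over polymorphic sites (`He > 0`) and derives
#' the inbreeding coefficient `FIS = 1 - mean(Ho)/mean(He)`.
#'
#' @param panel a [genotype_panel()].
#' @param popmap a [population_map()].
#' @param pop population label.
#' @return list with `He`, `Ho`, `MAF`, `FIS` and `n_polymorphic`.
#' @export
diversity_stats <- function(panel, popmap, pop) {
  s <- pop_samples(popmap, pop)
  if (length(s) < 2L) stop("population ", pop, " has fewer than 2 samples")
  idx <- match(s, panel$samples)
  a <- panel$geno[, 2L * idx - 1L, drop = FALSE]
  b <- panel$geno[, 2L * idx, drop = FALSE]
  called_gt <- a >= 0L & b >= 0L
  n_called <- rowSums(called_gt)
  alt <- rowSums((a == 1L) * called_gt) + rowSums((b == 1L) * called_gt)
  p <- ifelse(n_called > 0L, alt / (2L * n_called), NA_real_)
  he <- 2 * p * (1 - p)
  ho <- ifelse(n_called > 0L, rowSums((a != b) & called_gt) / n_called, NA_real_)
  poly <- !is.na(he) & he > 0
  if (!any(poly)) stop("no polymorphic sites in population ", pop)
  He <- mean(he[poly]); Ho <- mean(ho[poly])
  list(He = He, Ho = Ho, MAF = mean(pmin(p, 1 - p)[poly]),
       FIS = 1 - Ho / He, n_polymorphic = sum(poly))
}

#' Sliding genomic windows
#'
#' Windows start at 0 and advance by `step`, truncated at the chromosome
#' end; every start below the chromosome length is emitted, so trailing
#' windows may be shorter than `size`.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param size window size (bp).
#' @param step sliding step (bp); `size >= step > 0`.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
make_windows <- function(chrom_lengths, size = 100000, step = 50000) {
  if (step <= 0 || size < step) stop("need size >= step > 0")
  do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, L - 1), by = step)
    data.frame(chrom = ch, start = starts, end = pmin(starts + size, L),
               stringsAsFactors = FALSE)
  }))
}

# internal: per-window sums of per-SNP values via cumulative sums; returns
# a matrix with one column per value vector plus an n_snps column.
# `chrom`/`pos` must be sorted within chromosome (panel invariant).
.window_sums <- function(chrom, pos, values, windows) {
  values <- as.matrix(values)
  out <- matrix(0, nrow = nrow(windows), ncol = ncol(values) + 1L,
                dimnames = list(NULL, c(colnames(values), "n_snps")))
  for (ch in unique(windows$chrom)) {
    ridx <- which(chrom == ch)
    widx <- which(windows$chrom == ch)
    if (length(ridx) == 0L) next
    p <- pos[ridx]
    cs <- rbind(0, apply(values[ridx, , drop = FALSE], 2L, cumsum))
    lo <- findInterval(windows$start[widx] - 0.5, p) + 1L  # first SNP >= start
    hi <- findInterval(windows$end[widx] - 0.5, p)          # last SNP < end
    n <- pmax(hi - lo + 1L, 0L)
    sums <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
    sums[n == 0L, ] <- 0
    out[widx, ] <- cbind(sums, n)
  }
  out
}

#' Windowed pooled heterozygosity (Hp)
#'
#' For each window, `Hp = 2 * S_maj * S_min / (S_maj + S_min)^2`, where
#' `S_maj` and `S_min` sum the per-SNP major and minor allele counts of
#' the population over the SNPs in the window. Major/minor labels are
#' assigned per SNP from that population's pooled counts; ties go to the
#' reference allele. Windows with fewer than `min_snps` SNPs carry no
#' score, and Z-scores are computed across all scored windows.
#'
#' @param counts output of [allele_counts()] for one population.
#' @param windows data.frame from [make_windows()].
#' @param min_snps minimum SNPs per scored window.
#' @return data.frame `chrom`, `start`, `end`, `n_snps`, `hp`, `z`.
#' @export
pooled_heterozygosity <- function(counts, windows, min_snps = 10) {
  if (nrow(windows) == 0L) stop("empty window set")
  maj <- pmax(counts$ref_count, counts$alt_count)
  mnr <- pmin(counts$ref_count, counts$alt_count)
  w <- .window_sums(counts$chrom, counts$pos,
                    cbind(maj = maj, mnr = mnr), windows)
  tot <- w[, "maj"] + w[, "mnr"]
  hp <- ifelse(tot > 0, 2 * w[, "maj"] * w[, "mnr"] / tot^2, NA_real_)
  hp[w[, "n_snps"] < min_snps] <- NA_real_
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, n_snps = as.integer(w[, "n_snps"]),
             hp = hp, z = z_transform(hp), stringsAsFactors = FALSE)
}

#' Z-transform a vector of scores
#'
#' Standardizes to mean 0 and sample standard deviation 1 (n - 1
#' denominator) over the defined values; `NA` inputs propagate. A
#' zero-spread input yields all-`NA` with a warning.
#'
#' @param values numeric vector.
#' @return numeric vector of Z-scores.
#' @export
z_transform <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) {
    warning("fewer than 2 defined values; Z-scores undefined")
    return(rep(NA_real_, length(values)))
  }
  s <- sd(values[ok])
  if (!is.finite(s) || s == 0) {
    warning("zero spread; Z-scores undefined")
    return(rep(NA_real_, length(values)))
  }
  (values - mean(values[ok])) / s
}
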