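#' PLINK-style ROH scan parameters
#'
#' Defaults follow the standard flag set for whole-genome resequencing
#' panels: `--homozyg-window-kb 5000 --homozyg-window-snp 50
#' --homozyg-window-het 1 --homozyg-window-missing 5 --homozyg-snp 10
#' --homozyg-kb 200 --homozyg-density 50 --homozyg-gap 1000`, plus the
#' tool's default hit-rate threshold of 0.05.
#'
#' @param window_kb maximum span (kb) of a scanning window.
#' @param window_snp SNPs per scanning window.
#' @param window_het maximum heterozygous calls in a passing window.
#' @param window_missing maximum missing calls in a passing window.
#' @param min_snp minimum SNPs per emitted segment.
#' @param min_kb minimum segment length (kb).
#' @param max_density_kb_per_snp maximum kb per SNP within a segment.
#' @param max_gap_kb segments are split at inter-SNP gaps above this (kb).
#' @param hit_threshold minimum fraction of passing windows covering a SNP.
#' @export
roh_params <- function(window_kb = 5000, window_snp = 50, window_het = 1,
                       window_missing = 5, min_snp = 10, min_kb = 200,
                       max_density_kb_per_snp = 50, max_gap_kb = 1000,
                       hit_threshold = 0.05) {
  p <- list(window_kb = window_kb, window_snp = window_snp,
            window_het = window_het, window_missing = window_missing,
            min_snp = min_snp, min_kb = min_kb,
            max_density_kb_per_snp = max_density_kb_per_snp,
            max_gap_kb = max_gap_kb, hit_threshold = hit_threshold)
  if (any(unlist(p) <= 0 & names(p) != "window_het" &
            names(p) != "window_missing"))
    stop("ROH parameters must be positive")
  p
}

# rolling sums of x over windows of w consecutive entries
.roll_sum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]
}

#' Detect runs of homozygosity in one sample
#'
#' Scanning-window procedure: windows of `window_snp` consecutive SNPs
#' (failing when their span exceeds `window_kb`) pass if they contain at
#' most `window_het` heterozygous and `window_missing` missing calls.
#' Each SNP's hit rate is the fraction of covering windows that pass;
#' SNPs at or above `hit_threshold` form candidate runs, which are split
#' at gaps above `max_gap_kb`, trimmed to called homozygous endpoints and
#' emitted when they satisfy the SNP-count, length and density floors.
#' Chromosomes with fewer SNPs than `window_snp` are scanned with a
#' single window of all their SNPs.
#'
#' @param panel a [genotype_panel()].
#' @param sample sample identifier.
#' @param params a [roh_params()] list.
#' @return data.frame `sample`, `chrom`, `start`, `end` (0-based
#'   half-open, first to last SNP of the run), `n_snps`, `length_kb`.
#' @export
detect_roh <- function(panel, sample, params = roh_params()) {
  i <- match(sample, panel$samples)
  if (is.na(i)) stop("unknown sample: ", sample)
  segs <- list()
  for (ch in unique(panel$chrom)) {
    rows <- which(panel$chrom == ch)
    pos <- panel$pos[rows]
    a <- panel$geno[rows, 2L * i - 1L]
    b <- panel$geno[rows, 2L * i]
    missing <- a < 0L | b < 0L
    het <- !missing & a != b
    hom <- !missing & a == b
    n <- length(rows)
    w <- params$window_snp
    if (n < w) {
      pass <- sum(het) <= params$window_het &&
        sum(missing) <= params$window_missing &&
        (pos[n] - pos[1L]) <= params$window_kb * 1000
      hit <- rep(as.numeric(pass), n)
    } else {
      span_ok <- (pos[w:n] - pos[1L:(n - w + 1L)]) <= params$window_kb * 1000
      pass <- .roll_sum(het, w) <= params$window_het &
        .roll_sum(missing, w) <= params$window_missing & span_ok
      # windows covering SNP s start in [s-w+1, s] (clipped to valid range)
      csp <- c(0, cumsum(pass))
      s <- seq_len(n)
      lo <- pmax(s - w + 1L, 1L); hi <- pmin(s, n - w + 1L)
      covering <- hi - lo + 1L
      hits <- csp[hi + 1L] - csp[lo]
      hit <- hits / covering
    }
    cand <- hit >= params$hit_threshold
    # candidate runs of consecutive SNPs, split at large gaps
    r <- rle(cand)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- starts[k]:ends[k]
      gap_break <- which(diff(pos[run]) > params$max_gap_kb * 1000)
      pieces <- split(run, cumsum(c(0L, seq_along(run)[-1L] %in%
                                      (gap_break + 1L))))
      for (piece in pieces) {
        # trim to called homozygous endpoints
        while (length(piece) && !hom[piece[1L]]) piece <- piece[-1L]
        while (length(piece) && !hom[piece[length(piece)]])
          piece <- piece[-length(piece)]
        ns <- length(piece)
        if (ns < params$min_snp) next
        len_kb <- (pos[piece[ns]] - pos[piece[1L]]) / 1000
        if (len_kb < params$min_kb) next
        if (len_kb / ns > params$max_density_kb_per_snp) next
        segs[[length(segs) + 1L]] <-
          data.frame(sample = sample, chrom = ch,
                     start = pos[piece[1L]], end = pos[piece[ns]] + 1L,
                     n_snps = ns, length_kb = len_kb,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(segs))
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), length_kb = numeric(0)))
  do.call(rbind, segs)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' `r2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = P(1,1) - pA pB`, computed
#' over haplotypes with no missing allele at either site.
#'
#' @param hap_a,hap_b equal-length 0/1 haplotype vectors (-1 missing).
#' @return scalar in `[0, 1]`; `NA` when either site is monomorphic over
#'   the complete pairs.
#' @export
r2 <- function(hap_a, hap_b) {
  ok <- hap_a >= 0L & hap_b >= 0L
  a <- hap_a[ok]; b <- hap_b[ok]
  if (!length(a)) return(NA_real_)
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  D <- mean(a * b) - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Binned LD decay
#'
#' For every SNP pair within `max_dist` on the same chromosome, computes
#' haplotype r-squared and bins it by physical distance, reporting the
#' per-bin pair count and mean.
#'
#' @param panel a phased [genotype_panel()].
#' @param popmap a [population_map()]; with `pop = NULL` all samples are
#'   pooled.
#' @param pop population label or `NULL`.
#' @param max_dist maximum pair distance (bp).
#' @param bin_size bin width (bp).
#' @return data.frame `lo`, `hi`, `n_pairs`, `mean_r2` (`NA` for empty
#'   bins).
#' @export
ld_decay <- function(panel, popmap = NULL, pop = NULL, max_dist = 300000,
                     bin_size = 5000) {
  cols <- if (is.null(pop)) seq_len(ncol(panel$geno))
          else hap_columns(panel, pop_samples(popmap, pop))
  if (length(cols) < 4L) stop("need at least 4 haplotypes")
  nb <- ceiling(max_dist / bin_size)
  sums <- numeric(nb); cnts <- integer(nb)
  for (ch in unique(panel$chrom)) {
    rows <- which(panel$chrom == ch)
    H <- panel$geno[rows, cols, drop = FALSE]
    pos <- panel$pos[rows]
    n <- length(rows)
    storage.mode(H) <- "double"
    miss <- H < 0
    Hc <- H; Hc[miss] <- 0
    valid <- !miss
    for (k in seq_len(n - 1L)) {
      d <- pos[(k + 1L):n] - pos[1L:(n - k)]
      if (all(d > max_dist)) break
      keep <- which(d <= max_dist)
      i1 <- keep; i2 <- keep + k
      M <- valid[i1, , drop = FALSE] & valid[i2, , drop = FALSE]
      nh <- rowSums(M)
      pa <- rowSums(Hc[i1, , drop = FALSE] * M) / nh
      pb <- rowSums(Hc[i2, , drop = FALSE] * M) / nh
      pab <- rowSums(Hc[i1, , drop = FALSE] * Hc[i2, , drop = FALSE] * M) / nh
      va <- pa * (1 - pa); vb <- pb * (1 - pb)
      ok <- nh > 0 & va > 0 & vb > 0
      if (!any(ok)) next
      rr <- (pab[ok] - pa[ok] * pb[ok])^2 / (va[ok] * vb[ok])
      bin <- pmin(pmax(ceiling(d[keep][ok] / bin_size), 1L), nb)
      for (bb in unique(bin)) {
        sel <- bin == bb
        sums[bb] <- sums[bb] + sum(rr[sel])
        cnts[bb] <- cnts[bb] + sum(sel)
      }
    }
  }
  data.frame(lo = (seq_len(nb) - 1L) * bin_size, hi = seq_len(nb) * bin_size,
             n_pairs = cnts,
             mean_r2 = ifelse(cnts > 0, sums / cnts, NA_real_))
}
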