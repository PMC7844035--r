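#' Extended haplotype homozygosity profile from a core SNP
#'
#' EHH at a flanking SNP `x` is the probability that two randomly drawn
#' haplotypes are identical over every SNP from the core through `x`:
#' `EHH(x) = sum_g C(n_g, 2) / C(n, 2)`, where `n_g` are the sizes of the
#' identity classes. EHH at the core itself is 1 by convention; the core
#' allele participates in identity from the first flanking SNP onwards.
#' Computed over all haplotypes of the population (the cross-population
#' convention; no split by core allele). A missing allele breaks identity
#' for that haplotype.
#'
#' @param haps integer matrix, variants x haplotypes (0/1, -1 missing),
#'   one chromosome, positions sorted.
#' @param pos positions (bp) per variant row.
#' @param core_index row index of the core SNP.
#' @param direction `"downstream"` (increasing position) or `"upstream"`.
#' @return data.frame with `index`, `pos`, `ehh`, starting at the core
#'   (`ehh = 1`); attribute `truncation` records why the walk stopped
#'   (`"chromosome_end"` or `"collapsed"`, i.e. all haplotypes distinct).
#' @export
ehh <- function(haps, pos, core_index,
                direction = c("downstream", "upstream")) {
  direction <- match.arg(direction)
  n <- ncol(haps)
  if (n < 2L) stop("need at least 2 haplotypes")
  steps <- if (direction == "downstream")
    seq(core_index, nrow(haps)) else seq(core_index, 1L)
  idx <- steps[1L]; out_i <- idx; out_e <- 1
  grp <- rep(1L, n)
  denom <- n * (n - 1) / 2
  truncation <- "chromosome_end"
  for (j in steps) {
    al <- haps[j, ]
    al[al < 0L] <- 1L + seq_len(n)[al < 0L]  # missing: unique forever
    key <- grp * (n + 2L) + al
    grp <- match(key, key)
    cnt <- tabulate(grp, nbins = n)
    e <- sum(cnt * (cnt - 1) / 2) / denom
    if (j != core_index) { out_i <- c(out_i, j); out_e <- c(out_e, e) }
    if (e == 0) { truncation <- "collapsed"; break }
  }
  res <- data.frame(index = out_i, pos = pos[out_i], ehh = out_e)
  attr(res, "truncation") <- truncation
  res
}

#' Integrated EHH of one profile
#'
#' Trapezoidal integral of EHH over physical distance from the core,
#' truncated at the first point where EHH drops below `cutoff` (that
#' trapezoid is still included, as is standard for this statistic) or
#' before any inter-SNP gap larger than `max_gap` (area across and beyond
#' the gap is excluded).
#'
#' @param profile data.frame from [ehh()] (one direction).
#' @param cutoff EHH truncation level.
#' @param max_gap largest allowed inter-SNP gap (bp).
#' @return scalar integral (bp units); 0 for a single-point profile.
#' @export
ihh <- function(profile, cutoff = 0.05, max_gap = 200000) {
  p <- profile$pos; e <- profile$ehh
  if (length(p) < 2L) return(0)
  total <- 0
  for (k in 2:length(p)) {
    gap <- abs(p[k] - p[k - 1L])
    if (gap > max_gap) break
    total <- total + gap * (e[k] + e[k - 1L]) / 2
    if (e[k] < cutoff) break
  }
  total
}

# internal: iHH at one core, both directions (pure-R reference route)
.ihh_core_r <- function(haps, pos, core_index, cutoff = 0.05,
                        max_gap = 200000) {
  ihh(ehh(haps, pos, core_index, "downstream"), cutoff, max_gap) +
    ihh(ehh(haps, pos, core_index, "upstream"), cutoff, max_gap)
}

#' Cross-population EHH scan (XP-EHH)
#'
#' At every SNP, integrates EHH in each population (over all haplotypes,
#' both directions, trapezoidal in bp, truncated at `cutoff` and at gaps
#' above `max_gap`) and forms `raw = ln(iHH_A / iHH_B)`; raw scores are
#' standardized genome-wide to mean 0, sample sd 1. Positive normalized
#' scores indicate longer haplotype homozygosity in `popA`. SNPs where
#' either integral is zero are undefined (`NA`).
#'
#' @param panel a phased [genotype_panel()].
#' @param popmap a [population_map()].
#' @param popA,popB population labels.
#' @param cutoff,max_gap integration controls, see [ihh()].
#' @return data.frame `chrom`, `pos`, `ihh_a`, `ihh_b`, `raw`, `norm`.
#' @export
xpehh <- function(panel, popmap, popA, popB, cutoff = 0.05,
                  max_gap = 200000) {
  if (!panel$phased)
    stop("XP-EHH requires phased haplotypes; phase the input first")
  hapsA_all <- hap_columns(panel, pop_samples(popmap, popA))
  hapsB_all <- hap_columns(panel, pop_samples(popmap, popB))
  if (length(hapsA_all) < 5L || length(hapsB_all) < 5L)
    stop("each population needs at least 5 haplotypes")
  res <- lapply(unique(panel$chrom), function(ch) {
    rows <- which(panel$chrom == ch)
    pos <- as.numeric(panel$pos[rows])
    HA <- panel$geno[rows, hapsA_all, drop = FALSE]
    HB <- panel$geno[rows, hapsB_all, drop = FALSE]
    data.frame(chrom = ch, pos = panel$pos[rows],
               ihh_a = ihh_scan_cpp(HA, pos, cutoff, max_gap),
               ihh_b = ihh_scan_cpp(HB, pos, cutoff, max_gap),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$raw <- ifelse(out$ihh_a > 0 & out$ihh_b > 0,
                    log(out$ihh_a / out$ihh_b), NA_real_)
  out$norm <- z_transform(out$raw)
  out
}

#' Tail extraction for XP-EHH scores
#'
#' Default: the top fraction `q` of defined SNPs by normalized-score rank
#' (`side = "both"` ranks by absolute value; `"upper"`/`"lower"` take one
#' tail). `mode = "pvalue"` instead flags SNPs with two-sided normal
#' p-value at or below `q`.
#'
#' @param result data.frame from [xpehh()].
#' @param q tail fraction in `(0, 0.5]` (or p-value threshold).
#' @param side `"both"`, `"upper"` or `"lower"`.
#' @param mode `"rank"` (empirical top fraction) or `"pvalue"`.
#' @return `result` restricted to the tail SNPs, with a `tail` column.
#' @export
top_fraction <- function(result, q = 0.01, side = c("both", "upper", "lower"),
                         mode = c("rank", "pvalue")) {
  side <- match.arg(side); mode <- match.arg(mode)
  if (q <= 0 || q > 0.5) stop("q must lie in (0, 0.5]")
  z <- result$norm
  ok <- !is.na(z)
  score <- switch(side, both = abs(z), upper = z, lower = -z)
  if (mode == "rank") {
    k <- floor(sum(ok) * q)
    if (k < 1L) return(result[0, , drop = FALSE])
    thr <- sort(score[ok], decreasing = TRUE)[k]
    sel <- ok & score >= thr
    # resolve boundary ties deterministically by genome order
    if (sum(sel) > k) sel[which(sel)[-seq_len(k)]] <- FALSE
  } else {
    sel <- ok & 2 * stats::pnorm(-abs(switch(side, both = z, upper = z,
                                             lower = z))) <= q &
      (side == "both" | (side == "upper" & z > 0) | (side == "lower" & z < 0))
  }
  out <- result[sel, , drop = FALSE]
  out$tail <- TRUE
  out
}

#' Map XP-EHH SNP scores to windows
#'
#' Window score is the maximum `|normalized|` among the window's SNPs
#' (signed value of that SNP retained); a window is flagged `in_tail`
#' when it contains at least one tail SNP.
#'
#' @param result data.frame from [xpehh()].
#' @param windows data.frame from [make_windows()].
#' @param tail_snps output of [top_fraction()].
#' @return windows with `n_snps`, `peak_norm` and `in_tail` columns.
#' @export
xpehh_windows <- function(result, windows, tail_snps = NULL) {
  out <- windows
  out$n_snps <- 0L; out$peak_norm <- NA_real_; out$in_tail <- FALSE
  for (i in seq_len(nrow(windows))) {
    sel <- result$chrom == windows$chrom[i] &
      result$pos >= windows$start[i] & result$pos < windows$end[i] &
      !is.na(result$norm)
    out$n_snps[i] <- sum(sel)
    if (any(sel)) {
      z <- result$norm[sel]
      out$peak_norm[i] <- z[which.max(abs(z))]
    }
    if (!is.null(tail_snps))
      out$in_tail[i] <- any(tail_snps$chrom == windows$chrom[i] &
                              tail_snps$pos >= windows$start[i] &
                              tail_snps$pos < windows$end[i])
  }
  out
}
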