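#' Default configuration of the planted-sweep benchmark
#'
#' Two populations of 25 samples on two 8-Mb chromosomes (4,000 SNPs
#' each, background differentiation F = 0.05), with one 500-kb hard
#' sweep planted in `pop1` (derived frequency 0.95, founder fraction
#' 0.9) -- the regime the outlier thresholds `ZHp < -4`, `ZFst > 4` and
#' the top-1% XP-EHH tail are meant to flag.
#'
#' @param seed integer seed.
#' @param with_sweep logical; `FALSE` yields the matched sweep-free null
#'   panel.
#' @return a [sim_config()].
#' @export
sweep_benchmark_config <- function(seed, with_sweep = TRUE) {
  sweep <- if (with_sweep)
    list(sweep_spec(pop = "pop1", chrom = "chr1", start = 3.0e6,
                    end = 3.5e6, core_pos = 3.25e6,
                    derived_freq = 0.95, founder_fraction = 0.9))
  else list()
  sim_config(seed = seed, n_pops = 2, samples_per_pop = 25,
             chrom_lengths = c(chr1 = 8e6, chr2 = 8e6),
             n_snps_per_chrom = 4000, fst_target = 0.05,
             sweep_specs = sweep)
}

#' Planted-sweep detection experiment
#'
#' Runs the three scans on one seed of the planted-sweep benchmark and
#' reports whether each flags the sweep interval: at least one window
#' overlapping the interval with `ZHp < zhp_max` in the selected
#' population, at least one with `ZFst > zfst_min` in the selected-vs-
#' control comparison, and at least one top-tail XP-EHH SNP inside the
#' interval. Also reports the fraction of top-tail SNPs within the
#' interval padded by 100 kb, and the standardized XP-EHH elevation
#' inside the interval.
#'
#' @param seed integer seed.
#' @param zhp_max,zfst_min,xpehh_top outlier thresholds.
#' @return list of per-method hit indicators and summary quantities.
#' @export
sweep_detection_experiment <- function(seed, zhp_max = -4, zfst_min = 4,
                                       xpehh_top = 0.01) {
  cfg <- sweep_benchmark_config(seed, with_sweep = TRUE)
  sim <- simulate_panel(cfg)
  sp <- cfg$sweep_specs[[1L]]
  cl <- vapply(split(sim$panel$pos, sim$panel$chrom), max, 0)[
    unique(sim$panel$chrom)] + 1
  windows <- make_windows(cl)
  in_interval <- function(df)
    df$chrom == sp$chrom & df$end > sp$start & df$start < sp$end

  hp <- pooled_heterozygosity(allele_counts(sim$panel, sim$popmap, sp$pop),
                              windows)
  hp_hit <- any(in_interval(hp) & !is.na(hp$z) & hp$z < zhp_max)

  comp <- wc_components(sim$panel, sim$popmap, sp$pop, "pop2")
  fst <- windowed_fst(comp, windows)
  fst_hit <- any(in_interval(fst) & !is.na(fst$z) & fst$z > zfst_min)

  xp <- xpehh(sim$panel, sim$popmap, sp$pop, "pop2")
  tails <- top_fraction(xp, q = xpehh_top, side = "both")
  snp_in <- tails$chrom == sp$chrom & tails$pos >= sp$start &
    tails$pos < sp$end
  snp_near <- tails$chrom == sp$chrom & tails$pos >= sp$start - 1e5 &
    tails$pos < sp$end + 1e5
  inside <- xp$chrom == sp$chrom & xp$pos >= sp$start & xp$pos < sp$end
  elev <- mean(xp$norm[inside], na.rm = TRUE)

  list(hp_hit = hp_hit, fst_hit = fst_hit,
       xpehh_hit = any(snp_in),
       tail_frac_near = if (nrow(tails)) mean(snp_near) else 0,
       xpehh_elevation_sd = elev,
       global_fst = global_fst(comp))
}

#' Null-calibration experiment
#'
#' Runs the ZHp and ZFst scans on a sweep-free benchmark panel and
#' counts windows jointly passing `ZHp < zhp_max` (in either population)
#' and `ZFst > zfst_min`.
#'
#' @param seed integer seed.
#' @param zhp_max,zfst_min outlier thresholds.
#' @return number of jointly passing windows.
#' @export
null_joint_windows <- function(seed, zhp_max = -4, zfst_min = 4) {
  cfg <- sweep_benchmark_config(seed, with_sweep = FALSE)
  sim <- simulate_panel(cfg)
  cl <- vapply(split(sim$panel$pos, sim$panel$chrom), max, 0)[
    unique(sim$panel$chrom)] + 1
  windows <- make_windows(cl)
  hp1 <- pooled_heterozygosity(allele_counts(sim$panel, sim$popmap, "pop1"),
                               windows)
  hp2 <- pooled_heterozygosity(allele_counts(sim$panel, sim$popmap, "pop2"),
                               windows)
  fst <- windowed_fst(wc_components(sim$panel, sim$popmap, "pop1", "pop2"),
                      windows)
  zhp_low <- pmin(ifelse(is.na(hp1$z), Inf, hp1$z),
                  ifelse(is.na(hp2$z), Inf, hp2$z))
  sum(zhp_low < zhp_max & !is.na(fst$z) & fst$z > zfst_min)
}

#' ROH recovery experiment
#'
#' Builds a panel in which one sample is forced heterozygous at every
#' SNP (the heterozygote-rich control), plants a homozygous segment of
#' the requested length, and runs the scanning-window ROH detector with
#' its default (PLINK-style) parameters. Reports recall of the planted
#' segment, the boundary error in units of the local inter-SNP gap, and
#' the number of segments called on the untouched fully heterozygous
#' control sample.
#'
#' @param seed integer seed.
#' @param roh_length planted segment length (bp).
#' @param params a [roh_params()] list.
#' @return list with `recovered`, `boundary_gaps` (max over both ends),
#'   `n_segments`, `control_calls`.
#' @export
roh_recovery_experiment <- function(seed, roh_length = 600000,
                                    params = roh_params()) {
  cfg <- sim_config(seed = seed, n_pops = 1, samples_per_pop = 10,
                    chrom_lengths = c(chr1 = 5e6),
                    n_snps_per_chrom = 2500, fst_target = 0)
  sim <- simulate_panel(cfg)
  sim <- force_heterozygous(sim, "pop1", 1L)   # ROH target sample
  sim <- force_heterozygous(sim, "pop1", 2L)   # untouched control
  start <- 2e6
  spec <- roh_spec("pop1", 1L, "chr1", start, start + roh_length)
  sim <- plant_roh(sim, spec)
  target <- pop_samples(sim$popmap, "pop1")[1L]
  control <- pop_samples(sim$popmap, "pop1")[2L]
  segs <- detect_roh(sim$panel, target, params)
  ctrl <- detect_roh(sim$panel, control, params)
  pos <- sim$panel$pos[sim$panel$chrom == "chr1"]
  inside <- pos >= spec$start & pos < spec$end
  truth_lo <- min(pos[inside]); truth_hi <- max(pos[inside])
  hit <- segs$chrom == "chr1" & segs$end > spec$start & segs$start < spec$end
  boundary_gaps <- NA_real_
  if (any(hit)) {
    s <- segs[hit, ][1L, ]
    gap_at <- function(p) {
      i <- findInterval(p, pos)
      max(diff(pos[max(1L, i - 1L):min(length(pos), i + 1L)]))
    }
    boundary_gaps <- max(abs(s$start - truth_lo) / gap_at(truth_lo),
                         abs((s$end - 1L) - truth_hi) / gap_at(truth_hi))
  }
  list(recovered = any(hit), boundary_gaps = boundary_gaps,
       n_segments = sum(hit), control_calls = nrow(ctrl))
}
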