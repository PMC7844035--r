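#' Simulation configuration
#'
#' Parameters of the Balding-Nichols founder-mosaic simulator. Population
#' allele frequencies at each SNP are drawn around a uniform ancestral
#' frequency from the Balding-Nichols Beta distribution with parameter
#' `fst_target` (the expected genome-wide FST); haplotypes are mosaics of
#' `n_founders` founder haplotypes with a per-bp switch probability, which
#' yields linkage disequilibrium that decays with physical distance.
#'
#' @param seed integer seed; a fixed config (including the seed) reproduces
#'   the panel exactly.
#' @param n_pops number of populations.
#' @param samples_per_pop diploid samples per population.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param n_snps_per_chrom SNPs simulated per chromosome.
#' @param fst_target Balding-Nichols F in `[0, 1)`; 0 means identical
#'   population frequencies.
#' @param mosaic_break_rate per-bp probability of switching founder
#'   haplotype along a sample haplotype.
#' @param n_founders founder haplotypes per population (>= 2).
#' @param resample_rate per-site probability that a copied allele is
#'   replaced by a fresh Bernoulli draw at the population frequency;
#'   controls residual haplotype diversity within founder groups.
#' @param sweep_specs list of [sweep_spec()] planted after simulation.
#' @param roh_specs list of [roh_spec()] planted after simulation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_pops = 3L, samples_per_pop = 15L,
                       chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
                       n_snps_per_chrom = 5000L, fst_target = 0.05,
                       mosaic_break_rate = 1e-5, n_founders = 16L,
                       resample_rate = 0.05,
                       sweep_specs = list(), roh_specs = list()) {
  if (n_pops < 1L || samples_per_pop < 1L || n_snps_per_chrom < 1L)
    stop("dimensions must be positive")
  if (fst_target < 0 || fst_target >= 1)
    stop("fst_target must lie in [0, 1)")
  if (n_founders < 2L) stop("n_founders must be >= 2")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  structure(list(seed = as.integer(seed), n_pops = as.integer(n_pops),
                 samples_per_pop = as.integer(samples_per_pop),
                 chrom_lengths = chrom_lengths,
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 fst_target = fst_target,
                 mosaic_break_rate = mosaic_break_rate,
                 n_founders = as.integer(n_founders),
                 resample_rate = resample_rate,
                 sweep_specs = sweep_specs, roh_specs = roh_specs),
            class = "sim_config")
}

#' Specification of a planted hard sweep
#'
#' @param pop population label carrying the sweep.
#' @param chrom chromosome label.
#' @param start,end sweep interval, 0-based half-open (bp).
#' @param core_pos position of the core SNP (bp); `start <= core_pos < end`.
#' @param derived_freq target alternate-allele frequency inside the
#'   interval, in `(0.5, 1]`.
#' @param founder_fraction fraction of core-carrier haplotypes overwritten
#'   by a single founder haplotype across the interval.
#' @export
sweep_spec <- function(pop, chrom, start, end, core_pos,
                       derived_freq = 0.95, founder_fraction = 0.9) {
  stopifnot(start <= core_pos, core_pos < end,
            derived_freq > 0.5, derived_freq <= 1,
            founder_fraction >= 0, founder_fraction <= 1)
  list(pop = pop, chrom = chrom, start = start, end = end,
       core_pos = core_pos, derived_freq = derived_freq,
       founder_fraction = founder_fraction)
}

#' Specification of a planted homozygous segment
#'
#' @param pop population label.
#' @param sample_index 1-based index of the sample within that population.
#' @param chrom chromosome label.
#' @param start,end interval, 0-based half-open (bp), `end > start`.
#' @export
roh_spec <- function(pop, sample_index, chrom, start, end) {
  stopifnot(end > start, sample_index >= 1)
  list(pop = pop, sample_index = as.integer(sample_index),
       chrom = chrom, start = start, end = end)
}

# exact-count founder allele assignment: at each site, ~ m*p founders carry
# the alternate allele (randomized rounding), so the expected founder-pool
# frequency equals p and per-site sampling noise in the emitted haplotypes
# is binomial (no extra between-population variance beyond Balding-Nichols)
.founder_alleles <- function(m, p) {
  n <- length(p)
  k <- floor(m * p) + (runif(n) < (m * p - floor(m * p)))
  f <- matrix(0L, nrow = m, ncol = n)
  r <- matrix(runif(m * n), nrow = m)
  thr <- vapply(seq_len(n), function(j)
    if (k[j] == 0) -Inf else sort(r[, j], partial = k[j])[k[j]], numeric(1))
  f[r <= rep(thr, each = m)] <- 1L
  f
}

# one mosaic haplotype: founder segments with exponential break spacing
.mosaic_hap <- function(founders, pos, chrom_len, break_rate) {
  m <- nrow(founders)
  nb <- rpois(1L, chrom_len * break_rate)
  bp <- sort(runif(nb, 0, chrom_len))
  fid <- sample.int(m, nb + 1L, replace = TRUE)
  founders[cbind(fid[findInterval(pos, bp) + 1L], seq_along(pos))]
}

#' Simulate a multi-population diploid panel
#'
#' Draws per-SNP ancestral frequencies uniformly on `[0.05, 0.95]`, then
#' per-population frequencies from the Balding-Nichols distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst_target` (`F = 0` keeps the
#' ancestral frequency). Haplotypes are founder mosaics with per-bp switch
#' probability `mosaic_break_rate`, with a per-site resampling step toward
#' the population frequency. Any sweeps or homozygous segments named in the
#' config are planted before returning, so the whole construction is
#' reproducible from the seed alone.
#'
#' @param config a [sim_config()].
#' @return list with elements `panel` (a [genotype_panel()]), `popmap`
#'   (a [population_map()]) and `truth` (planted sweeps/ROH and the
#'   realized Balding-Nichols per-population allele frequencies).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  F <- config$fst_target
  pops <- paste0("pop", seq_len(config$n_pops))
  samples <- unlist(lapply(pops, function(p)
    paste0(p, "_s", seq_len(config$samples_per_pop))))
  popmap <- population_map(samples, rep(pops, each = config$samples_per_pop))

  chroms <- names(config$chrom_lengths)
  all_chrom <- character(0); all_pos <- integer(0)
  geno_blocks <- list(); freq_blocks <- list()
  for (ci in seq_along(chroms)) {
    L <- config$chrom_lengths[ci]
    n <- config$n_snps_per_chrom
    pos <- sort(sample.int(L, n)) - 1L         # 0-based, unique, sorted
    p_anc <- runif(n, 0.05, 0.95)
    pf <- matrix(NA_real_, nrow = n, ncol = config$n_pops,
                 dimnames = list(NULL, pops))
    geno <- matrix(0L, nrow = n, ncol = 2L * length(samples))
    for (k in seq_len(config$n_pops)) {
      pk <- if (F == 0) p_anc else
        rbeta(n, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
      pf[, k] <- pk
      founders <- .founder_alleles(config$n_founders, pk)
      cols <- hap_columns_from(popmap, pops[k], length(samples))
      for (h in cols) {
        a <- .mosaic_hap(founders, pos, L, config$mosaic_break_rate)
        if (config$resample_rate > 0) {
          msk <- runif(n) < config$resample_rate
          if (any(msk)) a[msk] <- rbinom(sum(msk), 1L, pk[msk])
        }
        geno[, h] <- a
      }
    }
    all_chrom <- c(all_chrom, rep(chroms[ci], n))
    all_pos <- c(all_pos, pos)
    geno_blocks[[ci]] <- geno
    freq_blocks[[ci]] <- pf
  }
  geno <- do.call(rbind, geno_blocks)
  panel <- genotype_panel(all_chrom, all_pos,
                          ref = rep("A", length(all_pos)),
                          alt = rep("G", length(all_pos)),
                          geno = geno, samples = samples, phased = TRUE)
  truth <- list(sweeps = list(), roh = list(),
                pop_freq = do.call(rbind, freq_blocks),
                chrom = all_chrom, pos = all_pos)
  out <- list(panel = panel, popmap = popmap, truth = truth)
  for (sp in config$sweep_specs) out <- plant_sweep(out, sp)
  for (rs in config$roh_specs) out <- plant_roh(out, rs)
  out
}

# internal: haplotype columns of a population given a popmap ordered as the
# panel's samples will be
hap_columns_from <- function(popmap, pop, n_total) {
  idx <- which(popmap$pop == pop)
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

#' Plant a hard selective sweep into a simulated panel
#'
#' Raises the alternate-allele frequency at every SNP inside the interval
#' to `derived_freq` in the target population, then overwrites a fraction
#' `founder_fraction` of the haplotypes carrying the alternate core allele
#' with the sweeping founder haplotype (derived at every interval SNP)
#' across the interval -- producing both the depressed heterozygosity and
#' the long shared haplotype that the scans target.
#'
#' @param sim a list with `panel`, `popmap`, `truth` as returned by
#'   [simulate_panel()].
#' @param spec a [sweep_spec()].
#' @return the modified simulation list; `truth$sweeps` gains a record.
#' @export
plant_sweep <- function(sim, spec) {
  panel <- sim$panel
  if (!spec$pop %in% sim$popmap$pop) stop("unknown population: ", spec$pop)
  if (!spec$chrom %in% panel$chrom) stop("unknown chromosome: ", spec$chrom)
  cols <- hap_columns(panel, pop_samples(sim$popmap, spec$pop))
  rows <- which(panel$chrom == spec$chrom &
                panel$pos >= spec$start & panel$pos < spec$end)
  if (length(rows)) {
    nh <- length(cols)
    target <- round(nh * spec$derived_freq)
    for (r in rows) {
      g <- panel$geno[r, cols]
      carriers <- sum(g == 1L)
      if (carriers < target) {
        refs <- which(g != 1L)
        flip <- refs[sample.int(length(refs), target - carriers)]
        g[flip] <- 1L
        panel$geno[r, cols] <- g
      }
    }
    # core SNP: the interval SNP closest to core_pos
    core_row <- rows[which.min(abs(panel$pos[rows] - spec$core_pos))]
    carrier_cols <- cols[panel$geno[core_row, cols] == 1L]
    if (length(carrier_cols) >= 1L && spec$founder_fraction > 0) {
      n_copy <- round(spec$founder_fraction * length(carrier_cols))
      if (n_copy >= 1L) {
        # the sweeping founder haplotype carries the derived allele across
        # the interval, so heavier copying only removes minor alleles
        template <- rep(1L, length(rows))
        take <- carrier_cols[seq_len(n_copy)]
        panel$geno[rows, take] <- matrix(template, nrow = length(rows),
                                         ncol = length(take))
      }
    }
  }
  sim$panel <- panel
  sim$truth$sweeps <- c(sim$truth$sweeps, list(spec))
  sim
}

#' Plant a homozygous segment into one sample
#'
#' Overwrites the sample's second haplotype with its first across the
#' interval, so every SNP inside becomes homozygous.
#'
#' @param sim simulation list (`panel`, `popmap`, `truth`).
#' @param spec a [roh_spec()].
#' @return the modified simulation list; `truth$roh` gains a record even
#'   when the interval covers no SNP.
#' @export
plant_roh <- function(sim, spec) {
  panel <- sim$panel
  s <- pop_samples(sim$popmap, spec$pop)
  if (spec$sample_index > length(s)) stop("sample index out of range")
  sample_id <- s[spec$sample_index]
  i <- match(sample_id, panel$samples)
  rows <- which(panel$chrom == spec$chrom &
                panel$pos >= spec$start & panel$pos < spec$end)
  if (length(rows))
    panel$geno[rows, 2L * i] <- panel$geno[rows, 2L * i - 1L]
  sim$panel <- panel
  sim$truth$roh <- c(sim$truth$roh, list(c(spec, sample = sample_id)))
  sim
}

#' Force a sample to be heterozygous at every variant
#'
#' Control construction for ROH benchmarking: sets the second haplotype to
#' the complement of the first at every SNP, so no homozygous run exists
#' anywhere unless planted afterwards with [plant_roh()].
#'
#' @param sim simulation list.
#' @param pop population label.
#' @param sample_index 1-based index within the population.
#' @return the modified simulation list.
#' @export
force_heterozygous <- function(sim, pop, sample_index) {
  s <- pop_samples(sim$popmap, pop)
  i <- match(s[sample_index], sim$panel$samples)
  a <- sim$panel$geno[, 2L * i - 1L]
  a[a < 0L] <- 0L
  sim$panel$geno[, 2L * i - 1L] <- a
  sim$panel$geno[, 2L * i] <- 1L - a
  sim
}

#' Tile synthetic gene models over chromosomes
#'
#' Lays regularly spaced single-exon genes along each chromosome, giving
#' downstream annotation something to intersect with.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param gene_size gene length (bp).
#' @param spacing distance between gene starts (bp).
#' @return a `gene_models` list (see [read_gene_models()]).
#' @export
tile_genes <- function(chrom_lengths, gene_size = 30000, spacing = 100000) {
  rows <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- as.integer(seq(0, max(0, chrom_lengths[[ch]] - gene_size),
                             by = spacing))
    data.frame(chrom = ch, start = starts,
               end = starts + as.integer(gene_size),
               gene = sprintf("%s_g%03d", ch, seq_along(starts)),
               stringsAsFactors = FALSE)
  }))
  gene_models(rows, exons = rows)
}

#' Write a simulated panel to disk
#'
#' Emits a phased VCF v4.2 (1-based positions, `|`-separated GT), a
#' two-column population map TSV, a BED of synthetic gene models tiled
#' over the chromosomes, and a JSON truth file recording planted sweeps
#' and homozygous segments.
#'
#' @param sim simulation list (`panel`, `popmap`, `truth`).
#' @param outdir output directory (created if absent).
#' @param chrom_lengths chromosome lengths used for gene tiling; defaults
#'   to the maximum position + 1 per chromosome.
#' @return invisibly, a named list of the written file paths.
#' @export
write_panel <- function(sim, outdir, chrom_lengths = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  panel <- sim$panel
  vcf <- file.path(outdir, "panel.vcf")
  write_vcf(panel, vcf)
  pm <- file.path(outdir, "popmap.tsv")
  write.table(sim$popmap, pm, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(panel$pos, panel$chrom, max) + 1
    chrom_lengths <- chrom_lengths[unique(panel$chrom)]
  }
  gm <- tile_genes(chrom_lengths)
  bed <- file.path(outdir, "genes.bed")
  write.table(gm$genes_df[, c("chrom", "start", "end", "gene")], bed,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- file.path(outdir, "truth.json")
  jsonlite::write_json(sim$truth[c("sweeps", "roh")], truth,
                       auto_unbox = TRUE, digits = NA)
  invisible(list(vcf = vcf, popmap = pm, genes = bed, truth = truth))
}

#' Write a genotype panel as a phased VCF
#'
#' @param panel a [genotype_panel()].
#' @param path output file.
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sweepscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$samples), collapse = "\t"), con)
  sep <- if (panel$phased) "|" else "/"
  a <- panel$geno[, seq(1L, ncol(panel$geno), by = 2L), drop = FALSE]
  b <- panel$geno[, seq(2L, ncol(panel$geno), by = 2L), drop = FALSE]
  gt <- matrix(paste0(ifelse(a < 0L, ".", a), sep, ifelse(b < 0L, ".", b)),
               nrow = nrow(a))
  lines <- paste(panel$chrom, panel$pos + 1L, ".", panel$ref, panel$alt,
                 ".", "PASS", ".", "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
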