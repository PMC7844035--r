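test_that("same config reproduces the panel byte for byte", {
  cfg <- sim_config(seed = 42, n_pops = 2, samples_per_pop = 5,
                    chrom_lengths = c(chr1 = 1e6), n_snps_per_chrom = 500)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$panel$geno, s2$panel$geno)
  expect_identical(s1$panel$pos, s2$panel$pos)
  expect_identical(s1$truth$pop_freq, s2$truth$pop_freq)
})

test_that("simulated positions are sorted, unique and in bounds", {
  cfg <- sim_config(seed = 3, chrom_lengths = c(c1 = 2e5, c2 = 1e5),
                    n_snps_per_chrom = 300)
  p <- simulate_panel(cfg)$panel
  for (ch in unique(p$chrom)) {
    pos <- p$pos[p$chrom == ch]
    expect_false(is.unsorted(pos, strictly = TRUE))
    expect_true(all(pos >= 0 & pos < cfg$chrom_lengths[[ch]]))
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(fst_target = 1), "fst_target")
  expect_error(sim_config(n_pops = 0), "positive")
  expect_error(sim_config(n_founders = 1), "n_founders")
})

test_that("realized WC FST tracks the Balding-Nichols target", {
  for (F in c(0, 0.05, 0.15)) {
    cfg <- sim_config(seed = 11, n_pops = 2, samples_per_pop = 25,
                      chrom_lengths = c(chr1 = 6e6, chr2 = 6e6),
                      n_snps_per_chrom = 5000, fst_target = F)
    sim <- simulate_panel(cfg)
    est <- global_fst(wc_components(sim$panel, sim$popmap, "pop1", "pop2"))
    expect_lt(abs(est - F), 0.03)
    if (F == 0) expect_lte(est, 0.01)
  }
})

test_that("mosaic haplotypes show distance-decaying LD", {
  sim <- simulate_panel(sim_config(seed = 5, n_pops = 1,
                                   samples_per_pop = 25,
                                   chrom_lengths = c(chr1 = 5e6),
                                   n_snps_per_chrom = 4000))
  ld <- ld_decay(sim$panel, sim$popmap, "pop1", max_dist = 3e5)
  near <- with(ld, mean_r2[hi <= 1e4])
  far <- with(ld, mean_r2[lo >= 2e5 & hi <= 3e5])
  expect_gt(mean(near, na.rm = TRUE), mean(far, na.rm = TRUE))
})

test_that("planting a complete sweep fixes the interval", {
  sp <- sweep_spec("pop1", "chr1", 2e5, 6e5, core_pos = 4e5,
                   derived_freq = 1, founder_fraction = 1)
  cfg <- sim_config(seed = 9, n_pops = 2, samples_per_pop = 10,
                    chrom_lengths = c(chr1 = 1e6), n_snps_per_chrom = 600,
                    sweep_specs = list(sp))
  sim <- simulate_panel(cfg)
  rows <- sim$panel$pos >= 2e5 & sim$panel$pos < 6e5
  cols <- hap_columns(sim$panel, pop_samples(sim$popmap, "pop1"))
  expect_true(all(sim$panel$geno[rows, cols] == 1L))
  counts <- allele_counts(sim$panel, sim$popmap, "pop1")
  win <- data.frame(chrom = "chr1", start = 2e5, end = 6e5)
  hp <- suppressWarnings(pooled_heterozygosity(counts[rows, ], win, min_snps = 1))
  expect_equal(hp$hp, 0)
  # other population untouched by the sweep
  colsB <- hap_columns(sim$panel, pop_samples(sim$popmap, "pop2"))
  expect_gt(mean(sim$panel$geno[rows, colsB] == 0L), 0)
})

test_that("heavier founder copying never raises sweep-window Hp", {
  hps <- sapply(c(0, 0.3, 0.6, 1), function(ff) {
    sp <- sweep_spec("pop1", "chr1", 2e5, 7e5, core_pos = 45e4,
                     derived_freq = 0.9, founder_fraction = ff)
    cfg <- sim_config(seed = 13, n_pops = 1, samples_per_pop = 15,
                      chrom_lengths = c(chr1 = 1e6),
                      n_snps_per_chrom = 800, sweep_specs = list(sp))
    sim <- simulate_panel(cfg)
    counts <- allele_counts(sim$panel, sim$popmap, "pop1")
    win <- data.frame(chrom = "chr1", start = 2e5, end = 7e5)
    suppressWarnings(pooled_heterozygosity(counts, win, min_snps = 1))$hp
  })
  expect_true(all(diff(hps) <= 1e-12))
})

test_that("plant_roh makes the interval homozygous and records truth", {
  cfg <- sim_config(seed = 2, n_pops = 1, samples_per_pop = 4,
                    chrom_lengths = c(chr1 = 1e6), n_snps_per_chrom = 400)
  sim <- simulate_panel(cfg)
  sim <- plant_roh(sim, roh_spec("pop1", 2L, "chr1", 3e5, 8e5))
  i <- match(pop_samples(sim$popmap, "pop1")[2], sim$panel$samples)
  rows <- sim$panel$pos >= 3e5 & sim$panel$pos < 8e5
  expect_true(all(sim$panel$geno[rows, 2 * i - 1] ==
                    sim$panel$geno[rows, 2 * i]))
  expect_length(sim$truth$roh, 1)
  # interval covering no SNP: panel unchanged, truth still records it
  before <- sim$panel$geno
  gap_lo <- max(sim$panel$pos) + 10
  sim2 <- plant_roh(sim, roh_spec("pop1", 1L, "chr1", gap_lo, gap_lo + 5))
  expect_identical(sim2$panel$geno, before)
  expect_length(sim2$truth$roh, 2)
  expect_error(plant_roh(sim, roh_spec("pop1", 99L, "chr1", 0, 10)),
               "out of range")
})

test_that("write_panel round-trips through read_vcf", {
  cfg <- sim_config(seed = 21, n_pops = 2, samples_per_pop = 3,
                    chrom_lengths = c(chr1 = 2e5, chr2 = 1e5),
                    n_snps_per_chrom = 150)
  sim <- simulate_panel(cfg)
  # inject some missingness to exercise the "." path
  sim$panel$geno[5, 3] <- -1L
  sim$panel$geno[7, 4] <- -1L
  out <- withr::local_tempdir()
  files <- write_panel(sim, out)
  # VCF positions strictly increasing within chromosome
  lines <- readLines(files$vcf)
  body <- strsplit(grep("^[^#]", lines, value = TRUE), "\t")
  chrom <- vapply(body, `[`, "", 1L)
  posn <- as.integer(vapply(body, `[`, "", 2L))
  for (ch in unique(chrom))
    expect_false(is.unsorted(posn[chrom == ch], strictly = TRUE))
  rd <- read_vcf(files$vcf, files$popmap)
  expect_identical(rd$panel$geno, sim$panel$geno)
  expect_identical(rd$panel$pos, sim$panel$pos)
  expect_true(rd$panel$phased)
  # popmap covers every sample exactly once
  expect_setequal(rd$popmap$sample, sim$panel$samples)
  expect_false(anyDuplicated(rd$popmap$sample) > 0)
  # truth JSON readable
  expect_silent(jsonlite::read_json(files$truth))
})
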