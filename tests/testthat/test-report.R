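test_that("select_windows applies each outlier rule", {
  sc <- data.frame(chrom = "chr1", start = c(0, 1, 2, 3) * 1e5,
                   end = c(2, 3, 4, 5) * 1e5, n_snps = 20,
                   z = c(-5, -2, 0, -4.1))
  expect_equal(nrow(select_windows(sc, "zhp")), 2)
  expect_equal(select_windows(sc, "zhp")$z, c(-5, -4.1))
  expect_equal(nrow(select_windows(sc, "zfst")), 0)   # empty set, no error
  scx <- sc; scx$in_tail <- c(TRUE, FALSE, NA, TRUE)
  expect_equal(select_windows(scx, "xpehh")$start, c(0, 3e5))
})

test_that("merge_regions merges book-ended windows and is idempotent", {
  w <- data.frame(chrom = "chr1", start = c(0, 50e3), end = c(100e3, 150e3),
                  z = c(-5, -6))
  m <- merge_regions(w)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 150e3))
  expect_equal(m$peak, -6)
  expect_equal(merge_regions(m)[, c("chrom", "start", "end")],
               m[, c("chrom", "start", "end")])
  # disjoint windows beyond max_gap stay unmerged
  w2 <- data.frame(chrom = "chr1", start = c(0, 200e3),
                   end = c(100e3, 300e3), z = c(1, 2))
  expect_equal(nrow(merge_regions(w2)), 2)
  expect_equal(nrow(merge_regions(w2, max_gap = 100e3)), 1)
  # n identical windows collapse to that window
  w3 <- w[c(1, 1, 1), ]
  m3 <- merge_regions(w3)
  expect_equal(c(m3$start, m3$end), c(0, 100e3))
})

test_that("genes are reported on >= 1 bp half-open overlap", {
  gm <- gene_models(data.frame(chrom = "chr1", start = 100, end = 200,
                               gene = "g1"))
  hit <- genes_in_regions(data.frame(chrom = "chr1", start = 150,
                                     end = 300), gm)
  expect_equal(hit$union, "g1")
  miss <- genes_in_regions(data.frame(chrom = "chr1", start = 200,
                                      end = 300), gm)
  expect_equal(miss$union, character(0))
  gm3 <- tile_genes(c(chr1 = 1e6), gene_size = 30e3, spacing = 100e3)
  got <- genes_in_regions(data.frame(chrom = "chr1", start = 0,
                                     end = 25e4), gm3)
  expect_equal(got$union, c("chr1_g001", "chr1_g002", "chr1_g003"))
})

test_that("overlap_genes is an exact sorted intersection", {
  expect_equal(overlap_genes(list(c("A", "B", "C"), c("B", "C", "D"))),
               c("B", "C"))
  expect_equal(overlap_genes(list(c("A"), character(0))), character(0))
  s <- c("x", "y", "z")
  expect_equal(overlap_genes(list(s, s, s)), s)
  # order-invariant and associative
  sets <- list(c("a", "b", "c"), c("b", "c"), c("c", "b", "a"))
  expect_equal(overlap_genes(sets), overlap_genes(rev(sets)))
  expect_error(overlap_genes(list(s)), "at least 2")
})

test_that("hypergeometric tail matches combinatorics and enumeration", {
  bg <- paste0("g", 1:10)
  terms <- list(t1 = bg[1:5])
  res <- hypergeom_enrich(bg[1:5], terms, bg)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  # k = 0 -> upper tail includes everything
  res0 <- hypergeom_enrich(bg[6:10], terms, bg)
  expect_equal(res0$p, 1)
  # full enumeration oracle over random small instances
  set.seed(21)
  for (i in 1:50) {
    N <- sample(5:30, 1)
    bgN <- paste0("g", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    term <- list(tt = sample(bgN, K))
    study <- sample(bgN, n)
    got <- hypergeom_enrich(study, term, bgN)
    k <- length(intersect(term$tt, study))
    expect_equal(got$p, hyper_tail_oracle(k, K, N, n), tolerance = 1e-12)
  }
  expect_error(hypergeom_enrich(c("zzz"), terms, bg), "absent")
})

test_that("null type-I error of the enrichment flag is controlled", {
  set.seed(77)
  N <- 60; K <- 12; n <- 15
  bg <- paste0("g", seq_len(N))
  term <- list(tm = bg[seq_len(K)])
  hits <- replicate(1000, {
    hypergeom_enrich(sample(bg, n), term, bg)$p <= 0.05
  })
  # discrete test: rejection rate must stay at or below nominal
  # (binomial 3-sigma slack around the exact attainable level)
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("the pipeline runs end to end and is deterministic", {
  cfg <- sim_config(seed = 99, n_pops = 3, samples_per_pop = 6,
                    chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                    n_snps_per_chrom = 700,
                    sweep_specs = list(sweep_spec("pop1", "chr1",
                                                  5e5, 9e5, 7e5)))
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  gene_sets <- list(term_a = paste0("chr1_g", sprintf("%03d", 1:10)),
                    term_b = paste0("chr2_g", sprintf("%03d", 1:5)))
  b1 <- run_pipeline(sim = simulate_panel(cfg), outdir = out1,
                     gene_sets = gene_sets)
  b2 <- run_pipeline(sim = simulate_panel(cfg), outdir = out2,
                     gene_sets = gene_sets)
  expected <- c("diversity.tsv", "hp_pop1.tsv", "fst_pop1_vs_pop2.tsv",
                "xpehh_pop2_vs_pop3.tsv", "roh.tsv", "ld_pop1.tsv",
                "pca.tsv", "nj.nwk", "fst_xpehh_shared_genes.tsv",
                "manifest.json")
  for (f in expected) expect_true(file.exists(file.path(out1, f)))
  # identical seed and config -> byte-identical outputs
  for (f in expected)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  expect_s3_class(b1$tree, "phylo")
  expect_true(all(c("He", "Ho", "MAF", "FIS") %in% names(b1$diversity)))
})
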