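test_that("PC1 separates two internally identical groups", {
  n <- 60
  set.seed(14)
  a <- rbinom(n, 1, 0.5); b <- 1L - a
  H <- cbind(a, a, a, a, b, b, b, b)    # 2 samples per group
  p <- hap_panel(H)
  pc <- pca(p, k = 2)
  g1 <- pc$coords[1:2, 1]; g2 <- pc$coords[3:4, 1]
  expect_lt(max(abs(diff(g1)), abs(diff(g2))), 1e-8)  # zero within-group spread
  expect_gt(abs(mean(g1) - mean(g2)), 0.1)
  # duplicated samples get identical coordinates
  expect_lt(max(abs(pc$coords[1, ] - pc$coords[2, ])), 1e-6)
  # axes orthogonal, variance fractions bounded
  expect_lt(abs(sum(pc$coords[, 1] * pc$coords[, 2])), 1e-8)
  expect_lte(sum(pc$var_frac), 1)
  expect_error(pca(p, k = 4), "smaller")
})

test_that("PCA coordinates are stable under sample reordering", {
  sim <- simulate_panel(sim_config(seed = 25, n_pops = 2,
                                   samples_per_pop = 6,
                                   chrom_lengths = c(chr1 = 1e6),
                                   n_snps_per_chrom = 800))
  p <- sim$panel
  pc1 <- pca(p, k = 2)
  perm <- c(7:12, 1:6)
  cols <- as.vector(rbind(2L * perm - 1L, 2L * perm))
  p2 <- genotype_panel(p$chrom, p$pos, p$ref, p$alt,
                       p$geno[, cols], p$samples[perm], p$phased)
  pc2 <- pca(p2, k = 2)
  for (j in 1:2) {
    x <- pc1$coords[p$samples, j]; y <- pc2$coords[p$samples, j]
    expect_lt(min(max(abs(x - y)), max(abs(x + y))), 1e-6)
  }
})

test_that("PCA separates simulated populations", {
  sim <- simulate_panel(sim_config(seed = 19, n_pops = 3,
                                   samples_per_pop = 20,
                                   chrom_lengths = c(chr1 = 3e6),
                                   n_snps_per_chrom = 3000,
                                   fst_target = 0.15))
  pc <- pca(sim$panel, k = 4)
  km <- kmeans(pc$coords[, 1:2], centers = 3, nstart = 20)
  tab <- table(km$cluster, sim$popmap$pop)
  agreement <- sum(apply(tab, 2, max)) / sum(tab)
  expect_gte(agreement, 0.95)
})

test_that("p-distance follows the 0 / 0.5 / 1 per-site convention", {
  p <- toy_panel(cbind(c("0|0", "0|0", "0|1"),
                       c("0|0", "1|1", "0|0")))
  d <- p_distance_matrix(p)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))
  expect_equal(d["s1", "s2"], mean(c(0, 1, 0.5)))
  expect_equal(d, t(d))
  # identical samples -> 0; opposite homozygotes everywhere -> 1
  p2 <- toy_panel(cbind(c("0|0", "1|1"), c("0|0", "1|1"), c("1|1", "0|0")))
  d2 <- p_distance_matrix(p2)
  expect_equal(d2["s1", "s2"], 0)
  expect_equal(d2["s1", "s3"], 1)
  # a pair with no co-called site errors by default
  p3 <- toy_panel(cbind(c("0|0", "./."), c("./.", "1|1")))
  expect_error(p_distance_matrix(p3), "co-called")
  expect_true(is.na(p_distance_matrix(p3, on_empty = "na")[1, 2]))
})

test_that("NJ solves the additive 4-taxon case exactly", {
  # tree ((A,B),(C,D)) with pendant branches 1,2,3,4 and internal edge 1
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(dm)
  expect_s3_class(tr, "phylo")
  # topology: A+B form a cherry
  pairs <- ape::cophenetic.phylo(tr)
  expect_equal(pairs[LETTERS[1:4], LETTERS[1:4]], dm)
  ab_mrca <- ape::getMRCA(tr, c("A", "B"))
  cd_mrca <- ape::getMRCA(tr, c("C", "D"))
  expect_false(ab_mrca == cd_mrca)
  # taxon order does not change the unrooted topology
  o <- c(3, 1, 4, 2)
  tr2 <- nj_tree(dm[o, o])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, 1, 1, 0), 2, 2)), "3 taxa")
  asym <- dm; asym[1, 2] <- 99
  expect_error(nj_tree(asym), "symmetric")
})

test_that("NJ recovers random additive topologies", {
  set.seed(33)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    tr0 <- ape::rtree(n)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.5, 2)
    dm <- ape::cophenetic.phylo(tr0)
    tr <- nj_tree(dm[sort(rownames(dm)), sort(rownames(dm))])
    expect_equal(ape::dist.topo(ape::unroot(tr0), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("negative NJ branch lengths are clamped, paths preserved", {
  set.seed(44)
  # noisy distances commonly induce negative NJ branches
  for (i in 1:10) {
    n <- 6
    M <- matrix(runif(n * n, 0.2, 1), n, n)
    dm <- (M + t(M)) / 2; diag(dm) <- 0
    rownames(dm) <- colnames(dm) <- paste0("t", 1:n)
    tr <- nj_tree(dm)
    expect_true(all(tr$edge.length >= 0))
  }
})
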