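vcf_header <- c(
  "##fileformat=VCFv4.2",
  '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2")

write_toy_vcf <- function(records) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(vcf_header, records), path)
  path
}

test_that("read_vcf parses genotypes, missing calls and skips indels", {
  path <- write_toy_vcf(c(
    "chr1\t101\t.\tA\tG\t50\tPASS\t.\tGT\t0|0\t0|1",
    "chr1\t201\t.\tC\tT\t50\tPASS\t.\tGT\t1|1\t./.",
    "chr1\t301\t.\tG\tGA\t50\tPASS\t.\tGT\t0|0\t0|0",   # indel
    "chr1\t401\t.\tT\tA\t50\tPASS\t.\tGT\t0|1\t1|1"))
  expect_message(rd <- read_vcf(path), "1 non-biallelic-SNP")
  expect_equal(rd$skipped, 1)
  expect_equal(n_variants(rd$panel), 3)
  expect_equal(rd$panel$pos, c(100L, 200L, 400L))  # 0-based internally
  expect_equal(rd$panel$geno[1, ], c(0L, 0L, 0L, 1L))
  expect_equal(rd$panel$geno[2, ], c(1L, 1L, -1L, -1L))
})

test_that("read_vcf enforces popmap coverage", {
  path <- write_toy_vcf("chr1\t101\t.\tA\tG\t50\tPASS\t.\tGT\t0|0\t0|1")
  pm <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\tpopA", pm)
  expect_error(read_vcf(path, pm), "absent from popmap")
})

test_that("hard_filter removes records per criterion and tallies them", {
  rec <- data.frame(
    QUAL = c(50, 50, 100, 20, 50),
    QD = c(12, 5, NA, 15, 12),
    FS = c(2, 2, NA, 2, 30),
    DP = c(10, 10, NA, 10, 2),
    ReadPosRankSum = c(0, 0, NA, 0, -9))
  res <- hard_filter(rec)
  # row 1 passes; row 2 fails QD; row 3 has only QUAL (passes);
  # row 4 fails QUAL; row 5 fails FS, DP and ReadPosRankSum
  expect_equal(nrow(res$kept), 2)
  expect_equal(res$removed, 3)
  expect_equal(unname(res$tally[c("QD", "QUAL", "FS", "DP",
                                  "ReadPosRankSum")]),
               c(1, 1, 1, 1, 1))
})

test_that("loosening any threshold never removes more records", {
  set.seed(1)
  rec <- data.frame(QUAL = runif(200, 0, 60), QD = runif(200, 0, 20),
                    FS = runif(200, 0, 20), DP = sample(1:10, 200, TRUE),
                    ReadPosRankSum = runif(200, -12, 2))
  base <- hard_filter(rec)$removed
  looser <- list(filter_thresholds(qd_min = 5),
                 filter_thresholds(fs_max = 20),
                 filter_thresholds(qual_min = 10),
                 filter_thresholds(dp_min = 2),
                 filter_thresholds(readpos_ranksum_min = -20))
  for (th in looser)
    expect_lte(hard_filter(rec, th)$removed, base)
})

test_that("site_filter applies call-rate and MAF rules", {
  # 10 sites x 10 samples; 3 sites pushed below MAF 0.01 (monomorphic),
  # one site fully missing
  set.seed(2)
  H <- matrix(rbinom(200, 1, 0.4), nrow = 10)
  H[1:3, ] <- 0L
  H[4, ] <- -1L
  p <- hap_panel(H)
  kept <- site_filter(p, min_call_rate = 0.9, min_maf = 0.01)
  expect_equal(n_variants(kept), 6)
  # maf = 0 keeps monomorphic sites, still drops the all-missing one
  kept2 <- site_filter(p, min_call_rate = 0.5, min_maf = 0)
  expect_equal(n_variants(kept2), 9)
})

test_that("variants classify as exonic, intronic or intergenic", {
  genes <- data.frame(chrom = "chr1", start = 100, end = 400, gene = "g1")
  exons <- data.frame(chrom = "chr1",
                      start = c(100, 300), end = c(200, 400),
                      gene = "g1")
  gm <- gene_models(genes, exons)
  H <- matrix(0L, nrow = 5, ncol = 4)
  H[, 1] <- 1L
  p <- hap_panel(H, pos = c(50L, 150L, 250L, 350L, 450L))
  cls <- classify_variants(p, gm)
  expect_equal(as.character(cls),
               c("intergenic", "exonic", "intronic", "exonic", "intergenic"))
  # half-open: position `end` itself is outside
  p2 <- hap_panel(H[1:2, , drop = FALSE], pos = c(99L, 400L))
  expect_equal(as.character(classify_variants(p2, gm)),
               c("intergenic", "intergenic"))
  # categories always partition the variant set
  expect_equal(sum(table(cls)), n_variants(p))
})

test_that("annotation summary reproduces report arithmetic", {
  s <- summarize_annotation(
    c(exonic = 214098, other = 30163679 - 214098),
    c(nonsynonymous = 62154, synonymous = 81504))
  expect_equal(round(s$category_pct[["exonic"]], 2), 0.71)
  expect_equal(round(s$effect_pct[["nonsynonymous"]], 2), 29.03)
  expect_equal(round(s$effect_pct[["synonymous"]], 2), 38.07)
  expect_equal(s$ns_s_ratio, 0.762, tolerance = 1e-3)
  # zero synonymous count: undefined marker, no crash
  s0 <- summarize_annotation(c(exonic = 10, other = 0),
                             c(nonsynonymous = 3, synonymous = 0))
  expect_true(is.na(s0$ns_s_ratio))
  expect_error(summarize_annotation(c(exonic = -1)), "non-negative")
})

test_that("strict mode removes records with missing annotations", {
  rec <- data.frame(QUAL = c(50, 50), QD = c(12, NA))
  expect_equal(hard_filter(rec)$removed, 0)
  strict <- hard_filter(rec, strict = TRUE)
  expect_equal(strict$removed, 1)
  expect_equal(unname(strict$tally[["QD"]]), 1)
})

test_that("GFF3 gene models convert to half-open coordinates", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=gene1;Name=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=exon1;Parent=gene1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tID=exon2;Parent=gene1"), gff)
  gm <- read_gene_models(gff)
  expect_equal(gm$genes_df$start, 100)  # 1-based inclusive -> 0-based
  expect_equal(gm$genes_df$end, 400)
  expect_equal(nrow(gm$exons_df), 2)
  H <- matrix(0L, nrow = 3, ncol = 4); H[, 1] <- 1L
  p <- hap_panel(H, pos = c(150L, 250L, 450L))
  expect_equal(as.character(classify_variants(p, gm)),
               c("exonic", "intronic", "intergenic"))
})
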