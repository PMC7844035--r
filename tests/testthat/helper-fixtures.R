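# Build a toy panel from per-sample genotype strings like "0|1".
# `gt` is a character matrix (variants x samples); "." marks missing.
toy_panel <- function(gt, chrom = rep("chr1", nrow(gt)),
                      pos = seq(0L, by = 1000L, length.out = nrow(gt)),
                      samples = paste0("s", seq_len(ncol(gt))),
                      phased = TRUE) {
  gt <- as.matrix(gt)
  code <- function(x) {
    out <- suppressWarnings(as.integer(x))
    out[x == "."] <- -1L
    out
  }
  geno <- matrix(-1L, nrow = nrow(gt), ncol = 2L * ncol(gt))
  for (j in seq_len(ncol(gt))) {
    geno[, 2L * j - 1L] <- code(substr(gt[, j], 1L, 1L))
    geno[, 2L * j] <- code(substr(gt[, j], 3L, 3L))
  }
  genotype_panel(chrom, pos, rep("A", nrow(gt)), rep("G", nrow(gt)),
                 geno, samples, phased)
}

# Build a panel directly from a haplotype matrix (variants x haplotypes).
hap_panel <- function(H, pos = seq(0L, by = 1000L, length.out = nrow(H)),
                      chrom = rep("chr1", nrow(H))) {
  ns <- ncol(H) / 2L
  genotype_panel(chrom, pos, rep("A", nrow(H)), rep("G", nrow(H)),
                 H, paste0("s", seq_len(ns)), phased = TRUE)
}

two_pop_map <- function(n1, n2) {
  population_map(c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2))),
                 rep(c("A", "B"), c(n1, n2)))
}
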