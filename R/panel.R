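#' @useDynLib sweepscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbeta rbinom rpois runif sd kmeans phyper p.adjust setNames
#' @importFrom utils read.table write.table head combn
NULL

#' Construct a genotype panel
#'
#' A `genotype_panel` holds phased biallelic SNP genotypes as an integer
#' matrix of variants x haplotypes (two consecutive columns per sample),
#' with allele codes 0 = reference, 1 = alternate, -1 = missing. Positions
#' are 0-based internally; conversion to the 1-based VCF convention happens
#' only at I/O.
#'
#' @param chrom character vector, chromosome label per variant.
#' @param pos integer vector, 0-based position per variant; must be sorted
#'   and unique within each chromosome.
#' @param ref,alt single-base allele per variant.
#' @param geno integer matrix `length(pos)` x `2 * length(samples)`; columns
#'   `2*i - 1` and `2*i` are the two haplotypes of sample `i`.
#' @param samples character vector of sample identifiers.
#' @param phased logical; `TRUE` when every genotype carries phase.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(chrom, pos, ref, alt, geno, samples, phased = TRUE) {
  stopifnot(is.matrix(geno), nrow(geno) == length(pos),
            ncol(geno) == 2L * length(samples),
            length(chrom) == length(pos))
  if (!all(geno %in% c(-1L, 0L, 1L)))
    stop("allele codes must be in {-1, 0, 1}")
  ord_ok <- all(tapply(pos, chrom, function(p) !is.unsorted(p, strictly = TRUE)))
  if (!isTRUE(ord_ok))
    stop("positions must be sorted and unique within each chromosome")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 geno = geno, samples = as.character(samples),
                 phased = isTRUE(phased)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d variants x %d samples (%s), %d chromosome(s)\n",
              n_variants(x), n_samples(x),
              if (x$phased) "phased" else "unphased",
              length(unique(x$chrom))))
  invisible(x)
}

#' Number of variants in a panel
#' @param panel a `genotype_panel`.
#' @export
n_variants <- function(panel) length(panel$pos)

#' Number of samples in a panel
#' @param panel a `genotype_panel`.
#' @export
n_samples <- function(panel) length(panel$samples)

#' Haplotype column indices for given samples
#' @param panel a `genotype_panel`.
#' @param samples character vector of sample ids (default: all).
#' @return integer vector of column indices into `panel$geno`.
#' @export
hap_columns <- function(panel, samples = panel$samples) {
  idx <- match(samples, panel$samples)
  if (anyNA(idx)) stop("unknown sample(s): ", paste(samples[is.na(idx)], collapse = ", "))
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

#' Subset a panel by variant index
#' @param panel a `genotype_panel`.
#' @param i integer or logical index over variants.
#' @export
subset_variants <- function(panel, i) {
  genotype_panel(panel$chrom[i], panel$pos[i], panel$ref[i], panel$alt[i],
                 panel$geno[i, , drop = FALSE], panel$samples, panel$phased)
}

#' Per-sample diploid genotype codes
#'
#' Collapses the two haplotype columns of each sample into one code per
#' variant: 0/1/2 alternate-allele dosage, `NA` when either allele is missing.
#'
#' @param panel a `genotype_panel`.
#' @param samples samples to include (default all).
#' @return integer matrix variants x samples with values 0, 1, 2 or `NA`.
#' @export
dosage_matrix <- function(panel, samples = panel$samples) {
  idx <- match(samples, panel$samples)
  a <- panel$geno[, 2L * idx - 1L, drop = FALSE]
  b <- panel$geno[, 2L * idx, drop = FALSE]
  d <- a + b
  d[a < 0L | b < 0L] <- NA_integer_
  colnames(d) <- samples
  d
}

#' Construct a population map
#'
#' @param sample character vector of sample ids.
#' @param pop character vector of population labels, one per sample.
#' @return data.frame with columns `sample` and `pop`.
#' @export
population_map <- function(sample, pop) {
  stopifnot(length(sample) == length(pop), !anyDuplicated(sample))
  data.frame(sample = as.character(sample), pop = as.character(pop),
             stringsAsFactors = FALSE)
}

#' Samples belonging to one population
#' @param popmap a population map (see [population_map()]).
#' @param pop population label.
#' @export
pop_samples <- function(popmap, pop) {
  s <- popmap$sample[popmap$pop == pop]
  if (length(s) == 0L) stop("unknown population: ", pop)
  s
}

# internal: haplotype matrix (variants x haplotypes) for one population,
# restricted to one chromosome when `chrom` is given
.hap_matrix <- function(panel, popmap, pop, chrom = NULL) {
  cols <- hap_columns(panel, pop_samples(popmap, pop))
  rows <- if (is.null(chrom)) seq_len(n_variants(panel)) else which(panel$chrom == chrom)
  panel$geno[rows, cols, drop = FALSE]
}
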