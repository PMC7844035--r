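#' Read a phased VCF and population map into a genotype panel
#'
#' Loads biallelic SNP records only; multiallelic sites and indels are
#' skipped with a reported count. Missing alleles (`.`) become code -1.
#' The panel is flagged phased only when every genotype separator is `|`.
#'
#' @param path VCF file (v4.2; plain text or gzipped).
#' @param popmap_path optional two-column TSV (sample, population) without
#'   header; must cover every VCF sample.
#' @return list with `panel` (a [genotype_panel()]), `popmap` (or `NULL`),
#'   and `skipped` (count of non-biallelic-SNP records dropped).
#' @export
read_vcf <- function(path, popmap_path = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))                    # single-record VCF
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("no variant records in ", path)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!keep)
  if (skipped > 0L)
    message(skipped, " non-biallelic-SNP record(s) skipped")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt)
  a1 <- substr(gt, 1L, 1L); sep <- substr(gt, 2L, 2L); a2 <- substr(gt, 3L, 3L)
  phased <- all(sep == "|", na.rm = TRUE) && !anyNA(gt)
  code <- function(x) {
    out <- rep(-1L, length(x))
    out[x == "0"] <- 0L
    out[x == "1"] <- 1L
    out
  }
  n <- sum(keep)
  geno <- matrix(-1L, nrow = n, ncol = 2L * length(samples))
  geno[, seq(1L, ncol(geno), 2L)] <- code(a1)
  geno[, seq(2L, ncol(geno), 2L)] <- code(a2)
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"]) - 1L
  o <- order(match(chrom, unique(chrom)), pos)
  panel <- genotype_panel(chrom[o], pos[o], ref[keep][o], alt[keep][o],
                          geno[o, , drop = FALSE], samples, phased)
  popmap <- NULL
  if (!is.null(popmap_path)) {
    tab <- read.table(popmap_path, sep = "\t", header = FALSE,
                      col.names = c("sample", "pop"),
                      colClasses = "character")
    miss <- setdiff(samples, tab$sample)
    if (length(miss))
      stop("samples absent from popmap: ", paste(miss, collapse = ", "))
    popmap <- population_map(tab$sample, tab$pop)
    popmap <- popmap[popmap$sample %in% samples, , drop = FALSE]
  }
  list(panel = panel, popmap = popmap, skipped = skipped)
}

#' Hard-filter thresholds for variant records
#'
#' GATK-style site filters: a record is excluded when any *present* field
#' falls in the rejection region `QD < qd_min`, `ReadPosRankSum <
#' readpos_ranksum_min`, `FS > fs_max`, `QUAL < qual_min` or `DP < dp_min`.
#'
#' @param qd_min,fs_max,qual_min,dp_min,readpos_ranksum_min numeric cutoffs.
#' @export
filter_thresholds <- function(qd_min = 10.0, fs_max = 10, qual_min = 30,
                              dp_min = 4, readpos_ranksum_min = -8.0) {
  list(qd_min = qd_min, fs_max = fs_max, qual_min = qual_min,
       dp_min = dp_min, readpos_ranksum_min = readpos_ranksum_min)
}

#' Apply hard filters to variant records
#'
#' @param records data.frame with any of the numeric columns `QUAL`, `QD`,
#'   `FS`, `DP`, `ReadPosRankSum`; `NA` or absent fields never trigger
#'   removal unless `strict = TRUE` (then `NA` in a present column counts
#'   as failing).
#' @param thresholds a [filter_thresholds()] list.
#' @param strict logical; remove records whose fields are missing.
#' @return list with `kept` (the surviving rows), `removed` (count) and
#'   `tally` (named removal counts per criterion; a record failing several
#'   criteria is tallied under each).
#' @export
hard_filter <- function(records, thresholds = filter_thresholds(),
                        strict = FALSE) {
  get <- function(col) {
    if (col %in% names(records)) as.numeric(records[[col]])
    else rep(NA_real_, nrow(records))
  }
  viol <- function(x, bad) {
    v <- bad(x)
    v[is.na(v)] <- strict & !all(is.na(x))
    v
  }
  fails <- cbind(
    QD = viol(get("QD"), function(x) x < thresholds$qd_min),
    ReadPosRankSum = viol(get("ReadPosRankSum"),
                          function(x) x < thresholds$readpos_ranksum_min),
    FS = viol(get("FS"), function(x) x > thresholds$fs_max),
    QUAL = viol(get("QUAL"), function(x) x < thresholds$qual_min),
    DP = viol(get("DP"), function(x) x < thresholds$dp_min))
  drop <- rowSums(fails) > 0L
  list(kept = records[!drop, , drop = FALSE],
       removed = sum(drop),
       tally = colSums(fails))
}

#' Site-level call-rate and frequency filter
#'
#' @param panel a [genotype_panel()].
#' @param min_call_rate minimum fraction of non-missing alleles per site.
#' @param min_maf minimum pooled minor-allele frequency.
#' @return the filtered panel.
#' @export
site_filter <- function(panel, min_call_rate = 0.9, min_maf = 0.01) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, min_maf >= 0, min_maf <= 1)
  g <- panel$geno
  called <- rowSums(g >= 0L)
  total <- ncol(g)
  alt <- rowSums(g == 1L)
  p <- ifelse(called > 0L, alt / called, NA_real_)
  maf <- pmin(p, 1 - p)
  keep <- (called / total) >= min_call_rate & !is.na(maf) & maf >= min_maf
  subset_variants(panel, keep)
}

#' Gene models container
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `gene`
#'   (0-based half-open coordinates).
#' @param exons data.frame in the same layout; defaults to the gene bodies
#'   (single-exon genes).
#' @return list of class `gene_models` with `GRanges` members `genes` and
#'   `exons`.
#' @export
gene_models <- function(genes, exons = genes) {
  as_gr <- function(df) {
    gr <- GenomicRanges::GRanges(df$chrom,
            IRanges::IRanges(start = df$start + 1L, end = df$end))
    names(gr) <- df$gene
    gr
  }
  structure(list(genes = as_gr(genes), exons = as_gr(exons),
                 genes_df = genes, exons_df = exons),
            class = "gene_models")
}

#' Read gene models from BED or GFF3
#'
#' BED is 0-based half-open (columns chrom, start, end, name) and yields
#' single-exon genes; GFF3 (1-based inclusive, converted on read) uses
#' `gene` and `exon` features, with exons assigned to genes by containment.
#'
#' @param path input file.
#' @param format `"bed"` or `"gff"` (guessed from the extension by default).
#' @return a [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff" else "bed"
  if (format == "bed") {
    df <- read.table(path, sep = "\t", header = FALSE,
                     colClasses = c("character", "numeric", "numeric",
                                    "character"))[, 1:4]
    names(df) <- c("chrom", "start", "end", "gene")
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    return(gene_models(df))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  to_df <- function(x, nm) data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L, end = GenomicRanges::end(x),
    gene = nm, stringsAsFactors = FALSE)
  g <- gr[gr$type == "gene"]
  gname <- if (!is.null(g$Name)) as.character(g$Name) else as.character(g$ID)
  e <- gr[gr$type == "exon"]
  genes_df <- to_df(g, gname)
  if (length(e)) {
    hit <- GenomicRanges::findOverlaps(e, g, type = "within", select = "first")
    exons_df <- to_df(e[!is.na(hit)], gname[hit[!is.na(hit)]])
  } else exons_df <- genes_df
  gene_models(genes_df, exons_df)
}

#' Classify variants against gene models
#'
#' A variant inside any exon is `exonic`; inside a gene body but no exon,
#' `intronic`; otherwise `intergenic`. Overlapping or unsorted exons are
#' handled by union semantics; intervals are half-open.
#'
#' @param panel a [genotype_panel()].
#' @param models a [gene_models()] object.
#' @return factor of length `n_variants(panel)` with levels
#'   `exonic`, `intronic`, `intergenic`.
#' @export
classify_variants <- function(panel, models) {
  vr <- GenomicRanges::GRanges(panel$chrom,
          IRanges::IRanges(start = panel$pos + 1L, width = 1L))
  in_exon <- GenomicRanges::countOverlaps(vr, models$exons) > 0L
  in_gene <- GenomicRanges::countOverlaps(vr, models$genes) > 0L
  out <- ifelse(in_exon, "exonic", ifelse(in_gene, "intronic", "intergenic"))
  factor(out, levels = c("exonic", "intronic", "intergenic"))
}

#' Annotation summary arithmetic
#'
#' Turns category counts (against the total variant count) and exonic
#' effect counts (against the exonic count) into the proportions and the
#' non-synonymous/synonymous ratio that annotation reports quote.
#'
#' @param category_counts named non-negative integer vector; must include
#'   `exonic` when effect counts are supplied.
#' @param effect_counts optional named vector with `nonsynonymous` and
#'   `synonymous`.
#' @return object of class `annotation_summary` with `counts`, `total`,
#'   `category_pct`, `effect_pct` (relative to the exonic count) and
#'   `ns_s_ratio` (`NA` when the synonymous count is zero).
#' @export
summarize_annotation <- function(category_counts, effect_counts = NULL) {
  if (any(category_counts < 0) || (!is.null(effect_counts) && any(effect_counts < 0)))
    stop("counts must be non-negative")
  total <- sum(category_counts)
  category_pct <- 100 * category_counts / total
  effect_pct <- NULL; ratio <- NA_real_
  if (!is.null(effect_counts)) {
    exonic <- category_counts[["exonic"]]
    effect_pct <- 100 * effect_counts / exonic
    syn <- effect_counts[["synonymous"]]
    ratio <- if (syn > 0) effect_counts[["nonsynonymous"]] / syn else NA_real_
  }
  structure(list(counts = category_counts, total = total,
                 category_pct = category_pct,
                 effect_counts = effect_counts, effect_pct = effect_pct,
                 ns_s_ratio = ratio),
            class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat("annotation summary over", format(x$total, big.mark = ","), "variants\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-12s %12s  (%.2f%%)\n", nm,
                format(x$counts[[nm]], big.mark = ","), x$category_pct[[nm]]))
  if (!is.null(x$effect_counts)) {
    for (nm in names(x$effect_counts))
      cat(sprintf("  %-12s %12s  (%.2f%% of exonic)\n", nm,
                  format(x$effect_counts[[nm]], big.mark = ","),
                  x$effect_pct[[nm]]))
    cat(sprintf("  non-synonymous/synonymous ratio: %.3f\n", x$ns_s_ratio))
  }
  invisible(x)
}
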