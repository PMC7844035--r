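#' Select significant windows under a scan rule
#'
#' Rules mirror the operative outlier criteria of selection scans:
#' `"zhp"` keeps windows with `z < cutoff` (default -4, depressed pooled
#' heterozygosity), `"zfst"` keeps `z > cutoff` (default 4), and
#' `"xpehh"` keeps windows flagged `in_tail` by [xpehh_windows()].
#'
#' @param scores window data.frame; needs a `z` column for `zhp`/`zfst`,
#'   an `in_tail` column for `xpehh`.
#' @param rule one of `"zhp"`, `"zfst"`, `"xpehh"`.
#' @param cutoff threshold for the Z rules.
#' @return the selected rows, sorted by genome position.
#' @export
select_windows <- function(scores, rule = c("zhp", "zfst", "xpehh"),
                           cutoff = NULL) {
  rule <- match.arg(rule)
  sel <- switch(rule,
    zhp = !is.na(scores$z) & scores$z < (if (is.null(cutoff)) -4 else cutoff),
    zfst = !is.na(scores$z) & scores$z > (if (is.null(cutoff)) 4 else cutoff),
    xpehh = !is.na(scores$in_tail) & scores$in_tail)
  out <- scores[which(sel), , drop = FALSE]
  out[order(match(out$chrom, unique(scores$chrom)), out$start), ,
      drop = FALSE]
}

#' Merge significant windows into candidate regions
#'
#' Overlapping or book-ended windows (gap at most `max_gap` bp) merge
#' into maximal regions; the peak score of a region is the member window
#' Z (or peak score) of largest magnitude, sign retained. Idempotent.
#'
#' @param windows data.frame with `chrom`, `start`, `end` and optionally
#'   `z` or `peak_norm`.
#' @param max_gap merge gap (bp), default 0 (book-ended windows merge).
#' @return data.frame `chrom`, `start`, `end`, `n_windows`, `peak`.
#' @export
merge_regions <- function(windows, max_gap = 0) {
  if (nrow(windows) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      peak = numeric(0)))
  gr <- GenomicRanges::GRanges(windows$chrom,
          IRanges::IRanges(start = windows$start + 1L, end = windows$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  hits <- GenomicRanges::findOverlaps(gr, red, maxgap = max_gap)
  score <- if ("z" %in% names(windows)) windows$z
           else if ("peak_norm" %in% names(windows)) windows$peak_norm
           else rep(NA_real_, nrow(windows))
  peak <- vapply(seq_along(red), function(i) {
    zs <- score[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]]
    zs <- zs[!is.na(zs)]
    if (!length(zs)) NA_real_ else zs[which.max(abs(zs))]
  }, numeric(1))
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             n_windows = S4Vectors::countSubjectHits(hits),
             peak = peak, stringsAsFactors = FALSE)
}

#' Genes overlapping candidate regions
#'
#' A gene is reported for a region when their half-open intervals overlap
#' by at least one bp.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param models a [gene_models()] object.
#' @return list with `per_region` (list of gene-name vectors, one per
#'   region row) and `union` (sorted unique gene names).
#' @export
genes_in_regions <- function(regions, models) {
  if (nrow(regions) == 0L)
    return(list(per_region = list(), union = character(0)))
  rr <- GenomicRanges::GRanges(regions$chrom,
          IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  hits <- GenomicRanges::findOverlaps(models$genes, rr)
  per <- lapply(seq_along(rr), function(i)
    sort(unique(names(models$genes)[S4Vectors::queryHits(hits)[
      S4Vectors::subjectHits(hits) == i]])))
  list(per_region = per, union = sort(unique(unlist(per))))
}

#' Intersection of gene sets
#'
#' @param sets list of two or more character vectors.
#' @return sorted character vector of genes present in every set.
#' @export
overlap_genes <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 gene sets")
  sort(Reduce(intersect, sets))
}

#' Hypergeometric gene-set over-representation test
#'
#' For each term, the upper-tail probability `P(X >= k)` of drawing `k`
#' term genes in a study set of size `n` from a background of `N` genes
#' containing `K` term genes. Terms with `p <= alpha` are flagged;
#' Benjamini-Hochberg adjusted p-values are reported alongside.
#'
#' @param study_genes character vector, must be a subset of `background`.
#' @param term_to_genes named list mapping term ids to gene vectors.
#' @param background character vector of background genes.
#' @param alpha significance flag threshold on the raw p-value.
#' @return data.frame `term`, `K`, `k`, `n`, `N`, `p`, `p_adj`,
#'   `significant`, sorted by p.
#' @export
hypergeom_enrich <- function(study_genes, term_to_genes, background,
                             alpha = 0.05) {
  study_genes <- unique(study_genes)
  background <- unique(background)
  stray <- setdiff(study_genes, background)
  if (length(stray))
    stop("study genes absent from background: ",
         paste(stray, collapse = ", "))
  N <- length(background); n <- length(study_genes)
  rows <- lapply(names(term_to_genes), function(tm) {
    term_bg <- intersect(unique(term_to_genes[[tm]]), background)
    K <- length(term_bg)
    k <- length(intersect(term_bg, study_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, K = K, k = k, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p <= alpha
  out[order(out$p), , drop = FALSE]
}

#' Run the full selection-signature pipeline
#'
#' Simulates (or loads) a panel, then executes: site filtering,
#' per-population diversity, Hp/ZHp scans per population, pairwise
#' windowed FST, pairwise XP-EHH, ROH per sample, LD decay per
#' population, PCA and a neighbor-joining tree, candidate-region
#' extraction per method, gene overlap across methods, and optional
#' gene-set enrichment. All outputs are written to `outdir` as TSV /
#' BED / newick / JSON, together with a manifest recording every
#' parameter.
#'
#' @param sim simulation list from [simulate_panel()], or `NULL` to load
#'   from files.
#' @param vcf,popmap_path,gene_models_path input files used when
#'   `sim = NULL`.
#' @param outdir output directory.
#' @param window,step scan window geometry (bp).
#' @param min_snps minimum SNPs per scored window.
#' @param zhp_max,zfst_min,xpehh_top outlier thresholds.
#' @param roh a [roh_params()] list.
#' @param ld_max_dist,ld_bin_size LD-decay controls (bp).
#' @param gene_sets optional named list (term -> genes) for enrichment.
#' @param min_call_rate,min_maf site-filter thresholds.
#' @return invisibly, a list bundle with every computed table.
#' @export
run_pipeline <- function(sim = NULL, vcf = NULL, popmap_path = NULL,
                         gene_models_path = NULL, outdir,
                         window = 100000, step = 50000, min_snps = 10,
                         zhp_max = -4, zfst_min = 4, xpehh_top = 0.01,
                         roh = roh_params(), ld_max_dist = 300000,
                         ld_bin_size = 5000, gene_sets = NULL,
                         min_call_rate = 0.9, min_maf = 0.01) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  step_name <- "input"
  bundle <- tryCatch({
    if (is.null(sim)) {
      rd <- read_vcf(vcf, popmap_path)
      panel <- rd$panel; popmap <- rd$popmap
      models <- if (!is.null(gene_models_path))
        read_gene_models(gene_models_path) else NULL
    } else {
      panel <- sim$panel; popmap <- sim$popmap
      cl <- tapply(panel$pos, panel$chrom, max) + 1
      models <- tile_genes(cl[unique(panel$chrom)])
    }
    step_name <- "site_filter"
    panel <- site_filter(panel, min_call_rate, min_maf)
    chrom_lengths <- tapply(panel$pos, panel$chrom, max) + 1
    chrom_lengths <- chrom_lengths[unique(panel$chrom)]
    windows <- make_windows(chrom_lengths, window, step)
    pops <- unique(popmap$pop)
    tsv <- function(df, name) {
      write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }

    step_name <- "diversity"
    div <- do.call(rbind, lapply(pops, function(p) {
      d <- diversity_stats(panel, popmap, p)
      data.frame(pop = p, He = d$He, Ho = d$Ho, MAF = d$MAF, FIS = d$FIS)
    }))
    tsv(div, "diversity.tsv")

    step_name <- "hp_scan"
    hp <- lapply(pops, function(p)
      pooled_heterozygosity(allele_counts(panel, popmap, p), windows,
                            min_snps))
    names(hp) <- pops
    for (p in pops) tsv(hp[[p]], paste0("hp_", p, ".tsv"))

    pairs <- if (length(pops) >= 2L) combn(pops, 2L, simplify = FALSE)
             else list()
    step_name <- "fst_scan"
    fst <- lapply(pairs, function(pr) {
      comp <- wc_components(panel, popmap, pr[1L], pr[2L])
      windowed_fst(comp, windows, min_snps)
    })
    names(fst) <- vapply(pairs, paste, "", collapse = "_vs_")
    for (nm in names(fst)) tsv(fst[[nm]], paste0("fst_", nm, ".tsv"))

    step_name <- "xpehh_scan"
    xp <- lapply(pairs, function(pr) {
      r <- xpehh(panel, popmap, pr[1L], pr[2L])
      tails <- top_fraction(r, q = xpehh_top, side = "both")
      list(snps = r, tails = tails,
           windows = xpehh_windows(r, windows, tails))
    })
    names(xp) <- names(fst)
    for (nm in names(xp)) tsv(xp[[nm]]$snps, paste0("xpehh_", nm, ".tsv"))

    step_name <- "roh"
    rohs <- do.call(rbind, lapply(popmap$sample, function(s)
      detect_roh(panel, s, roh)))
    tsv(rohs, "roh.tsv")

    step_name <- "ld_decay"
    ld <- lapply(pops, function(p)
      ld_decay(panel, popmap, p, ld_max_dist, ld_bin_size))
    names(ld) <- pops
    for (p in pops) tsv(ld[[p]], paste0("ld_", p, ".tsv"))

    step_name <- "structure"
    pc <- pca(panel, k = min(4L, n_samples(panel) - 1L))
    tsv(data.frame(sample = rownames(pc$coords),
                   pop = popmap$pop[match(rownames(pc$coords),
                                          popmap$sample)],
                   pc$coords), "pca.tsv")
    tr <- nj_tree(p_distance_matrix(panel))
    ape::write.tree(tr, file.path(outdir, "nj.nwk"))

    step_name <- "regions"
    region_genes <- function(reg) {
      if (is.null(models)) character(0)
      else genes_in_regions(reg, models)$union
    }
    region_sets <- list()
    gene_sets_by_method <- list()
    for (p in pops) {
      sel <- select_windows(hp[[p]], "zhp", zhp_max)
      reg <- merge_regions(sel)
      region_sets[[paste0("zhp_", p)]] <- reg
      gene_sets_by_method[[paste0("zhp_", p)]] <- region_genes(reg)
    }
    for (nm in names(fst)) {
      reg <- merge_regions(select_windows(fst[[nm]], "zfst", zfst_min))
      region_sets[[paste0("zfst_", nm)]] <- reg
      gene_sets_by_method[[paste0("zfst_", nm)]] <- region_genes(reg)
      regx <- merge_regions(select_windows(xp[[nm]]$windows, "xpehh"))
      region_sets[[paste0("xpehh_", nm)]] <- regx
      gene_sets_by_method[[paste0("xpehh_", nm)]] <- region_genes(regx)
    }
    all_regions <- do.call(rbind, lapply(names(region_sets), function(nm) {
      r <- region_sets[[nm]]
      if (nrow(r)) cbind(method = nm, r) else NULL
    }))
    if (!is.null(all_regions)) {
      tsv(all_regions, "candidate_regions.tsv")
      bed <- all_regions[, c("chrom", "start", "end", "method")]
      write.table(bed, file.path(outdir, "candidate_regions.bed"),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }

    step_name <- "gene_overlap"
    fst_genes <- unique(unlist(gene_sets_by_method[grep("^zfst_",
                          names(gene_sets_by_method))]))
    xp_genes <- unique(unlist(gene_sets_by_method[grep("^xpehh_",
                          names(gene_sets_by_method))]))
    shared <- if (length(fst_genes) || length(xp_genes))
      overlap_genes(list(fst = fst_genes, xpehh = xp_genes))
    else character(0)
    writeLines(shared, file.path(outdir, "fst_xpehh_shared_genes.tsv"))

    step_name <- "enrichment"
    enrich <- NULL
    if (!is.null(gene_sets) && !is.null(models) && length(shared)) {
      background <- names(models$genes)
      enrich <- hypergeom_enrich(intersect(shared, background),
                                 gene_sets, background)
      tsv(enrich, "enrichment.tsv")
    }

    step_name <- "manifest"
    manifest <- list(window = window, step = step, min_snps = min_snps,
                     zhp_max = zhp_max, zfst_min = zfst_min,
                     xpehh_top = xpehh_top, roh = roh,
                     ld_max_dist = ld_max_dist, ld_bin_size = ld_bin_size,
                     min_call_rate = min_call_rate, min_maf = min_maf,
                     n_variants = n_variants(panel),
                     n_samples = n_samples(panel), populations = pops)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(panel = panel, popmap = popmap, diversity = div, hp = hp,
         fst = fst, xpehh = xp, roh = rohs, ld = ld, pca = pc, tree = tr,
         regions = region_sets, genes = gene_sets_by_method,
         shared_genes = shared, enrichment = enrich, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", step_name, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(bundle)
}
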