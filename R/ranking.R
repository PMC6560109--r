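#' Aggregate per-gene site statistics
#'
#' Counts, for every gene, the admitted segregating sites in its genomic span
#' and the lineage-specific high-frequency changes (fixed plus HF, since fixed
#' changes are a subset of HF changes) associated with it. A site is
#' associated with a gene if its position lies within the gene span or one of
#' its consequence records names the gene (so e.g. upstream changes count);
#' per-gene site sets are de-duplicated, and a site overlapping two genes
#' counts once in each. Gene length is the genomic span (`end - start + 1`).
#'
#' @param classified Output of [classify_sites()] (needs `admitted`).
#' @param models A `gene_models` object.
#' @param consequences Optional output of [annotate_sites()]; used both for
#'   gene association of flanking sites and for the missense subsets.
#' @return A data.frame with one row per gene: `gene_id`, `chrom`,
#'   `length_bp`, `segregating_sites`, `fixed_human`, `hf_human`,
#'   `fixed_archaic`, `hf_archaic`, `hhmc_count`, `ahmc_count`,
#'   `density_human`, `density_archaic`.
#' @export
aggregate_gene_stats <- function(classified, models, consequences = NULL) {
  genes <- models$genes
  no_span <- is.na(genes$start) | is.na(genes$end)
  if (any(no_span)) {
    warning("skipping ", sum(no_span), " gene(s) without a genomic span")
    genes <- genes[!no_span, , drop = FALSE]
  }
  adm <- classified[classified$admitted, , drop = FALSE]
  key <- paste(adm$chrom, adm$pos, adm$ref, adm$alt)

  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  site_gr <- GenomicRanges::GRanges(adm$chrom,
                                    IRanges::IRanges(adm$pos, adm$pos))
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr)
  assoc <- data.frame(site = S4Vectors::queryHits(hits),
                      gene = genes$gene_id[S4Vectors::subjectHits(hits)],
                      stringsAsFactors = FALSE)
  if (!is.null(consequences)) {
    ckey <- paste(consequences$chrom, consequences$pos, consequences$ref,
                  consequences$alt)
    cc <- consequences[!is.na(consequences$gene_id), , drop = FALSE]
    ckey <- ckey[!is.na(consequences$gene_id)]
    site_idx <- match(ckey, key)
    keep <- !is.na(site_idx)
    assoc <- rbind(assoc, data.frame(site = site_idx[keep],
                                     gene = cc$gene_id[keep],
                                     stringsAsFactors = FALSE))
  }
  assoc <- unique(assoc)
  assoc <- assoc[assoc$gene %in% genes$gene_id, , drop = FALSE]

  hf_human_site <- adm$lineage == "human" &
    adm$category %in% c("fixed", "high_frequency")
  hf_arch_site <- adm$lineage == "archaic" &
    adm$category %in% c("fixed", "high_frequency")
  fixed_human_site <- adm$lineage == "human" & adm$category == "fixed"
  fixed_arch_site <- adm$lineage == "archaic" & adm$category == "fixed"

  missense_site <- rep(FALSE, nrow(adm))
  if (!is.null(consequences)) {
    mk <- unique(paste(consequences$chrom, consequences$pos,
                       consequences$ref, consequences$alt)[
                         consequences$consequence_class == "missense"])
    missense_site <- key %in% mk
  }

  count_by_gene <- function(site_flag) {
    a <- assoc[site_flag[assoc$site], , drop = FALSE]
    tab <- table(a$gene)
    out <- setNames(integer(nrow(genes)), genes$gene_id)
    out[names(tab)] <- as.integer(tab)
    out
  }
  seg <- count_by_gene(rep(TRUE, nrow(adm)))
  hf_h <- count_by_gene(hf_human_site)
  hf_a <- count_by_gene(hf_arch_site)
  fx_h <- count_by_gene(fixed_human_site)
  fx_a <- count_by_gene(fixed_arch_site)
  hhmc <- count_by_gene(hf_human_site & missense_site)
  ahmc <- count_by_gene(hf_arch_site & missense_site)

  len <- genes$end - genes$start + 1L
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             length_bp = len,
             segregating_sites = seg,
             fixed_human = fx_h, hf_human = hf_h,
             fixed_archaic = fx_a, hf_archaic = hf_a,
             hhmc_count = hhmc, ahmc_count = ahmc,
             density_human = hf_h / len,
             density_archaic = hf_a / len,
             row.names = NULL, stringsAsFactors = FALSE)
}

top_fraction_threshold <- function(values, fraction) {
  k <- ceiling(fraction * length(values))
  sort(values, decreasing = TRUE)[k]
}

#' Rank genes by high-frequency change density
#'
#' Ranks genes by the number of lineage-specific HF changes divided by their
#' genomic length and returns the putatively enriched top fraction. Genes
#' shorter than `min_length_bp` or with fewer than `min_segregating`
#' segregating sites are excluded before ranking. The returned set is all
#' genes whose density is at least the threshold separating the top
#' `density_top_fraction` of the eligible empirical distribution; ties at the
#' threshold are all included.
#'
#' @param stats Output of [aggregate_gene_stats()].
#' @param cfg A [ranking_config()] object.
#' @param lineage `"human"` or `"archaic"`.
#' @return A list with `enriched` (character vector of gene ids), `eligible`
#'   (the eligible stats subset) and `threshold` (the density cutoff).
#' @export
rank_by_density <- function(stats, cfg = ranking_config(),
                            lineage = c("human", "archaic")) {
  lineage <- match.arg(lineage)
  elig <- stats[stats$length_bp >= cfg$min_length_bp &
                  stats$segregating_sites >= cfg$min_segregating, ,
                drop = FALSE]
  if (nrow(elig) < 20)
    stop("only ", nrow(elig), " genes eligible for the density ranking; ",
         "provide a larger input")
  dens <- if (lineage == "human") elig$density_human else elig$density_archaic
  thr <- top_fraction_threshold(dens, cfg$density_top_fraction)
  list(enriched = elig$gene_id[dens >= thr], eligible = elig, threshold = thr)
}

#' Rank genes by the lineage ratio of high-frequency changes
#'
#' For genes with at least `ratio_min_total` lineage-specific HF changes on
#' the two lineages combined, computes the ratio of HF changes on one lineage
#' over the other and returns the top `ratio_top_fraction` for each lineage.
#' Genes with no changes on the opposite lineage have an infinite ratio and
#' rank above all finite ratios, ordered among themselves by their own HF
#' count; ties at the threshold are all included.
#'
#' @param stats Output of [aggregate_gene_stats()].
#' @param cfg A [ranking_config()] object.
#' @return A list with `human_enriched` and `archaic_enriched` (character
#'   vectors of gene ids) and `eligible` (the eligible stats subset).
#' @export
rank_by_ratio <- function(stats, cfg = ranking_config()) {
  elig <- stats[stats$hf_human + stats$hf_archaic >= cfg$ratio_min_total, ,
                drop = FALSE]
  if (nrow(elig) < 20)
    stop("only ", nrow(elig), " genes eligible for the ratio ranking; ",
         "provide a larger input")
  pick <- function(num, den) {
    ratio <- ifelse(den == 0, Inf, num / den)
    # rank: infinite ratios first (by numerator), then finite ratios
    ord <- order(-is.infinite(ratio), -ifelse(is.infinite(ratio), num, -Inf),
                 -ratio)
    k <- ceiling(cfg$ratio_top_fraction * nrow(elig))
    thr <- ratio[ord][k]
    if (is.infinite(thr)) {
      thr_num <- num[ord][k]
      elig$gene_id[is.infinite(ratio) & num >= thr_num]
    } else {
      elig$gene_id[ratio >= thr]
    }
  }
  list(human_enriched = pick(elig$hf_human, elig$hf_archaic),
       archaic_enriched = pick(elig$hf_archaic, elig$hf_human),
       eligible = elig)
}

#' Correlation of per-gene site counts with gene length
#'
#' Pearson product-moment correlations of the per-gene counts of segregating
#' sites, lineage-specific HF changes and fixed changes against genomic gene
#' length, on untransformed counts. Requires at least three genes; a count
#' vector with zero variance yields `NA`.
#'
#' @param stats Output of [aggregate_gene_stats()].
#' @return A named numeric vector with elements `segregating`, `hf_human`,
#'   `fixed_human`, `hf_archaic`, `fixed_archaic`.
#' @export
length_correlations <- function(stats) {
  if (nrow(stats) < 3)
    stop("length correlations need at least 3 genes")
  safe_cor <- function(x) {
    if (stats::sd(x) == 0 || stats::sd(stats$length_bp) == 0) return(NA_real_)
    cor(x, stats$length_bp)
  }
  c(segregating = safe_cor(stats$segregating_sites),
    hf_human = safe_cor(stats$hf_human),
    fixed_human = safe_cor(stats$fixed_human),
    hf_archaic = safe_cor(stats$hf_archaic),
    fixed_archaic = safe_cor(stats$fixed_archaic))
}
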