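#' Likelihood-ratio (G) test of independence on a 2 x 2 table
#'
#' Computes the G statistic \eqn{G = 2 \sum O \ln(O/E)} over cells with
#' non-zero observed counts, with expected counts from the independence
#' model, and a p-value from the chi-square distribution with one degree of
#' freedom. No continuity correction is applied by default; the Williams
#' correction is available behind a flag.
#'
#' @param x A 2 x 2 matrix of non-negative counts with positive row and
#'   column sums.
#' @param williams Apply the Williams correction (default `FALSE`).
#' @return A list with `statistic`, `p.value`, `expected`.
#' @export
g_test <- function(x, williams = FALSE) {
  x <- as.matrix(x)
  stopifnot(all(dim(x) == c(2, 2)), all(x >= 0))
  rs <- rowSums(x)
  cs <- colSums(x)
  n <- sum(x)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column sum in G-test")
  e <- outer(rs, cs) / n
  if (any(e == 0)) stop("zero expected count in G-test")
  nz <- x > 0
  g <- 2 * sum(x[nz] * log(x[nz] / e[nz]))
  if (williams) {
    q <- 1 + ((n / rs[1] + n / rs[2] - 1) *
                (n / cs[1] + n / cs[2] - 1)) / (6 * n)
    g <- g / q
  }
  list(statistic = unname(g), p.value = pchisq(unname(g), df = 1,
                                               lower.tail = FALSE),
       expected = e)
}

# Assign universe genes to log-spaced length bins.
length_bin <- function(lengths, n_bins) {
  lo <- min(lengths)
  hi <- max(lengths)
  if (lo == hi) return(rep(1L, length(lengths)))
  breaks <- exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  breaks[1] <- lo
  breaks[length(breaks)] <- hi
  findInterval(lengths, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Length-matched empirical gene-set test
#'
#' Tests whether a target gene set contains more hits than expected for its
#' gene lengths. The gene universe is binned into `length_bins` log-spaced
#' length bins; each of `n_random_sets` random sets draws, per bin and
#' without replacement, as many genes as the target set has in that bin. The
#' observed statistic is the summed hit value over the target set (for a hit
#' gene list, the overlap size; for per-gene counts, the total count). The
#' empirical fraction is the proportion of random sets with strictly fewer
#' hits, and the decision is positive when that fraction reaches
#' `empirical_criterion` (at least 90% of the random sets by default). The
#' draw is seeded and reproducible.
#'
#' @param target_genes Character vector of target gene ids (subset of the
#'   universe).
#' @param hits Either a character vector of hit gene ids or a named numeric
#'   vector of per-gene hit counts.
#' @param universe Data.frame with columns `gene_id` and `length_bp`.
#' @param cfg An [enrichment_config()] object.
#' @param label Label used to derive this test's RNG substream from
#'   `cfg$rng_seed`.
#' @return A data.frame (one row) with `test_name`, `observed`,
#'   `empirical_fraction`, `n_random_sets`, `decision`, `null_description`.
#' @export
empirical_length_matched_test <- function(target_genes, hits, universe,
                                          cfg = enrichment_config(),
                                          label = "gene_set") {
  stopifnot(all(target_genes %in% universe$gene_id))
  if (is.character(hits)) {
    hitval <- setNames(as.numeric(universe$gene_id %in% hits),
                       universe$gene_id)
  } else {
    hitval <- setNames(rep(0, nrow(universe)), universe$gene_id)
    hitval[intersect(names(hits), universe$gene_id)] <-
      hits[intersect(names(hits), universe$gene_id)]
  }
  bins <- length_bin(universe$length_bp, cfg$length_bins)
  target_bins <- bins[match(target_genes, universe$gene_id)]
  need <- table(target_bins)
  bin_members <- split(seq_len(nrow(universe)), bins)
  hv <- unname(hitval)

  observed <- sum(hitval[target_genes])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$rng_seed, label))
  B <- cfg$n_random_sets
  stat <- numeric(B)
  need_bin <- as.integer(names(need))
  need_n <- as.integer(need)
  for (b in seq_len(B)) {
    s <- 0
    for (k in seq_along(need_bin)) {
      members <- bin_members[[as.character(need_bin[k])]]
      take <- if (length(members) == 1) members
              else sample(members, need_n[k])
      s <- s + sum(hv[take])
    }
    stat[b] <- s
  }
  frac <- mean(stat < observed)
  data.frame(test_name = label,
             observed = observed,
             empirical_fraction = frac,
             n_random_sets = B,
             decision = frac >= cfg$empirical_criterion,
             null_description = sprintf(
               "%d random sets length-matched in %d log bins", B,
               cfg$length_bins),
             stringsAsFactors = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Trait enrichment screen for high-frequency missense changes
#'
#' Screens trait-gene association tables (GWAS-catalog style) for traits
#' whose associated genes carry an excess of lineage-specific high-frequency
#' missense changes. A trait is reported as enriched for a lineage only when
#' all three stages pass: (i) a genome-wide G-test of the lineage's missense
#' changes in trait genes versus the trait's share of all genes, at
#' `gtest_p_cutoff`; (ii) a between-lineage G-test of the trait's share of
#' missense changes on the two lineages, at the same cutoff; and (iii) the
#' length-matched empirical criterion of
#' [empirical_length_matched_test()]. Both G-test stages also require the
#' excess to be in the tested lineage's direction. Traits with fewer than
#' `min_trait_loci` associated genes in the universe are skipped.
#'
#' @param traits Data.frame with columns `trait`, `gene_id`.
#' @param hhmc_counts Named numeric vector: human HF missense changes per
#'   gene.
#' @param ahmc_counts Named numeric vector: archaic HF missense changes per
#'   gene.
#' @param universe Data.frame with columns `gene_id`, `length_bp`.
#' @param cfg An [enrichment_config()] object.
#' @return A data.frame with one row per (trait, lineage): stage p-values,
#'   empirical fraction and the final `enriched` decision.
#' @export
gwas_trait_enrichment <- function(traits, hhmc_counts, ahmc_counts, universe,
                                  cfg = enrichment_config()) {
  counts <- list(human = hhmc_counts, archaic = ahmc_counts)
  total <- lapply(counts, function(x) sum(x[universe$gene_id], na.rm = TRUE))
  n_genes <- nrow(universe)
  skipped <- 0L
  rows <- list()
  for (tr in unique(traits$trait)) {
    genes <- intersect(unique(traits$gene_id[traits$trait == tr]),
                       universe$gene_id)
    if (length(genes) < cfg$min_trait_loci) {
      skipped <- skipped + 1L
      next
    }
    in_trait <- lapply(counts, function(x) sum(x[genes], na.rm = TRUE))
    for (lin in c("human", "archaic")) {
      other <- setdiff(c("human", "archaic"), lin)
      k1 <- in_trait[[lin]]
      t1 <- total[[lin]]
      # stage i: changes in trait genes vs the trait's share of all genes
      tab1 <- matrix(c(k1, t1 - k1, length(genes), n_genes - length(genes)),
                     nrow = 2, byrow = TRUE)
      g1 <- tryCatch(g_test(tab1), error = function(e) NULL)
      dir1 <- t1 > 0 && (k1 / t1) > (length(genes) / n_genes)
      p1 <- if (is.null(g1)) NA_real_ else g1$p.value
      pass1 <- !is.null(g1) && g1$p.value < cfg$gtest_p_cutoff && dir1
      # stage ii: trait share of this lineage's changes vs the other lineage's
      k2 <- in_trait[[other]]
      t2 <- total[[other]]
      tab2 <- matrix(c(k1, t1 - k1, k2, t2 - k2), nrow = 2, byrow = TRUE)
      g2 <- tryCatch(g_test(tab2), error = function(e) NULL)
      dir2 <- t1 > 0 && t2 > 0 && (k1 / t1) > (k2 / t2)
      p2 <- if (is.null(g2)) NA_real_ else g2$p.value
      pass2 <- !is.null(g2) && g2$p.value < cfg$gtest_p_cutoff && dir2
      # stage iii: length-matched empirical test on the counts
      emp <- empirical_length_matched_test(
        genes, counts[[lin]], universe, cfg,
        label = paste0("gwas:", tr, ":", lin))
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, lineage = lin, n_genes = length(genes),
        changes_in_trait = k1,
        p_genomewide = p1, pass_genomewide = pass1,
        p_between_lineage = p2, pass_between_lineage = pass2,
        empirical_fraction = emp$empirical_fraction,
        pass_empirical = emp$decision,
        enriched = pass1 && pass2 && emp$decision,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0)
    msg("gwas_trait_enrichment: skipped ", skipped,
        " trait(s) with fewer than ", cfg$min_trait_loci, " annotated loci")
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}

#' Gene-category enrichment tests with family-wise error control
#'
#' Tests gene categories (GO-style) for enrichment in a foreground gene set.
#' In `"hypergeometric"` mode the foreground (e.g. genes with missense
#' changes) is compared against a universe formed with a background set (e.g.
#' genes with synonymous changes on the same lineage), using the upper-tail
#' hypergeometric probability per category. In `"wilcoxon"` mode a per-gene
#' score (e.g. the lineage ratio of HF changes) is compared between genes in
#' and out of each category with a one-sided rank-sum test. Raw p-values are
#' Holm-adjusted, and the family-wise error rate is additionally estimated by
#' label permutation with the max-statistic (minimum-p) method over
#' `n_random_sets` permutations. A category is reported when its adjusted p
#' is below `adjusted_p_cutoff` and its permutation FWER below `fwer_alpha`.
#'
#' @param categories Data.frame with columns `category`, `gene_id`.
#' @param foreground Character vector of foreground gene ids
#'   (hypergeometric mode).
#' @param background Character vector of background gene ids
#'   (hypergeometric mode).
#' @param scores Named numeric per-gene scores (wilcoxon mode).
#' @param mode `"hypergeometric"` or `"wilcoxon"`.
#' @param cfg An [enrichment_config()] object.
#' @return A data.frame with one row per category: counts or statistic, raw,
#'   Holm-adjusted and permutation-FWER p-values, and the `reported` flag.
#' @export
category_tests <- function(categories, foreground = NULL, background = NULL,
                           scores = NULL,
                           mode = c("hypergeometric", "wilcoxon"),
                           cfg = enrichment_config()) {
  mode <- match.arg(mode)
  if (mode == "hypergeometric") {
    stopifnot(!is.null(foreground), !is.null(background))
    universe <- unique(c(foreground, background))
    member <- universe %in% foreground
  } else {
    stopifnot(!is.null(scores), !is.null(names(scores)))
    universe <- names(scores)
  }
  cats <- split(categories$gene_id, categories$category)
  cats <- lapply(cats, function(g) intersect(unique(g), universe))
  empty <- vapply(cats, length, integer(1)) == 0
  if (any(empty)) {
    msg("category_tests: skipping ", sum(empty),
        " categor(ies) with zero members in the universe")
    cats <- cats[!empty]
  }
  if (length(cats) == 0) return(data.frame())

  inc_list <- lapply(cats, function(g) universe %in% g)
  raw_p <- function(member_vec) {
    # member_vec: logical foreground membership (hypergeometric) or
    # score vector ordering (wilcoxon), aligned to `universe`
    vapply(inc_list, function(inc) {
      if (mode == "hypergeometric") {
        k <- sum(inc & member_vec)
        phyper(k - 1, sum(inc), length(universe) - sum(inc),
               sum(member_vec), lower.tail = FALSE)
      } else {
        suppressWarnings(
          wilcox.test(member_vec[inc], member_vec[!inc],
                      alternative = "greater", exact = FALSE)$p.value)
      }
    }, numeric(1))
  }

  obs_vec <- if (mode == "hypergeometric") member else unname(scores[universe])
  p_raw <- raw_p(obs_vec)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$rng_seed, paste0("category:", mode)))
  B <- cfg$n_random_sets
  min_p <- numeric(B)
  for (b in seq_len(B)) {
    perm <- sample(obs_vec)
    min_p[b] <- min(raw_p(perm))
  }
  fwer <- vapply(p_raw, function(p) mean(min_p <= p), numeric(1))
  holm <- p.adjust(p_raw, method = "holm")
  out <- data.frame(category = names(cats),
                    n_category = vapply(cats, length, integer(1)),
                    p_raw = p_raw, p_holm = holm, fwer = fwer,
                    reported = holm < cfg$adjusted_p_cutoff &
                      fwer < cfg$fwer_alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (mode == "hypergeometric")
    out$overlap <- vapply(cats, function(g)
      sum(universe %in% g & member), integer(1))
  out
}

#' Sites within a window of selective-sweep regions
#'
#' Returns the subset of sites whose minimum distance to any sweep region is
#' at most `window` bp (a site inside a region has distance zero).
#'
#' @param sites Site table with `chrom` and `pos`.
#' @param sweep_regions `GRanges` of sweep regions (internal 1-based
#'   coordinates, e.g. from [read_bed_features()]).
#' @param window Window in bp (default 50000).
#' @return The qualifying subset of `sites`, with a `sweep_distance` column.
#' @export
sweep_overlap <- function(sites, sweep_regions, window = 50000L) {
  if (length(sweep_regions) == 0 || nrow(sites) == 0) {
    out <- sites[integer(0), , drop = FALSE]
    out$sweep_distance <- integer(0)
    return(out)
  }
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  d <- GenomicRanges::distanceToNearest(site_gr, sweep_regions)
  dist <- rep(NA_integer_, nrow(sites))
  # GRanges distance counts the gap (adjacent = 0); convert to base pairs
  # from the region edge, with 0 for sites inside a region
  gap <- S4Vectors::mcols(d)$distance
  inside <- GenomicRanges::countOverlaps(site_gr, sweep_regions) > 0
  dist[S4Vectors::queryHits(d)] <- gap + 1L
  dist[inside] <- 0L
  keep <- !is.na(dist) & dist <= window
  out <- sites[keep, , drop = FALSE]
  out$sweep_distance <- dist[keep]
  rownames(out) <- NULL
  out
}
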