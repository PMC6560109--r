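#' Apply per-genotype quality filters to archaic genotypes
#'
#' Applies the genotype-level filters to a long genotype table (one row per
#' site and individual): depth below `dp_min` fails (`low_coverage`), depth
#' above the individual's roster `dp_max` fails (`high_coverage`), genotype
#' quality below `gq_min` fails (`low_gq`), and heterozygous genotypes whose
#' minor-allele read fraction `min(AD)/sum(AD)` is strictly below
#' `min_minor_fraction` fail (`allele_imbalance`). Genotypes with missing
#' alleles get the verdict `missing`. Heterozygous genotypes without allelic
#' depths cannot be imbalance-tested and are judged on depth and quality
#' alone; their number is reported via a message. A failed genotype is treated
#' downstream as missing.
#'
#' The boundary semantics follow the strict wording of the filter
#' definitions: depth exactly `dp_min` passes, depth exactly `dp_max` passes,
#' quality exactly `gq_min` passes and a minor fraction exactly equal to
#' `min_minor_fraction` passes.
#'
#' @param genotypes Genotype table as returned by [read_archaic_vcf()].
#' @param thresholds A [filter_thresholds()] object.
#' @param roster An [archaic_roster()] supplying per-individual `dp_max`.
#' @return The genotype table with added columns `passed` (logical) and
#'   `reason` (one of `ok`, `low_coverage`, `high_coverage`, `low_gq`,
#'   `allele_imbalance`, `missing`).
#' @export
filter_genotypes <- function(genotypes, thresholds = filter_thresholds(),
                             roster = archaic_roster()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  unknown <- setdiff(unique(genotypes$individual), roster$individual)
  if (length(unknown) > 0)
    stop("genotypes for individuals not in roster: ",
         paste(unknown, collapse = ", "))
  dp_max <- roster$dp_max[match(genotypes$individual, roster$individual)]
  if (any(thresholds$dp_min > roster$dp_max))
    stop("dp_min exceeds a roster dp_max")

  n <- nrow(genotypes)
  reason <- rep("ok", n)
  is_missing <- is.na(genotypes$a1) | is.na(genotypes$a2)
  het <- !is_missing & genotypes$a1 != genotypes$a2
  have_ad <- !is.na(genotypes$ad1) & !is.na(genotypes$ad2) &
    (genotypes$ad1 + genotypes$ad2) > 0
  minor_frac <- ifelse(have_ad,
                       pmin(genotypes$ad1, genotypes$ad2) /
                         (genotypes$ad1 + genotypes$ad2), NA_real_)

  # precedence: missing, then coverage, quality, imbalance
  imb <- het & have_ad & minor_frac < thresholds$min_minor_fraction
  reason[imb] <- "allele_imbalance"
  reason[genotypes$gq < thresholds$gq_min] <- "low_gq"
  reason[genotypes$dp > dp_max] <- "high_coverage"
  reason[genotypes$dp < thresholds$dp_min] <- "low_coverage"
  reason[is_missing] <- "missing"

  untestable <- het & !have_ad & reason == "ok"
  if (any(untestable))
    msg("filter_genotypes: ", sum(untestable),
        " heterozygous genotype(s) without allelic depths passed on DP/GQ alone")

  genotypes$passed <- reason == "ok"
  genotypes$reason <- reason
  genotypes
}

#' Admit segregating sites
#'
#' A site is admitted to the catalog when both the human reference and
#' alternative alleles are defined, at least one archaic genotype at the site
#' passed filtering, and the alternative allele has actually been observed --
#' either in the human cohort (`alt_count > 0`) or in a passing archaic
#' genotype. Sites failing any of these are excluded from all downstream
#' counts.
#'
#' @param sites Site table from [build_sites()].
#' @param verdicts Filtered genotype table from [filter_genotypes()].
#' @return The site table with added logical column `admitted` and integer
#'   column `n_passing` (number of passing archaic genotypes).
#' @export
admit_sites <- function(sites, verdicts) {
  key_s <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  key_v <- paste(verdicts$chrom, verdicts$pos, verdicts$ref, verdicts$alt)
  pass <- verdicts$passed
  n_passing <- vapply(split(pass, factor(key_v, levels = unique(key_v))), sum,
                      integer(1))
  n_passing <- n_passing[key_s]
  n_passing[is.na(n_passing)] <- 0L

  alt_in_archaic <- pass &
    (verdicts$a1 == verdicts$alt | verdicts$a2 == verdicts$alt)
  alt_in_archaic[is.na(alt_in_archaic)] <- FALSE
  alt_seen <- tapply(alt_in_archaic, factor(key_v, levels = unique(key_v)), any)
  alt_seen <- as.logical(alt_seen[key_s])
  alt_seen[is.na(alt_seen)] <- FALSE

  alleles_ok <- !is.na(sites$ref) & !is.na(sites$alt) & sites$ref != sites$alt
  sites$n_passing <- as.integer(n_passing)
  sites$admitted <- alleles_ok & n_passing > 0 &
    (sites$alt_count > 0 | alt_seen)
  sites
}
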