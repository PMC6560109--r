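#' Archaic individual roster
#'
#' Describes the archaic individuals present in the genotype data: which one is
#' the Denisovan, which are Neanderthals, and the per-individual maximum-depth
#' cutoff used by [filter_genotypes()]. The defaults correspond to the three
#' published high-coverage archaic genomes: one Denisovan and the Altai and
#' Vindija Neanderthals, with a 105-fold depth ceiling for the Altai individual
#' and 75-fold for the others.
#'
#' @param individuals Character vector of individual identifiers.
#' @param groups Character vector, same length, each `"denisovan"` or
#'   `"neanderthal"`.
#' @param dp_max Integer vector, same length: per-individual maximum depth
#'   (inclusive; depth strictly above fails).
#' @return A data.frame with columns `individual`, `group`, `dp_max`.
#' @export
archaic_roster <- function(individuals = c("Denisovan", "AltaiNeanderthal", "VindijaNeanderthal"),
                           groups = c("denisovan", "neanderthal", "neanderthal"),
                           dp_max = c(75L, 105L, 75L)) {
  stopifnot(length(individuals) == length(groups),
            length(individuals) == length(dp_max),
            all(groups %in% c("denisovan", "neanderthal")),
            !anyDuplicated(individuals))
  out <- data.frame(individual = as.character(individuals),
                    group = as.character(groups),
                    dp_max = as.integer(dp_max),
                    stringsAsFactors = FALSE)
  class(out) <- c("archaic_roster", class(out))
  out
}

#' Genotype-level filter thresholds
#'
#' Quality thresholds applied per archaic genotype before a site is admitted:
#' minimum depth (sites with *less than* `dp_min`-fold coverage fail), a
#' per-individual maximum depth taken from the roster (*more than* `dp_max`
#' fails), minimum genotype quality (*smaller than* `gq_min` fails), and the
#' minor-allele read fraction below which a heterozygous call is considered
#' allele-imbalanced (strictly below `min_minor_fraction` fails). All four
#' boundaries are strict in that sense: DP = 5, DP = 105 (Altai), GQ = 20 and
#' minor fraction = 0.2 all pass under the defaults.
#'
#' @param dp_min Minimum read depth (default 5).
#' @param gq_min Minimum genotype quality (default 20).
#' @param min_minor_fraction Minimum minor-allele read fraction for
#'   heterozygous calls with allelic depths (default 0.2).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(dp_min = 5L, gq_min = 20L, min_minor_fraction = 0.2) {
  stopifnot(dp_min >= 0, gq_min >= 0,
            min_minor_fraction >= 0, min_minor_fraction <= 0.5)
  structure(list(dp_min = as.integer(dp_min),
                 gq_min = as.integer(gq_min),
                 min_minor_fraction = as.numeric(min_minor_fraction)),
            class = "filter_thresholds")
}

#' Lineage classification thresholds
#'
#' Frequency cutoffs used when assigning sites to lineage categories:
#' `hf_human_min` is the derived-allele frequency above which a site is a
#' candidate human high-frequency change (strictly more than 90% by default);
#' `archaic_fixed_human_ancestral_min` is the human ancestral-allele frequency
#' above which a site can be archaic-fixed (more than 99.999%); and
#' `archaic_hf_human_derived_max` is the ceiling on the human derived-allele
#' frequency for archaic high-frequency changes (less than 1%). All three are
#' exclusive bounds.
#'
#' @param hf_human_min Human HF derived-frequency threshold (default 0.90).
#' @param archaic_fixed_human_ancestral_min Human ancestral frequency for
#'   archaic-fixed sites (default 0.99999).
#' @param archaic_hf_human_derived_max Human derived-frequency ceiling for
#'   archaic HF sites (default 0.01).
#' @return An object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(hf_human_min = 0.90,
                                      archaic_fixed_human_ancestral_min = 0.99999,
                                      archaic_hf_human_derived_max = 0.01) {
  stopifnot(hf_human_min > 0, hf_human_min < 1,
            archaic_fixed_human_ancestral_min > 0,
            archaic_fixed_human_ancestral_min < 1,
            archaic_hf_human_derived_max > 0,
            archaic_hf_human_derived_max < 1,
            hf_human_min > archaic_hf_human_derived_max)
  structure(list(hf_human_min = hf_human_min,
                 archaic_fixed_human_ancestral_min = archaic_fixed_human_ancestral_min,
                 archaic_hf_human_derived_max = archaic_hf_human_derived_max),
            class = "classification_thresholds")
}

#' Gene ranking configuration
#'
#' Eligibility and cutoff parameters for the per-gene rankings: genes must span
#' at least `min_length_bp` in the genome and carry at least `min_segregating`
#' segregating sites to enter the density ranking, whose top
#' `density_top_fraction` is called enriched. The lineage-ratio ranking
#' requires at least `ratio_min_total` high-frequency changes on the two
#' lineages combined and reports the top `ratio_top_fraction`.
#'
#' @param min_length_bp Minimum genomic span (default 5000).
#' @param min_segregating Minimum segregating sites in span (default 25).
#' @param density_top_fraction Fraction of eligible genes called
#'   density-enriched (default 0.05).
#' @param ratio_min_total Minimum combined lineage-specific HF changes
#'   (default 20).
#' @param ratio_top_fraction Fraction called ratio-enriched (default 0.10).
#' @return An object of class `ranking_config`.
#' @export
ranking_config <- function(min_length_bp = 5000L, min_segregating = 25L,
                           density_top_fraction = 0.05,
                           ratio_min_total = 20L, ratio_top_fraction = 0.10) {
  stopifnot(min_length_bp >= 1, min_segregating >= 0,
            density_top_fraction > 0, density_top_fraction < 1,
            ratio_min_total >= 0,
            ratio_top_fraction > 0, ratio_top_fraction < 1)
  structure(list(min_length_bp = as.integer(min_length_bp),
                 min_segregating = as.integer(min_segregating),
                 density_top_fraction = density_top_fraction,
                 ratio_min_total = as.integer(ratio_min_total),
                 ratio_top_fraction = ratio_top_fraction),
            class = "ranking_config")
}

#' Enrichment testing configuration
#'
#' Parameters for the enrichment machinery: the number of random gene sets `B`
#' drawn by the length-matched empirical test, the fraction of those sets that
#' must contain strictly fewer hits than the observed set (`empirical_criterion`,
#' default 90%), the G-test p-value cutoff used by the trait screen, the
#' minimum number of annotated loci per trait, the number of log-spaced length
#' bins used for matching, the sweep-region proximity window in bp, and the
#' significance cutoffs for category tests (Holm-adjusted p and permutation
#' family-wise error rate).
#'
#' @param n_random_sets Number of random gene sets B (default 1000).
#' @param empirical_criterion Required fraction of random sets with strictly
#'   fewer hits (default 0.90).
#' @param gtest_p_cutoff P-value cutoff for the trait G-tests (default 0.1).
#' @param min_trait_loci Minimum annotated loci per trait (default 10).
#' @param length_bins Number of log-spaced length bins (default 20).
#' @param sweep_window_bp Sweep overlap window in bp (default 50000).
#' @param fwer_alpha Permutation FWER cutoff (default 0.05).
#' @param adjusted_p_cutoff Holm-adjusted p cutoff (default 0.05).
#' @param rng_seed Integer seed driving all resampling (default 1).
#' @return An object of class `enrichment_config`.
#' @export
enrichment_config <- function(n_random_sets = 1000L, empirical_criterion = 0.90,
                              gtest_p_cutoff = 0.1, min_trait_loci = 10L,
                              length_bins = 20L, sweep_window_bp = 50000L,
                              fwer_alpha = 0.05, adjusted_p_cutoff = 0.05,
                              rng_seed = 1L) {
  stopifnot(n_random_sets >= 1,
            empirical_criterion > 0, empirical_criterion < 1,
            gtest_p_cutoff > 0, gtest_p_cutoff < 1,
            min_trait_loci >= 1, length_bins >= 1, sweep_window_bp >= 0,
            fwer_alpha > 0, fwer_alpha < 1,
            adjusted_p_cutoff > 0, adjusted_p_cutoff < 1)
  structure(list(n_random_sets = as.integer(n_random_sets),
                 empirical_criterion = empirical_criterion,
                 gtest_p_cutoff = gtest_p_cutoff,
                 min_trait_loci = as.integer(min_trait_loci),
                 length_bins = as.integer(length_bins),
                 sweep_window_bp = as.integer(sweep_window_bp),
                 fwer_alpha = fwer_alpha,
                 adjusted_p_cutoff = adjusted_p_cutoff,
                 rng_seed = as.integer(rng_seed)),
            class = "enrichment_config")
}

# Deterministic 31-bit substream seed derived from a base seed and a label, so
# that each resampling test gets its own reproducible stream.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
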