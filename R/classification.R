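#' Polarize sites into ancestral and derived alleles
#'
#' Resolves the derived allele and the human derived-allele frequency for each
#' site. When the ancestral state is `"ref"` or `"alt"`, the derived allele is
#' the other one and the frequency is `derived_count / total_count`. When the
#' ancestral state is unknown the frequency is undefined (`NA`) and the site
#' remains eligible only for the extended categories that use the macaque
#' allele.
#'
#' @param sites Site table from [build_sites()].
#' @return The site table with added columns `derived` (base or `NA`),
#'   `derived_count`, `ancestral_count` and `f` (derived-allele frequency).
#' @export
polarize_sites <- function(sites) {
  known <- sites$ancestral %in% c("ref", "alt")
  sites$derived <- ifelse(sites$ancestral == "ref", sites$alt,
                          ifelse(sites$ancestral == "alt", sites$ref,
                                 NA_character_))
  sites$derived_count <- ifelse(sites$ancestral == "ref", sites$alt_count,
                                ifelse(sites$ancestral == "alt",
                                       sites$ref_count, NA_integer_))
  sites$ancestral_count <- ifelse(known,
                                  sites$total_count - sites$derived_count,
                                  NA_integer_)
  sites$f <- ifelse(known, sites$derived_count / sites$total_count, NA_real_)
  sites
}

#' Per-individual archaic allele states
#'
#' Classifies each archaic genotype at each polarized site into one of
#' `ancestral_hom`, `derived_hom`, `heterozygous` (one ancestral and one
#' derived allele), `other_allele` (a called allele matching neither), or
#' `missing` (failed filtering or uncalled). At sites with unknown ancestral
#' state the state is `NA`; the homozygous base, if any, is reported instead
#' so the macaque-based extended pathways can use it.
#'
#' @param sites Polarized site table from [polarize_sites()].
#' @param verdicts Filtered genotype table from [filter_genotypes()].
#' @return `verdicts` with added columns `state` and `hom_base`.
#' @export
archaic_states <- function(sites, verdicts) {
  key_s <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  key_v <- paste(verdicts$chrom, verdicts$pos, verdicts$ref, verdicts$alt)
  idx <- match(key_v, key_s)
  anc <- ifelse(sites$ancestral == "ref", sites$ref,
                ifelse(sites$ancestral == "alt", sites$alt, NA_character_))[idx]
  der <- sites$derived[idx]

  a1 <- verdicts$a1
  a2 <- verdicts$a2
  usable <- verdicts$passed & !is.na(a1) & !is.na(a2)
  state <- rep(NA_character_, nrow(verdicts))
  known <- !is.na(anc)
  state[known] <- "missing"
  k <- known & usable
  both_anc <- k & a1 == anc & a2 == anc
  both_der <- k & a1 == der & a2 == der
  het <- k & ((a1 == anc & a2 == der) | (a1 == der & a2 == anc))
  # any allele outside {ancestral, derived} makes the genotype other_allele
  other <- k & ((a1 != anc & a1 != der) | (a2 != anc & a2 != der))
  state[both_anc] <- "ancestral_hom"
  state[both_der] <- "derived_hom"
  state[het] <- "heterozygous"
  state[other] <- "other_allele"

  verdicts$state <- state
  verdicts$hom_base <- ifelse(usable & a1 == a2, a1, NA_character_)
  verdicts
}

#' Classify admitted sites into lineage categories
#'
#' Assigns every admitted site to a human- or archaic-lineage category
#' following the catalog definitions, in fixed order of precedence.
#'
#' Human lineage (derived-allele frequency `f`):
#' \itemize{
#'   \item \strong{fixed}: no present-day human carries the ancestral allele
#'     (ancestral count 0) and at least two of the three archaics carry the
#'     ancestral allele, allowing for human gene flow into Neanderthals.
#'   \item \strong{high_frequency}: `f` above `hf_human_min` and the Denisovan
#'     plus at least one Neanderthal carry the ancestral allele.
#'   \item \strong{extended}, conditions (only reached when HF fails):
#'     (a) not all archaics have reliable genotypes but those that do carry
#'     the ancestral allele; (b) some archaic carries a third allele matching
#'     neither the human derived nor the ancestral allele, and no archaic
#'     carries the derived allele; (c) the Denisovan carries the ancestral
#'     allele while at least one Neanderthal carries a derived allele
#'     (gene flow from humans into Neanderthals); (d) the ancestral allele is
#'     unknown but the macaque base is identical to the allele carried
#'     homozygously by all three archaics, with the other human allele above
#'     the HF threshold.
#' }
#'
#' Archaic lineage (mirrored): \strong{fixed} requires all three archaics to
#' carry the derived allele with humans ancestral at more than
#' `archaic_fixed_human_ancestral_min`; \strong{high_frequency} requires the
#' derived allele below `archaic_hf_human_derived_max` in humans with at least
#' two archaics carrying it; \strong{extended} covers unknown-ancestral sites
#' where the macaque allele equals the major human allele and at least two
#' archaics carry the other (rare) allele.
#'
#' "Carries the ancestral allele" means homozygous-ancestral in the default
#' `"strict"` mode; in `"lenient"` mode a heterozygous archaic also counts.
#' A heterozygous archaic always counts as carrying the derived allele.
#'
#' @param sites Site table with `admitted` column (see [admit_sites()]).
#' @param verdicts Filtered genotype table from [filter_genotypes()].
#' @param roster An [archaic_roster()].
#' @param thresholds A [classification_thresholds()] object.
#' @param carry_mode `"strict"` (default) or `"lenient"`.
#' @param neanderthal_derived For extended condition (c): whether
#'   `"at_least_one"` (default) or `"exactly_one"` Neanderthal must carry a
#'   derived allele.
#' @return The site table with per-individual state columns
#'   (`state_<individual>`), `lineage` (`human`, `archaic`, `none`),
#'   `category` (`fixed`, `high_frequency`, `extended`, `none`) and
#'   `extended_condition` (`a`--`d`, `macaque_match`, or `NA`).
#' @export
classify_sites <- function(sites, verdicts, roster = archaic_roster(),
                           thresholds = classification_thresholds(),
                           carry_mode = c("strict", "lenient"),
                           neanderthal_derived = c("at_least_one", "exactly_one")) {
  carry_mode <- match.arg(carry_mode)
  neanderthal_derived <- match.arg(neanderthal_derived)
  stopifnot(inherits(thresholds, "classification_thresholds"))
  if (!("admitted" %in% names(sites)))
    stop("sites must carry an 'admitted' column; run admit_sites() first")
  sites <- polarize_sites(sites)
  st <- archaic_states(sites, verdicts)

  key_s <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  key_v <- paste(st$chrom, st$pos, st$ref, st$alt)
  inds <- roster$individual
  n <- nrow(sites)
  state_m <- matrix(NA_character_, nrow = n, ncol = length(inds),
                    dimnames = list(NULL, inds))
  hom_m <- matrix(NA_character_, nrow = n, ncol = length(inds),
                  dimnames = list(NULL, inds))
  passed_m <- matrix(FALSE, nrow = n, ncol = length(inds),
                     dimnames = list(NULL, inds))
  a1_m <- matrix(NA_character_, nrow = n, ncol = length(inds))
  a2_m <- matrix(NA_character_, nrow = n, ncol = length(inds))
  colnames(a1_m) <- colnames(a2_m) <- inds
  for (ind in inds) {
    sel <- st$individual == ind
    i <- match(key_v[sel], key_s)
    ok <- !is.na(i)   # drop decomposed records with no matching site
    i <- i[ok]
    state_m[i, ind] <- st$state[sel][ok]
    hom_m[i, ind] <- st$hom_base[sel][ok]
    passed_m[i, ind] <- st$passed[sel][ok]
    a1_m[i, ind] <- st$a1[sel][ok]
    a2_m[i, ind] <- st$a2[sel][ok]
  }

  is_den <- roster$group == "denisovan"
  is_nea <- roster$group == "neanderthal"

  carries_anc <- state_m == "ancestral_hom"
  if (carry_mode == "lenient")
    carries_anc <- carries_anc | state_m == "heterozygous"
  carries_der <- state_m == "derived_hom" | state_m == "heterozygous"
  carries_anc[is.na(carries_anc)] <- FALSE
  carries_der[is.na(carries_der)] <- FALSE
  missing_m <- is.na(state_m) | state_m == "missing"
  other_m <- !is.na(state_m) & state_m == "other_allele"

  n_anc <- rowSums(carries_anc)
  n_der <- rowSums(carries_der)
  n_missing <- rowSums(missing_m)
  n_nonmissing <- length(inds) - n_missing
  den_anc <- rowSums(carries_anc[, is_den, drop = FALSE]) > 0
  nea_anc <- rowSums(carries_anc[, is_nea, drop = FALSE])
  nea_der <- rowSums(carries_der[, is_nea, drop = FALSE])
  any_other <- rowSums(other_m) > 0
  all_nonmissing_anc <- rowSums(carries_anc) == n_nonmissing & n_nonmissing > 0

  f <- sites$f
  f_known <- !is.na(f)
  hf_min <- thresholds$hf_human_min

  # macaque-based quantities for unknown-ancestral sites
  mac <- sites$macaque_allele
  mac_is_ref <- !is.na(mac) & mac == sites$ref
  mac_is_alt <- !is.na(mac) & mac == sites$alt
  mac_ok <- mac_is_ref | mac_is_alt
  mac_count <- ifelse(mac_is_ref, sites$ref_count,
                      ifelse(mac_is_alt, sites$alt_count, NA_integer_))
  mac_freq <- mac_count / sites$total_count
  nonmac_freq <- 1 - mac_freq
  nonmac_base <- ifelse(mac_is_ref, sites$alt,
                        ifelse(mac_is_alt, sites$ref, NA_character_))
  all_hom_mac <- rowSums(!is.na(hom_m) & hom_m == mac) == length(inds) &
    rowSums(passed_m) == length(inds)
  carries_nonmac <- passed_m &
    (a1_m == nonmac_base | a2_m == nonmac_base)
  carries_nonmac[is.na(carries_nonmac)] <- FALSE
  n_carry_nonmac <- rowSums(carries_nonmac)

  unknown <- sites$ancestral == "unknown"

  p_h_fixed <- f_known & sites$ancestral_count == 0 & n_anc >= 2
  p_h_hf <- f_known & f > hf_min & den_anc & nea_anc >= 1
  above_hf <- f_known & f > hf_min
  p_ext_a <- above_hf & n_missing >= 1 & all_nonmissing_anc
  p_ext_b <- above_hf & any_other & n_der == 0
  nea_der_ok <- if (neanderthal_derived == "at_least_one") nea_der >= 1
                else nea_der == 1
  p_ext_c <- above_hf & den_anc & nea_der_ok
  p_ext_d <- unknown & mac_ok & all_hom_mac & !is.na(nonmac_freq) &
    nonmac_freq > hf_min

  p_a_fixed <- f_known & (1 - f) > thresholds$archaic_fixed_human_ancestral_min &
    n_der == length(inds) & n_missing == 0
  p_a_hf <- f_known & f < thresholds$archaic_hf_human_derived_max & n_der >= 2
  p_a_ext <- unknown & mac_ok & !is.na(nonmac_freq) &
    nonmac_freq < thresholds$archaic_hf_human_derived_max &
    n_carry_nonmac >= 2

  lineage <- rep("none", n)
  category <- rep("none", n)
  condition <- rep(NA_character_, n)
  adm <- sites$admitted

  assign_cat <- function(pred, lin, cat, cond = NA_character_) {
    sel <- adm & pred & category == "none" & lineage == "none"
    lineage[sel] <<- lin
    category[sel] <<- cat
    condition[sel] <<- cond
  }
  assign_cat(p_h_fixed, "human", "fixed")
  assign_cat(p_h_hf, "human", "high_frequency")
  assign_cat(p_ext_a, "human", "extended", "a")
  assign_cat(p_ext_b, "human", "extended", "b")
  assign_cat(p_ext_c, "human", "extended", "c")
  assign_cat(p_ext_d, "human", "extended", "d")
  assign_cat(p_a_fixed, "archaic", "fixed")
  assign_cat(p_a_hf, "archaic", "high_frequency")
  assign_cat(p_a_ext, "archaic", "extended", "macaque_match")

  out <- sites
  for (ind in inds) out[[paste0("state_", ind)]] <- state_m[, ind]
  out$lineage <- lineage
  out$category <- category
  out$extended_condition <- condition
  out
}

#' Category tallies with subset semantics
#'
#' Counts classified sites per lineage and category. The reported
#' high-frequency tally includes the fixed sites (fixed changes are a subset
#' of HF changes); the extended tally is reported on its own.
#'
#' @param classified Output of [classify_sites()].
#' @return A data.frame with columns `lineage`, `category`, `n`.
#' @export
category_counts <- function(classified) {
  count <- function(lin, cat) {
    if (cat == "high_frequency")
      sum(classified$lineage == lin &
            classified$category %in% c("fixed", "high_frequency"))
    else sum(classified$lineage == lin & classified$category == cat)
  }
  grid <- expand.grid(lineage = c("human", "archaic"),
                      category = c("fixed", "high_frequency", "extended"),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(count, grid$lineage, grid$category)
  grid
}
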