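# build one site plus genotypes from compact role specs and classify it
classify_one <- function(roles, ref_count, alt_count, ancestral = "ref",
                         macaque = NA_character_, ref = "A", alt = "G",
                         carry_mode = "strict", ...) {
  anc_base <- if (identical(ancestral, "ref")) ref else
    if (identical(ancestral, "alt")) alt else NA
  der_base <- if (identical(ancestral, "ref")) alt else
    if (identical(ancestral, "alt")) ref else NA
  oth <- setdiff(c("A", "C", "G", "T"), c(ref, alt))[1]
  pick <- function(role) switch(role,
    anc = c(anc_base, anc_base), der = c(der_base, der_base),
    het = c(anc_base, der_base), other = c(oth, oth),
    ref_hom = c(ref, ref), alt_hom = c(alt, alt),
    miss = c(NA_character_, NA_character_))
  al <- lapply(roles, pick)
  gt <- make_genotypes(ref = ref, alt = alt,
                       a1 = vapply(al, `[`, "", 1), a2 = vapply(al, `[`, "", 2),
                       dp = rep(30L, 3), gq = rep(50L, 3),
                       ad1 = rep(15L, 3), ad2 = rep(15L, 3))
  v <- filter_genotypes(gt)
  src <- if (identical(ancestral, "unknown")) "none" else "alignment"
  s <- make_site(ref = ref, alt = alt, ref_count = ref_count,
                 alt_count = alt_count, ancestral = ancestral,
                 ancestral_source = src, macaque = macaque)
  s <- admit_sites(s, v)
  classify_sites(s, v, carry_mode = carry_mode, ...)
}

test_that("polarization resolves derived allele and frequency", {
  s <- polarize_sites(make_site(ref_count = 5L, alt_count = 9995L,
                                ancestral = "ref"))
  expect_equal(s$derived, "G")
  expect_equal(s$f, 0.9995)
  # polarity flip: ancestral is the alt allele
  s <- polarize_sites(make_site(ref_count = 5L, alt_count = 9995L,
                                ancestral = "alt"))
  expect_equal(s$derived, "A")
  expect_equal(s$f, 0.0005)
  # unknown ancestral leaves the frequency undefined
  s <- polarize_sites(make_site(ancestral = "unknown",
                                ancestral_source = "none", macaque = "A"))
  expect_true(is.na(s$f) && is.na(s$derived))
})

test_that("per-individual archaic states are assigned from the alleles", {
  site <- admit_sites(make_site(),
                      filter_genotypes(make_genotypes()))
  site <- polarize_sites(site)
  gt <- make_genotypes(a1 = c("A", "A", "A"), a2 = c("A", "G", "T"),
                       dp = rep(30L, 3), ad1 = rep(15L, 3), ad2 = rep(15L, 3))
  st <- archaic_states(site, filter_genotypes(gt))
  expect_equal(st$state, c("ancestral_hom", "heterozygous", "other_allele"))
  # a failed genotype is missing regardless of its alleles
  gt$dp <- c(2L, 30L, 30L)
  st <- archaic_states(site, quiet(filter_genotypes(gt)))
  expect_equal(st$state[1], "missing")
})

test_that("human-lineage categories follow the catalog definitions", {
  # all humans derived; two of three archaics ancestral: fixed
  r <- classify_one(c("anc", "der", "anc"), ref_count = 0L,
                    alt_count = 10000L)
  expect_equal(c(r$lineage, r$category), c("human", "fixed"))
  # f = 0.95 with Denisovan and one Neanderthal ancestral: high frequency
  r <- classify_one(c("anc", "miss", "anc"), ref_count = 500L,
                    alt_count = 9500L)
  expect_equal(c(r$lineage, r$category), c("human", "high_frequency"))
  # Denisovan ancestral, Neanderthals derived: extended (c)
  r <- classify_one(c("anc", "der", "der"), ref_count = 500L,
                    alt_count = 9500L)
  expect_equal(c(r$category, r$extended_condition), c("extended", "c"))
  # below the 90% threshold: unclassified
  r <- classify_one(c("anc", "der", "anc"), ref_count = 1100L,
                    alt_count = 8900L)
  expect_equal(r$category, "none")
  # only one reliable genotype, ancestral: extended (a)
  r <- classify_one(c("miss", "anc", "miss"), ref_count = 500L,
                    alt_count = 9500L)
  expect_equal(c(r$category, r$extended_condition), c("extended", "a"))
  # a third allele in an archaic, no derived carrier: extended (b)
  r <- classify_one(c("other", "anc", "anc"), ref_count = 500L,
                    alt_count = 9500L)
  expect_equal(c(r$category, r$extended_condition), c("extended", "b"))
  # ancestral unknown but all archaics match the macaque base: extended (d)
  r <- classify_one(c("ref_hom", "ref_hom", "ref_hom"), ref_count = 500L,
                    alt_count = 9500L, ancestral = "unknown", macaque = "A")
  expect_equal(c(r$lineage, r$category, r$extended_condition),
               c("human", "extended", "d"))
})

test_that("archaic-lineage categories mirror the human ones", {
  # all three archaics derived, humans ancestral at more than 99.999%
  r <- classify_one(c("der", "der", "der"), ref_count = 999999L,
                    alt_count = 0L)
  expect_equal(c(r$lineage, r$category), c("archaic", "fixed"))
  # derived below 1% in humans, two archaics derived
  r <- classify_one(c("der", "der", "miss"), ref_count = 9950L,
                    alt_count = 50L)
  expect_equal(c(r$lineage, r$category), c("archaic", "high_frequency"))
  # 1/5008 is above the 0.001% fixed ceiling: high frequency, not fixed
  r <- classify_one(c("der", "der", "der"), ref_count = 5007L,
                    alt_count = 1L)
  expect_equal(r$category, "high_frequency")
  # unknown ancestral, macaque equals the major human allele,
  # archaics carry the rare allele
  r <- classify_one(c("alt_hom", "alt_hom", "ref_hom"), ref_count = 9980L,
                    alt_count = 20L, ancestral = "unknown", macaque = "A")
  expect_equal(c(r$lineage, r$category, r$extended_condition),
               c("archaic", "extended", "macaque_match"))
})

test_that("strict versus lenient ancestral carriage and condition (c) toggles", {
  # heterozygous Neanderthal: carries derived in strict mode, so HF fails
  r <- classify_one(c("anc", "het", "der"), ref_count = 500L,
                    alt_count = 9500L)
  expect_equal(c(r$category, r$extended_condition), c("extended", "c"))
  r <- classify_one(c("anc", "het", "der"), ref_count = 500L,
                    alt_count = 9500L, carry_mode = "lenient")
  expect_equal(r$category, "high_frequency")
  # exactly-one mode declassifies two derived Neanderthals from (c)
  r <- classify_one(c("anc", "der", "der"), ref_count = 500L,
                    alt_count = 9500L,
                    neanderthal_derived = "exactly_one")
  expect_equal(r$category, "none")
})

test_that("classification agrees with a brute-force oracle on random sites", {
  set.seed(20191)
  n <- 10000
  N <- 5008L
  bases <- c("A", "C", "G", "T")
  out_cat <- character(n)
  sites_l <- vector("list", n)
  gts_l <- vector("list", n)
  anc_known <- runif(n) < 0.75
  anc_is_ref <- runif(n) < 0.5
  derived_count <- sample(c(0L, sample(1:45, n, TRUE), N,
                            N - sample(1:500, n, TRUE),
                            sample(0:N, n, TRUE)), n, TRUE)
  for (i in seq_len(n)) {
    ref <- "A"; alt <- "G"
    anc <- if (!anc_known[i]) "unknown" else if (anc_is_ref[i]) "ref" else "alt"
    mac <- sample(c("A", "G", "T", NA), 1)
    dc <- derived_count[i]
    if (anc == "unknown") dc <- sample(0:N, 1)
    rc <- if (anc == "alt") dc else N - dc
    ac <- N - rc
    sites_l[[i]] <- make_site(pos = i, ref_count = rc, alt_count = ac,
                              ancestral = anc,
                              ancestral_source = if (anc == "unknown")
                                "none" else "alignment",
                              macaque = mac)
    a1 <- sample(c(bases[1:3], NA), 3, TRUE)
    a2 <- ifelse(is.na(a1), NA, sample(c(bases[1:3], NA), 3, TRUE))
    dp <- sample(c(2L, 30L), 3, TRUE, prob = c(0.15, 0.85))
    gts_l[[i]] <- data.frame(chrom = "chr1", pos = i, ref = ref, alt = alt,
                             individual = c("Denisovan", "AltaiNeanderthal",
                                            "VindijaNeanderthal"),
                             a1 = a1, a2 = a2, dp = dp, gq = 50L,
                             ad1 = 15L, ad2 = 15L, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites_l)
  gts <- do.call(rbind, gts_l)
  v <- quiet(filter_genotypes(gts))
  sites <- admit_sites(sites, v)
  cl <- classify_sites(sites, v)

  # oracle inputs recomputed directly from the raw data
  for (i in seq_len(n)) {
    s <- sites[i, ]
    g <- v[v$pos == i, ]
    anc_base <- if (s$ancestral == "ref") "A" else
      if (s$ancestral == "alt") "G" else NA
    der_base <- if (s$ancestral == "ref") "G" else
      if (s$ancestral == "alt") "A" else NA
    st <- vapply(1:3, function(j) {
      if (!g$passed[j] || is.na(g$a1[j]) || is.na(g$a2[j]))
        return(if (is.na(anc_base)) NA_character_ else "missing")
      if (is.na(anc_base)) return(NA_character_)
      aa <- c(g$a1[j], g$a2[j])
      if (all(aa == anc_base)) "ancestral_hom"
      else if (all(aa == der_base)) "derived_hom"
      else if (setequal(aa, c(anc_base, der_base)) && length(unique(aa)) == 2)
        "heterozygous"
      else "other_allele"
    }, character(1))
    f <- if (is.na(anc_base)) NA else
      (if (s$ancestral == "ref") s$alt_count else s$ref_count) / s$total_count
    anc_count <- if (is.na(anc_base)) NA else s$total_count -
      (if (s$ancestral == "ref") s$alt_count else s$ref_count)
    mac <- s$macaque_allele
    mac_ok <- !is.na(mac) && mac %in% c("A", "G")
    all_hom_mac <- mac_ok && all(g$passed) &&
      all(!is.na(g$a1) & !is.na(g$a2) & g$a1 == mac & g$a2 == mac)
    nonmac <- if (!mac_ok) NA else if (mac == "A") "G" else "A"
    nonmac_freq <- if (!mac_ok) NA else
      (if (mac == "A") s$alt_count else s$ref_count) / s$total_count
    n_carry_nonmac <- if (!mac_ok) 0 else
      sum(g$passed & !is.na(g$a1) & (g$a1 == nonmac | g$a2 == nonmac))
    expected <- oracle_classify(f, anc_count, st, all_hom_mac, nonmac_freq,
                                n_carry_nonmac, admitted = s$admitted)
    got <- c(cl$lineage[i], cl$category[i], cl$extended_condition[i])
    expect_equal(unname(got[1:2]), expected[1:2],
                 info = paste("site", i))
    if (!identical(got[1:2], expected[1:2])) break
  }

  # exclusivity: every site gets exactly one label pair
  expect_true(all((cl$lineage == "none") == (cl$category == "none")))
  expect_true(all(is.na(cl$extended_condition) ==
                    (cl$category != "extended")))
})

test_that("lowering the HF threshold never shrinks the human HF set", {
  set.seed(5)
  hf_set <- function(th) {
    cl <- classify_one(c("anc", "der", "anc"), ref_count = 800L,
                       alt_count = 9200L,
                       thresholds = classification_thresholds(
                         hf_human_min = th))
    cl$category %in% c("fixed", "high_frequency")
  }
  expect_true(hf_set(0.90))
  expect_true(hf_set(0.85))   # still in the set with a lower threshold
  expect_false(hf_set(0.95))  # tighter threshold may drop it
})

test_that("category tallies keep fixed as a subset of high frequency", {
  v <- default_verify()
  cc <- category_counts(v$classified)
  for (lin in c("human", "archaic")) {
    expect_lte(cc$n[cc$lineage == lin & cc$category == "fixed"],
               cc$n[cc$lineage == lin & cc$category == "high_frequency"])
  }
})
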