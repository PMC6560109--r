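test_that("the computed Grantham matrix reproduces the bundled matrix", {
  ref <- as.matrix(read.delim(system.file("extdata",
                                          "grantham_distance_matrix.tsv",
                                          package = "sncatalog"),
                              row.names = 1, check.names = FALSE))
  m <- grantham_matrix()
  expect_identical(dim(m), c(20L, 20L))
  m <- m[rownames(ref), colnames(ref)]
  expect_identical(unname(m), unname(ref))
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  # mean over the 190 unordered pairs is 100 within 1
  expect_lt(abs(mean(m[upper.tri(m)]) - 100), 1)
})

test_that("Grantham distances hit the published anchor values", {
  expect_equal(grantham("S", "S"), 0L)
  expect_equal(grantham("L", "R"), 102L)
  expect_equal(grantham("R", "L"), 102L)
  expect_equal(grantham("L", "I"), 5L)    # published minimum
  expect_equal(grantham("C", "W"), 215L)  # published maximum
  expect_error(grantham("L", "B"), "non-standard")
})

test_that("the deleteriousness flag fires strictly above 180", {
  rec <- data.frame(consequence_class = "missense",
                    grantham = c(181L, 180L, NA))
  out <- flag_deleterious(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$grantham, 181L)
  # records without scores are never flagged; empty input stays empty
  expect_equal(nrow(flag_deleterious(data.frame(consequence_class = "x"))), 0)
  expect_equal(nrow(flag_deleterious(rec[0, ])), 0)
  # SIFT / PolyPhen columns are honoured when supplied
  rec$sift <- c(NA, 0.01, NA)
  rec$polyphen <- c(NA, NA, 0.95)
  out <- flag_deleterious(rec)
  expect_setequal(out$flagged_by, c("grantham", "sift", "polyphen"))
})

test_that("coding consequences come from codon substitution", {
  # toy CDS: ATG CTG TGG AAA GCA TAA  (M L W K A *)
  toy <- make_toy_models()
  models <- toy$models
  # CTG -> CTA at codon 2 position 3: still Leu, synonymous
  s <- toy_site_at(toy, toy_cds_genomic(toy, 6), alt = "A")
  a <- annotate_sites(s, models)
  expect_equal(a$consequence_class, "synonymous")
  # CTG -> CGG at codon 2 position 2: Leu -> Arg missense with Grantham 102
  s <- toy_site_at(toy, toy_cds_genomic(toy, 5), alt = "G")
  a <- annotate_sites(s, models)
  expect_equal(a$consequence_class, "missense")
  expect_equal(c(a$ref_aa, a$alt_aa), c("L", "R"))
  expect_equal(a$grantham, 102L)
  # TGG -> TGA at codon 3: stop gained
  s <- toy_site_at(toy, toy_cds_genomic(toy, 9), alt = "A")
  expect_equal(annotate_sites(s, models)$consequence_class, "stop_gained")
  # ATG -> CTG at codon 1: start lost
  s <- toy_site_at(toy, toy_cds_genomic(toy, 1), alt = "C")
  expect_equal(annotate_sites(s, models)$consequence_class, "start_lost")
  # TAA -> TCA at the terminal codon: stop lost
  s <- toy_site_at(toy, toy_cds_genomic(toy, 17), alt = "C")
  expect_equal(annotate_sites(s, models)$consequence_class, "stop_lost")
})

test_that("splice, UTR, flank and window classes are position-driven", {
  toy <- make_toy_models()
  models <- toy$models
  # 1 bp into the intron: splice site; 3 bp in: intronic
  expect_equal(annotate_sites(toy_site_at(toy, toy$intron[1]),
                              models)$consequence_class, "splice_site")
  expect_equal(annotate_sites(toy_site_at(toy, toy$intron[1] + 1L),
                              models)$consequence_class, "splice_site")
  expect_equal(annotate_sites(toy_site_at(toy, toy$intron[1] + 2L),
                              models)$consequence_class, "intronic")
  expect_equal(annotate_sites(toy_site_at(toy, toy$intron[2]),
                              models)$consequence_class, "splice_site")
  # exonic non-CDS positions are UTRs, by strand
  expect_equal(annotate_sites(toy_site_at(toy, toy$gene_start + 5L),
                              models)$consequence_class, "five_prime_utr")
  expect_equal(annotate_sites(toy_site_at(toy, toy$gene_end - 5L),
                              models)$consequence_class, "three_prime_utr")
  # 4,999 bp upstream is upstream; 5,001 bp is intergenic
  expect_equal(annotate_sites(toy_site_at(toy, toy$gene_start - 4999L),
                              models)$consequence_class, "upstream")
  expect_equal(annotate_sites(toy_site_at(toy, toy$gene_start - 5001L),
                              models)$consequence_class, "intergenic")
  expect_equal(annotate_sites(toy_site_at(toy, toy$gene_end + 100L),
                              models)$consequence_class, "downstream")
  # regulatory features override intergenic
  feats <- GenomicRanges::GRanges("chrT", IRanges::IRanges(100, 120))
  feats$name <- "t1"
  feats$feature_class <- "tfbs"
  expect_equal(annotate_sites(toy_site_at(toy, 110L), models,
                              feats)$consequence_class, "tfbs")
})

test_that("a strand-mirrored gene yields identical consequence classes", {
  plus <- make_toy_models(strand = "+")
  minus <- make_toy_models(strand = "-")
  for (cds_pos in c(1L, 5L, 6L, 9L, 17L)) {
    tpl_alt <- c("C", "G", "A", "A", "C")[match(cds_pos,
                                                c(1L, 5L, 6L, 9L, 17L))]
    sp <- toy_site_at(plus, toy_cds_genomic(plus, cds_pos), alt = tpl_alt)
    sm_pos <- toy_cds_genomic(minus, cds_pos)
    sm <- data.frame(chrom = "chrT", pos = sm_pos,
                     ref = minus$genome[sm_pos],
                     alt = chartr("ACGT", "TGCA", tpl_alt),
                     stringsAsFactors = FALSE)
    ap <- annotate_sites(sp, plus$models)
    am <- annotate_sites(sm, minus$models)
    expect_equal(am$consequence_class, ap$consequence_class,
                 info = paste("cds position", cds_pos))
    expect_equal(am$ref_aa, ap$ref_aa)
    expect_equal(am$alt_aa, ap$alt_aa)
  }
})

test_that("catalog summaries honour subset semantics and ratios", {
  # seven missense and four synonymous human-HF sites on one chromosome
  mk_class <- function(n, chrom, cat) {
    data.frame(chrom = chrom, pos = seq_len(n), ref = "A", alt = "G",
               lineage = "human", category = cat,
               extended_condition = NA, admitted = TRUE,
               stringsAsFactors = FALSE)
  }
  cl <- rbind(mk_class(11, "chr21", "high_frequency"))
  cons <- data.frame(chrom = "chr21", pos = 1:11, ref = "A", alt = "G",
                     gene_id = "g", feature_id = "t",
                     consequence_class = c(rep("missense", 7),
                                           rep("synonymous", 4)),
                     ref_aa = NA, alt_aa = NA, grantham = NA,
                     stringsAsFactors = FALSE)
  summ <- summarize_catalog(cl, cons)
  r <- summ$chrom_ratios
  expect_equal(r$ratio[r$chrom == "chr21" & r$lineage == "human"], 1.75)
  expect_equal(summ$table[summ$table$consequence == "Non-synonymous",
                          "HF human"], 7)

  # on the default bundle: every fixed cell is at most its HF cell, and the
  # class counts are conservative (each site at most once per class)
  v <- default_verify()
  summ <- summarize_catalog(v$classified, v$consequences)
  tab <- summ$table
  for (lin in c("human", "archaic")) {
    expect_true(all(tab[[paste("Fixed", lin)]] <= tab[[paste("HF", lin)]]))
  }
  n_adm <- sum(v$classified$admitted &
                 v$classified$lineage %in% c("human", "archaic"))
  cat_cols <- grep("Fixed|Extended|HF", names(tab))
  expect_gte(sum(tab[tab$consequence != "All", c("Fixed human",
                                                 "Extended human",
                                                 "Fixed archaic",
                                                 "Extended archaic",
                                                 "HF human", "HF archaic")]),
             0)
  # planted fixed-human missense sites are all counted in their cell
  truth <- read_truth("truth_sites.tsv")
  n_fx_mis <- sum(truth$lineage == "human" & truth$category == "fixed" &
                    truth$consequence_class == "missense", na.rm = TRUE)
  expect_equal(tab[tab$consequence == "Non-synonymous", "Fixed human"],
               n_fx_mis)
})
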