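# Independent re-implementations used as oracles; deliberately written as
# direct transcriptions of the filter and category definitions, not sharing
# code with the package.

# Single-boolean-expression genotype filter oracle.
oracle_filter_pass <- function(a1, a2, dp, gq, ad1, ad2, dp_max,
                               dp_min = 5, gq_min = 20, min_minor = 0.2) {
  !(is.na(a1) || is.na(a2)) &&
    dp >= dp_min && dp <= dp_max && gq >= gq_min &&
    !(a1 != a2 && !is.na(ad1) && !is.na(ad2) && (ad1 + ad2) > 0 &&
        min(ad1, ad2) / (ad1 + ad2) < min_minor)
}

# Brute-force category oracle. Takes one site's worth of data: human derived
# frequency f (NA if ancestral unknown), ancestral count, per-individual
# states (Denisovan, AltaiNeanderthal, VindijaNeanderthal), and the
# macaque-pathway facts. Checks each category predicate directly, in the
# documented precedence order.
oracle_classify <- function(f, anc_count, states, all_hom_macaque,
                            nonmac_freq, n_carry_nonmac, admitted = TRUE) {
  if (!admitted) return(c("none", "none", NA))
  den <- states[1]; neas <- states[2:3]
  carries_anc <- function(s) !is.na(s) && s == "ancestral_hom"
  carries_der <- function(s) !is.na(s) && s %in% c("derived_hom",
                                                   "heterozygous")
  is_missing <- function(s) is.na(s) || s == "missing"
  n_anc <- sum(vapply(states, carries_anc, logical(1)))
  n_der <- sum(vapply(states, carries_der, logical(1)))
  n_miss <- sum(vapply(states, is_missing, logical(1)))
  n_other <- sum(!is.na(states) & states == "other_allele")
  unknown <- is.na(f)

  if (!unknown && anc_count == 0 && n_anc >= 2)
    return(c("human", "fixed", NA))
  if (!unknown && f > 0.9 && carries_anc(den) &&
      any(vapply(neas, carries_anc, logical(1))))
    return(c("human", "high_frequency", NA))
  if (!unknown && f > 0.9) {
    if (n_miss >= 1 && n_miss < 3 && n_anc == 3 - n_miss)
      return(c("human", "extended", "a"))
    if (n_other >= 1 && n_der == 0)
      return(c("human", "extended", "b"))
    if (carries_anc(den) && any(vapply(neas, carries_der, logical(1))))
      return(c("human", "extended", "c"))
  }
  if (unknown && isTRUE(all_hom_macaque) && !is.na(nonmac_freq) &&
      nonmac_freq > 0.9)
    return(c("human", "extended", "d"))
  if (!unknown && (1 - f) > 0.99999 && n_der == 3)
    return(c("archaic", "fixed", NA))
  if (!unknown && f < 0.01 && n_der >= 2)
    return(c("archaic", "high_frequency", NA))
  if (unknown && !is.na(nonmac_freq) && nonmac_freq < 0.01 &&
      n_carry_nonmac >= 2)
    return(c("archaic", "extended", "macaque_match"))
  c("none", "none", NA)
}

# G statistic by an algebraically different route:
# G = 2[ sum O ln O - sum r ln r - sum c ln c + N ln N ]
oracle_g <- function(x) {
  xlx <- function(v) sum(ifelse(v > 0, v * log(v), 0))
  2 * (xlx(as.vector(x)) - xlx(rowSums(x)) - xlx(colSums(x)) +
         xlx(sum(x)))
}

# Exact upper-tail hypergeometric p by enumeration of all draws of size n
# from a universe of size N with K category members: P(overlap >= k_obs).
oracle_hyper <- function(N, K, n, k_obs) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)  # categories are items 1..K
  mean(hits >= k_obs)
}

# ---- small builders -------------------------------------------------------

make_genotypes <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                           a1 = c("A", "A", "A"), a2 = c("G", "A", "A"),
                           dp = c(30L, 30L, 30L), gq = c(50L, 50L, 50L),
                           ad1 = c(15L, 30L, 30L), ad2 = c(15L, 0L, 0L)) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             individual = c("Denisovan", "AltaiNeanderthal",
                            "VindijaNeanderthal"),
             a1 = a1, a2 = a2, dp = dp, gq = gq, ad1 = ad1, ad2 = ad2,
             stringsAsFactors = FALSE)
}

make_site <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                      ref_count = 100L, alt_count = 9900L,
                      ancestral = "ref", ancestral_source = "alignment",
                      macaque = NA_character_) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             ref_count = ref_count, alt_count = alt_count,
             total_count = ref_count + alt_count,
             ancestral = ancestral, ancestral_source = ancestral_source,
             macaque_allele = macaque, stringsAsFactors = FALSE)
}

# Write a toy single-gene annotation (GFF3 + FASTA) and load it.
# The gene: 60 bp 5' UTR, split CDS (codons spelled by `cds_seq`), one
# intron, 60 bp 3' UTR, on the requested strand.
make_toy_models <- function(cds_seq = "ATGCTGTGGAAAGCATAA",
                            strand = "+", intron_len = 100L,
                            chrom_len = 30000L, gene_start = 10001L,
                            dir = tempfile("models")) {
  dir.create(dir, showWarnings = FALSE)
  set.seed(42)
  genome <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  cds_len <- nchar(cds_seq)
  stopifnot(cds_len %% 3 == 0)
  cdsA_len <- cds_len %/% 2
  utr <- 60L
  s <- gene_start
  cdsA <- c(s + utr, s + utr + cdsA_len - 1L)
  intron <- c(cdsA[2] + 1L, cdsA[2] + intron_len)
  cdsB <- c(intron[2] + 1L, intron[2] + (cds_len - cdsA_len))
  gend <- cdsB[2] + utr
  content <- if (strand == "+") cds_seq else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
  cv <- strsplit(content, "")[[1]]
  genome[cdsA[1]:cdsA[2]] <- cv[1:cdsA_len]
  genome[cdsB[1]:cdsB[2]] <- cv[(cdsA_len + 1L):cds_len]
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chrT = paste(genome, collapse = ""))), fa)
  phaseA <- if (strand == "+") 0L else (3L - (cds_len - cdsA_len) %% 3L) %% 3L
  phaseB <- if (strand == "+") (3L - cdsA_len %% 3L) %% 3L else 0L
  gff <- c("##gff-version 3",
           sprintf("chrT\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=toygene", s, gend,
                   strand),
           sprintf("chrT\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=toy.t;Parent=toygene",
                   s, gend, strand),
           sprintf("chrT\ttoy\texon\t%d\t%d\t.\t%s\t.\tID=e1;Parent=toy.t",
                   s, cdsA[2], strand),
           sprintf("chrT\ttoy\texon\t%d\t%d\t.\t%s\t.\tID=e2;Parent=toy.t",
                   cdsB[1], gend, strand),
           sprintf("chrT\ttoy\tCDS\t%d\t%d\t.\t%s\t%d\tID=c1;Parent=toy.t",
                   cdsA[1], cdsA[2], strand, phaseA),
           sprintf("chrT\ttoy\tCDS\t%d\t%d\t.\t%s\t%d\tID=c2;Parent=toy.t",
                   cdsB[1], cdsB[2], strand, phaseB))
  gf <- file.path(dir, "genes.gff3")
  writeLines(gff, gf)
  models <- read_gene_models(gf, fa)
  list(models = models, gene_start = s, gene_end = gend, cdsA = cdsA,
       cdsB = cdsB, intron = intron, strand = strand, cds_len = cds_len,
       cdsA_len = cdsA_len, genome = genome)
}

# genomic position of a spliced-CDS position in the toy gene
toy_cds_genomic <- function(toy, cds_pos) {
  asc <- if (toy$strand == "+") cds_pos else toy$cds_len - cds_pos + 1L
  if (asc <= toy$cdsA_len) toy$cdsA[1] + asc - 1L
  else toy$cdsB[1] + (asc - toy$cdsA_len) - 1L
}

toy_site_at <- function(toy, pos, alt = NULL) {
  ref <- toy$genome[pos]
  if (is.null(alt))
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  data.frame(chrom = "chrT", pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
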