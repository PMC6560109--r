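# Writers for the synthetic bundle and the end-to-end verifier.

write_bundle_files <- function(cfg, out_dir, genes, genome_vec, chrom_len,
                               site_rows, feature_rows, roles, trait_gene_ids,
                               baseline_idx) {
  inds <- c("Denisovan", "AltaiNeanderthal", "VindijaNeanderthal")
  ord <- order(vapply(site_rows, `[[`, character(1), "chrom"),
               vapply(site_rows, `[[`, numeric(1), "pos"))
  site_rows <- site_rows[ord]

  # ---- VCF ----
  vcf_lines <- c("##fileformat=VCFv4.2",
                 paste0("##contig=<ID=chr", seq_along(chrom_len),
                        ",length=", unname(chrom_len), ">"),
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
                 "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
                 "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", inds), collapse = "\t"))
  body <- vapply(site_rows, function(s) {
    gt_bases <- unlist(lapply(s$gts, function(g) g$a))
    extra <- setdiff(unique(gt_bases[!is.na(gt_bases)]), c(s$ref, s$alt))
    alleles <- c(s$ref, s$alt, extra)
    cols <- vapply(inds, function(ind) {
      g <- s$gts[[ind]]
      if (any(is.na(g$a))) gt <- "./."
      else gt <- paste(match(g$a, alleles) - 1L, collapse = "/")
      ad <- vapply(alleles, function(a) {
        if (a == s$ref) g$ad_ref
        else if (a == s$alt) g$ad_alt
        else if (!any(is.na(g$a)) && all(g$a == a)) g$dp
        else 0L
      }, integer(1))
      paste(gt, g$dp, g$gq, paste(ad, collapse = ","), sep = ":")
    }, character(1))
    paste(c(s$chrom, s$pos, ".", s$ref,
            paste(alleles[-1], collapse = ","), ".", ".", ".",
            "GT:DP:GQ:AD", cols), collapse = "\t")
  }, character(1))
  writeLines(c(vcf_lines, body), file.path(out_dir, "archaics.vcf"))

  # ---- frequency table, ancestral track ----
  freq <- data.frame(chrom = vapply(site_rows, `[[`, character(1), "chrom"),
                     pos = as.integer(vapply(site_rows, `[[`, numeric(1),
                                             "pos")),
                     ref = vapply(site_rows, `[[`, character(1), "ref"),
                     alt = vapply(site_rows, `[[`, character(1), "alt"),
                     ref_count = as.integer(vapply(site_rows, `[[`,
                                                   numeric(1), "ref_count")),
                     alt_count = as.integer(vapply(site_rows, `[[`,
                                                   numeric(1), "alt_count")),
                     stringsAsFactors = FALSE)
  write_tsv_file(freq, file.path(out_dir, "frequencies.tsv"))
  anc <- data.frame(chrom = freq$chrom, pos = freq$pos,
                    ancestral_allele = vapply(site_rows, function(s)
                      if (is.na(s$epo)) NA_character_ else s$epo,
                      character(1)),
                    macaque_allele = vapply(site_rows, `[[`, character(1),
                                            "mac"),
                    stringsAsFactors = FALSE)
  write_tsv_file(anc, file.path(out_dir, "ancestral.tsv"))

  # ---- genome FASTA ----
  seqs <- Biostrings::DNAStringSet(vapply(genome_vec, paste, character(1),
                                          collapse = ""))
  names(seqs) <- names(genome_vec)
  Biostrings::writeXStringSet(seqs, file.path(out_dir, "genome.fa"),
                              width = 70L)

  # ---- GFF3 ----
  gff <- c("##gff-version 3")
  for (g in genes) {
    tid <- paste0(g$gene_id, ".t1")
    attr_g <- paste0("ID=", g$gene_id, ";Name=", g$gene_id)
    cdsB_len <- g$cds_len - g$cdsA_len
    if (g$strand == "+") {
      phaseA <- 0L
      phaseB <- (3L - g$cdsA_len %% 3L) %% 3L
    } else {
      phaseB <- 0L
      phaseA <- (3L - cdsB_len %% 3L) %% 3L
    }
    line <- function(type, s, e, phase, attrs)
      paste(g$chrom, "sncatalog", type, s, e, ".", g$strand,
            if (is.na(phase)) "." else phase, attrs, sep = "\t")
    gff <- c(gff,
             line("gene", g$start, g$end, NA, attr_g),
             line("mRNA", g$start, g$end, NA,
                  paste0("ID=", tid, ";Parent=", g$gene_id)),
             line("exon", g$start, g$intron[1] - 1L, NA,
                  paste0("ID=", tid, ".e1;Parent=", tid)),
             line("exon", g$intron[2] + 1L, g$end, NA,
                  paste0("ID=", tid, ".e2;Parent=", tid)),
             line("CDS", g$cdsA[1], g$cdsA[2], phaseA,
                  paste0("ID=", tid, ".c;Parent=", tid)),
             line("CDS", g$cdsB[1], g$cdsB[2], phaseB,
                  paste0("ID=", tid, ".c;Parent=", tid)))
  }
  writeLines(gff, file.path(out_dir, "genes.gff3"))

  # ---- regulatory + sweep BED ----
  if (length(feature_rows) > 0) {
    fr <- do.call(rbind, feature_rows)
  } else {
    fr <- data.frame(chrom = character(0), start0 = integer(0),
                     end0 = integer(0), name = character(0),
                     class = character(0))
  }
  writeLines(paste(fr$chrom, fr$start0, fr$end0, fr$name, sep = "\t"),
             file.path(out_dir, "regulatory.bed"))
  writeLines(paste(fr$chrom, fr$start0, fr$end0, fr$class, sep = "\t"),
             file.path(out_dir, "regulatory_classes.tsv"))
  sweep_genes <- genes[seq_len(min(cfg$n_sweep_regions, length(genes)))]
  sw <- data.frame(chrom = vapply(sweep_genes, `[[`, character(1), "chrom"),
                   start0 = as.integer(vapply(sweep_genes,
                                              function(g) g$start - 1L,
                                              numeric(1))),
                   end0 = as.integer(vapply(sweep_genes,
                                            function(g) g$end + 10000L,
                                            numeric(1))),
                   name = paste0("sweep_", seq_along(sweep_genes)))
  writeLines(paste(sw$chrom, sw$start0, sw$end0, sw$name, sep = "\t"),
             file.path(out_dir, "sweeps.bed"))

  # ---- traits ----
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  other_pool <- setdiff(gene_ids[baseline_idx], trait_gene_ids)
  trait_rows <- data.frame(trait = "trait_enriched",
                           gene_id = trait_gene_ids,
                           stringsAsFactors = FALSE)
  for (k in seq_len(cfg$n_traits - 1L)) {
    trait_rows <- rbind(trait_rows, data.frame(
      trait = sprintf("trait_%02d", k),
      gene_id = sample(other_pool, cfg$genes_per_trait),
      stringsAsFactors = FALSE))
  }
  write_tsv_file(trait_rows, file.path(out_dir, "traits.tsv"))

  # ---- truth tables ----
  truth_sites <- data.frame(
    chrom = freq$chrom, pos = freq$pos, ref = freq$ref, alt = freq$alt,
    lineage = vapply(site_rows, `[[`, character(1), "lineage"),
    category = vapply(site_rows, `[[`, character(1), "category"),
    extended_condition = vapply(site_rows, function(s)
      if (is.na(s$extended_condition)) NA_character_ else s$extended_condition,
      character(1)),
    consequence_class = vapply(site_rows, function(s)
      if (is.na(s$class)) NA_character_ else s$class, character(1)),
    gene_id = vapply(site_rows, function(s)
      if (is.na(s$gene_id)) NA_character_ else s$gene_id, character(1)),
    filter_fate = vapply(site_rows, `[[`, character(1), "filter_fate"),
    stringsAsFactors = FALSE)
  write_tsv_file(truth_sites, file.path(out_dir, "truth_sites.tsv"))

  truth_genes <- data.frame(
    gene_id = gene_ids,
    role = roles,
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    start = as.integer(vapply(genes, `[[`, numeric(1), "start")),
    end = as.integer(vapply(genes, `[[`, numeric(1), "end")),
    strand = vapply(genes, `[[`, character(1), "strand"),
    length_bp = as.integer(vapply(genes, `[[`, numeric(1), "span")),
    density_enriched = roles == "density",
    ratio_enriched_human = roles == "ratio_human",
    ratio_enriched_archaic = roles == "ratio_archaic",
    trait_enriched = gene_ids %in% trait_gene_ids,
    stringsAsFactors = FALSE)
  write_tsv_file(truth_genes, file.path(out_dir, "truth_genes.tsv"))

  truth_traits <- data.frame(trait = unique(trait_rows$trait),
                             enriched = unique(trait_rows$trait) ==
                               "trait_enriched",
                             stringsAsFactors = FALSE)
  write_tsv_file(truth_traits, file.path(out_dir, "truth_traits.tsv"))

  files <- c("archaics.vcf", "frequencies.tsv", "ancestral.tsv", "genome.fa",
             "genes.gff3", "regulatory.bed", "regulatory_classes.tsv",
             "sweeps.bed", "traits.tsv", "truth_sites.tsv", "truth_genes.tsv",
             "truth_traits.tsv")
  manifest <- list(seed = cfg$seed,
                   config_hash = rlang::hash(unclass(cfg)),
                   n_sites = nrow(freq),
                   n_genes = length(genes),
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = out_dir, files = files, truth_sites = truth_sites,
                 truth_genes = truth_genes, truth_traits = truth_traits,
                 config = cfg))
}

# Read the regulatory BED and re-attach the per-feature classes the generator
# recorded alongside it.
read_bundle_features <- function(dir) {
  cls <- read.delim(file.path(dir, "regulatory_classes.tsv"), header = FALSE,
                    col.names = c("chrom", "start0", "end0", "class"),
                    stringsAsFactors = FALSE)
  gr <- read_bed_features(file.path(dir, "regulatory.bed"))
  if (length(gr) > 0) gr$feature_class <- cls$class
  gr
}

#' Run the pipeline on a synthetic bundle and compare with its truth
#'
#' Reads a bundle written by [simulate_bundle()], runs filtering,
#' classification and annotation with default settings, and diffs the
#' recovered site labels against the planted truth.
#'
#' @param dir Bundle directory.
#' @return A list with `per_category` (data.frame of truth versus recovered
#'   counts and agreement per category), `agreement` (overall fraction of
#'   truth sites with exactly recovered lineage, category and condition),
#'   `merged` (per-site truth/recovered comparison), `classified`,
#'   `consequences` and `filter_ok` (logical: all distractors failed for the
#'   planted reason).
#' @export
verify_bundle <- function(dir) {
  truth <- read_tsv_file(file.path(dir, "truth_sites.tsv"))
  truth$pos <- as.integer(truth$pos)
  roster <- archaic_roster()
  genotypes <- read_archaic_vcf(file.path(dir, "archaics.vcf"), roster)
  verdicts <- filter_genotypes(genotypes, roster = roster)
  sites <- build_sites(read_frequency_table(file.path(dir, "frequencies.tsv")),
                       read_ancestral_track(file.path(dir, "ancestral.tsv")))
  sites <- admit_sites(sites, verdicts)
  classified <- classify_sites(sites, verdicts, roster)
  models <- read_gene_models(file.path(dir, "genes.gff3"),
                             file.path(dir, "genome.fa"))
  features <- read_bundle_features(dir)
  adm <- classified[classified$admitted, , drop = FALSE]
  consequences <- annotate_sites(adm, models, features)

  key_t <- paste(truth$chrom, truth$pos, truth$ref, truth$alt)
  key_c <- paste(classified$chrom, classified$pos, classified$ref,
                 classified$alt)
  idx <- match(key_t, key_c)
  merged <- truth
  merged$rec_lineage <- classified$lineage[idx]
  merged$rec_category <- classified$category[idx]
  merged$rec_condition <- classified$extended_condition[idx]
  merged$rec_admitted <- classified$admitted[idx]
  same <- merged$lineage == merged$rec_lineage &
    merged$category == merged$rec_category &
    (is.na(merged$extended_condition) == is.na(merged$rec_condition)) &
    (is.na(merged$extended_condition) |
       merged$extended_condition == merged$rec_condition)
  merged$agree <- same

  lab <- function(lin, cat, cond)
    ifelse(cat == "none", "none",
           paste(lin, cat, ifelse(is.na(cond), "", cond), sep = ":"))
  truth_lab <- lab(merged$lineage, merged$category, merged$extended_condition)
  per_category <- do.call(rbind, lapply(sort(unique(truth_lab)), function(L) {
    sel <- truth_lab == L
    data.frame(label = L, n_truth = sum(sel), n_agree = sum(same[sel]),
               stringsAsFactors = FALSE)
  }))

  # distractor sites must fail for the planted reason
  dis <- truth[truth$filter_fate != "admitted", , drop = FALSE]
  filter_ok <- TRUE
  if (nrow(dis) > 0) {
    key_v <- paste(verdicts$chrom, verdicts$pos, verdicts$ref, verdicts$alt)
    for (i in seq_len(nrow(dis))) {
      kk <- paste(dis$chrom[i], dis$pos[i], dis$ref[i], dis$alt[i])
      rs <- verdicts$reason[key_v == kk]
      if (!all(rs == dis$filter_fate[i])) filter_ok <- FALSE
    }
    adm_flag <- classified$admitted[match(paste(dis$chrom, dis$pos, dis$ref,
                                                dis$alt), key_c)]
    if (any(adm_flag)) filter_ok <- FALSE
  }

  list(per_category = per_category,
       agreement = mean(same),
       merged = merged,
       classified = classified,
       consequences = consequences,
       filter_ok = filter_ok)
}
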