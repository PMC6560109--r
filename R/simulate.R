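#' Synthetic bundle configuration
#'
#' Parameters of the synthetic-data generator. The generator emulates the
#' logical inputs of the catalog pipeline -- an archaic VCF for three diploid
#' individuals with per-site depth and quality, a present-day human cohort
#' summarized as allele counts over `cohort_chromosomes` chromosomes
#' (5,008 by default, the scale of a thousand-genomes cohort, so fixation
#' versus near-fixation is expressible), an ancestral-allele track with
#' macaque fallback, a genome FASTA, GFF3 transcript models, regulatory and
#' sweep BED tracks and a trait-association table -- while planting known
#' site categories, consequence classes, filter failures, gene-level
#' enrichments and one enriched trait, all recorded in a truth table.
#'
#' @param seed Integer RNG seed (mandatory; all randomness flows from it).
#' @param n_chromosomes Number of synthetic chromosomes.
#' @param n_genes Number of baseline genes.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal parameters of the
#'   gene genomic span (defaults give a median span of 6 kb).
#' @param cohort_chromosomes Human cohort size in chromosomes (default 5008).
#' @param category_counts Named integer vector of extra planted sites per
#'   category (beyond the per-gene baseline), covering every category and
#'   extended condition.
#' @param background_per_gene Unclassified segregating sites per gene
#'   (intermediate frequency; default 30).
#' @param distractor_counts Named integer vector: sites whose archaic
#'   genotypes all fail exactly one filter, by reason.
#' @param baseline_hf_density Planted high-frequency changes per bp per
#'   lineage in baseline genes (default 5e-4, about 3 per median gene).
#' @param n_density_enriched Genes planted with `density_multiplier` times
#'   the baseline HF density on both lineages.
#' @param density_multiplier Density excess factor (default 10).
#' @param n_ratio_enriched Genes per lineage planted with
#'   `ratio_enriched_hf` HF changes on one lineage and none on the other.
#' @param ratio_enriched_hf HF changes in one-sided ratio genes (default 27).
#' @param ratio_gene_length Span of the one-sided ratio genes (default
#'   12000).
#' @param n_ratio_background Genes planted with balanced
#'   `ratio_background_hf` HF changes per lineage so the ratio ranking has an
#'   eligible population (default 24 genes of 12 + 12 changes).
#' @param ratio_background_hf Per-lineage HF changes in those genes.
#' @param n_traits,genes_per_trait Trait table shape; the first trait is the
#'   planted enriched one.
#' @param trait_excess_multiplier Excess factor of human HF missense changes
#'   in the enriched trait's genes (default 5).
#' @param plant_boundary_genes Plant the three eligibility-boundary genes
#'   (4,999 bp span; 24 segregating sites; 19 combined HF changes).
#' @param depth_mean,depth_size Negative-binomial read-depth model for
#'   passing genotypes.
#' @param n_sweep_regions Selective-sweep regions written to the sweep BED.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_chromosomes = 3L,
                              n_genes = 100L,
                              gene_length_meanlog = log(6000),
                              gene_length_sdlog = 0.35,
                              cohort_chromosomes = 5008L,
                              category_counts = c(fixed_human = 40L,
                                                  hf_human = 40L,
                                                  extended_a = 32L,
                                                  extended_b = 32L,
                                                  extended_c = 32L,
                                                  extended_d = 32L,
                                                  fixed_archaic = 40L,
                                                  hf_archaic = 40L,
                                                  extended_archaic = 32L),
                              background_per_gene = 30L,
                              distractor_counts = c(low_coverage = 10L,
                                                    high_coverage = 10L,
                                                    low_gq = 10L,
                                                    allele_imbalance = 10L),
                              baseline_hf_density = 5e-4,
                              n_density_enriched = 4L,
                              density_multiplier = 10,
                              n_ratio_enriched = 4L,
                              ratio_enriched_hf = 27L,
                              ratio_gene_length = 12000L,
                              n_ratio_background = 24L,
                              ratio_background_hf = 12L,
                              n_traits = 12L,
                              genes_per_trait = 12L,
                              trait_excess_multiplier = 5,
                              plant_boundary_genes = TRUE,
                              depth_mean = 40,
                              depth_size = 10,
                              n_sweep_regions = 2L) {
  if (missing(seed)) stop("simulation_config() requires an explicit seed")
  need_cats <- c("fixed_human", "hf_human", "extended_a", "extended_b",
                 "extended_c", "extended_d", "fixed_archaic", "hf_archaic",
                 "extended_archaic")
  stopifnot(all(need_cats %in% names(category_counts)),
            all(category_counts >= 0), all(distractor_counts >= 0),
            n_genes >= 20, cohort_chromosomes > 0)
  structure(as.list(environment()), class = "simulation_config")
}

# --- gene layout -----------------------------------------------------------

FLANK <- 6000L   # upstream/downstream buffer around each gene
FARGAP <- 4000L  # intergenic scratch region per gene slot
UTR_LEN <- 60L

plan_gene <- function(gene_id, chrom, start, span, strand) {
  intron_base <- max(300L, span %/% 8L)
  cds_len <- 3L * ((span - 2L * UTR_LEN - intron_base) %/% 3L)
  intron_len <- span - 2L * UTR_LEN - cds_len
  stopifnot(cds_len >= 60, intron_len >= 300)
  cdsA_len <- cds_len %/% 2L
  cdsB_len <- cds_len - cdsA_len
  utrA_end <- start + UTR_LEN - 1L
  cdsA_start <- utrA_end + 1L
  cdsA_end <- cdsA_start + cdsA_len - 1L
  intron_start <- cdsA_end + 1L
  intron_end <- intron_start + intron_len - 1L
  cdsB_start <- intron_end + 1L
  cdsB_end <- cdsB_start + cdsB_len - 1L
  utrB_start <- cdsB_end + 1L
  end <- utrB_start + UTR_LEN - 1L
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       start = start, end = end, span = end - start + 1L,
       utrA = c(start, utrA_end), utrB = c(utrB_start, end),
       cdsA = c(cdsA_start, cdsA_end), cdsB = c(cdsB_start, cdsB_end),
       intron = c(intron_start, intron_end),
       cds_len = cds_len, cdsA_len = cdsA_len,
       n_codons = cds_len %/% 3L)
}

# genomic position and strand-adjusted base for a spliced CDS position
cds_genomic <- function(g, cds_pos) {
  asc <- if (g$strand == "+") cds_pos else g$cds_len - cds_pos + 1L
  if (asc <= g$cdsA_len) g$cdsA[1] + asc - 1L
  else g$cdsB[1] + (asc - g$cdsA_len) - 1L
}

tx_base <- function(g, base) if (g$strand == "+") base else complement_base(base)

random_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  nonstop <- names(code)[code != "*" & names(code) != "ATG"]
  paste0("ATG",
         paste(sample(nonstop, n_codons - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

# codon templates: transcript-orientation codon, offset, transcript alt base
coding_templates <- list(
  synonymous = list(c("CTG", "3", "A"), c("GGC", "3", "T"), c("TCC", "3", "T")),
  missense = list(c("CTG", "2", "G"), c("GCA", "1", "T"), c("AAA", "1", "G")),
  stop_gained = list(c("TGG", "3", "A")),
  start_lost = list(c("ATG", "1", "C")),
  stop_lost = list(c("TAA", "2", "C")))

# --- site realization ------------------------------------------------------

hf_freq <- function(n) runif(n, 0.92, 0.995)

role_templates <- list(
  fixed_human = list(c("anc", "anc", "der"), c("anc", "der", "anc"),
                     c("anc", "anc", "anc"), c("der", "anc", "anc")),
  hf_human = list(c("anc", "der", "anc"), c("anc", "anc", "der")),
  extended_a = list(c("anc", "miss", "miss"), c("miss", "anc", "miss"),
                    c("miss", "miss", "anc"), c("miss", "anc", "anc")),
  extended_b = list(c("other", "anc", "anc"), c("other", "anc", "miss"),
                    c("other", "miss", "anc"), c("anc", "other", "other")),
  extended_c = list(c("anc", "der", "der"), c("anc", "het", "der")),
  extended_d = list(c("mac", "mac", "mac")),
  fixed_archaic = list(c("der", "der", "der")),
  hf_archaic = list(c("der", "der", "anc"), c("der", "anc", "der"),
                    c("miss", "der", "der"), c("der", "der", "miss")),
  extended_archaic = list(c("min", "min", "maj"), c("min", "maj", "min"),
                          c("maj", "min", "min"), c("min", "min", "min")),
  background = list(c("anc", "het", "der"), c("het", "anc", "anc"),
                    c("der", "anc", "het"), c("anc", "anc", "het")))

other_base_for <- function(ref, alt) setdiff(c("A", "C", "G", "T"),
                                             c(ref, alt))[1]

#' Generate a synthetic input bundle with planted truth
#'
#' Writes a complete, seeded synthetic input bundle to `out_dir`: archaic VCF
#' (`archaics.vcf`), human allele-count table (`frequencies.tsv`), ancestral
#' track (`ancestral.tsv`), genome (`genome.fa`), transcript models
#' (`genes.gff3`), regulatory and sweep BED tracks, trait associations
#' (`traits.tsv`), truth tables (`truth_sites.tsv`, `truth_genes.tsv`,
#' `truth_traits.tsv`) and a `manifest.json` with the seed and a config hash.
#' Every planted site satisfies its category's defining predicate and no
#' stronger one; distractor sites violate exactly one genotype filter; coding
#' sites are placed at engineered codons so the internal annotator recovers
#' the intended consequence class. Identical configurations produce
#' byte-identical bundles.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths, the truth tables and the
#'   configuration.
#' @export
simulate_bundle <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  # ---- gene roles and layout ----
  roles <- c(rep("baseline", cfg$n_genes),
             rep("density", cfg$n_density_enriched),
             rep("ratio_human", cfg$n_ratio_enriched),
             rep("ratio_archaic", cfg$n_ratio_enriched),
             rep("ratio_background", cfg$n_ratio_background),
             if (cfg$plant_boundary_genes) c("len_boundary", "seg_boundary",
                                             "combined_boundary"))
  n_total <- length(roles)
  draw_len <- function(n, lo = 3000) {
    pmin(30000L, pmax(as.integer(lo),
                      as.integer(round(exp(rnorm(n, cfg$gene_length_meanlog,
                                                 cfg$gene_length_sdlog))))))
  }
  target_len <- integer(n_total)
  target_len[roles == "baseline"] <- draw_len(cfg$n_genes)
  target_len[roles == "density"] <- draw_len(cfg$n_density_enriched,
                                             lo = 6000)
  target_len[roles %in% c("ratio_human", "ratio_archaic")] <-
    cfg$ratio_gene_length
  target_len[roles == "ratio_background"] <-
    draw_len(cfg$n_ratio_background, lo = 6000)
  target_len[roles == "len_boundary"] <- 4999L
  target_len[roles %in% c("seg_boundary", "combined_boundary")] <- 6000L

  chrom_of <- rep_len(paste0("chr", seq_len(cfg$n_chromosomes)), n_total)
  strand_of <- ifelse(seq_len(n_total) %% 4L == 0L, "-", "+")
  cursor <- setNames(rep(1L, cfg$n_chromosomes),
                     paste0("chr", seq_len(cfg$n_chromosomes)))
  genes <- vector("list", n_total)
  far_regions <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    ch <- chrom_of[i]
    far_start <- cursor[ch] + 200L
    gstart <- cursor[ch] + FARGAP + FLANK
    g <- plan_gene(sprintf("gene%03d", i), ch, gstart, target_len[i],
                   strand_of[i])
    g$role <- roles[i]
    genes[[i]] <- g
    far_regions[[i]] <- c(far_start, cursor[ch] + FARGAP - 200L)
    cursor[ch] <- g$end + FLANK + 1L
  }
  chrom_len <- cursor + 5000L

  # ---- genome ----
  bases <- c("A", "C", "G", "T")
  genome_vec <- lapply(chrom_len, function(n) sample(bases, n, replace = TRUE))
  write_ascending_cds <- function(g, content) {
    ch <- g$chrom
    v <- strsplit(content, "")[[1]]
    genome_vec[[ch]][g$cdsA[1]:g$cdsA[2]] <<- v[seq_len(g$cdsA_len)]
    genome_vec[[ch]][g$cdsB[1]:g$cdsB[2]] <<- v[(g$cdsA_len + 1L):g$cds_len]
  }
  for (g in genes) {
    spliced <- random_cds(g$n_codons)
    content <- if (g$strand == "+") spliced else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(spliced)))
    write_ascending_cds(g, content)
  }

  # ---- per-gene placement counters ----
  ctr <- lapply(genes, function(g)
    list(codon = 2L, codon_bg = g$n_codons - 1L, intron = 3L,
         utrA = 5L, utrB = 5L, up = 0L, down = 0L, far = 0L,
         splice = 0L, start_used = FALSE, stop_used = FALSE,
         tpl = c(synonymous = 0L, missense = 0L)))
  feature_rows <- list()   # regulatory BED entries

  patch_codon <- function(g, j, codon_t) {
    for (off in 1:3) {
      p <- cds_genomic(g, (j - 1L) * 3L + off)
      genome_vec[[g$chrom]][p] <<- tx_base(g, substr(codon_t, off, off))
    }
  }
  rotate_base <- function(b) bases[(match(b, bases)) %% 4L + 1L]

  place_site <- function(gi, class) {
    g <- genes[[gi]]
    c_ <- ctr[[gi]]
    res <- NULL
    coding <- class %in% names(coding_templates)
    if (class == "start_lost" && c_$start_used) class <- "missense"
    if (class == "stop_lost" && c_$stop_used) class <- "missense"
    if (coding || class %in% c("missense")) {
      if (class == "start_lost") {
        j <- 1L
        tpl <- coding_templates$start_lost[[1]]
        ctr[[gi]]$start_used <<- TRUE
      } else if (class == "stop_lost") {
        j <- g$n_codons
        tpl <- coding_templates$stop_lost[[1]]
        ctr[[gi]]$stop_used <<- TRUE
      } else {
        j <- c_$codon
        if (j >= c_$codon_bg) stop("infeasible placement: CDS of ",
                                   g$gene_id, " exhausted")
        ctr[[gi]]$codon <<- j + 1L
        tpls <- coding_templates[[class]]
        k <- if (class %in% names(c_$tpl)) {
          ctr[[gi]]$tpl[class] <<- c_$tpl[class] + 1L
          (c_$tpl[class] %% length(tpls)) + 1L
        } else 1L
        tpl <- tpls[[k]]
        patch_codon(g, j, tpl[1])
      }
      off <- as.integer(tpl[2])
      pos <- cds_genomic(g, (j - 1L) * 3L + off)
      ref <- tx_base(g, substr(tpl[1], off, off))
      alt <- tx_base(g, tpl[3])
      res <- list(pos = pos, ref = ref, alt = alt, gene_id = g$gene_id)
    } else if (class == "cds_background") {
      j <- c_$codon_bg
      if (j <= c_$codon) stop("infeasible placement: CDS of ", g$gene_id,
                              " exhausted")
      ctr[[gi]]$codon_bg <<- j - 1L
      pos <- cds_genomic(g, (j - 1L) * 3L + 1L)
      ref <- genome_vec[[g$chrom]][pos]
      res <- list(pos = pos, ref = ref, alt = rotate_base(ref),
                  gene_id = g$gene_id)
    } else if (class == "splice_site") {
      slots <- c(g$intron[1], g$intron[1] + 1L, g$intron[2] - 1L, g$intron[2])
      if (c_$splice >= 4L) return(place_site(gi, "intronic"))
      pos <- slots[c_$splice + 1L]
      ctr[[gi]]$splice <<- c_$splice + 1L
      ref <- genome_vec[[g$chrom]][pos]
      res <- list(pos = pos, ref = ref, alt = rotate_base(ref),
                  gene_id = g$gene_id)
    } else if (class == "intronic") {
      pos <- g$intron[1] + c_$intron
      if (pos > g$intron[2] - 3L)
        stop("infeasible placement: intron of ", g$gene_id, " exhausted")
      ctr[[gi]]$intron <<- c_$intron + 1L
      ref <- genome_vec[[g$chrom]][pos]
      res <- list(pos = pos, ref = ref, alt = rotate_base(ref),
                  gene_id = g$gene_id)
    } else if (class %in% c("five_prime_utr", "three_prime_utr")) {
      want_A <- (class == "five_prime_utr") == (g$strand == "+")
      side <- if (want_A) "utrA" else "utrB"
      offv <- c_[[side]]
      if (offv > UTR_LEN - 5L)
        stop("infeasible placement: UTR of ", g$gene_id, " exhausted")
      pos <- g[[side]][1] + offv
      ctr[[gi]][[side]] <<- offv + 1L
      ref <- genome_vec[[g$chrom]][pos]
      res <- list(pos = pos, ref = ref, alt = rotate_base(ref),
                  gene_id = g$gene_id)
    } else if (class %in% c("upstream", "downstream")) {
      left <- (class == "upstream") == (g$strand == "+")
      kk <- if (class == "upstream") c_$up else c_$down
      d <- 200L + 13L * kk
      if (d > 4990L) stop("infeasible placement: flank of ", g$gene_id,
                          " exhausted")
      pos <- if (left) g$start - d else g$end + d
      if (class == "upstream") ctr[[gi]]$up <<- kk + 1L
      else ctr[[gi]]$down <<- kk + 1L
      ref <- genome_vec[[g$chrom]][pos]
      res <- list(pos = pos, ref = ref, alt = rotate_base(ref),
                  gene_id = g$gene_id)
    } else {  # tfbs / mirna / regulatory_element / intergenic
      fr <- far_regions[[gi]]
      pos <- fr[1] + 37L * c_$far
      if (pos > fr[2]) stop("infeasible placement: intergenic region near ",
                            g$gene_id, " exhausted")
      ctr[[gi]]$far <<- c_$far + 1L
      ref <- genome_vec[[g$chrom]][pos]
      if (class %in% c("tfbs", "mirna", "regulatory_element")) {
        feature_rows[[length(feature_rows) + 1L]] <<-
          data.frame(chrom = g$chrom, start0 = pos - 11L, end0 = pos + 10L,
                     name = paste0(class, "_", g$chrom, "_", pos),
                     class = class, stringsAsFactors = FALSE)
      }
      res <- list(pos = pos, ref = ref, alt = rotate_base(ref),
                  gene_id = NA_character_)
    }
    res$chrom <- g$chrom
    if (is.null(res$class)) res$class <- class
    res
  }

  # ---- site plan ----
  plan <- list()
  add_plan <- function(gi, category, class, n = 1L, filter_fate = "admitted") {
    for (z in seq_len(n))
      plan[[length(plan) + 1L]] <<- list(gi = gi, category = category,
                                         class = class,
                                         filter_fate = filter_fate)
  }
  baseline_idx <- which(roles == "baseline")
  base_cycle <- c("missense", "synonymous", "intronic")
  n_hf_base <- integer(n_total)
  for (gi in baseline_idx) {
    g <- genes[[gi]]
    n_hf <- max(1L, as.integer(round(cfg$baseline_hf_density * g$span)))
    n_hf_base[gi] <- n_hf
    for (z in seq_len(n_hf)) {
      cl <- base_cycle[(z - 1L) %% 3L + 1L]
      add_plan(gi, "hf_human", cl)
      add_plan(gi, "hf_archaic", cl)
    }
  }
  # trait table and planted excess
  trait_gene_ids <- vapply(genes[baseline_idx[seq_len(cfg$genes_per_trait)]],
                           `[[`, character(1), "gene_id")
  for (gi in baseline_idx[seq_len(cfg$genes_per_trait)]) {
    base_mis <- ceiling(n_hf_base[gi] / 3)
    extra <- as.integer(round((cfg$trait_excess_multiplier - 1) * base_mis))
    add_plan(gi, "hf_human", "missense", n = extra)
  }
  # category extras round-robin over baseline genes
  extra_cycle <- c("missense", "synonymous", "five_prime_utr",
                   "three_prime_utr", "upstream", "downstream", "splice_site",
                   "intronic", "tfbs", "mirna", "regulatory_element",
                   "intergenic", "stop_gained", "missense", "start_lost",
                   "synonymous", "stop_lost", "intronic")
  cat_map <- c(fixed_human = "fixed_human", hf_human = "hf_human",
               extended_a = "extended_a", extended_b = "extended_b",
               extended_c = "extended_c", extended_d = "extended_d",
               fixed_archaic = "fixed_archaic", hf_archaic = "hf_archaic",
               extended_archaic = "extended_archaic")
  for (ci in seq_along(cat_map)) {
    cat <- names(cat_map)[ci]
    n_cat <- cfg$category_counts[[cat]]
    for (z in seq_len(n_cat)) {
      gi <- baseline_idx[(z - 1L + 7L * ci) %% length(baseline_idx) + 1L]
      add_plan(gi, cat,
               extra_cycle[(z - 1L + 5L * ci) %% length(extra_cycle) + 1L])
    }
  }
  # special genes
  for (gi in which(roles == "density")) {
    n_hf <- as.integer(round(cfg$density_multiplier * cfg$baseline_hf_density *
                               genes[[gi]]$span))
    add_plan(gi, "hf_human", "intronic", n = n_hf)
    add_plan(gi, "hf_archaic", "intronic", n = n_hf)
  }
  for (gi in which(roles == "ratio_human"))
    add_plan(gi, "hf_human", "intronic", n = cfg$ratio_enriched_hf)
  for (gi in which(roles == "ratio_archaic"))
    add_plan(gi, "hf_archaic", "intronic", n = cfg$ratio_enriched_hf)
  for (gi in which(roles == "ratio_background")) {
    add_plan(gi, "hf_human", "intronic", n = cfg$ratio_background_hf)
    add_plan(gi, "hf_archaic", "intronic", n = cfg$ratio_background_hf)
  }
  for (gi in which(roles == "len_boundary")) {
    add_plan(gi, "hf_human", "intronic", n = 10L)
    add_plan(gi, "hf_archaic", "intronic", n = 10L)
  }
  for (gi in which(roles == "combined_boundary"))
    add_plan(gi, "hf_human", "intronic", n = 19L)
  # background segregating sites
  for (gi in seq_len(n_total)) {
    n_bg <- if (roles[gi] == "seg_boundary") 20L else cfg$background_per_gene
    add_plan(gi, "background", "cds_background", n = n_bg)
  }
  if (cfg$plant_boundary_genes) {
    gi <- which(roles == "seg_boundary")
    add_plan(gi, "hf_human", "intronic", n = 4L)
  }
  # distractors (placed intergenic)
  for (rsn in names(cfg$distractor_counts)) {
    n_d <- cfg$distractor_counts[[rsn]]
    for (z in seq_len(n_d)) {
      gi <- ((z - 1L) %% n_total) + 1L
      add_plan(gi, "distractor", "intergenic", filter_fate = rsn)
    }
  }

  # ---- realize sites ----
  inds <- c("Denisovan", "AltaiNeanderthal", "VindijaNeanderthal")
  dp_cap <- c(Denisovan = 75L, AltaiNeanderthal = 105L,
              VindijaNeanderthal = 75L)
  draw_dp <- function(ind) {
    min(dp_cap[[ind]], max(5L, as.integer(rnbinom(1, size = cfg$depth_size,
                                                  mu = cfg$depth_mean))))
  }
  n_sites <- length(plan)
  site_rows <- vector("list", n_sites)
  var_counter <- new.env()
  next_variant <- function(cat) {
    k <- get0(cat, envir = var_counter, ifnotfound = 0L)
    assign(cat, k + 1L, envir = var_counter)
    k
  }
  N <- cfg$cohort_chromosomes

  for (si in seq_len(n_sites)) {
    p <- plan[[si]]
    loc <- place_site(p$gi, p$class)
    ref <- loc$ref; alt <- loc$alt
    anc_is_ref <- (si %% 2L) == 0L
    anc_base <- if (anc_is_ref) ref else alt
    der_base <- if (anc_is_ref) alt else ref
    cat <- p$category
    epo <- anc_base
    mac <- anc_base
    extended_condition <- NA_character_

    if (p$category == "distractor") {
      rsn <- p$filter_fate
      derived_count <- as.integer(round(0.5 * N))
      gts <- lapply(inds, function(ind) {
        dp <- switch(rsn,
                     low_coverage = sample(0:4, 1),
                     high_coverage = dp_cap[[ind]] + sample(1:20, 1),
                     draw_dp(ind))
        gq <- if (rsn == "low_gq") sample(0:19, 1) else sample(20:99, 1)
        if (rsn == "allele_imbalance")
          list(a = c(ref, alt), dp = 20L, gq = gq, ad_ref = 2L, ad_alt = 18L)
        else
          list(a = c(anc_base, anc_base), dp = dp, gq = gq,
               ad_ref = if (anc_is_ref) dp else 0L,
               ad_alt = if (anc_is_ref) 0L else dp)
      })
      lineage <- "none"; category <- "none"
    } else {
      v <- next_variant(cat)
      tplset <- role_templates[[cat]]
      roles_v <- tplset[[(v %% length(tplset)) + 1L]]
      if (cat == "extended_d") {
        # ancestral unknown; macaque equals the archaic allele; humans carry
        # the other allele at high frequency
        epo <- NA_character_
        mac <- anc_base
        derived_count <- as.integer(round(hf_freq(1) * N))
        derived_count <- min(derived_count, N - 1L)
      } else if (cat == "extended_archaic") {
        epo <- NA_character_
        mac <- anc_base   # equals the major human allele
        derived_count <- sample(1:45, 1)   # rare allele carried by archaics
      } else if (cat == "fixed_human") {
        derived_count <- N
      } else if (cat %in% c("hf_human", "extended_a", "extended_b",
                            "extended_c")) {
        derived_count <- min(as.integer(round(hf_freq(1) * N)), N - 1L)
      } else if (cat == "fixed_archaic") {
        derived_count <- 0L
      } else if (cat == "hf_archaic") {
        derived_count <- sample(1:45, 1)
      } else {  # background
        derived_count <- as.integer(round(runif(1, 0.2, 0.8) * N))
      }
      oth <- other_base_for(ref, alt)
      uncalled_miss <- (v %% 2L) == 0L
      gts <- lapply(seq_along(inds), function(ii) {
        ind <- inds[ii]
        role <- roles_v[ii]
        dp <- draw_dp(ind)
        gq <- sample(20:99, 1)
        a <- switch(role,
                    anc = c(anc_base, anc_base),
                    der = c(der_base, der_base),
                    het = c(anc_base, der_base),
                    other = c(oth, oth),
                    mac = c(mac, mac),
                    maj = c(anc_base, anc_base),
                    min = c(der_base, der_base),
                    miss = c(NA_character_, NA_character_))
        if (role == "miss") {
          if (uncalled_miss) return(list(a = a, dp = dp, gq = gq,
                                         ad_ref = 0L, ad_alt = 0L))
          return(list(a = c(anc_base, anc_base), dp = sample(0:4, 1), gq = gq,
                      ad_ref = 0L, ad_alt = 0L))
        }
        n_ref <- sum(a == ref)
        if (n_ref == 2L) list(a = a, dp = dp, gq = gq, ad_ref = dp,
                              ad_alt = 0L)
        else if (n_ref == 0L && all(a == alt))
          list(a = a, dp = dp, gq = gq, ad_ref = 0L, ad_alt = dp)
        else if (n_ref == 1L) {
          ar <- as.integer(round(dp * runif(1, 0.35, 0.65)))
          list(a = a, dp = dp, gq = gq, ad_ref = ar, ad_alt = dp - ar)
        } else list(a = a, dp = dp, gq = gq, ad_ref = 0L, ad_alt = 0L)
      })
      lineage <- switch(cat,
                        fixed_human = , hf_human = , extended_a = ,
                        extended_b = , extended_c = , extended_d = "human",
                        fixed_archaic = , hf_archaic = ,
                        extended_archaic = "archaic",
                        "none")
      category <- switch(cat,
                         fixed_human = , fixed_archaic = "fixed",
                         hf_human = , hf_archaic = "high_frequency",
                         extended_a = , extended_b = , extended_c = ,
                         extended_d = , extended_archaic = "extended",
                         "none")
      extended_condition <- switch(cat, extended_a = "a", extended_b = "b",
                                   extended_c = "c", extended_d = "d",
                                   extended_archaic = "macaque_match",
                                   NA_character_)
    }

    if (p$category == "distractor") {
      alt_count <- as.integer(round(0.5 * N))
      ref_count <- N - alt_count
    } else if (anc_is_ref) {
      alt_count <- derived_count
      ref_count <- N - derived_count
    } else {
      ref_count <- derived_count
      alt_count <- N - derived_count
    }

    site_rows[[si]] <- list(chrom = loc$chrom, pos = loc$pos,
                            ref = ref, alt = alt,
                            ref_count = ref_count, alt_count = alt_count,
                            epo = epo, mac = mac,
                            gts = setNames(gts, inds),
                            lineage = lineage, category = category,
                            extended_condition = extended_condition,
                            class = if (p$class == "cds_background")
                              NA_character_ else loc$class,
                            gene_id = loc$gene_id,
                            filter_fate = p$filter_fate)
  }

  write_bundle_files(cfg, out_dir, genes, genome_vec, chrom_len, site_rows,
                     feature_rows, roles, trait_gene_ids, baseline_idx)
}
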