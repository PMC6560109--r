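#' Run the full catalog pipeline on an input bundle
#'
#' Executes the whole analysis end to end on a directory laid out like a
#' [simulate_bundle()] bundle: genotype filtering, site admission, lineage
#' classification, consequence annotation, per-gene ranking, trait and sweep
#' enrichment, and the final catalog summary. Every stage writes a TSV plus a
#' JSON sidecar into `out_dir`; a run is fully reproducible from the inputs,
#' the configuration and the seed, and reruns with identical inputs produce
#' byte-identical outputs. A stage failure aborts with the stage name;
#' partial outputs are retained.
#'
#' @param input_dir Directory with `archaics.vcf`, `frequencies.tsv`,
#'   `ancestral.tsv`, `genome.fa`, `genes.gff3`, `regulatory.bed`,
#'   `sweeps.bed`, `traits.tsv`.
#' @param out_dir Output directory (created if needed).
#' @param roster An [archaic_roster()].
#' @param filter A [filter_thresholds()] object.
#' @param thresholds A [classification_thresholds()] object.
#' @param ranking A [ranking_config()] object.
#' @param enrichment An [enrichment_config()] object (its `rng_seed` drives
#'   all resampling).
#' @param carry_mode Passed to [classify_sites()].
#' @return Invisibly, a list with the main stage results.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         roster = archaic_roster(),
                         filter = filter_thresholds(),
                         thresholds = classification_thresholds(),
                         ranking = ranking_config(),
                         enrichment = enrichment_config(),
                         carry_mode = "strict") {
  need <- c("archaics.vcf", "frequencies.tsv", "ancestral.tsv", "genome.fa",
            "genes.gff3", "regulatory.bed", "sweeps.bed", "traits.tsv")
  missing_files <- need[!file.exists(file.path(input_dir, need))]
  if (length(missing_files) > 0)
    stop("missing input file(s): ", paste(missing_files, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sidecar <- function(name, obj)
    jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # filter
  verdicts <- stage("filter", {
    genotypes <- read_archaic_vcf(file.path(input_dir, "archaics.vcf"),
                                  roster)
    filter_genotypes(genotypes, filter, roster)
  })
  write_tsv_file(verdicts, file.path(out_dir, "verdicts.tsv"))
  sidecar("filter_summary",
          list(n_genotypes = nrow(verdicts),
               by_reason = as.list(table(verdicts$reason))))

  # classify
  classified <- stage("classify", {
    sites <- build_sites(
      read_frequency_table(file.path(input_dir, "frequencies.tsv")),
      read_ancestral_track(file.path(input_dir, "ancestral.tsv")))
    sites <- admit_sites(sites, verdicts)
    classify_sites(sites, verdicts, roster, thresholds,
                   carry_mode = carry_mode)
  })
  write_tsv_file(classified, file.path(out_dir, "classified.tsv"))
  cc <- category_counts(classified)
  sidecar("classification_summary",
          list(n_sites = nrow(classified),
               n_admitted = sum(classified$admitted),
               counts = split(cc$n, paste(cc$lineage, cc$category, sep = "_"))))

  # annotate
  ann <- stage("annotate", {
    models <- read_gene_models(file.path(input_dir, "genes.gff3"),
                               file.path(input_dir, "genome.fa"))
    features <- if (file.exists(file.path(input_dir,
                                          "regulatory_classes.tsv")))
      read_bundle_features(input_dir)
    else read_bed_features(file.path(input_dir, "regulatory.bed"))
    adm <- classified[classified$admitted, , drop = FALSE]
    list(models = models, features = features,
         consequences = annotate_sites(adm, models, features))
  })
  write_tsv_file(ann$consequences, file.path(out_dir, "consequences.tsv"))

  # rank
  rk <- stage("rank", {
    stats <- aggregate_gene_stats(classified, ann$models, ann$consequences)
    list(stats = stats,
         density_human = rank_by_density(stats, ranking, "human"),
         density_archaic = rank_by_density(stats, ranking, "archaic"),
         ratio = rank_by_ratio(stats, ranking),
         correlations = length_correlations(stats))
  })
  gs <- rk$stats
  gs$density_enriched_human <- gs$gene_id %in% rk$density_human$enriched
  gs$density_enriched_archaic <- gs$gene_id %in% rk$density_archaic$enriched
  gs$ratio_enriched_human <- gs$gene_id %in% rk$ratio$human_enriched
  gs$ratio_enriched_archaic <- gs$gene_id %in% rk$ratio$archaic_enriched
  write_tsv_file(gs, file.path(out_dir, "gene_stats.tsv"))
  sidecar("ranking_summary",
          list(correlations = as.list(rk$correlations),
               n_density_enriched_human = length(rk$density_human$enriched),
               n_density_enriched_archaic =
                 length(rk$density_archaic$enriched),
               n_ratio_enriched_human = length(rk$ratio$human_enriched),
               n_ratio_enriched_archaic = length(rk$ratio$archaic_enriched)))

  # enrich
  en <- stage("enrich", {
    traits <- read_trait_table(file.path(input_dir, "traits.tsv"))
    universe <- data.frame(gene_id = rk$stats$gene_id,
                           length_bp = rk$stats$length_bp,
                           stringsAsFactors = FALSE)
    hh <- setNames(rk$stats$hhmc_count, rk$stats$gene_id)
    aa <- setNames(rk$stats$ahmc_count, rk$stats$gene_id)
    gwas <- gwas_trait_enrichment(traits, hh, aa, universe, enrichment)
    sweeps <- read_bed_features(file.path(input_dir, "sweeps.bed"),
                                "sweep_region")
    hhmc_sites <- unique(ann$consequences[
      ann$consequences$consequence_class == "missense",
      c("chrom", "pos", "ref", "alt")])
    key <- paste(classified$chrom, classified$pos, classified$ref,
                 classified$alt)
    hk <- paste(hhmc_sites$chrom, hhmc_sites$pos, hhmc_sites$ref,
                hhmc_sites$alt)
    hum_hf <- classified$lineage == "human" &
      classified$category %in% c("fixed", "high_frequency")
    hhmc_cl <- classified[hum_hf & key %in% hk, , drop = FALSE]
    swept <- sweep_overlap(hhmc_cl, sweeps, enrichment$sweep_window_bp)
    list(gwas = gwas, swept = swept)
  })
  write_tsv_file(en$gwas, file.path(out_dir, "trait_enrichment.tsv"))
  write_tsv_file(en$swept[, c("chrom", "pos", "ref", "alt",
                              "sweep_distance")],
                 file.path(out_dir, "sweep_sites.tsv"))
  sidecar("enrichment_summary",
          list(n_traits_tested = length(unique(en$gwas$trait)),
               enriched_traits = en$gwas[en$gwas$enriched,
                                         c("trait", "lineage")],
               n_hhmc_near_sweeps = nrow(en$swept),
               seed = enrichment$rng_seed))

  # summarize
  summ <- stage("summarize", summarize_catalog(classified, ann$consequences))
  write_tsv_file(summ$table, file.path(out_dir, "catalog_summary.tsv"))
  write_tsv_file(summ$chrom_ratios, file.path(out_dir, "chrom_ratios.tsv"))
  sidecar("run", list(
    seed = enrichment$rng_seed,
    config_hash = rlang::hash(list(unclass(filter), unclass(thresholds),
                                   unclass(ranking), unclass(enrichment),
                                   carry_mode)),
    stages = c("filter", "classify", "annotate", "rank", "enrich",
               "summarize")))

  invisible(list(verdicts = verdicts, classified = classified,
                 consequences = ann$consequences, gene_stats = gs,
                 ranking = rk, enrichment = en, summary = summ))
}
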