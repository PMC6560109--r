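#' @importFrom utils read.delim write.table head combn
#' @importFrom stats pchisq phyper quantile rbinom rnbinom rnorm runif sd
#'   setNames wilcox.test p.adjust cor rpois
NULL

default_chromosomes <- function() {
  base <- c(as.character(1:22), "X")
  c(base, paste0("chr", base))
}

msg <- function(...) {
  if (isTRUE(getOption("sncatalog.quiet", FALSE))) return(invisible(NULL))
  message(...)
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = ".")
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = ".", ...)
}

#' Convert BED half-open coordinates to 1-based inclusive
#'
#' BED intervals are 0-based half-open; the internal convention (matching VCF
#' and GFF3) is 1-based inclusive. `bed_to_internal` converts a BED
#' (start, end) pair to internal coordinates and `internal_to_bed` is its
#' inverse.
#'
#' @param start,end Numeric vectors of interval bounds.
#' @return A data.frame with columns `start` and `end` in the other convention.
#' @export
bed_to_internal <- function(start, end) {
  stopifnot(all(start < end))
  data.frame(start = start + 1L, end = end)
}

#' @rdname bed_to_internal
#' @export
internal_to_bed <- function(start, end) {
  stopifnot(all(start <= end))
  data.frame(start = start - 1L, end = end)
}

# Vectorized GT parser: gts like "0/1", "1|1", "./.", "." (one per site);
# alleles_mat[site, k] holds the k-th allele (ref first). Returns an
# n x 2 matrix of bases.
parse_gt_alleles_by_site <- function(gts, alleles_mat) {
  n <- length(gts)
  out <- matrix(NA_character_, n, 2)
  ok <- which(!is.na(gts) & gts != ".")
  if (length(ok) == 0) return(out)
  parts <- strsplit(gts[ok], "[/|]")
  one <- vapply(parts, `[`, character(1), 1)
  two <- vapply(parts, function(p) if (length(p) > 1) p[2] else p[1],
                character(1))
  idx1 <- suppressWarnings(as.integer(one))
  idx2 <- suppressWarnings(as.integer(two))
  good1 <- !is.na(idx1)
  good2 <- !is.na(idx2)
  out[ok[good1], 1] <- alleles_mat[cbind(ok[good1], idx1[good1] + 1L)]
  out[ok[good2], 2] <- alleles_mat[cbind(ok[good2], idx2[good2] + 1L)]
  out
}

#' Read archaic genotypes from a VCF file
#'
#' Reads a VCF 4.x file containing per-sample `GT`, `DP`, `GQ` and optionally
#' `AD` fields for the archaic individuals and returns a long genotype table
#' with one row per (site, individual). Multi-allelic rows are decomposed into
#' one biallelic record per alternative allele; genotype alleles are reported
#' as bases, so a genotype carrying a different alternative allele than the
#' record's own is visible as a third base. Records lacking `DP` or `GQ` carry
#' the value 0. If either called allele is missing the genotype is missing as
#' a whole.
#'
#' @param path Path to a VCF file (plain text or bgzip).
#' @param roster An [archaic_roster()]; samples in the VCF must cover it.
#' @param on_extra_sample What to do with VCF samples absent from the roster:
#'   `"skip"` (default) or `"error"`.
#' @param keep_chromosomes Character vector of chromosome names to retain;
#'   defaults to the 22 autosomes and X (with and without a `chr` prefix) plus
#'   any synthetic `chr<N>` name. Use `NULL` to keep everything.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `individual`, `a1`, `a2`, `dp`, `gq`, `ad1`, `ad2`.
#' @export
read_archaic_vcf <- function(path, roster = archaic_roster(),
                             on_extra_sample = c("skip", "error"),
                             keep_chromosomes = default_chromosomes()) {
  on_extra_sample <- match.arg(on_extra_sample)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (nrow(fix) == 0) stop("empty VCF: ", path)
  samples <- colnames(gt)[-1]
  missing_samples <- setdiff(roster$individual, samples)
  if (length(missing_samples) > 0)
    stop("roster individuals absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  extra <- setdiff(samples, roster$individual)
  if (length(extra) > 0 && on_extra_sample == "error")
    stop("VCF samples not in roster: ", paste(extra, collapse = ", "))

  keep <- rep(TRUE, nrow(fix))
  if (!is.null(keep_chromosomes)) {
    keep <- fix$CHROM %in% keep_chromosomes
    if (any(!keep))
      msg("read_archaic_vcf: dropped ", sum(!keep),
          " records on unrequested chromosomes")
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (nrow(fix) == 0) stop("no VCF records left after chromosome filter")

  n_sites <- nrow(fix)
  alts_list <- strsplit(fix$ALT, ",")
  n_alt <- lengths(alts_list)
  max_allele <- max(n_alt) + 1L
  alleles_mat <- matrix(NA_character_, n_sites, max_allele)
  alleles_mat[, 1] <- fix$REF
  for (j in seq_len(max_allele - 1L))
    alleles_mat[n_alt >= j, j + 1L] <-
      vapply(alts_list[n_alt >= j], `[`, character(1), j)

  na_mat <- function() matrix(NA_character_, sum(keep), length(samples),
                              dimnames = list(NULL, samples))
  ext <- function(el, num = FALSE) {
    tryCatch(vcfR::extract.gt(v, element = el,
                              as.numeric = num)[keep, , drop = FALSE],
             error = function(e) na_mat())
  }
  gt_m <- ext("GT")
  dp_m <- ext("DP", num = TRUE)
  gq_m <- ext("GQ", num = TRUE)
  ad_m <- ext("AD")
  if (n_sites == 1) {
    fixmat <- function(m) matrix(m, nrow = 1,
                                 dimnames = list(NULL, samples))
    gt_m <- fixmat(gt_m); dp_m <- fixmat(dp_m)
    gq_m <- fixmat(gq_m); ad_m <- fixmat(ad_m)
  }

  # expansion: one biallelic record per ALT allele
  rec_site <- rep(seq_len(n_sites), n_alt)
  rec_alt <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  n_rec <- length(rec_site)

  per_ind <- lapply(roster$individual, function(ind) {
    gts <- gt_m[, ind]
    al <- parse_gt_alleles_by_site(gts, alleles_mat)
    dp <- dp_m[, ind]
    gq <- gq_m[, ind]
    ad_parts <- strsplit(ifelse(is.na(ad_m[, ind]), "", ad_m[, ind]), ",")
    ad_mat <- matrix(NA_integer_, n_sites, max_allele)
    for (j in seq_len(max_allele)) {
      has <- lengths(ad_parts) >= j
      ad_mat[has, j] <- suppressWarnings(
        as.integer(vapply(ad_parts[has], `[`, character(1), j)))
    }
    data.frame(chrom = fix$CHROM[rec_site],
               pos = as.integer(fix$POS[rec_site]),
               ref = fix$REF[rec_site],
               alt = alleles_mat[cbind(rec_site, rec_alt + 1L)],
               individual = ind,
               a1 = al[rec_site, 1], a2 = al[rec_site, 2],
               dp = as.integer(ifelse(is.na(dp[rec_site]), 0,
                                      dp[rec_site])),
               gq = as.integer(ifelse(is.na(gq[rec_site]), 0,
                                      gq[rec_site])),
               ad1 = ad_mat[cbind(rec_site, rep(1L, n_rec))],
               ad2 = ad_mat[cbind(rec_site, rec_alt + 1L)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_ind)
  # restore interleaved order (site-major, individual-minor)
  out <- out[order(rep(seq_len(n_rec), length(per_ind)),
                   rep(seq_along(per_ind), each = n_rec)), , drop = FALSE]
  # a genotype with either allele missing is missing as a whole
  half <- xor(is.na(out$a1), is.na(out$a2))
  if (any(half)) {
    out$a1[half] <- NA_character_
    out$a2[half] <- NA_character_
  }
  rownames(out) <- NULL
  out
}

#' Read a human allele-count table
#'
#' Reads a TSV with columns `chrom`, `pos`, `ref`, `alt`, `ref_count`,
#' `alt_count` summarizing a present-day human cohort as allele counts at each
#' biallelic position (dbSNP-style). Rows with a zero total count are skipped
#' with a warning; duplicated (chrom, pos, ref, alt) keys are an error.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the six columns above plus `total_count`.
#' @export
read_frequency_table <- function(path) {
  df <- read_tsv_file(path)
  need <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  if (!all(need %in% names(df)))
    stop("frequency table must have columns: ", paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df$ref_count <- as.integer(df$ref_count)
  df$alt_count <- as.integer(df$alt_count)
  if (any(df$ref_count < 0 | df$alt_count < 0))
    stop("negative allele counts in frequency table")
  key <- paste(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate frequency-table entry at: ", d)
  }
  tot <- df$ref_count + df$alt_count
  if (any(tot == 0)) {
    warning("skipping ", sum(tot == 0),
            " frequency-table rows with zero total count")
    df <- df[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  df$total_count <- tot
  rownames(df) <- NULL
  df
}

#' Read an ancestral-allele track
#'
#' Reads a TSV with columns `chrom`, `pos`, `ancestral_allele` (the inferred
#' ancestral base from a multiple-genome alignment, `.` when unavailable) and
#' `macaque_allele` (the macaque reference base used as outgroup fallback,
#' `.` when unavailable).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the four columns; missing alleles are `NA`.
#' @export
read_ancestral_track <- function(path) {
  df <- read_tsv_file(path)
  need <- c("chrom", "pos", "ancestral_allele", "macaque_allele")
  if (!all(need %in% names(df)))
    stop("ancestral track must have columns: ", paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df
}

#' Read regulatory or sweep features from a BED file
#'
#' Reads a BED4 file (0-based half-open) and returns features in the internal
#' 1-based inclusive convention as a `GRanges`, labelled with a feature class
#' (for example `"tfbs"`, `"mirna"`, `"regulatory_element"` or
#' `"sweep_region"`).
#'
#' @param path Path to a BED file.
#' @param feature_class Class label attached to every feature.
#' @return A `GRanges` with metadata columns `name` and `feature_class`.
#' @export
read_bed_features <- function(path, feature_class = "regulatory_element") {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) && length(gr) > 0)
    gr$name <- paste0(feature_class, "_", seq_along(gr))
  if (is.null(gr$name)) gr$name <- character(0)
  gr$feature_class <- rep(feature_class, length(gr))
  gr
}

#' Read a trait-gene association table
#'
#' Reads a TSV with columns `trait` and `gene_id` (one association per row,
#' GWAS-catalog style) and de-duplicates pairs.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with unique (trait, gene_id) pairs.
#' @export
read_trait_table <- function(path) {
  df <- read_tsv_file(path)
  if (!all(c("trait", "gene_id") %in% names(df)))
    stop("trait table must have columns trait, gene_id")
  df <- unique(df[, c("trait", "gene_id")])
  rownames(df) <- NULL
  df
}

#' Read gene models from GFF3 and a genome FASTA
#'
#' Imports transcript models (gene, mRNA, exon, CDS features) from a GFF3 file
#' and the corresponding genome sequence from a FASTA file. Transcripts whose
#' summed CDS length is not a multiple of three after phase adjustment are
#' dropped with a message; CDS features without a parent transcript are
#' skipped with a warning.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param fasta_path Path to the genome FASTA.
#' @return An object of class `gene_models`: a list with data.frames `genes`,
#'   `transcripts`, `exons`, `cds` and a `DNAStringSet` `genome`.
#' @export
read_gene_models <- function(gff3_path, fasta_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  first_parent <- function(p) vapply(p, function(x)
    if (length(x) == 0) NA_character_ else x[1], character(1))

  g <- df[df$type == "gene", , drop = FALSE]
  genes <- data.frame(gene_id = g$ID,
                      gene_name = if (!is.null(g$Name)) g$Name else g$ID,
                      chrom = as.character(g$seqnames),
                      start = g$start, end = g$end,
                      strand = as.character(g$strand),
                      stringsAsFactors = FALSE)
  t <- df[df$type == "mRNA", , drop = FALSE]
  transcripts <- data.frame(transcript_id = t$ID,
                            gene_id = first_parent(t$Parent),
                            chrom = as.character(t$seqnames),
                            start = t$start, end = t$end,
                            strand = as.character(t$strand),
                            stringsAsFactors = FALSE)
  e <- df[df$type == "exon", , drop = FALSE]
  exons <- data.frame(transcript_id = first_parent(e$Parent),
                      start = e$start, end = e$end,
                      stringsAsFactors = FALSE)
  cd <- df[df$type == "CDS", , drop = FALSE]
  cds <- data.frame(transcript_id = first_parent(cd$Parent),
                    start = cd$start, end = cd$end,
                    phase = if (!is.null(cd$phase)) as.integer(cd$phase) else 0L,
                    stringsAsFactors = FALSE)
  orphan <- !is.na(cds$transcript_id) &
    !(cds$transcript_id %in% transcripts$transcript_id)
  orphan <- orphan | is.na(cds$transcript_id)
  if (any(orphan)) {
    warning("skipping ", sum(orphan), " CDS features without parent transcript")
    cds <- cds[!orphan, , drop = FALSE]
  }
  # CDS length must be a multiple of 3 after phase adjustment
  if (nrow(cds) > 0) {
    len <- tapply(cds$end - cds$start + 1L, cds$transcript_id, sum)
    # phase of the 5'-most CDS segment, strand-aware
    strand_of <- setNames(transcripts$strand, transcripts$transcript_id)
    ph <- vapply(names(len), function(id) {
      seg <- cds[cds$transcript_id == id, , drop = FALSE]
      if (identical(strand_of[[id]], "-")) seg$phase[which.max(seg$start)]
      else seg$phase[which.min(seg$start)]
    }, integer(1))
    bad <- names(len)[(len - ph) %% 3L != 0]
    if (length(bad) > 0) {
      msg("read_gene_models: dropping ", length(bad),
          " transcript(s) with CDS length not a multiple of 3")
      cds <- cds[!(cds$transcript_id %in% bad), , drop = FALSE]
      transcripts <- transcripts[!(transcripts$transcript_id %in% bad), , drop = FALSE]
    }
  }
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, cds = cds, genome = genome),
            class = "gene_models")
}

#' Assemble site observations from a frequency table and ancestral track
#'
#' Joins the human allele-count table with the ancestral-allele track to
#' produce the per-site observation table used downstream. The ancestral state
#' is resolved against the site's ref/alt alleles: it becomes `"ref"` or
#' `"alt"` when the alignment-inferred ancestral base matches one of them, and
#' `"unknown"` otherwise (including when it matches neither allele, which is
#' tallied). With `use_macaque_fallback = TRUE` the macaque base is promoted
#' to the ancestral state at positions where the alignment gives none;
#' by default it is kept as a separate column feeding the extended
#' classification pathways.
#'
#' @param freq Frequency table from [read_frequency_table()].
#' @param ancestral Ancestral track from [read_ancestral_track()].
#' @param use_macaque_fallback Promote the macaque allele to ancestral when
#'   the alignment allele is missing (default `FALSE`).
#' @return A site table: one row per biallelic site with `chrom`, `pos`,
#'   `ref`, `alt`, counts, `ancestral` (`"ref"`, `"alt"` or `"unknown"`),
#'   `ancestral_source` (`"alignment"`, `"macaque"` or `"none"`) and
#'   `macaque_allele`.
#' @export
build_sites <- function(freq, ancestral, use_macaque_fallback = FALSE) {
  key_f <- paste(freq$chrom, freq$pos)
  key_a <- paste(ancestral$chrom, ancestral$pos)
  idx <- match(key_f, key_a)
  epo <- ancestral$ancestral_allele[idx]
  mac <- ancestral$macaque_allele[idx]
  anc <- rep("unknown", nrow(freq))
  src <- rep("none", nrow(freq))
  anc[!is.na(epo) & epo == freq$ref] <- "ref"
  anc[!is.na(epo) & epo == freq$alt] <- "alt"
  src[anc != "unknown"] <- "alignment"
  mismatch <- !is.na(epo) & epo != freq$ref & epo != freq$alt
  if (any(mismatch))
    msg("build_sites: ", sum(mismatch),
        " sites whose alignment ancestral allele matches neither ref nor alt",
        " (set to unknown)")
  if (use_macaque_fallback) {
    fb <- anc == "unknown" & !is.na(mac) & (mac == freq$ref | mac == freq$alt)
    anc[fb & mac == freq$ref] <- "ref"
    anc[fb & mac == freq$alt] <- "alt"
    src[fb] <- "macaque"
  }
  out <- freq
  out$ancestral <- anc
  out$ancestral_source <- src
  out$macaque_allele <- mac
  out
}
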