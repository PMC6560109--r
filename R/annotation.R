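complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

# Precompute per-transcript structures used by the annotator: sorted exon and
# CDS intervals, the spliced CDS sequence (5'->3') and its codon translation.
prepare_transcripts <- function(models) {
  tx <- models$transcripts
  out <- vector("list", nrow(tx))
  names(out) <- tx$transcript_id
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    strand <- tx$strand[i]
    ex <- models$exons[models$exons$transcript_id == id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cd <- models$cds[models$cds$transcript_id == id, , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    chrom <- tx$chrom[i]
    seq <- models$genome[[chrom]]
    spliced <- NULL
    if (nrow(cd) > 0) {
      segs <- lapply(seq_len(nrow(cd)), function(k)
        Biostrings::subseq(seq, cd$start[k], cd$end[k]))
      spliced <- do.call(Biostrings::xscat, segs)
      if (strand == "-")
        spliced <- Biostrings::reverseComplement(spliced)
    }
    out[[i]] <- list(transcript_id = id, gene_id = tx$gene_id[i],
                     chrom = chrom, strand = strand,
                     start = tx$start[i], end = tx$end[i],
                     exons = ex, cds = cd, spliced = spliced)
  }
  out
}

# Position of a genomic coordinate within the spliced CDS (1-based), or NA.
cds_position <- function(tr, pos) {
  cd <- tr$cds
  if (nrow(cd) == 0) return(NA_integer_)
  hit <- which(pos >= cd$start & pos <= cd$end)
  if (length(hit) == 0) return(NA_integer_)
  lens <- cd$end - cd$start + 1L
  if (tr$strand == "+") {
    before <- if (hit > 1) sum(lens[seq_len(hit - 1)]) else 0L
    before + (pos - cd$start[hit]) + 1L
  } else {
    after <- if (hit < nrow(cd)) sum(lens[seq(hit + 1, nrow(cd))]) else 0L
    after + (cd$end[hit] - pos) + 1L
  }
}

classify_in_transcript <- function(tr, pos, ref, alt, params) {
  rec <- function(class, ref_aa = NA_character_, alt_aa = NA_character_,
                  gr = NA_integer_) {
    list(class = class, ref_aa = ref_aa, alt_aa = alt_aa, grantham = gr)
  }
  # coding?
  cpos <- cds_position(tr, pos)
  if (!is.na(cpos)) {
    codon_idx <- (cpos - 1L) %/% 3L + 1L
    offset <- (cpos - 1L) %% 3L + 1L
    codon_start <- (codon_idx - 1L) * 3L + 1L
    codon <- as.character(Biostrings::subseq(tr$spliced, codon_start,
                                             codon_start + 2L))
    ref_t <- if (tr$strand == "+") ref else complement_base(ref)
    alt_t <- if (tr$strand == "+") alt else complement_base(alt)
    if (substr(codon, offset, offset) != ref_t) {
      warning("reference mismatch in CDS of ", tr$transcript_id,
              " at position ", pos, "; falling back to intronic")
      return(rec("intronic"))
    }
    alt_codon <- codon
    substr(alt_codon, offset, offset) <- alt_t
    code <- Biostrings::GENETIC_CODE
    ref_aa <- code[[codon]]
    alt_aa <- code[[alt_codon]]
    if (is.null(ref_aa) || is.null(alt_aa)) return(rec("intronic"))
    if (ref_aa == alt_aa) return(rec("synonymous", ref_aa, alt_aa))
    if (alt_aa == "*") return(rec("stop_gained", ref_aa, alt_aa))
    if (ref_aa == "*") return(rec("stop_lost", ref_aa, alt_aa))
    if (codon_idx == 1L && ref_aa == "M")
      return(rec("start_lost", ref_aa, alt_aa))
    rec("missense", ref_aa, alt_aa, grantham(ref_aa, alt_aa, params))
  } else if (pos >= tr$start && pos <= tr$end) {
    ex <- tr$exons
    in_exon <- any(pos >= ex$start & pos <= ex$end)
    if (!in_exon) {
      # intron: first/last two intronic bases are splice sites
      ends <- ex$end[-nrow(ex)]
      starts <- ex$start[-1]
      splice <- any(pos >= ends + 1L & pos <= ends + 2L) ||
        any(pos >= starts - 2L & pos <= starts - 1L)
      if (splice) return(rec("splice_site"))
      return(rec("intronic"))
    }
    cd <- tr$cds
    if (nrow(cd) == 0) return(rec("intronic"))
    cds_lo <- min(cd$start)
    cds_hi <- max(cd$end)
    if (pos < cds_lo)
      return(rec(if (tr$strand == "+") "five_prime_utr" else "three_prime_utr"))
    if (pos > cds_hi)
      return(rec(if (tr$strand == "+") "three_prime_utr" else "five_prime_utr"))
    rec("intronic")
  } else {
    # flanking
    if (pos < tr$start) {
      rec(if (tr$strand == "+") "upstream" else "downstream")
    } else {
      rec(if (tr$strand == "+") "downstream" else "upstream")
    }
  }
}

#' Annotate sites with functional consequences
#'
#' A minimal variant consequence annotator: every site is compared against all
#' transcript models and regulatory features it overlaps, producing one record
#' per (site, transcript/feature) pair. Coding consequences are computed by
#' codon substitution against the spliced CDS using the standard genetic code,
#' with strand-aware complementation; the first and last two bases of each
#' intron are splice sites; exonic non-CDS positions are 5' or 3' UTR relative
#' to the CDS and strand; positions within `window` bp of a transcript end
#' are upstream/downstream (strand-aware). Sites overlapping user-supplied
#' regulatory features receive that feature's class (`tfbs`, `mirna`,
#' `regulatory_element`). Sites touching nothing are `intergenic`. Missense
#' records carry the reference and alternate amino acids and the Grantham
#' score; classes are not mutually exclusive across transcripts.
#'
#' @param sites Site table (needs `chrom`, `pos`, `ref`, `alt`; typically the
#'   admitted subset of a classified table).
#' @param models A `gene_models` object from [read_gene_models()].
#' @param features Optional `GRanges` of regulatory features from
#'   [read_bed_features()].
#' @param window Upstream/downstream window in bp (default 5000).
#' @param params Grantham parameters.
#' @return A data.frame of consequence records: `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `feature_id`, `consequence_class`, `ref_aa`, `alt_aa`,
#'   `grantham`.
#' @export
annotate_sites <- function(sites, models, features = NULL, window = 5000L,
                           params = grantham_params()) {
  trs <- prepare_transcripts(models)
  if (length(trs) > 0) {
    tx_gr <- GenomicRanges::GRanges(
      vapply(trs, `[[`, character(1), "chrom"),
      IRanges::IRanges(pmax(1L, vapply(trs, `[[`, numeric(1), "start") - window),
                       vapply(trs, `[[`, numeric(1), "end") + window))
  } else tx_gr <- GenomicRanges::GRanges()
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(site_gr, tx_gr)
  si <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)

  # column accumulators (one data.frame built at the end)
  env <- new.env()
  env$i <- integer(0); env$gene_id <- character(0)
  env$feature_id <- character(0); env$class <- character(0)
  env$ref_aa <- character(0); env$alt_aa <- character(0)
  env$grantham <- integer(0)
  add <- function(i, gene_id, feature_id, r) {
    n <- length(env$i) + 1L
    env$i[n] <- i; env$gene_id[n] <- gene_id
    env$feature_id[n] <- feature_id; env$class[n] <- r$class
    env$ref_aa[n] <- r$ref_aa; env$alt_aa[n] <- r$alt_aa
    env$grantham[n] <- r$grantham
  }
  for (j in seq_along(si)) {
    tr <- trs[[ti[j]]]
    i <- si[j]
    r <- classify_in_transcript(tr, sites$pos[i], sites$ref[i], sites$alt[i],
                                params)
    add(i, tr$gene_id, tr$transcript_id, r)
  }
  covered <- rep(FALSE, nrow(sites))
  covered[unique(si)] <- TRUE

  if (!is.null(features) && length(features) > 0) {
    feats <- features[features$feature_class != "sweep_region"]
    if (length(feats) > 0) {
      fh <- GenomicRanges::findOverlaps(site_gr, feats)
      fi <- S4Vectors::queryHits(fh)
      fj <- S4Vectors::subjectHits(fh)
      for (j in seq_along(fi)) {
        cls <- feats$feature_class[fj[j]]
        if (!(cls %in% c("tfbs", "mirna", "regulatory_element")))
          cls <- "regulatory_element"
        add(fi[j], NA_character_, feats$name[fj[j]],
            list(class = cls, ref_aa = NA_character_,
                 alt_aa = NA_character_, grantham = NA_integer_))
      }
      covered[unique(fi)] <- TRUE
    }
  }
  for (i in which(!covered)) {
    add(i, NA_character_, NA_character_,
        list(class = "intergenic", ref_aa = NA_character_,
             alt_aa = NA_character_, grantham = NA_integer_))
  }
  out <- data.frame(chrom = sites$chrom[env$i], pos = sites$pos[env$i],
                    ref = sites$ref[env$i], alt = sites$alt[env$i],
                    gene_id = env$gene_id, feature_id = env$feature_id,
                    consequence_class = env$class,
                    ref_aa = env$ref_aa, alt_aa = env$alt_aa,
                    grantham = env$grantham, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

catalog_class_rows <- function() {
  list("All" = NULL,
       "Non-synonymous" = "missense",
       "Synonymous" = "synonymous",
       "Start/stop" = c("start_lost", "stop_gained", "stop_lost"),
       "Splice site" = "splice_site",
       "TFBS" = "tfbs",
       "Upstream" = "upstream",
       "5' UTR" = "five_prime_utr",
       "3' UTR" = "three_prime_utr",
       "Downstream" = "downstream",
       "miRNA" = "mirna",
       "Regulatory element" = "regulatory_element",
       "Intronic" = "intronic",
       "Intergenic" = "intergenic")
}

#' Summarize the catalog by category and consequence class
#'
#' Builds the per-lineage, per-category, per-consequence-class count table
#' (one row per consequence class, one column per lineage and category) and
#' per-chromosome missense/synonymous ratios. High-frequency columns include
#' the fixed sites (fixed changes are a subset of HF changes); each site
#' counts once per consequence class regardless of how many transcripts give
#' it that class, so classes overlap and column sums can exceed the number of
#' sites. Ratios with zero synonymous counts are reported as `NA`.
#'
#' @param classified Output of [classify_sites()].
#' @param consequences Output of [annotate_sites()].
#' @return A list with `table` (data.frame, consequence classes x categories)
#'   and `chrom_ratios` (data.frame with per-chromosome missense/synonymous
#'   ratios per lineage, computed over HF-including-fixed sites).
#' @export
summarize_catalog <- function(classified, consequences) {
  key_c <- paste(classified$chrom, classified$pos, classified$ref,
                 classified$alt)
  key_q <- paste(consequences$chrom, consequences$pos, consequences$ref,
                 consequences$alt)
  cls_by_site <- split(consequences$consequence_class, key_q)

  cols <- list(
    "Fixed human" = quote(lineage == "human" & category == "fixed"),
    "HF human" = quote(lineage == "human" &
                         category %in% c("fixed", "high_frequency")),
    "Extended human" = quote(lineage == "human" & category == "extended"),
    "Fixed archaic" = quote(lineage == "archaic" & category == "fixed"),
    "HF archaic" = quote(lineage == "archaic" &
                           category %in% c("fixed", "high_frequency")),
    "Extended archaic" = quote(lineage == "archaic" & category == "extended"))
  rows <- catalog_class_rows()
  tab <- matrix(0L, nrow = length(rows), ncol = length(cols),
                dimnames = list(names(rows), names(cols)))
  for (cn in names(cols)) {
    sel <- eval(cols[[cn]], classified)
    keys <- key_c[sel]
    tab["All", cn] <- length(keys)
    site_classes <- cls_by_site[keys]
    for (rn in setdiff(names(rows), "All")) {
      wanted <- rows[[rn]]
      tab[rn, cn] <- sum(vapply(site_classes, function(x)
        !is.null(x) && any(x %in% wanted), logical(1)))
    }
  }
  tab_df <- data.frame(consequence = rownames(tab), tab, check.names = FALSE,
                       row.names = NULL, stringsAsFactors = FALSE)

  ratio_rows <- list()
  for (lin in c("human", "archaic")) {
    sel <- classified$lineage == lin &
      classified$category %in% c("fixed", "high_frequency")
    keys <- key_c[sel]
    chroms <- classified$chrom[sel]
    for (ch in unique(classified$chrom)) {
      kk <- keys[chroms == ch]
      scls <- cls_by_site[kk]
      mis <- sum(vapply(scls, function(x)
        !is.null(x) && "missense" %in% x, logical(1)))
      syn <- sum(vapply(scls, function(x)
        !is.null(x) && "synonymous" %in% x, logical(1)))
      ratio_rows[[length(ratio_rows) + 1L]] <-
        data.frame(chrom = ch, lineage = lin, missense = mis,
                   synonymous = syn,
                   ratio = if (syn > 0) mis / syn else NA_real_,
                   stringsAsFactors = FALSE)
    }
  }
  chrom_ratios <- do.call(rbind, ratio_rows)
  list(table = tab_df, chrom_ratios = chrom_ratios)
}
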