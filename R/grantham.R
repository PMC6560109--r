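#' Grantham amino-acid property parameters
#'
#' The physicochemical properties underlying the Grantham (1974) distance:
#' per-residue composition `c` (atomic weight ratio of non-carbon side-chain
#' atoms), polarity `p` and molecular volume `v`, together with the weights
#' `alpha`, `beta`, `gamma` and the scale factor `rho`. By default `rho` is
#' chosen so that the mean distance over all 190 unordered residue pairs is
#' exactly 100, which reproduces the published extremes (Leu-Ile = 5,
#' Cys-Trp = 215).
#'
#' @param alpha,beta,gamma Property weights (defaults 1.833, 0.1018,
#'   0.000399).
#' @param rho Scale factor; `NULL` (default) normalizes the mean pair
#'   distance to 100.
#' @return An object of class `grantham_params`: list with `properties`
#'   (data.frame with rownames = one-letter codes and columns `c`, `p`, `v`),
#'   `alpha`, `beta`, `gamma`, `rho`.
#' @export
grantham_params <- function(alpha = 1.833, beta = 0.1018, gamma = 0.000399,
                            rho = NULL) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  props <- data.frame(
    c = c(0, 0.65, 1.33, 1.38, 2.75, 0.89, 0.92, 0.74, 0.58, 0,
          0, 0.33, 0, 0, 0.39, 1.42, 0.71, 0.13, 0.20, 0),
    p = c(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4, 5.2,
          4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9),
    v = c(31, 124, 56, 54, 55, 85, 83, 3, 96, 111,
          111, 119, 105, 132, 32.5, 32, 61, 170, 136, 84),
    row.names = aa)
  raw <- function(i, j) {
    sqrt(alpha * (props$c[i] - props$c[j])^2 +
           beta * (props$p[i] - props$p[j])^2 +
           gamma * (props$v[i] - props$v[j])^2)
  }
  if (is.null(rho)) {
    pairs <- combn(20L, 2L)
    rho <- 100 / mean(raw(pairs[1, ], pairs[2, ]))
  }
  structure(list(properties = props, alpha = alpha, beta = beta,
                 gamma = gamma, rho = rho),
            class = "grantham_params")
}

#' Grantham distance between amino acids
#'
#' Computes the Grantham physicochemical distance
#' \deqn{D = \rho \sqrt{\alpha (c_1-c_2)^2 + \beta (p_1-p_2)^2 +
#'   \gamma (v_1-v_2)^2}}
#' rounded to the nearest integer, for one-letter amino-acid codes. The
#' distance is symmetric and zero for identical residues.
#'
#' @param ref_aa,alt_aa Character vectors of one-letter amino-acid codes
#'   (the 20 standard residues).
#' @param params A [grantham_params()] object.
#' @return Integer vector of distances.
#' @export
grantham <- function(ref_aa, alt_aa, params = grantham_params()) {
  props <- params$properties
  bad <- !(ref_aa %in% rownames(props)) | !(alt_aa %in% rownames(props))
  if (any(bad))
    stop("non-standard amino acid(s): ",
         paste(unique(c(ref_aa[bad], alt_aa[bad])), collapse = ", "))
  i <- match(ref_aa, rownames(props))
  j <- match(alt_aa, rownames(props))
  d <- sqrt(params$alpha * (props$c[i] - props$c[j])^2 +
              params$beta * (props$p[i] - props$p[j])^2 +
              params$gamma * (props$v[i] - props$v[j])^2)
  as.integer(round(params$rho * d))
}

#' The full 20 x 20 Grantham distance matrix
#'
#' @param params A [grantham_params()] object.
#' @return An integer matrix with residue one-letter codes as dimnames.
#' @export
grantham_matrix <- function(params = grantham_params()) {
  aa <- rownames(params$properties)
  m <- outer(aa, aa, function(x, y) grantham(x, y, params))
  dimnames(m) <- list(aa, aa)
  m
}

#' Flag deleterious consequence records
#'
#' Selects the records whose scores exceed the deleteriousness rules: a
#' Grantham score strictly greater than `grantham_min` (so 181 is flagged,
#' 180 is not), a SIFT score strictly below `sift_max`, or a PolyPhen score
#' strictly above `polyphen_min`. The SIFT and PolyPhen rules apply only to
#' records that carry those columns (external scores are consumed, never
#' computed). Records without any relevant score are never flagged.
#'
#' @param records Consequence records (see [annotate_sites()]); may carry
#'   optional columns `sift` and `polyphen`.
#' @param grantham_min Grantham cutoff (default 180, exclusive).
#' @param sift_max SIFT cutoff (default 0.05, exclusive).
#' @param polyphen_min PolyPhen cutoff (default 0.908, exclusive).
#' @return The flagged subset of `records`, with a `flagged_by` column.
#' @export
flag_deleterious <- function(records, grantham_min = 180,
                             sift_max = 0.05, polyphen_min = 0.908) {
  if (nrow(records) == 0) {
    records$flagged_by <- character(0)
    return(records)
  }
  by <- rep(NA_character_, nrow(records))
  if ("polyphen" %in% names(records)) {
    hit <- !is.na(records$polyphen) & records$polyphen > polyphen_min
    by[hit] <- "polyphen"
  }
  if ("sift" %in% names(records)) {
    hit <- !is.na(records$sift) & records$sift < sift_max
    by[hit] <- "sift"
  }
  if ("grantham" %in% names(records)) {
    hit <- !is.na(records$grantham) & records$grantham > grantham_min
    by[hit] <- "grantham"
  }
  out <- records[!is.na(by), , drop = FALSE]
  out$flagged_by <- by[!is.na(by)]
  rownames(out) <- NULL
  out
}
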