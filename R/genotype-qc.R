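# Per-genotype and per-variant quality filters applied to raw WGS calls.

#' Apply per-genotype depth and quality filters
#'
#' A genotype call is set to missing iff the summed local allele depth is
#' below `min_depth` or genotype quality is below `min_gq` (both strict
#' `<`: sum(LAD) = 8 and GQ = 10 are retained). Filters are idempotent.
#'
#' @param dosage samples x variants dosage matrix (0/1/2, NA allowed).
#' @param lad_sum matrix of summed per-allele read depths, same shape.
#' @param gq matrix of genotype qualities, same shape.
#' @param min_depth,min_gq thresholds (defaults 8 and 10).
#' @return dosage matrix with failing calls set to `NA`.
#' @export
apply_call_filters <- function(dosage, lad_sum, gq, min_depth = 8,
                               min_gq = 10) {
  stopifnot(all(dim(dosage) == dim(lad_sum)), all(dim(dosage) == dim(gq)))
  bad_depth <- is.na(lad_sum) | lad_sum < min_depth
  bad_gq <- is.na(gq) | gq < min_gq
  dosage[bad_depth | bad_gq] <- NA
  dosage
}

#' Drop variants by missingness
#'
#' A variant is retained iff its missingness is at most `max_missing`
#' (strictly greater than 10% is dropped; exactly 10% is retained).
#'
#' @param dosage filtered dosage matrix.
#' @param max_missing maximum tolerated missingness (default 0.10).
#' @return list: `keep` (logical per variant), `missingness`,
#'   `dosage` (retained columns only).
#' @export
filter_missingness <- function(dosage, max_missing = 0.10) {
  miss <- colMeans(is.na(dosage))
  keep <- miss <= max_missing
  list(keep = keep, missingness = miss,
       dosage = dosage[, keep, drop = FALSE])
}

#' Per-variant QC summary after call filtering
#'
#' Recomputes MAC, MAF and missingness from the filtered dosage matrix
#' (frequencies always refer to post-filter non-missing calls).
#'
#' @param dosage dosage matrix with NAs for filtered calls.
#' @return data.frame with `vid`, `mac`, `maf`, `missingness`,
#'   `n_nonmissing`.
#' @export
variant_qc_table <- function(dosage) {
  s <- allele_summary(dosage)
  cbind(data.frame(vid = colnames(dosage) %||%
                     as.character(seq_len(ncol(dosage))),
                   stringsAsFactors = FALSE), s)
}

# Parse a diploid GT string ("0/1", "1|1", "./.", half-calls) to a dosage.
#' @noRd
gt_to_dosage <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  a <- sub("/.*", "", gt)
  b <- sub(".*/", "", gt)
  da <- suppressWarnings(as.numeric(a))
  db <- suppressWarnings(as.numeric(b))
  out <- da + db
  out[is.na(da) | is.na(db)] <- NA   # any half-call or ./. -> missing
  out
}
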