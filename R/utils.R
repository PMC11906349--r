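# Internal helpers shared across modules.

# Intervals are 0-based half-open [start, end) throughout the package;
# 1-based VCF/GFF positions are converted at the I/O boundary.

#' @noRd
pos_in_interval <- function(pos1, start0, end0) {
  pos1 > start0 & pos1 <= end0
}

#' @noRd
interval_width <- function(start0, end0) end0 - start0

# Derive a reproducible 31-bit sub-seed from a master seed and a stage label.
# Keeps every source of randomness traceable to one integer.
#' @noRd
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483647L)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Mean-impute missing dosages column-wise (standard practice before OLS on
# genotype dosages; frequencies are computed before imputation).
#' @noRd
impute_dosage <- function(G) {
  nas <- which(is.na(G))
  if (length(nas) == 0L) return(G)
  cm <- colMeans(G, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- arrayInd(nas, dim(G))
  G[nas] <- cm[idx[, 2L]]
  G
}

# Minor allele count / frequency from a dosage matrix with possible NAs.
#' @noRd
allele_summary <- function(G) {
  nonmiss <- colSums(!is.na(G))
  alt <- colSums(G, na.rm = TRUE)
  mac <- pmin(alt, 2 * nonmiss - alt)
  maf <- ifelse(nonmiss > 0, mac / (2 * nonmiss), NA_real_)
  miss <- 1 - nonmiss / nrow(G)
  data.frame(mac = as.numeric(mac), maf = maf, missingness = miss,
             n_nonmissing = as.integer(nonmiss))
}

#' @noRd
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
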