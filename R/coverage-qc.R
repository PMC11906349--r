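# Locus-level sequencing-coverage QC: per-base pass fractions, the two
# protein-exclusion filters, and the problematic-region logistic check.

#' Coverage profile of an interval
#'
#' From a run-length encoded pass-count track (number of samples with depth
#' strictly greater than 8 at each base), computes the fraction of interval
#' bases at which more than 90% of samples pass. Both thresholds are
#' strict: depth exactly 8 fails, exactly 90% of samples fails.
#'
#' @param track data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `n_pass` (samples with depth > 8).
#' @param interval list or vector with `start` and `end` (0-based
#'   half-open).
#' @param n_samples number of samples assessed.
#' @param min_sample_frac per-base pass threshold (default 0.90, strict).
#' @return list of class `coverage_profile`: `interval`,
#'   `n_samples_assessed`, `fraction_bases_passing`.
#' @export
compute_coverage <- function(track, interval, n_samples,
                             min_sample_frac = 0.90) {
  s <- interval[["start"]]; e <- interval[["end"]]
  assert_that(e > s, "interval end must exceed start")
  assert_that(min(track$start) <= s && max(track$end) >= e,
              "interval outside the depth track")
  ov <- track[track$start < e & track$end > s, , drop = FALSE]
  covered <- sum(pmin(ov$end, e) - pmax(ov$start, s))
  assert_that(covered == e - s, "depth track has gaps inside the interval")
  w <- pmin(ov$end, e) - pmax(ov$start, s)
  pass <- ov$n_pass / n_samples > min_sample_frac
  structure(list(interval = c(start = s, end = e),
                 n_samples_assessed = n_samples,
                 fraction_bases_passing = sum(w[pass]) / (e - s)),
            class = "coverage_profile")
}

#' Coverage pass/fail verdict for a protein
#'
#' A protein passes iff both its gene-body (UTR-to-UTR) coverage fraction
#' and its full cis-window coverage fraction strictly exceed the threshold
#' (99.5% of bases by default).
#'
#' @param gene_profile,region_profile [compute_coverage()] results (or
#'   bare fractions).
#' @param threshold minimum fraction of passing bases (default 0.995,
#'   strict).
#' @return list: `gene_coverage_frac`, `region_coverage_frac`,
#'   `passes_coverage`.
#' @export
coverage_filter <- function(gene_profile, region_profile,
                            threshold = 0.995) {
  gf <- if (is.list(gene_profile))
    gene_profile$fraction_bases_passing else gene_profile
  rf <- if (is.list(region_profile))
    region_profile$fraction_bases_passing else region_profile
  list(gene_coverage_frac = gf, region_coverage_frac = rf,
       passes_coverage = gf > threshold && rf > threshold)
}

#' Beta-discrepancy exclusion filter
#'
#' Excludes proteins whose maximum absolute difference between marginal and
#' joint effect estimates, over their pQTLs, lies strictly beyond the
#' empirical 90th percentile across proteins (linear-interpolation
#' quantile, `type = 7`). A large discrepancy indicates an uncalled causal
#' variant distorting the joint model.
#'
#' @param max_discrepancy named numeric vector, one value per protein.
#' @param percentile percentile defining "beyond" (default 90).
#' @return list: `threshold`, `excluded` (names), `passes` (named
#'   logical).
#' @export
discrepancy_filter <- function(max_discrepancy, percentile = 90) {
  assert_that(length(max_discrepancy) >= 2,
              "need at least 2 proteins to define a percentile")
  thr <- stats::quantile(max_discrepancy, percentile / 100, type = 7,
                         names = FALSE)
  passes <- max_discrepancy <= thr
  list(threshold = thr,
       excluded = names(max_discrepancy)[!passes],
       passes = passes)
}

# Firth-penalized logistic regression (Jeffreys-prior score adjustment).
# Used when the ML fit separates; written here because no penalized-
# likelihood logistic package is part of this package's dependency set.
#' @noRd
firth_logistic <- function(Xm, yb, max_iter = 100L, tol = 1e-8) {
  beta <- rep(0, ncol(Xm))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(Xm %*% beta)
    mu <- 1 / (1 + exp(-eta))
    Wv <- mu * (1 - mu)
    XtWX <- crossprod(Xm * Wv, Xm)
    inv <- solve(XtWX)
    h <- rowSums((Xm %*% inv) * (Xm * Wv))
    U <- crossprod(Xm, yb - mu + h * (0.5 - mu))
    step <- inv %*% U
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(Xm %*% beta)
  mu <- 1 / (1 + exp(-eta))
  se <- sqrt(diag(solve(crossprod(Xm * (mu * (1 - mu)), Xm))))
  list(coef = beta, se = se)
}

#' Problematic-region enrichment among coverage-excluded proteins
#'
#' Logistic regression of the exclusion indicator on per-protein counts of
#' overlapping problematic regions (one covariate per region type),
#' adjusting for the total cis-window length. Reports the odds ratio per
#' overlapping region with a Wald 95% CI. Perfect separation is detected
#' (non-convergence or exploding estimates) and triggers a Firth
#' penalized-likelihood refit, flagged in the output.
#'
#' @param excluded logical vector per protein.
#' @param overlap_counts data.frame/matrix of overlap counts, one column
#'   per region type.
#' @param window_length numeric vector of cis-window lengths per protein.
#' @return data.frame: `region_type`, `or`, `ci_lo`, `ci_hi`, `p`,
#'   `separation` flag.
#' @export
problematic_region_enrichment <- function(excluded, overlap_counts,
                                          window_length) {
  assert_that(length(unique(excluded)) == 2,
              "both excluded and retained proteins are required")
  assert_that(length(excluded) >= 20,
              "need at least 20 proteins for a stable logistic fit")
  oc <- as.data.frame(overlap_counts)
  df <- data.frame(.excluded = as.integer(excluded), oc,
                   .window_length = as.numeric(scale(window_length)))
  fit <- suppressWarnings(
    stats::glm(.excluded ~ ., data = df, family = stats::binomial()))
  sep <- !fit$converged || any(abs(stats::coef(fit)[-1L]) > 15,
                               na.rm = TRUE)
  if (sep) {
    Xm <- stats::model.matrix(.excluded ~ ., data = df)
    ff <- firth_logistic(Xm, df$.excluded)
    est <- ff$coef; se <- ff$se
    names(est) <- names(se) <- colnames(Xm)
  } else {
    est <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
  }
  keep <- names(oc)
  z <- est[keep] / se[keep]
  data.frame(region_type = keep,
             or = exp(est[keep]),
             ci_lo = exp(est[keep] - 1.96 * se[keep]),
             ci_hi = exp(est[keep] + 1.96 * se[keep]),
             p = 2 * stats::pnorm(-abs(z)),
             separation = sep, row.names = NULL,
             stringsAsFactors = FALSE)
}
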