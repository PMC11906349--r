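# Consequence-category Fisher enrichment, bootstrap regulatory-region
# enrichment with empirical P values, and empirical significance
# thresholds from null-trait scans.

#' Fisher consequence-category enrichment
#'
#' For each category, an exact two-sided test of the 2x2 table (lead
#' in/out of category vs non-lead in/out), with a Bonferroni significance
#' flag at `0.05 / n_categories`. The reported odds ratio is the sample
#' cross-product ratio; zero margins get a Haldane (+0.5) correction and
#' are flagged.
#'
#' @param lead_counts named counts of lead variants per category.
#' @param background_counts named counts over the full tested universe
#'   (must include the leads: `background >= lead` per category).
#' @param n_categories number of tests for the Bonferroni flag
#'   (default: number of categories).
#' @return data.frame of class `fisher_result` rows.
#' @export
fisher_enrichment <- function(lead_counts, background_counts,
                              n_categories = length(lead_counts)) {
  cats <- names(lead_counts)
  assert_that(!is.null(cats) && all(cats %in% names(background_counts)),
              "categories must be named and present in the background")
  assert_that(all(lead_counts <= background_counts[cats]),
              "lead count exceeds background count")
  n_lead <- sum(lead_counts)
  n_bg <- sum(background_counts)
  out <- lapply(cats, function(cat) {
    a <- lead_counts[[cat]]
    b <- n_lead - a
    c_ <- background_counts[[cat]] - a
    d <- (n_bg - background_counts[[cat]]) - b
    tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      any(tab == 0)
    or <- if (degenerate)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    data.frame(category = cat, a = a, b = b, c = c_, d = d,
               odds_ratio = or, p_two_sided = p,
               haldane_corrected = degenerate,
               significant = p < 0.05 / n_categories,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("fisher_result", class(out))
  out
}

# Logical flag per query element: does it overlap any region in the set?
#' @noRd
overlaps_regions <- function(q_start, q_end, r_start, r_end) {
  if (length(r_start) == 0L) return(rep(FALSE, length(q_start)))
  IRanges::overlapsAny(IRanges::IRanges(q_start + 1L, q_end),
                       IRanges::IRanges(r_start + 1L, r_end))
}

#' Bootstrap enrichment of signals in regulatory regions
#'
#' For each stratum (feature type x tissue group over active regions),
#' compares the observed number of signals overlapping a region with the
#' distribution obtained by drawing `n_sim` random sets of the same size
#' from the tested candidate pool (without replacement by default). The
#' empirical P is plus-one corrected:
#' `(1 + #{sims with overlap >= observed}) / (1 + n_sim)`, so it is never
#' zero and is decreasing in the observed overlap.
#'
#' @param signals data.frame of signal intervals `start`, `end` (0-based
#'   half-open; use `pos - 1`, `pos` for single variants).
#' @param pool data.frame of all candidate intervals tested (must be at
#'   least as large as the signal set).
#' @param regions data.frame `start`, `end`, `feature_type`,
#'   `tissue_group`, `active`; only active regions are considered.
#' @param n_sim number of bootstrap draws (default 10,000).
#' @param seed integer seed.
#' @param replace sample with replacement (default FALSE).
#' @param by stratify by `"both"` (feature x tissue), `"feature_type"`,
#'   `"tissue_group"`, or `"none"` (all active regions pooled).
#' @return data.frame per stratum: `stratum`, `observed_overlap`,
#'   `null_mean`, `null_sd`, `null_q95`, `empirical_p`; the per-stratum
#'   null vectors are attached as the `"null_overlaps"` attribute.
#' @export
bootstrap_region_enrichment <- function(signals, pool, regions,
                                        n_sim = 10000L, seed = 1L,
                                        replace = FALSE,
                                        by = c("both", "feature_type",
                                               "tissue_group", "none")) {
  by <- match.arg(by)
  n_sig <- nrow(signals)
  assert_that(n_sig > 0, "empty signal set")
  assert_that(nrow(pool) >= n_sig, "candidate pool smaller than signal set")
  act <- regions[regions$active %||% TRUE == TRUE, , drop = FALSE]
  assert_that(nrow(act) > 0, "no active regions")
  strata <- switch(by,
    both = interaction(act$feature_type, act$tissue_group, drop = TRUE,
                       sep = ":"),
    feature_type = factor(act$feature_type),
    tissue_group = factor(act$tissue_group),
    none = factor(rep("all", nrow(act))))
  set.seed(seed)
  draws <- matrix(0L, n_sim, n_sig)
  for (i in seq_len(n_sim))
    draws[i, ] <- sample.int(nrow(pool), n_sig, replace = replace)
  out <- list()
  nulls <- list()
  for (st in levels(strata)) {
    rr <- act[strata == st, , drop = FALSE]
    obs_flag <- overlaps_regions(signals$start, signals$end,
                                 rr$start, rr$end)
    pool_flag <- overlaps_regions(pool$start, pool$end, rr$start, rr$end)
    obs <- sum(obs_flag)
    null_counts <- rowSums(matrix(pool_flag[draws], n_sim, n_sig))
    ep <- (1 + sum(null_counts >= obs)) / (1 + n_sim)
    out[[st]] <- data.frame(stratum = st, observed_overlap = obs,
                            null_mean = mean(null_counts),
                            null_sd = stats::sd(null_counts),
                            null_q95 = stats::quantile(null_counts, 0.95,
                                                       names = FALSE),
                            empirical_p = ep, stringsAsFactors = FALSE)
    nulls[[st]] <- null_counts
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "null_overlaps") <- nulls
  res
}

#' Empirical significance thresholds from null-trait scans
#'
#' Generates `n_traits` independent standard-normal phenotypes, runs the
#' full single-variant and aggregate scans on each, and returns the
#' minimum P value observed in each class across all traits. The two
#' thresholds are treated as independent. With `m` total single-variant
#' tests the single-variant minimum behaves like the first order statistic
#' of `m` uniforms (about `1/m` in magnitude).
#'
#' @param G dosage matrix.
#' @param units aggregate-unit catalogue.
#' @param X covariates.
#' @param n_traits number of null traits (default 20).
#' @param seed integer seed (deterministic given the seed).
#' @param min_mac single-variant MAC floor.
#' @param config a [test_config()].
#' @return list: `single_variant_threshold`, `aggregate_threshold`,
#'   `m_single`, `m_aggregate` (total test counts), `per_trait`
#'   (data.frame of per-trait minima).
#' @export
empirical_thresholds <- function(G, units, X = NULL, n_traits = 20L,
                                 seed = 1L, min_mac = 5,
                                 config = test_config()) {
  assert_that(n_traits >= 1, "n_traits must be >= 1")
  n <- nrow(G)
  per <- vector("list", n_traits)
  m_single <- 0L
  m_agg <- 0L
  for (i in seq_len(n_traits)) {
    set.seed(sub_seed(seed, paste0("nulltrait", i)))
    y <- rank_inverse_normalize(rnorm(n))
    sv <- single_variant_assoc(G, y, X, min_mac = min_mac)
    adj <- residualize(y, X, NULL)
    sc <- aggregate_scan(units, G, adj, config)
    ps <- sc$p[!is.na(sc$p)]
    m_single <- m_single + nrow(sv)
    m_agg <- m_agg + length(ps)
    per[[i]] <- data.frame(trait = i, min_p_single = min(sv$p),
                           min_p_aggregate = if (length(ps)) min(ps) else NA)
  }
  per <- do.call(rbind, per)
  list(single_variant_threshold = min(per$min_p_single),
       aggregate_threshold = min(per$min_p_aggregate, na.rm = TRUE),
       m_single = m_single, m_aggregate = m_agg, per_trait = per)
}
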