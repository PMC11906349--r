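#' Configuration for a simulated cis-locus
#'
#' Defines the shape of a synthetic cis-window around a protein-coding gene:
#' how many samples and variants to draw, the allele-frequency spectrum, the
#' gene geometry and the density of regulatory regions. The defaults describe
#' a reduced-scale locus (5,000 samples, 2,000 variants in a 200-kb window)
#' whose statistical structure mirrors a sequencing-based cis-pQTL scan:
#' a site-frequency spectrum dominated by singletons and very rare variants,
#' a multi-exon gene with UTRs, and interval annotation tracks.
#'
#' @param n_samples number of diploid samples.
#' @param window_length length of the simulated window in bp.
#' @param n_variants number of variant sites to place in the window.
#' @param maf_spectrum named mixture weights over frequency bins
#'   `singleton` (MAC = 1), `mac2_5` (MAC 2-5), `rare` (MAF < 0.1%),
#'   `low` (0.1-1%) and `common` (> 1%); must sum to 1.
#' @param gene_span gene length in bp (placed at the window centre).
#' @param exon_count number of exons.
#' @param proximal_flank distance in bp from the UTRs within which a
#'   noncoding variant is considered gene-proximal (default 5,000).
#' @param regulatory_region_density expected regulatory regions per 100 kb.
#' @param window_start 0-based genomic start of the window.
#' @param chrom chromosome name.
#' @param seed integer seed; all randomness in [simulate_locus()] derives
#'   from it.
#' @return an object of class `locus_config`.
#' @export
locus_config <- function(n_samples = 5000L,
                         window_length = 200000L,
                         n_variants = 2000L,
                         maf_spectrum = c(singleton = 0.35, mac2_5 = 0.25,
                                          rare = 0.15, low = 0.15,
                                          common = 0.10),
                         gene_span = 20000L,
                         exon_count = 5L,
                         proximal_flank = 5000L,
                         regulatory_region_density = 5,
                         window_start = 1000000L,
                         chrom = "chr1",
                         seed = 1L) {
  assert_that(all(c(n_samples, window_length, n_variants, gene_span,
                    exon_count) > 0), "all counts must be > 0")
  assert_that(abs(sum(maf_spectrum) - 1) < 1e-9,
              "maf_spectrum weights must sum to 1")
  bins <- c("singleton", "mac2_5", "rare", "low", "common")
  assert_that(all(bins %in% names(maf_spectrum)),
              "maf_spectrum must name bins singleton, mac2_5, rare, low, common")
  assert_that(n_variants <= window_length,
              "cannot place n_variants unique positions in window_length bases")
  assert_that(gene_span + 2L * proximal_flank < window_length,
              "gene_span plus flanks must fit inside the window")
  structure(list(n_samples = as.integer(n_samples),
                 window_length = as.integer(window_length),
                 n_variants = as.integer(n_variants),
                 maf_spectrum = maf_spectrum[bins],
                 gene_span = as.integer(gene_span),
                 exon_count = as.integer(exon_count),
                 proximal_flank = as.integer(proximal_flank),
                 regulatory_region_density = regulatory_region_density,
                 window_start = as.integer(window_start),
                 chrom = chrom,
                 seed = as.integer(seed)),
            class = "locus_config")
}

#' Genetic architecture for a simulated protein level
#'
#' Describes how many causal variants of each class drive the phenotype and
#' the magnitude/direction statistics of their effects. Default effect
#' statistics reproduce the observed behaviour of rare cis-pQTLs: noncoding
#' causal effects average |beta| = 1.15 s.d. with 65.2% decreasing the
#' protein level, while coding effects are larger on average (1.55 s.d.) and
#' predominantly decreasing (86.3%). Magnitudes are drawn from a half-normal
#' scaled to the configured mean.
#'
#' @param n_causal_common,n_causal_rare_coding,n_causal_rare_noncoding counts
#'   of causal variants per class.
#' @param mean_abs_beta_noncoding mean |beta| (phenotype s.d. per allele) of
#'   rare noncoding causal variants.
#' @param frac_decreasing_noncoding probability a noncoding causal effect is
#'   negative.
#' @param mean_abs_beta_coding,frac_decreasing_coding as above for coding.
#' @param mean_abs_beta_common mean |beta| of common causal variants
#'   (default 0.3, which puts the jointly explained cis variance near the
#'   few-percent level typical of cis protein QTLs).
#' @param causal_aggregate_units optional list; each element
#'   `list(start =, end =, causal_fraction =, beta =)` plants per-variant
#'   effects of size `beta` into that fraction of the rare noncoding variants
#'   inside the 0-based half-open interval.
#' @param covariate_effects named numeric vector of covariate coefficients
#'   (matched to the covariate table columns); `NULL` uses a small default.
#' @param noise_sd residual standard deviation (> 0).
#' @param seed integer seed for phenotype randomness.
#' @return an object of class `arch_config`.
#' @export
arch_config <- function(n_causal_common = 2L,
                        n_causal_rare_coding = 2L,
                        n_causal_rare_noncoding = 3L,
                        mean_abs_beta_noncoding = 1.15,
                        frac_decreasing_noncoding = 0.652,
                        mean_abs_beta_coding = 1.55,
                        frac_decreasing_coding = 0.863,
                        mean_abs_beta_common = 0.3,
                        causal_aggregate_units = NULL,
                        covariate_effects = NULL,
                        noise_sd = 1,
                        seed = 1L) {
  assert_that(noise_sd > 0, "noise_sd must be > 0")
  assert_that(frac_decreasing_noncoding >= 0 && frac_decreasing_noncoding <= 1 &&
              frac_decreasing_coding >= 0 && frac_decreasing_coding <= 1,
              "direction fractions must lie in [0, 1]")
  structure(list(n_causal_common = as.integer(n_causal_common),
                 n_causal_rare_coding = as.integer(n_causal_rare_coding),
                 n_causal_rare_noncoding = as.integer(n_causal_rare_noncoding),
                 mean_abs_beta_noncoding = mean_abs_beta_noncoding,
                 frac_decreasing_noncoding = frac_decreasing_noncoding,
                 mean_abs_beta_coding = mean_abs_beta_coding,
                 frac_decreasing_coding = frac_decreasing_coding,
                 mean_abs_beta_common = mean_abs_beta_common,
                 causal_aggregate_units = causal_aggregate_units,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "arch_config")
}

# Frequency-bin classifier used both by the generator and by its tests.
#' @noRd
maf_bin <- function(mac, maf) {
  ifelse(mac == 1, "singleton",
  ifelse(mac <= 5, "mac2_5",
  ifelse(maf < 0.001, "rare",
  ifelse(maf < 0.01, "low", "common"))))
}

# Draw a target minor allele count for a frequency bin. Bins that are
# infeasible at the given sample size (2n too small for MAC > 5 with
# MAF < 0.1%) are clipped to the nearest feasible count.
#' @noRd
draw_mac <- function(bin, n2) {
  switch(bin,
    singleton = 1L,
    mac2_5 = sample(2:5, 1L),
    rare = {
      hi <- ceiling(0.001 * n2) - 1L
      if (hi < 6L) 6L else sample(6:hi, 1L)
    },
    low = {
      lo <- max(6L, ceiling(0.001 * n2))
      hi <- max(lo, ceiling(0.01 * n2) - 1L)
      sample(lo:hi, 1L)
    },
    common = {
      lo <- max(2L, ceiling(0.01 * n2))
      sample(lo:floor(n2 / 2), 1L)
    })
}

#' Simulate a complete cis-locus fixture
#'
#' Generates variant sites with Hardy-Weinberg genotypes drawn to match the
#' configured allele-frequency spectrum (alt alleles are placed on randomly
#' chosen haplotypes, so each variant's minor allele count is exact), a gene
#' model with two transcripts (UTRs, exons, introns), VEP-style consequence
#' labels determined by position, per-variant annotation scores (GERP, CADD,
#' JARVIS, SpliceAI), regulatory regions and per-window constraint and
#' conservation score tracks. Deterministic given `config$seed`.
#'
#' An optional LD mode copies blocks of haplotypes so that nearby variants
#' are correlated, to exercise conditional analysis; the default draws
#' variants independently, which keeps downstream analytic oracles exact.
#'
#' @param config a [locus_config()].
#' @param ld_blocks optional integer; if > 0, the window is divided into this
#'   many blocks and within each block rare-variant carriers are preferentially
#'   drawn from carriers of the block's common "background" haplotype variant.
#' @return an object of class `rarecis_locus`: list with elements `variants`
#'   (data.frame), `G` (samples x variants dosage matrix), `gene`, `regions`,
#'   `score_tracks`, `window`, `config`, `sample_ids`.
#' @export
simulate_locus <- function(config, ld_blocks = 0L) {
  stopifnot(inherits(config, "locus_config"))
  set.seed(config$seed)
  n <- config$n_samples
  n2 <- 2L * n
  m <- config$n_variants
  w0 <- config$window_start
  wlen <- config$window_length

  pos <- sort(sample.int(wlen, m)) + w0          # 1-based positions
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")

  bins <- sample(names(config$maf_spectrum), m, replace = TRUE,
                 prob = config$maf_spectrum)
  macs <- vapply(bins, draw_mac, 1L, n2 = n2)

  G <- matrix(0, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    haps <- sample.int(n2, macs[j])
    G[, j] <- tabulate(((haps - 1L) %/% 2L) + 1L, nbins = n)
  }

  if (ld_blocks > 0L) {
    # Block-LD mode: within each block, re-place rare alt alleles onto the
    # carrier haplotypes of the block's most common variant so that rare
    # variants tag a shared background.
    block <- cut(pos, breaks = ld_blocks, labels = FALSE)
    for (b in unique(block)) {
      idx <- which(block == b)
      anchor <- idx[which.max(macs[idx])]
      carriers <- which(G[, anchor] > 0)
      if (length(carriers) < 2L) next
      for (j in setdiff(idx, anchor)) {
        if (macs[j] >= length(carriers)) next
        G[, j] <- 0
        sel <- sample(carriers, macs[j], replace = FALSE)
        G[cbind(sel, j)] <- 1
      }
    }
    macs <- pmin(colSums(G), n2 - colSums(G))
  }

  gene <- build_synthetic_gene(config)
  regions <- build_synthetic_regions(config)
  tracks <- build_synthetic_tracks(config)

  vdf <- data.frame(
    vid = variant_id(config$chrom, pos, ref, alt),
    chrom = config$chrom, pos = pos, ref = ref, alt = alt,
    mac = as.numeric(macs), maf = macs / n2,
    missingness = 0, bin = maf_bin(macs, macs / n2),
    stringsAsFactors = FALSE)

  vdf <- annotate_synthetic_consequences(vdf, gene, regions, config)
  colnames(G) <- vdf$vid
  sample_ids <- sprintf("S%05d", seq_len(n))
  rownames(G) <- sample_ids

  structure(list(variants = vdf, G = G, gene = gene, regions = regions,
                 score_tracks = tracks,
                 window = list(chrom = config$chrom, start = w0,
                               end = w0 + wlen),
                 config = config, sample_ids = sample_ids),
            class = "rarecis_locus")
}

# Two-transcript gene model centred in the window. Transcript T1 is the
# longer; T2 is inset 500 bp at each end with one fewer exon, giving the
# union-vs-longest cis-window modes something to distinguish.
#' @noRd
build_synthetic_gene <- function(config) {
  gstart <- config$window_start +
    (config$window_length - config$gene_span) %/% 2L   # 0-based
  gend <- gstart + config$gene_span
  k <- config$exon_count
  exon_len <- max(50L, config$gene_span %/% (2L * k))
  starts <- round(seq(gstart, gend - exon_len, length.out = k))
  exons <- data.frame(start = as.integer(starts),
                      end = as.integer(starts + exon_len))
  utr_len <- min(200L, exon_len %/% 2L)
  utr5 <- data.frame(start = exons$start[1L], end = exons$start[1L] + utr_len)
  utr3 <- data.frame(start = exons$end[k] - utr_len, end = exons$end[k])
  t1 <- list(transcript_id = "T1", start = gstart, end = gend,
             exons = exons, utr5 = utr5, utr3 = utr3)
  inset <- min(500L, config$gene_span %/% 10L)
  ex2 <- exons[seq_len(max(1L, k - 1L)), , drop = FALSE]
  ex2$start[1L] <- min(ex2$start[1L] + inset, ex2$end[1L] - utr_len - 1L)
  t2 <- list(transcript_id = "T2", start = ex2$start[1L],
             end = max(ex2$end), exons = ex2,
             utr5 = data.frame(start = ex2$start[1L],
                               end = ex2$start[1L] + utr_len %/% 2L),
             utr3 = data.frame(start = max(ex2$end) - utr_len %/% 2L,
                               end = max(ex2$end)))
  gene_model(gene_id = "GENE1", chrom = config$chrom, strand = "+",
             transcripts = list(t1, t2))
}

#' @noRd
build_synthetic_regions <- function(config) {
  k <- max(1L, round(config$regulatory_region_density *
                       config$window_length / 1e5))
  starts <- sort(sample.int(config$window_length - 2000L, k)) +
    config$window_start
  widths <- sample(200:2000, k, replace = TRUE)
  feats <- sample(c("promoter", "enhancer", "CTCF_binding", "TF_binding",
                    "open_chromatin"), k, replace = TRUE)
  tissues <- sample(paste0("tissue_group_", 1:22), k, replace = TRUE)
  data.frame(chrom = config$chrom, start = starts,
             end = pmin(starts + widths, config$window_start +
                          config$window_length),
             feature_type = feats, tissue_group = tissues,
             active = sample(c(TRUE, FALSE), k, replace = TRUE,
                             prob = c(0.8, 0.2)),
             stringsAsFactors = FALSE)
}

# Per-1kb-window constraint z-scores and phastCon percentiles.
#' @noRd
build_synthetic_tracks <- function(config) {
  starts <- seq(config$window_start,
                config$window_start + config$window_length - 1L, by = 1000L)
  ends <- pmin(starts + 1000L, config$window_start + config$window_length)
  list(constraint = data.frame(chrom = config$chrom, start = starts,
                               end = ends, z = rnorm(length(starts), 0, 1.6)),
       phastcon = data.frame(chrom = config$chrom, start = starts, end = ends,
                             percentile = runif(length(starts), 0, 100)))
}

#' @noRd
annotate_synthetic_consequences <- function(vdf, gene, regions, config) {
  tx <- gene$transcripts[[1L]]
  in_exon <- rep(FALSE, nrow(vdf))
  for (i in seq_len(nrow(tx$exons)))
    in_exon <- in_exon | pos_in_interval(vdf$pos, tx$exons$start[i],
                                         tx$exons$end[i])
  in_utr5 <- pos_in_interval(vdf$pos, tx$utr5$start, tx$utr5$end)
  in_utr3 <- pos_in_interval(vdf$pos, tx$utr3$start, tx$utr3$end)
  in_gene <- pos_in_interval(vdf$pos, tx$start, tx$end)
  in_flank <- pos_in_interval(vdf$pos, tx$start - config$proximal_flank,
                              tx$end + config$proximal_flank) & !in_gene
  upstream <- vdf$pos <= tx$start
  in_region <- rep(FALSE, nrow(vdf))
  for (i in seq_len(nrow(regions)))
    in_region <- in_region | pos_in_interval(vdf$pos, regions$start[i],
                                             regions$end[i])

  m <- nrow(vdf)
  cons <- rep("intergenic_variant", m)
  cons[in_region & !in_gene & !in_flank] <- "regulatory_region_variant"
  cons[in_flank & upstream] <- "upstream_gene_variant"
  cons[in_flank & !upstream] <- "downstream_gene_variant"
  cons[in_gene & !in_exon] <- "intron_variant"
  cod <- in_exon & !in_utr5 & !in_utr3
  cons[cod] <- sample(c("missense_variant", "synonymous_variant",
                        "stop_gained"), sum(cod), replace = TRUE,
                      prob = c(0.55, 0.35, 0.10))
  cons[in_utr5] <- "5_prime_UTR_variant"
  cons[in_utr3] <- "3_prime_UTR_variant"

  vdf$consequence <- cons
  vdf$annotated_gene <- ifelse(in_gene | in_flank, gene$gene_id, NA_character_)
  vdf$gerp <- rnorm(m, 0, 2)
  vdf$cadd <- ifelse(cod, stats::rgamma(m, shape = 2, scale = 8),
                     stats::rgamma(m, shape = 2, scale = 3))
  vdf$jarvis <- runif(m)
  intronic <- cons == "intron_variant"
  vdf$spliceai <- ifelse(intronic & runif(m) < 0.03, runif(m, 50, 100),
                         runif(m, 0, 10))
  vdf$loftee_hc <- cons == "stop_gained" & runif(m) < 0.9
  vdf$classification <- classify_variants(vdf, gene,
                                          flank = config$proximal_flank)
  vdf
}

# Half-normal magnitudes with the requested mean, signed negative with the
# requested probability.
#' @noRd
draw_effects <- function(k, mean_abs, frac_decreasing) {
  mag <- abs(rnorm(k, 0, mean_abs * sqrt(pi / 2)))
  sgn <- ifelse(runif(k) < frac_decreasing, -1, 1)
  mag * sgn
}

#' Simulate covariates for a synthetic cohort
#'
#' Reduced covariate set standing in for the full epidemiological model:
#' age (standardized), sex, four continuous ancestry-PC-like covariates and
#' one assay-batch factor.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @return data.frame with `sample_id` plus covariate columns.
#' @export
simulate_covariates <- function(n, seed = 1L) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%05d", seq_len(n)),
             age = rnorm(n), sex = rbinom(n, 1L, 0.5),
             pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n),
             batch = factor(sample(paste0("B", 1:4), n, replace = TRUE)),
             stringsAsFactors = FALSE)
}

#' Simulate a protein phenotype with known causal truth
#'
#' Builds `y = sum_j beta_j g_j + X gamma + e`, selecting causal variants of
#' each class from the locus and drawing their effects per the architecture.
#' Noncoding (coding) causal effects are negative with probability
#' `frac_decreasing_noncoding` (`frac_decreasing_coding`).
#'
#' @param locus a [simulate_locus()] result.
#' @param arch an [arch_config()].
#' @param covariates optional covariate data.frame (as
#'   [simulate_covariates()]); generated from `arch$seed` when `NULL`.
#' @return list of class `rarecis_pheno`: `y` (raw phenotype), `covariates`,
#'   `truth` (data.frame of causal vids, class, true beta),
#'   `aggregate_truth` (per planted aggregate unit), `arch`.
#' @export
simulate_phenotype <- function(locus, arch, covariates = NULL) {
  stopifnot(inherits(locus, "rarecis_locus"), inherits(arch, "arch_config"))
  set.seed(arch$seed)
  v <- locus$variants
  n <- nrow(locus$G)
  if (is.null(covariates))
    covariates <- simulate_covariates(n, seed = sub_seed(arch$seed, "covar"))

  # "rare" covers the MAF < 0.1% range; at reduced sample sizes where that
  # frequency is unattainable, the MAC <= 5 bins play the same role.
  rare <- v$maf < 0.001 | v$mac <= 5
  pick <- function(pool, k, what) {
    if (k == 0L) return(character(0))
    assert_that(length(pool) >= k,
                sprintf("not enough %s candidates (%d needed, %d available)",
                        what, k, length(pool)))
    sample(pool, k)
  }
  common_ids <- pick(v$vid[v$maf >= 0.01], arch$n_causal_common, "common")
  coding_ids <- pick(v$vid[rare & v$classification == "coding"],
                     arch$n_causal_rare_coding, "rare coding")
  noncod_ids <- pick(v$vid[rare & v$classification != "coding"],
                     arch$n_causal_rare_noncoding, "rare noncoding")

  truth_block <- function(ids, class, mean_abs, frac_dec) {
    if (length(ids) == 0L) return(NULL)
    data.frame(vid = ids, class = class,
               beta = draw_effects(length(ids), mean_abs, frac_dec),
               stringsAsFactors = FALSE)
  }
  truth <- rbind(
    truth_block(common_ids, "common", arch$mean_abs_beta_common, 0.5),
    truth_block(coding_ids, "rare_coding", arch$mean_abs_beta_coding,
                arch$frac_decreasing_coding),
    truth_block(noncod_ids, "rare_noncoding",
                arch$mean_abs_beta_noncoding,
                arch$frac_decreasing_noncoding))
  if (is.null(truth))
    truth <- data.frame(vid = character(0), class = character(0),
                        beta = numeric(0), stringsAsFactors = FALSE)

  agg_truth <- NULL
  for (u in arch$causal_aggregate_units) {
    inside <- v$vid[pos_in_interval(v$pos, u$start, u$end) & rare &
                      v$classification != "coding"]
    inside <- setdiff(inside, truth$vid)
    assert_that(length(inside) > 0,
                "causal_aggregate_unit interval contains no rare noncoding variants")
    k <- max(1L, round((u$causal_fraction %||% 0.5) * length(inside)))
    sel <- sample(inside, k)
    betas <- if (length(u$beta) == 1L) rep(u$beta, k) else
      rnorm(k, 0, u$beta_sd %||% 1)
    agg_truth <- rbind(agg_truth,
                       data.frame(unit_start = u$start, unit_end = u$end,
                                  vid = sel, beta = betas))
    truth <- rbind(truth, data.frame(vid = sel, class = "aggregate",
                                     beta = betas))
  }

  X <- stats::model.matrix(~ . - 1,
                           covariates[, setdiff(names(covariates),
                                                "sample_id"), drop = FALSE])
  gamma <- arch$covariate_effects
  if (is.null(gamma)) gamma <- rep(0.1, ncol(X))
  if (length(gamma) < ncol(X)) gamma <- rep_len(gamma, ncol(X))

  g_part <- if (nrow(truth) > 0)
    locus$G[, truth$vid, drop = FALSE] %*% truth$beta else rep(0, n)
  y <- as.numeric(g_part) + as.numeric(X %*% gamma) +
    rnorm(n, 0, arch$noise_sd)

  structure(list(y = y, sample_ids = locus$sample_ids,
                 covariates = covariates, truth = truth,
                 aggregate_truth = agg_truth, arch = arch),
            class = "rarecis_pheno")
}

#' Simulate raw per-genotype depth/quality calls and a per-base depth track
#'
#' Emulates sequencing-depth structure: per-genotype total depth is drawn
#' from a mixture of Poisson components, split into reference/alternate
#' local allele depths (LAD) according to the genotype; genotype quality is
#' below 10 with each component's configured probability. Inside
#' `low_coverage_segments` depths are scaled by the segment's `depth_factor`
#' (default 0, a dropout). The per-base track counts samples with depth > 8
#' and is exactly consistent with the per-genotype depths at variant sites.
#'
#' @param locus a [simulate_locus()] result.
#' @param depth_model list with `components`: data.frame of `weight`,
#'   `mean_depth`, `gq_low_prob` rows.
#' @param low_coverage_segments optional data.frame `start`, `end`
#'   (0-based half-open, within the window) and optional `depth_factor`.
#' @param seed integer seed.
#' @return list of class `rarecis_rawcalls`: `lad_ref`, `lad_alt`, `gq`
#'   (samples x variants matrices) and `depth_track`
#'   (chrom/start/end/n_pass run-length encoded pass-count track).
#' @export
simulate_raw_calls <- function(locus,
                               depth_model = list(components = data.frame(
                                 weight = 1, mean_depth = 30,
                                 gq_low_prob = 0)),
                               low_coverage_segments = NULL,
                               seed = 1L) {
  stopifnot(inherits(locus, "rarecis_locus"))
  comp <- depth_model$components
  assert_that(all(comp$mean_depth >= 0) && all(comp$weight >= 0),
              "depth parameters must be non-negative")
  assert_that(all(comp$gq_low_prob >= 0 & comp$gq_low_prob <= 1),
              "gq_low_prob must lie in [0, 1]")
  if (!is.null(low_coverage_segments)) {
    assert_that(all(low_coverage_segments$start >= locus$window$start) &&
                all(low_coverage_segments$end <= locus$window$end),
                "low_coverage_segments must lie within the locus window")
    if (is.null(low_coverage_segments$depth_factor))
      low_coverage_segments$depth_factor <- 0
  }
  set.seed(seed)
  n <- nrow(locus$G); m <- ncol(locus$G)
  pos <- locus$variants$pos

  seg_factor <- rep(1, m)
  if (!is.null(low_coverage_segments)) {
    for (i in seq_len(nrow(low_coverage_segments))) {
      hit <- pos_in_interval(pos, low_coverage_segments$start[i],
                             low_coverage_segments$end[i])
      seg_factor[hit] <- low_coverage_segments$depth_factor[i]
    }
  }

  comp_id <- matrix(sample.int(nrow(comp), n * m, replace = TRUE,
                               prob = comp$weight), n, m)
  mu <- matrix(comp$mean_depth[comp_id], n, m) *
    matrix(seg_factor, n, m, byrow = TRUE)
  depth <- matrix(rpois(n * m, mu), n, m)
  alt_frac <- locus$G / 2
  lad_alt <- matrix(rbinom(n * m, depth, as.numeric(alt_frac)), n, m)
  lad_ref <- depth - lad_alt
  low <- matrix(runif(n * m) <
                  matrix(comp$gq_low_prob[comp_id], n, m), n, m)
  gq <- matrix(sample(10:99, n * m, replace = TRUE), n, m)
  gq[low] <- sample(0:9, sum(low), replace = TRUE)
  dimnames(lad_ref) <- dimnames(lad_alt) <- dimnames(gq) <- dimnames(locus$G)

  depth_track <- build_depth_track(locus, comp, depth, low_coverage_segments)

  structure(list(lad_ref = lad_ref, lad_alt = lad_alt, gq = gq,
                 depth_track = depth_track),
            class = "rarecis_rawcalls")
}

# Per-base counts of samples with depth > 8: binomial draws from the mixture
# pass probability, overwritten at variant sites with the realized counts,
# then run-length encoded.
#' @noRd
build_depth_track <- function(locus, comp, depth, segments) {
  n <- nrow(depth)
  wstart <- locus$window$start; wend <- locus$window$end
  wlen <- wend - wstart
  p_pass <- sum(comp$weight / sum(comp$weight) *
                  stats::ppois(8, comp$mean_depth, lower.tail = FALSE))
  counts <- rbinom(wlen, n, p_pass)
  if (!is.null(segments)) {
    for (i in seq_len(nrow(segments))) {
      f <- segments$depth_factor[i]
      p_seg <- sum(comp$weight / sum(comp$weight) *
                     stats::ppois(8, comp$mean_depth * f,
                                  lower.tail = FALSE))
      idx <- (segments$start[i] - wstart + 1L):(segments$end[i] - wstart)
      counts[idx] <- rbinom(length(idx), n, p_seg)
    }
  }
  at <- locus$variants$pos - wstart        # 1-based offset into counts
  counts[at] <- colSums(depth > 8)
  r <- rle(counts)
  ends0 <- cumsum(r$lengths)
  data.frame(chrom = locus$window$chrom,
             start = wstart + c(0L, utils::head(ends0, -1L)),
             end = wstart + ends0, n_pass = r$values,
             stringsAsFactors = FALSE)
}
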