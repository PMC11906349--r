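# End-to-end orchestration: QC -> annotation/masks -> single-variant ->
# conditional-joint -> coverage QC -> conditioned aggregate testing ->
# stepwise independence -> enrichment. Every output table is written as it
# is produced, so a failing stage preserves the partial results.

#' Pipeline run configuration
#'
#' Thresholds default to the discovery settings: single-variant
#' significance 2.95e-10, aggregate significance 8.71e-9, MAC >= 5 for
#' single-variant testing, MAF < 0.1% for rare-aggregate membership and
#' for the conditioning-lead frequency floor, missingness <= 10%,
#' coverage 99.5% of bases / 90% of samples / depth > 8.
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param single_p,aggregate_p significance thresholds.
#' @param min_mac single-variant MAC floor.
#' @param max_maf rare-aggregate MAF ceiling.
#' @param conditioning_maf lead-variant frequency floor for conditioning.
#' @param max_missing per-variant missingness ceiling.
#' @param coverage_frac,sample_frac,min_depth,min_gq coverage/QC
#'   thresholds.
#' @param cis_flank cis-window flank in bp.
#' @param n_sim_enrichment bootstrap draws for the enrichment stage.
#' @param n_traits null traits for the optional thresholds stage.
#' @param stages character vector of stages to run.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, single_p = 2.95e-10,
                       aggregate_p = 8.71e-9, min_mac = 5,
                       max_maf = 0.001, conditioning_maf = 0.001,
                       max_missing = 0.10, coverage_frac = 0.995,
                       sample_frac = 0.90, min_depth = 8, min_gq = 10,
                       cis_flank = 1000000L, n_sim_enrichment = 1000L,
                       n_traits = 20L,
                       stages = c("qc", "single", "cojo", "coverage",
                                  "aggregate", "stepwise", "enrichment")) {
  assert_that(single_p > 0 && single_p < 1 && aggregate_p > 0 &&
                aggregate_p < 1, "thresholds must lie in (0, 1)")
  structure(list(seed = as.integer(seed), single_p = single_p,
                 aggregate_p = aggregate_p, min_mac = min_mac,
                 max_maf = max_maf, conditioning_maf = conditioning_maf,
                 max_missing = max_missing, coverage_frac = coverage_frac,
                 sample_frac = sample_frac, min_depth = min_depth,
                 min_gq = min_gq, cis_flank = as.integer(cis_flank),
                 n_sim_enrichment = as.integer(n_sim_enrichment),
                 n_traits = as.integer(n_traits), stages = stages),
            class = "run_config")
}

#' @noRd
normalize_fixture <- function(fixture, pheno = NULL, raw = NULL) {
  if (is.character(fixture)) fixture <- read_fixture(fixture)
  if (inherits(fixture, "rarecis_locus")) {
    assert_that(!is.null(pheno), "a phenotype is required")
    fixture <- list(variants = fixture$variants, G = fixture$G,
                    gene = fixture$gene, regions = fixture$regions,
                    score_tracks = fixture$score_tracks,
                    window = fixture$window,
                    sample_ids = fixture$sample_ids,
                    raw = if (!is.null(raw))
                      list(lad_sum = raw$lad_ref + raw$lad_alt,
                           gq = raw$gq) else NULL,
                    depth_track = raw$depth_track,
                    pheno = data.frame(sample_id = pheno$sample_ids,
                                       y = pheno$y),
                    covariates = pheno$covariates, truth = pheno$truth)
  }
  fixture
}

#' Run the full cis discovery pipeline on one locus fixture
#'
#' Deterministic given the config seed: identical config and inputs give
#' byte-identical result tables. A stage failure halts the run with the
#' stage name; tables already written are preserved.
#'
#' @param fixture a fixture directory path, or a `rarecis_locus` (then
#'   `pheno` is required), or a list as returned by [read_fixture()].
#' @param config a [run_config()].
#' @param out_dir output directory for result tables.
#' @param pheno,raw companions when `fixture` is a `rarecis_locus`.
#' @return invisibly, a list with the in-memory results (`summary_stats`,
#'   `joint`, `aggregate_results`, `independent_aggregates`, `coverage`,
#'   `enrichment`, `qc_report`, `config`).
#' @export
run_pipeline <- function(fixture, config = run_config(), out_dir,
                         pheno = NULL, raw = NULL) {
  fx <- normalize_fixture(fixture, pheno, raw)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat(sprintf("rarecis pipeline, seed %d\n", config$seed), file = logf)
  note <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = logf, append = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[[3L]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    note("stage %-10s %.2fs", name, proc.time()[[3L]] - t0)
    res
  }
  emit <- function(df, name) {
    data.table::fwrite(df, file.path(out_dir, name), sep = "\t")
    df
  }
  out <- list(config = config)
  jsonlite::write_json(config[setdiff(names(config), "stages")],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  G <- fx$G
  variants <- fx$variants
  if (is.null(variants$classification))
    variants$classification <- classify_variants(variants, fx$gene)

  # --- genotype QC -------------------------------------------------------
  if ("qc" %in% config$stages && !is.null(fx$raw)) {
    out$qc_report <- stage("qc", {
      d <- apply_call_filters(G, fx$raw$lad_sum, fx$raw$gq,
                              min_depth = config$min_depth,
                              min_gq = config$min_gq)
      fm <- filter_missingness(d, config$max_missing)
      rep <- variant_qc_table(d)
      rep$kept <- fm$keep
      G <- fm$dosage
      variants <- variants[fm$keep, , drop = FALSE]
      s <- allele_summary(G)
      variants$mac <- s$mac; variants$maf <- s$maf
      variants$missingness <- s$missingness
      emit(rep, "qc_report.tsv")
    })
  }

  units <- stage("annotation", {
    lx <- list(variants = variants, gene = fx$gene, regions = fx$regions,
               score_tracks = fx$score_tracks, window = fx$window)
    build_aggregate_units(lx, max_maf = config$max_maf)
  })

  y <- rank_inverse_normalize(fx$pheno$y)
  X <- fx$covariates

  # --- single-variant + joint -------------------------------------------
  sv <- NULL; joint <- NULL
  if ("single" %in% config$stages) {
    sv <- stage("single", {
      r <- single_variant_assoc(G, y, X, min_mac = config$min_mac)
      r$classification <- variants$classification[match(r$vid,
                                                        variants$vid)]
      emit(r, "summary_stats.tsv")
    })
    out$summary_stats <- sv
  }
  if ("cojo" %in% config$stages) {
    joint <- stage("cojo", {
      cojo_select(G, y, X, p_threshold = config$single_p,
                  min_mac = config$min_mac, variants = variants)
    })
    js <- joint$signals
    js$classification <- variants$classification[match(js$vid,
                                                       variants$vid)]
    emit(js, "joint_signals.tsv")
    out$joint <- joint
  }

  # --- coverage QC -------------------------------------------------------
  if ("coverage" %in% config$stages && !is.null(fx$depth_track)) {
    out$coverage <- stage("coverage", {
      b <- gene_bounds(fx$gene, "union")
      n_s <- length(fx$sample_ids)
      gp <- compute_coverage(fx$depth_track,
                             list(start = b[["start"]], end = b[["end"]]),
                             n_s, config$sample_frac)
      rp <- compute_coverage(fx$depth_track, fx$window, n_s,
                             config$sample_frac)
      v <- coverage_filter(gp, rp, config$coverage_frac)
      emit(data.frame(gene_coverage_frac = v$gene_coverage_frac,
                      region_coverage_frac = v$region_coverage_frac,
                      passes_coverage = v$passes_coverage,
                      max_abs_beta_discrepancy =
                        if (!is.null(joint))
                          joint$max_abs_beta_discrepancy else NA),
           "coverage_verdict.tsv")
    })
  }

  # --- conditioned aggregate testing ------------------------------------
  agg <- NULL; cond <- character(0)
  if ("aggregate" %in% config$stages) {
    agg <- stage("aggregate", {
      cond <- build_conditioning_set(joint, variants, fx$gene$gene_id,
                                     maf_min = config$conditioning_maf)
      adj <- residualize(y, X, if (length(cond) > 0)
        G[, intersect(cond, colnames(G)), drop = FALSE] else NULL)
      r <- aggregate_scan(units, G, adj,
                          test_config(max_maf = config$max_maf))
      r$conditioning_set_size <- length(cond)
      emit(r, "aggregate_results.tsv")
    })
    out$aggregate_results <- agg
  }

  # --- stepwise independence + flags + sensitivity ----------------------
  indep <- NULL
  if ("stepwise" %in% config$stages && !is.null(agg)) {
    indep <- stage("stepwise", {
      ia <- stepwise_aggregate_conditioning(
        units, G, y, X, base_conditioning = cond,
        threshold = config$aggregate_p,
        config = test_config(max_maf = config$max_maf))
      ia <- flag_single_lead_aggregates(
        ia, if (!is.null(joint)) joint$signals$vid else character(0),
        sv, sv_threshold = config$single_p)
      emit(ia, "independent_aggregates.tsv")
    })
    out$independent_aggregates <- indep
    sens <- stage("sensitivity", {
      pq <- if (!is.null(joint)) joint$signals$vid else character(0)
      emit(sensitivity_condition_all_pqtls(
        indep, units, G, y, X, base_conditioning = cond,
        pqtl_vids = pq, config = test_config(max_maf = config$max_maf)),
        "sensitivity.tsv")
    })
    out$sensitivity <- sens
  }

  # --- regulatory-region enrichment -------------------------------------
  if ("enrichment" %in% config$stages && !is.null(joint)) {
    out$enrichment <- stage("enrichment", {
      rare_nc <- variants[variants$maf < 0.01 &
                            variants$classification != "coding", ,
                          drop = FALSE]
      sig <- rare_nc[rare_nc$vid %in% joint$signals$vid, , drop = FALSE]
      if (nrow(sig) == 0L || nrow(rare_nc) < 2L) {
        emit(data.frame(stratum = character(0),
                        observed_overlap = integer(0),
                        null_mean = numeric(0), null_sd = numeric(0),
                        null_q95 = numeric(0), empirical_p = numeric(0)),
             "enrichment.tsv")
      } else {
        er <- bootstrap_region_enrichment(
          data.frame(start = sig$pos - 1L, end = sig$pos),
          data.frame(start = rare_nc$pos - 1L, end = rare_nc$pos),
          fx$regions, n_sim = config$n_sim_enrichment,
          seed = sub_seed(config$seed, "enrich"), by = "feature_type")
        emit(er, "enrichment.tsv")
      }
    })
  }

  # --- empirical thresholds (optional stage) ----------------------------
  if ("thresholds" %in% config$stages) {
    out$thresholds <- stage("thresholds", {
      th <- empirical_thresholds(G, units, X,
                                 n_traits = config$n_traits,
                                 seed = sub_seed(config$seed, "thresholds"),
                                 min_mac = config$min_mac,
                                 config = test_config(max_maf =
                                                        config$max_maf))
      emit(data.frame(single_variant_threshold =
                        th$single_variant_threshold,
                      aggregate_threshold = th$aggregate_threshold,
                      m_single = th$m_single,
                      m_aggregate = th$m_aggregate),
           "thresholds.tsv")
      th
    })
  }

  tables <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(package = "rarecis",
                   version = as.character(utils::packageVersion("rarecis")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   tables = stats::setNames(
                     as.list(unname(tools::md5sum(tables))),
                     basename(tables)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out)
}

#' Summarize a completed pipeline run
#'
#' Recomputes every reported number from the shipped result tables:
#' per-stage counts, direction-of-effect splits among joint signals, and
#' the fraction of independent aggregates whose strongest framework was
#' the burden test.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return list of summaries (also printed).
#' @export
pipeline_report <- function(run_dir) {
  rd <- function(name) {
    f <- file.path(run_dir, name)
    if (file.exists(f)) as.data.frame(data.table::fread(f)) else NULL
  }
  sv <- rd("summary_stats.tsv")
  js <- rd("joint_signals.tsv")
  agg <- rd("aggregate_results.tsv")
  ia <- rd("independent_aggregates.tsv")
  rep <- list(n_variants_tested = if (!is.null(sv)) nrow(sv) else 0L,
              n_joint_signals = if (!is.null(js)) nrow(js) else 0L,
              n_aggregate_tests = if (!is.null(agg))
                sum(!is.na(agg$p)) else 0L,
              n_independent_aggregates = if (!is.null(ia)) nrow(ia)
              else 0L)
  if (!is.null(js) && nrow(js) > 0) {
    rare <- js[js$maf < 0.01, , drop = FALSE]
    rep$frac_decreasing_joint <- mean(js$beta_joint < 0)
    if (nrow(rare) > 0) {
      for (cl in c("coding", "proximal_regulatory",
                   "intergenic_regulatory")) {
        sub <- rare[rare$classification == cl, , drop = FALSE]
        if (nrow(sub) > 0)
          rep[[paste0("frac_decreasing_rare_", cl)]] <-
            mean(sub$beta_joint < 0)
      }
    }
  }
  if (!is.null(ia) && nrow(ia) > 0 && !is.null(agg)) {
    wins <- vapply(ia$unit_id, function(id) {
      sub <- agg[agg$unit_id == id & !is.na(agg$p), , drop = FALSE]
      if (nrow(sub) == 0L) return(NA)
      bp <- suppressWarnings(min(sub$p[sub$test == "BURDEN"]))
      dp <- suppressWarnings(min(sub$p[sub$test %in% c("SKAT",
                                                       "ACAT_V")]))
      is.finite(bp) && (!is.finite(dp) || bp <= dp)
    }, NA)
    rep$burden_win_fraction <- mean(wins, na.rm = TRUE)
  }
  for (nm in names(rep))
    cat(sprintf("%-35s %s\n", nm,
                format(rep[[nm]], digits = 4)))
  invisible(rep)
}
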