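# Variant classification and aggregate-unit construction for a cis-locus.
#
# All intervals are 0-based half-open; variant positions are 1-based.

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome.
#' @param strand "+" or "-" (carried, not used for window arithmetic:
#'   coordinates are genomic).
#' @param transcripts list of transcripts, each a list with `transcript_id`,
#'   `start`, `end` (0-based half-open) and data.frames `exons`, `utr5`,
#'   `utr3` with `start`/`end` columns.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand = "+", transcripts) {
  for (tx in transcripts) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    if (nrow(ex) > 1L)
      assert_that(all(ex$start[-1L] >= ex$end[-nrow(ex)]),
                  "exons overlap within a transcript")
    for (u in list(tx$utr5, tx$utr3))
      if (!is.null(u) && nrow(u) > 0)
        assert_that(all(u$start >= tx$start & u$end <= tx$end),
                    "UTRs must lie within the transcript span")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts), class = "gene_model")
}

# UTR-to-UTR bounds of a gene: union over transcripts of the outermost
# UTR coordinates (falling back to the transcript span when UTRs are
# absent), or the single longest transcript when mode = "longest".
#' @noRd
gene_bounds <- function(gene, mode = c("union", "longest")) {
  mode <- match.arg(mode)
  txs <- gene$transcripts
  if (mode == "longest") {
    len <- vapply(txs, function(t) t$end - t$start, 0)
    txs <- txs[which.max(len)]
  }
  lo <- Inf; hi <- -Inf
  for (tx in txs) {
    us <- rbind(tx$utr5, tx$utr3)
    if (is.null(us) || nrow(us) == 0)
      us <- data.frame(start = tx$start, end = tx$end)
    lo <- min(lo, min(us$start)); hi <- max(hi, max(us$end))
  }
  c(start = lo, end = hi)
}

#' Define the cis-window around a gene
#'
#' The cis-window extends `flank` bp beyond the outermost 5'- and 3'-UTR
#' bounds of the gene (by default over the union of all transcripts; set
#' `mode = "longest"` to use only the longest transcript), clipped at the
#' chromosome bounds.
#'
#' @param gene a [gene_model()].
#' @param flank bp added either side of the UTR bounds (default 1 Mb).
#' @param chrom_length chromosome length for clipping (default `Inf`).
#' @param mode transcript-bound mode, `"union"` or `"longest"`.
#' @return list of class `cis_window` with `chrom`, `start`, `end`
#'   (0-based half-open), `gene_id`.
#' @export
define_cis_window <- function(gene, flank = 1000000L, chrom_length = Inf,
                              mode = c("union", "longest")) {
  stopifnot(inherits(gene, "gene_model"))
  b <- gene_bounds(gene, match.arg(mode))
  structure(list(chrom = gene$chrom,
                 start = max(0, b[["start"]] - flank),
                 end = min(chrom_length, b[["end"]] + flank),
                 gene_id = gene$gene_id),
            class = "cis_window")
}

# Consequence terms with predicted impact on the coding sequence.
coding_consequences <- c(
  "missense_variant", "synonymous_variant", "stop_gained", "stop_lost",
  "start_lost", "frameshift_variant", "inframe_insertion",
  "inframe_deletion", "splice_acceptor_variant", "splice_donor_variant",
  "protein_altering_variant", "coding_sequence_variant")

#' Classify variants as coding, proximal-regulatory or intergenic-regulatory
#'
#' A variant is `coding` if its consequence predicts a coding impact on any
#' transcript (coding takes priority over every other label); otherwise
#' `proximal_regulatory` if it lies within the gene body (UTRs or introns)
#' or within `flank` bp of the outermost UTRs; otherwise
#' `intergenic_regulatory`. Every variant receives exactly one class.
#'
#' @param variants data.frame with `pos` and `consequence` columns.
#' @param gene a [gene_model()] (or list of them; proximity to any counts).
#' @param flank proximal window in bp (default 5,000).
#' @return character vector of classifications.
#' @export
classify_variants <- function(variants, gene, flank = 5000L) {
  genes <- if (inherits(gene, "gene_model")) list(gene) else gene
  proximal <- rep(FALSE, nrow(variants))
  for (g in genes) {
    b <- gene_bounds(g, "union")
    proximal <- proximal | pos_in_interval(variants$pos,
                                           b[["start"]] - flank,
                                           b[["end"]] + flank)
  }
  ifelse(variants$consequence %in% coding_consequences, "coding",
         ifelse(proximal, "proximal_regulatory", "intergenic_regulatory"))
}

#' Default mask catalogue
#'
#' The masks applied to rare variants (MAF below `max_maf`): high-confidence
#' loss of function, missense with CADD > 25, all coding, gene-proximal,
#' highly conserved (GERP > 2), highly constrained (JARVIS > 0.99),
#' predicted splice (SpliceAI > 50, intronic), and an unscored all-noncoding
#' mask. Score thresholds are strict inequalities; variants missing a score
#' a mask requires are excluded from that mask.
#'
#' @param max_maf maximum minor allele frequency for mask membership
#'   (default 0.001).
#' @return named list of mask definitions.
#' @export
default_masks <- function(max_maf = 0.001) {
  lof <- c("stop_gained", "stop_lost", "start_lost", "frameshift_variant",
           "splice_acceptor_variant", "splice_donor_variant")
  list(
    lof_hc = list(name = "lof_hc", kind = "coding",
                  classes = "coding", consequences = lof,
                  require_loftee = TRUE, max_maf = max_maf),
    missense_cadd25 = list(name = "missense_cadd25", kind = "coding",
                           classes = "coding",
                           consequences = "missense_variant",
                           score = list(field = "cadd", threshold = 25),
                           max_maf = max_maf),
    coding_all = list(name = "coding_all", kind = "coding",
                      classes = "coding", max_maf = max_maf),
    proximal_all = list(name = "proximal_all", kind = "noncoding",
                        classes = "proximal_regulatory", max_maf = max_maf),
    conserved_gerp = list(name = "conserved_gerp", kind = "noncoding",
                          classes = c("proximal_regulatory",
                                      "intergenic_regulatory"),
                          score = list(field = "gerp", threshold = 2),
                          max_maf = max_maf),
    constrained_jarvis = list(name = "constrained_jarvis", kind = "noncoding",
                              classes = c("proximal_regulatory",
                                          "intergenic_regulatory"),
                              score = list(field = "jarvis",
                                           threshold = 0.99),
                              max_maf = max_maf),
    splice_ai50 = list(name = "splice_ai50", kind = "noncoding",
                       classes = c("proximal_regulatory",
                                   "intergenic_regulatory"),
                       consequences = "intron_variant",
                       score = list(field = "spliceai", threshold = 50),
                       max_maf = max_maf),
    noncoding_all = list(name = "noncoding_all", kind = "noncoding",
                         classes = c("proximal_regulatory",
                                     "intergenic_regulatory"),
                         max_maf = max_maf))
}

#' Evaluate mask membership
#'
#' @param variants variant data.frame (columns `vid`, `maf`,
#'   `classification`, `consequence`, score columns, `loftee_hc`).
#' @param definitions named list of mask definitions
#'   (see [default_masks()]).
#' @return named list mapping mask name to member vids.
#' @export
build_masks <- function(variants, definitions = default_masks()) {
  lapply(definitions, function(d) {
    assert_that(!is.null(d$name) && !is.null(d$classes),
                "malformed mask definition")
    keep <- variants$maf < (d$max_maf %||% 0.001) &
      variants$classification %in% d$classes
    if (!is.null(d$consequences))
      keep <- keep & variants$consequence %in% d$consequences
    if (isTRUE(d$require_loftee))
      keep <- keep & !is.na(variants$loftee_hc) & variants$loftee_hc
    if (!is.null(d$score)) {
      s <- variants[[d$score$field]]
      assert_that(!is.null(s),
                  sprintf("mask '%s' requires missing score column '%s'",
                          d$name, d$score$field))
      keep <- keep & !is.na(s) & s > d$score$threshold
    }
    variants$vid[keep]
  })
}

#' @noRd
new_aggregate_unit <- function(unit_id, unit_kind, chrom, start, end,
                               mask, members) {
  list(unit_id = unit_id, unit_kind = unit_kind, chrom = chrom,
       start = start, end = end, mask = mask, members = members)
}

#' Sliding-window aggregate units
#'
#' 2-kb windows starting every 1 kb from the cis-window start (so interior
#' bases are covered by exactly two windows); the trailing window at the 3'
#' edge may be shorter than 2 kb. Members are the rare noncoding variants
#' inside each half-open window; coding variants are never members. Empty
#' windows are retained but flagged untestable.
#'
#' @param window a [define_cis_window()] (or any list with `chrom`,
#'   `start`, `end`).
#' @param variants variant data.frame.
#' @param size,step window size and step in bp.
#' @param max_maf rare-variant threshold for membership.
#' @return list of aggregate units (each with `testable` flag).
#' @export
build_sliding_windows <- function(window, variants, size = 2000L,
                                  step = 1000L, max_maf = 0.001) {
  starts <- seq(window$start, window$end - 1L, by = step)
  elig <- variants$classification != "coding" & variants$maf < max_maf
  lapply(starts, function(s) {
    e <- min(s + size, window$end)
    mem <- variants$vid[elig & pos_in_interval(variants$pos, s, e)]
    u <- new_aggregate_unit(
      unit_id = sprintf("%s:%d-%d", window$chrom, s, e),
      unit_kind = "sliding_window", chrom = window$chrom,
      start = s, end = e, mask = "noncoding_all", members = mem)
    u$testable <- length(mem) > 0
    u
  })
}

#' Score-defined window units (constraint and conservation)
#'
#' Constrained windows are those with constraint z-score >= 4 (inclusive);
#' conserved windows require a phastCon percentile >= 99 and no exon overlap
#' (a single base of overlap excludes the window).
#'
#' @param window cis-window.
#' @param constraint data.frame `start`, `end`, `z` per 1-kb window.
#' @param phastcon data.frame `start`, `end`, `percentile`.
#' @param exons data.frame of exon intervals (`start`, `end`).
#' @param variants variant data.frame for membership.
#' @param z_min,pct_min inclusion thresholds.
#' @param max_maf rare-variant threshold.
#' @return list of aggregate units.
#' @export
build_score_windows <- function(window, constraint, phastcon, exons,
                                variants, z_min = 4, pct_min = 99,
                                max_maf = 0.001) {
  for (tr in list(constraint, phastcon))
    assert_that(min(tr$start) <= window$start && max(tr$end) >= window$end,
                "score track does not cover the cis-window")
  elig <- variants$classification != "coding" & variants$maf < max_maf
  members_in <- function(s, e)
    variants$vid[elig & pos_in_interval(variants$pos, s, e)]
  units <- list()
  keep <- constraint$z >= z_min
  for (i in which(keep)) {
    s <- constraint$start[i]; e <- constraint$end[i]
    units[[length(units) + 1L]] <- new_aggregate_unit(
      sprintf("constrained:%s:%d-%d", window$chrom, s, e),
      "constrained_window", window$chrom, s, e, "constrained_z4",
      members_in(s, e))
  }
  overlaps_exon <- function(s, e)
    any(exons$start < e & exons$end > s)
  for (i in which(phastcon$percentile >= pct_min)) {
    s <- phastcon$start[i]; e <- phastcon$end[i]
    if (overlaps_exon(s, e)) next
    units[[length(units) + 1L]] <- new_aggregate_unit(
      sprintf("conserved:%s:%d-%d", window$chrom, s, e),
      "conserved_window", window$chrom, s, e, "phastcon_p99",
      members_in(s, e))
  }
  units
}

#' Build the full catalogue of aggregate units for a locus
#'
#' Gene-centric units (one coding and one proximal unit per gene, carrying
#' every applicable mask), one unit per active regulatory region, score
#' windows and sliding windows. Coding and noncoding masks are kept on
#' separate units so that all-mask combination never mixes them.
#'
#' @param locus a `rarecis_locus` (or list with `variants`, `gene`,
#'   `regions`, `score_tracks`, `window`).
#' @param masks mask catalogue (default [default_masks()]).
#' @param max_maf rare threshold.
#' @param sliding include sliding windows (default TRUE).
#' @return list of aggregate units; each unit has `masks`: a named list of
#'   member vids per mask.
#' @export
build_aggregate_units <- function(locus, masks = default_masks(),
                                  max_maf = 0.001, sliding = TRUE) {
  v <- locus$variants
  mask_members <- build_masks(v, masks)
  kind_of <- vapply(masks, `[[`, "", "kind")
  gene <- locus$gene
  b <- gene_bounds(gene, "union")

  in_interval <- function(s, e) v$vid[pos_in_interval(v$pos, s, e)]
  make_unit <- function(id, ukind, s, e, mask_names) {
    mem <- in_interval(s, e)
    ml <- lapply(mask_names, function(mn) intersect(mask_members[[mn]], mem))
    names(ml) <- mask_names
    ml <- ml[vapply(ml, length, 0L) > 0]
    u <- new_aggregate_unit(id, ukind, locus$window$chrom, s, e,
                            mask = paste(names(ml), collapse = ","),
                            members = unique(unlist(ml)))
    u$masks <- ml
    u$testable <- length(u$members) > 0
    u
  }

  units <- list(
    make_unit(paste0(gene$gene_id, ":coding"), "gene_coding",
              b[["start"]], b[["end"]], names(masks)[kind_of == "coding"]),
    make_unit(paste0(gene$gene_id, ":proximal"), "gene_proximal",
              b[["start"]] - 5000L, b[["end"]] + 5000L,
              names(masks)[kind_of == "noncoding"]))

  act <- locus$regions[locus$regions$active, , drop = FALSE]
  nc_masks <- names(masks)[kind_of == "noncoding"]
  for (i in seq_len(nrow(act))) {
    units[[length(units) + 1L]] <- make_unit(
      sprintf("ENSR:%s:%d-%d:%s", act$chrom[i], act$start[i], act$end[i],
              act$feature_type[i]),
      "regulatory_region", act$start[i], act$end[i], nc_masks)
  }

  if (!is.null(locus$score_tracks)) {
    tx <- gene$transcripts[[1L]]
    sw <- build_score_windows(locus$window, locus$score_tracks$constraint,
                              locus$score_tracks$phastcon, tx$exons, v,
                              max_maf = max_maf)
    for (u in sw) {
      u$masks <- stats::setNames(list(intersect(
        mask_members$noncoding_all, u$members)), u$mask)
      u$members <- u$masks[[1L]]
      u$testable <- length(u$members) > 0
      units[[length(units) + 1L]] <- u
    }
  }

  if (sliding) {
    for (u in build_sliding_windows(locus$window, v, max_maf = max_maf)) {
      u$masks <- stats::setNames(list(u$members), "noncoding_all")
      units[[length(units) + 1L]] <- u
    }
  }
  units
}
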