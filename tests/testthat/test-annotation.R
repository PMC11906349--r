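# cis-window definition, variant classification, masks and window units.

test_that("cis-window arithmetic, clipping and zero flank", {
  g <- toy_gene(s = 2000000L, span = 10000L)
  w <- define_cis_window(g, flank = 1000000L)
  expect_equal(w$start, 1000000)
  expect_equal(w$end, 3010000)

  near <- toy_gene(s = 200000L, span = 10000L)
  wc <- define_cis_window(near, flank = 1000000L)
  expect_equal(wc$start, 0)

  w0 <- define_cis_window(g, flank = 0L)
  expect_equal(w0$start, 2000000)
  expect_equal(w0$end, 2010000)
})

test_that("union and longest transcript modes differ as built", {
  loc <- small_locus(seed = 3L)
  wu <- define_cis_window(loc$gene, flank = 0L, mode = "union")
  wl <- define_cis_window(loc$gene, flank = 0L, mode = "longest")
  expect_true(wu$end - wu$start >= wl$end - wl$start)
})

test_that("classification prioritizes coding and respects boundaries", {
  g <- toy_gene(s = 2000000L, span = 10000L)
  v <- data.frame(
    pos = c(2000500L,        # coding consequence inside gene
            2000000L - 4999L,  # 4,999 bp upstream of the 5'UTR start
            2000000L - 900000L),  # far away
    consequence = c("missense_variant", "upstream_gene_variant",
                    "intergenic_variant"))
  cl <- classify_variants(v, g, flank = 5000L)
  expect_identical(cl, c("coding", "proximal_regulatory",
                         "intergenic_regulatory"))
  # coding wins even within the proximal flank of another gene
  v2 <- data.frame(pos = 2000000L - 100L,
                   consequence = "missense_variant")
  expect_identical(classify_variants(v2, g), "coding")
  # every variant gets exactly one class
  loc <- small_locus(seed = 6L)
  expect_true(all(loc$variants$classification %in%
                    c("coding", "proximal_regulatory",
                      "intergenic_regulatory")))
})

test_that("mask score thresholds are strict and MAF-bounded", {
  v <- data.frame(
    vid = c("a", "b", "c", "d"),
    maf = c(0.0005, 0.0005, 0.002, 0.0005),
    classification = c("proximal_regulatory", "proximal_regulatory",
                       "proximal_regulatory", "proximal_regulatory"),
    consequence = c("intron_variant", "intron_variant",
                    "intron_variant", "intron_variant"),
    gerp = c(2.0, 2.01, 5, NA), cadd = 0, jarvis = 0.5,
    spliceai = c(10, 51, 60, 51), loftee_hc = FALSE,
    stringsAsFactors = FALSE)
  mm <- build_masks(v)
  expect_false("a" %in% mm$conserved_gerp)   # GERP = 2.0 is not > 2
  expect_true("b" %in% mm$conserved_gerp)
  expect_false("c" %in% mm$conserved_gerp)   # MAF 0.002 over the 0.1% cap
  expect_false("d" %in% mm$conserved_gerp)   # missing required score
  expect_true(all(c("b", "d") %in% mm$splice_ai50))
  expect_false("a" %in% mm$splice_ai50)      # SpliceAI 10 below 50
  expect_false("c" %in% mm$splice_ai50)
})

test_that("mask membership is monotone in score thresholds", {
  loc <- small_locus(seed = 12L)
  lo <- build_masks(loc$variants, list(
    m = list(name = "m", kind = "noncoding",
             classes = c("proximal_regulatory", "intergenic_regulatory"),
             score = list(field = "gerp", threshold = 1))))$m
  hi <- build_masks(loc$variants, list(
    m = list(name = "m", kind = "noncoding",
             classes = c("proximal_regulatory", "intergenic_regulatory"),
             score = list(field = "gerp", threshold = 2))))$m
  expect_true(all(hi %in% lo))
})

test_that("sliding windows tile the cis-window with 1-kb overlap", {
  win <- list(chrom = "chr1", start = 0L, end = 10000L)
  v <- data.frame(vid = "x", pos = 5L, maf = 1e-4,
                  classification = "intergenic_regulatory")
  sw <- build_sliding_windows(win, v)
  expect_length(sw, 10L)           # 9 full + 1 trailing partial
  widths <- vapply(sw, function(u) u$end - u$start, 0)
  expect_equal(sum(widths == 2000), 9L)
  expect_equal(sum(widths == 1000), 1L)
  # interior bases covered by exactly two windows
  cover <- integer(10000)
  for (u in sw) cover[(u$start + 1):u$end] <- cover[(u$start + 1):u$end] + 1L
  expect_true(all(cover[1001:9000] == 2L))
  expect_true(all(cover[1:1000] == 1L))
})

test_that("sliding-window membership follows half-open convention and excludes coding", {
  win <- list(chrom = "chr1", start = 0L, end = 6000L)
  v <- data.frame(
    vid = c("edge", "coding", "inside"),
    pos = c(2000L, 1500L, 1500L),     # pos 2000 = half-open end of [0,2000)
    maf = 1e-4,
    classification = c("intergenic_regulatory", "coding",
                       "intergenic_regulatory"),
    stringsAsFactors = FALSE)
  sw <- build_sliding_windows(win, v)
  first <- sw[[1L]]                    # [0, 2000)
  second <- sw[[2L]]                   # [1000, 3000)
  expect_true("edge" %in% first$members)    # pos 2000 is base index 1999
  expect_false("edge" %in% sw[[3L]]$members)
  expect_false("coding" %in% first$members)
  expect_true("inside" %in% first$members)
  expect_true("inside" %in% second$members)
})

test_that("score windows: inclusive z threshold, exon exclusion", {
  win <- list(chrom = "chr1", start = 0L, end = 3000L)
  constraint <- data.frame(start = c(0L, 1000L, 2000L),
                           end = c(1000L, 2000L, 3000L),
                           z = c(4.0, 3.99, 5))
  phast <- data.frame(start = c(0L, 1000L, 2000L),
                      end = c(1000L, 2000L, 3000L),
                      percentile = c(99.5, 99.5, 50))
  exons <- data.frame(start = 999L, end = 1100L)  # 1-bp overlap with [0,1000)
  v <- data.frame(vid = "x", pos = 500L, maf = 1e-4,
                  classification = "intergenic_regulatory")
  u <- build_score_windows(win, constraint, phast, exons, v)
  kinds <- vapply(u, `[[`, "", "unit_kind")
  starts <- vapply(u, `[[`, 0, "start")
  expect_true(0 %in% starts[kinds == "constrained_window"])   # z = 4.0 in
  expect_false(1000 %in% starts[kinds == "constrained_window"])
  # both phastCon windows hit an exon ([0,1000) by 1 bp; [1000,2000) fully)
  expect_false(any(starts[kinds == "conserved_window"] %in% c(0, 1000)))
  none <- build_score_windows(win, transform(constraint, z = 0), phast,
                              data.frame(start = 0L, end = 3000L), v)
  expect_length(none, 0L)
  expect_error(build_score_windows(list(chrom = "chr1", start = 0L,
                                        end = 99999L),
                                   constraint, phast, exons, v),
               "does not cover")
})
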