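# Fixture serialization: VCF 4.2 (GT:AD:GQ), TSV tables, GFF3 gene model,
# BED regulatory/problematic regions, BEDGRAPH-like pass-count track.
# Writers emit the standard text formats; readers go through vcfR and
# rtracklayer and are the same readers the pipeline uses.

#' @noRd
dosage_to_gt <- function(d) {
  out <- c("0/0", "0/1", "1/1")[d + 1L]
  out[is.na(d)] <- "./."
  out
}

#' Write a complete locus fixture to a directory
#'
#' Emits `genotypes.vcf` (VCF 4.2, FORMAT `GT` or `GT:AD:GQ` when raw
#' calls are supplied), `annotations.tsv`, `gene_model.gff3`,
#' `regulatory.bed` (BED6+2: name = feature type, then tissue group and
#' activity), `depth.bedgraph` (pass counts), `phenotypes.tsv`,
#' `covariates.tsv`, `truth.tsv` and `config.json`.
#'
#' @param locus a `rarecis_locus`.
#' @param dir output directory (created if needed).
#' @param pheno optional `rarecis_pheno`.
#' @param raw optional `rarecis_rawcalls`.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(locus, dir, pheno = NULL, raw = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  assert_that(ok && file.access(dir, 2L) == 0L,
              sprintf("cannot write to directory '%s'", dir))
  v <- locus$variants
  n <- nrow(locus$G); m <- ncol(locus$G)

  gt <- matrix(dosage_to_gt(locus$G), n, m)
  if (!is.null(raw)) {
    body <- matrix(sprintf("%s:%d,%d:%d", gt, raw$lad_ref, raw$lad_alt,
                           raw$gq), n, m)
    fmt <- "GT:AD:GQ"
  } else {
    body <- gt
    fmt <- "GT"
  }
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s>", locus$window$chrom),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
            "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", locus$sample_ids), collapse = "\t"))
  fixed <- paste(v$chrom, v$pos, v$vid, v$ref, v$alt, ".", "PASS", ".",
                 fmt, sep = "\t")
  lines <- paste(fixed, apply(body, 2L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(c(meta, lines), file.path(dir, "genotypes.vcf"))

  data.table::fwrite(
    v[, c("vid", "chrom", "pos", "consequence", "annotated_gene",
          "classification", "gerp", "cadd", "jarvis", "spliceai",
          "loftee_hc")],
    file.path(dir, "annotations.tsv"), sep = "\t")

  write_gff3(locus$gene, file.path(dir, "gene_model.gff3"))

  reg <- locus$regions
  data.table::fwrite(
    data.frame(reg$chrom, reg$start, reg$end, reg$feature_type, 0L, ".",
               reg$tissue_group, reg$active),
    file.path(dir, "regulatory.bed"), sep = "\t", col.names = FALSE)

  if (!is.null(raw))
    data.table::fwrite(raw$depth_track, file.path(dir, "depth.bedgraph"),
                       sep = "\t", col.names = FALSE)

  if (!is.null(pheno)) {
    data.table::fwrite(data.frame(sample_id = pheno$sample_ids,
                                  y = pheno$y),
                       file.path(dir, "phenotypes.tsv"), sep = "\t")
    data.table::fwrite(pheno$covariates, file.path(dir, "covariates.tsv"),
                       sep = "\t")
    data.table::fwrite(pheno$truth, file.path(dir, "truth.tsv"),
                       sep = "\t")
  }

  cfg <- unclass(locus$config)
  cfg$maf_spectrum <- as.list(cfg$maf_spectrum)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @noRd
write_gff3 <- function(gene, path) {
  row <- function(type, s0, e, id, parent = NULL) {
    attrs <- paste0("ID=", id)
    if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
    paste(gene$chrom, "rarecis", type, s0 + 1L, e, ".", gene$strand, ".",
          attrs, sep = "\t")
  }
  span <- range(unlist(lapply(gene$transcripts,
                              function(t) c(t$start, t$end))))
  lines <- c("##gff-version 3", row("gene", span[1L], span[2L],
                                    gene$gene_id))
  for (tx in gene$transcripts) {
    lines <- c(lines, row("mRNA", tx$start, tx$end, tx$transcript_id,
                          gene$gene_id))
    for (i in seq_len(nrow(tx$exons)))
      lines <- c(lines, row("exon", tx$exons$start[i], tx$exons$end[i],
                            paste0(tx$transcript_id, ":exon", i),
                            tx$transcript_id))
    lines <- c(lines, row("five_prime_UTR", tx$utr5$start, tx$utr5$end,
                          paste0(tx$transcript_id, ":utr5"),
                          tx$transcript_id),
               row("three_prime_UTR", tx$utr3$start, tx$utr3$end,
                   paste0(tx$transcript_id, ":utr3"), tx$transcript_id))
  }
  writeLines(lines, path)
}

#' @noRd
read_gff3_gene <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  as_iv <- function(x) data.frame(
    start = GenomicRanges::start(x) - 1L, end = GenomicRanges::end(x))
  gene_row <- gr[md$type == "gene"]
  txs <- gr[md$type == "mRNA"]
  transcripts <- lapply(seq_along(txs), function(i) {
    tid <- S4Vectors::mcols(txs)$ID[i]
    kids <- gr[vapply(md$Parent, function(p) tid %in% unlist(p), TRUE)]
    kmd <- S4Vectors::mcols(kids)
    list(transcript_id = tid,
         start = GenomicRanges::start(txs[i]) - 1L,
         end = GenomicRanges::end(txs[i]),
         exons = as_iv(kids[kmd$type == "exon"]),
         utr5 = as_iv(kids[kmd$type == "five_prime_UTR"]),
         utr3 = as_iv(kids[kmd$type == "three_prime_UTR"]))
  })
  gene_model(gene_id = S4Vectors::mcols(gene_row)$ID[1L],
             chrom = as.character(GenomicRanges::seqnames(gene_row))[1L],
             strand = as.character(GenomicRanges::strand(gene_row))[1L],
             transcripts = transcripts)
}

#' Read a locus fixture from a directory
#'
#' Counterpart of [write_fixture()]; genotypes are parsed with vcfR (GT to
#' dosage, summed AD and GQ kept when present), the gene model with
#' rtracklayer. Dosages round-trip losslessly.
#'
#' @param dir fixture directory.
#' @return list with `variants`, `G`, `raw` (NULL without AD/GQ), `gene`,
#'   `regions`, `depth_track`, `pheno`, `covariates`, `truth`, `config`,
#'   `window`, `sample_ids`.
#' @export
read_fixture <- function(dir) {
  vcf <- vcfR::read.vcfR(file.path(dir, "genotypes.vcf"), verbose = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  G <- t(apply(gt_raw, 2L, gt_to_dosage))
  fx <- vcfR::getFIX(vcf)
  colnames(G) <- fx[, "ID"]

  raw <- NULL
  if ("AD" %in% strsplit(vcf@gt[1L, "FORMAT"], ":")[[1L]]) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
    lad_sum <- t(apply(ad, 2L, function(col) {
      parts <- strsplit(col, ",", fixed = TRUE)
      vapply(parts, function(p) sum(suppressWarnings(as.numeric(p))),
             0)
    }))
    raw <- list(lad_sum = lad_sum, gq = t(gq))
  }

  ann <- as.data.frame(data.table::fread(file.path(dir,
                                                   "annotations.tsv")))
  variants <- data.frame(vid = fx[, "ID"], chrom = fx[, "CHROM"],
                         pos = as.integer(fx[, "POS"]),
                         ref = fx[, "REF"], alt = fx[, "ALT"],
                         stringsAsFactors = FALSE)
  variants <- cbind(variants,
                    ann[match(variants$vid, ann$vid),
                        setdiff(names(ann), c("vid", "chrom", "pos")),
                        drop = FALSE])
  variants <- cbind(variants, allele_summary(G)[, c("mac", "maf",
                                                    "missingness")])

  bed <- as.data.frame(data.table::fread(file.path(dir,
                                                   "regulatory.bed")))
  names(bed) <- c("chrom", "start", "end", "feature_type", "score",
                  "strand", "tissue_group", "active")[seq_len(ncol(bed))]

  gene <- read_gff3_gene(file.path(dir, "gene_model.gff3"))

  depth_track <- NULL
  if (file.exists(file.path(dir, "depth.bedgraph"))) {
    depth_track <- as.data.frame(
      data.table::fread(file.path(dir, "depth.bedgraph")))
    names(depth_track) <- c("chrom", "start", "end", "n_pass")
  }

  pheno <- covariates <- truth <- NULL
  if (file.exists(file.path(dir, "phenotypes.tsv"))) {
    pheno <- as.data.frame(data.table::fread(file.path(dir,
                                                       "phenotypes.tsv")))
    covariates <- as.data.frame(
      data.table::fread(file.path(dir, "covariates.tsv")))
    covariates$batch <- factor(covariates$batch)
    truth <- as.data.frame(data.table::fread(file.path(dir,
                                                       "truth.tsv")))
  }
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  window <- list(chrom = config$chrom, start = config$window_start,
                 end = config$window_start + config$window_length)
  rownames(G) <- colnames(gt_raw)
  list(variants = variants, G = G, raw = raw, gene = gene,
       regions = bed[, c("chrom", "start", "end", "feature_type",
                         "tissue_group", "active")],
       depth_track = depth_track, pheno = pheno,
       covariates = covariates, truth = truth, config = config,
       window = window, sample_ids = rownames(G))
}
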