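# Readers and writers for the plain-text formats the pipeline consumes and
# emits. Genotypes, labels, counts, MAF-lite and clinical tables are TSV;
# copy-number segmentations use the SEG convention (1-based inclusive);
# gene models are GTF (1-based inclusive, via rtracklayer); planted regions
# and signal tracks use BED/bedGraph 0-based half-open coordinates,
# converted on load.

#' @name io
#' @rdname io
#' @title Plain-text readers and writers
#' @param path file path.
#' @param x object to write.
NULL

#' @rdname io
#' @export
write_genotypes_tsv <- function(x, path) {
  df <- data.frame(sample = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  storage.mode(m) <- "integer"
  m
}

#' @rdname io
#' @export
write_labels_tsv <- function(x, path) {
  utils::write.table(data.frame(sample = names(x), label = unname(x)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path)
  stats::setNames(as.character(df$label), df$sample)
}

#' @rdname io
#' @param scale `"log2"` (native) or `"absolute"`; absolute copy numbers are
#'   converted to log2 ratios around ploidy 2 on load.
#' @export
read_seg <- function(path, scale = c("log2", "absolute")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path)
  names(df) <- tolower(names(df))
  out <- data.frame(sample = df$sample, chrom = as.character(df$chrom),
                    start = df$loc.start, end = df$loc.end,
                    num_mark = if ("num.mark" %in% names(df)) df$num.mark else NA,
                    value = df$seg.mean, stringsAsFactors = FALSE)
  if (scale == "absolute") out$value <- log2(pmax(out$value, 0.01) / 2)
  out
}

#' @rdname io
#' @export
write_seg <- function(x, path) {
  df <- data.frame(Sample = x$sample, Chrom = x$chrom, loc.start = x$start,
                   loc.end = x$end, num.mark = x$num_mark, seg.mean = x$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @export
write_maf_lite <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @export
read_maf_lite <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @export
write_counts_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "integer"
  m
}

#' @rdname io
#' @export
write_clinical_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @param grade_levels ordered grade categories for the clinical table.
#' @export
read_clinical_tsv <- function(path, grade_levels = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(grade_levels)) grade_levels <- sort(unique(df$grade))
  df$grade <- factor(df$grade, levels = grade_levels, ordered = TRUE)
  df
}

#' @rdname io
#' @export
write_signatures_tsv <- function(x, path) {
  df <- data.frame(channel = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @export
read_signatures_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$channel
  m
}

#' Write/read focal-region tables (BED-like, type in column 5)
#'
#' Columns: chrom, start, end, region id, type. Coordinates on disk are
#' 0-based half-open (BED convention) and converted to 1-based inclusive in
#' memory.
#' @rdname io
#' @export
write_regions_bed <- function(x, path) {
  df <- data.frame(chrom = x$chrom, start = x$start - 1, end = x$end,
                   name = x$region, type = x$type)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' @rdname io
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "name", "type"))
  data.frame(region = df$name, chrom = as.character(df$chrom),
             start = df$start + 1, end = df$end, type = df$type,
             stringsAsFactors = FALSE)
}

#' Read gene models from a GTF file
#'
#' Exon features are extracted with their `gene_id`, `transcript_id` and
#' `gene_biotype` attributes; coordinates stay 1-based inclusive.
#'
#' @rdname io
#' @export
read_gene_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  data.frame(gene_id = gr$gene_id, transcript_id = gr$transcript_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             biotype = gr$gene_biotype, stringsAsFactors = FALSE)
}

#' Write gene models as GTF (gene/transcript/exon features)
#'
#' @rdname io
#' @export
write_gene_models_gtf <- function(x, path) {
  rows <- list()
  for (g in unique(x$gene_id)) {
    ex <- x[x$gene_id == g, , drop = FALSE]
    attr_g <- sprintf('gene_id "%s"; gene_biotype "%s";', g, ex$biotype[1])
    rows[[length(rows) + 1]] <- sprintf(
      "%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
      ex$chrom[1], min(ex$start), max(ex$end), ex$strand[1], attr_g)
    for (tr in unique(ex$transcript_id)) {
      te <- ex[ex$transcript_id == tr, , drop = FALSE]
      attr_t <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                        g, tr, te$biotype[1])
      rows[[length(rows) + 1]] <- sprintf(
        "%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
        te$chrom[1], min(te$start), max(te$end), te$strand[1], attr_t)
      for (i in seq_len(nrow(te)))
        rows[[length(rows) + 1]] <- sprintf(
          "%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s",
          te$chrom[i], te$start[i], te$end[i], te$strand[i], attr_t)
    }
  }
  writeLines(unlist(rows), path)
}

#' Read a bedGraph signal track
#'
#' Returns 0-based half-open `chrom, start, end, value` as used by
#' [tss_aggregate()].
#'
#' @rdname io
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             value = gr$score, stringsAsFactors = FALSE)
}

#' @rdname io
#' @export
write_bedgraph <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Read genotype dosages from a VCF
#'
#' GT fields are mapped to alternate-allele dosage (0/1/2, NA for missing)
#' via the vcfR parser. Returns a samples x SNPs matrix.
#'
#' @rdname io
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_dosages requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(as.integer(a) > 0)
  }
  m <- apply(gt, c(1, 2), dos)
  t(m)
}
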