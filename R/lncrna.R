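# lncRNA locus-biotype classification relative to protein-coding genes,
# chromatin-state proximity annotation, subcellular-localization comparison,
# androgen-receptor regulation calibration, and TSS signal aggregation.

CHROMATIN_STATES <- c("active_promoter", "bivalent_promoter", "active_enhancer",
                      "poised_enhancer", "polycomb", "transcribed", "unmarked")

LNC_CLASSES <- c("exonic", "intronic", "antisense", "intergenic")

models_to_granges <- function(models) {
  GenomicRanges::GRanges(models$chrom,
                         IRanges::IRanges(models$start, models$end),
                         strand = models$strand,
                         gene_id = models$gene_id,
                         transcript_id = models$transcript_id)
}

gene_spans <- function(models) {
  sp <- do.call(rbind, lapply(split(models, models$gene_id), function(m) {
    data.frame(gene_id = m$gene_id[1], chrom = m$chrom[1],
               start = min(m$start), end = max(m$end),
               strand = m$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

#' Classify lncRNA loci relative to protein-coding genes
#'
#' Per transcript: `antisense` when its span overlaps a coding gene's span
#' on the opposite strand only; with same-strand span overlap, `exonic` when
#' at least 1 bp of exonic sequence is shared, otherwise `intronic` (the
#' overlapping sequence lies entirely within introns); `intergenic` with no
#' span overlap at all. Gene-level classes follow the hierarchy
#' `exonic > intronic > antisense > intergenic` over the gene's transcripts.
#'
#' @param lnc,coding exon-level model data.frames (`gene_id, transcript_id,
#'   chrom, start, end, strand`), e.g. from [simulate_gene_models()] or
#'   [read_gene_models_gtf()].
#' @return list with `genes` (data.frame `gene_id, class`) and
#'   `transcripts` (data.frame `gene_id, transcript_id, class`).
#' @export
classify_lncrna <- function(lnc, coding) {
  if (nrow(lnc) == 0)
    return(list(genes = data.frame(gene_id = character(), class = character()),
                transcripts = data.frame(gene_id = character(),
                                         transcript_id = character(),
                                         class = character())))
  if (any(is.na(lnc$strand)) || any(is.na(coding$strand)))
    stop("strand must be present on all models")
  cod_span <- gene_spans(coding)
  gr_span <- GenomicRanges::GRanges(cod_span$chrom,
                                    IRanges::IRanges(cod_span$start, cod_span$end),
                                    strand = cod_span$strand)
  gr_exon <- models_to_granges(coding)
  tx <- unique(lnc[, c("gene_id", "transcript_id")])
  cls <- character(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    ex <- lnc[lnc$transcript_id == tx$transcript_id[i], , drop = FALSE]
    if (nrow(ex) == 0) stop("transcript ", tx$transcript_id[i], " has no exons")
    t_strand <- ex$strand[1]
    t_span <- GenomicRanges::GRanges(ex$chrom[1],
                                     IRanges::IRanges(min(ex$start), max(ex$end)),
                                     strand = t_strand)
    ov <- GenomicRanges::findOverlaps(t_span, gr_span, ignore.strand = TRUE)
    if (length(ov) == 0) { cls[i] <- "intergenic"; next }
    hit_strand <- as.character(GenomicRanges::strand(gr_span))[S4Vectors::subjectHits(ov)]
    same <- hit_strand == t_strand
    if (!any(same)) { cls[i] <- "antisense"; next }
    gr_ex <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end),
                                    strand = t_strand)
    ove <- GenomicRanges::findOverlaps(gr_ex, gr_exon, ignore.strand = FALSE)
    cls[i] <- if (length(ove) > 0) "exonic" else "intronic"
  }
  tx$class <- cls
  gene_cls <- vapply(split(cls, tx$gene_id), function(cc)
    LNC_CLASSES[min(match(cc, LNC_CLASSES))], character(1))
  genes <- data.frame(gene_id = names(gene_cls), class = unname(gene_cls),
                      stringsAsFactors = FALSE)
  list(genes = genes, transcripts = tx)
}

#' Annotate genes by proximity to chromatin states
#'
#' A gene is flagged for a state when the gap distance between the gene span
#' and any interval of that state is at most `window` (overlap counts as
#' distance 0). When DE flags are supplied, per-state enrichment among DE vs
#' non-DE genes is tested by Fisher's exact test with BH correction across
#' states.
#'
#' @param spans data.frame `gene_id, chrom, start, end` (gene spans).
#' @param states data.frame `chrom, start, end, state` with states from the
#'   declared seven-state set.
#' @param window proximity in bp (default 10000).
#' @param de optional logical DE indicator per gene.
#' @return list with `flags` (genes x states logical matrix) and
#'   `enrichment` (association data.frame, NULL without `de`).
#' @export
chromatin_state_annotation <- function(spans, states, window = 10000, de = NULL) {
  bad <- setdiff(unique(states$state), CHROMATIN_STATES)
  if (length(bad)) stop("unknown chromatin state(s): ", paste(bad, collapse = ", "))
  gr_g <- GenomicRanges::GRanges(spans$chrom,
                                 IRanges::IRanges(spans$start, spans$end))
  flags <- matrix(FALSE, nrow(spans), length(CHROMATIN_STATES),
                  dimnames = list(spans$gene_id, CHROMATIN_STATES))
  for (st in intersect(CHROMATIN_STATES, unique(states$state))) {
    s <- states[states$state == st, , drop = FALSE]
    gr_s <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start, s$end))
    d <- GenomicRanges::distanceToNearest(gr_g, gr_s, ignore.strand = TRUE)
    dd <- rep(NA_real_, nrow(spans))
    dd[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    flags[, st] <- !is.na(dd) & dd <= window
  }
  enrichment <- NULL
  if (!is.null(de)) {
    rows <- lapply(colnames(flags), function(st) {
      f <- flags[, st]
      if (all(f) || !any(f) || all(de) || !any(de))
        return(association_row(st, NA_real_, NA_real_, NA_real_, NA_real_,
                               "fisher_exact", "empty_stratum"))
      tab <- table(factor(de, levels = c(TRUE, FALSE)),
                   factor(f, levels = c(TRUE, FALSE)))
      fisher_2x2(as.matrix(tab), unit = st)
    })
    enrichment <- do.call(rbind, rows)
    ok <- !is.na(enrichment$p)
    enrichment$q[ok] <- bh_fdr(enrichment$p[ok])
  }
  list(flags = flags, enrichment = enrichment)
}

#' Compare subcellular localization (CN-RCI) between DE and non-DE genes
#'
#' Two-sample pooled-variance t-test of the cytoplasmic/nuclear relative
#' concentration index; lower values indicate nuclear enrichment.
#'
#' @param rci per-gene CN-RCI values (log scale).
#' @param de logical DE indicator per gene.
#' @return list `mean_de, mean_non, diff, t, p` (NA when variance is
#'   degenerate).
#' @export
rci_compare <- function(rci, de) {
  if (sum(de) < 2 || sum(!de) < 2) stop("need >= 2 genes per stratum")
  a <- rci[de]; b <- rci[!de]
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(list(mean_de = mean(a), mean_non = mean(b), diff = mean(a) - mean(b),
                t = NA_real_, p = NA_real_))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(mean_de = mean(a), mean_non = mean(b), diff = mean(a) - mean(b),
       t = unname(tt$statistic), p = tt$p.value)
}

#' Calibrate the AR-regulation fold-change cutoff on control genes
#'
#' For each candidate cutoff, sensitivity is the fraction of
#' experimentally-validated control genes whose stimulation fold change
#' reaches the cutoff (boundary included). The largest cutoff achieving
#' sensitivity at least `floor` is chosen; when none qualifies the lowest
#' candidate is returned with a flag.
#'
#' @param folds fold changes of the positive-control genes (> 0).
#' @param cutoffs candidate cutoffs.
#' @param floor required sensitivity (default 0.85).
#' @return list `cutoff, sensitivity, curve` (data.frame cutoff,
#'   sensitivity), `flagged`.
#' @export
calibrate_arg_cutoff <- function(folds, cutoffs, floor = 0.85) {
  if (length(folds) == 0) stop("need at least one control gene")
  sens <- vapply(cutoffs, function(ct) mean(folds >= ct), numeric(1))
  curve <- data.frame(cutoff = cutoffs, sensitivity = sens)
  ok <- which(sens >= floor)
  if (length(ok) == 0) {
    i <- which.min(cutoffs)
    return(list(cutoff = cutoffs[i], sensitivity = sens[i], curve = curve,
                flagged = TRUE))
  }
  i <- ok[which.max(cutoffs[ok])]
  list(cutoff = cutoffs[i], sensitivity = sens[i], curve = curve,
       flagged = FALSE)
}

#' Classify genes as AR-regulated by fold change
#'
#' A gene is AR-regulated when its stimulation fold change is at least
#' `cutoff` (enhanced) or at most `1/cutoff` (suppressed); boundaries count
#' as regulated.
#'
#' @param folds named per-gene fold changes (> 0).
#' @param cutoff fold-change cutoff (default 1.2).
#' @return data.frame `gene, fold, regulated, direction`
#'   (enhanced/suppressed/none).
#' @export
classify_args <- function(folds, cutoff = 1.2) {
  if (any(folds <= 0)) stop("fold changes must be positive")
  enh <- folds >= cutoff
  sup <- folds <= 1 / cutoff
  data.frame(gene = names(folds) %||% seq_along(folds), fold = unname(folds),
             regulated = enh | sup,
             direction = ifelse(enh, "enhanced", ifelse(sup, "suppressed", "none")),
             stringsAsFactors = FALSE)
}

#' Aggregate a signal track around transcription start sites
#'
#' Per-base signal on `[-flank, +flank)` around each TSS in TSS-relative
#' coordinates (minus-strand windows reversed so downstream is always to the
#' right), averaged across TSSs in bins of `bin` bp. Missing track regions
#' contribute 0; coverage (fraction of bases with signal) is reported.
#'
#' @param track data.frame `chrom, start, end, value` in 0-based half-open
#'   coordinates (bedGraph convention).
#' @param tss data.frame `chrom, pos, strand` (1-based TSS position).
#' @param flank half-window in bp; must be a multiple of `bin`.
#' @param bin bin width in bp.
#' @return data.frame `position` (bin start relative to the TSS), `value`
#'   (mean signal), `coverage`.
#' @export
tss_aggregate <- function(track, tss, flank = 2000, bin = 50) {
  if (nrow(tss) == 0) stop("empty TSS list")
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  nb <- 2 * flank / bin
  acc <- numeric(2 * flank)
  cov <- numeric(2 * flank)
  for (i in seq_len(nrow(tss))) {
    p0 <- tss$pos[i] - 1                       # 0-based TSS
    minus <- identical(tss$strand[i], "-")
    # relative position r maps to genomic p0 + r (plus) or p0 - r (minus)
    if (minus) { w_start <- p0 - flank + 1; w_end <- p0 + flank + 1 }
    else { w_start <- p0 - flank; w_end <- p0 + flank }
    vals <- numeric(2 * flank)
    hit <- logical(2 * flank)
    tr <- track[track$chrom == tss$chrom[i] &
                  track$end > w_start & track$start < w_end, , drop = FALSE]
    if (nrow(tr)) {
      for (j in seq_len(nrow(tr))) {
        a <- max(tr$start[j], w_start); b <- min(tr$end[j], w_end)
        idx <- (a - w_start + 1):(b - w_start)
        vals[idx] <- tr$value[j]
        hit[idx] <- TRUE
      }
    }
    if (minus) { vals <- rev(vals); hit <- rev(hit) }
    acc <- acc + vals
    cov <- cov + hit
  }
  grp <- rep(seq_len(nb), each = bin)
  data.frame(position = seq(-flank, flank - bin, by = bin),
             value = as.numeric(tapply(acc / nrow(tss), grp, mean)),
             coverage = as.numeric(tapply(cov / nrow(tss), grp, mean)))
}
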