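# Category enrichment, pre-ranked GSEA and sample-set enrichment (SSEA)
# with fractional ranks.

# running-sum enrichment score: hit increments proportional to
# |metric|^weight, uniform miss decrements; ES is the extremum of the walk.
es_walk <- function(metric, is_member, weight) {
  N <- length(metric)
  nh <- sum(is_member)
  inc <- abs(metric)^weight * is_member
  denom <- sum(inc)
  if (denom == 0) inc[is_member] <- 1 / nh else inc <- inc / denom
  dec <- (!is_member) / (N - nh)
  run <- cumsum(inc - dec)
  i <- which.max(abs(run))
  list(es = run[i], pos = i, running = run)
}

# deterministic ranking: metric descending, ties broken by id
order_ranked <- function(ids, metric) order(-metric, ids)

#' Pre-ranked gene-set enrichment analysis
#'
#' Running-sum enrichment score over the ranked list (descending metric,
#' ties broken by id): hit increments proportional to `|metric|^weight`,
#' uniform miss decrements; ES is the extremum of the walk. The null is
#' random member sets of the same size drawn from the universe; NES divides
#' ES by the mean `|null ES|` of matching sign and the permutation p is
#' the fraction of matching-sign null scores at least as extreme as the
#' observed ES (the sign-matched convention; uniform for random sets).
#'
#' @param ids item (gene) identifiers of the universe.
#' @param metric ranking metric, one value per id.
#' @param set character vector of member ids (intersection with the
#'   universe must have >= 2 items).
#' @param weight metric exponent (default 1; 0 gives the classical
#'   Kolmogorov-Smirnov-style statistic).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `es`, `nes`, `p`, `leading_edge`, `n_members`; all-NA
#'   with `reason` when the intersection is too small.
#' @export
preranked_gsea <- function(ids, metric, set, weight = 1, n_perm = 1000, seed = 1) {
  stopifnot(length(ids) == length(metric), !anyDuplicated(ids))
  o <- order_ranked(ids, metric)
  ids <- ids[o]; metric <- metric[o]
  member <- ids %in% set
  nh <- sum(member)
  if (nh < 2)
    return(list(es = NA_real_, nes = NA_real_, p = NA_real_,
                leading_edge = character(0), n_members = nh,
                reason = "fewer than 2 set members in the universe"))
  obs <- es_walk(metric, member, weight)
  set_generator_seed(seed)
  null_es <- replicate(n_perm, {
    m <- logical(length(ids))
    m[sample.int(length(ids), nh)] <- TRUE
    es_walk(metric, m, weight)$es
  })
  same <- null_es * sign(obs$es) > 0
  denom <- mean(abs(null_es[same]))
  nes <- if (is.finite(denom) && denom > 0) obs$es / denom else NA_real_
  p_one <- (1 + sum(same & abs(null_es) >= abs(obs$es))) / (1 + sum(same))
  le <- if (obs$es >= 0) ids[seq_len(obs$pos)][member[seq_len(obs$pos)]]
  else ids[obs$pos:length(ids)][member[obs$pos:length(ids)]]
  list(es = obs$es, nes = nes, p = p_one, leading_edge = le, n_members = nh)
}

#' Pre-ranked GSEA over a collection of sets with BH correction
#'
#' @inheritParams preranked_gsea
#' @param sets named list of member-id vectors.
#' @return data.frame `set, n_members, es, nes, p, q`.
#' @export
preranked_gsea_sets <- function(ids, metric, sets, weight = 1, n_perm = 1000,
                                seed = 1) {
  rows <- lapply(seq_along(sets), function(i) {
    r <- preranked_gsea(ids, metric, sets[[i]], weight, n_perm, seed + i)
    data.frame(set = names(sets)[i], n_members = r$n_members, es = r$es,
               nes = r$nes, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  out
}

#' Sample-set enrichment analysis for one gene
#'
#' Samples are ranked by the gene's expression (descending) and each
#' cancer-type sample set is scored exactly as in [preranked_gsea()] with
#' the expression values as the metric. Types with fewer than 2 samples are
#' skipped.
#'
#' @param expr named expression vector across the pan-cohort samples.
#' @param sets named list: cancer type -> sample ids (a partition of the
#'   samples).
#' @param weight,n_perm,seed as in [preranked_gsea()].
#' @return data.frame `type, n_samples, es, nes, p`.
#' @export
ssea <- function(expr, sets, weight = 1, n_perm = 1000, seed = 1) {
  if (is.null(names(expr))) stop("expr must be named by sample")
  assigned <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(assigned))
    stop("every sample must belong to exactly one cancer type")
  rows <- lapply(seq_along(sets), function(i) {
    members <- intersect(sets[[i]], names(expr))
    if (length(members) < 2)
      return(data.frame(type = names(sets)[i], n_samples = length(members),
                        es = NA_real_, nes = NA_real_, p = NA_real_))
    r <- preranked_gsea(names(expr), unname(expr), members, weight, n_perm,
                        seed + i)
    data.frame(type = names(sets)[i], n_samples = length(members), es = r$es,
               nes = r$nes, p = r$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fractional ranks of NES values within one cancer type
#'
#' `rank / n` with ascending ranks and ties averaged, so the highest NES
#' gets 1 and the second-highest of 20 genes gets 0.95; values lie in
#' `(0, 1]`.
#'
#' @param nes per-gene NES values (NA allowed, returned NA).
#' @return numeric vector of fractional ranks.
#' @export
fractional_ranks <- function(nes) {
  if (length(nes) == 0) stop("need at least one gene")
  out <- rep(NA_real_, length(nes))
  ok <- !is.na(nes)
  out[ok] <- rank(nes[ok], ties.method = "average") / sum(ok)
  out
}

#' Category enrichment among DEGs at multiple FDR thresholds
#'
#' At each FDR level, a 2x2 Fisher test of DEG status (`q < level`) against
#' category membership (eGene, GWAS-proximal, TWAS, regulatory class, ...).
#'
#' @param q per-gene FDR-adjusted p-values.
#' @param category logical membership indicator per gene.
#' @param fdr_levels thresholds (default 0.1, 0.01, 0.001).
#' @param unit label prefix for result rows.
#' @return association data.frame, one row per level (flagged NA when a
#'   stratum is empty).
#' @export
category_enrichment <- function(q, category, fdr_levels = c(0.1, 0.01, 0.001),
                                unit = "category") {
  stopifnot(length(q) == length(category))
  ok <- !is.na(q)
  rows <- lapply(fdr_levels, function(lv) {
    deg <- q[ok] < lv
    cat_ok <- category[ok]
    u <- paste0(unit, "@", lv)
    if (all(deg) || !any(deg) || all(cat_ok) || !any(cat_ok))
      return(association_row(u, NA_real_, NA_real_, NA_real_, NA_real_,
                             "fisher_exact", "empty_stratum"))
    tab <- table(factor(deg, levels = c(TRUE, FALSE)),
                 factor(cat_ok, levels = c(TRUE, FALSE)))
    fisher_2x2(as.matrix(tab), unit = u)
  })
  do.call(rbind, rows)
}

#' Flag genes within a window of GWAS SNPs
#'
#' A gene is flagged when any SNP lies within
#' `[gene start - window, gene end + window]` on the same chromosome.
#'
#' @param genes data.frame `gene, chrom, start, end`.
#' @param snps data.frame `chrom, pos`.
#' @param window proximity window in bp (default 1e6).
#' @return named logical vector per gene.
#' @export
gwas_proximity_genes <- function(genes, snps, window = 1e6) {
  flags <- stats::setNames(rep(FALSE, nrow(genes)), genes$gene)
  if (nrow(snps) == 0) return(flags)
  offenders <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(offenders))
    stop("chromosome names absent from the gene table: ",
         paste(offenders, collapse = ", "))
  for (ch in unique(snps$chrom)) {
    pos <- snps$pos[snps$chrom == ch]
    g <- which(genes$chrom == ch)
    for (i in g) {
      if (any(pos >= genes$start[i] - window & pos <= genes$end[i] + window))
        flags[i] <- TRUE
    }
  }
  flags
}
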