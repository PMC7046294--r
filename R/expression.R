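# Normalization and a simplified negative-binomial Wald differential
# expression stage. This stage is an explicitly simplified stand-in for a
# full shrinkage-based DE fit: per-gene method-of-moments dispersion, no
# dispersion or fold-change shrinkage, no independent filtering. An external
# DE result table with the same columns can be substituted anywhere a
# `de_result` is consumed.

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in every sample, each sample's factor is
#' the median of `count / geometric mean across samples`.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @return named per-sample factor vector (> 0).
#' @export
size_factors_median_ratio <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts == 0) == 0
  if (!any(ok))
    stop("no gene has nonzero counts in all samples; supply size factors ",
         "from a pseudo-reference instead")
  lg <- log(counts[ok, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2, stats::median)
}

#' Simplified negative-binomial Wald differential expression
#'
#' Per gene: a negative-binomial log-linear model of counts on the group
#' indicator (plus the propensity covariate when given) with
#' `log(size factor)` offsets. Dispersion is estimated per gene by method of
#' moments on normalized counts within groups, floored at `1e-8`; the group
#' coefficient is tested by a Wald z. Genes with all-zero counts are flagged
#' `filtered` and excluded from testing and from the BH denominator.
#' Positive log2 fold change means higher expression in group 1.
#'
#' @param counts genes x samples matrix.
#' @param group 0/1 indicator per sample (1 = group of interest).
#' @param propensity optional propensity scores or `propensity_model`.
#' @param size_factors optional; [size_factors_median_ratio()] by default.
#' @return `de_result` data.frame: `gene, base_mean, log2fc, se, stat, p, q,
#'   filtered`.
#' @export
nb_wald_de <- function(counts, group, propensity = NULL, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (min(table(group)) < 3) stop("need >= 3 samples per group")
  if (inherits(propensity, "propensity_model")) propensity <- propensity$score
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(counts)
  sf <- as.numeric(size_factors)
  n_gene <- nrow(counts)
  out <- data.frame(gene = rownames(counts) %||% seq_len(n_gene),
                    base_mean = NA_real_, log2fc = NA_real_, se = NA_real_,
                    stat = NA_real_, p = NA_real_, q = NA_real_,
                    filtered = FALSE, stringsAsFactors = FALSE)
  z <- sweep(counts, 2, sf, "/")
  out$base_mean <- rowMeans(z)
  g0 <- group == 0; g1 <- group == 1
  # per-group method-of-moments dispersion, pooled by degrees of freedom
  mom <- function(zz, idx) {
    q <- rowMeans(zz[, idx, drop = FALSE])
    v <- apply(zz[, idx, drop = FALSE], 1, stats::var)
    w <- v - q * mean(1 / sf[idx])
    pmax(w / q^2, 0)
  }
  a0 <- mom(z, g0); a1 <- mom(z, g1)
  n0 <- sum(g0); n1 <- sum(g1)
  alpha <- pmax(((n0 - 1) * a0 + (n1 - 1) * a1) / (n0 + n1 - 2), 1e-8)
  dat <- data.frame(x = as.numeric(group))
  form <- y ~ x
  if (!is.null(propensity)) {
    dat$ps <- as.numeric(propensity)
    form <- y ~ x + ps
  }
  off <- log(sf)
  for (i in seq_len(n_gene)) {
    y <- counts[i, ]
    if (all(y == 0)) { out$filtered[i] <- TRUE; next }
    dat$y <- y
    fit <- tryCatch(
      suppressWarnings(stats::glm(form, data = dat, offset = off,
                                  family = MASS::negative.binomial(1 / alpha[i]))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { out$p[i] <- NA; next }
    sm <- summary(fit)$coefficients
    if (!"x" %in% rownames(sm)) next
    b <- sm["x", "Estimate"]; s <- sm["x", "Std. Error"]
    out$log2fc[i] <- b / log(2)
    out$se[i] <- s / log(2)
    out$stat[i] <- b / s
    out$p[i] <- 2 * stats::pnorm(-abs(b / s))
  }
  tested <- !out$filtered & !is.na(out$p)
  out$q[tested] <- bh_fdr(out$p[tested])
  class(out) <- c("de_result", class(out))
  out
}

#' Direction concordance of two DE analyses
#'
#' Among shared genes, a 2x2 table of DEG status (in the primary analysis)
#' against agreement of fold-change sign between the two analyses, tested by
#' Fisher's exact test. An odds ratio above 1 indicates that primary DEGs
#' replicate their direction in the secondary cohort more often than
#' non-DEGs do.
#'
#' @param primary,secondary `de_result` data.frames sharing gene ids.
#' @param deg optional logical DEG mask for the primary genes (default
#'   `q < 0.1`).
#' @return one-row association data.frame with attribute `table`.
#' @export
direction_concordance <- function(primary, secondary, deg = NULL) {
  common <- intersect(primary$gene, secondary$gene)
  if (length(common) == 0) stop("no shared genes")
  p1 <- primary[match(common, primary$gene), ]
  p2 <- secondary[match(common, secondary$gene), ]
  if (is.null(deg)) deg <- !is.na(p1$q) & p1$q < 0.1
  else deg <- deg[match(common, primary$gene)]
  agree <- sign(p1$log2fc) == sign(p2$log2fc)
  ok <- !is.na(agree) & !is.na(deg)
  tab <- table(factor(deg[ok], levels = c(TRUE, FALSE)),
               factor(agree[ok], levels = c(TRUE, FALSE)))
  res <- fisher_2x2(as.matrix(tab), unit = "direction_concordance")
  attr(res, "table") <- tab
  res
}

#' Screen DE results by fold change and FDR
#'
#' @param results a `de_result`.
#' @param min_fold minimum fold change (default 2; boundary included).
#' @param q_cut FDR threshold (default 0.1).
#' @return character vector of gene ids with `q < q_cut` and
#'   `|log2fc| >= log2(min_fold)`.
#' @export
fold_change_screen <- function(results, min_fold = 2, q_cut = 0.1) {
  keep <- !is.na(results$q) & results$q < q_cut &
    !is.na(results$log2fc) & abs(results$log2fc) >= log2(min_fold)
  results$gene[keep]
}
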