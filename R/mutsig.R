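# 96-channel mutation catalogs, constrained signature refitting with weight
# discard and cosine-similarity pruning, and burden / per-gene frequency
# statistics.

#' Canonical 96-channel ordering
#'
#' Substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then the 5' flank and
#' the 3' flank each in alphabetical order (A, C, G, T). Channel names use
#' the `"A[C>A]A"` convention. This ordering is fixed and stable.
#'
#' @return character vector of 96 channel names.
#' @export
mutation_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  b <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    unlist(lapply(b, function(p5) paste0(p5, "[", s, "]", b)))))
}

#' Built-in synthetic signature set
#'
#' Three clearly distinct 96-channel signatures used by the test-suite and
#' the demo pipeline (no external signature download is required): one
#' concentrated on C>A channels, one on C>T, and one spread over T>C and
#' T>G. Columns sum to 1. These are synthetic constructions, not estimates
#' from tumor data.
#'
#' @return 96 x 3 matrix with channel rownames and columns `sig1..sig3`.
#' @export
builtin_signatures <- function() {
  ch <- mutation_channels()
  sub_of <- substr(ch, 3, 5)
  S <- matrix(0, 96, 3, dimnames = list(ch, paste0("sig", 1:3)))
  w1 <- sub_of == "C>A"
  S[w1, 1] <- seq(1, 2, length.out = sum(w1))
  w2 <- sub_of == "C>T"
  S[w2, 2] <- seq(2, 1, length.out = sum(w2))
  w3 <- sub_of %in% c("T>C", "T>G")
  S[w3, 3] <- rep(c(1, 3), length.out = sum(w3))
  # a little mass everywhere so reconstructions are never exactly orthogonal
  S <- S + 0.02
  sweep(S, 2, colSums(S), "/")
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Build 96-channel mutation catalogs from MAF-lite records
#'
#' Each single-nucleotide variant is assigned to one of the 96 trinucleotide
#' channels; purine-reference mutations are reverse-complemented into the
#' pyrimidine (C/T reference) representation. Records that are not SNVs are
#' ignored and counted; contexts containing `N` are skipped and counted.
#'
#' @param mutations data.frame with columns `sample`, `ref`, `alt` and
#'   either a `context` column (trinucleotide around the site, reference
#'   strand) or a `context_fn(chrom, pos)` provider.
#' @param context_fn optional function returning the trinucleotide context.
#' @param samples optional sample universe (rows of the catalog); defaults
#'   to the samples present.
#' @return samples x 96 integer matrix; attributes `n_non_snv`, `n_skipped`.
#' @export
build_catalog <- function(mutations, context_fn = NULL, samples = NULL) {
  stopifnot(all(c("sample", "ref", "alt") %in% names(mutations)))
  ctx <- mutations$context
  if (is.null(ctx)) {
    if (is.null(context_fn)) stop("need a context column or context_fn")
    ctx <- mapply(context_fn, mutations$chrom, mutations$pos)
  }
  ref <- toupper(mutations$ref); alt <- toupper(mutations$alt)
  ctx <- toupper(ctx)
  is_snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% names(REVCOMP) & alt %in% names(REVCOMP) & ref != alt
  n_non_snv <- sum(!is_snv)
  bad_ctx <- is_snv & (nchar(ctx) != 3 | grepl("N", ctx))
  n_skipped <- sum(bad_ctx)
  use <- is_snv & !bad_ctx
  ref <- ref[use]; alt <- alt[use]; ctx <- ctx[use]
  smp <- as.character(mutations$sample)[use]
  # pyrimidine convention
  pur <- ref %in% c("A", "G")
  rc3 <- function(s) vapply(strsplit(s, ""), function(x)
    paste(rev(unname(REVCOMP[x])), collapse = ""), character(1))
  ctx[pur] <- rc3(ctx[pur])
  alt[pur] <- unname(REVCOMP[alt[pur]])
  ref[pur] <- unname(REVCOMP[ref[pur]])
  channel <- if (length(ref))
    paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
  else character(0)
  if (is.null(samples)) samples <- sort(unique(as.character(mutations$sample)))
  out <- matrix(0L, length(samples), 96,
                dimnames = list(samples, mutation_channels()))
  if (length(channel)) {
    tb <- table(factor(smp, levels = samples),
                factor(channel, levels = mutation_channels()))
    out[] <- as.integer(tb)
  }
  attr(out, "n_non_snv") <- n_non_snv
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Cosine similarity of two non-negative spectra
#'
#' @param a,b numeric vectors of equal length; neither all-zero.
#' @return `dot(a, b) / (|a| |b|)`, in `[0, 1]` for non-negative input.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# non-negative least squares of y on the columns of A
nnls_fit <- function(A, y) {
  drop(pracma::lsqnonneg(A, y)$x)
}

#' Refit fixed mutational signatures to a catalog
#'
#' Per sample: (1) the normalized spectrum is fit onto the candidate
#' signatures by non-negative least squares; (2) coefficients are normalized
#' to weights summing to 1; (3) weights below `discard_below` are removed;
#' (4) remaining signatures are pruned greedily, lowest weight first: a
#' signature is removed whenever refitting without it lowers the
#' reconstruction cosine similarity by no more than `prune_gain`;
#' (5) the surviving raw coefficients (sum <= ~1) and the final cosine
#' similarity are reported, together with a renormalized view. The procedure
#' is deterministic.
#'
#' @param catalog 96-vector or samples x 96 count matrix.
#' @param sigs 96 x S signature matrix (columns sum to 1).
#' @param discard_below minimum retained normalized weight (default 0.06).
#' @param prune_gain minimum cosine-similarity contribution required to keep
#'   a signature (default 0.02).
#' @return object of class `exposure_fit`: list with `weights` (samples x S,
#'   raw surviving coefficients, zero when discarded), `weights_norm`
#'   (rows renormalized to 1 over survivors), `cosine`, `discarded` (list of
#'   signature names per sample), `flagged` (no signature survived).
#' @export
refit_signatures <- function(catalog, sigs, discard_below = 0.06, prune_gain = 0.02) {
  if (is.null(dim(catalog))) catalog <- matrix(catalog, 1)
  sigs <- as.matrix(sigs)
  if (ncol(catalog) != nrow(sigs)) stop("catalog/signature dimension mismatch")
  S <- ncol(sigs)
  snames <- colnames(sigs) %||% paste0("sig", seq_len(S))
  n <- nrow(catalog)
  W <- matrix(0, n, S, dimnames = list(rownames(catalog), snames))
  Wn <- W
  cosv <- rep(NA_real_, n)
  discarded <- vector("list", n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    y <- catalog[i, ]
    tot <- sum(y)
    if (tot == 0) stop("empty spectrum for sample ", i)
    y <- y / tot
    co <- nnls_fit(sigs, y)
    if (sum(co) == 0) { flagged[i] <- TRUE; discarded[[i]] <- snames; next }
    w <- co / sum(co)
    active <- which(w >= discard_below)
    if (length(active) == 0) { flagged[i] <- TRUE; discarded[[i]] <- snames; next }
    refit <- function(act) {
      cc <- nnls_fit(sigs[, act, drop = FALSE], y)
      rec <- drop(sigs[, act, drop = FALSE] %*% cc)
      list(coef = cc, cos = if (sum(rec) == 0) 0 else cosine_similarity(y, rec))
    }
    cur <- refit(active)
    repeat {
      if (length(active) <= 1) break
      ord <- order(cur$coef)           # lowest-weight first
      removed <- FALSE
      for (j in ord) {
        cand <- active[-j]
        alt <- refit(cand)
        if (cur$cos - alt$cos <= prune_gain) {
          active <- cand; cur <- alt; removed <- TRUE
          break
        }
      }
      if (!removed) break
    }
    # re-apply the discard rule to the final normalized weights
    wn <- cur$coef / sum(cur$coef)
    keep <- wn >= discard_below | length(active) == 1
    if (!all(keep)) {
      active <- active[keep]
      cur <- refit(active)
      wn <- cur$coef / sum(cur$coef)
    }
    W[i, active] <- cur$coef
    Wn[i, active] <- wn
    cosv[i] <- cur$cos
    discarded[[i]] <- snames[setdiff(seq_len(S), active)]
  }
  structure(list(weights = W, weights_norm = Wn, cosine = cosv,
                 discarded = discarded, flagged = flagged,
                 discard_below = discard_below, prune_gain = prune_gain),
            class = "exposure_fit")
}

#' Per-signature contribution association with group status
#'
#' Linear model of each signature's normalized contribution on the group
#' indicator plus the propensity covariate; BH q-values across signatures.
#'
#' @param fits an `exposure_fit`.
#' @param groups 0/1 group indicator per sample.
#' @param propensity propensity scores or a `propensity_model`.
#' @return association data.frame, one row per signature.
#' @export
signature_contribution_association <- function(fits, groups, propensity) {
  W <- fits$weights_norm
  if (min(table(groups)) < 2) stop("need >= 2 samples per group")
  rows <- lapply(colnames(W), function(sn) {
    w <- W[, sn]
    if (length(unique(w)) == 1)
      return(association_row(sn, NA_real_, NA_real_, NA_real_, NA_real_,
                             "adjusted_linear", "constant_weight"))
    adjusted_linear(w, groups, propensity, unit = sn)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Rank-normalized burden association
#'
#' Per-sample totals (mutation or fusion burden) are inverse-normal
#' transformed (Blom offset, ties averaged) and regressed on group plus the
#' propensity covariate.
#'
#' @param totals per-sample non-negative totals.
#' @inheritParams signature_contribution_association
#' @return one-row association data.frame.
#' @export
burden_association <- function(totals, groups, propensity) {
  if (length(totals) < 4) stop("need n >= 4")
  adjusted_linear_ranknorm(totals, groups, propensity, unit = "burden")
}

#' Per-gene mutation-frequency association
#'
#' Genes with cohort mutation frequency below `min_freq` are excluded
#' before testing. Each remaining gene is tested by a propensity-adjusted
#' logistic model (mutated ~ group + propensity); separated tables fall back
#' to Fisher's exact test with a flag. BH q-values across tested genes.
#'
#' @param table samples x genes binary mutation-indicator matrix.
#' @inheritParams signature_contribution_association
#' @param min_freq minimum cohort mutation frequency (default 0.01).
#' @return association data.frame, one row per tested gene.
#' @export
gene_frequency_association <- function(table, groups, propensity, min_freq = 0.01) {
  table <- as.matrix(table)
  if (!all(table %in% c(0, 1))) stop("mutation table must be binary")
  freq <- colMeans(table)
  keep <- freq >= min_freq
  genes <- colnames(table)[keep]
  rows <- lapply(genes, function(g) {
    y <- table[, g]
    res <- tryCatch(adjusted_logistic(y, groups, propensity, unit = g),
                    error = function(e)
                      association_row(g, NA_real_, NA_real_, NA_real_, NA_real_,
                                      "adjusted_logistic", "fit_error"))
    if (!is.na(res$flags) && res$flags == "ridge_fallback") {
      tab <- table(factor(y, levels = 0:1), factor(groups, levels = 0:1))
      res <- fisher_2x2(as.matrix(tab), unit = g)
      res$flags <- paste0("fisher_fallback;", res$flags)
    }
    res
  })
  out <- do.call(rbind, rows)
  if (nrow(out)) out$q <- bh_fdr(out$p)
  out
}

#' Clonal/subclonal frequency comparison by Fisher's exact test
#'
#' 2x2 table of clonal/subclonal mutation counts by group; shared
#' [fisher_2x2()] implementation (clonality labels are inputs).
#'
#' @param tab 2x2 matrix: rows clonal/subclonal, columns the two groups.
#' @param unit label for the result row.
#' @return one-row association data.frame.
#' @export
clonality_fisher <- function(tab, unit = "clonality") {
  fisher_2x2(tab, unit = unit)
}
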