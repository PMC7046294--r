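# Supervised genetic-ancestry inference: principal components fitted on a
# labeled reference panel only, projection of study samples into that space,
# k-NN ancestry calls, and a supervised admixture-fraction estimator.

#' Fit reference-only principal components of genotype variation
#'
#' SNP dosages are centered by twice the panel allele frequency and scaled by
#' `sqrt(2p(1-p))` (the EIGENSTRAT convention); eigenvectors come from the
#' reference panel alone, so study samples never influence the axes.
#' All-missing SNPs are dropped with a warning; SNPs that are monomorphic in
#' the panel or exceed the missing-rate cap are dropped silently as part of
#' the documented filter. The sign of each loading is fixed so that its
#' largest-magnitude entry is positive.
#'
#' @param panel a `reference_panel` (see [simulate_reference_panel()]) or a
#'   list with `genotypes` (samples x SNPs, 0/1/2, NA allowed) and `labels`.
#' @param n_axes number of axes to retain (default 10).
#' @param max_missing maximum per-SNP missing rate (default 0.05).
#' @return object of class `pc_model`: list with `snps`, `center`, `scale`,
#'   `loadings` (SNPs x axes, orthonormal), `eigenvalues`, `ref_scores`,
#'   `labels`.
#' @export
fit_reference_pca <- function(panel, n_axes = 10, max_missing = 0.05) {
  G <- panel$genotypes
  labels <- panel$labels
  if (is.null(G) || is.null(labels)) stop("panel needs genotypes and labels")
  if (length(unique(labels)) < 2) stop("need >= 2 reference populations")
  miss <- colMeans(is.na(G))
  if (any(miss == 1)) {
    warning(sum(miss == 1), " all-missing SNP(s) dropped")
  }
  keep <- miss < 1 & miss <= max_missing
  G <- G[, keep, drop = FALSE]
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  center <- 2 * p
  scl <- sqrt(2 * p * (1 - p))
  Z <- sweep(sweep(G, 2, center), 2, scl, "/")
  Z[is.na(Z)] <- 0
  sv <- svd(Z)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (n_axes > rank) stop("n_axes exceeds the rank of the panel (", rank, ")")
  load <- sv$v[, seq_len(n_axes), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each loading positive
  for (j in seq_len(n_axes)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(G)
  colnames(load) <- paste0("PC", seq_len(n_axes))
  ev <- sv$d[seq_len(n_axes)]^2 / (nrow(G) - 1)
  scores <- Z %*% load
  structure(list(snps = colnames(G), center = center, scale = scl,
                 loadings = load, eigenvalues = ev,
                 ref_scores = scores, labels = labels),
            class = "pc_model")
}

#' Project samples into a fitted reference PC space
#'
#' Dosages are centered and scaled with the panel parameters and multiplied
#' by the loadings; missing dosages (and model SNPs absent from the input)
#' are imputed to the panel mean, i.e. contribute zero. The model is never
#' altered by the projected samples.
#'
#' @param model a `pc_model` from [fit_reference_pca()].
#' @param genotypes samples x SNPs dosage matrix with SNP column names.
#' @return samples x axes coordinate matrix.
#' @export
project_samples <- function(model, genotypes) {
  stopifnot(inherits(model, "pc_model"))
  common <- intersect(model$snps, colnames(genotypes))
  if (length(common) == 0) stop("no SNP overlap with the PC model")
  idx <- match(common, model$snps)
  Z <- matrix(0, nrow(genotypes), length(model$snps))
  Zc <- sweep(sweep(genotypes[, common, drop = FALSE], 2, model$center[idx]),
              2, model$scale[idx], "/")
  Zc[is.na(Zc)] <- 0
  Z[, idx] <- Zc
  out <- Z %*% model$loadings
  rownames(out) <- rownames(genotypes)
  out
}

#' k-nearest-neighbor ancestry classification in PC space
#'
#' Euclidean distance on the retained axes; majority vote among the `k`
#' nearest reference samples, ties broken by the nearest population
#' centroid. Optionally, targets whose nearest-reference distance exceeds a
#' quantile of the panel's own nearest-same-population-neighbor distances are
#' called `"other"`.
#'
#' @param targets projected coordinates of the samples to classify.
#' @param refs projected coordinates of the reference samples.
#' @param labels population label per reference sample.
#' @param k number of neighbors (default 5).
#' @param other_quantile `NULL` (default, off) or a quantile in (0,1); see
#'   Details.
#' @return data.frame `sample, label, tie_broken` with a `votes` matrix
#'   attribute (targets x populations; each row sums to `k`).
#' @export
classify_knn <- function(targets, refs, labels, k = 5, other_quantile = NULL) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(refs)) stop("k exceeds the number of reference samples")
  targets <- as.matrix(targets); refs <- as.matrix(refs)
  pops <- sort(unique(labels))
  cent <- t(vapply(pops, function(p) colMeans(refs[labels == p, , drop = FALSE]),
                   numeric(ncol(refs))))
  d2 <- outer(rowSums(targets^2), rep(1, nrow(refs))) +
    outer(rep(1, nrow(targets)), rowSums(refs^2)) -
    2 * tcrossprod(targets, refs)
  d2[d2 < 0] <- 0
  votes <- matrix(0L, nrow(targets), length(pops),
                  dimnames = list(rownames(targets), pops))
  label <- character(nrow(targets))
  tie <- logical(nrow(targets))
  thr <- Inf
  if (!is.null(other_quantile)) {
    # panel's own nearest same-population neighbor distances
    dr <- as.matrix(stats::dist(refs))
    diag(dr) <- Inf
    nnd <- vapply(seq_len(nrow(refs)), function(i)
      min(dr[i, labels == labels[i]]), numeric(1))
    thr <- stats::quantile(nnd, other_quantile)
  }
  for (i in seq_len(nrow(targets))) {
    ord <- order(d2[i, ])[seq_len(k)]
    v <- table(factor(labels[ord], levels = pops))
    votes[i, ] <- as.integer(v)
    top <- names(v)[v == max(v)]
    if (length(top) == 1) {
      label[i] <- top
    } else {
      dc <- sqrt(rowSums(sweep(cent[top, , drop = FALSE], 2, targets[i, ])^2))
      label[i] <- top[which.min(dc)]
      tie[i] <- TRUE
    }
    if (sqrt(min(d2[i, ])) > thr) label[i] <- "other"
  }
  out <- data.frame(sample = rownames(targets) %||% seq_len(nrow(targets)),
                    label = label, tie_broken = tie, stringsAsFactors = FALSE)
  attr(out, "votes") <- votes
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Supervised admixture-fraction estimation
#'
#' Maximizes the binomial likelihood of a sample's dosages under the per-SNP
#' mixture frequency `sum_a q_a f_{a,snp}` over the probability simplex by
#' EM from a uniform start; the log-likelihood is monotone non-decreasing
#' and iteration stops when it improves by less than `tol`. Identical
#' reference populations make the optimum non-unique; such degeneracy is
#' flagged and the symmetric (uniform-across-duplicates) solution returned.
#'
#' @param dosages vector (one sample) or samples x SNPs matrix of 0/1/2
#'   dosages; NA dosages are ignored in the likelihood.
#' @param pop_freqs populations x SNPs allele-frequency matrix (clipped to
#'   `[1e-6, 1 - 1e-6]`).
#' @param max_iter iteration cap (default 5000); non-convergence is flagged.
#' @param tol log-likelihood improvement threshold (default 1e-8).
#' @return samples x populations fraction matrix (rows sum to 1) with
#'   attributes `converged` (logical per sample), `degenerate` (scalar),
#'   `loglik`.
#' @export
estimate_admixture <- function(dosages, pop_freqs, max_iter = 5000, tol = 1e-8) {
  if (is.null(dim(dosages))) dosages <- matrix(dosages, 1)
  K <- nrow(pop_freqs); L <- ncol(pop_freqs)
  if (ncol(dosages) != L) stop("dosage/frequency dimension mismatch")
  f <- pmin(pmax(pop_freqs, 1e-6), 1 - 1e-6)
  degenerate <- anyDuplicated(round(f, 12)) > 0
  n <- nrow(dosages)
  # vectorized EM over samples: derived (G) and ancestral (G2) allele counts,
  # NA dosages masked out of both sums
  G <- dosages; G[is.na(G)] <- 0
  G2 <- 2 - dosages; G2[is.na(G2)] <- 0
  tf <- t(f); tf1 <- t(1 - f)
  Q <- matrix(1 / K, n, K, dimnames = list(rownames(dosages), rownames(pop_freqs)))
  conv <- logical(n)
  ll_out <- rep(-Inf, n)
  active <- seq_len(n)
  # the log-likelihood is evaluated every `check_every` iterations and
  # convergence declared when the mean per-iteration improvement over the
  # block falls below tol (the likelihood itself is monotone under EM)
  check_every <- 10L
  for (it in seq_len(max_iter)) {
    Qa <- Q[active, , drop = FALSE]
    P <- Qa %*% f[, , drop = FALSE]
    Ga <- G[active, , drop = FALSE]; G2a <- G2[active, , drop = FALSE]
    check <- it %% check_every == 0L || it == max_iter
    if (check) ll <- rowSums(Ga * log(P) + G2a * log1p(-P))
    num <- Qa * ((Ga / P) %*% tf + (G2a / (1 - P)) %*% tf1)
    Q[active, ] <- num / rowSums(num)
    if (check) {
      done <- it > check_every & (ll - ll_out[active]) < tol * check_every
      ll_out[active] <- ll
      conv[active[done]] <- TRUE
      active <- active[!done]
      if (!length(active)) break
    }
  }
  attr(Q, "converged") <- conv
  attr(Q, "degenerate") <- degenerate
  attr(Q, "loglik") <- ll_out
  Q
}
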