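# Weighted genome instability index (wGII) and the margin-preserving
# permutation test for ancestry-differential recurrent focal copy-number
# alterations. The working scale is log2 copy-number ratio centered at 0;
# set `scale = "absolute"` on the readers to convert absolute copy numbers.

#' Remove hypersegmented samples
#'
#' Samples contributing more than `max_segments` segments are excluded (a
#' sample with exactly `max_segments` is retained).
#'
#' @param segments data.frame with columns `sample, chrom, start, end, value`.
#' @param max_segments cap (default 2000).
#' @return filtered data.frame; attribute `removed` lists dropped samples.
#' @export
filter_hypersegmented <- function(segments, max_segments = 2000) {
  if (nrow(segments) == 0) {
    attr(segments, "removed") <- character(0)
    return(segments)
  }
  n <- table(segments$sample)
  drop <- names(n)[n > max_segments]
  out <- segments[!segments$sample %in% drop, , drop = FALSE]
  attr(out, "removed") <- drop
  out
}

# length-weighted median: smallest value whose cumulative weight reaches
# half the total
weighted_median <- function(v, w) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  v[which(cumsum(w) >= sum(w) / 2)[1]]
}

#' Weighted genome instability index
#'
#' Per sample: ploidy is the length-weighted median segment value over the
#' included autosomes; per-chromosome GII is the fraction of the
#' chromosome's covered length whose segment value deviates from ploidy by
#' more than `deviation`; wGII is the unweighted mean of the per-chromosome
#' GIIs, so every chromosome counts equally regardless of size.
#'
#' @param segments data.frame `sample, chrom, start, end, value` (1-based
#'   inclusive, log2-ratio values).
#' @param deviation aberration threshold on the segment-value scale
#'   (default 0.3).
#' @param autosomes chromosomes to include; every sample must cover each.
#' @return data.frame `sample, ploidy, wgii` with attribute `gii`
#'   (samples x chromosomes matrix of per-chromosome fractions).
#' @export
compute_wgii <- function(segments, deviation = 0.3,
                         autosomes = unique(segments$chrom)) {
  samples <- unique(segments$sample)
  gii <- matrix(NA_real_, length(samples), length(autosomes),
                dimnames = list(samples, autosomes))
  ploidy <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- segments[segments$sample == samples[i] &
                    segments$chrom %in% autosomes, , drop = FALSE]
    missing <- setdiff(autosomes, unique(s$chrom))
    if (length(missing))
      stop("sample ", samples[i], " does not cover: ",
           paste(missing, collapse = ", "))
    len <- s$end - s$start + 1
    pl <- weighted_median(s$value, len)
    ploidy[i] <- pl
    ab <- abs(s$value - pl) > deviation
    for (ch in autosomes) {
      j <- s$chrom == ch
      gii[i, ch] <- sum(len[j & ab]) / sum(len[j])
    }
  }
  out <- data.frame(sample = samples, ploidy = ploidy,
                    wgii = rowMeans(gii), stringsAsFactors = FALSE)
  attr(out, "gii") <- gii
  out
}

#' Length-weighted mean copy-number change over a region
#'
#' `c_ij`: the mean of segment values over the region, weighted by the
#' length of each segment's overlap with it.
#'
#' @param segments one sample's segments (`chrom, start, end, value`).
#' @param region list or one-row data.frame with `chrom, start, end`.
#' @return scalar change; `NA` with a warning when no segment overlaps.
#' @export
region_change <- function(segments, region) {
  if (region$end < region$start) stop("zero-length or inverted region")
  s <- segments[segments$chrom == region$chrom, , drop = FALSE]
  ov_start <- pmax(s$start, region$start)
  ov_end <- pmin(s$end, region$end)
  w <- pmax(ov_end - ov_start + 1, 0)
  if (sum(w) == 0) {
    warning("region not covered by any segment; treated as unaltered")
    return(NA_real_)
  }
  sum(s$value * w) / sum(w)
}

#' Per-sample, per-region change matrix
#'
#' @param segments multi-sample segment data.frame.
#' @param regions data.frame `region, chrom, start, end, type`.
#' @return samples x regions numeric matrix of `c_ij`.
#' @export
region_change_matrix <- function(segments, regions) {
  samples <- unique(segments$sample)
  out <- matrix(NA_real_, length(samples), nrow(regions),
                dimnames = list(samples, regions$region))
  for (i in seq_along(samples)) {
    s <- segments[segments$sample == samples[i], , drop = FALSE]
    for (j in seq_len(nrow(regions)))
      out[i, j] <- region_change(s, regions[j, ])
  }
  out
}

#' Binarize region changes into the alteration matrix X
#'
#' `X_ij = 1` when the region is an amplification and `c_ij >= threshold`,
#' or a deletion and `c_ij <= -threshold`; otherwise 0 (boundary values
#' count as altered). Missing changes are treated as unaltered.
#'
#' @param changes samples x regions `c_ij` matrix.
#' @param regions data.frame with `region` and `type`
#'   ("amplification"/"deletion").
#' @param threshold binarization threshold (default 0.25).
#' @return object of class `alteration_matrix`: list with `X` (binary),
#'   `changes`, `types`, `threshold`.
#' @export
build_alteration_matrix <- function(changes, regions, threshold = 0.25) {
  if (!all(regions$type %in% c("amplification", "deletion")))
    stop("every region needs type amplification or deletion")
  X <- matrix(0L, nrow(changes), ncol(changes), dimnames = dimnames(changes))
  for (j in seq_len(ncol(changes))) {
    cj <- changes[, j]
    cj[is.na(cj)] <- 0
    X[, j] <- if (regions$type[j] == "amplification")
      as.integer(cj >= threshold) else as.integer(cj <= -threshold)
  }
  structure(list(X = X, changes = changes, types = regions$type,
                 threshold = threshold),
            class = "alteration_matrix")
}

as_alt <- function(X, types) {
  if (inherits(X, "alteration_matrix")) return(X)
  if (is.null(types)) types <- rep("amplification", ncol(X))
  structure(list(X = X, changes = NULL, types = types, threshold = NA),
            class = "alteration_matrix")
}

#' Margin-preserving permutations of the alteration matrix
#'
#' Checkerboard-swap MCMC over the class of binary matrices sharing X's row
#' and column sums exactly: a random 2x2 submatrix equal to
#' `[[1,0],[0,1]]` or `[[0,1],[1,0]]` is swapped. Swaps are confined within
#' amplification columns and within deletion columns, so margins are
#' preserved separately for the two alteration types. Proposals are lazy
#' trial swaps (each attempt is skipped with probability 1/2 and otherwise
#' swaps only when the proposed submatrix is swappable), which keeps the
#' stationary distribution exactly uniform over the margin class. Burn-in
#' runs until `10 * (number of ones)` swaps have occurred; emissions are
#' separated by an attempt budget targeting `thin_mult * (number of ones)`
#' swaps, calibrated from the burn-in success rate so sparse matrices are
#' thinned as strongly as dense ones. A matrix admitting no swap (e.g. all
#' ones) yields identical emissions and a degeneracy flag.
#'
#' @param X binary matrix or an `alteration_matrix`.
#' @param n_perm number of matrices to emit (default 10000).
#' @param seed RNG seed.
#' @param types per-column "amplification"/"deletion" when `X` is a plain
#'   matrix (defaults to one type).
#' @param burn_mult,thin_mult burn-in and thinning multipliers.
#' @return list of binary matrices; attribute `degenerate` is TRUE when no
#'   swap ever succeeded.
#' @export
permute_fixed_margins <- function(X, n_perm = 10000, seed = 1, types = NULL,
                                  burn_mult = 10, thin_mult = 1) {
  alt <- as_alt(X, types)
  set_generator_seed(seed)
  ct <- as.integer(alt$types == "deletion")
  res <- cpp_permute_fixed_margins(alt$X, ct, as.integer(n_perm),
                                   as.integer(burn_mult), as.integer(thin_mult))
  out <- res$matrices
  attr(out, "degenerate") <- res$degenerate
  out
}

#' Permutation test for ancestry-differential focal alterations
#'
#' The observed statistic per region is the Wald Z of the alteration column
#' in a logistic model `group ~ X_j + propensity`. The null distribution
#' comes from refitting the same model on margin-preserving permutations of
#' X (see [permute_fixed_margins()]), which hold each tumor's alteration
#' burden and each region's alteration frequency fixed. The two-sided
#' empirical p is `(1 + #{|Z_null| >= |Z_obs|}) / (n_null + 1)`; BH
#' q-values are computed across regions and regions are flagged at
#' `q < q_flag`.
#'
#' @param X binary alteration matrix or `alteration_matrix`.
#' @param groups 0/1 indicator (1 = group of interest) per sample.
#' @param propensity propensity scores or a `propensity_model`.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param types per-column region types when `X` is a plain matrix.
#' @param q_flag flagging threshold on the BH q (default 0.25).
#' @return data.frame `region, z, p, q, flagged`; attribute `degenerate`.
#' @export
scna_association_test <- function(X, groups, propensity, n_perm = 10000,
                                  seed = 1, types = NULL, q_flag = 0.25) {
  alt <- as_alt(X, types)
  if (inherits(propensity, "propensity_model")) propensity <- propensity$score
  if (min(table(groups)) < 2) stop("need >= 2 samples per group")
  set_generator_seed(seed)
  ct <- as.integer(alt$types == "deletion")
  res <- cpp_scna_perm_test(alt$X, as.numeric(groups), as.numeric(propensity),
                            ct, as.integer(n_perm), 10L, 1L)
  p <- (1 + res$exceed) / (res$nulls_used + 1)
  q <- bh_fdr(p)
  out <- data.frame(region = colnames(alt$X) %||% paste0("region", seq_along(p)),
                    z = res$z_obs, p = p, q = q, flagged = q < q_flag,
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- res$degenerate
  out
}

#' Association of wGII with group status
#'
#' Linear model `wGII ~ group + propensity`.
#'
#' @param wgii per-sample wGII values.
#' @inheritParams scna_association_test
#' @return one-row association data.frame.
#' @export
wgii_association <- function(wgii, groups, propensity) {
  adjusted_linear(wgii, groups, propensity, unit = "wGII")
}
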