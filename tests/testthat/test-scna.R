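test_that("hypersegmented samples are excluded at the 2,000-segment boundary", {
  seg1 <- data.frame(sample = "keep", chrom = "chr1",
                     start = seq(1, by = 10, length.out = 2000),
                     end = seq(10, by = 10, length.out = 2000), value = 0)
  seg2 <- data.frame(sample = "drop", chrom = "chr1",
                     start = seq(1, by = 10, length.out = 2001),
                     end = seq(10, by = 10, length.out = 2001), value = 0)
  out <- filter_hypersegmented(rbind(seg1, seg2))
  expect_setequal(unique(out$sample), "keep")
  expect_equal(attr(out, "removed"), "drop")
  empty <- filter_hypersegmented(seg1[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("wGII matches the hand-computed toy and is refinement invariant", {
  segs <- data.frame(sample = "s1",
                     chrom = c("chr1", "chr1", "chr2"),
                     start = c(1, 60e6 + 1, 1),
                     end = c(60e6, 100e6, 100e6),
                     value = c(0, 0.58, 0))
  w <- compute_wgii(segs)
  expect_equal(w$ploidy, 0)
  expect_equal(unname(attr(w, "gii")["s1", ]), c(0.4, 0))
  expect_equal(w$wgii, 0.2)
  # all segments at one value
  flat <- compute_wgii(transform(segs, value = 1.3))
  expect_equal(flat$wgii, 0)
  # splitting segments in half never changes the score
  set.seed(61)
  for (r in 1:100) {
    ns <- sample(3:8, 1)
    br <- sort(sample(2:99, ns - 1)) * 1e5
    st <- c(1, br + 1); en <- c(br, 1e7)
    segs1 <- data.frame(sample = "x", chrom = "c1", start = st, end = en,
                        value = round(rnorm(ns, 0, 0.5), 2))
    mid <- floor((segs1$start + segs1$end) / 2)
    segs2 <- rbind(transform(segs1, end = mid),
                   transform(segs1, start = mid + 1))
    expect_equal(compute_wgii(segs2)$wgii, compute_wgii(segs1)$wgii)
  }
  expect_error(compute_wgii(segs, autosomes = c("chr1", "chr2", "chr3")),
               "chr3")
})

test_that("region change is the overlap-length-weighted mean", {
  segs <- data.frame(sample = "s", chrom = "c1",
                     start = c(1, 101), end = c(100, 200),
                     value = c(0, 0.5))
  expect_equal(region_change(segs, list(chrom = "c1", start = 51, end = 150)),
               0.25)
  one <- data.frame(sample = "s", chrom = "c1", start = 1, end = 1000,
                    value = -0.7)
  expect_equal(region_change(one, list(chrom = "c1", start = 10, end = 20)),
               -0.7)
  expect_warning(v <- region_change(one, list(chrom = "c2", start = 1, end = 5)),
                 "not covered")
  expect_true(is.na(v))
  expect_error(region_change(one, list(chrom = "c1", start = 5, end = 4)),
               "zero-length")
})

test_that("alteration-matrix binarization includes the 0.25 boundary", {
  regions <- data.frame(region = c("amp", "del"),
                        type = c("amplification", "deletion"))
  ch <- matrix(c(0.25, 0.10, -0.25, -0.10), 2, 2,
               dimnames = list(c("a", "b"), c("amp", "del")))
  am <- build_alteration_matrix(ch, regions)
  expect_equal(unname(am$X), matrix(c(1L, 0L, 1L, 0L), 2, 2))
  expect_error(build_alteration_matrix(ch, data.frame(region = c("amp", "del"),
                                                      type = c("gain", "loss"))),
               "type")
})

test_that("permuted matrices preserve both margins exactly", {
  set.seed(62)
  for (r in 1:10) {
    X <- matrix(rbinom(48, 1, runif(1, 0.2, 0.5)), 8, 6)
    types <- sample(c("amplification", "deletion"), 6, replace = TRUE)
    pm <- permute_fixed_margins(X, n_perm = 200, seed = r, types = types)
    for (m in pm) {
      expect_identical(rowSums(m), rowSums(X))
      expect_identical(colSums(m), colSums(X))
      # type-specific margins preserved too
      for (tp in unique(types)) {
        j <- types == tp
        expect_identical(rowSums(m[, j, drop = FALSE]),
                         rowSums(X[, j, drop = FALSE]))
      }
    }
  }
})

test_that("the sampler is uniform over a tiny enumerable margin class", {
  X <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  pm <- permute_fixed_margins(X, n_perm = 10000, seed = 9)
  freq <- table(vapply(pm, mat_key, character(1))) / 10000
  expect_equal(length(freq), 2L)
  expect_equal(unname(as.numeric(freq)), c(0.5, 0.5), tolerance = 0.04)
  # all-ones matrix: single-member class, flagged degenerate
  ones <- matrix(1L, 3, 4)
  pmo <- permute_fixed_margins(ones, n_perm = 20, seed = 1)
  expect_true(attr(pmo, "degenerate"))
  expect_true(all(vapply(pmo, function(m) all(m == 1L), logical(1))))
})

test_that("empirical p matches complete enumeration on a 6x3 toy", {
  set.seed(42)
  X <- matrix(rbinom(18, 1, 0.4), 6, 3)
  y <- rep(c(0, 1), each = 3)
  ps <- plogis(rnorm(6, 0, 0.3))
  types <- rep("amplification", 3)
  class_mats <- enumerate_margin_class(rowSums(X), colSums(X))
  zfun <- function(m, j) ancestrydisp:::cpp_logistic_wald_z(y, cbind(1, m[, j], ps))
  res <- scna_association_test(X, y, ps, n_perm = 10000, seed = 3,
                               types = types)
  for (j in 1:3) {
    zobs <- zfun(X, j)
    zs <- vapply(class_mats, zfun, numeric(1), j = j)
    pexact <- mean(abs(zs) >= abs(zobs) - 1e-10)
    expect_equal(res$p[j], pexact, tolerance = 0.02)
  }
})

test_that("swapping group labels negates Z and keeps empirical p", {
  set.seed(63)
  X <- matrix(rbinom(200, 1, 0.3), 40, 5)
  y <- rep(0:1, each = 20)
  ps <- runif(40, 0.4, 0.6)
  a <- scna_association_test(X, y, ps, n_perm = 500, seed = 4)
  b <- scna_association_test(X, 1 - y, ps, n_perm = 500, seed = 4)
  expect_equal(b$z, -a$z, tolerance = 1e-6)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("wGII association finds a planted shift and validates input", {
  set.seed(64)
  grp <- rep(0:1, each = 100)
  wg <- pmin(pmax(rnorm(200, 0.2 + 0.1 * grp, 0.1), 0), 1)
  ps <- runif(200, 0.4, 0.6)
  r <- wgii_association(wg, grp, ps)
  expect_lt(r$p, 0.01)
  expect_gt(r$effect, 0)
  expect_error(wgii_association(c(0.1, 0.2, 0.3), c(0, 1, 0), runif(3)),
               "n >= 4")
})
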