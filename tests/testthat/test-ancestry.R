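fx <- make_panel_fixture()

test_that("reference PCA is orthonormal, ordered and duplication-invariant", {
  pc <- fit_reference_pca(fx$panel, n_axes = 4)
  G <- crossprod(pc$loadings)
  expect_equal(G, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(pc$eigenvalues) <= 1e-8))
  expect_true(all(pc$eigenvalues >= 0))
  # every sample duplicated: same subspace, same loadings (fixed signs)
  dup <- list(genotypes = rbind(fx$panel$genotypes, fx$panel$genotypes),
              labels = c(fx$panel$labels, fx$panel$labels))
  pc2 <- fit_reference_pca(dup, n_axes = 4)
  expect_equal(pc2$loadings, pc$loadings, tolerance = 1e-6)
  # PC1 separates two far-apart populations with no score overlap
  two <- list(genotypes = fx$panel$genotypes[fx$panel$labels != "pop3", ],
              labels = fx$panel$labels[fx$panel$labels != "pop3"])
  pco <- fit_reference_pca(two, n_axes = 2)
  s1 <- pco$ref_scores[two$labels == "pop1", 1]
  s2 <- pco$ref_scores[two$labels == "pop2", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  expect_error(fit_reference_pca(fx$panel, n_axes = 10000), "rank")
})

test_that("projection reproduces fitted scores and maps panel means to the origin", {
  pc <- fit_reference_pca(fx$panel, n_axes = 4)
  proj <- project_samples(pc, fx$panel$genotypes)
  expect_equal(proj, pc$ref_scores, tolerance = 1e-8, ignore_attr = TRUE)
  # a sample sitting at the panel mean of every SNP projects to the origin
  mean_dos <- matrix(pc$center, 1, dimnames = list("m", pc$snps))
  expect_equal(drop(project_samples(pc, mean_dos)), rep(0, 4),
               tolerance = 1e-10, ignore_attr = TRUE)
  noovl <- matrix(0, 1, 2, dimnames = list("x", c("zz1", "zz2")))
  expect_error(project_samples(pc, noovl), "overlap")
})

test_that("50/50 admixed samples project between the parental centroids", {
  pc <- fit_reference_pca(fx$panel, n_axes = 2)
  frac <- matrix(rep(c(0.5, 0.5, 0), 20), 20, byrow = TRUE)
  coh <- simulate_admixed_cohort(fx$panel, frac, seed = 41)
  proj <- project_samples(pc, coh$genotypes)
  c1 <- colMeans(pc$ref_scores[fx$panel$labels == "pop1", ])
  c2 <- colMeans(pc$ref_scores[fx$panel$labels == "pop2", ])
  mid <- (c1 + c2) / 2
  spread <- apply(pc$ref_scores, 2, sd)
  for (j in 1:2)
    expect_lt(max(abs(proj[, j] - mid[j])), 3 * spread[j])
})

test_that("k-NN classification votes, ties and permutation invariance behave", {
  pc <- fit_reference_pca(fx$panel, n_axes = 3)
  # a target coincident with a reference sample at k = 1
  r <- classify_knn(pc$ref_scores[7, , drop = FALSE], pc$ref_scores,
                    fx$panel$labels, k = 1)
  expect_equal(r$label, fx$panel$labels[7])
  expect_equal(sum(attr(r, "votes")), 1)
  # constructed plurality (3-2 at k = 5) and exact 2-2 tie (k = 4)
  refs <- rbind(c(0, 0), c(0.1, -0.1), c(0, 3),
                c(1, 0), c(1.1, -0.1),
                c(5, 0))
  labs <- c("a", "a", "a", "b", "b", "c")
  tgt <- matrix(c(0.4, 0), 1, 2)
  t5 <- classify_knn(tgt, refs, labs, k = 5)
  expect_equal(unname(attr(t5, "votes")[1, ]), c(3L, 2L, 0L))
  expect_false(t5$tie_broken)
  expect_equal(t5$label, "a")
  t4 <- classify_knn(tgt, refs, labs, k = 4)
  expect_equal(unname(attr(t4, "votes")[1, ]), c(2L, 2L, 0L))
  expect_true(t4$tie_broken)
  # tie resolved toward the nearer population centroid
  ca <- colMeans(refs[1:3, ]); cb <- colMeans(refs[4:5, ])
  nearer <- if (sum((tgt - ca)^2) < sum((tgt - cb)^2)) "a" else "b"
  expect_equal(t4$label, nearer)
  # reference ordering must not matter
  set.seed(42)
  perm <- sample(nrow(refs))
  t4p <- classify_knn(tgt, refs[perm, ], labs[perm], k = 4)
  expect_equal(t4p$label, t4$label)
  expect_error(classify_knn(refs, refs, labs, k = 0), "positive")
  expect_error(classify_knn(refs, refs, labs, k = 10), "exceeds")
})

test_that("unadmixed targets are classified perfectly on a separated panel", {
  pc <- fit_reference_pca(fx$panel, n_axes = 10)
  set.seed(43)
  idx <- sample(1:3, 60, replace = TRUE)
  coh <- simulate_admixed_cohort(fx$panel, diag(3)[idx, ], seed = 44)
  proj <- project_samples(pc, coh$genotypes)
  cls <- classify_knn(proj, pc$ref_scores, fx$panel$labels, k = 5)
  expect_equal(cls$label, paste0("pop", idx))
})

test_that("admixture estimation recovers fractions and flags degeneracy", {
  coh <- simulate_admixed_cohort(fx$panel,
                                 matrix(c(1, 0, 0), 10, 3, byrow = TRUE),
                                 seed = 45)
  q <- estimate_admixture(coh$genotypes, fx$freqs)
  # estimation noise scales with SNP count; this fixture is deliberately small
  expect_true(all(q[, 1] >= 0.85))
  expect_gte(mean(q[, 1]), 0.93)
  expect_equal(rowSums(q), rep(1, 10), tolerance = 1e-9, ignore_attr = TRUE)
  # two identical reference populations: degenerate, symmetric solution
  f2 <- rbind(fx$freqs[1, ], fx$freqs[1, ])
  q2 <- estimate_admixture(coh$genotypes[1, ], f2)
  expect_true(attr(q2, "degenerate"))
  expect_equal(unname(q2[1, ]), c(0.5, 0.5), tolerance = 1e-9)
  # 50/50 truth recovered within 0.05 per component
  frac <- matrix(rep(c(0.5, 0.5, 0), 30), 30, byrow = TRUE)
  coh5 <- simulate_admixed_cohort(fx$panel, frac, seed = 46)
  q5 <- estimate_admixture(coh5$genotypes, fx$freqs)
  expect_lt(max(abs(colMeans(q5) - c(0.5, 0.5, 0))), 0.05)
})

test_that("admixture EM log-likelihood is monotone across iterations", {
  coh <- simulate_admixed_cohort(fx$panel, matrix(c(0.3, 0.3, 0.4), 1),
                                 seed = 47)
  lls <- vapply(c(10, 20, 40, 80, 160), function(it)
    attr(estimate_admixture(coh$genotypes, fx$freqs, max_iter = it),
         "loglik"), numeric(1))
  expect_true(all(diff(lls) >= -1e-9))
})
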