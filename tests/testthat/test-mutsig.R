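test_that("catalog construction follows the pyrimidine strand convention", {
  # G>A with 5'T/3'C reverse-complements to C>T with 5'G/3'A
  rec <- data.frame(sample = "s1", ref = "G", alt = "A", context = "TGC")
  cat1 <- build_catalog(rec)
  expect_equal(sum(cat1), 1)
  expect_equal(unname(cat1[1, "G[C>T]A"]), 1)
  # three identical records accumulate; empty input is a zero vector
  cat3 <- build_catalog(rec[c(1, 1, 1), ])
  expect_equal(unname(cat3[1, "G[C>T]A"]), 3)
  empty <- build_catalog(data.frame(sample = character(), ref = character(),
                                    alt = character(), context = character()),
                         samples = "s1")
  expect_true(all(empty == 0))
  # non-SNVs and N-contexts are skipped and counted
  messy <- data.frame(sample = "s1",
                      ref = c("C", "CT", "C", "-"),
                      alt = c("T", "C", "A", "G"),
                      context = c("ACA", "ACA", "ANA", "ACA"))
  cm <- build_catalog(messy)
  expect_equal(sum(cm), 1)
  expect_equal(attr(cm, "n_non_snv"), 2)
  expect_equal(attr(cm, "n_skipped"), 1)
  # channel conservation: total equals accepted SNVs
  S <- builtin_signatures()
  big <- simulate_mutation_catalogs(S, matrix(c(0.4, 0.3, 0.3), 1), 5000,
                                    seed = 3)
  expect_equal(sum(big), 5000)
})

test_that("cosine similarity matches hand computations and rejects zeros", {
  v <- runif(96)
  expect_equal(cosine_similarity(v, v), 1)
  a <- c(1, rep(0, 95)); b <- c(0, 1, rep(0, 94))
  expect_equal(cosine_similarity(a, b), 0)
  expect_equal(cosine_similarity(c(1, 1, rep(0, 94)), a), 1 / sqrt(2))
  expect_error(cosine_similarity(rep(0, 96), v), "zero")
})

test_that("NNLS refitting matches the support-enumeration oracle", {
  S <- builtin_signatures()
  set.seed(51)
  for (r in 1:20) {
    w <- rgamma(3, 1); w <- w / sum(w)
    y <- drop(S %*% w) + abs(rnorm(96, 0, 0.002))
    y <- y / sum(y)
    fit <- ancestrydisp:::nnls_fit(S, y)
    expect_equal(fit, nnls_oracle(S, y), tolerance = 1e-6)
  }
})

test_that("signature refitting recovers exact and mixed spectra", {
  S <- builtin_signatures()
  # spectrum equal to one signature
  f1 <- refit_signatures(round(S[, 2] * 1e6), S)
  expect_equal(unname(f1$weights_norm[1, ]), c(0, 1, 0), tolerance = 1e-4)
  expect_equal(f1$cosine, 1, tolerance = 1e-6)
  # 0.5/0.3/0.2 mixture at 50,000 mutations within +/- 0.02
  cat1 <- simulate_mutation_catalogs(S, matrix(c(0.5, 0.3, 0.2), 1), 50000,
                                     seed = 52)
  fm <- refit_signatures(cat1, S)
  expect_lt(max(abs(fm$weights_norm[1, ] - c(0.5, 0.3, 0.2))), 0.02)
  expect_error(refit_signatures(rep(0, 96), S), "empty")
})

test_that("weights below the discard threshold are removed", {
  S <- builtin_signatures()
  y <- drop(S %*% c(0.55, 0.40, 0.05))
  fit <- refit_signatures(round(y * 1e6), S)
  expect_true("sig3" %in% fit$discarded[[1]])
  expect_equal(unname(fit$weights_norm[1, "sig3"]), 0)
  retained <- fit$weights_norm[1, fit$weights_norm[1, ] > 0]
  expect_true(all(retained >= 0.06))
  # raw weights stay within [0, 1] and sum to at most ~1
  expect_true(all(fit$weights >= 0 & fit$weights <= 1 + 1e-8))
  expect_lte(sum(fit$weights[1, ]), 1 + 1e-6)
})

test_that("pruning removes signatures that fail to improve the cosine", {
  S <- builtin_signatures()
  # make two signatures nearly redundant for this spectrum
  y <- drop(S %*% c(0.9, 0.1, 0)) ; y <- y / sum(y)
  fit <- refit_signatures(round(y * 1e6), S, prune_gain = 0.2)
  # with a very permissive prune_gain only the dominant signature survives
  expect_equal(sum(fit$weights_norm[1, ] > 0), 1)
  expect_gt(fit$cosine, 0.9)
})

test_that("signature and burden associations detect planted group shifts", {
  S <- builtin_signatures()
  n <- 60
  grp <- rep(0:1, each = n / 2)
  w <- cbind(0.6 - 0.3 * grp, 0.3 + 0.3 * grp, rep(0.1, n))
  cat1 <- simulate_mutation_catalogs(S, w, 5000, seed = 53)
  fit <- refit_signatures(cat1, S)
  ps <- runif(n, 0.4, 0.6)
  sa <- signature_contribution_association(fit, grp, ps)
  expect_equal(nrow(sa), 3)
  expect_lt(sa$q[sa$unit == "sig2"], 0.05)
  expect_gt(sa$effect[sa$unit == "sig2"], 0)
  expect_error(signature_contribution_association(fit, c(1, rep(0, n - 1)), ps),
               ">= 2")
  # burden: monotone-invariant and sensitive to a location shift
  tot <- rgamma(n, 10) * exp(0.8 * grp)
  b1 <- burden_association(tot, grp, ps)
  b2 <- burden_association(tot^2, grp, ps)
  expect_equal(b1$p, b2$p)
  expect_lt(b1$p, 0.05)
})

test_that("gene-frequency association applies the 1% filter and direction", {
  n0 <- 400; n1 <- 60
  grp <- rep(c(0, 1), c(n0, n1))
  diff_or_gt1 <- flat_p <- numeric(20)
  rare_seen <- FALSE
  for (r in 1:20) {
    set.seed(540 + r)
    tab <- cbind(rare = rep(c(1, 0), c(2, n0 + n1 - 2)),  # 0.43% frequency
                 diff = rbinom(n0 + n1, 1, ifelse(grp == 1, 0.20, 0.10)),
                 flat = rbinom(n0 + n1, 1, 0.15))
    ps <- runif(n0 + n1, 0.4, 0.6)
    res <- gene_frequency_association(tab, grp, ps)
    rare_seen <- rare_seen || "rare" %in% res$unit
    diff_or_gt1[r] <- res$effect[res$unit == "diff"] > 1
    flat_p[r] <- res$p[res$unit == "flat"]
  }
  expect_false(rare_seen)               # ~0.5% frequency always excluded
  expect_gt(mean(diff_or_gt1), 0.8)     # planted direction found in most runs
  expect_gt(mean(flat_p), 0.25)         # null gene p roughly uniform on average
})

test_that("clonality comparison is the shared Fisher machinery", {
  tab <- matrix(c(8, 1, 2, 5), 2)
  expect_equal(clonality_fisher(tab)$p, fisher_2x2(tab)$p)
  expect_equal(clonality_fisher(tab)$effect, 20)
})
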