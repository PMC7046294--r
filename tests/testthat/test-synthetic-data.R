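test_that("generators are deterministic under a fixed seed", {
  pm <- population_model(2, 200, 0.05, seed = 5)
  expect_identical(simulate_reference_panel(pm, 10, seed = 3),
                   simulate_reference_panel(pm, 10, seed = 3))
  p <- simulate_reference_panel(pm, 10, seed = 3)
  frac <- matrix(c(0.5, 0.5), 5, 2, byrow = TRUE)
  expect_identical(simulate_admixed_cohort(p, frac, seed = 4),
                   simulate_admixed_cohort(p, frac, seed = 4))
  des <- simulate_design(5, 5, seed = 2)
  expect_identical(simulate_counts(50, des, seed = 9),
                   simulate_counts(50, des, seed = 9))
})

test_that("population divergence shrinks with Fst", {
  pm <- population_model(2, 5000, 1e-4, seed = 6)
  p <- simulate_reference_panel(pm, 50, seed = 7)
  d <- mean(abs(p$pop_freqs[1, ] - p$pop_freqs[2, ]))
  expect_lt(d, 0.02)
  pm2 <- population_model(2, 5000, 0.2, seed = 6)
  p2 <- simulate_reference_panel(pm2, 50, seed = 7)
  expect_gt(mean(abs(p2$pop_freqs[1, ] - p2$pop_freqs[2, ])), d * 5)
  expect_error(population_model(1, 10, 0.1), "n_pops")
  expect_error(population_model(3, 10, 1.2), "fst")
  expect_error(simulate_reference_panel(pm, 1), "n_per_pop")
})

test_that("admixed cohorts respect their mixing fractions", {
  fx <- make_panel_fixture()
  # degenerate mixture: indistinguishable from pop-1 allele frequencies
  coh <- simulate_admixed_cohort(fx$panel, matrix(c(1, 0, 0), 30, 3,
                                                  byrow = TRUE), seed = 8)
  exp_freq <- mean(fx$panel$pop_freqs[1, ])
  expect_equal(mean(coh$genotypes) / 2, exp_freq, tolerance = 0.02)
  # empty cohort
  e <- simulate_admixed_cohort(fx$panel, matrix(numeric(0), 0, 3), seed = 1)
  expect_equal(nrow(e$genotypes), 0)
  expect_error(simulate_admixed_cohort(fx$panel, matrix(c(0.6, 0.6, 0), 1),
                                       seed = 1), "simplex")
})

test_that("mutation catalogs conserve counts and concentrate on their signature", {
  S <- builtin_signatures()
  cat1 <- simulate_mutation_catalogs(S, matrix(c(1, 0, 0), 1), 50000, seed = 4)
  expect_equal(sum(cat1), 50000)
  expect_gt(cosine_similarity(cat1[1, ], S[, 1]), 0.99)
  z <- simulate_mutation_catalogs(S, matrix(c(0.2, 0.3, 0.5), 1), 0, seed = 4)
  expect_true(all(z == 0))
  # expectation identity for a mixture
  mix <- c(0.5, 0.3, 0.2)
  big <- simulate_mutation_catalogs(S, matrix(mix, 1), 2e5, seed = 5)
  expect_lt(max(abs(big[1, ] / 2e5 - drop(S %*% mix))), 0.005)
  expect_error(simulate_mutation_catalogs(S, matrix(c(0.5, 0.5), 1), 10),
               "simplex|dimension")
})

test_that("segment tables tile chromosomes and carry planted events", {
  genome <- c(chrA = 1e6, chrB = 5e5)
  planted <- data.frame(region = "r1", chrom = "chrA", start = 2e5,
                        end = 3e5 - 1, type = "deletion", effect = 0.8,
                        prob_0 = 0, prob_1 = 1)
  st <- simulate_segment_tables(genome, planted, groups = c("1", "1", "0"),
                                noise_sd = 0, n_extra_breaks = 2, seed = 3)
  segs <- st$segments
  for (smp in unique(segs$sample)) {
    for (ch in names(genome)) {
      s <- segs[segs$sample == smp & segs$chrom == ch, ]
      s <- s[order(s$start), ]
      expect_equal(s$start[1], 1)
      expect_equal(s$end[nrow(s)], unname(genome[ch]))
      if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)] + 1)
    }
  }
  # carriers in group 1 only (prob 1 vs 0) and the planted delta present
  expect_equal(unname(st$carriers[, 1]), c(1, 1, 0))
  s1 <- segs[segs$sample == "tumor0001" & segs$chrom == "chrA", ]
  inreg <- s1$start >= 2e5 & s1$end <= 3e5 - 1
  expect_true(all(s1$value[inreg] == -0.8))
  expect_true(all(s1$value[!inreg] == 0))
  # overlapping planted regions rejected
  bad <- rbind(planted, transform(planted, region = "r2", start = 25e4,
                                  end = 35e4))
  expect_error(simulate_segment_tables(genome, bad, "1", seed = 1), "overlap")
})

test_that("count simulation honors size factors and planted fold changes", {
  des <- simulate_design(20, 20, seed = 13)
  sf <- c(2, rep(1, 39))
  sim <- simulate_counts(800, des, lfc = 0, dispersion = 0.02,
                         size_factors = sf, seed = 14)
  tot <- colSums(sim$counts)
  expect_equal(tot[1] / mean(tot[-1]), 2, tolerance = 0.1, ignore_attr = TRUE)
  sim2 <- simulate_counts(400, des, lfc = 2, dispersion = 0.02, seed = 15)
  m1 <- rowMeans(sim2$counts[, des$group == 1])
  m0 <- rowMeans(sim2$counts[, des$group == 0])
  expect_equal(median(log2(m1 / m0)), 2, tolerance = 0.2)
  expect_error(simulate_counts(10, des, dispersion = 0), "dispersion")
})

test_that("gene-model construction matches the intended locus classes", {
  gm <- simulate_gene_models(12, 2, seed = 20)
  expect_equal(nrow(gm$truth), 8)
  expect_equal(unname(table(gm$truth$class)[LNC_CLASSES_EXPECTED <- c("antisense", "exonic", "intergenic", "intronic")]),
               rep(2L, 4), ignore_attr = TRUE)
  # intergenic lncRNAs sit > 10 kb from any coding gene
  cod <- gm$models[gm$models$biotype == "protein_coding", ]
  for (g in gm$truth$gene_id[gm$truth$class == "intergenic"]) {
    ex <- gm$models[gm$models$gene_id == g, ]
    gaps <- pmax(cod$start - max(ex$end), min(ex$start) - cod$end)
    expect_gt(min(gaps), 10000)
  }
  empty <- simulate_gene_models(4, 0, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  expect_error(simulate_gene_models(-1, 0), ">= 0")
})
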