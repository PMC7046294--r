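test_that("planted locus classes are recovered exactly", {
  gm <- simulate_gene_models(30, 5, seed = 91)
  lnc <- gm$models[gm$models$biotype == "lncRNA", ]
  cod <- gm$models[gm$models$biotype == "protein_coding", ]
  cls <- classify_lncrna(lnc, cod)
  m <- merge(cls$genes, gm$truth, by = "gene_id")
  expect_equal(nrow(m), 20)
  expect_true(all(m$class.x == m$class.y))
  # classes partition the input: one class per gene
  expect_equal(anyDuplicated(cls$genes$gene_id), 0L)
  empty <- classify_lncrna(lnc[0, ], cod)
  expect_equal(nrow(empty$genes), 0)
})

test_that("the class hierarchy resolves multi-transcript genes", {
  cod <- data.frame(gene_id = "C1", transcript_id = "C1.t1", chrom = "chr1",
                    start = c(1000, 5000), end = c(1999, 5999), strand = "+",
                    biotype = "protein_coding")
  # one intronic transcript and one exonic transcript -> gene class exonic
  lnc <- rbind(
    data.frame(gene_id = "L1", transcript_id = "L1.t1", chrom = "chr1",
               start = 3000, end = 3499, strand = "+", biotype = "lncRNA"),
    data.frame(gene_id = "L1", transcript_id = "L1.t2", chrom = "chr1",
               start = 1500, end = 2400, strand = "+", biotype = "lncRNA"))
  cls <- classify_lncrna(lnc, cod)
  expect_equal(sort(cls$transcripts$class), c("exonic", "intronic"))
  expect_equal(cls$genes$class, "exonic")
  # opposite strand only -> antisense; no overlap -> intergenic
  lnc2 <- rbind(
    data.frame(gene_id = "L2", transcript_id = "L2.t1", chrom = "chr1",
               start = 3000, end = 3499, strand = "-", biotype = "lncRNA"),
    data.frame(gene_id = "L3", transcript_id = "L3.t1", chrom = "chr1",
               start = 50000, end = 50999, strand = "+", biotype = "lncRNA"))
  cls2 <- classify_lncrna(lnc2, cod)
  expect_equal(cls2$genes$class[cls2$genes$gene_id == "L2"], "antisense")
  expect_equal(cls2$genes$class[cls2$genes$gene_id == "L3"], "intergenic")
})

test_that("classification is invariant under a constant coordinate shift", {
  gm <- simulate_gene_models(12, 2, seed = 92)
  lnc <- gm$models[gm$models$biotype == "lncRNA", ]
  cod <- gm$models[gm$models$biotype == "protein_coding", ]
  base <- classify_lncrna(lnc, cod)
  shift <- function(d) transform(d, start = start + 7777, end = end + 7777)
  moved <- classify_lncrna(shift(lnc), shift(cod))
  expect_equal(moved$genes, base$genes)
})

test_that("chromatin-state proximity respects the 10 kb boundary to the base pair", {
  states <- data.frame(chrom = "chr1", start = 100000, end = 101000,
                       state = "active_promoter")
  # gaps of exactly 10 kb, 10 kb - 1, and 10 kb + 1 downstream of the state
  spans <- data.frame(gene_id = c("at", "inside", "outside", "overlap", "far"),
                      chrom = "chr1",
                      start = c(111001, 111000, 111002, 100500, 300000),
                      end = c(111500, 111500, 111500, 100600, 300500))
  fl <- chromatin_state_annotation(spans, states)$flags
  expect_true(fl["at", "active_promoter"])        # gap == 10,000
  expect_true(fl["inside", "active_promoter"])    # gap == 9,999
  expect_false(fl["outside", "active_promoter"])  # gap == 10,001
  expect_true(fl["overlap", "active_promoter"])   # distance 0
  expect_false(fl["far", "active_promoter"])
  expect_error(chromatin_state_annotation(spans,
                                          transform(states, state = "odd")),
               "unknown")
  # enrichment among DE genes uses the shared Fisher machinery
  de <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  ann <- chromatin_state_annotation(spans, states, de = de)
  expect_s3_class(ann$enrichment, "data.frame")
})

test_that("RCI comparison detects a nuclear shift in DE lncRNAs", {
  set.seed(93)
  de <- rep(c(TRUE, FALSE), each = 100)
  rci <- c(rnorm(100, -1), rnorm(100, 0))
  r <- rci_compare(rci, de)
  expect_lt(r$p, 1e-6)
  expect_lt(r$diff, 0)
  expect_error(rci_compare(rnorm(5), c(TRUE, rep(FALSE, 4))), ">= 2")
  flatr <- rci_compare(rep(1, 10), rep(c(TRUE, FALSE), 5))
  expect_true(is.na(flatr$p))
})

test_that("ARG cutoff calibration picks the largest qualifying cutoff", {
  r <- calibrate_arg_cutoff(rep(2, 10), c(1.2, 1.5, 3))
  expect_equal(r$cutoff, 1.5)
  expect_equal(r$sensitivity, 1)
  expect_false(r$flagged)
  # a control exactly at the cutoff passes
  r2 <- calibrate_arg_cutoff(c(1.5, 1.5), c(1.5), floor = 1)
  expect_equal(r2$sensitivity, 1)
  # nothing qualifies: lowest candidate, flagged
  r3 <- calibrate_arg_cutoff(c(2, 1.0), c(1.2, 1.5), floor = 1)
  expect_equal(r3$cutoff, 1.2)
  expect_true(r3$flagged)
  expect_error(calibrate_arg_cutoff(numeric(0), 1.2), "control")
})

test_that("ARG classification is two-sided with inclusive boundaries", {
  folds <- c(up = 1.25, down = 0.80, none = 1.0, at = 1.2, inv = 1 / 1.2)
  r <- classify_args(folds, cutoff = 1.2)
  expect_equal(r$direction, c("enhanced", "suppressed", "none", "enhanced",
                              "suppressed"))
  expect_equal(r$regulated, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_error(classify_args(c(1.5, -2)), "positive")
})

test_that("TSS aggregation is flat on constant tracks and strand-symmetric", {
  track <- data.frame(chrom = "chr1", start = 0, end = 1e6, value = 3)
  tss <- data.frame(chrom = "chr1", pos = c(5000, 9000), strand = "+")
  prof <- tss_aggregate(track, tss, flank = 1000, bin = 100)
  expect_true(all(prof$value == 3))
  expect_true(all(prof$coverage == 1))
  expect_equal(nrow(prof), 20)
  # single spike at one TSS peaks at position 0
  spike <- data.frame(chrom = "chr1", start = 4999, end = 5001, value = 10)
  p2 <- tss_aggregate(spike, tss[1, ], flank = 500, bin = 50)
  expect_equal(p2$position[which.max(p2$value)], 0)
  # mirrored minus-strand geometry reproduces the plus-strand profile
  asym <- data.frame(chrom = "chr1", start = 5100, end = 5200, value = 7)
  plus <- tss_aggregate(asym, data.frame(chrom = "chr1", pos = 5000,
                                         strand = "+"), 500, 50)
  asym_m <- data.frame(chrom = "chr1", start = 9799, end = 9899, value = 7)
  minus <- tss_aggregate(asym_m, data.frame(chrom = "chr1", pos = 10000,
                                            strand = "-"), 500, 50)
  expect_equal(minus$value, plus$value)
  expect_error(tss_aggregate(track, tss[0, ], 500, 50), "empty")
  expect_error(tss_aggregate(track, tss, 501, 50), "multiple")
})
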