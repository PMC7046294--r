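# End-to-end orchestration: simulate a full synthetic dataset bundle with
# known truth, then run every analysis stage from the on-disk files alone,
# writing tidy TSV outputs and a JSON run manifest. Stages run in
# dependency order (ancestry -> propensity -> {mutsig, scna, expression} ->
# enrichment -> lncrna); a failure in one branch does not abort independent
# branches.

#' Default demo configuration
#'
#' Bundled problem sizes: 3 reference populations of 150 samples, 400 study
#' samples with a planted 60/340 group split, 5,000 SNPs, 2,000 genes, 20
#' focal regions, 22 autosomes of 100 Mb. All stage parameters can be
#' overridden before passing the config on.
#'
#' @param outdir output directory for the bundle and results.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return nested config list (YAML-serializable).
#' @export
default_config <- function(outdir, seed = 1) {
  list(
    seed = seed,
    outdir = outdir,
    stages = c("ancestry", "propensity", "mutsig", "scna", "expression",
               "enrichment", "lncrna"),
    cohort = list(n_group0 = 340, n_group1 = 60,
                  age_shift = 4, grade_shift = 0.3),
    ancestry = list(n_pops = 3, n_per_pop = 150, n_snps = 5000, fst = 0.1,
                    n_axes = 10, k = 5),
    mutsig = list(n_mutations = 300),
    scna = list(n_chrom = 22, chrom_mb = 100, n_regions = 20, n_perm = 1000,
                threshold = 0.25, deviation = 0.3, base_prob = 0.15,
                diff_prob = c(0.10, 0.30)),
    expression = list(n_genes = 2000, n_de = 200, lfc = 1, dispersion = 0.05),
    enrichment = list(n_sets = 5, set_size = 30, n_perm = 200),
    lncrna = list(n_coding = 30, n_lnc_per_class = 5, n_controls = 18)
  )
}

#' Read/write a pipeline config as YAML
#' @param path YAML file.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config config list.
#' @export
write_config <- function(config, path) yaml::write_yaml(config, path)

data_dir <- function(config) file.path(config$outdir, "data")
res_dir <- function(config) file.path(config$outdir, "results")

#' Simulate the full dataset bundle a pipeline run consumes
#'
#' Invokes every generator under seeds derived from the config's global
#' seed and writes the bundle (genotypes, labels, clinical table, MAF-lite
#' mutations, signatures, SEG segments, focal-region BED, counts, gene-model
#' GTF, gene sets, AR fold changes) plus a ground-truth JSON into
#' `<outdir>/data`.
#'
#' @param config config list from [default_config()] or [read_config()].
#' @return invisibly, the truth list.
#' @export
simulate_all <- function(config) {
  n0 <- config$cohort$n_group0; n1 <- config$cohort$n_group1
  if (n0 + n1 <= 0 || config$ancestry$n_per_pop <= 0)
    stop("config requests zero samples")
  dd <- data_dir(config)
  dir.create(dd, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  ac <- config$ancestry

  # reference panel + admixed study cohort; group 1 is pop2-dominated
  pm <- population_model(ac$n_pops, ac$n_snps, ac$fst, seed = seed)
  panel <- simulate_reference_panel(pm, ac$n_per_pop, seed = seed + 1)
  set_generator_seed(seed + 2)
  n <- n0 + n1
  group <- c(rep(0, n0), rep(1, n1))
  frac <- matrix(0, n, ac$n_pops)
  main_pop <- ifelse(group == 1, 2, 1)
  for (i in seq_len(n)) {
    a <- stats::rgamma(ac$n_pops, 1)
    a <- 0.1 * a / sum(a)                 # minor admixture
    frac[i, ] <- a
    frac[i, main_pop[i]] <- frac[i, main_pop[i]] + 0.9
  }
  cohort <- simulate_admixed_cohort(panel, frac, seed = seed + 3)
  clinical <- simulate_design(n0, n1, config$cohort$age_shift,
                              config$cohort$grade_shift, seed = seed + 4)
  samples <- clinical$sample
  rownames(cohort$genotypes) <- samples
  rownames(cohort$truth) <- samples
  write_genotypes_tsv(panel$genotypes, file.path(dd, "reference_genotypes.tsv"))
  write_labels_tsv(stats::setNames(panel$labels, rownames(panel$genotypes)),
                   file.path(dd, "reference_labels.tsv"))
  write_genotypes_tsv(cohort$genotypes, file.path(dd, "study_genotypes.tsv"))
  write_clinical_tsv(clinical, file.path(dd, "clinical.tsv"))

  # mutation catalogs -> MAF-lite records (context encodes the channel)
  sigs <- builtin_signatures()
  set_generator_seed(seed + 5)
  w <- matrix(rep(c(0.6, 0.3, 0.1), each = n), n)
  cat96 <- simulate_mutation_catalogs(sigs, w, config$mutsig$n_mutations,
                                      seed = seed + 5)
  rownames(cat96) <- samples
  maf <- catalog_to_maf(cat96, seed = seed + 6)
  write_maf_lite(maf, file.path(dd, "mutations.maf.tsv"))
  write_signatures_tsv(sigs, file.path(dd, "signatures.tsv"))

  # segments with one planted differential region among equal-frequency ones
  sc <- config$scna
  genome <- stats::setNames(rep(sc$chrom_mb * 1e6, sc$n_chrom),
                            paste0("chr", seq_len(sc$n_chrom)))
  set_generator_seed(seed + 7)
  reg_chrom <- sample(names(genome), sc$n_regions, replace = TRUE)
  reg_start <- round(stats::runif(sc$n_regions, 1e6, sc$chrom_mb * 1e6 - 4e6))
  planted <- data.frame(region = sprintf("region%02d", seq_len(sc$n_regions)),
                        chrom = reg_chrom, start = reg_start,
                        end = reg_start + 2e6 - 1,
                        type = rep(c("amplification", "deletion"),
                                   length.out = sc$n_regions),
                        effect = 0.6, stringsAsFactors = FALSE)
  # avoid same-chromosome overlap by re-drawing offenders
  repeat {
    bad <- FALSE
    for (ch in unique(planted$chrom)) {
      p <- planted[planted$chrom == ch, ]
      p <- p[order(p$start), ]
      if (nrow(p) > 1 && any(p$start[-1] <= p$end[-nrow(p)])) {
        i <- which(planted$chrom == ch)[2]
        planted$start[i] <- round(stats::runif(1, 1e6, sc$chrom_mb * 1e6 - 4e6))
        planted$end[i] <- planted$start[i] + 2e6 - 1
        bad <- TRUE
      }
    }
    if (!bad) break
  }
  p0 <- rep(sc$base_prob, sc$n_regions); p1 <- p0
  p0[1] <- sc$diff_prob[1]; p1[1] <- sc$diff_prob[2]
  planted$prob_0 <- p0; planted$prob_1 <- p1
  segtab <- simulate_segment_tables(genome, planted, as.character(group),
                                    noise_sd = 0.05, seed = seed + 8)
  segtab$segments$sample <- samples[match(segtab$segments$sample,
                                          sprintf("tumor%04d", seq_len(n)))]
  write_seg(segtab$segments, file.path(dd, "segments.seg"))
  write_regions_bed(planted, file.path(dd, "regions.bed"))

  # counts with planted DE
  ex <- config$expression
  lfc <- rep(0, ex$n_genes)
  de_idx <- seq_len(ex$n_de)
  lfc[de_idx] <- ex$lfc * rep(c(1, -1), length.out = ex$n_de)
  cnt <- simulate_counts(ex$n_genes, clinical, lfc = lfc,
                         dispersion = ex$dispersion, seed = seed + 9)
  write_counts_tsv(cnt$counts, file.path(dd, "counts.tsv"))

  # gene sets for the enrichment stage: one enriched in planted-up genes
  en <- config$enrichment
  set_generator_seed(seed + 10)
  genes <- rownames(cnt$counts)
  up <- genes[lfc > 0]
  sets <- list(planted_up = sample(up, min(en$set_size, length(up))))
  for (i in seq_len(en$n_sets - 1))
    sets[[paste0("random", i)]] <- sample(genes, en$set_size)
  write_gmt(sets, file.path(dd, "gene_sets.gmt"))

  # gene models, chromatin states, AR stimulation fold changes
  lc <- config$lncrna
  gm <- simulate_gene_models(lc$n_coding, lc$n_lnc_per_class, seed = seed + 11)
  write_gene_models_gtf(gm$models, file.path(dd, "gene_models.gtf"))
  set_generator_seed(seed + 12)
  lnc_ids <- gm$truth$gene_id
  st_start <- sort(sample.int(8e6, 40)) * 2
  states <- data.frame(chrom = "chrS", start = st_start, end = st_start + 5000,
                       state = sample(CHROMATIN_STATES, 40, replace = TRUE))
  utils::write.table(states, file.path(dd, "chromatin_states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  folds <- exp(stats::rnorm(length(lnc_ids), 0, 0.4))
  controls <- exp(stats::rnorm(lc$n_controls, log(1.6), 0.3))
  utils::write.table(data.frame(gene = lnc_ids, fold = folds),
                     file.path(dd, "ar_folds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = paste0("CTRL", seq_along(controls)),
                                fold = controls),
                     file.path(dd, "ar_controls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(group = stats::setNames(group, samples),
                admixture = cohort$truth,
                signature_weights = w,
                scna_planted = planted,
                scna_carriers = segtab$carriers,
                de_lfc = stats::setNames(lfc, genes),
                lnc_classes = gm$truth)
  jsonlite::write_json(
    list(group = as.list(truth$group),
         differential_region = planted$region[1],
         de_genes = genes[de_idx],
         lnc_classes = gm$truth),
    file.path(dd, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

# expand a 96-channel catalog back into MAF-lite SNV records
catalog_to_maf <- function(cat96, seed = 1) {
  set_generator_seed(seed)
  ch <- colnames(cat96)
  ref <- substr(ch, 3, 3); alt <- substr(ch, 5, 5)
  ctx <- paste0(substr(ch, 1, 1), ref, substr(ch, 7, 7))
  rows <- list()
  for (i in seq_len(nrow(cat96))) {
    idx <- rep(seq_len(96), cat96[i, ])
    if (!length(idx)) next
    rows[[i]] <- data.frame(
      sample = rownames(cat96)[i],
      gene = sprintf("GENE%03d", sample.int(500, length(idx), replace = TRUE)),
      chrom = paste0("chr", sample.int(22, length(idx), replace = TRUE)),
      pos = sample.int(1e8, length(idx), replace = TRUE),
      ref = ref[idx], alt = alt[idx], class = "Missense_Mutation",
      clonality = sample(c("clonal", "subclonal"), length(idx),
                         replace = TRUE, prob = c(0.7, 0.3)),
      context = ctx[idx], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @rdname io
#' @export
write_gmt <- function(x, path) {
  writeLines(vapply(names(x), function(nm)
    paste(c(nm, "na", x[[nm]]), collapse = "\t"), character(1)), path)
}

#' @rdname io
#' @export
read_gmt <- function(path) {
  ln <- strsplit(readLines(path), "\t")
  stats::setNames(lapply(ln, function(x) x[-(1:2)]),
                  vapply(ln, `[`, character(1), 1))
}

pipeline_inputs <- function(config) {
  dd <- data_dir(config)
  c(reference_genotypes = file.path(dd, "reference_genotypes.tsv"),
    reference_labels = file.path(dd, "reference_labels.tsv"),
    study_genotypes = file.path(dd, "study_genotypes.tsv"),
    clinical = file.path(dd, "clinical.tsv"),
    mutations = file.path(dd, "mutations.maf.tsv"),
    signatures = file.path(dd, "signatures.tsv"),
    segments = file.path(dd, "segments.seg"),
    regions = file.path(dd, "regions.bed"),
    counts = file.path(dd, "counts.tsv"),
    gene_sets = file.path(dd, "gene_sets.gmt"),
    gene_models = file.path(dd, "gene_models.gtf"),
    chromatin_states = file.path(dd, "chromatin_states.tsv"),
    ar_folds = file.path(dd, "ar_folds.tsv"),
    ar_controls = file.path(dd, "ar_controls.tsv"))
}

needed_inputs <- function(stage) {
  switch(stage,
         ancestry = c("reference_genotypes", "reference_labels", "study_genotypes"),
         propensity = "clinical",
         mutsig = c("mutations", "signatures", "clinical"),
         scna = c("segments", "regions", "clinical"),
         expression = c("counts", "clinical"),
         enrichment = "gene_sets",
         lncrna = c("gene_models", "chromatin_states", "ar_folds", "ar_controls"))
}

#' Validate a pipeline config before running
#'
#' Checks that every input file required by an enabled stage exists and that
#' parameters are in range; all problems are reported at once, before any
#' stage runs.
#'
#' @param config config list.
#' @return invisibly TRUE; stops with the full problem list otherwise.
#' @export
validate_config <- function(config) {
  probs <- character(0)
  inputs <- pipeline_inputs(config)
  for (st in config$stages) {
    need <- needed_inputs(st)
    miss <- need[!file.exists(inputs[need])]
    if (length(miss))
      probs <- c(probs, paste0("stage ", st, ": missing ",
                               paste(inputs[miss], collapse = ", ")))
  }
  if (!is.null(config$scna$n_perm) && config$scna$n_perm < 1)
    probs <- c(probs, "scna$n_perm must be >= 1")
  if (length(probs)) stop(paste(probs, collapse = "\n"))
  invisible(TRUE)
}

write_tidy <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline from an on-disk dataset bundle
#'
#' Executes the enabled stages in dependency order, writing tidy TSV
#' results into `<outdir>/results` and a JSON manifest (config snapshot,
#' package version, per-file MD5 checksums, per-stage status and timing)
#' into the output directory. A failing stage is recorded as `failed` and
#' does not abort stages that do not depend on it.
#'
#' @param config config list; validated before any stage runs.
#' @return the manifest list, invisibly; written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  rd <- res_dir(config)
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  inputs <- pipeline_inputs(config)
  seed <- config$seed
  outputs <- character(0)
  status <- list()
  state <- new.env()

  run_stage <- function(name, fun) {
    if (name != "propensity" && !name %in% config$stages) return()
    t0 <- Sys.time()
    res <- tryCatch({
      outs <- fun()
      list(status = "ok", outputs = outs)
    }, error = function(e) list(status = "failed", error = conditionMessage(e),
                                outputs = character(0)))
    res$seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    status[[name]] <<- res
    outputs <<- c(outputs, res$outputs)
  }

  run_stage("ancestry", function() {
    panel <- list(genotypes = read_genotypes_tsv(inputs["reference_genotypes"]),
                  labels = unname(read_labels_tsv(inputs["reference_labels"])))
    study <- read_genotypes_tsv(inputs["study_genotypes"])
    pc <- fit_reference_pca(panel, n_axes = config$ancestry$n_axes)
    proj <- project_samples(pc, study)
    refp <- pc$ref_scores
    cls <- classify_knn(proj, refp, pc$labels, k = config$ancestry$k)
    pf <- pop_freqs_from_panel(panel)
    adm <- estimate_admixture(study, pf)
    state$ancestry_call <- cls
    c(write_tidy(data.frame(sample = rownames(proj), proj),
                 file.path(rd, "projection.tsv")),
      write_tidy(cls, file.path(rd, "assignment.tsv")),
      write_tidy(data.frame(sample = rownames(adm), adm),
                 file.path(rd, "admixture.tsv")))
  })

  run_stage("propensity", function() {
    clin <- read_clinical_tsv(inputs["clinical"])
    ps <- fit_propensity(clin)
    state$clinical <- clin
    state$ps <- ps
    write_tidy(data.frame(sample = names(ps$score), propensity = unname(ps$score)),
               file.path(rd, "propensity.tsv"))
  })

  have_ps <- function() {
    if (is.null(state$ps)) stop("propensity stage did not run")
    list(clin = state$clinical, ps = state$ps)
  }

  run_stage("mutsig", function() {
    env <- have_ps()
    maf <- read_maf_lite(inputs["mutations"])
    sigs <- read_signatures_tsv(inputs["signatures"])
    cat96 <- build_catalog(maf, samples = env$clin$sample)
    fit <- refit_signatures(cat96, sigs)
    sa <- signature_contribution_association(fit, env$clin$group, env$ps)
    ba <- burden_association(rowSums(cat96), env$clin$group, env$ps)
    cl_tab <- table(factor(maf$clonality, levels = c("clonal", "subclonal")),
                    factor(env$clin$group[match(maf$sample, env$clin$sample)],
                           levels = 0:1))
    cf <- clonality_fisher(as.matrix(cl_tab))
    c(write_tidy(data.frame(sample = rownames(fit$weights_norm),
                            fit$weights_norm, cosine = fit$cosine),
                 file.path(rd, "exposures.tsv")),
      write_tidy(rbind(sa, ba, cf), file.path(rd, "mutsig_assoc.tsv")))
  })

  run_stage("scna", function() {
    env <- have_ps()
    segs <- read_seg(inputs["segments"])
    segs <- filter_hypersegmented(segs)
    regions <- read_regions_bed(inputs["regions"])
    wg <- compute_wgii(segs, deviation = config$scna$deviation)
    keep <- match(wg$sample, env$clin$sample)
    wa <- wgii_association(wg$wgii, env$clin$group[keep], env$ps$score[keep])
    ch <- region_change_matrix(segs, regions)
    am <- build_alteration_matrix(ch, regions,
                                  threshold = config$scna$threshold)
    tst <- scna_association_test(am, env$clin$group[keep], env$ps$score[keep],
                                 n_perm = config$scna$n_perm, seed = seed + 20)
    state$de_groups <- env$clin$group
    c(write_tidy(wg, file.path(rd, "wgii.tsv")),
      write_tidy(wa, file.path(rd, "wgii_assoc.tsv")),
      write_tidy(data.frame(sample = rownames(am$X), am$X),
                 file.path(rd, "alteration_matrix.tsv")),
      write_tidy(tst, file.path(rd, "scna_test.tsv")))
  })

  run_stage("expression", function() {
    env <- have_ps()
    counts <- read_counts_tsv(inputs["counts"])
    counts <- counts[, env$clin$sample, drop = FALSE]
    de_adj <- nb_wald_de(counts, env$clin$group, env$ps)
    de_un <- nb_wald_de(counts, env$clin$group)
    both <- intersect(fold_change_screen(de_adj, min_fold = 1),
                      fold_change_screen(de_un, min_fold = 1))
    state$de <- de_adj
    c(write_tidy(de_adj, file.path(rd, "de_adjusted.tsv")),
      write_tidy(de_un, file.path(rd, "de_unadjusted.tsv")),
      write_tidy(data.frame(gene = both), file.path(rd, "de_intersection.tsv")))
  })

  run_stage("enrichment", function() {
    if (is.null(state$de)) stop("expression stage did not run")
    de <- state$de
    ok <- !is.na(de$stat)
    sets <- read_gmt(inputs["gene_sets"])
    gs <- preranked_gsea_sets(de$gene[ok], de$stat[ok], sets,
                              n_perm = config$enrichment$n_perm,
                              seed = seed + 30)
    write_tidy(gs, file.path(rd, "gsea.tsv"))
  })

  run_stage("lncrna", function() {
    gm <- read_gene_models_gtf(inputs["gene_models"])
    lnc <- gm[gm$biotype == "lncRNA", , drop = FALSE]
    coding <- gm[gm$biotype == "protein_coding", , drop = FALSE]
    cls <- classify_lncrna(lnc, coding)
    states <- utils::read.delim(inputs["chromatin_states"])
    spans <- gene_spans(lnc)
    ann <- chromatin_state_annotation(spans, states)
    ctrl <- utils::read.delim(inputs["ar_controls"])
    cal <- calibrate_arg_cutoff(ctrl$fold, c(1.1, 1.2, 1.5, 2))
    folds <- utils::read.delim(inputs["ar_folds"])
    args <- classify_args(stats::setNames(folds$fold, folds$gene),
                          cutoff = cal$cutoff)
    c(write_tidy(cls$genes, file.path(rd, "lnc_classes.tsv")),
      write_tidy(data.frame(gene_id = rownames(ann$flags), ann$flags),
                 file.path(rd, "lnc_chromatin.tsv")),
      write_tidy(args, file.path(rd, "arg_calls.tsv")))
  })

  manifest <- list(
    config = config,
    package_version = as.character(utils::packageVersion("ancestrydisp")),
    seed = seed,
    created = format(Sys.time(), tz = "UTC"),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    stages = status,
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Per-population allele frequencies from a labeled panel
#'
#' @param panel list with `genotypes` and `labels`.
#' @return populations x SNPs frequency matrix (clipped away from 0/1).
#' @export
pop_freqs_from_panel <- function(panel) {
  pops <- sort(unique(panel$labels))
  f <- t(vapply(pops, function(p)
    colMeans(panel$genotypes[panel$labels == p, , drop = FALSE], na.rm = TRUE) / 2,
    numeric(ncol(panel$genotypes))))
  pmin(pmax(f, 1e-6), 1 - 1e-6)
}
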