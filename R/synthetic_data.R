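# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth, so each downstream stage is testable
# without external downloads. All generators are pure functions of
# (parameters, seed).

#' Define a multi-population allele-frequency model
#'
#' Ancestral allele frequencies plus a per-population divergence parameter
#' (Fst) under the Balding-Nichols model: population frequencies are drawn
#' from `Beta(p(1-F)/F, (1-p)(1-F)/F)` around each ancestral frequency `p`.
#'
#' @param n_pops number of populations (>= 2).
#' @param n_snps number of SNPs.
#' @param fst divergence parameter in (0,1); scalar or one value per
#'   population.
#' @param ancestral_freqs optional vector of per-SNP ancestral frequencies in
#'   (0,1); drawn Uniform(0.05, 0.95) under `seed` when omitted.
#' @param seed RNG seed used when `ancestral_freqs` is omitted.
#' @return object of class `population_model`.
#' @export
population_model <- function(n_pops, n_snps, fst, ancestral_freqs = NULL, seed = 1) {
  if (n_pops < 2) stop("n_pops must be >= 2")
  if (n_snps < 1) stop("n_snps must be >= 1")
  fst <- rep_len(fst, n_pops)
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0, 1)")
  if (is.null(ancestral_freqs)) {
    set_generator_seed(seed)
    ancestral_freqs <- stats::runif(n_snps, 0.05, 0.95)
  }
  if (length(ancestral_freqs) != n_snps) stop("ancestral_freqs length mismatch")
  if (any(ancestral_freqs <= 0 | ancestral_freqs >= 1))
    stop("ancestral frequencies must lie in (0, 1)")
  structure(list(n_pops = n_pops, n_snps = n_snps, fst = fst,
                 ancestral_freqs = ancestral_freqs),
            class = "population_model")
}

# all generators route their randomness through one validated seed call
set_generator_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single number")
  set.seed(as.integer(seed))
}

#' Simulate a labeled reference genotype panel
#'
#' Population-specific allele frequencies are drawn from the Balding-Nichols
#' beta around the model's ancestral frequencies; genotypes are
#' `Binomial(2, freq)` allele dosages.
#'
#' @param model a [population_model()].
#' @param n_per_pop samples per population (>= 2).
#' @param seed RNG seed.
#' @return object of class `reference_panel`: list with `genotypes`
#'   (samples x SNPs integer matrix, dimnames set), `labels` (population per
#'   sample) and `pop_freqs` (populations x SNPs).
#' @export
simulate_reference_panel <- function(model, n_per_pop, seed = 1) {
  stopifnot(inherits(model, "population_model"))
  if (n_per_pop < 2) stop("n_per_pop must be >= 2")
  set_generator_seed(seed)
  K <- model$n_pops; L <- model$n_snps
  pop_freqs <- matrix(NA_real_, K, L)
  for (k in seq_len(K)) {
    f <- model$fst[k]
    a <- model$ancestral_freqs * (1 - f) / f
    b <- (1 - model$ancestral_freqs) * (1 - f) / f
    pop_freqs[k, ] <- stats::rbeta(L, a, b)
  }
  # keep frequencies away from fixation so downstream likelihoods are proper
  pop_freqs <- pmin(pmax(pop_freqs, 1e-6), 1 - 1e-6)
  n <- K * n_per_pop
  labels <- rep(paste0("pop", seq_len(K)), each = n_per_pop)
  geno <- matrix(NA_integer_, n, L)
  for (k in seq_len(K)) {
    rows <- which(labels == paste0("pop", k))
    geno[rows, ] <- stats::rbinom(length(rows) * L, 2,
                                  rep(pop_freqs[k, ], each = length(rows)))
  }
  rownames(geno) <- sprintf("ref%04d", seq_len(n))
  colnames(geno) <- sprintf("snp%05d", seq_len(L))
  rownames(pop_freqs) <- paste0("pop", seq_len(K))
  colnames(pop_freqs) <- colnames(geno)
  structure(list(genotypes = geno, labels = labels, pop_freqs = pop_freqs,
                 model = model),
            class = "reference_panel")
}

#' Simulate an admixed study cohort from a reference panel
#'
#' Each of a sample's two allele copies at each SNP first draws a source
#' population from the sample's admixture fractions, then draws the allele
#' from that population's frequency.
#'
#' @param panel a `reference_panel`.
#' @param fractions matrix (samples x populations) of admixture fractions;
#'   every row must sum to 1.
#' @param seed RNG seed.
#' @return list with `genotypes` (samples x SNPs) and `truth` (the fractions
#'   matrix, row/col named).
#' @export
simulate_admixed_cohort <- function(panel, fractions, seed = 1) {
  stopifnot(inherits(panel, "reference_panel"))
  fractions <- as.matrix(fractions)
  K <- nrow(panel$pop_freqs)
  if (nrow(fractions) == 0) {
    g <- matrix(integer(0), 0, ncol(panel$genotypes),
                dimnames = list(NULL, colnames(panel$genotypes)))
    return(list(genotypes = g, truth = fractions))
  }
  if (ncol(fractions) != K) stop("fractions must have one column per population")
  if (any(fractions < 0) || any(abs(rowSums(fractions) - 1) > 1e-9))
    stop("each fractions row must be a point on the simplex")
  set_generator_seed(seed)
  n <- nrow(fractions); L <- ncol(panel$genotypes)
  geno <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    for (copy in 1:2) {
      src <- sample.int(K, L, replace = TRUE, prob = fractions[i, ])
      f <- panel$pop_freqs[cbind(src, seq_len(L))]
      geno[i, ] <- geno[i, ] + stats::rbinom(L, 1, f)
    }
  }
  rownames(geno) <- sprintf("study%04d", seq_len(n))
  colnames(geno) <- colnames(panel$genotypes)
  rownames(fractions) <- rownames(geno)
  colnames(fractions) <- rownames(panel$pop_freqs)
  list(genotypes = geno, truth = fractions)
}

#' Simulate 96-channel mutation catalogs as signature mixtures
#'
#' Per-sample counts are multinomial draws from the mixture spectrum
#' `signatures %*% weights`.
#'
#' @param signatures 96 x S matrix; each column sums to 1.
#' @param weights samples x S matrix of mixture weights; rows on the simplex.
#' @param n_mutations mutations per sample (scalar or per-sample).
#' @param seed RNG seed.
#' @return samples x 96 integer matrix with channel column names.
#' @export
simulate_mutation_catalogs <- function(signatures, weights, n_mutations, seed = 1) {
  signatures <- as.matrix(signatures)
  if (is.null(dim(weights))) weights <- matrix(weights, 1)
  if (ncol(weights) != ncol(signatures))
    stop("weight/signature dimension mismatch")
  if (nrow(signatures) != 96) stop("signatures must have 96 rows")
  if (any(abs(colSums(signatures) - 1) > 1e-9)) stop("signature columns must sum to 1")
  if (any(weights < 0) || any(abs(rowSums(weights) - 1) > 1e-9))
    stop("weight rows must lie on the simplex")
  n <- nrow(weights)
  n_mutations <- rep_len(n_mutations, n)
  if (any(n_mutations < 0)) stop("n_mutations must be non-negative")
  set_generator_seed(seed)
  out <- matrix(0L, n, 96, dimnames = list(sprintf("tumor%04d", seq_len(n)),
                                           mutation_channels()))
  for (i in seq_len(n)) {
    spectrum <- drop(signatures %*% weights[i, ])
    if (n_mutations[i] > 0)
      out[i, ] <- as.integer(stats::rmultinom(1, n_mutations[i], spectrum))
  }
  out
}

#' Simulate segmented copy-number profiles with planted focal events
#'
#' Baseline log2 ratio 0 plus per-segment Gaussian noise; planted focal
#' regions add `+effect` (amplification) or `-effect` (deletion) in carrier
#' samples, with carrier status Bernoulli at a group-specific probability.
#' Segments tile each chromosome without gaps or overlaps.
#'
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param planted data.frame with columns `region`, `chrom`, `start`, `end`,
#'   `type` ("amplification"/"deletion"), `effect` (absolute log2 shift,
#'   >= 0.5 recommended) and one `prob_<group>` column per group label.
#' @param groups character vector of group labels, one per sample.
#' @param noise_sd per-segment Gaussian noise SD.
#' @param n_extra_breaks random extra breakpoints per chromosome per sample.
#' @param seed RNG seed.
#' @return list with `segments` (data.frame: sample, chrom, start, end,
#'   num_mark, value), `carriers` (samples x regions 0/1 matrix) and
#'   `planted`.
#' @export
simulate_segment_tables <- function(genome, planted, groups, noise_sd = 0.05,
                                    n_extra_breaks = 3, seed = 1) {
  if (is.null(names(genome))) stop("genome must be a named vector of lengths")
  if (nrow(planted) > 0) {
    if (any(planted$start < 1) ||
        any(planted$end > genome[planted$chrom]))
      stop("planted regions must lie within chromosome bounds")
    for (ch in unique(planted$chrom)) {
      p <- planted[planted$chrom == ch, , drop = FALSE]
      p <- p[order(p$start), , drop = FALSE]
      if (nrow(p) > 1 && any(p$start[-1] <= p$end[-nrow(p)]))
        stop("planted regions overlap on ", ch)
    }
  }
  set_generator_seed(seed)
  n <- length(groups)
  samples <- sprintf("tumor%04d", seq_len(n))
  prob_cols <- paste0("prob_", groups)
  carriers <- matrix(0L, n, nrow(planted),
                     dimnames = list(samples, planted$region))
  if (nrow(planted) > 0) {
    for (j in seq_len(nrow(planted))) {
      pr <- as.numeric(planted[j, prob_cols])
      carriers[, j] <- stats::rbinom(n, 1, pr)
    }
  }
  res <- vector("list", n)
  for (i in seq_len(n)) {
    segs <- list()
    for (ch in names(genome)) {
      len <- genome[[ch]]
      pl <- planted[planted$chrom == ch, , drop = FALSE]
      brk <- sort(unique(c(0, pl$start - 1, pl$end,
                           if (n_extra_breaks > 0)
                             sample.int(len - 1, min(n_extra_breaks, len - 1)),
                           len)))
      brk <- brk[brk >= 0 & brk <= len]
      st <- brk[-length(brk)] + 1
      en <- brk[-1]
      val <- stats::rnorm(length(st), 0, noise_sd)
      if (nrow(pl) > 0) {
        for (j in seq_len(nrow(pl))) {
          jj <- which(planted$region == pl$region[j])
          if (carriers[i, jj] == 1) {
            hit <- st >= pl$start[j] & en <= pl$end[j]
            sgn <- if (pl$type[j] == "deletion") -1 else 1
            val[hit] <- val[hit] + sgn * pl$effect[j]
          }
        }
      }
      segs[[ch]] <- data.frame(sample = samples[i], chrom = ch, start = st,
                               end = en, num_mark = pmax(1L, as.integer((en - st + 1) / 1e4)),
                               value = val, stringsAsFactors = FALSE)
    }
    res[[i]] <- do.call(rbind, segs)
  }
  segments <- do.call(rbind, res)
  rownames(segments) <- NULL
  list(segments = segments, carriers = carriers, planted = planted)
}

#' Simulate a negative-binomial count matrix with planted DE
#'
#' Counts are `NB(mean = baseline * size_factor * 2^(lfc * group), size =
#' 1/dispersion)`. Baselines are log-normal; size factors log-normal around 1
#' (or supplied). Optional per-gene age coefficients let age act on
#' expression, which combined with a group-shifted age distribution produces
#' confounding for the adjustment machinery to remove.
#'
#' @param n_genes number of genes.
#' @param design data.frame with columns `sample`, `group` (0/1), `age`,
#'   `grade`.
#' @param lfc per-gene true log2 fold change (group 1 vs 0); recycled.
#' @param dispersion NB dispersion (1/size), > 0.
#' @param size_factors optional per-sample factors; log-normal when omitted.
#' @param age_beta optional per-gene log2-scale age coefficients (default 0).
#' @param baseline_log_mean,baseline_log_sd log-normal baseline parameters.
#' @param seed RNG seed.
#' @return list with `counts` (genes x samples integer matrix), `truth`
#'   (data.frame gene, lfc), `size_factors`.
#' @export
simulate_counts <- function(n_genes, design, lfc = 0, dispersion = 0.05,
                            size_factors = NULL, age_beta = 0,
                            baseline_log_mean = log(500), baseline_log_sd = 1,
                            seed = 1) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  stopifnot(all(c("sample", "group") %in% names(design)))
  set_generator_seed(seed)
  n <- nrow(design)
  lfc <- rep_len(lfc, n_genes)
  age_beta <- rep_len(age_beta, n_genes)
  base <- exp(stats::rnorm(n_genes, baseline_log_mean, baseline_log_sd))
  if (is.null(size_factors))
    size_factors <- exp(stats::rnorm(n, 0, 0.2))
  age_c <- if (!is.null(design$age)) design$age - mean(design$age) else rep(0, n)
  mu <- outer(base, size_factors) *
    2^(outer(lfc, design$group) + outer(age_beta, age_c))
  counts <- matrix(stats::rnbinom(n_genes * n, mu = mu, size = 1 / dispersion),
                   n_genes, n)
  rownames(counts) <- sprintf("gene%05d", seq_len(n_genes))
  colnames(counts) <- as.character(design$sample)
  list(counts = counts,
       truth = data.frame(gene = rownames(counts), lfc = lfc),
       size_factors = stats::setNames(size_factors, colnames(counts)))
}

#' Simulate a clinical design table with optional confounding
#'
#' Age is Gaussian and grade ordinal-categorical; when `age_shift` or
#' `grade_shift` are nonzero the group-1 distributions are shifted, creating
#' the group-covariate dependence that the propensity adjustment must remove.
#'
#' @param n0,n1 samples in group 0 / group 1.
#' @param age_shift additive shift of group-1 mean age (years).
#' @param grade_shift probability mass moved toward higher grades in group 1.
#' @param seed RNG seed.
#' @return data.frame `sample, group, age, grade` (grade an ordered factor).
#' @export
simulate_design <- function(n0, n1, age_shift = 0, grade_shift = 0, seed = 1) {
  if (n0 + n1 <= 0) stop("need at least one sample")
  set_generator_seed(seed)
  n <- n0 + n1
  group <- c(rep(0, n0), rep(1, n1))
  age <- stats::rnorm(n, 61 + age_shift * group, 7)
  base_p <- c(0.09, 0.30, 0.20, 0.41)  # grade mix of a typical tumor cohort
  lv <- c("<=6", "7(3+4)", "7(4+3)", ">=8")
  grade <- character(n)
  for (i in seq_len(n)) {
    p <- base_p
    if (group[i] == 1 && grade_shift > 0) {
      p <- p + grade_shift * c(-0.05, -0.10, 0.05, 0.10) / 0.15
      p <- pmax(p, 0.01); p <- p / sum(p)
    }
    grade[i] <- sample(lv, 1, prob = p)
  }
  data.frame(sample = sprintf("tumor%04d", seq_len(n)), group = group,
             age = age, grade = factor(grade, levels = lv, ordered = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate coding and lncRNA gene models with known locus classes
#'
#' Coding genes are multi-exon and widely spaced on one chromosome; lncRNAs
#' are constructed to be exonic-overlap same strand, intron-contained same
#' strand, antisense-overlap, or intergenic (placed > 10 kb from any coding
#' gene) by construction.
#'
#' @param n_coding number of coding genes.
#' @param n_lnc_per_class lncRNAs per locus class.
#' @param seed RNG seed.
#' @return list with `models` (exon-level data.frame: gene_id, transcript_id,
#'   chrom, start, end, strand, biotype) and `truth` (data.frame gene_id,
#'   class).
#' @export
simulate_gene_models <- function(n_coding, n_lnc_per_class, seed = 1) {
  if (n_coding < 0 || n_lnc_per_class < 0) stop("counts must be >= 0")
  set_generator_seed(seed)
  spacing <- 2e5
  exn <- function(gid, tid, chrom, starts, ends, strand, biotype) {
    data.frame(gene_id = gid, transcript_id = tid, chrom = chrom,
               start = starts, end = ends, strand = strand,
               biotype = biotype, stringsAsFactors = FALSE)
  }
  rows <- list()
  coding_spans <- NULL
  for (i in seq_len(n_coding)) {
    gs <- 50000 + (i - 1) * spacing
    strand <- if (i %% 2 == 0) "-" else "+"
    starts <- gs + c(0, 9000, 18000)
    ends <- starts + 999
    gid <- sprintf("CODING%03d", i)
    rows[[length(rows) + 1]] <- exn(gid, paste0(gid, ".t1"), "chrS", starts,
                                    ends, strand, "protein_coding")
    coding_spans <- rbind(coding_spans,
                          data.frame(gene_id = gid, start = gs, end = gs + 18999,
                                     strand = strand))
  }
  truth <- NULL
  n_need <- if (n_lnc_per_class > 0) 3 * n_lnc_per_class else 0
  if (n_need > n_coding && n_lnc_per_class > 0)
    stop("need at least 3 * n_lnc_per_class coding genes as anchors")
  used <- 0
  prefix <- c(exonic = "EX", intronic = "IN", antisense = "AS",
              intergenic = "IG")
  add_lnc <- function(idx, cls, starts, ends, strand) {
    gid <- sprintf("LNC_%s%03d", prefix[[cls]], idx)
    rows[[length(rows) + 1]] <<- exn(gid, paste0(gid, ".t1"), "chrS", starts,
                                     ends, strand, "lncRNA")
    truth <<- rbind(truth, data.frame(gene_id = gid, class = cls,
                                      stringsAsFactors = FALSE))
  }
  for (j in seq_len(n_lnc_per_class)) {
    # exonic: first exon overlaps the anchor's first coding exon, same strand
    a <- coding_spans[used + 1, ]; used <- used + 1
    add_lnc(j, "exonic", c(a$start + 500, a$start + 3000),
            c(a$start + 1499, a$start + 3799), a$strand)
    # intronic: wholly inside intron 1, same strand
    a <- coding_spans[used + 1, ]; used <- used + 1
    add_lnc(j, "intronic", a$start + c(2000, 5000), a$start + c(2599, 5599),
            a$strand)
    # antisense: inside the anchor span, opposite strand
    a <- coding_spans[used + 1, ]; used <- used + 1
    add_lnc(j, "antisense", a$start + c(2000, 5000), a$start + c(2599, 5599),
            setdiff(c("+", "-"), a$strand))
  }
  # intergenic: beyond the last coding gene, > 10 kb from any coding span
  far0 <- if (n_coding > 0) max(coding_spans$end) else 0
  for (j in seq_len(n_lnc_per_class)) {
    gs <- far0 + 50000 + (j - 1) * 40000
    add_lnc(j, "intergenic", gs + c(0, 2000), gs + c(999, 2999),
            if (j %% 2 == 0) "-" else "+")
  }
  models <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), transcript_id = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), biotype = character())
  rownames(models) <- NULL
  if (is.null(truth))
    truth <- data.frame(gene_id = character(), class = character())
  list(models = models, truth = truth)
}
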