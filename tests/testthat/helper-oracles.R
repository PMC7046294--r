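# Independent oracles used across the suite. Each reimplements the target
# quantity by direct definition (enumeration, exhaustive search, explicit
# loops), never by calling the code path it checks.

# BH step-up by definition: q_i = min over {j: p_j >= p_i} of m * p_j / rank_j
bh_oracle <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(m * p[js] / vapply(js, function(j) sum(p <= p[j]), numeric(1))))
  }, numeric(1))
}

# exact NNLS by support enumeration: the optimum is the feasible
# (non-negative) least-squares solution of some support with minimal residual
nnls_oracle <- function(A, y) {
  S <- ncol(A)
  best <- numeric(S)
  bestr <- sum(y^2)
  for (k in seq_len(S)) {
    for (sub in utils::combn(S, k, simplify = FALSE)) {
      cf <- tryCatch(qr.coef(qr(A[, sub, drop = FALSE]), y),
                     error = function(e) NULL)
      if (is.null(cf) || anyNA(cf) || any(cf < -1e-12)) next
      r <- sum((y - A[, sub, drop = FALSE] %*% pmax(cf, 0))^2)
      if (r < bestr - 1e-15) {
        bestr <- r
        best <- numeric(S); best[sub] <- pmax(cf, 0)
      }
    }
  }
  best
}

# two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins
fisher_p_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- sum(tab)
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# running-sum enrichment score by explicit loop
es_oracle <- function(ids, metric, set, weight) {
  o <- order(-metric, ids)
  ids <- ids[o]; metric <- metric[o]
  mem <- ids %in% set
  N <- length(ids)
  nr <- sum(abs(metric[mem])^weight)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- if (mem[i]) {
      if (nr == 0) run + 1 / sum(mem) else run + abs(metric[i])^weight / nr
    } else run - 1 / (N - sum(mem))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# exhaustive enumeration of the fixed-margin class of a small binary matrix
enumerate_margin_class <- function(rs, cs) {
  n <- length(rs); m <- length(cs)
  out <- list()
  mat <- matrix(0L, n, m)
  rec <- function(i, cs_left) {
    if (i > n) {
      if (all(cs_left == 0)) out[[length(out) + 1]] <<- mat
      return()
    }
    if (any(cs_left > n - i + 1)) return()
    mat[i, ] <<- 0L
    if (rs[i] == 0) { rec(i + 1, cs_left); return() }
    cols <- which(cs_left > 0)
    if (length(cols) < rs[i]) return()
    for (sel in utils::combn(cols, rs[i], simplify = FALSE)) {
      mat[i, ] <<- 0L
      mat[i, sel] <<- 1L
      rec(i + 1, cs_left - tabulate(sel, m))
    }
    mat[i, ] <<- 0L
  }
  rec(1, cs)
  out
}

mat_key <- function(m) paste(m, collapse = "")

# small labeled panel + unadmixed/admixed targets shared by ancestry tests
make_panel_fixture <- function(n_snps = 1500, n_per_pop = 60, fst = 0.1,
                               seed = 71) {
  pm <- population_model(3, n_snps, fst, seed = seed)
  panel <- simulate_reference_panel(pm, n_per_pop, seed = seed + 1)
  list(model = pm, panel = panel, freqs = pop_freqs_from_panel(panel))
}
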