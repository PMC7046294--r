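# Shared covariate-adjusted statistics: propensity score, adjusted
# logistic/linear models, rank normalization, Fisher's exact test, BH FDR.
# Every association is reported as a tidy one-row data.frame so results from
# different platforms can be stacked and written as a single TSV.

#' Construct a tidy association-result row
#'
#' @param unit identifier of the tested unit (gene, signature, region, ...).
#' @param effect point estimate (odds ratio or coefficient).
#' @param ci_low,ci_high 95% confidence limits.
#' @param p raw p-value.
#' @param method short method label.
#' @param flags semicolon-separated flags ("" when clean).
#' @return one-row `data.frame` with columns
#'   `unit, effect, ci_low, ci_high, p, q, method, flags` (`q` is `NA` until
#'   [bh_fdr()] is applied across a family of results).
#' @keywords internal
association_row <- function(unit, effect, ci_low, ci_high, p, method, flags = "") {
  data.frame(
    unit = as.character(unit), effect = effect, ci_low = ci_low,
    ci_high = ci_high, p = p, q = NA_real_, method = method,
    flags = flags, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment `q_i = min_{j: p_j >= p_i} m * p_j / rank_j`, capped at
#' 1 and order-preserving. Thin validating wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed; excluded
#'   from the denominator and returned as `NA`).
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Inverse-normal (Blom) rank transform
#'
#' Ranks with ties averaged, then `qnorm((r - 3/8) / (n + 1/4))`.
#'
#' @param x numeric vector without NA.
#' @return numeric vector of normal scores.
#' @export
rank_normalize <- function(x) {
  if (anyNA(x)) stop("x must not contain NA")
  n <- length(x)
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Fit a propensity-score model for group membership
#'
#' Logistic regression of the binary group indicator on age (continuous) and
#' tumor grade (ordinal category coded by its integer rank). The fitted
#' probabilities are the propensity scores used as an adjustment covariate in
#' all downstream association models. Perfect separation triggers a
#' ridge-penalized refit, flagged in the result.
#'
#' @param clinical data.frame with columns `sample` (id), `group` (0/1,
#'   1 = group of interest), `age` (years) and `grade` (ordered factor, or
#'   values coercible to an ordered factor by sorted unique level).
#' @return object of class `propensity_model`: list with `coef`, `score`
#'   (named per-sample propensity in (0,1)), `flags`.
#' @export
fit_propensity <- function(clinical) {
  stopifnot(is.data.frame(clinical),
            all(c("sample", "group", "age", "grade") %in% names(clinical)))
  g <- clinical$group
  if (!all(g %in% c(0, 1))) stop("group must be coded 0/1")
  if (length(unique(g)) < 2) stop("both groups must be present")
  grade <- clinical$grade
  if (!is.ordered(grade)) grade <- factor(grade, levels = sort(unique(grade)), ordered = TRUE)
  x_grade <- as.integer(grade)
  dat <- data.frame(g = g, age = clinical$age, grade_num = x_grade)
  fit <- suppressWarnings(stats::glm(g ~ age + grade_num, data = dat, family = stats::binomial()))
  flags <- ""
  ps <- stats::fitted(fit)
  if (!fit$converged || any(ps < 1e-8) || any(ps > 1 - 1e-8)) {
    # separation: fall back to a light ridge penalty on the coefficients
    X <- cbind(1, dat$age, dat$grade_num)
    beta <- ridge_logistic(X, g, lambda = 1e-2)
    ps <- stats::plogis(drop(X %*% beta))
    flags <- "ridge_fallback"
    cf <- drop(beta)
    names(cf) <- c("(Intercept)", "age", "grade_num")
  } else {
    cf <- stats::coef(fit)
  }
  ps <- pmin(pmax(ps, 1e-8), 1 - 1e-8)
  names(ps) <- as.character(clinical$sample)
  structure(list(coef = cf, score = ps, flags = flags), class = "propensity_model")
}

# L2-penalized logistic IRLS (intercept unpenalized); used as the separation
# fallback for fit_propensity and adjusted_logistic.
ridge_logistic <- function(X, y, lambda = 1e-2, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w) + pen
    gvec <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, gvec)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Propensity-adjusted logistic association
#'
#' Wald test of a binary or continuous exposure on a binary outcome, with the
#' propensity score as a covariate.
#'
#' @param outcome binary 0/1 vector (the dependent variable).
#' @param exposure numeric or binary vector (the term being tested).
#' @param propensity per-sample propensity scores (or a `propensity_model`).
#' @param unit label for the result row.
#' @return one-row association data.frame; `effect` is the odds ratio for
#'   the exposure term.
#' @export
adjusted_logistic <- function(outcome, exposure, propensity, unit = "exposure") {
  if (inherits(propensity, "propensity_model")) propensity <- propensity$score
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (sum(outcome) == 0 || sum(outcome) == length(outcome))
    stop("outcome needs at least one event and one non-event")
  dat <- data.frame(y = outcome, x = exposure, ps = propensity)
  fit <- suppressWarnings(stats::glm(y ~ x + ps, data = dat, family = stats::binomial()))
  flags <- ""
  sm <- summary(fit)$coefficients
  sep <- !fit$converged || !"x" %in% rownames(sm) ||
    any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  if (sep) {
    X <- cbind(1, dat$x, dat$ps)
    beta <- ridge_logistic(X, dat$y, lambda = 1e-2)
    mu <- stats::plogis(drop(X %*% beta))
    H <- crossprod(X, X * (mu * (1 - mu))) + diag(c(0, 1e-2, 1e-2))
    se <- sqrt(diag(solve(H)))
    b <- beta[2]; s <- se[2]
    flags <- "ridge_fallback"
  } else {
    b <- sm["x", "Estimate"]; s <- sm["x", "Std. Error"]
  }
  z <- b / s
  association_row(unit, exp(b), exp(b - 1.96 * s), exp(b + 1.96 * s),
                  2 * stats::pnorm(-abs(z)), "adjusted_logistic", flags)
}

#' Propensity-adjusted linear model on rank-normalized outcome
#'
#' The outcome is replaced by its inverse-normal transformed ranks (Blom 3/8
#' offset, ties averaged) and regressed on the exposure plus the propensity
#' score. The test statistic is therefore invariant to any strictly monotone
#' transform of the outcome.
#'
#' @inheritParams adjusted_logistic
#' @param outcome numeric vector (burden, score, ...), length >= 4.
#' @return one-row association data.frame; `effect` is the regression
#'   coefficient of the exposure on the normal-score scale.
#' @export
adjusted_linear_ranknorm <- function(outcome, exposure, propensity, unit = "exposure") {
  if (inherits(propensity, "propensity_model")) propensity <- propensity$score
  if (length(outcome) < 4) stop("need n >= 4")
  if (length(unique(outcome)) == 1) {
    return(association_row(unit, NA_real_, NA_real_, NA_real_, NA_real_,
                           "adjusted_linear_ranknorm", "constant_outcome"))
  }
  y <- rank_normalize(outcome)
  fit <- stats::lm(y ~ x + ps, data = data.frame(y = y, x = exposure, ps = propensity))
  sm <- summary(fit)$coefficients
  b <- sm["x", "Estimate"]; s <- sm["x", "Std. Error"]; p <- sm["x", "Pr(>|t|)"]
  association_row(unit, b, b - 1.96 * s, b + 1.96 * s, p, "adjusted_linear_ranknorm")
}

#' Unadjusted linear association (shared machinery)
#'
#' Ordinary least squares of a continuous outcome on exposure plus the
#' propensity covariate, without rank normalization. Used for wGII and
#' signature-weight comparisons.
#'
#' @inheritParams adjusted_linear_ranknorm
#' @export
adjusted_linear <- function(outcome, exposure, propensity, unit = "exposure") {
  if (inherits(propensity, "propensity_model")) propensity <- propensity$score
  if (length(outcome) < 4) stop("need n >= 4")
  if (length(unique(outcome)) == 1) {
    return(association_row(unit, NA_real_, NA_real_, NA_real_, NA_real_,
                           "adjusted_linear", "constant_outcome"))
  }
  fit <- stats::lm(y ~ x + ps, data = data.frame(y = outcome, x = exposure, ps = propensity))
  sm <- summary(fit)$coefficients
  b <- sm["x", "Estimate"]; s <- sm["x", "Std. Error"]; p <- sm["x", "Pr(>|t|)"]
  association_row(unit, b, b - 1.96 * s, b + 1.96 * s, p, "adjusted_linear")
}

#' Fisher's exact test on a 2x2 table with sample odds ratio
#'
#' Exact two-sided p-value (sum of hypergeometric table probabilities no
#' larger than the observed one, via [stats::fisher.test()]). The reported
#' effect is the sample odds ratio `(a*d)/(b*c)`; when any cell is zero the
#' Haldane 0.5 continuity correction is applied to the odds ratio and its
#' confidence interval only (the exact p is unaffected) and the result is
#' flagged.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param unit label for the result row.
#' @return one-row association data.frame; `effect` is the odds ratio.
#' @export
#' @examples
#' fisher_2x2(matrix(c(8, 1, 2, 5), 2))
fisher_2x2 <- function(tab, unit = "table") {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("tab must be 2x2")
  if (any(tab < 0)) stop("cell counts must be non-negative")
  if (any(tab != round(tab))) stop("cell counts must be integers")
  p <- stats::fisher.test(tab)$p.value
  flags <- ""
  ct <- tab
  if (any(tab == 0)) {
    ct <- tab + 0.5
    flags <- "haldane"
  }
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  se <- sqrt(sum(1 / ct))
  association_row(unit, or, exp(log(or) - 1.96 * se), exp(log(or) + 1.96 * se),
                  p, "fisher_exact", flags)
}
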