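#' Two-sample Student t-test with Cohen's d
#'
#' Pooled-variance two-tailed t-test (delegating to [stats::t.test()]) plus
#' Cohen's d computed as the mean difference over the pooled SD.
#'
#' @param a,b Numeric score vectors (NAs dropped; pairwise deletion is the
#'   caller's responsibility).
#' @return One-row tibble: `t`, `df`, `p`, `d`, `n1`, `n2`, `method`.
#' @examples
#' student_t(c(0, 1, 2), c(1, 2, 3))
#' @export
student_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both groups have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, d = cohens_d(a, b),
    n1 = length(a), n2 = length(b), method = "student"
  )
}

#' Two-sample Welch t-test with Cohen's d
#'
#' Unequal-variance t-test with Welch-Satterthwaite fractional degrees of
#' freedom; d still uses the pooled SD so effect sizes stay comparable across
#' the Student and Welch variants.
#'
#' @inheritParams student_t
#' @return One-row tibble as [student_t()], `method = "welch"`.
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both groups have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, d = cohens_d(a, b),
    n1 = length(a), n2 = length(b), method = "welch"
  )
}

cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' One-way Welch ANOVA with classical eta-squared
#'
#' Heteroscedastic F-test over two or more groups (delegating to
#' [stats::oneway.test()] with `var.equal = FALSE`, i.e. fractional
#' denominator degrees of freedom), reported together with the classical
#' between/total sum-of-squares eta-squared.
#'
#' @param groups A list of numeric vectors, one per group.
#' @return One-row tibble: `F`, `df1`, `df2`, `p`, `eta2`, `n`.
#' @export
welch_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  if (any(vapply(groups, stats::var, 1) == 0)) {
    stop("a group has zero variance: Welch weights are undefined", call. = FALSE)
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ht <- stats::oneway.test(y ~ g, var.equal = FALSE)
  ss_total <- sum((y - mean(y))^2)
  ss_between <- sum(vapply(groups, function(v) length(v) * (mean(v) - mean(y))^2, 1))
  tibble::tibble(
    F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
    df2 = unname(ht$parameter[2]), p = ht$p.value,
    eta2 = ss_between / ss_total, n = length(y)
  )
}

#' Bonferroni-Holm adjusted p-values
#'
#' Step-down Holm adjustment (monotone-enforced, capped at 1), via
#' [stats::p.adjust()].
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values, elementwise >= `p`.
#' @examples
#' holm(c(0.01, 0.04, 0.03))
#' @export
holm <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}

#' Spearman correlation with pairwise deletion
#'
#' Midrank-tie Spearman rho; the two-sided p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return One-row tibble: `rho`, `p`, `n_used`, `partial` (FALSE),
#'   `covariate` (NA). Fewer than 3 complete pairs gives an NA row.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n_used = n,
                          partial = FALSE, covariate = NA_character_))
  }
  rho <- stats::cor(rank(x[ok]), rank(y[ok]))
  tibble::tibble(rho = rho, p = rho_pvalue(rho, n, df = n - 2),
                 n_used = n, partial = FALSE, covariate = NA_character_)
}

rho_pvalue <- function(rho, n, df) {
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt(df / (1 - rho^2))
  2 * stats::pt(-abs(tval), df)
}

#' Age-partialled (or other covariate) Spearman correlation
#'
#' Rank-transforms all three variables and computes the first-order partial
#' Pearson correlation on the ranks,
#' \eqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}},
#' with the p-value from the t approximation on n - 3 degrees of freedom. A
#' degenerate (constant) covariate falls back to the plain Spearman
#' correlation, flagged by `covariate = NA`.
#'
#' @param x,y Numeric vectors.
#' @param covariate Numeric covariate (e.g. age).
#' @param covariate_name Label stored in the result.
#' @return One-row tibble as [spearman()], with `partial = TRUE`.
#' @export
partial_spearman <- function(x, y, covariate, covariate_name = "age") {
  ok <- is.finite(x) & is.finite(y) & is.finite(covariate)
  n <- sum(ok)
  if (n < 4L) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n_used = n,
                          partial = TRUE, covariate = covariate_name))
  }
  if (stats::sd(covariate[ok]) == 0) {
    res <- spearman(x, y)
    res$partial <- TRUE
    return(res)
  }
  rx <- rank(x[ok]); ry <- rank(y[ok]); rz <- rank(covariate[ok])
  rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz); ryz <- stats::cor(ry, rz)
  pr <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  tibble::tibble(rho = pr, p = rho_pvalue(pr, n, df = n - 3), n_used = n,
                 partial = TRUE, covariate = covariate_name)
}

#' Cohen's effect-size magnitude labels
#'
#' Standard interpretation bands: for d, small/medium/large at 0.2/0.5/0.8;
#' for rho, 0.1/0.3/0.5.
#'
#' @param x Effect sizes.
#' @param type `"d"` or `"rho"`.
#' @return Character vector in
#'   `c("negligible", "small", "medium", "large")`.
#' @export
effect_label <- function(x, type = c("d", "rho")) {
  type <- match.arg(type)
  cuts <- if (type == "d") c(0.2, 0.5, 0.8) else c(0.1, 0.3, 0.5)
  lab <- c("negligible", "small", "medium", "large")
  lab[findInterval(abs(x), cuts) + 1L]
}
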