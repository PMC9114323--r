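#' Mann-Whitney rank-sum comparison of two groups
#'
#' Computes the Mann-Whitney U statistic (first sample as reference) with
#' midrank tie handling, an exact p-value by enumeration of rank assignments
#' when `n_a + n_b <= 12` and there are no ties, and otherwise the normal
#' approximation with continuity correction and the tie correction to the
#' variance. Alongside the test it reports group means and the percent
#' reduction of group b relative to the reference group a,
#' `100 * (mean_a - mean_b) / mean_a`.
#'
#' @param a,b numeric vectors, both nonempty; `a` is the reference (e.g.
#'   control) group.
#' @param alternative `"two.sided"` (default), `"less"` (a tends smaller),
#'   or `"greater"`.
#' @param labels optional length-2 character vector naming the groups.
#' @return A `group_comparison` object: `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `percent_reduction`, `u_statistic`, `p_value`, `alternative`, `method`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6), alternative = "less")
#' @export
rank_sum_test <- function(a, b, alternative = c("two.sided", "less", "greater"),
                          labels = c("a", "b")) {
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  n_a <- length(a); n_b <- length(b)

  r <- rank(c(a, b))                      # midranks
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (n_a + n_b) <= 12L

  wt <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = alternative, exact = exact, correct = TRUE))

  mean_a <- mean(a); mean_b <- mean(b)
  structure(
    list(n_a = n_a, n_b = n_b, mean_a = mean_a, mean_b = mean_b,
         percent_reduction = if (mean_a != 0) 100 * (mean_a - mean_b) / mean_a else NA_real_,
         u_statistic = unname(u),
         p_value = unname(wt$p.value),
         alternative = alternative,
         method = if (exact) "exact" else "normal approximation",
         labels = labels),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d) vs %s (n=%d), Mann-Whitney U-test (%s)\n",
              x$labels[1L], x$n_a, x$labels[2L], x$n_b, x$method))
  cat(sprintf("  means: %.6g vs %.6g  (percent reduction %.4g%%)\n",
              x$mean_a, x$mean_b, x$percent_reduction))
  cat(sprintf("  U = %g, p = %.4g (%s)\n", x$u_statistic, x$p_value, x$alternative))
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, ...) {
  data.frame(group_a = x$labels[1L], group_b = x$labels[2L],
             n_a = x$n_a, n_b = x$n_b, mean_a = x$mean_a, mean_b = x$mean_b,
             percent_reduction = x$percent_reduction,
             u_statistic = x$u_statistic, p_value = x$p_value,
             alternative = x$alternative, method = x$method,
             stringsAsFactors = FALSE)
}

#' Pearson correlation of paired per-cell ratios
#'
#' Drops pairs where either ratio is undefined (NA), then computes the
#' Pearson product-moment coefficient and its two-sided p-value from the
#' t distribution with n - 2 degrees of freedom. With fewer than 3 complete
#' pairs, or zero variance in either vector, the correlation is undefined and
#' reported as NA.
#'
#' @param ratios_a,ratios_b numeric vectors of per-cell ratios, paired by cell.
#' @return list with `r`, `p_value`, `n` (complete pairs used).
#' @export
ratio_correlation <- function(ratios_a, ratios_b) {
  if (length(ratios_a) != length(ratios_b)) stop("ratios must be paired (equal length)")
  ok <- is.finite(ratios_a) & is.finite(ratios_b)
  a <- ratios_a[ok]; b <- ratios_b[ok]
  n <- length(a)
  if (n < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Kruskal-Wallis omnibus with Dunn's pairwise post-hoc z-tests
#'
#' For three or more groups of ratios the omnibus test is Kruskal-Wallis;
#' pairwise follow-ups use Dunn's z statistic on mean midranks with the tie
#' correction, and the p-values are adjusted (Bonferroni by default).
#'
#' @param values numeric vector of observations.
#' @param groups factor/character vector of group labels, same length.
#' @param p_adjust adjustment method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return list with `kruskal` (the `htest` from [stats::kruskal.test()]) and
#'   `pairwise` (data.frame: `group_1`, `group_2`, `z`, `p_value`,
#'   `p_adjusted`).
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (length(values) != length(groups)) stop("values and groups must align")
  kw <- stats::kruskal.test(values, groups)

  n <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))

  lev <- levels(groups)
  combs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    g1 <- combs[1L, k]; g2 <- combs[2L, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    z[k] <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  list(kruskal = kw,
       pairwise = data.frame(group_1 = combs[1L, ], group_2 = combs[2L, ],
                             z = z, p_value = p,
                             p_adjusted = stats::p.adjust(p, method = p_adjust),
                             stringsAsFactors = FALSE))
}
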