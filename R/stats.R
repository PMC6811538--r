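# Statistical primitives shared by every stage. These wrap the base R
# implementations behind the contracts the pipeline relies on (explicit
# degeneracy errors, effective sample sizes, [0, 1] p-values).

#' Pearson correlation on complete observations
#'
#' Pairwise deletion: positions missing in either vector are dropped before
#' computing the sample correlation. Fewer than three complete pairs or a
#' constant restricted vector is an error, never a silent `NaN`.
#'
#' @param x,y Numeric vectors of equal length; `NA` marks missing.
#' @param return_n Also return the number of complete pairs used?
#' @return The correlation, or (with `return_n`) a list `r`, `n_effective`.
#' @export
#' @examples
#' pearson_complete(c(1, 2, NA, 4), c(2, 4, 6, 8))
pearson_complete <- function(x, y, return_n = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) abort("insufficient observations: fewer than 3 complete pairs")
  xs <- x[ok]; ys <- y[ok]
  if (sd(xs) == 0 || sd(ys) == 0) {
    abort("undefined correlation: a vector is constant on the complete pairs")
  }
  r <- cor(xs, ys)
  if (return_n) list(r = r, n_effective = n) else r
}

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' U is computed with midranks for ties. The p-value is exact (full
#' enumeration of rank assignments) when `n_a * n_b <= 400` and there are no
#' ties, otherwise a normal approximation with tie and continuity correction.
#'
#' @param a,b Numeric vectors, each of length at least 3.
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`.
#' @return A tibble `statistic` (U of the first sample), `p_value`,
#'   `n_effective`, `method`.
#' @export
mann_whitney_u <- function(a, b, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) abort("each group needs at least 3 observations")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= 400
  ht <- suppressWarnings(wilcox.test(
    a, b,
    alternative = switch(alternative, two_sided = "two.sided", less = "less",
                         greater = "greater"),
    exact = exact, correct = TRUE
  ))
  tibble(statistic = unname(ht$statistic),
         p_value = min(1, ht$p.value),
         n_effective = length(a) + length(b),
         method = if (exact) "exact" else "normal")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order and
#' capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided. Used to compare per-permutation performance distributions,
#' which carry no variance-equality guarantee.
#'
#' @param a,b Numeric vectors, each of length at least 3.
#' @return A tibble `statistic`, `p_value`, `df`, `n_effective`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) abort("each group needs at least 3 observations")
  if (sd(a) == 0 && sd(b) == 0) abort("zero variance in both groups")
  ht <- t.test(a, b, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic),
         p_value = ht$p.value,
         df = unname(ht$parameter),
         n_effective = length(a) + length(b))
}
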