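#' Tie-corrected Kruskal-Wallis rank test between groups
#'
#' Rank-based comparison of a quantitative variable (the score, LDL-C,
#' age, ...) across two or more groups, as used for all quantitative
#' clinical parameters in the analysis stage. The statistic is the
#' tie-corrected H with a chi-square reference on k - 1 degrees of
#' freedom; for two groups it coincides with the squared normal
#' approximation of the two-sided Mann-Whitney test.
#'
#' @param data A data frame.
#' @param value,group Column names (strings or bare names) of the
#'   quantitative variable and the grouping variable. Rows with missing
#'   values are dropped.
#' @return A one-row tibble `statistic`, `df`, `p.value`, `n`, with a
#'   `"groups"` attribute holding per-group `n`, `median`, `min`, `max`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' kruskal_rank_test(d, y, g)
#' @export
kruskal_rank_test <- function(data, value, group) {
  value <- tidyselect::eval_select(rlang::enquo(value), data)
  group <- tidyselect::eval_select(rlang::enquo(group), data)
  if (length(value) != 1 || length(group) != 1) {
    abort("select exactly one value column and one group column")
  }
  y <- data[[value]]
  g <- as.factor(data[[group]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("kruskal_rank_test needs at least 2 non-empty groups")
  if (any(tabulate(g) < 1)) abort("every group needs at least one observation")
  # degenerate all-tied input: H = 0 under the tie-correction convention
  if (length(unique(y)) == 1) {
    kt <- list(statistic = c(H = 0), parameter = nlevels(g) - 1, p.value = 1)
  } else {
    kt <- kruskal.test(y, g)
  }
  out <- tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p.value = unname(kt$p.value),
    n = length(y)
  )
  gsum <- tibble(group = levels(g)) |>
    mutate(
      n = as.integer(tabulate(g)),
      median = vapply(levels(g), function(l) median(y[g == l]), 0),
      min = vapply(levels(g), function(l) min(y[g == l]), 0),
      max = vapply(levels(g), function(l) max(y[g == l]), 0)
    )
  attr(out, "groups") <- gsum
  out
}

#' Pearson chi-square test on a contingency table
#'
#' `chi2 = sum (O - E)^2 / E` with expectations from the row/column
#' margins and `(r-1)(c-1)` degrees of freedom. No continuity correction
#' is applied (for a 2x2 table the statistic therefore equals the squared
#' two-proportion z statistic), which is the convention needed to
#' reproduce published group-characteristic statistics such as 0.252 for
#' the sex split.
#'
#' @param x A matrix/table of non-negative integer counts, or a data frame
#'   of counts convertible with `as.matrix()`.
#' @return A one-row tibble `statistic`, `df`, `p.value`, `n`.
#' @examples
#' pearson_chi2(matrix(c(48, 34, 45, 27), nrow = 2))
#' @export
pearson_chi2 <- function(x) {
  x <- as_count_matrix(x)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    abort("contingency table has a zero row or column margin")
  }
  ct <- suppressWarnings(chisq.test(x, correct = FALSE))
  tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p.value = unname(ct$p.value),
    n = sum(x)
  )
}

#' Two-sided Fisher exact test for small contingency tables
#'
#' For a 2x2 table the two-sided p-value is computed over the
#' hypergeometric distribution of the first cell given fixed margins, as
#' the sum of the probabilities of all tables whose point probability does
#' not exceed that of the observed table (the point-probability rule, with
#' the customary `1 + 1e-7` relative tolerance for floating-point ties).
#' 2x3 tables are handled by the exact network algorithm of
#' [stats::fisher.test()]. Larger layouts are rejected with a pointer to
#' [pearson_chi2()].
#'
#' @param x A 2x2 or 2x3 count matrix (or coercible data frame).
#' @return A one-row tibble `p.value`, `n`.
#' @examples
#' fisher_exact(matrix(c(1, 11, 9, 3), nrow = 2))
#' @export
fisher_exact <- function(x) {
  x <- as_count_matrix(x)
  if (nrow(x) == 2 && ncol(x) == 2) {
    p <- fisher2x2_p(x[1, 1], sum(x[1, ]), sum(x[2, ]), sum(x[, 1]))
  } else if (nrow(x) == 2 && ncol(x) == 3) {
    p <- fisher.test(x)$p.value
  } else {
    abort("fisher_exact handles 2x2 and 2x3 tables; use pearson_chi2() for larger layouts")
  }
  tibble(p.value = p, n = sum(x))
}

# two-sided point-probability 2x2 Fisher p for observed first cell `a`
# with row margins r1, r2 and first column margin c1
fisher2x2_p <- function(a, r1, r2, c1) {
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

as_count_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (inherits(x, "table")) x <- unclass(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expected a numeric matrix or table of counts")
  }
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    abort("counts must be non-negative integers without missing values")
  }
  storage.mode(x) <- "integer"
  x
}

#' Dichotomize LDL-C at a clinical threshold
#'
#' Splits LDL-C concentrations (mmol/L) at a threshold, by default the
#' 4.9 mmol/L level suggestive of familial hypercholesterolemia. The
#' split is strict: values equal to the threshold fall in the lower class.
#'
#' @param ldl_c Positive numeric vector of LDL-C concentrations in mmol/L
#'   (`NA` allowed and propagated).
#' @param threshold Threshold in mmol/L; default 4.9.
#' @return Integer vector of 0/1 (1 = above threshold), `NA` preserved.
#' @examples
#' dichotomize_ldl(c(5.67, 4.9, 3.88))
#' @export
dichotomize_ldl <- function(ldl_c, threshold = 4.9) {
  if (!is.numeric(ldl_c)) abort("ldl_c must be numeric (mmol/L)")
  if (any(ldl_c <= 0, na.rm = TRUE)) {
    abort("LDL-C concentrations must be positive")
  }
  as.integer(ldl_c > threshold)
}
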