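test_that("the rank test matches the direct H formula with ties", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      n1 <- sample(3:15, 1); n2 <- sample(3:15, 1); n3 <- sample(0:10, 1)
      # discrete values force ties
      vals <- sample(1:6, n1 + n2 + n3, replace = TRUE)
      groups <- rep(c("a", "b", "c"), c(n1, n2, n3))
      d <- data.frame(y = vals, g = groups)
      res <- kruskal_rank_test(d, y, g)
      expect_equal(res$statistic, kruskal_brute_force(vals, groups),
                   tolerance = 1e-10)
    }
  })
})

test_that("two-group rank test equals the tie-corrected Mann-Whitney z^2", {
  withr::with_seed(9, {
    for (rep in 1:10) {
      y1 <- sample(1:8, 12, replace = TRUE)
      y2 <- sample(2:9, 9, replace = TRUE)
      d <- data.frame(y = c(y1, y2), g = rep(c("a", "b"), c(12, 9)))
      res <- kruskal_rank_test(d, y, g)
      # two-sided normal approximation of U without continuity correction
      r <- rank(d$y)
      n1 <- 12; n2 <- 9; n <- n1 + n2
      u <- sum(r[d$g == "a"]) - n1 * (n1 + 1) / 2
      ties <- table(d$y)
      var_u <- n1 * n2 / 12 *
        ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
      z <- (u - n1 * n2 / 2) / sqrt(var_u)
      p_mw <- 2 * stats::pnorm(-abs(z))
      expect_equal(res$p.value, p_mw, tolerance = 1e-9)
    }
  })
})

test_that("rank test degenerate and invariance properties hold", {
  d <- data.frame(y = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_rank_test(d, y, g)$statistic, 0, tolerance = 1e-12)
  # two single-value tied groups
  d2 <- data.frame(y = c(5, 5), g = c("a", "b"))
  res2 <- kruskal_rank_test(d2, y, g)
  expect_identical(res2$statistic, 0)
  # invariance under strictly monotone transforms
  withr::with_seed(3, {
    d3 <- data.frame(y = rlnorm(40), g = sample(c("a", "b"), 40, TRUE))
    a <- kruskal_rank_test(d3, y, g)
    d3$y <- exp(d3$y)          # strictly increasing transform
    b <- kruskal_rank_test(d3, y, g)
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  })
  expect_error(kruskal_rank_test(data.frame(y = 1, g = "a"), y, g),
               "at least 2")
})

test_that("chi-square on a 2x2 equals the squared two-proportion z statistic", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      tab <- matrix(sample(5:60, 4, TRUE), 2)
      res <- pearson_chi2(tab)
      n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
      p1 <- tab[1, 1] / n1; p2 <- tab[2, 1] / n2
      pp <- (tab[1, 1] + tab[2, 1]) / (n1 + n2)
      z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
      expect_equal(res$statistic, z^2, tolerance = 1e-10)
    }
  })
})

test_that("chi-square handles independence, margins, and layout errors", {
  expect_equal(pearson_chi2(matrix(10, 2, 2))$statistic, 0)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "zero row or column")
  expect_error(pearson_chi2(matrix(c(1.5, 2, 3, 4), 2)), "integers")
  r <- pearson_chi2(matrix(c(10, 5, 8, 12, 4, 9), 2))
  expect_identical(r$df, 2L)
})

test_that("2x2 Fisher p agrees with brute-force enumeration and fisher.test", {
  tab <- matrix(c(1, 11, 9, 3), 2)
  expect_equal(fisher_exact(tab)$p.value, fisher_brute_force(tab),
               tolerance = 1e-12)
  expect_equal(fisher_exact(tab)$p.value, fisher.test(tab)$p.value,
               tolerance = 1e-12)
  expect_identical(fisher_exact(matrix(5, 2, 2))$p.value, 1)
  withr::with_seed(13, {
    for (rep in 1:30) {
      tab <- matrix(sample(0:25, 4, TRUE), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab)$p.value, fisher_brute_force(tab),
                   tolerance = 1e-12)
      expect_equal(fisher_exact(tab)$p.value, fisher.test(tab)$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("2x3 Fisher tables use the exact network algorithm", {
  tab <- matrix(c(0, 3, 55, 14, 38, 44), nrow = 2)
  expect_equal(fisher_exact(tab)$p.value, fisher.test(tab)$p.value,
               tolerance = 1e-12)
  expect_error(fisher_exact(matrix(1, 2, 4)), "pearson_chi2")
  expect_error(fisher_exact(matrix(1, 3, 3)), "pearson_chi2")
})

test_that("LDL-C dichotomization is strict at the threshold", {
  expect_identical(dichotomize_ldl(c(5.67, 4.9, 3.88, NA)),
                   c(1L, 0L, 0L, NA))
  expect_identical(dichotomize_ldl(4.91), 1L)
  expect_error(dichotomize_ldl(c(3, -1)), "positive")
  expect_error(dichotomize_ldl("high"), "numeric")
})
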