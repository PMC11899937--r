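test_that("IRLS agrees with the reference ML fit", {
  withr::with_seed(42, {
    n <- 500
    d <- data.frame(x = rnorm(n), w = rbinom(n, 1, 0.4))
    d$y <- rbinom(n, 1, plogis(-0.5 + 0.9 * d$x + 0.6 * d$w))
  })
  fit <- logistic_fit(d, y ~ x + w)
  ref <- glm(y ~ x + w, data = d, family = binomial(),
             control = list(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$std.error),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("the log-likelihood trace is non-decreasing across iterations", {
  withr::with_seed(7, {
    d <- data.frame(x = rnorm(300))
    d$y <- rbinom(300, 1, plogis(2 * d$x))
  })
  fit <- logistic_fit(d, y ~ x)
  expect_true(all(diff(fit$loglik_trace) >= -1e-10))
})

test_that("known coefficients are recovered within 3 standard errors", {
  withr::with_seed(101, {
    n <- 2000
    d <- data.frame(x = rnorm(n))
    d$y <- rbinom(n, 1, plogis(-1 + 0.8 * d$x))
  })
  td <- tidy(logistic_fit(d, y ~ x))
  expect_lt(abs(td$estimate[1] - (-1)) / td$std.error[1], 3)
  expect_lt(abs(td$estimate[2] - 0.8) / td$std.error[2], 3)
})

test_that("the Wald test holds its size under the null", {
  rejections <- withr::with_seed(55, {
    vapply(1:200, function(i) {
      d <- data.frame(x = rnorm(400))
      d$y <- rbinom(400, 1, 0.4)  # outcome independent of x
      td <- tidy(logistic_fit(d, y ~ x))
      td$p.value[td$term == "x"] < 0.05
    }, TRUE)
  })
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.10)
})

test_that("perfect separation raises a structured diagnostic", {
  d <- data.frame(x = c(-3, -2, -1, 1, 2, 3))
  d$y <- as.integer(d$x > 0)
  expect_error(logistic_fit(d, y ~ x), class = "ldlprs_separation")
  expect_warning(fit <- logistic_fit(d, y ~ x, on_separation = "warn"),
                 class = "ldlprs_separation")
  expect_true(fit$separation)
})

test_that("degenerate designs are rejected", {
  d <- data.frame(x = rnorm(20), k = 1)
  d$y <- rbinom(20, 1, 0.5)
  expect_error(logistic_fit(d, y ~ x + k), "constant column")
  expect_error(logistic_fit(d[1:2, ], y ~ x), "more observations")
  d$y2 <- d$y + 1
  expect_error(logistic_fit(d, y2 ~ x), "binary")
})

test_that("backward selection drops null terms and keeps strong ones", {
  kept <- withr::with_seed(77, {
    vapply(1:50, function(i) {
      d <- data.frame(x = rnorm(800), z = rnorm(800))
      d$y <- rbinom(800, 1, plogis(2 * d$x))  # z is pure noise
      sel <- backward_select(d, y ~ x + z, alpha = 0.05)
      surviving <- setdiff(names(sel$fit$coefficients), "(Intercept)")
      c(strong = "x" %in% surviving, null = "z" %in% surviving)
    }, c(strong = TRUE, null = TRUE))
  })
  expect_gte(mean(kept["strong", ]), 0.95)
  expect_lt(mean(kept["null", ]), 0.25)
})

test_that("backward selection boundary behaviour", {
  withr::with_seed(3, {
    d <- data.frame(x = rnorm(300), z = rnorm(300))
    d$y <- rbinom(300, 1, plogis(1.5 * d$x))
  })
  # alpha = 1: nothing can be dropped
  sel_all <- backward_select(d, y ~ x + z, alpha = 1)
  expect_identical(nrow(sel_all$trace), 0L)
  expect_setequal(names(sel_all$fit$coefficients),
                  c("(Intercept)", "x", "z"))
  # single strong candidate: zero drop steps
  sel_one <- backward_select(d, y ~ x, alpha = 0.05)
  expect_identical(nrow(sel_one$trace), 0L)
  # all terms null at a strict threshold: intercept-only model, no error
  d$y <- rbinom(300, 1, 0.5)
  sel_none <- backward_select(d, y ~ z, alpha = 1e-6)
  expect_identical(names(sel_none$fit$coefficients), "(Intercept)")
  expect_identical(sel_none$trace$dropped, "z")
})
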