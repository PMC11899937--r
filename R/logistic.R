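#' Logistic regression with Wald odds-ratio intervals
#'
#' Maximum-likelihood logistic regression fitted by iteratively
#' reweighted least squares (IRLS), the engine behind the association
#' stage's odds-ratio models (case status on score and smoking; high
#' LDL-C on score). Convergence is declared when the largest absolute
#' score (gradient) component falls below `tol_score` or the relative
#' change in log-likelihood falls below `tol_loglik`. The per-iteration
#' log-likelihood trace is retained (step-halving guarantees it is
#' non-decreasing).
#'
#' Complete or quasi-complete separation — fitted probabilities pinned to
#' 0/1 on a perfectly classified margin, with coefficients diverging — is
#' detected and reported as a structured condition instead of returning
#' divergent estimates.
#'
#' @param data A data frame.
#' @param formula Model formula with a binary (0/1 or logical or
#'   two-level factor) outcome, e.g. `case ~ prs + smoking`.
#' @param max_iter Maximum IRLS iterations (default 50).
#' @param tol_score,tol_loglik Convergence tolerances (defaults 1e-8 and
#'   1e-10).
#' @param on_separation `"error"` (default) or `"warn"`; with `"warn"` the
#'   last iterate is returned and flagged.
#' @return An object of class `ldl_logit` with elements `coefficients`,
#'   `std.error`, `vcov`, `loglik` (final), `loglik_trace`, `iterations`,
#'   `converged`, `separation`, `n`, `formula`. Use [tidy()] for the
#'   odds-ratio table and [glance()] for the fit summary.
#' @examples
#' d <- data.frame(x = c(-2, -1, -0.5, 0.5, 1, 2, -1.5, 1.5),
#'                 y = c(0, 0, 1, 0, 1, 1, 0, 1))
#' fit <- logistic_fit(d, y ~ x)
#' tidy(fit)
#' @export
logistic_fit <- function(data, formula, max_iter = 50L, tol_score = 1e-8,
                         tol_loglik = 1e-10,
                         on_separation = c("error", "warn")) {
  on_separation <- match.arg(on_separation)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) {
    if (nlevels(y) != 2) abort("outcome factor must have exactly 2 levels")
    y <- as.integer(y) - 1L
  }
  if (!all(y %in% c(0, 1))) abort("outcome must be binary (0/1)")
  X <- model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) abort("need more observations than model terms")
  if (p > 1 && any(apply(X[, -1, drop = FALSE], 2,
                         function(v) length(unique(v)) == 1))) {
    abort("constant column in the design besides the intercept")
  }

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    # numerically stable log(1 + exp(eta))
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  beta <- rep(0, p)
  ll <- loglik(beta)
  ll_trace <- ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol_score) { converged <- TRUE; break }
    wt <- pmax(mu * (1 - mu), .Machine$double.eps)
    info <- crossprod(X * wt, X)
    step <- tryCatch(solve(info, score), error = function(e) {
      abort(sprintf("IRLS information matrix is singular at iteration %d", iter))
    })
    # step-halve so the log-likelihood never decreases
    ll_new <- loglik(beta + step)
    halvings <- 0L
    while (ll_new < ll && halvings < 30L) {
      step <- step / 2
      ll_new <- loglik(beta + step)
      halvings <- halvings + 1L
    }
    beta <- beta + step
    rel_change <- abs(ll_new - ll) / (abs(ll) + .Machine$double.eps)
    ll <- ll_new
    ll_trace <- c(ll_trace, ll)
    if (rel_change < tol_loglik) { converged <- TRUE; break }
  }

  mu <- plogis(drop(X %*% beta))
  separated <- detect_separation(y, mu, beta)
  if (separated) {
    msg <- "complete or quasi-complete separation detected: coefficients diverge and Wald intervals are meaningless"
    if (on_separation == "error") {
      abort(msg, class = "ldlprs_separation")
    }
    warn(msg, class = "ldlprs_separation")
  }
  if (!converged && !separated) {
    abort(sprintf(
      "IRLS did not converge in %d iterations (last max |score| = %.3g, loglik = %.6g)",
      max_iter, max(abs(drop(crossprod(X, y - mu)))), ll
    ))
  }

  wt <- pmax(mu * (1 - mu), .Machine$double.eps)
  vc <- solve(crossprod(X * wt, X))
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(
    list(
      coefficients = setNames(drop(beta), colnames(X)),
      std.error = setNames(sqrt(diag(vc)), colnames(X)),
      vcov = vc,
      loglik = ll,
      loglik_trace = ll_trace,
      iterations = iter,
      converged = converged,
      separation = separated,
      n = n,
      formula = formula
    ),
    class = "ldl_logit"
  )
}

# fitted probabilities pinned to the boundary on a perfectly classified
# subset together with a runaway coefficient is the IRLS signature of
# (quasi-)separation
detect_separation <- function(y, mu, beta, eps = 1e-7, beta_big = 12) {
  pinned <- (mu > 1 - eps & y == 1) | (mu < eps & y == 0)
  any(abs(beta) > beta_big) && any(pinned)
}

#' @exportS3Method base::print
print.ldl_logit <- function(x, ...) {
  cat(sprintf("<ldl_logit: %s; n = %d, logLik = %.4f, %d IRLS iteration(s)%s>\n",
              deparse(x$formula), x$n, x$loglik, x$iterations,
              if (x$separation) ", SEPARATION" else ""))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy an `ldl_logit` fit into an odds-ratio table
#'
#' @param x An `ldl_logit` object.
#' @param conf.level Wald confidence level (default 0.95); intervals are
#'   `exp(beta +/- z * SE)`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (log-odds), `std.error`,
#'   `statistic` (Wald z), `p.value`, `odds.ratio`, `conf.low`,
#'   `conf.high` (odds-ratio scale).
#' @export
tidy.ldl_logit <- function(x, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  est <- x$coefficients
  se <- x$std.error
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se))),
    odds.ratio = exp(unname(est)),
    conf.low = exp(unname(est - z * se)),
    conf.high = exp(unname(est + z * se))
  )
}

#' @rdname tidy.ldl_logit
#' @export
glance.ldl_logit <- function(x, ...) {
  tibble(
    n = x$n,
    logLik = x$loglik,
    deviance = -2 * x$loglik,
    AIC = -2 * x$loglik + 2 * length(x$coefficients),
    iterations = x$iterations,
    converged = x$converged,
    separation = x$separation
  )
}

#' Backward elimination over logistic model terms
#'
#' Starting from the full candidate model, repeatedly refits and drops
#' the term with the largest Wald p-value at or above `alpha` until every
#' surviving term has `p < alpha`. The intercept is never dropped. When
#' all candidates are eliminated the intercept-only model is returned
#' (with its trace), not an error.
#'
#' @param data A data frame.
#' @param formula Full model formula (binary outcome ~ candidate terms).
#' @param alpha Retention threshold on the Wald p-value (default 0.05).
#' @param ... Passed to [logistic_fit()].
#' @return An object of class `ldl_selection`: list with `fit` (final
#'   [logistic_fit()] object, or `NULL` if even the intercept-only fit is
#'   empty), `trace` (tibble `step`, `dropped`, `p.value`, `surviving`),
#'   `alpha`, `formula`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(200), z = rnorm(200))
#' d$y <- rbinom(200, 1, plogis(2 * d$x))
#' backward_select(d, y ~ x + z)$trace
#' @export
backward_select <- function(data, formula, alpha = 0.05, ...) {
  outcome <- rlang::f_lhs(formula)
  terms_now <- labels(stats::terms(formula, data = data))
  trace <- tibble(step = integer(), dropped = character(),
                  p.value = double(), surviving = character())
  step_i <- 0L
  repeat {
    f <- if (length(terms_now) == 0) {
      stats::reformulate("1", response = outcome)
    } else {
      stats::reformulate(terms_now, response = outcome)
    }
    fit <- logistic_fit(data, f, ...)
    td <- filter(tidy(fit), .data$term != "(Intercept)")
    if (nrow(td) == 0 || all(td$p.value < alpha)) break
    worst <- td[which.max(td$p.value), ]
    # map the model-matrix column back to its source term
    drop_term <- terms_now[vapply(terms_now, function(t)
      startsWith(worst$term, t) || worst$term == t, TRUE)][1]
    if (is.na(drop_term)) drop_term <- worst$term
    terms_now <- setdiff(terms_now, drop_term)
    step_i <- step_i + 1L
    trace <- bind_rows(trace, tibble(
      step = step_i, dropped = drop_term, p.value = worst$p.value,
      surviving = paste(terms_now, collapse = "+")
    ))
  }
  structure(
    list(fit = fit, trace = trace, alpha = alpha,
         formula = stats::formula(fit$formula)),
    class = "ldl_selection"
  )
}

#' @exportS3Method base::print
print.ldl_selection <- function(x, ...) {
  cat(sprintf("<ldl_selection: alpha = %g, %d term(s) dropped>\n",
              x$alpha, nrow(x$trace)))
  if (nrow(x$trace) > 0) print(x$trace, ...)
  cat("final model:\n")
  print(x$fit, ...)
  invisible(x)
}

#' @export
tidy.ldl_selection <- function(x, ...) tidy(x$fit, ...)

#' @export
glance.ldl_selection <- function(x, ...) glance(x$fit, ...)
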