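test_that("lambda = 0 reproduces the unpenalized maximum-likelihood fit", {
  set.seed(3)
  n <- 20
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, stats::plogis(0.8 * x[, 1] - 0.4 * x[, 2]))
  stopifnot(length(unique(y)) == 2)   # seed chosen to give both classes
  fit <- fit_ridge_logistic(x, y, lambda = 0)
  z <- scale(x)
  ref <- stats::glm(y ~ z, family = stats::binomial())
  expect_true(fit$converged)
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(stats::coef(ref)), tolerance = 1e-6)
})

test_that("an overwhelming penalty shrinks coefficients to zero", {
  set.seed(4)
  x <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(40, 1, 0.4)
  while (length(unique(y)) < 2) y <- rbinom(40, 1, 0.4)
  fit <- fit_ridge_logistic(x, y, lambda = 1e6)
  expect_lt(sqrt(sum(fit$coefficients^2)), 1e-3)
  expect_equal(unname(fit$intercept), stats::qlogis(mean(y)), tolerance = 1e-3)
})

test_that("the returned optimum beats a grid search over the penalized objective", {
  # 6-point, 2-feature instance; objective evaluated independently
  x <- cbind(f1 = c(-1.2, -0.5, 0.1, 0.4, 0.9, 1.5),
             f2 = c(0.3, -0.8, 1.1, -0.2, 0.7, -1.0))
  y <- c(0, 0, 1, 0, 1, 1)
  lambda <- 1
  fit <- fit_ridge_logistic(x, y, lambda = lambda, standardize = FALSE)
  obj <- function(b0, b1, b2) {
    eta <- b0 + x[, 1] * b1 + x[, 2] * b2
    sum(y * eta - log1p(exp(eta))) - lambda * (b1^2 + b2^2)
  }
  grid <- seq(-2, 2, length.out = 41)
  best_grid <- -Inf
  for (b0 in grid) for (b1 in grid) for (b2 in grid) {
    best_grid <- max(best_grid, obj(b0, b1, b2))
  }
  expect_gte(fit$objective + 1e-9, best_grid)
  expect_equal(fit$objective,
               unname(obj(fit$intercept, fit$coefficients[[1]],
                          fit$coefficients[[2]])),
               tolerance = 1e-9)
})

test_that("the coefficient norm is nonincreasing along the penalty path", {
  set.seed(5)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(50, 1, stats::plogis(x %*% c(1, -0.5, 0.3, 0)))
  norms <- vapply(c(0.01, 0.1, 1, 10, 100), function(l) {
    sqrt(sum(fit_ridge_logistic(x, y, lambda = l)$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("separable data at lambda = 0 reports non-convergence", {
  x <- matrix(c(-3, -2, -1.5, 1.5, 2, 3), 6, 1, dimnames = list(NULL, "f"))
  y <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fit <- fit_ridge_logistic(x, y, lambda = 0),
                 "separable")
  expect_false(fit$converged)
  # with any positive penalty the same data fit cleanly
  expect_silent(fit1 <- fit_ridge_logistic(x, y, lambda = 0.5))
  expect_true(fit1$converged)
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(6)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(40, 1, 0.5)
  while (length(unique(y)) < 2) y <- rbinom(40, 1, 0.5)
  fit <- fit_ridge_logistic(x, y, lambda = 2)
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "a", "b"))
  gl <- glance(fit)
  expect_equal(gl$lambda, 2)
  expect_true(gl$converged)
  # predictions are monotone in the linear predictor
  eta <- predict(fit, x)
  pr <- predict(fit, x, type = "response")
  expect_equal(pr, stats::plogis(eta))
})
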