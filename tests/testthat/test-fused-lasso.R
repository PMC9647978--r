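test_that("prox_tv1d satisfies closed-form cases", {
  expect_equal(prox_tv1d(c(3, 3, 3), 5), c(3, 3, 3))
  # large penalty collapses to the mean
  y <- c(1, 5, 2, 8)
  expect_equal(prox_tv1d(y, 100), rep(mean(y), 4))
  # two points: soft shrinkage of the jump toward the midpoint
  y2 <- c(0, 4)
  expect_equal(prox_tv1d(y2, 1), c(1, 3))
  expect_equal(prox_tv1d(y2, 2), c(2, 2))
  # prox optimality vs direct 1-D objective on random cases
  set.seed(2)
  for (i in 1:5) {
    y <- rnorm(7); lam <- runif(1, 0.1, 2)
    th <- prox_tv1d(y, lam)
    obj <- function(b) 0.5 * sum((b - y)^2) + lam * sum(abs(diff(b)))
    for (j in 1:20) {
      expect_lte(obj(th), obj(th + rnorm(7, sd = 0.01)) + 1e-10)
    }
  }
})

test_that("fit_fused_lasso approaches per-time OLS as penalties vanish", {
  set.seed(4)
  y <- lapply(1:3, function(i) matrix(rnorm(60), 20, 3))
  x <- lapply(1:3, function(i) rnorm(20))
  fit <- fit_fused_lasso(x, y, drmn_hyper(0, 0, 0), intercept = FALSE,
                         tol = 1e-14, max_iter = 100000)
  for (cc in 1:3) {
    ols <- qr.solve(y[[cc]], x[[cc]])
    expect_equal(unname(fit$theta[, cc]), unname(ols), tolerance = 1e-6)
  }
})

test_that("the objective trace is non-increasing", {
  set.seed(5)
  y <- lapply(1:4, function(i) matrix(rnorm(40), 10, 4))
  x <- lapply(1:4, function(i) rnorm(10))
  fit <- fit_fused_lasso(x, y, drmn_hyper(2, 3, 0.5), intercept = FALSE)
  expect_true(all(diff(fit$obj_trace) <= 1e-9 * (1 + abs(fit$obj_trace[-1]))))
})

test_that("intercepts absorb per-time offsets", {
  set.seed(6)
  y <- lapply(1:2, function(i) matrix(rnorm(60), 20, 3))
  x0 <- lapply(1:2, function(i) rnorm(20))
  shift <- c(5, -3)
  x <- lapply(1:2, function(i) x0[[i]] + shift[i])
  f0 <- fit_fused_lasso(x0, y, drmn_hyper(1, 1, 0), tol = 1e-12)
  f1 <- fit_fused_lasso(x, y, drmn_hyper(1, 1, 0), tol = 1e-12)
  expect_equal(f1$theta, f0$theta, tolerance = 1e-8)
  expect_equal(f1$intercepts, f0$intercepts + shift, tolerance = 1e-8)
})

test_that("row-group penalty zeroes whole rows as rho3 grows", {
  set.seed(7)
  y <- lapply(1:3, function(i) matrix(rnorm(45), 15, 3))
  x <- lapply(1:3, function(i) y[[i]][, 1] * 2 + rnorm(15, sd = 0.1))
  fit <- fit_fused_lasso(x, y, drmn_hyper(0, 0, 8), intercept = FALSE,
                         tol = 1e-12)
  norms <- sqrt(rowSums(fit$theta^2))
  expect_gt(norms[1], 0)
  expect_equal(unname(norms[2:3]), c(0, 0))
})
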