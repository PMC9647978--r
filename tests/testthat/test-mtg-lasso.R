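test_that("mtg_lambda_max is the smallest all-zero penalty", {
  set <- random_mtg_set(seed = 3)
  lmax <- mtg_lambda_max(set)
  f_at <- fit_mtg_lasso(set, lambda = 1, fractional = TRUE)
  expect_length(f_at$selected, 0)
  f_below <- fit_mtg_lasso(set, lambda = lmax * 0.95, fractional = FALSE)
  expect_gt(length(f_below$selected), 0)
})

test_that("fit_mtg_lasso validates the fractional range and is monotone", {
  set <- random_mtg_set(seed = 4)
  expect_error(fit_mtg_lasso(set, lambda = 0), "lambda")
  expect_error(fit_mtg_lasso(set, lambda = 1.2), "lambda")
  fit <- fit_mtg_lasso(set, lambda = 0.4)
  expect_true(all(diff(fit$obj_trace) <= 1e-9 * (1 + abs(fit$obj_trace[-1]))))
  expect_true(fit$converged)
  # selection is nested as lambda grows (standard group-lasso behavior on
  # this instance)
  sel <- lapply(c(0.3, 0.6, 0.9), function(l)
    fit_mtg_lasso(set, lambda = l)$selected)
  expect_true(all(sel[[2]] %in% sel[[1]]))
  expect_true(all(sel[[3]] %in% sel[[2]]))
})

test_that("single-group single-gene solution matches the closed form", {
  # one motif, one gene: theta = (1 - lam/||Y'x||) Y'x / ||Y||^2-style
  # shrinkage; verify against optimize()
  set.seed(8)
  yv <- rnorm(6); xv <- yv * 1.5 + rnorm(6, sd = 0.2)
  ft <- feature_tensor(array(yv, c(1, 1, 6)), "g1", "m1", 1:6)
  xm <- matrix(xv, 1, 6, dimnames = list("g1", NULL))
  set <- mtg_set_data("g1", xm, ft)
  lam <- 0.5 * mtg_lambda_max(set)
  fit <- fit_mtg_lasso(set, lambda = lam, fractional = FALSE, tol = 1e-14)
  obj <- function(b) 0.5 * sum((xv - yv * b)^2) + lam * abs(b)
  best <- optimize(obj, c(-5, 5), tol = 1e-12)$minimum
  expect_equal(unname(fit$theta[1, 1]), best, tolerance = 1e-6)
})

test_that("loo_selection counts folds and scores predictive power", {
  sim <- simulate_mtg_set(seed = 2)
  loo <- loo_selection(sim, lambda = 0.85)
  expect_equal(loo$n_folds, 8)
  truth <- attr(sim, "truth")
  expect_true(all(loo$folds_selected[truth$regulators] >= 6))
  expect_gt(loo$mean_power, 0.5)
})

test_that("null_selection flags planted regulators and not decoys", {
  sim <- simulate_mtg_set(seed = 2)
  res <- null_selection(sim, lambda = 0.85, n_random = 40, seed = 1)
  truth <- attr(sim, "truth")
  expect_true(all(res$significant[res$motif %in% truth$regulators]))
  decoys <- setdiff(res$motif, truth$regulators)
  expect_lte(sum(res$significant[res$motif %in% decoys]), 1)
  expect_equal(dim(attr(res, "null")), c(length(res$motif), 40))
})

test_that("null_selection is deterministic in its seed", {
  sim <- simulate_mtg_set(n_genes = 20, n_decoys = 10, seed = 5)
  r1 <- null_selection(sim, lambda = 0.8, n_random = 5, seed = 9)
  r2 <- null_selection(sim, lambda = 0.8, n_random = 5, seed = 9)
  expect_identical(r1$p, r2$p)
})

test_that("choose_lambda reports a grid and flags no-model sets", {
  sim <- simulate_mtg_set(n_genes = 25, n_regulators = 2, n_decoys = 10,
                          seed = 3)
  cl <- choose_lambda(sim, lambda_grid = c(0.5, 0.7, 0.9), n_random = 8,
                      seed = 1)
  expect_equal(nrow(cl$report), 3)
  if (!cl$no_model) expect_true(cl$lambda %in% c(0.5, 0.7, 0.9))
  # pure-noise set: no regulator should be stably significant
  noise <- random_mtg_set(n_genes = 10, n_motifs = 5, n_times = 8, seed = 11)
  cn <- choose_lambda(noise, lambda_grid = c(0.6, 0.9), n_random = 8, seed = 1)
  expect_true(is.logical(cn$no_model))
})

test_that("build_edges assembles and ranks regulator-target edges", {
  theta <- rbind(mA = c(1, 0.5, 0), mB = c(-2, 0, 0))
  colnames(theta) <- c("g1", "g2", "g3")
  res <- build_edges(list(
    list(set_id = "s1", genes = c("g1", "g2", "g3"), theta = theta,
         significant = "mA"),
    list(set_id = "s2", genes = c("g1", "g2", "g3"), theta = theta,
         significant = c("mA", "mB"))))
  expect_equal(nrow(res$edges), 3 + 6)
  expect_equal(res$ranking$motif[1], "mA")
  expect_equal(res$ranking$n_targets, c(3L, 3L))
  # tie on n_targets broken by total absolute weight: mA = 2*(1+.5+0)=3 > mB=2
  expect_gt(res$ranking$total_weight[1], res$ranking$total_weight[2])
})

test_that("simulate_mtg_set plants equal-magnitude orthogonalized regulators", {
  sim <- simulate_mtg_set(seed = 7)
  truth <- attr(sim, "truth")
  expect_length(truth$regulators, 3)
  expect_true(all(abs(truth$theta_star[truth$regulators, ]) == 1))
  decoys <- setdiff(rownames(truth$theta_star), truth$regulators)
  expect_true(all(truth$theta_star[decoys, ] == 0))
  # planted profiles are orthogonal per gene with norm sqrt(T)
  g <- 1
  Q <- sim$y[, seq_len(3), g]
  expect_equal(crossprod(Q), diag(3) * 8, tolerance = 1e-8)
})
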