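test_that("permutation_correlation_test is valid, seeded and add-one corrected", {
  a <- c(0.1, 0.9, 0.3, 1.2, 0.8, 1.5, 1.1, 2.0)
  b <- a * 2 + c(0.05, -0.02, 0.01, 0.03, -0.04, 0.02, 0, -0.01)
  r1 <- permutation_correlation_test(a, b, n_perm = 500, seed = 3)
  r2 <- permutation_correlation_test(a, b, n_perm = 500, seed = 3)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$r, 0.99)
  expect_lte(r1$p, 0.05)
  expect_gte(r1$p, 1 / 501)          # add-one estimator can never reach 0
  expect_equal(r1$sign, "positive")
  expect_error(permutation_correlation_test(a, rep(1, 8)), "constant")
  expect_error(permutation_correlation_test(a, b[1:5]), "length")
})

test_that("directed alternative counts one tail only", {
  set.seed(4)
  a <- rnorm(10); b <- -a + rnorm(10, sd = 0.1)
  m <- permutation_correlation_test(a, b, n_perm = 2000, seed = 1)$p
  d <- permutation_correlation_test(a, b, n_perm = 2000, seed = 1,
                                    alternative = "directed")$p
  expect_lte(d, m + 1 / 2001)
  expect_equal(permutation_correlation_test(a, b, seed = 1)$sign, "negative")
})

test_that("correlate_promoter_expression screens genes with per-gene seeds", {
  st <- simulate_study(sim_config(n_genes = 30, seed = 21))
  xm <- expr_profile_matrix(st$expr)
  # planted promoter signal is independent of expression here, so roughly
  # alpha of genes pass; linked signal passes for nearly all
  linked <- xm + matrix(rnorm(length(xm), sd = 0.05), nrow(xm))
  rownames(linked) <- rownames(xm)
  colnames(linked) <- colnames(xm)
  res <- correlate_promoter_expression(xm, linked, n_perm = 200, seed = 2)
  expect_equal(nrow(res), 30)
  expect_gte(attr(res, "summary")$n_significant, 25)
  r2 <- correlate_promoter_expression(xm, linked, n_perm = 200, seed = 2)
  expect_identical(res$p, r2$p)
})

test_that("best_peak_per_gene picks the most correlated mapped peak", {
  set.seed(5)
  times <- 8
  xm <- matrix(rnorm(2 * times), 2, times,
               dimnames = list(c("gA", "gB"), NULL))
  peaks <- rbind(p1 = xm["gA", ] + rnorm(times, sd = 0.01),
                 p2 = rnorm(times),
                 p3 = xm["gB", ] * -1 + rnorm(times, sd = 0.01))
  map <- tibble::tibble(peak_id = c("p1", "p2", "p3"),
                        gene_id = c("gA", "gA", "gB"),
                        distance = c(-500, -100, 200))
  res <- best_peak_per_gene(xm, peaks, map, n_perm = 300, seed = 1)
  expect_equal(res$peak_id[res$gene_id == "gA"], "p1")
  expect_equal(res$peak_id[res$gene_id == "gB"], "p3")
  expect_equal(res$sign[res$gene_id == "gB"], "negative")
})
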