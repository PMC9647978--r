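make_level_expr <- function(n_per = 20, k = 3, times = c(0, 1, 2, 4),
                            sd = 0.05, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_per * k))
  module <- rep(seq_len(k), each = n_per)
  tidyr::expand_grid(gene_id = genes, time = times, replicate = 1:3) |>
    dplyr::mutate(value = rnorm(dplyr::n(),
                                mean = 2 * module[match(gene_id, genes)],
                                sd = sd)) |>
    dplyr::select(gene_id, time, replicate, value)
}

test_that("fit_modules recovers well-separated levels with ordered labels", {
  expr <- make_level_expr()
  fit <- fit_modules(expr, k = 3, seed = 2)
  expect_s3_class(fit, "escarole_fit")
  truth <- rep(1:3, each = 20)
  for (cc in 1:4) {
    expect_equal(unname(fit$assignments[, cc]), truth)
  }
  # module means are reported sorted: label 1 = lowest level
  expect_true(all(apply(fit$module_means, 2, function(m) all(diff(m) > 0))))
  # log-likelihood traces are non-decreasing
  for (tr in fit$loglik_trace) {
    expect_true(all(diff(tr) >= -1e-6 * (1 + abs(tr[-length(tr)]))))
  }
})

test_that("find_transitioning_genes flags exactly the movers", {
  am <- cbind(c(1L, 1L, 2L), c(1L, 2L, 2L))
  rownames(am) <- c("a", "b", "c")
  expect_equal(find_transitioning_genes(am), "b")
})

test_that("mismatch_distance is the disagreement fraction", {
  prof <- rbind(a = c(1, 1, 1, 1, 2, 2, 2, 2),
                b = c(1, 1, 1, 1, 2, 2, 1, 1),
                c = c(2, 2, 2, 2, 1, 1, 1, 1))
  d <- as.matrix(mismatch_distance(prof))
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 1)
  expect_lte(d["a", "b"], 0.26)  # two mismatches of 8 pass the default cut
})

test_that("cluster_transitioning groups equal profiles and drops small sets", {
  prof <- rbind(
    matrix(rep(c(1, 1, 2, 2), each = 12), 12, byrow = FALSE),
    matrix(rep(c(2, 2, 1, 1), each = 11), 11, byrow = FALSE),
    matrix(rep(c(3, 1, 2, 3), each = 2), 2, byrow = FALSE))
  rownames(prof) <- sprintf("g%02d", 1:25)
  cl <- cluster_transitioning(prof, distance_threshold = 0.26, min_size = 10)
  expect_s3_class(cl, "transitioning_sets")
  sizes <- table(cl$sets$set_id)
  expect_equal(sort(as.integer(sizes), decreasing = TRUE), c(12L, 11L))
  expect_length(cl$discarded, 2)
  # ids ordered by decreasing size
  expect_equal(as.integer(sizes[["set001"]]), 12L)
})

test_that("fscore_sets matches the harmonic-mean formula", {
  expect_equal(fscore_sets(letters[1:5], letters[1:5])$fscore, 1)
  expect_equal(fscore_sets(letters[1:5], letters[6:10])$fscore, 0)
  a <- sprintf("x%02d", 1:10)
  b <- c(a[1:5], sprintf("y%02d", 1:15))
  expect_equal(fscore_sets(a, b)$fscore, 1 / 3)
  expect_error(fscore_sets(character(), character()), "empty")
})

test_that("hypergeom_enrichment matches phyper and applies BH", {
  bg <- sprintf("g%03d", 1:100)
  sets <- list(hit = bg[1:20], miss = bg[81:100])
  cl <- bg[1:15]
  res <- hypergeom_enrichment(cl, sets, bg)
  p_hit <- phyper(15 - 1, 20, 80, 15, lower.tail = FALSE)
  expect_equal(res$p[res$term == "hit"], p_hit)
  expect_equal(res$q, p.adjust(res$p[order(res$q)], "BH")[rank(res$q)],
               ignore_attr = TRUE)
  expect_true(res$significant[res$term == "hit"])
  expect_false(res$significant[res$term == "miss"])
  expect_error(hypergeom_enrichment(c("zzz"), sets, bg), "outside")
})

test_that("select_k prefers the planted number of modules", {
  expr <- make_level_expr(n_per = 15, k = 3, sd = 0.05, seed = 6)
  sel <- select_k(expr, k_grid = 2:4, seed = 3)
  expect_equal(sel$chosen_k, 3)
  expect_s3_class(sel$fit, "escarole_fit")
})
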