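test_that("fit_drmn recovers the planted sparse program on default data", {
  st <- default_study()
  fit <- fit_drmn(st$expr, st$features, k = 7, hyper = drmn_hyper(5, 45, 0),
                  modules = st$truth$module_of_gene_per_time, seed = 1)
  expect_s3_class(fit, "drmn_fit")
  expect_equal(dim(fit$theta), c(40, 8, 7))
  tt <- st$truth$theta_true
  for (k in 1:7) {
    sel <- rownames(fit$theta)[abs(fit$theta[, 1, k]) > 1e-8]
    tru <- rownames(tt)[tt[, k, 1] != 0]
    expect_setequal(sel, tru)
  }
  # objective traces are monotone for every module
  for (tr in fit$obj_traces) {
    expect_true(all(diff(tr) <= 1e-8 * (1 + abs(tr[-1]))))
  }
})

test_that("cross_validate_drmn reports held-out correlation per module and time", {
  st <- default_study()
  cv <- cross_validate_drmn(st$expr, st$features, k = 7,
                            hyper = drmn_hyper(5, 45, 0),
                            modules = st$truth$module_of_gene_per_time,
                            folds = 3, seed = 1)
  expect_true(all(c("by_module_time", "mean_cor") %in% names(cv)))
  expect_gt(cv$mean_cor, 0.5)
  expect_true(all(cv$by_module_time$r >= -1 & cv$by_module_time$r <= 1,
                  na.rm = TRUE))
})

test_that("feature z-scoring centers and scales, tolerating constants", {
  m <- cbind(a = c(1, 2, 3, 4), b = rep(7, 4))
  z <- regdyn:::zscore_features(m)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(sd(z[, "a"]), 1)
  expect_equal(unname(z[, "b"]), rep(0, 4))
})

test_that("module-wise prediction tracks held-in expression", {
  st2 <- simulate_study(sim_config(n_genes = 80, seed = 12))
  fit <- fit_drmn(st2$expr, st2$features, k = 7, hyper = drmn_hyper(1, 1, 0),
                  modules = st2$truth$module_of_gene_per_time, seed = 1)
  xm <- expr_profile_matrix(st2$expr)
  featz <- regdyn:::tensor_zscore(st2$features)
  pred <- regdyn:::predict_expression(fit, featz,
                                      st2$truth$module_of_gene_per_time,
                                      rownames(xm))
  expect_equal(dim(pred), dim(xm))
  # in-sample prediction correlates strongly with observed expression
  for (cc in c(1, 8)) {
    expect_gt(cor(pred[, cc], xm[, cc]), 0.8)
  }
})

test_that("drmn_grid_search returns staged reports and a chosen setting", {
  st2 <- simulate_study(sim_config(n_genes = 120, seed = 13))
  gs <- drmn_grid_search(st2$expr, st2$features, k = 7,
                         rho1_grid = c(1, 5), rho2_grid = c(0, 15),
                         rho3_grid = 0, folds = 2, seed = 1,
                         modules = st2$truth$module_of_gene_per_time)
  expect_true(all(c("report", "hyper") %in% names(gs)))
  expect_true(all(gs$report$stage %in% c(1L, 2L)))
  expect_true(gs$hyper$rho1 %in% c(1, 5))
})

test_that("filter_module_edges keeps only strong, consistently enriched edges", {
  st <- default_study()
  fit <- fit_drmn(st$expr, st$features, k = 7, hyper = drmn_hyper(5, 45, 0),
                  modules = st$truth$module_of_gene_per_time, seed = 1)
  kept <- filter_module_edges(fit, motif_gene_sets = NULL,
                              weight_min = 0.02, skip_enrichment = TRUE)
  expect_true(all(c("module", "feature", "kept", "reason") %in% names(kept)))
  small <- kept[!kept$kept & kept$reason == "weight", ]
  # every rejected-by-weight edge really is below the cutoff at all times
  for (i in seq_len(min(nrow(small), 5))) {
    w <- fit$theta[small$feature[i], , small$module[i]]
    expect_lt(max(abs(w)), 0.02 + 1e-12)
  }
})

test_that("prioritize_regulators separates stepping from constant programs", {
  # membership is held fixed so the soft-threshold bias (which scales with
  # module size) is identical in both windows and only coefficient steps
  # separate the two groups
  st <- simulate_study(sim_config(seed = 1, transition_fraction = 0))
  fit <- fit_drmn(st$expr, st$features, k = 7, hyper = drmn_hyper(5, 0, 0),
                  modules = st$truth$module_of_gene_per_time, seed = 1)
  pr <- prioritize_regulators(fit, boundary = 1, alpha = 0.05)
  expect_true(all(c("tests", "ranking") %in% names(pr)))
  tt <- st$truth$theta_true
  key <- paste0(pr$tests$module, ":", pr$tests$feature)
  truth_step <- unlist(lapply(1:7, function(k) {
    paste0(k, ":", rownames(tt)[tt[, k, 1] != 0 & tt[, k, 5] != tt[, k, 1]])
  }))
  flagged <- key[pr$tests$p < 0.05]
  expect_gte(mean(flagged %in% truth_step), 0.8)
  expect_gte(mean(truth_step %in% flagged), 0.8)
})
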