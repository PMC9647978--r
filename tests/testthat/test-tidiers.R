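test_that("escarole tidiers flatten assignments and summarize the fit", {
  st <- default_study()
  fit <- fit_modules(st$expr, k = 7, seed = 1)
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(fit$assignments) * ncol(fit$assignments))
  expect_equal(names(td), c("gene_id", "time", "module"))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$k, 7)
  expect_equal(gl$n_transitioning, length(find_transitioning_genes(fit)))
})

test_that("drmn tidiers expose every coefficient including exact zeros", {
  st <- default_study()
  fit <- fit_drmn(st$expr, st$features, k = 7, hyper = drmn_hyper(5, 45, 0),
                  modules = st$truth$module_of_gene_per_time, seed = 1)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 7 * 8 * length(st$features$features))
  expect_equal(sum(td$weight != 0), sum(fit$theta != 0))
  gl <- generics::glance(fit)
  expect_equal(gl$n_nonzero, sum(fit$theta != 0))
  expect_equal(gl$rho2, 45)
})

test_that("transitioning-set tidiers return membership and counts", {
  prof <- rbind(matrix(rep(c(1, 1, 2, 2), each = 12), 12),
                matrix(rep(c(2, 2, 1, 1), each = 11), 11))
  rownames(prof) <- sprintf("g%02d", 1:23)
  cl <- cluster_transitioning(prof, distance_threshold = 0.26, min_size = 10)
  expect_equal(generics::tidy(cl), cl$sets)
  gl <- generics::glance(cl)
  expect_equal(gl$n_sets, 2)
  expect_equal(gl$n_genes, 23)
})

test_that("autoplot methods build ggplot objects", {
  st <- default_study()
  fit <- fit_modules(st$expr, k = 7, seed = 1)
  p1 <- ggplot2::autoplot(fit)
  expect_s3_class(p1, "ggplot")
  dfit <- fit_drmn(st$expr, st$features, k = 7, hyper = drmn_hyper(5, 45, 0),
                   modules = st$truth$module_of_gene_per_time, seed = 1)
  p2 <- ggplot2::autoplot(dfit, modules = 1:2)
  expect_s3_class(p2, "ggplot")
  # plots render without error
  expect_silent(ggplot2::ggplot_build(p1))
  expect_silent(ggplot2::ggplot_build(p2))
})
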