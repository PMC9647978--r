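test_that("sim_config validates inputs and fills derived defaults", {
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_timepoints, 8L)
  expect_equal(cfg$mean_separation, 10 * cfg$noise_sd)
  expect_error(sim_config(times = c(2, 1)), "strictly increasing")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(transition_fraction = 1.5), "transition_fraction")
  expect_error(sim_config(active_motifs_per_module = 99), "active_motifs_per_module")
  expect_error(sim_config(times = c(0, 0.5, 1)), "after the 1 h boundary")
})

test_that("the generator is deterministic in the master seed", {
  s1 <- simulate_study(sim_config(n_genes = 60, seed = 5))
  s2 <- simulate_study(sim_config(n_genes = 60, seed = 5))
  s3 <- simulate_study(sim_config(n_genes = 60, seed = 6))
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$features$values, s2$features$values)
  expect_identical(s1$truth$theta_true, s2$truth$theta_true)
  expect_false(identical(s1$expr$value, s3$expr$value))
})

test_that("module switching happens exactly at the 1->2 h boundary", {
  cfg <- sim_config(n_genes = 100, seed = 3)
  ex <- simulate_expression(cfg)
  am <- ex$truth$module_of_gene_per_time
  # constant within each side of the boundary (times <= 1 are columns 1:4)
  expect_true(all(am[, 1] == am[, 2] & am[, 2] == am[, 3] & am[, 3] == am[, 4]))
  expect_true(all(am[, 5] == am[, 6] & am[, 6] == am[, 7] & am[, 7] == am[, 8]))
  switchers <- ex$truth$transitioning_gene_ids
  expect_length(switchers, floor(0.2 * 100))
  moved <- rownames(am)[am[, 4] != am[, 5]]
  expect_setequal(moved, switchers)
})

test_that("replicate values concentrate on module mean + delta as noise_sd -> 0", {
  cfg <- sim_config(n_genes = 40, noise_sd = 1e-7, mean_separation = 1,
                    seed = 2)
  fe <- simulate_features(cfg)
  ex <- simulate_expression(cfg, delta = fe$delta)
  am <- ex$truth$module_of_gene_per_time
  mu <- ex$truth$module_means
  wide <- tidyr::pivot_wider(ex$expr, names_from = "replicate",
                             values_from = "value")
  gi <- match(wide$gene_id, rownames(am))
  ci <- match(as.character(wide$time), colnames(am))
  expected <- mu[am[cbind(gi, ci)]] + fe$delta[cbind(gi, ci)]
  for (col in c("1", "2", "3")) {
    expect_equal(wide[[col]], expected, tolerance = 1e-4)
  }
})

test_that("coef_magnitude = 0 decouples features from expression", {
  cfg <- sim_config(n_genes = 150, coef_magnitude = 0, seed = 4)
  fe <- simulate_features(cfg)
  expect_true(all(fe$theta_true == 0))
  expect_true(all(fe$delta == 0))
  ex <- simulate_expression(cfg, delta = fe$delta)
  xm <- expr_profile_matrix(ex$expr)
  am <- ex$truth$module_of_gene_per_time
  # within-module correlation between any motif feature and expression is
  # zero up to Monte-Carlo error
  cors <- numeric(0)
  for (cc in c(1L, 5L)) {
    for (k in 1:3) {
      g <- which(am[, cc] == k)
      for (m in c(1L, 20L, 40L)) {
        cors <- c(cors, cor(xm[g, cc], fe$features$values[g, m, cc]))
      }
    }
  }
  expect_lt(max(abs(cors)), 4 / sqrt(150 / 7))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("planted coefficients step only at the boundary for a planted subset", {
  cfg <- sim_config(seed = 11)
  fe <- simulate_features(cfg)
  th <- fe$theta_true
  for (k in seq_len(cfg$n_modules)) {
    early <- th[, k, 1]; late <- th[, k, 5]
    expect_equal(th[, k, 2], early)
    expect_equal(th[, k, 4], early)
    expect_equal(th[, k, 6], late)
    expect_equal(th[, k, 8], late)
    active <- which(early != 0)
    expect_length(active, cfg$active_motifs_per_module)
    stepping <- which(early != 0 & late != early)
    expect_length(stepping, ceiling(cfg$step_fraction *
                                      cfg$active_motifs_per_module))
    expect_equal(late[stepping], early[stepping] * cfg$step_multiplier)
    expect_equal(unname(abs(early[active])),
                 rep(cfg$coef_magnitude * cfg$feature_signal_sd,
                     length(active)))
  }
})

test_that("annotation geometry matches the configured layout", {
  cfg <- sim_config(n_genes = 30, seed = 8)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 30)
  expect_equal(diff(ann$genes$tss), rep(cfg$gene_spacing, 29))
  expect_equal(ann$chrom_sizes$length, 30L * cfg$gene_spacing)
  # every motif instance lies inside its gene's oriented -10 kbp..+1 kbp window
  m <- dplyr::left_join(ann$motifs, ann$genes,
                        by = c("gene_id", "chrom", "strand"))
  ctr <- (m$start + m$end) / 2
  d <- ifelse(m$strand == "+", ctr - m$tss, m$tss - ctr)
  expect_true(all(d >= -10000 & d <= 1000))
  expect_error(simulate_annotation(sim_config(n_genes = 30, chrom_length = 100)),
               "cannot hold")
})

test_that("planted peak scenarios produce the documented universal answer", {
  cfg <- sim_config(n_genes = 9, seed = 10)
  ann <- simulate_annotation(cfg)
  cp <- simulate_coverage_peaks(cfg, ann)
  expect_length(cp$peaks, cfg$n_timepoints)
  sc <- table(cp$scenario)
  expect_equal(sort(names(sc)), c("containment", "identical", "partial"))
  # identical/containment loci contribute one universal peak, partial two
  n_partial <- sum(cp$scenario == "partial")
  expect_equal(nrow(cp$universal_truth), 9 + n_partial)
  # coverage tracks are piecewise-constant and non-negative, covering chr1
  for (cov in cp$coverage) {
    expect_true(all(cov$score > 0))
    expect_equal(min(cov$start), 0L)
    expect_equal(max(cov$end), ann$chrom_sizes$length[1])
  }
})
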