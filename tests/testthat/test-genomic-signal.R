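make_track <- function() {
  runs <- tibble::tibble(chrom = "chr1",
                         start = c(0L, 100L, 200L),
                         end = c(100L, 200L, 1000L),
                         score = c(2, 10, 2))
  coverage_track(runs, tibble::tibble(chrom = "chr1", length = 1000L))
}

test_that("coverage_track computes the genome-wide mean and validates runs", {
  tr <- make_track()
  expect_s3_class(tr, "coverage_track")
  expect_equal(tr$global_mean, (2 * 100 + 10 * 100 + 2 * 800) / 1000)
  bad <- tibble::tibble(chrom = "chr1", start = c(0L, 50L),
                        end = c(100L, 150L), score = c(1, 1))
  expect_error(coverage_track(bad, tibble::tibble(chrom = "chr1", length = 1000L)),
               "overlapping")
})

test_that("aggregate_region_signal reproduces hand-computed log ratios", {
  tr <- make_track()
  regions <- tibble::tibble(chrom = "chr1", start = c(100L, 0L),
                            end = c(200L, 1000L),
                            region_id = c("hot", "all"))
  out <- aggregate_region_signal(tr, regions, pseudo = 0)
  expect_equal(out$mean_coverage, c(10, tr$global_mean))
  expect_equal(out$signal, c(log2(10 / tr$global_mean), 0))
  # default pseudo of 1/width shifts, never errors on zero coverage
  zero <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L, score = 0)
  trz <- coverage_track(zero, tibble::tibble(chrom = "chr1", length = 1000L))
  expect_error(aggregate_region_signal(trz, regions[1, ], pseudo = 0),
               "all-zero")
})

test_that("quantile_normalize forces multiset-identical columns", {
  set.seed(1)
  m <- matrix(rnorm(60), 15, 4)
  q <- quantile_normalize(m)
  ref <- sort(q[, 1])
  for (j in 2:4) expect_equal(sort(q[, j]), ref)
  # rank order within columns preserved
  for (j in 1:4) expect_equal(order(q[, j]), order(m[, j]))
})

test_that("merge_universal_peaks applies identity, containment and Jaccard rules", {
  p1 <- tibble::tibble(chrom = "chr1", start = c(100L, 1000L, 5000L),
                       end = c(200L, 2000L, 5600L))
  p2 <- tibble::tibble(chrom = "chr1", start = c(100L, 1120L, 5400L),
                       end = c(200L, 1980L, 6000L))
  m <- merge_universal_peaks(list(t1 = p1, t2 = p2), jaccard_min = 0.9)
  expect_equal(nrow(m), 4)
  expect_equal(m$start, c(100L, 1000L, 5000L, 5400L))
  expect_equal(m$end, c(200L, 2000L, 5600L, 6000L))
  expect_equal(m$n_source, c(2L, 2L, 1L, 1L))
  # containment merges even though Jaccard < 0.9
  jac <- (1980 - 1120) / (2000 - 1000)
  expect_lt(jac, 0.9)
  # the documented toy example: [100,200) with [120,180) -> one peak
  ex <- merge_universal_peaks(list(
    t1 = tibble::tibble(chrom = "chr1", start = 100L, end = 200L),
    t2 = tibble::tibble(chrom = "chr1", start = 120L, end = 180L)))
  expect_equal(nrow(ex), 1)
  expect_equal(c(ex$start, ex$end), c(100L, 200L))
})

test_that("merging is transitive across time points", {
  sets <- list(
    t1 = tibble::tibble(chrom = "chr1", start = 0L, end = 100L),
    t2 = tibble::tibble(chrom = "chr1", start = 5L, end = 100L),
    t3 = tibble::tibble(chrom = "chr1", start = 5L, end = 105L))
  m <- merge_universal_peaks(sets, jaccard_min = 0.9)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end, m$n_peaks), c(0L, 105L, 3L))
})

test_that("annotate_peaks applies promoter-over-upstream precedence", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          tss = c(20000L, 60000L), strand = c("+", "-"))
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(19500L, 14900L, 60500L, 99000L),
                          end = c(19700L, 15100L, 61500L, 99200L),
                          name = paste0("p", 1:4))
  ann <- annotate_peaks(peaks, genes)
  expect_equal(ann$category, c("Promoter", "Upstream", "Promoter", "other"))
  expect_equal(ann$gene_id, c("a", "a", "b", NA))
  # strand orientation: p3 center 61000 is upstream of b on '-' => distance -1000
  expect_equal(ann$distance[3], -1000)
})

test_that("map_peaks_to_genes matches a brute-force window scan", {
  set.seed(7)
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:12), chrom = "chr1",
                          tss = sort(sample.int(2e5, 12)),
                          strand = sample(c("+", "-"), 12, replace = TRUE))
  starts <- sort(sample.int(2e5, 40))
  peaks <- tibble::tibble(chrom = "chr1", start = starts,
                          end = starts + sample(100:400, 40, replace = TRUE),
                          name = sprintf("p%02d", 1:40))
  up <- 10000; down <- 1000
  got <- map_peaks_to_genes(peaks, genes, upstream = up, downstream = down) |>
    dplyr::arrange(peak_id, gene_id)
  centers <- as.integer(floor((peaks$start + peaks$end) / 2))
  brute <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      d <- if (genes$strand[j] == "+") centers[i] - genes$tss[j] else
        genes$tss[j] - centers[i]
      if (d >= -up && d <= down) {
        brute[[length(brute) + 1]] <- tibble::tibble(
          peak_id = peaks$name[i], gene_id = genes$gene_id[j], distance = d)
      }
    }
  }
  brute <- dplyr::bind_rows(brute) |> dplyr::arrange(peak_id, gene_id)
  expect_equal(as.data.frame(got), as.data.frame(brute))
})

test_that("aggregate_motif_features builds a normalized tensor over instances", {
  cfg <- sim_config(n_genes = 12, seed = 9)
  st <- simulate_study(cfg)
  tracks <- purrr::map(st$coverage_peaks$coverage, coverage_track,
                       chrom_sizes = st$annotation$chrom_sizes)
  ft <- aggregate_motif_features(tracks, st$annotation$motifs,
                                 st$annotation$genes, times = cfg$times)
  expect_s3_class(ft, "feature_tensor")
  expect_equal(dim(ft$values), c(12, length(unique(st$annotation$motifs$motif_id)), 8))
  expect_equal(ft$times, cfg$times)
  # the normalized tensor is exactly the quantile-normalized raw tensor
  # (piecewise-constant coverage makes many instance signals tie, so the
  # columns are not multiset-identical; ranks must still be preserved)
  flat <- matrix(ft$values, ncol = 8)
  raw <- aggregate_motif_features(tracks, st$annotation$motifs,
                                  st$annotation$genes, times = cfg$times,
                                  normalize = FALSE)
  rawflat <- matrix(raw$values, ncol = 8)
  expect_equal(unname(flat), unname(as.matrix(quantile_normalize(rawflat))))
  for (j in 1:8) expect_equal(rank(flat[, j]), rank(rawflat[, j]))
})
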