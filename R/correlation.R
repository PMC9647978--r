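# Permutation-based significance of Pearson correlation between expression
# and accessibility time profiles.

#' Permutation test for the correlation of two time profiles
#'
#' Computes the Pearson correlation of two zero-meaned profiles and a
#' permutation p-value from random re-orderings of one profile's time
#' points. The default (`alternative = "magnitude"`) p-value estimates the
#' probability of a permuted correlation at least as large in magnitude as
#' the observed one, with positive and negative correlations reported
#' separately through the `sign` column; `alternative = "directed"` counts
#' only permutations at least as extreme in the observed direction. Both
#' use the add-one estimator `(1 + count) / (1 + n_perm)`, which can never
#' return zero and is a valid (conservative) permutation p-value.
#'
#' @param a,b Numeric profiles of equal length (>= 3), both non-constant.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed.
#' @param alternative `"magnitude"` (default) or `"directed"`.
#' @return Tibble with `r`, `p`, `sign` and `n_perm`.
#' @export
permutation_correlation_test <- function(a, b, n_perm = 1000, seed = NULL,
                                         alternative = c("magnitude", "directed")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b) || length(a) < 3) {
    stop_bad_arg("profiles must share length >= 3")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop_bad_arg("constant profile: correlation undefined")
  }
  a <- a - mean(a); b <- b - mean(b)
  r_obs <- cor(a, b)
  with_seed(seed, {
    r_null <- vapply(seq_len(n_perm), function(i) cor(a, sample(b)),
                     numeric(1))
    count <- if (alternative == "magnitude") {
      sum(abs(r_null) >= abs(r_obs))
    } else if (r_obs >= 0) sum(r_null >= r_obs) else sum(r_null <= r_obs)
    tibble(r = r_obs, p = (1 + count) / (1 + n_perm),
           sign = ifelse(r_obs >= 0, "positive", "negative"),
           n_perm = as.integer(n_perm))
  })
}

profile_matrix_of <- function(x) {
  if (is.matrix(x)) x else expr_profile_matrix(x)
}

#' Correlate promoter accessibility with expression, gene by gene
#'
#' Runs [permutation_correlation_test()] for every gene shared between the
#' expression profiles and the promoter signal matrix, with per-gene child
#' seeds derived from `seed`. Genes with a constant profile or without a
#' promoter signal are skipped and counted.
#'
#' @param expr Long expression tibble or a genes x times profile matrix.
#' @param promoter_signals Genes x times matrix of promoter accessibility
#'   signals (rownames = gene ids).
#' @param n_perm Permutations per gene.
#' @param alpha Per-gene significance level (no multiple-testing
#'   correction, matching the genome-wide screening usage).
#' @param seed Master seed.
#' @param alternative Passed to [permutation_correlation_test()].
#' @return Tibble with `gene_id`, `r`, `p`, `sign`, `significant`; the
#'   counts of significant positive/negative genes and skipped genes are
#'   attached as attribute `"summary"` and shown by `summary()` on the
#'   result of this function.
#' @export
correlate_promoter_expression <- function(expr, promoter_signals,
                                          n_perm = 1000, alpha = 0.05,
                                          seed = 1,
                                          alternative = "magnitude") {
  xm <- profile_matrix_of(expr)
  shared <- intersect(rownames(xm), rownames(promoter_signals))
  missing <- setdiff(rownames(xm), rownames(promoter_signals))
  if (length(missing)) {
    inform(sprintf("%d gene(s) without a promoter signal skipped", length(missing)))
  }
  res <- map(shared, function(g) {
    a <- xm[g, ]; b <- promoter_signals[g, ]
    if (sd(a) == 0 || sd(b) == 0) return(NULL)
    out <- permutation_correlation_test(a, b, n_perm = n_perm,
                                        seed = child_seed(seed, g),
                                        alternative = alternative)
    mutate(out, gene_id = g, .before = 1)
  }) |> list_rbind()
  res <- mutate(res, significant = .data$p <= alpha)
  attr(res, "summary") <- tibble(
    n_tested = nrow(res),
    n_significant = sum(res$significant),
    n_positive = sum(res$significant & res$sign == "positive"),
    n_negative = sum(res$significant & res$sign == "negative"),
    n_skipped = length(missing) + (length(shared) - nrow(res)),
    alpha = alpha)
  res
}

#' Most-correlated peak per gene
#'
#' For each gene with mapped peaks, selects the peak whose signal profile
#' maximizes the absolute Pearson correlation with the gene's expression
#' profile (ties broken by smaller absolute TSS distance, then
#' lexicographic peak id), and applies the permutation test to the
#' selected pair. Genes without a mapped peak are omitted and counted in
#' the `"summary"` attribute.
#'
#' @param expr Long expression tibble or genes x times profile matrix.
#' @param peak_signals Peaks x times signal matrix (rownames = peak ids).
#' @param peak_gene_map Tibble from [map_peaks_to_genes()] (`peak_id`,
#'   `gene_id`, `distance`).
#' @inheritParams correlate_promoter_expression
#' @return Tibble with `gene_id`, `peak_id`, `distance`, `r`, `p`, `sign`,
#'   `significant`.
#' @export
best_peak_per_gene <- function(expr, peak_signals, peak_gene_map,
                               n_perm = 1000, alpha = 0.05, seed = 1,
                               alternative = "magnitude") {
  xm <- profile_matrix_of(expr)
  map_tbl <- filter(peak_gene_map,
                    .data$gene_id %in% rownames(xm),
                    .data$peak_id %in% rownames(peak_signals))
  omitted <- setdiff(unique(peak_gene_map$gene_id), unique(map_tbl$gene_id))
  res <- map(split(map_tbl, map_tbl$gene_id), function(mp) {
    g <- mp$gene_id[1]
    a <- xm[g, ]
    if (sd(a) == 0) return(NULL)
    rr <- vapply(mp$peak_id, function(pk) {
      b <- peak_signals[pk, ]
      if (sd(b) == 0) NA_real_ else cor(a - mean(a), b - mean(b))
    }, numeric(1))
    mp <- mutate(mp, r = rr) |> filter(!is.na(.data$r))
    if (!nrow(mp)) return(NULL)
    mp <- arrange(mp, dplyr::desc(abs(.data$r)), abs(.data$distance), .data$peak_id)
    best <- mp[1, ]
    out <- permutation_correlation_test(a, peak_signals[best$peak_id, ],
                                        n_perm = n_perm,
                                        seed = child_seed(seed, g),
                                        alternative = alternative)
    bind_cols(best[c("gene_id", "peak_id", "distance")], out)
  }) |> list_rbind()
  res <- mutate(res, significant = .data$p <= alpha)
  attr(res, "summary") <- tibble(
    n_tested = nrow(res),
    n_significant = sum(res$significant),
    n_omitted = length(omitted),
    alpha = alpha)
  res
}
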