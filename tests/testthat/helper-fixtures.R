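# Shared fixtures, built once per test run.

# Small default-config study used by several files; memoized.
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(sim_config(seed = 42))
    cache
  }
})

# Tiny random mtg_set for solver-level tests.
random_mtg_set <- function(n_genes = 5, n_motifs = 4, n_times = 4, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  vals <- array(rnorm(n_genes * n_motifs * n_times),
                c(n_genes, n_motifs, n_times))
  ft <- feature_tensor(vals, genes, sprintf("m%02d", seq_len(n_motifs)),
                       seq_len(n_times))
  xm <- matrix(rnorm(n_genes * n_times), n_genes, n_times,
               dimnames = list(genes, NULL))
  mtg_set_data(genes, xm, ft, set_id = "test")
}

# All permutations of 1..n (n small), for exhaustive enumeration checks.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
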