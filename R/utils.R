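# Internal helpers shared across modules.

#' Derive a deterministic child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed plus a stage label, so stages are independently reproducible: the
#' same stage re-run in isolation with the same master seed sees the same
#' random stream regardless of which other stages ran before it.
#'
#' The derivation is `(seed * 69069 + sum(utf8(label) * 31^i)) mod (2^31 - 1)`,
#' kept below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed Master integer seed.
#' @param label Character stage label.
#' @return An integer seed.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 31 + cp) %% m
  as.integer((as.numeric(seed) %% m * 69069 + h) %% m)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_bad_arg <- function(msg, ...) abort(sprintf(msg, ...), class = "regdyn_error")

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_bad_arg("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper))
  }
  invisible(x)
}

#' Reshape a long expression table to a gene-by-time profile matrix
#'
#' Replicates are averaged per (gene, time); rows are genes, columns are
#' time points in increasing time order.
#'
#' @param expr Tibble with columns `gene_id`, `time`, `replicate`, `value`.
#' @return Numeric matrix, genes x times, with dimnames.
#' @export
expr_profile_matrix <- function(expr) {
  stopifnot(all(c("gene_id", "time", "value") %in% names(expr)))
  wide <- expr |>
    group_by(.data$gene_id, .data$time) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "time", values_from = "value")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$gene_id
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

# Gene x replicate matrix for a single time point.
expr_replicate_matrix <- function(expr, time_point) {
  sub <- expr[expr$time == time_point, , drop = FALSE]
  wide <- tidyr::pivot_wider(sub[c("gene_id", "replicate", "value")],
                             names_from = "replicate", values_from = "value")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$gene_id
  m
}

#' Construct a regulatory feature tensor
#'
#' A feature tensor holds one genes-by-features signal matrix per time point
#' with a shared gene universe and feature set; it is the container the DRMN
#' and MTG-LASSO stages consume.
#'
#' @param values 3-d numeric array, genes x features x times.
#' @param genes,features Character identifiers for the first two dimensions.
#' @param times Numeric time points (hours) for the third dimension.
#' @return An object of class `feature_tensor`.
#' @export
feature_tensor <- function(values, genes, features, times) {
  stopifnot(length(dim(values)) == 3L,
            dim(values)[1] == length(genes),
            dim(values)[2] == length(features),
            dim(values)[3] == length(times))
  dimnames(values) <- list(genes, features, NULL)
  structure(
    list(values = values, genes = as.character(genes),
         features = as.character(features), times = as.numeric(times)),
    class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(sprintf("<feature_tensor> %d genes x %d features x %d time points\n",
              length(x$genes), length(x$features), length(x$times)))
  invisible(x)
}

#' @export
as_tibble.feature_tensor <- function(x, ...) {
  g <- length(x$genes); m <- length(x$features); k <- length(x$times)
  tibble(
    gene_id = rep(x$genes, times = m * k),
    feature = rep(rep(x$features, each = g), times = k),
    time    = rep(x$times, each = g * m),
    value   = as.vector(x$values))
}

# Slice a genes x features matrix for one time index.
tensor_slice <- function(tensor, time_index) {
  tensor$values[, , time_index, drop = TRUE]
}
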