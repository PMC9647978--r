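# Multi-task group LASSO over a transitioning gene set: each member gene
# is a task, each regulator motif is a group (its per-gene coefficient
# vector), and the group penalty selects motifs shared across the set.
# Includes leave-one-time-point-out selection frequency, randomized
# nulls with a Z-test, fractional-lambda selection, and edge building.

#' Assemble one gene set's multi-task regression data
#'
#' @param genes Character vector of member gene ids.
#' @param expr Long expression tibble or genes x times profile matrix.
#' @param features A `feature_tensor` (genes x motifs x times).
#' @param set_id Identifier carried through to edges.
#' @param center Subtract the per-time mean expression across the member
#'   genes (a shared intercept profile). A transitioning set shares one
#'   dominant trajectory -- the module-mean path all members follow --
#'   which no motif feature explains; centering removes it so the
#'   regression targets the gene-specific, feature-driven deviations.
#'   Requires >= 3 genes; default `FALSE` (raw trajectories).
#' @return An `mtg_set`: `x` (times x genes), `y` (times x motifs x
#'   genes), plus ids.
#' @export
mtg_set_data <- function(genes, expr, features, set_id = "set",
                         center = FALSE) {
  stopifnot(inherits(features, "feature_tensor"))
  xm <- profile_matrix_of(expr)
  genes <- as.character(genes)
  missing <- setdiff(genes, intersect(rownames(xm), features$genes))
  if (length(missing)) {
    stop_bad_arg("%d member gene(s) missing from expression or features",
                 length(missing))
  }
  times <- features$times
  if (length(times) < 3) stop_bad_arg("need >= 3 time points")
  G <- length(genes); M <- length(features$features); T <- length(times)
  x <- t(xm[genes, , drop = FALSE])                      # T x G
  if (center) {
    if (G < 3) stop_bad_arg("centering needs >= 3 member genes")
    x <- x - rowMeans(x)
  }
  gidx <- match(genes, features$genes)
  y <- array(0, dim = c(T, M, G))
  for (g in seq_len(G)) {
    y[, , g] <- t(features$values[gidx[g], , ])          # T x M
  }
  structure(list(x = x, y = y, genes = genes, motifs = features$features,
                 times = times, set_id = set_id),
            class = "mtg_set")
}

#' @export
print.mtg_set <- function(x, ...) {
  cat(sprintf("<mtg_set '%s'> %d genes x %d motifs x %d times\n",
              x$set_id, length(x$genes), length(x$motifs), length(x$times)))
  invisible(x)
}

#' Smallest group penalty that zeroes every motif group
#'
#' @param set An [mtg_set_data()] object (optionally row-subset).
#' @return A single number: `max` over motifs of the L2 norm of the
#'   per-gene gradient at zero.
#' @export
mtg_lambda_max <- function(set) {
  M <- length(set$motifs); G <- length(set$genes)
  b <- matrix(0, M, G)
  for (g in seq_len(G)) {
    b[, g] <- crossprod(set$y[, , g], set$x[, g])
  }
  max(sqrt(rowSums(b^2)))
}

subset_times <- function(set, keep) {
  out <- set
  out$x <- set$x[keep, , drop = FALSE]
  out$y <- set$y[keep, , , drop = FALSE]
  out$times <- set$times[keep]
  out
}

#' Fit the multi-task group LASSO for one gene set
#'
#' Minimizes `sum_g 0.5 ||x_g - sum_m Y_mg theta_mg||^2 +
#' lambda * sum_m sqrt(sum_g theta_mg^2)` by block coordinate descent
#' with exact group updates. `lambda` is by default a fraction of
#' [mtg_lambda_max()]; pass `fractional = FALSE` for an absolute penalty.
#'
#' @param set An `mtg_set`.
#' @param lambda Penalty level: in (0, 1] when fractional.
#' @param fractional Interpret `lambda` as a fraction of lambda_max.
#' @param tol,max_sweeps Solver controls.
#' @return List with `theta` (motifs x genes, rows exactly zero or free),
#'   `selected` (motif ids with nonzero group norm), `objective`,
#'   `obj_trace` (non-increasing), `lambda_abs`, `sweeps`, `converged`.
#' @export
fit_mtg_lasso <- function(set, lambda = 0.5, fractional = TRUE,
                          tol = 1e-6, max_sweeps = 10000) {
  stopifnot(inherits(set, "mtg_set"))
  if (fractional) {
    if (!is.numeric(lambda) || lambda <= 0 || lambda > 1) {
      stop_bad_arg("fractional lambda must lie in (0, 1]")
    }
    lambda_abs <- lambda * mtg_lambda_max(set)
  } else {
    check_number(lambda, "lambda", 0)
    lambda_abs <- lambda
  }
  res <- .mtg_bcd_cpp(set$x, set$y, lambda_abs,
                      matrix(0, length(set$motifs), length(set$genes)),
                      as.integer(max_sweeps), tol)
  if (!res$converged) {
    warn(sprintf("group-lasso solver hit max_sweeps = %d", max_sweeps))
  }
  theta <- res$theta
  dimnames(theta) <- list(set$motifs, set$genes)
  grp <- sqrt(rowSums(theta^2))
  # floating-point dust can survive the group-shrinkage boundary (e.g. at
  # the exact fractional lambda = 1 threshold); a norm this small is zero
  sel_tol <- 1e-10 * max(1, grp)
  theta[grp <= sel_tol, ] <- 0
  grp <- sqrt(rowSums(theta^2))
  list(theta = theta, selected = set$motifs[grp > 0],
       objective = res$objective, obj_trace = as.numeric(res$obj_trace),
       lambda_abs = lambda_abs, sweeps = res$sweeps,
       converged = res$converged)
}

#' Objective value of the multi-task group LASSO
#'
#' @param theta Motifs x genes coefficient matrix.
#' @param set An `mtg_set`.
#' @param lambda_abs Absolute group penalty.
#' @return A single number.
#' @export
mtg_objective <- function(theta, set, lambda_abs) {
  loss <- 0
  for (g in seq_along(set$genes)) {
    r <- set$x[, g] - set$y[, , g] %*% theta[, g]
    loss <- loss + 0.5 * sum(r^2)
  }
  loss + lambda_abs * sum(sqrt(rowSums(theta^2)))
}

#' Leave-one-time-point-out selection and predictive power
#'
#' Leaves out each time point in turn, refits on the rest (with the
#' fractional penalty re-anchored to the training lambda_max), counts how
#' often each motif is selected, and scores predictive power as the
#' Pearson correlation between predicted and observed expression across
#' member genes at the held-out time. A constant prediction vector makes
#' that fold's power missing.
#'
#' @inheritParams fit_mtg_lasso
#' @return List with `folds_selected` (named integer per motif),
#'   `fold_power` (length-T numeric, NA where undefined), `mean_power`,
#'   and `n_folds`.
#' @export
loo_selection <- function(set, lambda = 0.5, fractional = TRUE,
                          tol = 1e-6, max_sweeps = 10000) {
  T <- length(set$times)
  counts <- stats::setNames(integer(length(set$motifs)), set$motifs)
  power <- rep(NA_real_, T)
  for (t in seq_len(T)) {
    train <- subset_times(set, setdiff(seq_len(T), t))
    fit <- fit_mtg_lasso(train, lambda = lambda, fractional = fractional,
                         tol = tol, max_sweeps = max_sweeps)
    counts[fit$selected] <- counts[fit$selected] + 1L
    pred <- vapply(seq_along(set$genes), function(g) {
      sum(set$y[t, , g] * fit$theta[, g])
    }, numeric(1))
    obs <- set$x[t, ]
    if (sd(pred) > 0 && sd(obs) > 0) power[t] <- cor(pred, obs)
  }
  list(folds_selected = counts, fold_power = power,
       mean_power = mean(power, na.rm = TRUE), n_folds = T)
}

#' Null selection frequencies and significance per motif
#'
#' Breaks the expression-to-feature linkage `n_random` times (by default
#' permuting which member gene each expression profile belongs to),
#' recomputes leave-one-out selection counts, and tests each motif's
#' observed count against its null mean and SD with a one-sided Z-test.
#' A motif is significant when it was selected in at least `min_folds`
#' folds AND P < `alpha`. When the null SD is zero, P is 1 if the
#' observed count does not exceed the null mean, and otherwise falls back
#' to an exact binomial tail on the pooled null selection rate.
#'
#' @inheritParams fit_mtg_lasso
#' @param n_random Number of randomizations.
#' @param seed Seed for the randomizations.
#' @param min_folds Minimum folds-selected for significance.
#' @param alpha Significance level.
#' @param randomize `"genes"` (permute expression-to-gene assignment,
#'   default) or `"times"` (permute time order of expression).
#' @param test `"z"` (normal reference, default) or `"t"` (Student
#'   reference with `n_random - 1` df).
#' @param loo Optional precomputed [loo_selection()] result for the
#'   observed data.
#' @return Tibble: `motif`, `folds_selected`, `null_mean`, `null_sd`,
#'   `z`, `p`, `significant`; null count matrix in attribute `"null"`.
#' @export
null_selection <- function(set, lambda = 0.5, n_random = 40, seed = 1,
                           min_folds = 6, alpha = 0.05,
                           randomize = c("genes", "times"),
                           test = c("z", "t"),
                           fractional = TRUE, loo = NULL,
                           tol = 1e-6, max_sweeps = 10000) {
  randomize <- match.arg(randomize)
  test <- match.arg(test)
  loo <- loo %||% loo_selection(set, lambda = lambda, fractional = fractional,
                                tol = tol, max_sweeps = max_sweeps)
  T <- length(set$times)
  M <- length(set$motifs)
  null_counts <- matrix(0L, M, n_random, dimnames = list(set$motifs, NULL))
  for (i in seq_len(n_random)) {
    perm_set <- with_seed(child_seed(seed, paste0("null", i)), {
      ps <- set
      if (randomize == "genes") {
        ps$x <- set$x[, sample(ncol(set$x)), drop = FALSE]
      } else {
        ps$x <- set$x[sample(T), , drop = FALSE]
      }
      ps
    })
    nl <- loo_selection(perm_set, lambda = lambda, fractional = fractional,
                        tol = tol, max_sweeps = max_sweeps)
    null_counts[, i] <- nl$folds_selected
  }
  null_mean <- rowMeans(null_counts)
  null_sd <- apply(null_counts, 1, sd)
  obs <- loo$folds_selected
  p <- numeric(M)
  z <- numeric(M)
  for (m in seq_len(M)) {
    if (null_sd[m] > 0) {
      z[m] <- (obs[m] - null_mean[m]) / null_sd[m]
      p[m] <- if (test == "z") pnorm(z[m], lower.tail = FALSE) else
        pt(z[m], df = n_random - 1, lower.tail = FALSE)
    } else if (obs[m] <= null_mean[m]) {
      z[m] <- 0; p[m] <- 1
    } else {
      # degenerate null: exact binomial tail on the pooled selection rate
      z[m] <- Inf
      phat <- sum(null_counts[m, ]) / (n_random * T)
      p[m] <- pbinom(obs[m] - 1, T, phat, lower.tail = FALSE)
    }
  }
  out <- tibble(motif = set$motifs,
                folds_selected = as.integer(obs),
                null_mean = null_mean, null_sd = null_sd,
                z = z, p = p,
                significant = obs >= min_folds & p < alpha)
  attr(out, "null") <- null_counts
  attr(out, "loo") <- loo
  out
}

#' Choose the penalty level for one gene set
#'
#' Scans a fractional-lambda grid; at each level computes leave-one-out
#' predictive power and the number of significant regulators. The chosen
#' lambda has regulator:target ratio nearest `target_ratio` (ties broken
#' by higher mean predictive power, then smaller lambda). Sets whose grid
#' yields significant regulators at fewer than 2 points are marked
#' "no-model".
#'
#' @inheritParams null_selection
#' @param lambda_grid Fractional penalties to scan.
#' @param target_ratio Desired significant-regulator : member-gene ratio.
#' @return List with `lambda` (NA when no-model), `no_model` flag, and
#'   `report` (tibble per grid point: lambda, mean_power, n_significant,
#'   ratio).
#' @export
choose_lambda <- function(set, lambda_grid = c(seq(0.2, 0.9, by = 0.1), 0.99),
                          n_random = 40, seed = 1, min_folds = 6,
                          alpha = 0.05, target_ratio = 0.05,
                          tol = 1e-6, max_sweeps = 10000) {
  if (!length(lambda_grid)) stop_bad_arg("lambda grid is empty")
  G <- length(set$genes)
  rows <- map(sort(lambda_grid), function(lam) {
    loo <- loo_selection(set, lambda = lam, tol = tol, max_sweeps = max_sweeps)
    sig <- null_selection(set, lambda = lam, n_random = n_random,
                          seed = child_seed(seed, paste0("lam", lam)),
                          min_folds = min_folds, alpha = alpha, loo = loo,
                          tol = tol, max_sweeps = max_sweeps)
    tibble(lambda = lam, mean_power = loo$mean_power,
           n_significant = sum(sig$significant),
           ratio = sum(sig$significant) / G)
  })
  report <- list_rbind(rows)
  no_model <- sum(report$n_significant >= 1) < 2
  lambda <- NA_real_
  if (!no_model) {
    cand <- report |>
      filter(.data$n_significant >= 1) |>
      arrange(abs(.data$ratio - target_ratio),
              dplyr::desc(.data$mean_power), .data$lambda)
    lambda <- cand$lambda[1]
  }
  list(lambda = lambda, no_model = no_model, report = report)
}

#' Build the regulator-target edge list across gene sets
#'
#' @param set_results List of per-set results; each element needs
#'   `set_id`, `genes`, `theta` (motifs x genes) and `significant`
#'   (character vector of significant motif ids).
#' @return List with `edges` (tibble: motif, gene, weight, set_id) and
#'   `ranking` (tibble: motif, n_targets, total_weight; descending by
#'   distinct target count, ties by summed absolute weight).
#' @export
build_edges <- function(set_results) {
  edges <- map(set_results, function(res) {
    if (!length(res$significant)) return(NULL)
    tidyr::expand_grid(motif = res$significant, gene = res$genes) |>
      mutate(weight = purrr::map2_dbl(.data$motif, .data$gene,
                                      function(m, g) res$theta[m, g]),
             set_id = res$set_id)
  }) |> list_rbind()
  if (is.null(edges) || !nrow(edges)) {
    edges <- tibble(motif = character(), gene = character(),
                    weight = numeric(), set_id = character())
  }
  ranking <- edges |>
    summarise(n_targets = dplyr::n_distinct(.data$gene),
              total_weight = sum(abs(.data$weight)), .by = "motif") |>
    arrange(dplyr::desc(.data$n_targets), dplyr::desc(.data$total_weight),
            .data$motif)
  list(edges = edges, ranking = ranking)
}

#' Simulate a planted-regulator gene set for the multi-task group LASSO
#'
#' Builds one gene set in which a few regulator motifs truly drive the
#' member genes' expression over time and the remaining motifs are
#' decoys: per-motif per-gene accessibility profiles are standard normal
#' over time, expression is the planted linear combination plus Gaussian
#' noise. Planted coefficients have equal magnitude (random sign), as in
#' the main study generator, so the planted regulators' group signal
#' strengths are comparable and a single penalty level can recover all of
#' them.
#'
#' @param n_genes,n_regulators,n_decoys Scenario size.
#' @param times Time grid (default the 8-point study design).
#' @param coef_magnitude Magnitude of planted per-gene coefficients
#'   (sign random per gene).
#' @param noise_sd SD of the expression noise.
#' @param seed Seed.
#' @return An `mtg_set` with attribute `"truth"` (list: `regulators`,
#'   `theta_star`).
#' @export
simulate_mtg_set <- function(n_genes = 50, n_regulators = 3, n_decoys = 40,
                             times = c(0, 0.25, 0.5, 1, 2, 4, 8, 24),
                             coef_magnitude = 1, noise_sd = 0.3, seed = 1) {
  M <- n_regulators + n_decoys
  T <- length(times)
  motifs <- sprintf("m%03d", seq_len(M))
  genes <- sprintf("g%04d", seq_len(n_genes))
  regulators <- motifs[seq_len(n_regulators)]
  with_seed(child_seed(seed, "mtg_scenario"), {
    y <- array(rnorm(T * M * n_genes), dim = c(T, M, n_genes))
    # orthogonalize the planted regulators' profiles within each gene (and
    # rescale to the norm of a typical random profile) so each planted
    # regulator contributes an independent signal component of equal
    # strength -- the benchmark probes selection, not confounding
    if (n_regulators > 1) {
      for (g in seq_len(n_genes)) {
        q <- qr.Q(qr(y[, seq_len(n_regulators), g]))
        y[, seq_len(n_regulators), g] <- q * sqrt(T)
      }
    }
    theta_star <- matrix(0, M, n_genes, dimnames = list(motifs, genes))
    theta_star[seq_len(n_regulators), ] <-
      sample(c(-1, 1), n_regulators * n_genes, replace = TRUE) * coef_magnitude
    x <- matrix(0, T, n_genes)
    for (g in seq_len(n_genes)) {
      x[, g] <- y[, , g] %*% theta_star[, g] + rnorm(T, sd = noise_sd)
    }
    structure(list(x = x, y = y, genes = genes, motifs = motifs,
                   times = times, set_id = "planted"),
              class = "mtg_set",
              truth = list(regulators = regulators, theta_star = theta_star))
  })
}
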