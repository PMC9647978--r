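# Dynamic regulatory module networks: per-time expression modules (from
# the Gaussian-mixture module fit) coupled to fused-lasso multi-task
# regression of module expression on accessibility features, plus
# hyperparameter selection, cross-validation, edge filtering, and
# regulator prioritization across the early/late boundary.

zscore_features <- function(mat) {
  mu <- colMeans(mat)
  sdv <- apply(mat, 2, sd)
  sdv[sdv == 0] <- 1           # constant feature: centered to exact zero
  sweep(sweep(mat, 2, mu), 2, sdv, "/")
}

tensor_zscore <- function(features) {
  stopifnot(inherits(features, "feature_tensor"))
  out <- features
  for (cc in seq_along(features$times)) {
    out$values[, , cc] <- zscore_features(features$values[, , cc])
  }
  out
}

assignment_matrix_of <- function(modules, genes) {
  am <- if (inherits(modules, "escarole_fit")) modules$assignments else modules
  if (!is.matrix(am)) stop_bad_arg("`modules` must be an escarole_fit or an assignment matrix")
  missing <- setdiff(genes, rownames(am))
  if (length(missing)) {
    stop_bad_arg("%d gene(s) in the feature tensor lack module assignments",
                 length(missing))
  }
  am[genes, , drop = FALSE]
}

#' Fit a dynamic regulatory module network
#'
#' Groups genes into `k` expression modules per time point (via
#' [fit_modules()], unless assignments are supplied) and learns, for each
#' module, a fused-lasso regression of the module genes' expression on
#' their accessibility features jointly across time points. Features are
#' z-scored per time point and an unpenalized intercept is included, so
#' coefficient magnitudes are comparable across features and the
#' edge-weight threshold used downstream is scale-meaningful.
#'
#' @param expr Long expression tibble (`gene_id`, `time`, `replicate`,
#'   `expression`) or a genes x times replicate-mean matrix.
#' @param features A `feature_tensor` (genes x features x times).
#' @param k Number of modules (used only when `modules` is NULL).
#' @param hyper A [drmn_hyper()].
#' @param modules Optional `escarole_fit` or genes x times assignment
#'   matrix; when NULL, modules are fit from `expr`.
#' @param seed Seed for the module fit.
#' @param tol,max_iter Solver controls, passed to [fit_fused_lasso()].
#' @return A `drmn_fit`: `theta` (features x times x modules array with
#'   exact zeros), `intercepts` (modules x times), `assignments`,
#'   `module_sizes` (modules x times), `objective` per module,
#'   `obj_traces`, feature/time/gene metadata, and the module fit (if
#'   computed here).
#' @export
fit_drmn <- function(expr, features, k = 7, hyper = drmn_hyper(),
                     modules = NULL, seed = 1, tol = 1e-6, max_iter = 10000) {
  stopifnot(inherits(features, "feature_tensor"))
  xm <- profile_matrix_of(expr)
  genes <- intersect(rownames(xm), features$genes)
  if (!length(genes)) stop_bad_arg("expression and features share no genes")
  C <- length(features$times)
  if (ncol(xm) != C) stop_bad_arg("expression has %d time points, features %d",
                                  ncol(xm), C)
  module_fit <- NULL
  if (is.null(modules)) {
    module_fit <- fit_modules(expr, k = k, seed = seed)
    modules <- module_fit
  }
  am <- assignment_matrix_of(modules, genes)
  k <- max(am)
  xm <- xm[genes, , drop = FALSE]
  featz <- tensor_zscore(features)
  gidx <- match(genes, featz$genes)
  p <- length(featz$features)

  theta <- array(0, dim = c(p, C, k),
                 dimnames = list(featz$features, NULL, NULL))
  intercepts <- matrix(0, k, C)
  sizes <- matrix(0L, k, C)
  objective <- numeric(k)
  traces <- vector("list", k)
  skipped <- character(0)
  for (kk in seq_len(k)) {
    x_list <- vector("list", C); y_list <- vector("list", C)
    for (cc in seq_len(C)) {
      members <- which(am[, cc] == kk)
      sizes[kk, cc] <- length(members)
      if (!length(members)) {
        skipped <- c(skipped, sprintf("module %d at time index %d", kk, cc))
      }
      x_list[[cc]] <- xm[members, cc]
      y_list[[cc]] <- featz$values[gidx[members], , cc, drop = FALSE]
      dim(y_list[[cc]]) <- c(length(members), p)
      colnames(y_list[[cc]]) <- featz$features
    }
    fit <- fit_fused_lasso(x_list, y_list, hyper = hyper, intercept = TRUE,
                           tol = tol, max_iter = max_iter)
    theta[, , kk] <- fit$theta
    intercepts[kk, ] <- fit$intercepts
    objective[kk] <- fit$objective
    traces[[kk]] <- fit$obj_trace
  }
  if (length(skipped)) {
    inform(c("empty module/time combinations skipped:", skipped))
  }
  structure(list(theta = theta, intercepts = intercepts,
                 assignments = am, module_sizes = sizes,
                 objective = objective, obj_traces = traces,
                 genes = genes, features = featz$features,
                 times = featz$times, k = k, hyper = hyper,
                 module_fit = module_fit),
            class = "drmn_fit")
}

#' @export
print.drmn_fit <- function(x, ...) {
  nz <- sum(x$theta != 0)
  cat(sprintf("<drmn_fit> %d modules x %d times, %d features; %d nonzero coefficients\n",
              x$k, length(x$times), length(x$features), nz))
  cat(sprintf("  rho1 = %g, rho2 = %g, rho3 = %g; total objective %.4g\n",
              x$hyper$rho1, x$hyper$rho2, x$hyper$rho3, sum(x$objective)))
  invisible(x)
}

predict_expression <- function(fit, featz, am, genes) {
  C <- length(fit$times)
  gidx <- match(genes, featz$genes)
  pred <- matrix(NA_real_, length(genes), C, dimnames = list(genes, NULL))
  for (cc in seq_len(C)) {
    for (kk in seq_len(fit$k)) {
      members <- which(am[, cc] == kk)
      if (!length(members)) next
      Y <- featz$values[gidx[members], , cc, drop = FALSE]
      dim(Y) <- c(length(members), length(fit$features))
      pred[members, cc] <- fit$intercepts[kk, cc] +
        as.vector(Y %*% fit$theta[, cc, kk])
    }
  }
  pred
}

#' Cross-validate a DRMN fit
#'
#' Splits genes into folds (stratified by each gene's most frequent
#' module assignment), refits the fused-lasso regressions on the training
#' genes of every module, and reports the Pearson correlation between
#' predicted and measured expression of the held-out genes per (module,
#' time point), plus the overall mean.
#'
#' @inheritParams fit_drmn
#' @param folds Number of gene folds (>= 2).
#' @param modules Module assignments used throughout (an `escarole_fit`
#'   or matrix); when NULL they are fit once on all genes.
#' @return List with `by_cell` (tibble: fold, module, time, r, n_test),
#'   `by_module_time` (mean over folds), `mean_cor` (grand mean over all
#'   defined cells), and `skipped` module/fold combinations.
#' @export
cross_validate_drmn <- function(expr, features, k = 7, hyper = drmn_hyper(),
                                folds = 3, seed = 1, modules = NULL,
                                tol = 1e-6, max_iter = 10000) {
  if (folds < 2) stop_bad_arg("`folds` must be >= 2")
  xm <- profile_matrix_of(expr)
  genes <- intersect(rownames(xm), features$genes)
  xm <- xm[genes, , drop = FALSE]
  if (is.null(modules)) modules <- fit_modules(xm, k = k, seed = seed)
  am <- assignment_matrix_of(modules, genes)
  k <- max(am)
  C <- ncol(am)
  featz <- tensor_zscore(features)

  modal <- apply(am, 1, function(z) as.integer(names(which.max(table(z)))))
  fold_id <- integer(length(genes))
  skipped <- character(0)
  with_seed(child_seed(seed, "cv_folds"), {
    for (kk in sort(unique(modal))) {
      idx <- which(modal == kk)
      if (length(idx) < folds) {
        skipped <- c(skipped, sprintf("module %d (%d genes < %d folds)",
                                      kk, length(idx), folds))
        fold_id[idx] <- NA_integer_
        next
      }
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  if (length(skipped)) inform(c("modules skipped in cross-validation:", skipped))

  rows <- list()
  for (ff in seq_len(folds)) {
    test <- which(fold_id == ff)
    train <- which(!is.na(fold_id) & fold_id != ff)
    fit <- fit_drmn(xm[train, , drop = FALSE],
                    tensor_subset_genes(featz, genes[train]),
                    hyper = hyper,
                    modules = am[train, , drop = FALSE],
                    tol = tol, max_iter = max_iter)
    pred <- predict_expression(fit, featz, am[test, , drop = FALSE],
                               genes[test])
    for (cc in seq_len(C)) {
      for (kk in seq_len(k)) {
        members <- which(am[test, cc] == kk)
        if (length(members) < 3) next
        obs <- xm[test[members], cc]; hat <- pred[members, cc]
        if (sd(obs) == 0 || sd(hat) == 0) next
        rows[[length(rows) + 1]] <- tibble(
          fold = ff, module = kk, time = featz$times[cc],
          r = cor(obs, hat), n_test = length(members))
      }
    }
  }
  by_cell <- list_rbind(rows)
  if (!nrow(by_cell)) {
    by_cell <- tibble(fold = integer(), module = integer(), time = numeric(),
                      r = numeric(), n_test = integer())
  }
  by_module_time <- by_cell |>
    summarise(r = mean(.data$r), n_folds = dplyr::n(),
              .by = c("module", "time"))
  list(by_cell = by_cell, by_module_time = by_module_time,
       mean_cor = mean(by_cell$r), skipped = skipped)
}

tensor_subset_genes <- function(features, genes) {
  idx <- match(genes, features$genes)
  if (anyNA(idx)) stop_bad_arg("unknown gene(s) in tensor subset")
  out <- features
  out$values <- features$values[idx, , , drop = FALSE]
  out$genes <- genes
  out
}

#' Two-stage hyperparameter grid search for DRMN
#'
#' Stage 1 scans `rho1_grid` x `rho2_grid` (at the smallest `rho3`),
#' stage 2 fixes the chosen `rho1` and scans `rho2_grid` x `rho3_grid`.
#' Each setting is scored by mean cross-validated Pearson correlation;
#' ties go to the smaller hyperparameters.
#'
#' @inheritParams cross_validate_drmn
#' @param rho1_grid,rho2_grid,rho3_grid Non-empty penalty grids.
#' @return List with `hyper` (chosen [drmn_hyper()]) and `report` (tibble
#'   of stage, rho1, rho2, rho3, mean_cv_cor).
#' @export
drmn_grid_search <- function(expr, features, k = 7,
                             rho1_grid = c(1, seq(5, 60, by = 5), 75, 100),
                             rho2_grid = seq(0, 60, by = 15),
                             rho3_grid = c(0, 5, 15),
                             folds = 3, seed = 1, modules = NULL) {
  if (!length(rho1_grid) || !length(rho2_grid) || !length(rho3_grid)) {
    stop_bad_arg("all penalty grids must be non-empty")
  }
  xm <- profile_matrix_of(expr)
  if (is.null(modules)) {
    modules <- fit_modules(xm, k = k, seed = seed)
  }
  score <- function(rho1, rho2, rho3) {
    cv <- cross_validate_drmn(xm, features, hyper = drmn_hyper(rho1, rho2, rho3),
                              folds = folds, seed = seed, modules = modules)
    cv$mean_cor
  }
  s1 <- tidyr::expand_grid(rho1 = sort(rho1_grid), rho2 = sort(rho2_grid),
                           rho3 = min(rho3_grid))
  s1$mean_cv_cor <- purrr::pmap_dbl(s1, score)
  if (all(!is.finite(s1$mean_cv_cor))) stop_bad_arg("all grid settings degenerate")
  best1 <- s1 |> arrange(dplyr::desc(.data$mean_cv_cor), .data$rho1, .data$rho2) |>
    dplyr::slice(1)
  s2 <- tidyr::expand_grid(rho1 = best1$rho1, rho2 = sort(rho2_grid),
                           rho3 = sort(rho3_grid))
  s2$mean_cv_cor <- purrr::pmap_dbl(s2, score)
  best2 <- s2 |> arrange(dplyr::desc(.data$mean_cv_cor), .data$rho2, .data$rho3) |>
    dplyr::slice(1)
  report <- bind_rows(mutate(s1, stage = 1L, .before = 1),
                      mutate(s2, stage = 2L, .before = 1))
  list(hyper = drmn_hyper(best2$rho1, best2$rho2, best2$rho3),
       report = report)
}

#' Filter regulator-module edges by weight and motif enrichment
#'
#' Keeps a (module, feature) edge when (1) the coefficient magnitude
#' exceeds `weight_min` at one or more time points, and (2) the motif's
#' gene set is enriched in the module (hypergeometric test, BH q <
#' `enrichment_q`) at every time point. Dropped edges carry a reason code.
#'
#' @param model A `drmn_fit`.
#' @param motif_gene_sets Named list: feature name -> character vector of
#'   gene ids carrying that motif. Features without an entry fail the
#'   enrichment criterion unless `skip_enrichment = TRUE`.
#' @param weight_min Minimum max-over-time coefficient magnitude.
#' @param enrichment_q BH q-value threshold.
#' @param skip_enrichment Set TRUE to filter on weight only (explicit
#'   opt-out when motif gene sets are unavailable).
#' @return Tibble with `module`, `feature`, `max_abs_weight`, `kept`,
#'   `reason` ("" when kept, else "weight" / "enrichment").
#' @export
filter_module_edges <- function(model, motif_gene_sets = NULL,
                                weight_min = 0.02, enrichment_q = 0.05,
                                skip_enrichment = FALSE) {
  stopifnot(inherits(model, "drmn_fit"))
  if (is.null(motif_gene_sets) && !skip_enrichment) {
    stop_bad_arg("`motif_gene_sets` missing; pass skip_enrichment = TRUE to filter on weight only")
  }
  C <- length(model$times)
  background <- model$genes
  enriched_all_times <- function(feature, module) {
    gs <- motif_gene_sets[[feature]]
    if (is.null(gs)) return(FALSE)
    for (cc in seq_len(C)) {
      cluster <- model$genes[model$assignments[, cc] == module]
      if (!length(cluster)) return(FALSE)
      res <- hypergeom_enrichment(cluster, list(set = intersect(gs, background)),
                                  background, q_max = enrichment_q)
      if (!res$significant[1]) return(FALSE)
    }
    TRUE
  }
  rows <- list()
  for (kk in seq_len(model$k)) {
    w <- apply(abs(model$theta[, , kk, drop = FALSE]), 1, max)
    for (j in seq_along(model$features)) {
      keep_w <- w[j] > weight_min
      reason <- ""
      kept <- FALSE
      if (!keep_w) {
        reason <- "weight"
      } else if (skip_enrichment) {
        kept <- TRUE
      } else if (enriched_all_times(model$features[j], kk)) {
        kept <- TRUE
      } else {
        reason <- "enrichment"
      }
      rows[[length(rows) + 1]] <- tibble(
        module = kk, feature = model$features[j],
        max_abs_weight = unname(w[j]), kept = kept, reason = reason)
    }
  }
  list_rbind(rows)
}

pooled_t_test <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  m1 <- mean(x1); m2 <- mean(x2)
  ss <- sum((x1 - m1)^2) + sum((x2 - m2)^2)
  df <- n1 + n2 - 2
  sp <- sqrt(ss / df)
  if (sp == 0) {
    if (m1 == m2) return(list(t = 0, p = 1))
    return(list(t = sign(m1 - m2) * Inf, p = 0))
  }
  tt <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), df))
}

#' Prioritize regulators by coefficient change across the boundary
#'
#' For every (module, feature), compares the fitted coefficient values in
#' the early window against the late window with a pooled two-sample
#' two-sided t-test; a regulator is selected when P < `alpha`. Regulators
#' are additionally ranked by the number of modules in which they are
#' selected.
#'
#' @param model A `drmn_fit`.
#' @param boundary Last time point of the early window (default 1, i.e.
#'   hours 0-1 vs 2-24; set 2 for the 0-2 vs 4-24 variant).
#' @param alpha Significance level (raw P, no correction).
#' @return List with `tests` (module, feature, t, p, mean_early,
#'   mean_late, selected) and `ranking` (feature, n_modules_selected,
#'   ordered descending).
#' @export
prioritize_regulators <- function(model, boundary = 1, alpha = 0.05) {
  stopifnot(inherits(model, "drmn_fit"))
  early <- which(model$times <= boundary)
  late <- which(model$times > boundary)
  if (length(early) < 2 || length(late) < 2) {
    stop_bad_arg("each window needs >= 2 time points (boundary = %g gives %d vs %d)",
                 boundary, length(early), length(late))
  }
  rows <- list()
  for (kk in seq_len(model$k)) {
    for (j in seq_along(model$features)) {
      x1 <- model$theta[j, early, kk]
      x2 <- model$theta[j, late, kk]
      tt <- pooled_t_test(x1, x2)
      rows[[length(rows) + 1]] <- tibble(
        module = kk, feature = model$features[j],
        t = tt$t, p = tt$p,
        mean_early = mean(x1), mean_late = mean(x2),
        selected = tt$p < alpha)
    }
  }
  tests <- list_rbind(rows)
  ranking <- tests |>
    summarise(n_modules_selected = sum(.data$selected), .by = "feature") |>
    arrange(dplyr::desc(.data$n_modules_selected), .data$feature)
  list(tests = tests, ranking = ranking)
}
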