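# Non-stationary expression clustering: per-time-point Gaussian mixtures
# over replicate vectors sharing k across time, k-means initialized, with
# module labels aligned by expression level. Downstream: transitioning-gene
# extraction, mismatch-distance clustering, set F-scores and hypergeometric
# enrichment.

# One EM fit at a single time point, k-means initialized with several
# restarts (best final log-likelihood kept, guarding against EM local
# optima that merge or split components), with the log-likelihood trace
# recorded. Falls back to a conjugate prior on the component covariances
# when the unregularized M-step degenerates.
fit_gmm_one_time <- function(data, k, max_iter, tol = 1e-8, n_init = 5) {
  n <- nrow(data)
  if (k > n) stop_bad_arg("k = %d exceeds the %d available genes", k, n)
  model <- if (ncol(data) == 1) "V" else "VVV"
  if (k == 1) {
    # single component: closed-form Gaussian fit, no EM needed
    fit <- mclust::mvn(if (ncol(data) == 1) "X" else "XXX", data = data)
    df <- mclust::nMclustParams(if (ncol(data) == 1) "X" else "XXX",
                                d = ncol(data), G = 1)
    mu <- mean(as.numeric(fit$parameters$mean))
    return(list(labels = rep(1L, n), loglik = fit$loglik, trace = fit$loglik,
                bic = 2 * fit$loglik - df * log(n), df = df,
                means = mu, regularized = FALSE))
  }
  # model-specific M/E-step functions: mclust's generic mstep()/estep()
  # build unqualified calls that fail unless mclust is attached
  mstep_fn <- if (model == "V") mclust::mstepV else mclust::mstepVVV
  estep_fn <- if (model == "V") mclust::estepV else mclust::estepVVV
  run_em <- function(z, prior) {
    trace <- numeric(0)
    zz <- z
    params <- NULL
    for (it in seq_len(max_iter)) {
      ms <- mstep_fn(data = data, z = zz, prior = prior)
      es <- estep_fn(data = data, parameters = ms$parameters)
      if (is.na(es$loglik)) return(NULL)
      trace <- c(trace, es$loglik)
      zz <- es$z
      params <- ms$parameters
      if (it > 1 && abs(trace[it] - trace[it - 1]) <=
            tol * (1 + abs(trace[it]))) break
    }
    list(z = zz, parameters = params, loglik = tail(trace, 1), trace = trace)
  }
  # initial partitions: deterministic model-based hierarchical clustering
  # plus several multi-start k-means runs
  inits <- list(tryCatch(
    as.integer(mclust::hclass(mclust::hc(data, modelName = if (model == "V") "V" else "VVV"), k)),
    error = function(e) NULL))
  for (init in seq_len(max(1L, n_init))) {
    km <- kmeans(data, centers = k, nstart = 25)
    inits <- c(inits, list(km$cluster))
  }
  inits <- inits[!vapply(inits, is.null, logical(1))]
  fit <- NULL
  regularized <- FALSE
  for (cl in inits) {
    z <- mclust::unmap(cl, groups = seq_len(k))
    cand <- run_em(z, prior = NULL)
    cand_reg <- FALSE
    if (is.null(cand)) {
      cand <- run_em(z, prior = mclust::priorControl())
      cand_reg <- TRUE
    }
    if (!is.null(cand) && (is.null(fit) || cand$loglik > fit$loglik)) {
      fit <- cand
      regularized <- cand_reg
    }
  }
  if (is.null(fit)) stop_bad_arg("EM failed even with covariance regularization")
  if (regularized) warn("degenerate component covariance; prior regularization applied")
  means <- fit$parameters$mean
  comp_mean <- if (is.matrix(means)) colMeans(means) else as.numeric(means)
  # relabel so module 1 has the lowest expression level
  ord <- order(comp_mean)
  relabel <- match(seq_len(k), ord)
  labels <- relabel[max.col(fit$z)]
  df <- mclust::nMclustParams(model, d = ncol(data), G = k)
  list(labels = labels, loglik = fit$loglik, trace = fit$trace,
       bic = 2 * fit$loglik - df * log(n), df = df,
       means = sort(comp_mean), regularized = regularized)
}

#' Fit per-time-point expression-level modules
#'
#' Non-stationary clustering of an expression time course: at each time
#' point the per-gene replicate vectors are modelled with a k-component
#' Gaussian mixture with unconstrained ("non-fixed") covariance,
#' initialized from k-means labels and fit by EM; genes receive hard
#' assignments by maximum posterior. Module labels are aligned across time
#' points by sorting component means, so module 1 is always the lowest
#' expression level and module k the highest.
#'
#' @param expr Long expression tibble (`gene_id`, `time`, `replicate`,
#'   `value`) of normalized log expression.
#' @param k Number of modules per time point.
#' @param max_iter Maximum EM iterations per time point (default 100).
#' @param seed Optional seed for the k-means initializations.
#' @return Object of class `escarole_fit` with `assignments` (genes x
#'   times integer matrix, labels 1..k ordered by expression level),
#'   `report` (per-time log-likelihood, BIC, parameter count),
#'   `module_means`, and `loglik_trace` per time point.
#' @export
fit_modules <- function(expr, k = 7, max_iter = 100, seed = NULL) {
  check_number(k, "k", 1)
  times <- sort(unique(expr$time))
  with_seed(seed, {
    fits <- map(times, function(tp) {
      data <- expr_replicate_matrix(expr, tp)
      fit_gmm_one_time(data, k = k, max_iter = max_iter)
    })
    genes <- rownames(expr_replicate_matrix(expr, times[1]))
    assignments <- vapply(fits, `[[`, integer(length(genes)), "labels")
    if (is.null(dim(assignments))) {
      assignments <- matrix(assignments, nrow = length(genes))
    }
    dimnames(assignments) <- list(genes, as.character(times))
    structure(list(
      assignments = assignments,
      k = as.integer(k),
      times = times,
      report = tibble(time = times,
                      loglik = map_dbl(fits, "loglik"),
                      bic = map_dbl(fits, "bic"),
                      df = map_dbl(fits, "df"),
                      regularized = map_lgl(fits, "regularized")),
      module_means = vapply(fits, `[[`, numeric(k), "means"),
      loglik_trace = map(fits, "trace")),
      class = "escarole_fit")
  })
}

#' @export
print.escarole_fit <- function(x, ...) {
  cat(sprintf("<escarole_fit> %d genes x %d time points, k = %d modules\n",
              nrow(x$assignments), length(x$times), x$k))
  cat(sprintf("  transitioning genes: %d\n", length(find_transitioning_genes(x))))
  invisible(x)
}

#' Select the number of expression modules
#'
#' Fits [fit_modules()] for each candidate `k` and reports the mean
#' silhouette width per time point (Euclidean distance on replicate
#' vectors) together with the summed BIC-corrected likelihood. The chosen
#' `k` maximizes mean silhouette among candidates whose BIC is within 1%
#' of the best; ties go to the smaller `k`.
#'
#' @inheritParams fit_modules
#' @param k_grid Candidate module counts (each >= 2).
#' @return List with `chosen_k`, `report` tibble and the `escarole_fit`
#'   for the chosen k.
#' @export
select_k <- function(expr, k_grid, max_iter = 100, seed = NULL) {
  k_grid <- sort(unique(as.integer(k_grid)))
  if (!length(k_grid) || any(k_grid < 2)) {
    stop_bad_arg("`k_grid` must be a non-empty set of integers >= 2")
  }
  if (sd(expr$value) == 0) {
    stop_bad_arg("constant expression: no clustering structure, silhouette undefined")
  }
  times <- sort(unique(expr$time))
  data_by_time <- map(times, function(tp) expr_replicate_matrix(expr, tp))
  dists <- map(data_by_time, dist)
  with_seed(seed, {
    rows <- map(k_grid, function(k) {
      fit <- fit_modules(expr, k = k, max_iter = max_iter)
      sil <- map_dbl(seq_along(times), function(i) {
        lab <- fit$assignments[, i]
        if (length(unique(lab)) < 2) return(NA_real_)
        mean(cluster::silhouette(lab, dists[[i]])[, "sil_width"])
      })
      tibble(k = k, mean_silhouette = mean(sil, na.rm = TRUE),
             bic = sum(fit$report$bic), fit = list(fit))
    }) |> list_rbind()
    best_bic <- max(rows$bic)
    ok <- rows$bic >= best_bic - 0.01 * abs(best_bic)
    cand <- rows[ok, , drop = FALSE]
    chosen <- cand$k[which.max(cand$mean_silhouette)]
    list(chosen_k = chosen,
         report = select(rows, -"fit"),
         fit = rows$fit[[match(chosen, rows$k)]])
  })
}

#' Genes whose module assignment changes over time
#'
#' @param x An `escarole_fit` or a genes x times assignment matrix.
#' @return Character vector of transitioning gene ids.
#' @export
find_transitioning_genes <- function(x) {
  assign <- if (inherits(x, "escarole_fit")) x$assignments else as.matrix(x)
  moving <- apply(assign, 1, function(r) length(unique(r)) > 1)
  rownames(assign)[moving]
}

#' Mismatch-fraction distance between module-assignment profiles
#'
#' `d(a, b)` is the fraction of time points at which the two label
#' profiles disagree.
#'
#' @param profiles Genes x times label matrix.
#' @return A `dist` object.
#' @export
mismatch_distance <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) == 0) stop_bad_arg("profiles have zero time points")
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(ncol(profiles))) {
    d <- d + outer(profiles[, i], profiles[, i], `!=`)
  }
  as.dist(d / ncol(profiles))
}

#' Cluster transitioning genes by module-profile similarity
#'
#' Agglomerative hierarchical clustering under mismatch-fraction distance,
#' cut at `distance_threshold` (default 0.26, corresponding to two
#' mismatches across an 8-point time course); clusters smaller than
#' `min_size` are discarded and reported.
#'
#' @param x An `escarole_fit` (restricted internally to transitioning
#'   genes) or a label matrix of profiles to cluster.
#' @param distance_threshold Dendrogram cut height on the cophenetic
#'   (linkage) distance scale.
#' @param min_size Minimum cluster size to retain (default 10).
#' @param linkage Agglomeration method (default "average").
#' @return Object of class `transitioning_sets` with `sets` (tibble
#'   `set_id`, `gene_id`), `profiles` (per-set mean module profile),
#'   `discarded` gene ids and the parameters used.
#' @export
cluster_transitioning <- function(x, distance_threshold = 0.26, min_size = 10,
                                  linkage = "average") {
  profiles <- if (inherits(x, "escarole_fit")) {
    x$assignments[find_transitioning_genes(x), , drop = FALSE]
  } else as.matrix(x)
  if (nrow(profiles) == 0) {
    return(structure(list(sets = tibble(set_id = character(),
                                        gene_id = character()),
                          profiles = NULL, discarded = character(),
                          distance_threshold = distance_threshold,
                          min_size = min_size),
                     class = "transitioning_sets"))
  }
  d <- mismatch_distance(profiles)
  member <- if (nrow(profiles) == 1) setNames(1L, rownames(profiles)) else {
    hc <- hclust(d, method = linkage)
    cutree(hc, h = distance_threshold)
  }
  tab <- table(member)
  keep_ids <- names(tab)[tab >= min_size]
  # stable set ids ordered by decreasing size then first member
  keep_ids <- keep_ids[order(-tab[keep_ids], as.integer(keep_ids))]
  sets <- imap(setNames(keep_ids, sprintf("set%03d", seq_along(keep_ids))),
               function(cl, nm) {
                 tibble(set_id = nm, gene_id = names(member)[member == cl])
               }) |> list_rbind()
  prof <- if (length(keep_ids)) {
    t(vapply(keep_ids, function(cl) {
      colMeans(profiles[member == cl, , drop = FALSE])
    }, numeric(ncol(profiles))))
  }
  if (!is.null(prof)) rownames(prof) <- sprintf("set%03d", seq_along(keep_ids))
  structure(list(sets = sets,
                 profiles = prof,
                 discarded = setdiff(rownames(profiles), sets$gene_id),
                 distance_threshold = distance_threshold,
                 min_size = min_size),
            class = "transitioning_sets")
}

#' @export
print.transitioning_sets <- function(x, ...) {
  cat(sprintf("<transitioning_sets> %d set(s), %d gene(s) kept, %d discarded (min size %d)\n",
              length(unique(x$sets$set_id)), nrow(x$sets),
              length(x$discarded), x$min_size))
  invisible(x)
}

#' Harmonic-mean overlap score between two gene sets
#'
#' `F = 2 * ((NO/N1) * (NO/N2)) / ((NO/N1) + (NO/N2))`, the harmonic mean
#' of the two directional overlap fractions; `F = 0` when the sets are
#' disjoint and 1 when they coincide.
#'
#' @param a,b Character vectors of gene ids (at least one nonempty).
#' @return Tibble with `n1`, `n2`, `n_overlap`, `fscore`.
#' @export
fscore_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) stop_bad_arg("both sets are empty: F undefined")
  no <- length(intersect(a, b))
  f <- if (no == 0) 0 else {
    f1 <- no / length(a); f2 <- no / length(b)
    2 * (f1 * f2) / (f1 + f2)
  }
  tibble(n1 = length(a), n2 = length(b), n_overlap = no, fscore = f)
}

#' Hypergeometric over-representation of annotation terms in a gene set
#'
#' One-sided hypergeometric test per term against a fixed background, with
#' Benjamini-Hochberg correction across terms.
#'
#' @param cluster Character vector of gene ids (subset of `background`).
#' @param annotation_sets Named list of gene-id vectors (each a subset of
#'   `background`).
#' @param background Character vector defining the gene universe.
#' @param q_max Significance threshold on the BH q-value (default 0.05).
#' @return Tibble with `term`, `n_term`, `n_cluster`, `n_overlap`, `p`,
#'   `q`, `significant`.
#' @export
hypergeom_enrichment <- function(cluster, annotation_sets, background,
                                 q_max = 0.05) {
  background <- unique(background)
  if (!length(background)) stop_bad_arg("empty background")
  cluster <- unique(cluster)
  if (length(setdiff(cluster, background))) {
    stop_bad_arg("cluster contains genes outside the background")
  }
  stopifnot(is.list(annotation_sets), !is.null(names(annotation_sets)))
  res <- imap(annotation_sets, function(term_genes, term) {
    term_genes <- intersect(unique(term_genes), background)
    no <- length(intersect(cluster, term_genes))
    p <- phyper(no - 1, length(term_genes),
                length(background) - length(term_genes),
                length(cluster), lower.tail = FALSE)
    tibble(term = term, n_term = length(term_genes),
           n_cluster = length(cluster), n_overlap = no, p = p)
  }) |> list_rbind()
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q <= q_max
  arrange(res, .data$q, .data$p)
}
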