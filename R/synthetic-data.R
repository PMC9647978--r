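# Synthetic multi-omic time-course generator.
#
# Emulates the statistical structure of an LCO-treatment style study: an
# 8-point expression time course with replicate noise and a fixed number of
# expression-level modules, a planted module reorganization at the 1->2 h
# boundary, motif-accessibility features wired to expression through sparse
# per-module coefficients, piecewise-constant coverage tracks consistent
# with planted promoter signals, and per-time-point peak sets with a known
# universal-merge answer. Every stage downstream of the generator can be
# verified against the planted ground truth.

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the study design the package models: 8 time points
#' (0, 0.25, 0.5, 1, 2, 4, 8, 24 h), 3 replicates, 7 expression-level
#' modules whose means are separated by `10 * noise_sd` on the log scale,
#' 40 candidate regulatory motifs with 5 active per module, and a planted
#' module reorganization at the 1->2 h boundary affecting
#' `transition_fraction` of genes.
#'
#' @param n_genes Number of genes.
#' @param times Strictly increasing time points in hours.
#' @param n_replicates Expression replicates per time point.
#' @param n_modules Number of expression-level modules (>= 2).
#' @param n_motifs Number of candidate motif features.
#' @param active_motifs_per_module Number of motifs with nonzero planted
#'   coefficients in each module's regulatory program.
#' @param coef_magnitude Unitless effect-size multiplier on the planted
#'   feature-to-expression coefficients; 0 decouples features from
#'   expression entirely.
#' @param noise_sd Replicate noise standard deviation on the log-expression
#'   scale (> 0).
#' @param mean_separation Distance between consecutive module means;
#'   defaults to `10 * noise_sd`, which keeps the levels well separated
#'   even after the feature-driven within-module deviations widen them.
#' @param transition_fraction Fraction of genes planted to switch module at
#'   the 1->2 h boundary (in \[0, 1\]).
#' @param n_transition_patterns Number of shared source -> target module
#'   patterns the switching genes are concentrated into (capped at
#'   `n_modules`). Concentration mirrors coordinated regulatory
#'   reprogramming: transitioning genes arrive in a few sizeable clusters
#'   with identical assignment profiles rather than as isolated movers, so
#'   downstream transitioning-set clustering has sets large enough to keep.
#' @param feature_signal_sd Standard deviation of the feature-driven
#'   within-module expression deviation contributed per active motif
#'   (expression units, at `coef_magnitude = 1`); the total planted signal
#'   sd per gene is `feature_signal_sd * sqrt(active_motifs_per_module)`
#'   before the boundary.
#' @param feature_noise_sd Gaussian measurement noise added to the
#'   accessibility features after the expression signal is derived from
#'   them.
#' @param step_fraction Fraction of each module's active motifs whose
#'   planted coefficient steps at the 1->2 h boundary.
#' @param step_multiplier Multiplier applied to stepping coefficients after
#'   the boundary.
#' @param gene_spacing Genomic spacing between consecutive TSSs in bp; at
#'   the default 20 kbp the -10 kbp..+1 kbp motif windows never overlap.
#' @param motif_presence_prob Probability that a given (gene, motif) pair
#'   receives a motif instance in the annotation.
#' @param background_coverage Per-bp background coverage of the synthetic
#'   tracks.
#' @param chrom_length Optional chromosome length in bp; computed from
#'   `n_genes * gene_spacing` when `NULL`. An explicit value too small to
#'   hold all genes is an error.
#' @param seed Master seed; each stage derives its own child seed from it
#'   via [child_seed()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500,
                       times = c(0, 0.25, 0.5, 1, 2, 4, 8, 24),
                       n_replicates = 3,
                       n_modules = 7,
                       n_motifs = 40,
                       active_motifs_per_module = 5,
                       coef_magnitude = 1,
                       noise_sd = 0.25,
                       mean_separation = NULL,
                       transition_fraction = 0.2,
                       n_transition_patterns = 4,
                       feature_signal_sd = 0.1,
                       feature_noise_sd = 0.05,
                       step_fraction = 0.5,
                       step_multiplier = 2,
                       gene_spacing = 20000,
                       motif_presence_prob = 0.8,
                       background_coverage = 10,
                       chrom_length = NULL,
                       seed = 1) {
  check_number(n_genes, "n_genes", 0)
  check_number(n_replicates, "n_replicates", 1)
  check_number(n_modules, "n_modules", 2)
  check_number(n_motifs, "n_motifs", 1)
  check_number(active_motifs_per_module, "active_motifs_per_module", 0, n_motifs)
  check_number(transition_fraction, "transition_fraction", 0, 1)
  check_number(n_transition_patterns, "n_transition_patterns", 1)
  check_number(step_fraction, "step_fraction", 0, 1)
  if (!is.numeric(times) || length(times) < 2 || any(diff(times) <= 0)) {
    stop_bad_arg("`times` must be a strictly increasing numeric vector")
  }
  if (all(times <= 1) || all(times > 1)) {
    stop_bad_arg("`times` must contain points both before and after the 1 h boundary")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop_bad_arg("`noise_sd` must be > 0")
  }
  mean_separation <- mean_separation %||% (10 * noise_sd)
  cfg <- list(
    n_genes = as.integer(n_genes), times = as.numeric(times),
    n_timepoints = length(times), n_replicates = as.integer(n_replicates),
    n_modules = as.integer(n_modules), n_motifs = as.integer(n_motifs),
    active_motifs_per_module = as.integer(active_motifs_per_module),
    coef_magnitude = coef_magnitude, noise_sd = noise_sd,
    mean_separation = mean_separation,
    transition_fraction = transition_fraction,
    n_transition_patterns = as.integer(min(n_transition_patterns, n_modules)),
    feature_signal_sd = feature_signal_sd,
    feature_noise_sd = feature_noise_sd,
    step_fraction = step_fraction, step_multiplier = step_multiplier,
    gene_spacing = gene_spacing,
    motif_presence_prob = motif_presence_prob,
    background_coverage = background_coverage,
    chrom_length = chrom_length, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Index of the last time point at or before the 1->2 h boundary.
boundary_index <- function(config) {
  idx <- max(which(config$times <= 1))
  if (idx >= config$n_timepoints) {
    stop_bad_arg("`times` must contain points after the 1 h boundary")
  }
  idx
}

sim_gene_ids <- function(n) sprintf("g%04d", seq_len(n))
sim_motif_ids <- function(n) sprintf("m%03d", seq_len(n))

#' Generate synthetic gene and motif-instance annotation
#'
#' Places genes on a single linear chromosome at fixed spacing with
#' alternating strands, and drops short motif instances uniformly inside
#' each gene's strand-oriented -10 kbp..+1 kbp TSS window.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (gene_id, chrom, tss, strand), `motifs`
#'   (BED-style chrom, start, end, motif_id, score, strand, gene_id) and
#'   `chrom_sizes` (chrom, length) tibbles.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  needed <- n * config$gene_spacing
  len <- config$chrom_length %||% max(needed, config$gene_spacing)
  if (len < needed) {
    stop_bad_arg("chromosome of length %d cannot hold %d genes at %d bp spacing",
                 len, n, config$gene_spacing)
  }
  chrom_sizes <- tibble(chrom = "chr1", length = as.integer(len))
  if (n == 0L) {
    return(list(
      genes = tibble(gene_id = character(), chrom = character(),
                     tss = integer(), strand = character()),
      motifs = tibble(chrom = character(), start = integer(), end = integer(),
                      motif_id = character(), score = numeric(),
                      strand = character(), gene_id = character()),
      chrom_sizes = chrom_sizes))
  }
  genes <- tibble(
    gene_id = sim_gene_ids(n),
    chrom = "chr1",
    tss = as.integer(config$gene_spacing / 2 + (seq_len(n) - 1) * config$gene_spacing),
    strand = rep_len(c("+", "-"), n))
  motifs <- with_seed(child_seed(config$seed, "annotation"), {
    pairs <- tidyr::expand_grid(gene_id = genes$gene_id,
                                motif_id = sim_motif_ids(config$n_motifs))
    keep <- runif(nrow(pairs)) < config$motif_presence_prob
    pairs <- pairs[keep, , drop = FALSE]
    pairs <- left_join(pairs, genes, by = "gene_id")
    up <- 10000; down <- 1000; half <- 5L
    lo <- ifelse(pairs$strand == "+", pairs$tss - up, pairs$tss - down)
    hi <- ifelse(pairs$strand == "+", pairs$tss + down, pairs$tss + up)
    center <- floor(runif(nrow(pairs), lo + half + 1, hi - half - 1))
    tibble(chrom = pairs$chrom,
           start = as.integer(pmax(0, center - half)),
           end = as.integer(center + half),
           motif_id = pairs$motif_id,
           score = round(runif(nrow(pairs), 5, 20), 3),
           strand = pairs$strand,
           gene_id = pairs$gene_id) |>
      arrange(.data$start, .data$motif_id)
  })
  list(genes = genes, motifs = motifs, chrom_sizes = chrom_sizes)
}

#' Generate a synthetic expression time course with planted modules
#'
#' Each gene belongs to one of `n_modules` expression-level modules at each
#' time point; a planted fraction of genes switches module exactly at the
#' 1->2 h boundary. Replicate values are Gaussian around the module mean.
#'
#' @param config A [sim_config()].
#' @param delta Optional genes x times matrix of gene-level expression
#'   deviations (e.g. the feature-driven signal from
#'   [simulate_features()]) added to the module mean of every replicate.
#' @return List with `expr` (long tibble: gene_id, time, replicate, value)
#'   and `truth` (module assignment matrix, transitioning gene ids, module
#'   means).
#' @export
simulate_expression <- function(config, delta = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes; k <- config$n_modules; tt <- config$times
  mu <- 2 + (seq_len(k) - 1) * config$mean_separation
  genes <- sim_gene_ids(n)
  st <- sim_module_structure(config)
  assign <- st$assign
  if (!is.null(delta)) {
    if (!identical(dim(delta), dim(assign))) {
      stop_bad_arg("`delta` must be a %d x %d matrix", n, config$n_timepoints)
    }
  } else {
    delta <- matrix(0, n, config$n_timepoints)
  }
  with_seed(child_seed(config$seed, "expression"), {
    expr <- tidyr::expand_grid(time = tt, replicate = seq_len(config$n_replicates),
                               gene_id = genes) |>
      mutate(gi = match(.data$gene_id, genes),
             ci = match(.data$time, tt),
             module = as.vector(assign[cbind(.data$gi, .data$ci)])) |>
      mutate(value = rnorm(n(), mean = mu[.data$module] +
                             delta[cbind(.data$gi, .data$ci)],
                           sd = config$noise_sd)) |>
      select("gene_id", "time", "replicate", "value") |>
      arrange(.data$gene_id, .data$time, .data$replicate)
    truth <- list(
      module_of_gene_per_time = assign,
      transitioning_gene_ids = genes[st$switchers],
      module_means = mu)
    list(expr = expr, truth = truth)
  })
}

# Module-membership structure: per-time assignment matrix with the
# planted switch at the 1->2 h boundary. Deterministic given the config,
# so features and expression can be generated in either order.
sim_module_structure <- function(config) {
  n <- config$n_genes; k <- config$n_modules; tt <- config$times
  genes <- sim_gene_ids(n)
  with_seed(child_seed(config$seed, "structure"), {
    base <- sample(rep_len(seq_len(k), n))
    n_switch <- floor(config$transition_fraction * n)
    after <- base
    switchers <- integer(0)
    if (n_switch > 0) {
      # concentrate switchers into a few shared source -> target patterns
      np <- min(config$n_transition_patterns, k, n_switch)
      sources <- sample.int(k, np)
      targets <- vapply(sources, function(a) {
        cand <- setdiff(seq_len(k), a)
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      quota <- diff(round(seq(0, n_switch, length.out = np + 1)))
      carry <- 0L
      for (i in seq_len(np)) {
        avail <- setdiff(which(base == sources[i]), switchers)
        take <- min(quota[i] + carry, length(avail))
        carry <- quota[i] + carry - take
        if (take > 0) {
          sel <- avail[sample.int(length(avail), take)]
          after[sel] <- targets[i]
          switchers <- c(switchers, sel)
        }
      }
      if (carry > 0) {
        # rare overflow when a source module is smaller than its quota:
        # fill up with isolated movers so the planted count stays exact
        rest <- setdiff(seq_len(n), switchers)
        sel <- rest[sample.int(length(rest), carry)]
        after[sel] <- vapply(base[sel], function(m) {
          cand <- setdiff(seq_len(k), m)
          cand[sample.int(length(cand), 1L)]
        }, integer(1))
        switchers <- c(switchers, sel)
      }
      switchers <- sort(switchers)
    }
    bi <- boundary_index(config)
    assign <- matrix(rep(base, config$n_timepoints), nrow = n,
                     dimnames = list(genes, as.character(tt)))
    if (bi < length(tt)) {
      assign[, (bi + 1):length(tt)] <- after
    }
    list(assign = assign, switchers = switchers)
  })
}

#' Generate motif-accessibility features wired to expression
#'
#' For each (module, time) the generator plants a sparse coefficient vector
#' over motifs: each of the module's `active_motifs_per_module` active
#' motifs contributes `+/- coef_magnitude * feature_signal_sd` expression
#' units, and a planted subset of coefficients steps by `step_multiplier`
#' after the 1->2 h boundary. Underlying accessibility values are iid
#' standard normal per (gene, motif, time); the feature-driven expression
#' deviation of gene g at time c is the planted linear combination
#' `delta[g, c] = sum_m vals[g, m, c] * theta[m, module(g, c), c]`, which
#' [simulate_expression()] adds to the module mean. The observed feature
#' tensor is the underlying values plus independent Gaussian measurement
#' noise of sd `feature_noise_sd`, quantile-normalized across time points
#' as the matching analysis pipeline does to real accessibility features.
#'
#' With `coef_magnitude = 0` the planted coefficients vanish, so features
#' carry no expression signal.
#'
#' @param config A [sim_config()].
#' @return List with `features` (a [feature_tensor()]), `theta_true`
#'   (array motifs x modules x times of planted coefficients, expression
#'   units) and `delta` (genes x times matrix of feature-driven expression
#'   deviations to pass to [simulate_expression()]).
#' @export
simulate_features <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  st <- sim_module_structure(config)
  assign <- st$assign
  n <- nrow(assign); M <- config$n_motifs; K <- config$n_modules
  C <- config$n_timepoints
  genes <- rownames(assign)
  motifs <- sim_motif_ids(M)
  bi <- boundary_index(config)
  with_seed(child_seed(config$seed, "features"), {
    theta <- array(0, dim = c(M, K, C),
                   dimnames = list(motifs, paste0("module", seq_len(K)),
                                   as.character(config$times)))
    scale <- config$coef_magnitude * config$feature_signal_sd
    for (k in seq_len(K)) {
      a <- config$active_motifs_per_module
      if (a == 0) next
      act <- sample(M, a)
      base <- sample(c(-1, 1), a, replace = TRUE) * scale
      stepping <- seq_len(ceiling(config$step_fraction * a))
      late <- base
      late[stepping] <- late[stepping] * config$step_multiplier
      theta[act, k, seq_len(bi)] <- base
      theta[act, k, (bi + 1):C] <- late
    }
    vals <- array(rnorm(n * M * C), dim = c(n, M, C))
    delta <- matrix(0, n, C, dimnames = list(genes, as.character(config$times)))
    for (cc in seq_len(C)) {
      for (k in seq_len(K)) {
        g <- which(assign[, cc] == k)
        if (!length(g)) next
        delta[g, cc] <- matrix(vals[g, , cc], nrow = length(g)) %*% theta[, k, cc]
      }
    }
    if (config$feature_noise_sd > 0) {
      vals <- vals + array(rnorm(n * M * C, sd = config$feature_noise_sd),
                           dim = dim(vals))
    }
    flat <- matrix(vals, nrow = n * M, ncol = C)
    flat <- as.matrix(quantile_normalize(flat))
    vals <- array(flat, dim = c(n, M, C))
    list(features = feature_tensor(vals, genes, motifs, config$times),
         theta_true = theta, delta = delta)
  })
}

# Scenario labels used for the planted peak sets.
peak_scenarios <- c("identical", "containment", "partial")

#' Generate coverage tracks and peak sets with a known universal answer
#'
#' Coverage is piecewise-constant: a flat background with each gene's
#' +/-2 kbp promoter window raised (or lowered) to
#' `background * 2^signal`, where the planted per-gene per-time signal is
#' standard normal. Peak sets cycle through three planted scenarios per
#' gene locus: identical intervals at every time point, alternating
#' containment, and partial overlap below the Jaccard threshold (two
#' universal peaks). The universal-merge answer is constructed alongside.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @return List with `coverage` (per-time list of bedGraph-style tibbles),
#'   `peaks` (per-time list of BED-style tibbles), `universal_truth`
#'   (tibble of merged peaks with source counts), `promoter_signal`
#'   (planted genes x times log2 signal matrix) and `scenario` (per-gene
#'   scenario labels).
#' @export
simulate_coverage_peaks <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotation$genes
  n <- nrow(genes); C <- config$n_timepoints
  len <- annotation$chrom_sizes$length[1]
  half <- 2000L
  with_seed(child_seed(config$seed, "coverage"), {
    sig <- matrix(rnorm(n * C), nrow = n,
                  dimnames = list(genes$gene_id, as.character(config$times)))
    coverage <- vector("list", C)
    for (cc in seq_len(C)) {
      lev <- config$background_coverage * 2^sig[, cc]
      starts <- pmax(0L, genes$tss - half)
      ends <- pmin(len, genes$tss + half)
      runs <- tibble(start = starts, end = ends, score = lev) |>
        arrange(.data$start)
      bg <- tibble(start = c(0L, runs$end),
                   end = c(runs$start, len),
                   score = config$background_coverage) |>
        filter(.data$end > .data$start)
      coverage[[cc]] <- bind_rows(runs, bg) |>
        mutate(chrom = "chr1", .before = 1) |>
        arrange(.data$start)
    }
    scenario <- rep_len(peak_scenarios, n)
    peaks <- map(seq_len(C), function(cc) {
      p <- map(seq_len(n), function(i) {
        tss <- genes$tss[i]
        switch(scenario[i],
          identical = c(tss - 500L, tss + 500L),
          containment = if (cc %% 2 == 1) c(tss - 500L, tss + 500L)
                        else c(tss - 300L, tss + 200L),
          partial = if (cc <= C / 2) c(tss - 500L, tss + 100L)
                    else c(tss - 100L, tss + 500L))
      })
      tibble(chrom = "chr1",
             start = as.integer(vapply(p, `[`, numeric(1), 1)),
             end = as.integer(vapply(p, `[`, numeric(1), 2)),
             name = sprintf("peak_t%d_%s", cc, genes$gene_id)) |>
        arrange(.data$start)
    })
    universal_truth <- map(seq_len(n), function(i) {
      tss <- genes$tss[i]
      switch(scenario[i],
        identical = ,
        containment = tibble(chrom = "chr1", start = tss - 500L,
                             end = tss + 500L, n_source = C),
        partial = tibble(chrom = "chr1",
                         start = c(tss - 500L, tss - 100L),
                         end = c(tss + 100L, tss + 500L),
                         n_source = c(floor(C / 2), C - floor(C / 2))))
    }) |> list_rbind() |> arrange(.data$start)
    list(coverage = coverage, peaks = peaks,
         universal_truth = universal_truth,
         promoter_signal = sig,
         scenario = setNames(scenario, genes$gene_id))
  })
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper generating annotation, expression, features, and
#' coverage/peak fixtures from one configuration, optionally writing the
#' standard plain-text files (genes.tsv, motifs.bed, expr.tsv,
#' coverage.t*.bedGraph, peaks.t*.bed, truth.json) to a directory.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `config`, `annotation`, `expr`, `features`,
#'   `coverage_peaks` and consolidated `truth`.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  ann <- simulate_annotation(config)
  fe <- simulate_features(config)
  ex <- simulate_expression(config, delta = fe$delta)
  cp <- simulate_coverage_peaks(config, ann)
  truth <- c(ex$truth, list(theta_true = fe$theta_true,
                            universal_peaks = cp$universal_truth,
                            promoter_signal = cp$promoter_signal))
  out <- list(config = config, annotation = ann, expr = ex$expr,
              features = fe$features, coverage_peaks = cp, truth = truth)
  if (!is.null(dir)) write_study(out, dir)
  invisible(out)
}
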