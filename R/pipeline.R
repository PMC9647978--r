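# End-to-end pipeline driver: configuration, validation, stage ordering
# (signal -> modules -> correlation -> drmn -> mtg), caching, structured
# per-stage logging, and a run manifest with output hashes and the seed
# registry.

pipeline_stages <- c("signal", "modules", "correlation", "drmn", "mtg")
stage_deps <- list(signal = character(), modules = character(),
                   correlation = c("signal", "modules"),
                   drmn = "modules", mtg = "modules")

#' Pipeline configuration
#'
#' Collects every stage parameter with the analysis defaults: `k = 7`
#' modules, 100 EM iterations, transition-set distance threshold 0.26 and
#' minimum size 10, Jaccard 0.9 peak merging, promoter window +/- 2 kbp
#' and mapping window -10 kbp..+1 kbp, fused-lasso penalties rho1 = 5,
#' rho2 = 45, rho3 = 0, fractional lambda grid 0.20-0.99, 1000
#' correlation permutations, 40 null randomizations, and 6-of-8 minimum
#' fold selection.
#'
#' @param study_dir Directory with the input files (see [write_study()]).
#' @param out_dir Output directory.
#' @param stages Stages to run, a subset of
#'   `c("signal", "modules", "correlation", "drmn", "mtg")`.
#' @param seed Master seed for the run's seed registry.
#' @param k,em_iterations Module count and EM iteration cap.
#' @param distance_threshold,min_set_size Transitioning-set clustering.
#' @param jaccard_min Universal-peak merge threshold.
#' @param promoter_up,promoter_down Promoter window extents (bp).
#' @param map_upstream,map_downstream Feature/mapping window extents (bp).
#' @param rho1,rho2,rho3 Fused-lasso penalties.
#' @param lambda Fractional group-lasso penalty for the mtg stage.
#' @param lambda_grid Grid for per-set lambda selection (used when
#'   `select_lambda` is TRUE).
#' @param select_lambda Select lambda per gene set from `lambda_grid`
#'   (expensive) instead of using `lambda` everywhere.
#' @param n_perm Correlation permutations.
#' @param n_random Null randomizations per gene set.
#' @param min_folds Minimum leave-one-out folds for significance.
#' @param alpha Significance level shared by the correlation and
#'   selection tests.
#' @param cv_folds Cross-validation folds for the drmn stage report.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(study_dir, out_dir,
                            stages = pipeline_stages,
                            seed = 1, k = 7, em_iterations = 100,
                            distance_threshold = 0.26, min_set_size = 10,
                            jaccard_min = 0.9,
                            promoter_up = 2000, promoter_down = 2000,
                            map_upstream = 10000, map_downstream = 1000,
                            rho1 = 5, rho2 = 45, rho3 = 0,
                            lambda = 0.5,
                            lambda_grid = c(seq(0.2, 0.9, by = 0.1), 0.99),
                            select_lambda = FALSE,
                            n_perm = 1000, n_random = 40, min_folds = 6,
                            alpha = 0.05, cv_folds = 3) {
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  for (st in stages) {
    missing_dep <- setdiff(stage_deps[[st]], stages)
    if (length(missing_dep)) {
      stop_bad_arg("stage '%s' requires disabled stage(s): %s", st,
                   paste(missing_dep, collapse = ", "))
    }
  }
  cfg <- list(study_dir = study_dir, out_dir = out_dir,
              stages = stages, seed = as.integer(seed), k = k,
              em_iterations = em_iterations,
              distance_threshold = distance_threshold,
              min_set_size = min_set_size, jaccard_min = jaccard_min,
              promoter_up = promoter_up, promoter_down = promoter_down,
              map_upstream = map_upstream, map_downstream = map_downstream,
              rho1 = rho1, rho2 = rho2, rho3 = rho3,
              lambda = lambda, lambda_grid = lambda_grid,
              select_lambda = select_lambda,
              n_perm = n_perm, n_random = n_random, min_folds = min_folds,
              alpha = alpha, cv_folds = cv_folds)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file with `study_dir`, `out_dir` and any parameter
#'   overrides.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop_bad_arg("config file %s does not exist", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_bad_arg("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

validate_pipeline_inputs <- function(config) {
  if (!dir.exists(config$study_dir)) {
    stop_bad_arg("study directory %s does not exist", config$study_dir)
  }
  need <- c("genes.tsv", "expr.tsv", "truth.json")
  study <- read_study(config$study_dir)
  times <- as.numeric(study$truth$times)
  files <- character(0)
  if ("signal" %in% config$stages) {
    files <- c(files,
               sprintf("coverage.t%d.bedGraph", seq_along(times)),
               sprintf("peaks.t%d.bed", seq_along(times)))
  }
  if (any(c("drmn", "mtg") %in% config$stages)) {
    files <- c(files, sprintf("features.t%d.tsv", seq_along(times)))
  }
  missing <- files[!file.exists(file.path(config$study_dir, files))]
  if (length(missing)) {
    stop_bad_arg("missing input file(s) for enabled stages: %s",
                 paste(missing, collapse = ", "))
  }
  study
}

run_stage <- function(name, fun) {
  t0 <- Sys.time()
  inform(sprintf("[%s] starting", name))
  res <- tryCatch(fun(), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = "regdyn_stage_error", parent = e)
  })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  inform(sprintf("[%s] done in %.1fs", name, elapsed))
  list(result = res, seconds = elapsed)
}

md5_of <- function(paths) {
  paths <- paths[file.exists(paths)]
  stats::setNames(as.character(tools::md5sum(paths)), basename(paths))
}

#' Run the full analysis pipeline on a study directory
#'
#' Executes the enabled stages in dependency order: `signal` (coverage
#' aggregation, universal-peak merging, promoter signals), `modules`
#' (expression modules and transitioning gene sets), `correlation`
#' (permutation tests of promoter signal vs expression), `drmn`
#' (fused-lasso module networks, cross-validation, prioritization), and
#' `mtg` (per-set multi-task group LASSO and edge list). Each stage
#' writes its artifacts under `out_dir` and is skipped on re-runs when
#' its outputs already exist for an identical configuration; the manifest
#' records the config hash, per-stage output hashes, timings, and the
#' seed registry.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- validate_pipeline_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_for_hash <- unclass(config)
  cfg_hash <- digest_config(cfg_for_hash)
  seeds <- list()
  stage_seed <- function(st) {
    seeds[[st]] <<- child_seed(config$seed, st)
    seeds[[st]]
  }
  manifest <- list(tool = "regdyn",
                   version = as.character(utils::packageVersion("regdyn")),
                   config_hash = cfg_hash, stages = list())
  prev_path <- file.path(config$out_dir, "manifest.json")
  prev <- if (file.exists(prev_path)) {
    tryCatch(jsonlite::read_json(prev_path, simplifyVector = TRUE),
             error = function(e) NULL)
  }
  cached <- function(st, outputs) {
    !is.null(prev) && identical(prev$config_hash, cfg_hash) &&
      st %in% names(prev$stages) &&
      all(file.exists(file.path(config$out_dir, outputs)))
  }
  state <- new.env(parent = emptyenv())
  times <- as.numeric(study$truth$times)

  stage_outputs <- list(
    signal = c("promoter_signal.tsv", "universal_peaks.tsv",
               "peak_annotation.tsv"),
    modules = c("modules.tsv", "transitioning_sets.tsv"),
    correlation = "correlation.tsv",
    drmn = c("drmn_modules.tsv", "drmn_coefficients.tsv",
             "prioritized_regulators.tsv", "cv_report.json"),
    mtg = c("edges.tsv", "regulator_ranking.tsv"))

  load_cached <- function(st) {
    out <- config$out_dir
    if (st == "signal") {
      df <- readr::read_tsv(file.path(out, "promoter_signal.tsv"),
                            show_col_types = FALSE, progress = FALSE)
      m <- as.matrix(df[-1]); rownames(m) <- df$gene_id
      state$promoter_signal <- m
    }
    if (st == "modules") {
      df <- readr::read_tsv(file.path(out, "modules.tsv"),
                            show_col_types = FALSE, progress = FALSE)
      m <- as.matrix(df[-1]); rownames(m) <- df$gene_id
      storage.mode(m) <- "integer"
      state$assignments <- m
      state$sets <- readr::read_tsv(file.path(out, "transitioning_sets.tsv"),
                                    show_col_types = FALSE, progress = FALSE)
    }
  }

  for (st in pipeline_stages) {
    if (!st %in% config$stages) next
    if (cached(st, stage_outputs[[st]])) {
      inform(sprintf("[%s] cached outputs found, skipping", st))
      load_cached(st)
      manifest$stages[[st]] <- prev$stages[[st]]
      if (st != "signal") seeds[[st]] <- child_seed(config$seed, st)
      next
    }
    if (st != "signal") stage_seed(st)  # register even if the stage ends early
    run <- switch(st,
      signal = run_stage(st, function() {
        stage_signal(study, config, times)
      }),
      modules = run_stage(st, function() {
        stage_modules(study, config, stage_seed(st))
      }),
      correlation = run_stage(st, function() {
        stage_correlation(study, config, state, stage_seed(st))
      }),
      drmn = run_stage(st, function() {
        stage_drmn(study, config, state, stage_seed(st))
      }),
      mtg = run_stage(st, function() {
        stage_mtg(study, config, state, stage_seed(st))
      }))
    for (nm in names(run$result$state)) {
      assign(nm, run$result$state[[nm]], envir = state)
    }
    manifest$stages[[st]] <- list(
      seconds = run$seconds,
      counters = run$result$counters,
      outputs = as.list(md5_of(file.path(config$out_dir,
                                         stage_outputs[[st]]))))
  }
  manifest$seed_registry <- seeds
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

digest_config <- function(x) {
  # order-stable serialization hashed with md5
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x[order(names(x))], auto_unbox = TRUE,
                              digits = NA), tmp)
  as.character(tools::md5sum(tmp))
}

stage_signal <- function(study, config, times) {
  tracks <- map(study$coverage, function(cov) {
    coverage_track(cov, study$chrom_sizes)
  })
  universal <- merge_universal_peaks(study$peaks,
                                     jaccard_min = config$jaccard_min)
  annotated <- annotate_peaks(universal, study$genes,
                              promoter_up = config$promoter_up)
  prom <- tibble(chrom = study$genes$chrom,
                 start = pmax(0L, study$genes$tss - config$promoter_up),
                 end = study$genes$tss + config$promoter_down,
                 region_id = study$genes$gene_id)
  sig <- vapply(tracks, function(tr) {
    aggregate_region_signal(tr, prom)$signal
  }, numeric(nrow(prom)))
  sig <- quantile_normalize(matrix(sig, nrow = nrow(prom)))
  dimnames(sig) <- list(study$genes$gene_id, as.character(times))
  out <- config$out_dir
  write_tsv_quiet(bind_cols(tibble(gene_id = rownames(sig)),
                            as_tibble(as.data.frame(sig))),
                  file.path(out, "promoter_signal.tsv"))
  write_tsv_quiet(universal, file.path(out, "universal_peaks.tsv"))
  write_tsv_quiet(annotated, file.path(out, "peak_annotation.tsv"))
  list(state = list(promoter_signal = sig, universal_peaks = universal),
       counters = list(n_universal_peaks = nrow(universal),
                       n_promoter_peaks = sum(annotated$category == "Promoter")))
}

stage_modules <- function(study, config, seed) {
  fit <- fit_modules(study$expr, k = config$k,
                     max_iter = config$em_iterations, seed = seed)
  sets <- cluster_transitioning(fit,
                                distance_threshold = config$distance_threshold,
                                min_size = config$min_set_size)
  out <- config$out_dir
  am <- fit$assignments
  write_tsv_quiet(bind_cols(tibble(gene_id = rownames(am)),
                            as_tibble(as.data.frame(am))),
                  file.path(out, "modules.tsv"))
  write_tsv_quiet(sets$sets, file.path(out, "transitioning_sets.tsv"))
  list(state = list(module_fit = fit, assignments = am, sets = sets$sets),
       counters = list(n_transitioning = length(find_transitioning_genes(fit)),
                       n_sets = length(unique(sets$sets$set_id)),
                       n_discarded = length(sets$discarded)))
}

stage_correlation <- function(study, config, state, seed) {
  res <- correlate_promoter_expression(study$expr, state$promoter_signal,
                                       n_perm = config$n_perm,
                                       alpha = config$alpha, seed = seed)
  write_tsv_quiet(res, file.path(config$out_dir, "correlation.tsv"))
  s <- attr(res, "summary")
  list(state = list(correlation = res),
       counters = as.list(s))
}

stage_drmn <- function(study, config, state, seed) {
  hyper <- drmn_hyper(config$rho1, config$rho2, config$rho3)
  model <- fit_drmn(study$expr, study$features, hyper = hyper,
                    modules = state$assignments, seed = seed)
  cv <- cross_validate_drmn(study$expr, study$features, hyper = hyper,
                            folds = config$cv_folds, seed = seed,
                            modules = state$assignments)
  pri <- prioritize_regulators(model, alpha = config$alpha)
  write_drmn_outputs(model, config$out_dir, cv = cv, prioritized = pri)
  list(state = list(drmn = model, drmn_cv = cv, drmn_prioritized = pri),
       counters = list(mean_cv_cor = cv$mean_cor,
                       n_selected_regulators =
                         sum(pri$ranking$n_modules_selected > 0)))
}

stage_mtg <- function(study, config, state, seed) {
  sets_tbl <- state$sets
  set_ids <- unique(sets_tbl$set_id)
  lambda_reports <- list()
  results <- map(set_ids, function(sid) {
    genes <- sets_tbl$gene_id[sets_tbl$set_id == sid]
    set <- mtg_set_data(genes, study$expr, study$features, set_id = sid,
                        center = TRUE)
    lam <- config$lambda
    if (config$select_lambda) {
      ch <- choose_lambda(set, lambda_grid = config$lambda_grid,
                          n_random = config$n_random,
                          seed = child_seed(seed, sid),
                          min_folds = config$min_folds,
                          alpha = config$alpha)
      lambda_reports[[sid]] <<- ch
      if (ch$no_model) return(NULL)
      lam <- ch$lambda
    }
    fit <- fit_mtg_lasso(set, lambda = lam)
    sig <- null_selection(set, lambda = lam, n_random = config$n_random,
                          seed = child_seed(seed, sid),
                          min_folds = config$min_folds,
                          alpha = config$alpha)
    list(set_id = sid, genes = set$genes, theta = fit$theta,
         significant = sig$motif[sig$significant])
  })
  results <- purrr::compact(results)
  edge_list <- build_edges(results)
  write_mtg_outputs(edge_list, config$out_dir,
                    lambda_reports = if (length(lambda_reports)) lambda_reports)
  list(state = list(edges = edge_list),
       counters = list(n_sets_modeled = length(results),
                       n_edges = nrow(edge_list$edges),
                       n_regulators = nrow(edge_list$ranking)))
}
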