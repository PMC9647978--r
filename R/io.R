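# Plain-text readers and writers for the study's file formats: TSV
# tables, BED intervals, bedGraph coverage, and a JSON ground-truth
# bundle for synthetic fixtures.

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Writes `genes.tsv`, `motifs.bed`, `expr.tsv`, per-time
#' `features.t{i}.tsv`, `coverage.t{i}.bedGraph`, `peaks.t{i}.bed`, and
#' `truth.json` in the layout the pipeline reads back.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv_quiet(study$annotation$genes, file.path(dir, "genes.tsv"))
  write_tsv_quiet(study$annotation$chrom_sizes, file.path(dir, "chrom_sizes.tsv"))
  motifs <- study$annotation$motifs[c("chrom", "start", "end", "motif_id",
                                      "score", "strand")]
  readr::write_tsv(motifs, file.path(dir, "motifs.bed"),
                   col_names = FALSE, progress = FALSE)
  write_tsv_quiet(study$expr, file.path(dir, "expr.tsv"))
  fe <- study$features
  for (cc in seq_along(fe$times)) {
    m <- tensor_slice(fe, cc)
    df <- bind_cols(tibble(gene_id = fe$genes), as_tibble(as.data.frame(m)))
    write_tsv_quiet(df, file.path(dir, sprintf("features.t%d.tsv", cc)))
  }
  cp <- study$coverage_peaks
  for (cc in seq_along(cp$coverage)) {
    readr::write_tsv(cp$coverage[[cc]][c("chrom", "start", "end", "score")],
                     file.path(dir, sprintf("coverage.t%d.bedGraph", cc)),
                     col_names = FALSE, progress = FALSE)
    readr::write_tsv(cp$peaks[[cc]],
                     file.path(dir, sprintf("peaks.t%d.bed", cc)),
                     col_names = FALSE, progress = FALSE)
  }
  truth <- study$truth
  json <- list(
    times = study$config$times,
    module_of_gene_per_time = truth$module_of_gene_per_time,
    transitioning_gene_ids = truth$transitioning_gene_ids,
    module_means = truth$module_means,
    theta_true = truth$theta_true,
    universal_peaks = truth$universal_peaks,
    promoter_signal = truth$promoter_signal,
    scenario = as.list(cp$scenario))
  jsonlite::write_json(json, file.path(dir, "truth.json"),
                       digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory path.
#' @return List with `genes`, `chrom_sizes`, `motifs`, `expr`, `features`
#'   (a [feature_tensor()]), `coverage`, `peaks`, and `truth` (parsed
#'   JSON with assignment/coefficient matrices restored).
#' @export
read_study <- function(dir) {
  need <- c("genes.tsv", "expr.tsv", "truth.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop_bad_arg("study directory %s is missing: %s", dir,
                 paste(missing, collapse = ", "))
  }
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  chrom_sizes <- readr::read_tsv(file.path(dir, "chrom_sizes.tsv"),
                                 show_col_types = FALSE, progress = FALSE)
  motifs <- read_bed(file.path(dir, "motifs.bed"),
                     col_names = c("chrom", "start", "end", "motif_id",
                                   "score", "strand"))
  expr <- readr::read_tsv(file.path(dir, "expr.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  times <- as.numeric(truth$times)
  ftensor <- NULL
  ffiles <- file.path(dir, sprintf("features.t%d.tsv", seq_along(times)))
  if (all(file.exists(ffiles))) {
    slices <- map(ffiles, function(f) {
      df <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
      m <- as.matrix(df[-1]); rownames(m) <- df$gene_id; m
    })
    vals <- array(0, dim = c(nrow(slices[[1]]), ncol(slices[[1]]),
                             length(slices)))
    for (cc in seq_along(slices)) vals[, , cc] <- slices[[cc]]
    ftensor <- feature_tensor(vals, rownames(slices[[1]]),
                              colnames(slices[[1]]), times)
  }
  coverage <- peaks <- NULL
  cfiles <- file.path(dir, sprintf("coverage.t%d.bedGraph", seq_along(times)))
  if (all(file.exists(cfiles))) {
    coverage <- map(cfiles, read_bedgraph)
  }
  pfiles <- file.path(dir, sprintf("peaks.t%d.bed", seq_along(times)))
  if (all(file.exists(pfiles))) {
    peaks <- map(pfiles, read_bed)
  }
  list(genes = genes, chrom_sizes = chrom_sizes, motifs = motifs,
       expr = expr, features = ftensor, coverage = coverage, peaks = peaks,
       truth = truth)
}

#' Read a BED-style interval file
#'
#' Plain-text, tab-separated, no header; 0-based half-open coordinates as
#' in the BED convention.
#'
#' @param path File path.
#' @param col_names Column names for the leading columns (defaults to
#'   chrom/start/end/name for up to 4 columns).
#' @return Tibble.
#' @export
read_bed <- function(path, col_names = NULL) {
  first <- readr::read_tsv(path, col_names = FALSE, n_max = 1,
                           show_col_types = FALSE, progress = FALSE)
  nc <- ncol(first)
  default <- c("chrom", "start", "end", "name", "score", "strand")
  col_names <- col_names %||% default[seq_len(min(nc, 6))]
  if (length(col_names) < nc) {
    col_names <- c(col_names, paste0("extra", seq_len(nc - length(col_names))))
  }
  readr::read_tsv(path, col_names = col_names, show_col_types = FALSE,
                  progress = FALSE)
}

#' Read a bedGraph coverage file
#'
#' @param path File path (tab-separated chrom/start/end/score, no header).
#' @return Tibble with columns `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "score"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Write DRMN outputs as TSV/JSON artifacts
#'
#' @param model A `drmn_fit`.
#' @param dir Output directory.
#' @param cv Optional [cross_validate_drmn()] result for `cv_report.json`.
#' @param prioritized Optional [prioritize_regulators()] result.
#' @return `dir`, invisibly.
#' @export
write_drmn_outputs <- function(model, dir, cv = NULL, prioritized = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  am <- model$assignments
  modules <- as_tibble(as.data.frame(am)) |>
    mutate(gene_id = rownames(am), .before = 1)
  write_tsv_quiet(modules, file.path(dir, "drmn_modules.tsv"))
  coef_tbl <- as_tibble_theta(model)
  write_tsv_quiet(coef_tbl, file.path(dir, "drmn_coefficients.tsv"))
  if (!is.null(prioritized)) {
    write_tsv_quiet(prioritized$tests,
                    file.path(dir, "prioritized_regulators.tsv"))
  }
  if (!is.null(cv)) {
    jsonlite::write_json(
      list(mean_cor = cv$mean_cor, by_module_time = cv$by_module_time,
           skipped = cv$skipped),
      file.path(dir, "cv_report.json"), digits = NA, dataframe = "rows")
  }
  invisible(dir)
}

as_tibble_theta <- function(model) {
  th <- model$theta
  tibble(
    module = rep(seq_len(model$k), each = length(model$features) * length(model$times)),
    time = rep(rep(model$times, each = length(model$features)), times = model$k),
    feature = rep(model$features, times = length(model$times) * model$k),
    weight = as.vector(th))
}

#' Write MTG-LASSO outputs as TSV/JSON artifacts
#'
#' @param edge_list Output of [build_edges()].
#' @param dir Output directory.
#' @param lambda_reports Optional named list of [choose_lambda()] results
#'   per gene set for `lambda_report.json`.
#' @return `dir`, invisibly.
#' @export
write_mtg_outputs <- function(edge_list, dir, lambda_reports = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv_quiet(edge_list$edges, file.path(dir, "edges.tsv"))
  write_tsv_quiet(edge_list$ranking, file.path(dir, "regulator_ranking.tsv"))
  if (!is.null(lambda_reports)) {
    jsonlite::write_json(
      map(lambda_reports, function(r) {
        list(lambda = r$lambda, no_model = r$no_model, report = r$report)
      }),
      file.path(dir, "lambda_report.json"), digits = NA, dataframe = "rows")
  }
  invisible(dir)
}
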