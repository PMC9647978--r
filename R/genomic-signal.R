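# Region-level accessibility signal machinery: coverage tracks, log-ratio
# aggregation, quantile normalization, universal peak merging, peak
# annotation/mapping, motif-level feature construction and profile
# clustering. All coordinates are 0-based half-open (BED convention).

#' Build a coverage track from bedGraph-style runs
#'
#' @param runs Tibble with columns `chrom`, `start`, `end`, `score`
#'   (0-based half-open, per-bp coverage). Gaps are treated as zero
#'   coverage; runs must not overlap.
#' @param chrom_sizes Tibble with columns `chrom`, `length`.
#' @return An object of class `coverage_track` holding one run-length
#'   vector per chromosome and the genome-wide mean per-bp coverage (total
#'   coverage divided by genome length).
#' @export
coverage_track <- function(runs, chrom_sizes) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(runs)),
            all(c("chrom", "length") %in% names(chrom_sizes)))
  if (any(runs$score < 0)) stop_bad_arg("coverage must be non-negative")
  if (any(runs$end <= runs$start)) stop_bad_arg("runs must satisfy start < end")
  rle_list <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    chrom <- chrom_sizes$chrom[i]; len <- chrom_sizes$length[i]
    r <- runs[runs$chrom == chrom, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 0) {
      if (any(r$start[-1] < r$end[-nrow(r)])) {
        stop_bad_arg("overlapping coverage runs on %s", chrom)
      }
      if (max(r$end) > len) stop_bad_arg("coverage runs exceed %s length", chrom)
    }
    starts <- c(0, r$end); ends <- c(r$start, len)
    gaps <- ends - starts
    vals <- c(rep(0, nrow(r) + 1), r$score)
    lens <- c(gaps, r$end - r$start)
    pos <- c(starts, r$start)
    keep <- lens > 0
    o <- order(pos[keep])
    S4Vectors::Rle(vals[keep][o], lens[keep][o])
  })
  names(rle_list) <- chrom_sizes$chrom
  total <- sum(vapply(rle_list, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                                 S4Vectors::runLength(r)), numeric(1)))
  genome_len <- sum(as.numeric(chrom_sizes$length))
  structure(list(rle = rle_list,
                 chrom_sizes = as_tibble(chrom_sizes),
                 global_mean = total / genome_len),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), genome-wide mean %.4g per bp\n",
              nrow(x$chrom_sizes), x$global_mean))
  invisible(x)
}

as_coverage_track <- function(x, chrom_sizes = NULL) {
  if (inherits(x, "coverage_track")) return(x)
  if (is.null(chrom_sizes)) stop_bad_arg("`chrom_sizes` required to build a coverage track")
  coverage_track(x, chrom_sizes)
}

#' Aggregate coverage into per-region log-ratio signals
#'
#' For each region the mean per-bp coverage is computed and log-ratio
#' transformed relative to the genome-wide average per-bp coverage:
#' `signal = log((mean + pseudo) / global_mean, log_base)`.
#'
#' @param track A [coverage_track()] (or bedGraph-style runs plus
#'   `chrom_sizes`).
#' @param regions Tibble with `chrom`, `start`, `end` and optionally
#'   `region_id`.
#' @param pseudo Pseudo-coverage added to the region mean before the ratio.
#'   `NULL` (default) uses one fragment-bp per region, i.e. `1 / width`;
#'   `0` requests the exact ratio and signals an error on zero-coverage
#'   regions.
#' @param log_base Base of the logarithm (default 2).
#' @param chrom_sizes Only used when `track` is a plain run table.
#' @return Tibble with `region_id`, `chrom`, `start`, `end`,
#'   `mean_coverage`, `signal`.
#' @export
aggregate_region_signal <- function(track, regions, pseudo = NULL,
                                    log_base = 2, chrom_sizes = NULL) {
  track <- as_coverage_track(track, chrom_sizes)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (track$global_mean <= 0) {
    stop_bad_arg("cannot normalize against an all-zero coverage track")
  }
  if (any(regions$end <= regions$start) || any(regions$start < 0)) {
    stop_bad_arg("regions must satisfy 0 <= start < end")
  }
  region_id <- regions[["region_id"]] %||%
    sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  means <- numeric(nrow(regions))
  for (chrom in unique(regions$chrom)) {
    idx <- which(regions$chrom == chrom)
    rle <- track$rle[[chrom]]
    if (is.null(rle)) stop_bad_arg("region on unknown chromosome %s", chrom)
    if (any(regions$end[idx] > length(rle))) {
      stop_bad_arg("region outside %s bounds", chrom)
    }
    v <- IRanges::Views(rle, start = regions$start[idx] + 1L,
                        end = regions$end[idx])
    means[idx] <- IRanges::viewMeans(v)
  }
  width <- regions$end - regions$start
  eps <- if (is.null(pseudo)) 1 / width else rep_len(pseudo, nrow(regions))
  if (any(means + eps <= 0)) {
    stop_bad_arg("zero-coverage region with pseudo-coverage 0: log of zero")
  }
  tibble(region_id = region_id, chrom = regions$chrom,
         start = regions$start, end = regions$end,
         mean_coverage = means,
         signal = log((means + eps) / track$global_mean, base = log_base))
}

#' Quantile-normalize signal columns
#'
#' Forces every column (time point) to share one value distribution: each
#' column's sorted values are replaced by the across-column means of sorted
#' values, preserving within-column ranks; ties receive the mean of the
#' tied target values.
#'
#' @param x Numeric matrix or data frame (rows = regions, columns = time
#'   points).
#' @return Object of the same shape and type as the input.
#' @export
quantile_normalize <- function(x) {
  was_df <- is.data.frame(x)
  m <- as.matrix(x)
  if (!is.numeric(m)) stop_bad_arg("`x` must be numeric")
  if (anyNA(m)) stop_bad_arg("`x` contains missing values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  if (was_df) as_tibble(as.data.frame(out)) else out
}

# Minimal union-find over integer indices.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}

#' Merge per-time-point peak sets into universal peaks
#'
#' Peaks from different time points are merged (transitively) when their
#' Jaccard overlap `|intersection| / |union|` is at least `jaccard_min`
#' *or* one peak is contained within the other. Each universal peak is the
#' coordinate union of its merged cluster and records the contributing time
#' points.
#'
#' @param peak_sets Named list of BED-style tibbles (`chrom`, `start`,
#'   `end`), one per time point; each set must be internally
#'   non-overlapping per chromosome.
#' @param jaccard_min Minimum Jaccard overlap for merging (default 0.9).
#' @return Tibble with `chrom`, `start`, `end`, `sources`
#'   (comma-separated contributing set names), `n_source`, `n_peaks`,
#'   sorted by position.
#' @export
merge_universal_peaks <- function(peak_sets, jaccard_min = 0.9) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
  if (is.null(names(peak_sets)) || any(names(peak_sets) == "")) {
    names(peak_sets) <- paste0("t", seq_along(peak_sets))
  }
  all_peaks <- imap(peak_sets, function(p, nm) {
    stopifnot(all(c("chrom", "start", "end") %in% names(p)))
    if (any(p$end <= p$start)) stop_bad_arg("malformed interval in set %s", nm)
    for (chrom in unique(p$chrom)) {
      q <- p[p$chrom == chrom, , drop = FALSE]
      q <- q[order(q$start), , drop = FALSE]
      if (nrow(q) > 1 && any(q$start[-1] < q$end[-nrow(q)])) {
        stop_bad_arg("peak set %s self-overlaps on %s", nm, chrom)
      }
    }
    mutate(p[c("chrom", "start", "end")], source = nm)
  }) |> list_rbind()
  n <- nrow(all_peaks)
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  sources = character(), n_source = integer(),
                  n_peaks = integer()))
  }
  parent <- uf_new(n)
  for (chrom in unique(all_peaks$chrom)) {
    idx <- which(all_peaks$chrom == chrom)
    ir <- IRanges::IRanges(start = all_peaks$start[idx] + 1L,
                           end = all_peaks$end[idx])
    hits <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- qh < sh &
      all_peaks$source[idx[qh]] != all_peaks$source[idx[sh]]
    qh <- qh[keep]; sh <- sh[keep]
    if (length(qh)) {
      s1 <- all_peaks$start[idx[qh]]; e1 <- all_peaks$end[idx[qh]]
      s2 <- all_peaks$start[idx[sh]]; e2 <- all_peaks$end[idx[sh]]
      inter <- pmin(e1, e2) - pmax(s1, s2)
      uni <- pmax(e1, e2) - pmin(s1, s2)
      contained <- (s1 <= s2 & e2 <= e1) | (s2 <= s1 & e1 <= e2)
      mergeable <- contained | (inter / uni >= jaccard_min)
      for (h in which(mergeable)) {
        parent <- uf_union(parent, idx[qh[h]], idx[sh[h]])
      }
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  all_peaks |>
    mutate(cluster = root) |>
    group_by(.data$chrom, .data$cluster) |>
    summarise(start = min(.data$start), end = max(.data$end),
              sources = paste(sort(unique(.data$source)), collapse = ","),
              n_source = dplyr::n_distinct(.data$source),
              n_peaks = n(), .groups = "drop") |>
    select(-"cluster") |>
    arrange(.data$chrom, .data$start, .data$end)
}

# Signed strand-oriented distance from TSS to a position: negative values
# are upstream of the TSS along the gene's strand, positive downstream.
oriented_distance <- function(center, tss, strand) {
  ifelse(strand == "+", center - tss, tss - center)
}

check_strand <- function(genes, strand_agnostic) {
  if (!"strand" %in% names(genes) || anyNA(genes$strand) ||
      any(!genes$strand %in% c("+", "-"))) {
    if (!strand_agnostic) {
      stop_bad_arg("gene annotation lacks usable strand; set `strand_agnostic = TRUE`")
    }
  }
  invisible(genes)
}

# All (peak/point index, gene index, signed distance) pairs with the point
# center inside the strand-oriented [-upstream, +downstream] TSS window.
center_in_window_pairs <- function(chrom, center, genes, upstream, downstream,
                                   strand_agnostic = FALSE) {
  check_strand(genes, strand_agnostic)
  if (strand_agnostic) {
    lo <- genes$tss - max(upstream, downstream)
    hi <- genes$tss + max(upstream, downstream)
  } else {
    lo <- ifelse(genes$strand == "+", genes$tss - upstream, genes$tss - downstream)
    hi <- ifelse(genes$strand == "+", genes$tss + downstream, genes$tss + upstream)
  }
  out <- list()
  for (ch in unique(chrom)) {
    pi <- which(chrom == ch); gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    pts <- IRanges::IRanges(start = center[pi], width = 1L)
    win <- IRanges::IRanges(start = lo[gi], end = hi[gi])
    hits <- IRanges::findOverlaps(pts, win)
    if (!length(hits)) next
    p <- pi[S4Vectors::queryHits(hits)]; g <- gi[S4Vectors::subjectHits(hits)]
    d <- if (strand_agnostic) abs(center[p] - genes$tss[g]) else
      oriented_distance(center[p], genes$tss[g], genes$strand[g])
    out[[length(out) + 1]] <- tibble(point = p, gene = g, distance = d)
  }
  if (!length(out)) return(tibble(point = integer(), gene = integer(),
                                  distance = numeric()))
  list_rbind(out)
}

peak_centers <- function(peaks) as.integer(floor((peaks$start + peaks$end) / 2))

#' Annotate peaks relative to gene TSSs
#'
#' Three-step precedence: a peak whose center lies within `promoter_up` bp
#' upstream to `promoter_down` bp downstream of any TSS (strand-oriented)
#' is a "Promoter" peak; otherwise a center within `promoter_up` to
#' `upstream_max` bp upstream is "Upstream"; everything else is "other".
#'
#' @param peaks Tibble with `chrom`, `start`, `end` (and optional `name`).
#' @param genes Tibble with `gene_id`, `chrom`, `tss`, `strand`.
#' @param promoter_up,promoter_down Promoter window extents in bp
#'   (defaults 2000 upstream, 100 downstream).
#' @param upstream_max Outer bound of the "Upstream" category in bp.
#' @param strand_agnostic Use symmetric windows when strand is absent.
#' @return Tibble with `peak_id`, `category`, `gene_id` (nearest qualifying
#'   TSS, `NA` for "other"), `distance` (signed, strand-oriented).
#' @export
annotate_peaks <- function(peaks, genes, promoter_up = 2000,
                           promoter_down = 100, upstream_max = 10000,
                           strand_agnostic = FALSE) {
  peak_id <- peaks[["name"]] %||% sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  centers <- peak_centers(peaks)
  pairs <- center_in_window_pairs(peaks$chrom, centers, genes,
                                  upstream = upstream_max,
                                  downstream = promoter_down,
                                  strand_agnostic = strand_agnostic)
  pairs <- pairs |>
    mutate(category = if (strand_agnostic) dplyr::case_when(
      .data$distance <= promoter_up ~ "Promoter",
      .data$distance <= upstream_max ~ "Upstream",
      TRUE ~ NA_character_) else dplyr::case_when(
      .data$distance >= -promoter_up & .data$distance <= promoter_down ~ "Promoter",
      .data$distance >= -upstream_max & .data$distance < -promoter_up ~ "Upstream",
      TRUE ~ NA_character_)) |>
    filter(!is.na(.data$category)) |>
    mutate(rank = ifelse(.data$category == "Promoter", 1L, 2L)) |>
    group_by(.data$point) |>
    arrange(.data$rank, abs(.data$distance), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  out <- tibble(peak_id = peak_id, category = "other",
                gene_id = NA_character_, distance = NA_real_)
  out$category[pairs$point] <- pairs$category
  out$gene_id[pairs$point] <- genes$gene_id[pairs$gene]
  out$distance[pairs$point] <- pairs$distance
  out
}

#' Map peaks to genes by TSS windows
#'
#' Emits every (peak, gene) pair whose peak center lies within `upstream`
#' bp upstream to `downstream` bp downstream of the gene TSS, oriented by
#' gene strand. A peak may map to several genes and vice versa.
#'
#' @inheritParams annotate_peaks
#' @param upstream,downstream Window extents in bp (defaults 10 kbp
#'   upstream, 1 kbp downstream).
#' @return Tibble with `peak_id`, `gene_id`, `distance` (signed bp from
#'   TSS along the gene strand).
#' @export
map_peaks_to_genes <- function(peaks, genes, upstream = 10000,
                               downstream = 1000, strand_agnostic = FALSE) {
  peak_id <- peaks[["name"]] %||% sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  centers <- peak_centers(peaks)
  pairs <- center_in_window_pairs(peaks$chrom, centers, genes,
                                  upstream = upstream, downstream = downstream,
                                  strand_agnostic = strand_agnostic)
  if (!strand_agnostic) {
    pairs <- filter(pairs, .data$distance >= -upstream,
                    .data$distance <= downstream)
  }
  tibble(peak_id = peak_id[pairs$point],
         gene_id = genes$gene_id[pairs$gene],
         distance = pairs$distance) |>
    arrange(.data$peak_id, .data$gene_id)
}

#' Aggregate motif-instance accessibility into per-gene features
#'
#' For each gene and motif, the log-ratio signals of all motif instances
#' whose centers fall in the gene's strand-oriented window (default
#' -10 kbp..+1 kbp of the TSS) are summed, per time point; the resulting
#' (gene, motif) x time matrix is then quantile-normalized across time
#' points. Motifs with no instance in any gene window are dropped with a
#' message.
#'
#' @param tracks List of [coverage_track()] objects, one per time point.
#' @param motifs Tibble of motif instances: `chrom`, `start`, `end`,
#'   `motif_id`.
#' @param genes Gene table with `gene_id`, `chrom`, `tss`, `strand`.
#' @param times Numeric time points labelling `tracks`.
#' @param upstream,downstream Window extents in bp.
#' @param pseudo,log_base Passed to [aggregate_region_signal()].
#' @param normalize Quantile-normalize across time (default TRUE).
#' @return A [feature_tensor()] (genes x motifs x times).
#' @export
aggregate_motif_features <- function(tracks, motifs, genes, times = NULL,
                                     upstream = 10000, downstream = 1000,
                                     pseudo = NULL, log_base = 2,
                                     normalize = TRUE) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  times <- times %||% seq_along(tracks)
  centers <- peak_centers(motifs)
  pairs <- center_in_window_pairs(motifs$chrom, centers, genes,
                                  upstream = upstream, downstream = downstream)
  mapped_motifs <- sort(unique(motifs$motif_id[pairs$point]))
  dropped <- setdiff(unique(motifs$motif_id), mapped_motifs)
  if (length(dropped)) {
    inform(sprintf("dropping %d motif(s) with no instance in any gene window: %s",
                   length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  if (!nrow(pairs)) stop_bad_arg("no motif instance maps to any gene window")
  gene_ids <- genes$gene_id
  vals <- array(0, dim = c(length(gene_ids), length(mapped_motifs),
                           length(tracks)))
  inst <- motifs[pairs$point, , drop = FALSE]
  gi <- match(genes$gene_id[pairs$gene], gene_ids)
  mi <- match(inst$motif_id, mapped_motifs)
  for (cc in seq_along(tracks)) {
    sig <- aggregate_region_signal(tracks[[cc]], inst, pseudo = pseudo,
                                   log_base = log_base)$signal
    acc <- rowsum(sig, group = (mi - 1L) * length(gene_ids) + gi)
    idx <- as.integer(rownames(acc))
    slice <- matrix(0, length(gene_ids), length(mapped_motifs))
    slice[idx] <- acc[, 1]
    vals[, , cc] <- slice
  }
  if (normalize && length(tracks) >= 2) {
    flat <- matrix(vals, ncol = length(tracks))
    vals <- array(as.matrix(quantile_normalize(flat)), dim = dim(vals))
  }
  feature_tensor(vals, gene_ids, mapped_motifs, times)
}

#' Append a promoter-accessibility feature to a feature tensor
#'
#' @param tensor A [feature_tensor()].
#' @param promoter_signal Genes x times matrix of promoter signals (rows
#'   matching `tensor$genes`).
#' @param name Feature name (default `"promoter"`).
#' @return A [feature_tensor()] with one extra feature.
#' @export
add_promoter_feature <- function(tensor, promoter_signal, name = "promoter") {
  stopifnot(inherits(tensor, "feature_tensor"),
            nrow(promoter_signal) == length(tensor$genes),
            ncol(promoter_signal) == length(tensor$times))
  d <- dim(tensor$values)
  vals <- array(0, dim = c(d[1], d[2] + 1L, d[3]))
  vals[, seq_len(d[2]), ] <- tensor$values
  vals[, d[2] + 1L, ] <- as.matrix(promoter_signal)
  feature_tensor(vals, tensor$genes, c(tensor$features, name), tensor$times)
}

#' Cluster accessibility profiles with k-means and silhouette selection
#'
#' Profiles are zero-meaned per region and clustered with k-means for each
#' candidate `k`; the mean silhouette width under correlation distance
#' (`1 - Pearson r` between profiles) selects the final `k` (ties go to
#' the smaller `k`). Constant profiles, whose correlation distance is
#' undefined, are excluded with a warning.
#'
#' @param mat Regions x times numeric matrix (rownames = region ids).
#' @param k_grid Candidate cluster counts (each must satisfy
#'   `2 <= k <` number of usable regions).
#' @param nstart k-means restarts.
#' @param seed Optional seed for the k-means initializations.
#' @return List of class `accessibility_clusters` with `chosen_k`,
#'   `report` (tibble of k and mean silhouette), `labels` (named vector for
#'   the chosen k) and `excluded` region ids.
#' @export
cluster_accessibility_profiles <- function(mat, k_grid, nstart = 10,
                                           seed = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("r%d", seq_len(nrow(mat)))
  const <- apply(mat, 1, function(r) sd(r) == 0 || !all(is.finite(r)))
  if (any(const)) {
    warn(sprintf("excluding %d constant profile(s): correlation distance undefined",
                 sum(const)))
  }
  zm <- mat[!const, , drop = FALSE]
  zm <- zm - rowMeans(zm)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 2) || any(k_grid >= nrow(zm))) {
    stop_bad_arg("each k must satisfy 2 <= k < number of usable regions (%d)",
                 nrow(zm))
  }
  d <- as.dist(1 - cor(t(zm)))
  with_seed(seed, {
    report <- map(k_grid, function(k) {
      km <- kmeans(zm, centers = k, nstart = nstart)
      sil <- cluster::silhouette(km$cluster, d)
      tibble(k = k, mean_silhouette = mean(sil[, "sil_width"]),
             labels = list(setNames(km$cluster, rownames(zm))))
    }) |> list_rbind()
    chosen <- report$k[which.max(report$mean_silhouette)]
    structure(list(chosen_k = chosen, report = select(report, -"labels"),
                   labels = report$labels[[match(chosen, report$k)]],
                   excluded = rownames(mat)[const]),
              class = "accessibility_clusters")
  })
}

#' @export
print.accessibility_clusters <- function(x, ...) {
  cat(sprintf("<accessibility_clusters> chosen k = %d (mean silhouette %.3f)\n",
              x$chosen_k,
              x$report$mean_silhouette[match(x$chosen_k, x$report$k)]))
  invisible(x)
}
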