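# broom-style tidiers and ggplot2 autoplot methods for the fitted
# objects, so results drop straight into dplyr/ggplot workflows.

#' Tidy an expression-module fit
#'
#' @param x An `escarole_fit`.
#' @param ... Unused.
#' @return Tibble with one row per (gene, time): `gene_id`, `time`,
#'   `module`.
#' @export
tidy.escarole_fit <- function(x, ...) {
  am <- x$assignments
  tibble(gene_id = rep(rownames(am), times = ncol(am)),
         time = rep(as.numeric(colnames(am)), each = nrow(am)),
         module = as.integer(am))
}

#' @rdname tidy.escarole_fit
#' @return For `glance`: one row with `k`, `n_genes`, `n_times`,
#'   `total_loglik`, `total_bic`, `n_transitioning`.
#' @export
glance.escarole_fit <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$assignments),
         n_times = ncol(x$assignments),
         total_loglik = sum(x$report$loglik),
         total_bic = sum(x$report$bic),
         n_transitioning = length(find_transitioning_genes(x)))
}

#' Tidy a DRMN fit
#'
#' @param x A `drmn_fit`.
#' @param ... Unused.
#' @return Tibble with one row per (module, time, feature): `module`,
#'   `time`, `feature`, `weight` (exact zeros retained).
#' @export
tidy.drmn_fit <- function(x, ...) {
  as_tibble_theta(x)
}

#' @rdname tidy.drmn_fit
#' @return For `glance`: one row with `k`, `n_features`, `n_times`,
#'   `rho1`, `rho2`, `rho3`, `total_objective`, `n_nonzero`.
#' @export
glance.drmn_fit <- function(x, ...) {
  tibble(k = x$k, n_features = length(x$features),
         n_times = length(x$times),
         rho1 = x$hyper$rho1, rho2 = x$hyper$rho2, rho3 = x$hyper$rho3,
         total_objective = sum(x$objective),
         n_nonzero = sum(x$theta != 0))
}

#' Tidy a transitioning-set clustering
#'
#' @param x A `transitioning_sets` object.
#' @param ... Unused.
#' @return The membership tibble (`set_id`, `gene_id`).
#' @export
tidy.transitioning_sets <- function(x, ...) {
  x$sets
}

#' @rdname tidy.transitioning_sets
#' @export
glance.transitioning_sets <- function(x, ...) {
  tibble(n_sets = length(unique(x$sets$set_id)),
         n_genes = nrow(x$sets),
         n_discarded = length(x$discarded),
         distance_threshold = x$distance_threshold,
         min_size = x$min_size)
}

#' Plot module mean-expression trajectories
#'
#' @param object An `escarole_fit`.
#' @param ... Unused.
#' @return A ggplot: module mean expression over time, one line per
#'   module.
#' @export
autoplot.escarole_fit <- function(object, ...) {
  mm <- object$module_means
  df <- tibble(module = factor(rep(seq_len(nrow(mm)), times = ncol(mm))),
               time = rep(object$times, each = nrow(mm)),
               mean_expression = as.vector(mm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean_expression,
                                   colour = .data$module)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "module mean expression",
                  colour = "module")
}

#' Plot a DRMN coefficient heatmap
#'
#' @param object A `drmn_fit`.
#' @param modules Modules to show (default all).
#' @param drop_zero Drop features that are zero everywhere (default TRUE).
#' @param ... Unused.
#' @return A ggplot: feature x time coefficient heatmap, faceted by
#'   module.
#' @export
autoplot.drmn_fit <- function(object, modules = NULL, drop_zero = TRUE, ...) {
  df <- tidy(object)
  if (!is.null(modules)) df <- filter(df, .data$module %in% modules)
  if (drop_zero) {
    keep <- df |> summarise(any_nz = any(.data$weight != 0),
                            .by = c("module", "feature"))
    df <- inner_join(df, filter(keep, .data$any_nz), by = c("module", "feature"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$time), y = .data$feature,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~ module, scales = "free_y") +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time (h)", y = NULL, fill = "weight")
}
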