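#' Tidy a phasing result
#'
#' @param x A `phasing_result` from [estimate_period()].
#' @param ... Unused.
#' @return The autocorrelation curve as a tibble (`lag`, `r`).
#' @export
tidy.phasing_result <- function(x, ...) x$acf

#' @rdname tidy.phasing_result
#' @return `glance()` returns a one-row tibble with `period`, `peak_r`,
#'   `periodic` and the search range.
#' @export
glance.phasing_result <- function(x, ...) {
  tibble(period = x$period, peak_r = x$peak_r, periodic = x$periodic,
         lag_min = x$lag_range[1], lag_max = x$lag_range[2])
}

#' Tidy a cluster result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return The per-gene label tibble (`gene_id`, `cluster`).
#' @export
tidy.cluster_result <- function(x, ...) x$labels

#' @rdname tidy.cluster_result
#' @return `glance()` returns a one-row tibble with `k`, `n_genes`,
#'   `tot_withinss`, `seed` and (when present) the shifted cluster label.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(
    k = x$k, n_genes = nrow(x$labels), tot_withinss = x$tot_withinss,
    seed = x$seed,
    shifted_cluster = x$shifted_cluster %||% NA_integer_
  )
}

#' Tidy a pipeline run report
#'
#' @param x A `run_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble with one row per headline metric (`metric`, `value`).
#' @export
tidy.run_report <- function(x, ...) {
  num <- x$metrics[vapply(x$metrics, is.numeric, logical(1))]
  tibble(metric = names(num), value = unlist(num, use.names = FALSE))
}
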