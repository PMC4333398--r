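## rows with more than `max_missing` NA are dropped (reported); remaining
## NAs are filled by within-row linear interpolation, then rows are
## z-scored. Returns list(x = matrix, dropped = gene ids).
prepare_rows <- function(m, max_missing = 0.2, standardize = TRUE) {
  v <- mg_values(m)
  frac_na <- rowMeans(is.na(v))
  drop <- frac_na > max_missing
  if (any(drop)) {
    inform(paste0(sum(drop), " gene(s) dropped (> ", 100 * max_missing,
                  "% missing cells)."))
  }
  v <- v[!drop, , drop = FALSE]
  if (nrow(v) == 0) abort("no rows left after the missingness filter.")
  v <- t(apply(v, 1, function(r) zoo::na.approx(r, na.rm = FALSE, rule = 2)))
  if (standardize) {
    sds <- apply(v, 1, sd)
    flat <- sds == 0 | !is.finite(sds)
    if (any(flat)) {
      inform(paste0(sum(flat), " constant row(s) dropped before z-scoring."))
      v <- v[!flat, , drop = FALSE]
    }
    if (nrow(v) == 0) abort("no non-constant rows to cluster.")
    v <- t(scale(t(v)))
  }
  list(x = v, dropped = rownames(mg_values(m))[drop])
}

new_cluster_result <- function(km, x, seed, n_init, extra = list()) {
  res <- c(list(
    labels = tibble(gene_id = rownames(x), cluster = unname(km$cluster)),
    centroids = km$centers,
    k = nrow(km$centers),
    seed = seed,
    n_init = n_init,
    tot_withinss = km$tot.withinss
  ), extra)
  structure(res, class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, %d genes, total within-SS = %.2f\n",
              x$k, nrow(x$labels), x$tot_withinss))
  print(table(x$labels$cluster))
  invisible(x)
}

#' k-means clustering of per-gene metagene profiles
#'
#' Rows with more than `max_missing` missing cells are dropped (and
#' reported), remaining gaps are filled by within-row linear interpolation,
#' rows are z-scored (so the grouping reflects profile *shape*, not
#' per-gene signal level), and k-means is run with `n_init` random
#' restarts, keeping the solution with the best total within-cluster sum
#' of squares. Deterministic given `seed`. Cluster labels are `1..k`.
#'
#' @param m A `metagene_matrix`.
#' @param k Number of clusters (default 6, the grouping used for 5'-end
#'   nucleosomal-profile classes).
#' @param seed Integer seed.
#' @param n_init Number of random restarts.
#' @param max_missing Maximum tolerated fraction of missing cells per row.
#' @return A `cluster_result`: `labels` (tibble `gene_id`, `cluster`),
#'   `centroids` (k x offsets), `k`, `seed`, `n_init`, `tot_withinss`,
#'   `dropped`.
#' @export
cluster_profiles <- function(m, k = 6, seed = 1, n_init = 25,
                             max_missing = 0.2) {
  prep <- prepare_rows(m, max_missing)
  if (nrow(prep$x) < k) abort("fewer rows than clusters.")
  set.seed(seed)
  km <- kmeans(prep$x, centers = k, nstart = n_init, iter.max = 100)
  new_cluster_result(km, prep$x, seed, n_init, list(dropped = prep$dropped))
}

#' Cluster genes by their between-condition profile change
#'
#' Each input matrix's rows are z-scored, the per-gene difference
#' (`mut - wt`) is formed, and the difference rows are clustered with
#' k-means (the differences themselves are deliberately not re-scaled, so
#' genes whose profiles did not move form a tight near-zero cluster). The
#' cluster with the largest mean absolute difference is reported as the
#' "shifted" cluster — the gene set whose profiles moved between
#' conditions, e.g. upon deletion of a chromatin remodeler.
#'
#' @param m_wt,m_mut `metagene_matrix` objects on identical genes and
#'   offsets.
#' @param k Number of clusters (2 separates moved from unmoved genes).
#' @inheritParams cluster_profiles
#' @return A `cluster_result` with additional fields `shifted_cluster`
#'   (label) and `shifted_genes` (gene ids).
#' @export
cluster_condition_shift <- function(m_wt, m_mut, k = 2, seed = 1,
                                    n_init = 25, max_missing = 0.2) {
  if (!identical(m_wt$gene_id, m_mut$gene_id) ||
      !identical(mg_offsets(m_wt), mg_offsets(m_mut))) {
    abort("the two matrices must cover the same genes and offsets.")
  }
  a <- prepare_rows(m_wt, max_missing)
  b <- prepare_rows(m_mut, max_missing)
  common <- intersect(rownames(a$x), rownames(b$x))
  if (length(common) < k) abort("fewer rows than clusters after filtering.")
  d <- b$x[common, , drop = FALSE] - a$x[common, , drop = FALSE]
  set.seed(seed)
  if (nrow(unique(d)) < k) {
    ## degenerate case (e.g. identical conditions): one cluster of all rows
    km <- list(
      cluster = setNames(rep(1L, nrow(d)), rownames(d)),
      centers = matrix(colMeans(d), 1, dimnames = list(NULL, colnames(d))),
      tot.withinss = sum(sweep(d, 2, colMeans(d))^2)
    )
  } else {
    km <- kmeans(d, centers = k, nstart = n_init, iter.max = 100)
  }
  mean_abs <- tapply(rowMeans(abs(d)), km$cluster, mean)
  shifted <- as.integer(names(mean_abs)[which.max(mean_abs)])
  res <- new_cluster_result(km, d, seed, n_init, list(
    shifted_cluster = shifted,
    shifted_genes = rownames(d)[km$cluster == shifted],
    dropped = union(a$dropped, b$dropped)
  ))
  res
}
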