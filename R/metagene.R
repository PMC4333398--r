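#' Build an anchor-aligned metagene matrix
#'
#' One row per gene, one column per anchor-relative offset on the probe
#' grid. Offsets are in bp relative to the anchor with positive values
#' downstream in the transcription direction: for a plus-strand gene the
#' column at offset `o` reads the track at `anchor + o`, for a minus-strand
#' gene at `anchor - o`, so minus-strand rows are mirror-oriented. Each
#' cell takes the value of the probe nearest to its target position within
#' half a grid step; positions without a probe are missing.
#'
#' @param track A [signal_track()].
#' @param genes Gene annotation tibble (requires `gene_id`, `chrom`,
#'   `strand`, `tss`, `pa`).
#' @param anchor `"tss"` or `"pa"`.
#' @param window Length-2 numeric, `c(lo, hi)` in bp around the anchor.
#' @return A `metagene_matrix`: a tibble with `gene_id` plus one numeric
#'   column per offset, and attributes `offsets`, `anchor`, `scale`,
#'   `spacing`.
#' @export
build_matrix <- function(track, genes, anchor = c("tss", "pa"), window) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0) abort("empty gene list.")
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be c(lo, hi) with lo < hi.")
  }
  step <- track_spacing(track)
  if (!is.finite(step) || step < 1) abort("cannot infer the track's probe spacing.")
  offsets <- seq(ceiling(window[1] / step), floor(window[2] / step)) * step

  anchor_pos <- if (anchor == "tss") genes$tss else genes$pa
  q <- tidyr::expand_grid(i = seq_len(nrow(genes)), offset = offsets) |>
    mutate(
      gene_id = genes$gene_id[.data$i],
      chrom = genes$chrom[.data$i],
      strand = genes$strand[.data$i],
      target = anchor_pos[.data$i] +
        gene_dir(genes$strand[.data$i]) * .data$offset
    )
  q$value <- NA_real_
  for (key in unique(paste(q$chrom, q$strand))) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    tsub <- track[track$chrom == parts[1] & track$strand == parts[2], ]
    sel <- which(q$chrom == parts[1] & q$strand == parts[2])
    if (nrow(tsub) == 0 || length(sel) == 0) next
    tpos <- tsub$pos
    idx <- findInterval(q$target[sel], tpos)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(tpos))
    dlo <- abs(tpos[lo] - q$target[sel])
    dhi <- abs(tpos[hi] - q$target[sel])
    best <- ifelse(dhi < dlo, hi, lo)
    dist <- pmin(dlo, dhi)
    ok <- dist <= step / 2
    q$value[sel[ok]] <- tsub$value[best[ok]]
  }
  wide <- q |>
    select("gene_id", "offset", "value") |>
    tidyr::pivot_wider(names_from = "offset", values_from = "value")
  wide <- wide[match(genes$gene_id, wide$gene_id), ]
  structure(wide,
    offsets = offsets, anchor = anchor,
    scale = track_scale(track), spacing = step,
    class = c("metagene_matrix", class(as_tibble(wide)))
  )
}

mg_offsets <- function(m) attr(m, "offsets")

#' Extract the numeric matrix from a metagene matrix
#'
#' @param m A `metagene_matrix`.
#' @return A numeric matrix (genes x offsets) with gene ids as row names.
#' @export
mg_values <- function(m) {
  v <- as.matrix(as_tibble(m)[, -1])
  mode(v) <- "numeric"
  rownames(v) <- m$gene_id
  colnames(v) <- as.character(mg_offsets(m))
  v
}

new_profile <- function(offset, value, n, anchor, scale, stat = "mean",
                        spacing = NA_integer_) {
  structure(
    tibble(offset = offset, value = value, n = n),
    anchor = anchor, scale = scale, stat = stat, spacing = spacing,
    class = c("metagene_profile", class(tibble()))
  )
}

#' Average a metagene matrix into a profile
#'
#' Per-offset mean (or median) over the non-missing cells, with the number
#' of contributing genes reported per offset; offsets supported by fewer
#' than `min_n` genes are masked (value `NA`).
#'
#' @param m A `metagene_matrix`.
#' @param stat `"mean"` (the default, matching average-profile figures) or
#'   `"median"`.
#' @param min_n Minimum per-offset support.
#' @return A `metagene_profile` tibble: `offset`, `value`, `n`.
#' @export
average_profile <- function(m, stat = c("mean", "median"), min_n = 20) {
  stat <- match.arg(stat)
  v <- mg_values(m)
  if (nrow(v) == 0) abort("empty metagene matrix.")
  n <- colSums(!is.na(v))
  f <- if (stat == "mean") colMeans else function(x, ...) apply(x, 2, median, na.rm = TRUE)
  val <- if (stat == "mean") colMeans(v, na.rm = TRUE) else apply(v, 2, median, na.rm = TRUE)
  val[n < min_n] <- NA_real_
  val[n == 0] <- NA_real_
  new_profile(mg_offsets(m), unname(val), unname(n),
              anchor = attr(m, "anchor"), scale = attr(m, "scale"),
              stat = stat, spacing = attr(m, "spacing"))
}

profile_linear_values <- function(p) {
  if (identical(attr(p, "scale"), "log2")) 2^p$value else p$value
}

#' Ratio of two average profiles
#'
#' Per-offset `log2((num + pseudo) / (den + pseudo))` computed on the
#' linear scale (log2 profiles are antilogged internally). Used e.g. for
#' the active/total "specific activity" ratio of nascent run-on over
#' polymerase ChIP, where low values flag a high backtracked fraction.
#'
#' @param numerator,denominator `metagene_profile`s on identical offsets.
#' @param pseudo Pseudocount on the linear scale.
#' @return A `metagene_profile` on the log2-ratio scale; `n` is the
#'   per-offset minimum of the two inputs.
#' @export
ratio_profile <- function(numerator, denominator, pseudo = 0) {
  if (!identical(numerator$offset, denominator$offset)) {
    abort("profiles are on different offset grids.")
  }
  a <- profile_linear_values(numerator)
  b <- profile_linear_values(denominator)
  new_profile(
    numerator$offset,
    log2((a + pseudo) / (b + pseudo)),
    pmin(numerator$n, denominator$n),
    anchor = attr(numerator, "anchor"), scale = "log2",
    stat = paste0("ratio(", attr(numerator, "stat") %||% "mean", ")"),
    spacing = attr(numerator, "spacing")
  )
}

#' Split genes into groups by a covariate
#'
#' Supports the groupings used throughout the analysis: categorical splits
#' (promoter class, gene class, intron status), tertile splits of a numeric
#' covariate (low / medium / high), and extreme-thirds splits (top third vs
#' bottom third, e.g. by H2AZ enrichment). Genes with a missing covariate
#' go to group `"unknown"`.
#'
#' @param genes Gene tibble.
#' @param by Name of the covariate column.
#' @param method `"categorical"`, `"tertile"` or `"extreme_thirds"`.
#' @return Named list of gene-id character vectors.
#' @export
#' @examples
#' g <- tibble::tibble(gene_id = letters[1:9], score = 1:9)
#' group_genes(g, "score", "tertile")$low
group_genes <- function(genes, by,
                        method = c("categorical", "tertile", "extreme_thirds")) {
  method <- match.arg(method)
  if (!by %in% names(genes)) abort(paste0("no column `", by, "` in `genes`."))
  x <- genes[[by]]
  miss <- is.na(x)
  out <- list()
  if (method == "categorical") {
    for (lev in sort(unique(as.character(x[!miss])))) {
      out[[lev]] <- genes$gene_id[!miss & as.character(x) == lev]
    }
  } else {
    if (!is.numeric(x)) abort("tertile splits need a numeric covariate.")
    if (sum(!miss) < 3) abort("fewer than 3 genes with a covariate value; cannot split into tertiles.")
    tert <- ntile(x[!miss], 3)
    ids <- genes$gene_id[!miss]
    if (method == "tertile") {
      out$low <- ids[tert == 1]
      out$medium <- ids[tert == 2]
      out$high <- ids[tert == 3]
    } else {
      out$bottom_third <- ids[tert == 1]
      out$top_third <- ids[tert == 3]
    }
  }
  if (any(miss)) out$unknown <- genes$gene_id[miss]
  out
}

#' Order a metagene matrix by gene length (heat-map layout)
#'
#' Rows are sorted by transcribed-unit length (`|pa - tss|`, ascending),
#' the layout used for length-ordered heat maps of nascent vs mature
#' signal. With `ratio_with` supplied, each cell becomes the per-gene
#' `log2((m + pseudo) / (ratio_with + pseudo))` on the linear scale — the
#' mRNA-vs-nascent ratio panel.
#'
#' @param m A `metagene_matrix`.
#' @param genes Gene tibble carrying `tss` and `pa`.
#' @param ratio_with Optional second `metagene_matrix` on the same genes
#'   and offsets (the denominator).
#' @param pseudo Pseudocount on the linear scale for the ratio variant.
#' @return A `metagene_matrix` with rows reordered (attribute `row_order`
#'   gives the gene ids shortest-to-longest).
#' @export
length_sorted_heatmap <- function(m, genes, ratio_with = NULL, pseudo = 0) {
  if (!is.null(ratio_with)) {
    if (!identical(m$gene_id, ratio_with$gene_id) ||
        !identical(mg_offsets(m), mg_offsets(ratio_with))) {
      abort("`ratio_with` must cover the same genes and offsets.")
    }
    a <- mg_values(m)
    b <- mg_values(ratio_with)
    if (identical(attr(m, "scale"), "log2")) a <- 2^a
    if (identical(attr(ratio_with, "scale"), "log2")) b <- 2^b
    v <- log2((a + pseudo) / (b + pseudo))
    df <- as_tibble(cbind(tibble(gene_id = m$gene_id), as_tibble(v)))
    m <- structure(df,
      offsets = mg_offsets(m), anchor = attr(m, "anchor"),
      scale = "log2", spacing = attr(m, "spacing"),
      class = class(m)
    )
  }
  len <- setNames(abs(genes$pa - genes$tss), genes$gene_id)
  if (anyNA(len[m$gene_id])) abort("gene lengths unavailable for some matrix rows.")
  ord <- order(len[m$gene_id])
  out <- m[ord, ]
  attrs <- attributes(m)
  for (a in c("offsets", "anchor", "scale", "spacing")) {
    attr(out, a) <- attrs[[a]]
  }
  class(out) <- class(m)
  attr(out, "row_order") <- m$gene_id[ord]
  out
}
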