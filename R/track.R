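#' Signal-track tibbles
#'
#' A signal track is a tibble with columns `chrom` (character), `strand`
#' (`"+"` or `"-"`), `pos` (0-based genomic probe position) and `value`
#' (intensity). Two attributes qualify the values: `scale` (`"linear"` for
#' raw/antilogged intensities, `"log2"` after normalization) and `spacing`
#' (the probe-grid step in bp, when known). Positions are strictly
#' increasing within each `(chrom, strand)`.
#'
#' @param x A data frame with columns `chrom`, `strand`, `pos`, `value`.
#' @param scale `"linear"` or `"log2"`.
#' @param spacing Probe spacing in bp, or `NA` if irregular/unknown.
#' @return A `signal_track` tibble.
#' @export
signal_track <- function(x, scale = c("linear", "log2"), spacing = NA_integer_) {
  scale <- match.arg(scale)
  need <- c("chrom", "strand", "pos", "value")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("signal track is missing column(s): ", paste(miss, collapse = ", ")))
  }
  x <- as_tibble(x)[need]
  x <- arrange(x, .data$chrom, .data$strand, .data$pos)
  if (!all(x$strand %in% c("+", "-"))) abort("`strand` must be '+' or '-'.")
  dup <- x |>
    summarise(bad = anyDuplicated(.data$pos) > 0, .by = c("chrom", "strand"))
  if (any(dup$bad)) abort("probe positions must be unique within (chrom, strand).")
  if (any(!is.finite(x$value))) abort("track values must be finite.")
  if (scale == "linear" && any(x$value < 0)) {
    abort("linear-scale track values must be non-negative.")
  }
  structure(x,
    scale = scale, spacing = spacing,
    class = c("signal_track", class(as_tibble(x)))
  )
}

track_scale <- function(track) attr(track, "scale") %||% "linear"
track_spacing <- function(track) {
  sp <- attr(track, "spacing")
  if (!is.null(sp) && is.finite(sp)) return(as.integer(sp))
  d <- track |>
    mutate(step = .data$pos - lag(.data$pos), .by = c("chrom", "strand")) |>
    filter(is.finite(.data$step))
  if (nrow(d) == 0) return(NA_integer_)
  as.integer(median(d$step))
}

restore_track <- function(df, template, scale = NULL) {
  signal_track(df,
    scale = scale %||% track_scale(template),
    spacing = attr(template, "spacing") %||% NA_integer_
  )
}

#' Convert a log2 track back to the linear scale
#'
#' @param track A `signal_track`.
#' @return The track with `value = 2^value` and scale `"linear"`; a track
#'   already on the linear scale is returned unchanged.
#' @export
linearize_track <- function(track) {
  if (track_scale(track) == "linear") return(track)
  out <- mutate(as_tibble(track), value = 2^.data$value)
  restore_track(out, track, scale = "linear")
}
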