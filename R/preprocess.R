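#' Normalize a sample track against the genomic-DNA control
#'
#' Per-probe log2 ratio of sample to genomic-DNA hybridization, computed on
#' the intersection of the two probe grids; probes present in only one
#' input are dropped. The pseudocount bounds the log ratio where the
#' control is weak; its default, 5% of the median control intensity, is
#' small enough not to attenuate mid-range signal (which matters when
#' antilogged ratios are compared against fold thresholds downstream).
#'
#' @param sample,gdna Linear-scale [signal_track()]s on the same probe grid
#'   (the intersection is taken otherwise).
#' @param pseudocount Added to both numerator and denominator; default
#'   `0.05 * median(gdna$value)`.
#' @return A log2-scale [signal_track()].
#' @export
#' @examples
#' t <- signal_track(data.frame(chrom = "chrI", strand = "+",
#'                              pos = c(0, 8), value = c(4, 4)))
#' g <- signal_track(data.frame(chrom = "chrI", strand = "+",
#'                              pos = c(0, 8), value = c(1, 1)))
#' normalize_by_gdna(t, g, pseudocount = 0)$value  # 2, 2
normalize_by_gdna <- function(sample, gdna, pseudocount = NULL) {
  if (track_scale(sample) != "linear" || track_scale(gdna) != "linear") {
    abort("both tracks must be on the linear scale.")
  }
  pseudocount <- pseudocount %||% (0.05 * median(gdna$value))
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")
  joined <- inner_join(
    as_tibble(sample), as_tibble(gdna),
    by = c("chrom", "strand", "pos"), suffix = c("", ".g")
  )
  if (nrow(joined) == 0) {
    abort("sample and gdna tracks share no probes (grid mismatch).")
  }
  out <- joined |>
    mutate(value = log2((.data$value + pseudocount) /
                          (.data$value.g + pseudocount))) |>
    select("chrom", "strand", "pos", "value")
  restore_track(out, sample, scale = "log2")
}

#' Correct the run-on displacement with a 5' shift
#'
#' Run-on extension displaces the detected signal downstream of the
#' polymerase position; this moves every probe `shift_nt` back towards the
#' 5' end in the transcription direction (`pos - shift` on the plus strand,
#' `pos + shift` on the minus strand). Values are untouched; probes shifted
#' off the chromosome are dropped.
#'
#' @param track A [signal_track()].
#' @param shift_nt Shift in nt (default 25, the average run-on extension);
#'   a negative value undoes a previous shift.
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   drop probes shifted past the right end.
#' @return The shifted [signal_track()].
#' @export
shift_5prime <- function(track, shift_nt = 25, chrom_lengths = NULL) {
  out <- as_tibble(track) |>
    mutate(pos = .data$pos + ifelse(.data$strand == "+", -shift_nt, shift_nt)) |>
    filter(.data$pos >= 0)
  if (!is.null(chrom_lengths)) {
    out <- filter(out, .data$pos < chrom_lengths[.data$chrom])
  }
  restore_track(arrange(out, .data$chrom, .data$strand, .data$pos), track)
}

## merge intervals and test positions for overlap, per chromosome
in_any_interval <- function(chrom, pos, iv) {
  hit <- logical(length(pos))
  for (ch in unique(chrom)) {
    sub <- iv[iv$chrom == ch, ]
    sel <- chrom == ch
    if (nrow(sub) == 0) next
    o <- order(sub$lo)
    lo <- sub$lo[o]; hi <- sub$hi[o]
    hi <- cummax(hi)
    keep <- c(TRUE, lo[-1] > hi[-length(hi)])
    grp <- cumsum(keep)
    mlo <- tapply(lo, grp, min)
    mhi <- tapply(hi, grp, max)
    idx <- findInterval(pos[sel], mlo)
    hit[sel] <- idx > 0 & pos[sel] < mhi[pmax(idx, 1L)]
  }
  hit
}

#' Estimate the array background from intergenic probes
#'
#' Background is the `stat` (median by default) intensity over probes that
#' do not overlap any annotated transcribed unit extended by `margin` bp on
#' both sides (on either strand). The median is robust to stray signal; the
#' mean is the right statistic when the background is compared against
#' gene-level *mean* intensities on a ratio-normalized track, because
#' multiplicative probe noise inflates means and medians differently
#' (see the methods vignette).
#'
#' @param track A [signal_track()] (any scale; the estimate is reported on
#'   the track's scale).
#' @param genes Gene annotation tibble.
#' @param margin Exclusion margin around each transcribed unit (bp).
#' @param stat `"median"` (default) or `"mean"`.
#' @return A list with `value`, `n_probes`, `definition` and `scale`.
#' @export
estimate_background <- function(track, genes, margin = 200,
                                stat = c("median", "mean")) {
  stat <- match.arg(stat)
  span <- gene_span(genes)
  iv <- tibble(chrom = genes$chrom,
               lo = span$lo - margin, hi = span$hi + margin)
  excl <- in_any_interval(track$chrom, track$pos, iv)
  vals <- track$value[!excl]
  if (length(vals) == 0) {
    abort("no intergenic probes left after exclusion; cannot estimate background.")
  }
  list(
    value = if (stat == "median") median(vals) else mean(vals),
    n_probes = length(vals),
    definition = paste0(stat, " over probes > ", margin,
                        " bp away from any transcribed unit"),
    scale = track_scale(track)
  )
}

#' Select confident genes above a fold-over-background threshold
#'
#' Keeps genes whose nascent transcription rate exceeds `fold` times the
#' background estimate (strict inequality), the filter used to define the
#' confident high-signal gene set. Both quantities must be on the linear
#' scale so that the fold threshold is meaningful.
#'
#' @param ntr An nTR table from [compute_ntr()] (linear scale).
#' @param background A background estimate from [estimate_background()]
#'   computed on a linear-scale track.
#' @param fold Fold threshold (default 6).
#' @return Character vector of retained gene ids.
#' @export
filter_confident_genes <- function(ntr, background, fold = 6) {
  if (!identical(attr(ntr, "scale"), "linear") ||
      !identical(background$scale, "linear")) {
    abort("nTR table and background must both be on the linear scale.")
  }
  keep <- !is.na(ntr$ntr) & ntr$ntr > fold * background$value
  ids <- ntr$gene_id[keep]
  if (length(ids) == 0) {
    warn("no genes pass the confidence threshold.")
  }
  ids
}

#' Check probe intensities for template-composition (uracil) bias
#'
#' The run-on label is incorporated opposite template A residues, so a
#' labelling bias would show up as a correlation between probe intensity
#' and the U content of the transcript fragment — i.e. the T content of the
#' coding-strand sequence under the probe. This computes the Pearson
#' correlation between probe values and the T fraction of a `window` nt
#' sequence window centred on each probe (A fraction of the plus strand for
#' minus-strand probes). Probes whose window falls outside the available
#' sequence are skipped and counted.
#'
#' @param track A [signal_track()].
#' @param seqs A [Biostrings::DNAStringSet] named by chromosome (plus-strand
#'   sequence).
#' @param window Window width in nt (default 50).
#' @return One-row tibble with `r`, `p_value`, `n`, `n_skipped`.
#' @export
uracil_bias_check <- function(track, seqs, window = 50) {
  half <- floor(window / 2)
  df <- as_tibble(track)
  tfrac <- rep(NA_real_, nrow(df))
  for (ch in unique(df$chrom)) {
    if (!ch %in% names(seqs)) next
    s <- seqs[[ch]]
    sel <- which(df$chrom == ch)
    start1 <- df$pos[sel] - half + 1L
    end1 <- start1 + window - 1L
    ok <- start1 >= 1L & end1 <= length(s)
    if (!any(ok)) next
    v <- Biostrings::Views(s, start = start1[ok], end = end1[ok])
    lf <- Biostrings::letterFrequency(v, c("A", "T"))
    frac <- ifelse(df$strand[sel][ok] == "+",
                   lf[, "T"], lf[, "A"]) / window
    tfrac[sel[ok]] <- frac
  }
  keep <- !is.na(tfrac)
  n_skipped <- sum(!keep)
  if (sum(keep) < 3) {
    abort("fewer than 3 probes with sequence context; correlation undefined.")
  }
  ct <- cor.test(df$value[keep], tfrac[keep])
  tibble(r = unname(ct$estimate), p_value = ct$p.value,
         n = sum(keep), n_skipped = n_skipped)
}
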