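#' Per-gene nascent transcription rate (nTR)
#'
#' The nTR of a gene is the mean probe intensity over its ORF (for tRNA and
#' rDNA genes the annotated ORF spans the whole gene body). Computed on the
#' linear scale; a log2 track is antilogged first. Genes covered by fewer
#' than 3 probes are flagged as unreliable (genes with no probes at all get
#' `NA`).
#'
#' @param track A [signal_track()] (normalized; linear or log2 scale).
#' @param genes Gene annotation tibble.
#' @return An nTR table: tibble with `gene_id`, `gene_class`, `ntr`,
#'   `n_probes`, `flagged`, plus the `trna_family` / `copy_number`
#'   covariates when present; attribute `scale = "linear"`.
#' @export
compute_ntr <- function(track, genes) {
  track <- linearize_track(track)
  ntr <- rep(NA_real_, nrow(genes))
  n_probes <- integer(nrow(genes))
  for (key in unique(paste(genes$chrom, genes$strand))) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    tsub <- track[track$chrom == parts[1] & track$strand == parts[2], ]
    sel <- which(genes$chrom == parts[1] & genes$strand == parts[2])
    if (nrow(tsub) == 0) next
    pos <- tsub$pos
    for (i in sel) {
      lo <- findInterval(genes$orf_start[i] - 1L, pos) + 1L
      hi <- findInterval(genes$orf_end[i] - 1L, pos)
      if (hi >= lo) {
        n_probes[i] <- hi - lo + 1L
        ntr[i] <- mean(tsub$value[lo:hi])
      }
    }
  }
  flagged <- n_probes < 3
  out <- tibble(
    gene_id = genes$gene_id, gene_class = genes$gene_class,
    ntr = ntr, n_probes = n_probes, flagged = flagged
  )
  for (col in c("trna_family", "copy_number", "true_rate")) {
    if (col %in% names(genes)) out[[col]] <- genes[[col]]
  }
  structure(out, scale = "linear",
            class = c("ntr_table", class(tibble())))
}

#' Fold difference in mean nTR between two gene classes
#'
#' Ratio of the mean (and, alongside, median) nTR of `class_a` over
#' `class_b`. When a genomic copy number is supplied the per-copy fold is
#' also multiplied up to the total fold contributed by all copies — e.g.
#' a 50-fold per-copy rDNA signal over ~150 repeat copies amounts to a
#' >7500-fold total output relative to the average pol II gene.
#'
#' @param ntr An nTR table from [compute_ntr()].
#' @param class_a,class_b Gene-class labels.
#' @param copies Optional copy number for `class_a`.
#' @return One-row tibble: `class_a`, `class_b`, `fold` (ratio of means),
#'   `median_fold`, `copies`, `fold_total`.
#' @export
#' @examples
#' ntr <- tibble::tibble(gene_id = c("r1", "p1"),
#'                       gene_class = c("rDNA", "polII"),
#'                       ntr = c(50, 1))
#' attr(ntr, "scale") <- "linear"
#' class_fold(ntr, "rDNA", "polII", copies = 150)$fold_total  # 7500
class_fold <- function(ntr, class_a, class_b, copies = NULL) {
  a <- ntr$ntr[ntr$gene_class == class_a & !is.na(ntr$ntr)]
  b <- ntr$ntr[ntr$gene_class == class_b & !is.na(ntr$ntr)]
  if (length(a) == 0 || length(b) == 0) {
    abort("both classes must have at least one gene with an nTR value.")
  }
  if (mean(b) == 0) abort("zero denominator: mean nTR of class_b is 0.")
  fold <- mean(a) / mean(b)
  tibble(
    class_a = class_a, class_b = class_b,
    fold = fold,
    median_fold = median(a) / median(b),
    copies = copies %||% NA_integer_,
    fold_total = if (is.null(copies)) NA_real_ else fold * copies
  )
}

#' tRNA family aggregates and copy-number correlations
#'
#' Aggregates tRNA-gene nTR by isoacceptor family (per-copy mean, family
#' total, copy count) and correlates both the family total and the
#' per-copy mean with gene copy number (Pearson and Spearman). If
#' transcription is constant per gene copy, the total tracks copy number
#' tightly while the per-copy rate is uncorrelated with it.
#'
#' @param ntr An nTR table carrying `trna_family` and `copy_number`.
#' @param min_families Minimum number of families required.
#' @return A list: `families` (tibble `family`, `copies`, `percopy_ntr`,
#'   `total_ntr`, `n_genes`) and `correlations` (tibble `relation`,
#'   `pearson`, `spearman`).
#' @export
family_copy_correlation <- function(ntr, min_families = 5) {
  fam <- ntr |>
    filter(!is.na(.data$trna_family), !is.na(.data$ntr)) |>
    summarise(
      copies = .data$copy_number[1],
      percopy_ntr = mean(.data$ntr),
      total_ntr = sum(.data$ntr),
      n_genes = n(),
      .by = "trna_family"
    ) |>
    rename(family = "trna_family")
  if (nrow(fam) < min_families) {
    abort(paste0("need at least ", min_families,
                 " tRNA families; got ", nrow(fam), "."))
  }
  if (length(unique(fam$copies)) < 2) {
    abort("copy numbers are constant across families; correlation undefined.")
  }
  correlations <- tibble(
    relation = c("total_vs_copies", "percopy_vs_copies"),
    pearson = c(cor(fam$total_ntr, fam$copies),
                cor(fam$percopy_ntr, fam$copies)),
    spearman = c(cor(fam$total_ntr, fam$copies, method = "spearman"),
                 cor(fam$percopy_ntr, fam$copies, method = "spearman"))
  )
  list(families = fam, correlations = correlations)
}

#' Per-gene response to a treatment condition
#'
#' Per-gene `log2((treated + eps) / (control + eps))` together with
#' per-class summaries: the median change, an ordinary least-squares trend
#' line of treated vs control on the log2 scale, and a coarse
#' classification — `"inhibited"` if the class median change is below
#' `-1`, `"resistant"` if its absolute value is below `0.3`, otherwise
#' `"intermediate"`. This is the comparison that separates
#' alpha-amanitin-sensitive pol II genes from resistant pol III genes.
#'
#' @param ntr_ctrl,ntr_treated nTR tables over the same genes.
#' @param epsilon Guard added to both sides; default 0.001 x the median
#'   control nTR (keeps zero-control genes finite without distorting the
#'   fold change of expressed genes).
#' @return A list: `per_gene` (tibble `gene_id`, `gene_class`, `ctrl`,
#'   `treated`, `log2_change`) and `classes` (tibble `gene_class`,
#'   `median_change`, `slope`, `intercept`, `n`, `status`).
#' @export
condition_response <- function(ntr_ctrl, ntr_treated, epsilon = NULL) {
  if (!setequal(ntr_ctrl$gene_id, ntr_treated$gene_id)) {
    abort("control and treated nTR tables cover different gene sets.")
  }
  j <- inner_join(
    select(as_tibble(ntr_ctrl), "gene_id", "gene_class", ctrl = "ntr"),
    select(as_tibble(ntr_treated), "gene_id", treated = "ntr"),
    by = "gene_id"
  ) |>
    filter(!is.na(.data$ctrl), !is.na(.data$treated))
  epsilon <- epsilon %||% (0.001 * median(j$ctrl))
  per_gene <- mutate(
    j, log2_change = log2((.data$treated + epsilon) / (.data$ctrl + epsilon))
  )
  classes <- per_gene |>
    summarise(
      median_change = median(.data$log2_change),
      slope = coef(lm(log2(treated + epsilon) ~ log2(ctrl + epsilon),
                      data = pick(everything())))[[2]],
      intercept = coef(lm(log2(treated + epsilon) ~ log2(ctrl + epsilon),
                          data = pick(everything())))[[1]],
      n = n(),
      .by = "gene_class"
    ) |>
    mutate(status = case_when(
      .data$median_change < -1 ~ "inhibited",
      abs(.data$median_change) < 0.3 ~ "resistant",
      .default = "intermediate"
    ))
  list(per_gene = per_gene, classes = classes)
}

#' G+C difference between exons and introns
#'
#' For every intron-containing gene, the G+C percentage of the exonic part
#' of the ORF and of the intron; the headline number is the mean exon G+C
#' minus the mean intron G+C in percentage points (positive = introns are
#' A+T richer, the composition contrast proposed to slow the polymerase
#' within tRNA introns).
#'
#' @param genes Gene tibble with `has_intron`, `intron_start`,
#'   `intron_end`.
#' @param seqs A [Biostrings::DNAStringSet] named by chromosome.
#' @return A list: `per_gene` (tibble `gene_id`, `exon_gc`, `intron_gc`)
#'   and `diff_points` (mean exon minus mean intron G+C, percentage
#'   points).
#' @export
gc_intron_exon_diff <- function(genes, seqs) {
  sub <- genes[genes$has_intron %in% TRUE, ]
  if (nrow(sub) == 0) abort("no intron-containing genes.")
  gc_pct <- function(chrom, ranges) {
    tot <- c(gc = 0, n = 0)
    for (r in ranges) {
      if (r[2] <= r[1]) next
      v <- Biostrings::subseq(seqs[[chrom]], start = r[1] + 1L, end = r[2])
      tot["gc"] <- tot["gc"] +
        sum(Biostrings::letterFrequency(v, c("G", "C")))
      tot["n"] <- tot["n"] + (r[2] - r[1])
    }
    100 * tot[["gc"]] / tot[["n"]]
  }
  per_gene <- purrr::map(seq_len(nrow(sub)), function(i) {
    g <- sub[i, ]
    exon_ranges <- list(
      c(g$orf_start, min(g$orf_end, g$intron_start)),
      c(max(g$orf_start, g$intron_end), g$orf_end)
    )
    tibble(
      gene_id = g$gene_id,
      exon_gc = gc_pct(g$chrom, exon_ranges),
      intron_gc = gc_pct(g$chrom, list(c(g$intron_start, g$intron_end)))
    )
  }) |> list_rbind()
  list(per_gene = per_gene,
       diff_points = mean(per_gene$exon_gc) - mean(per_gene$intron_gc))
}
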