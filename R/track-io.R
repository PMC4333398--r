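#' Read a bedGraph file into a signal track
#'
#' bedGraph carries no strand, so strand-specific tracks live in one file
#' per strand; the strand is supplied by the caller. Intervals must be
#' non-overlapping. With `grid = NULL` (the default) each interval
#' contributes one probe at its (0-based) start — the convention used by
#' [write_bedgraph()], which emits 1 bp intervals, so read/write round-trips
#' are exact. With a numeric `grid`, each interval contributes its value at
#' every probe position it covers, with probes laid out every `grid` bp from
#' the interval start (array bedGraphs tile intervals on the probe grid, so
#' interval starts are probe positions).
#'
#' @param path bedGraph file (4 columns, UTF-8).
#' @param strand `"+"` or `"-"`.
#' @param grid Optional probe-grid step in bp.
#' @param scale Scale of the stored values; negative values are a format
#'   error for `"linear"` tracks.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, strand, grid = NULL,
                          scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!strand %in% c("+", "-")) abort("`strand` must be '+' or '-'.")
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) {
    return(signal_track(
      tibble(chrom = character(), strand = character(),
             pos = integer(), value = double()),
      scale = scale, spacing = if (is.null(grid)) NA_integer_ else as.integer(grid)
    ))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  value <- gr$score
  o <- order(chrom, start0)
  chrom <- chrom[o]; start0 <- start0[o]; end0 <- end0[o]; value <- value[o]
  same <- chrom[-1] == chrom[-length(chrom)]
  if (length(same) > 0 && any(same & start0[-1] < end0[-length(end0)])) {
    abort(paste0("overlapping intervals in bedGraph file: ", path))
  }
  if (scale == "linear" && any(value < 0)) {
    abort(paste0("negative values in linear-scale bedGraph file: ", path))
  }
  if (is.null(grid)) {
    df <- tibble(chrom = chrom, strand = strand, pos = start0, value = value)
  } else {
    grid <- as.integer(grid)
    reps <- pmax(1L, as.integer(ceiling((end0 - start0) / grid)))
    df <- tibble(
      chrom = rep(chrom, reps),
      strand = strand,
      pos = unlist(purrr::map2(start0, reps, function(f, r) {
        f + grid * (seq_len(r) - 1L)
      })),
      value = rep(value, reps)
    )
  }
  signal_track(df, scale = scale,
               spacing = if (is.null(grid)) NA_integer_ else grid)
}

#' Write a signal track to per-strand bedGraph files
#'
#' Each probe becomes a 1 bp interval `[pos, pos + 1)`. Values are written
#' with shortest-round-trip precision so that
#' `read_bedgraph(write_bedgraph(x))` reproduces `x` exactly.
#'
#' @param track A [signal_track()].
#' @param prefix Output path prefix; files `<prefix>.plus.bedgraph` and/or
#'   `<prefix>.minus.bedgraph` are written for the strands present.
#' @return Named character vector of the paths written (invisibly).
#' @export
write_bedgraph <- function(track, prefix) {
  paths <- c()
  for (s in intersect(c("+", "-"), unique(track$strand))) {
    sub <- filter(track, .data$strand == s) |> arrange(.data$chrom, .data$pos)
    path <- paste0(prefix, if (s == "+") ".plus.bedgraph" else ".minus.bedgraph")
    readr::write_tsv(
      tibble(sub$chrom, sub$pos, sub$pos + 1L, sub$value),
      path, col_names = FALSE
    )
    paths[s] <- path
  }
  invisible(paths)
}

gene_span <- function(genes) {
  plus <- genes$strand == "+"
  tibble(
    lo = ifelse(plus, genes$tss, genes$pa + 1L),
    hi = ifelse(plus, genes$pa, genes$tss + 1L)
  )
}

#' Write / read gene annotations (GFF3 + covariate TSV)
#'
#' The GFF3 file carries the gene features (1-based inclusive coordinates,
#' converted to the package's 0-based half-open convention at the boundary)
#' with `ID` and `gene_class` attributes; every other column of the gene
#' table — ORF bounds, promoter class, H2AZ level, tRNA family, intron
#' coordinates, simulation ground truth — lives in the tab-separated
#' covariate file, keyed by `gene_id`. Numeric covariates are written with
#' shortest-round-trip precision, so `read_genes(write_genes(x))` is exact.
#'
#' @param genes Gene tibble as produced by [make_genome()].
#' @param gff_path,covariate_tsv File paths.
#' @return `write_genes()` returns the paths invisibly; `read_genes()`
#'   returns the gene tibble.
#' @export
write_genes <- function(genes, gff_path, covariate_tsv) {
  span <- gene_span(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = span$lo + 1L, end = span$hi),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$gene_class <- genes$gene_class
  rtracklayer::export(gr, gff_path, format = "gff3")
  readr::write_tsv(genes, covariate_tsv)
  invisible(c(gff = gff_path, tsv = covariate_tsv))
}

#' @rdname write_genes
#' @export
read_genes <- function(gff_path, covariate_tsv) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (is.null(gr$ID) || anyNA(gr$ID)) {
    abort("GFF3 gene features must carry an ID attribute.")
  }
  cov <- readr::read_tsv(
    covariate_tsv, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      gene_id = "c", chrom = "c", strand = "c", gene_class = "c",
      tata_status = "c", trna_family = "c",
      tss = "i", pa = "i", orf_start = "i", orf_end = "i",
      intron_start = "i", intron_end = "i", copy_number = "i", length = "i",
      h2az_level = "d", true_rate = "d",
      has_intron = "l", isw2_target = "l",
      .default = readr::col_guess()
    )
  )
  for (f in c("gene_id", "gene_class", "tss", "pa", "orf_start", "orf_end")) {
    if (!f %in% names(cov)) {
      abort(paste0("covariate table is missing mandatory column `", f, "`."))
    }
    bad <- cov$gene_id[!complete.cases(cov[[f]])]
    if (length(bad) > 0) {
      abort(paste0("missing `", f, "` for gene(s): ",
                   paste(head(bad, 3), collapse = ", ")))
    }
  }
  missing_ids <- setdiff(gr$ID, cov$gene_id)
  if (length(missing_ids) > 0) {
    abort(paste0("gene(s) in GFF3 but not in covariate table: ",
                 paste(head(missing_ids, 3), collapse = ", ")))
  }
  ## coordinates come from the GFF (1-based inclusive -> 0-based half-open)
  lo <- GenomicRanges::start(gr) - 1L
  hi <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  coords <- tibble(
    gene_id = gr$ID,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = ifelse(strand == "+", lo, hi - 1L),
    pa = ifelse(strand == "+", hi, lo - 1L)
  )
  out <- cov |>
    select(-any_of(c("chrom", "strand", "tss", "pa"))) |>
    left_join(coords, by = "gene_id", relationship = "one-to-one")
  mism <- which(out$tss != cov$tss | out$pa != cov$pa)
  if (length(mism) > 0) {
    abort(paste0("GFF3 and covariate coordinates disagree for gene(s): ",
                 paste(head(out$gene_id[mism], 3), collapse = ", ")))
  }
  out <- as_tibble(out[, names(cov)])
  attr(out, "spec") <- NULL
  out
}

#' Write / read a nucleosome dyad map (BED6)
#'
#' Dyads are stored as 1 bp intervals; the BED name field encodes the gene
#' assignment and positional label (`gene|label`, e.g. `polII_0001|+2`),
#' and the score field carries the occupancy weight.
#'
#' @param nucleosomes Dyad tibble as produced by [make_genome()].
#' @param path BED file path.
#' @return `write_nucleosomes()` returns `path` invisibly;
#'   `read_nucleosomes()` returns the dyad tibble (sorted by position).
#' @export
write_nucleosomes <- function(nucleosomes, path) {
  nm <- ifelse(is.na(nucleosomes$gene_id), ".",
               paste(nucleosomes$gene_id, nucleosomes$label, sep = "|"))
  readr::write_tsv(
    tibble(nucleosomes$chrom, nucleosomes$pos, nucleosomes$pos + 1L,
           nm, nucleosomes$occupancy, "."),
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_nucleosomes
#' @export
read_nucleosomes <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  parts <- strsplit(ifelse(is.na(nm) | nm == ".", "NA|NA", nm), "|", fixed = TRUE)
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    occupancy = as.numeric(gr$score),
    gene_id = vapply(parts, `[`, character(1), 1L),
    label = vapply(parts, `[`, character(1), 2L)
  ) |>
    mutate(
      gene_id = ifelse(.data$gene_id == "NA", NA_character_, .data$gene_id),
      label = ifelse(.data$label == "NA", NA_character_, .data$label)
    ) |>
    arrange(.data$chrom, .data$pos)
  if (any(out$occupancy < 0, na.rm = TRUE)) {
    abort("nucleosome occupancy weights must be >= 0.")
  }
  ok <- out |>
    summarise(ok = all(diff(.data$pos) > 0), .by = "chrom")
  if (!all(ok$ok)) abort("dyad positions must be strictly increasing per chromosome.")
  out
}
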