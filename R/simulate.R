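#' Generate a synthetic genome annotation and nucleosome map
#'
#' Lays out non-overlapping transcribed units of four classes (pol II, RP,
#' tRNA, rDNA) along the configured chromosomes and assigns each gene its
#' positioned nucleosomes and a ground-truth transcription rate. Pol II and
#' RP genes carry +1..+4 dyads downstream of the TSS (repeat length
#' `nucleosome_spacing`, or the shorter `rp_nucleosome_spacing` for RP
#' genes) and -1..-3 dyads upstream of a nucleosome-depleted region spanning
#' the pA site; tRNA and rDNA genes carry flanking dyads only, with the gene
#' body sitting in between the positioned nucleosomes. tRNA genes share a
#' constant per-copy rate equal to `trna_fold` times the mean pol II rate,
#' and are organised into isoacceptor families of distinct copy numbers.
#'
#' Coordinates are 0-based, half-open. On the `+` strand
#' `tss < orf_start <= orf_end < pa`; minus-strand genes are exact mirror
#' images (`pa < orf_start <= orf_end < tss`), and all "downstream"
#' arithmetic elsewhere in the package is in the transcription direction.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genes` (tibble, one row per gene) and
#'   `nucleosomes` (tibble of dyads: `chrom`, `pos`, `occupancy`,
#'   `gene_id`, `label`).
#' @export
#' @examples
#' g <- make_genome(sim_config(seed = 1, n_genes = c(polII = 10, tRNA = 3)))
#' nrow(g$genes)
make_genome <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes

  specs <- list()
  if (n[["polII"]] > 0) {
    specs$polII <- tibble(
      gene_class = "polII",
      utr5 = 50L, utr3 = 80L,
      orf_len = sample(seq(1200L, 2000L, by = 4L), n[["polII"]], replace = TRUE)
    )
  }
  if (n[["RP"]] > 0) {
    specs$RP <- tibble(
      gene_class = "RP",
      utr5 = 50L, utr3 = 80L,
      orf_len = sample(seq(1200L, 2000L, by = 4L), n[["RP"]], replace = TRUE)
    )
  }
  if (n[["tRNA"]] > 0) {
    specs$tRNA <- tibble(
      gene_class = "tRNA",
      utr5 = 2L, utr3 = 2L,
      orf_len = sample(seq(88L, 128L, by = 2L), n[["tRNA"]], replace = TRUE)
    )
  }
  if (n[["rDNA"]] > 0) {
    specs$rDNA <- tibble(
      gene_class = "rDNA",
      utr5 = 2L, utr3 = 2L,
      orf_len = rep(3000L, n[["rDNA"]])
    )
  }
  if (length(specs) == 0) abort("`n_genes` requests no genes at all.")
  genes <- bind_rows(specs)
  genes$length <- genes$utr5 + genes$orf_len + genes$utr3

  ## per-class ground-truth rates
  rate <- numeric(nrow(genes))
  is_p2 <- genes$gene_class == "polII"
  is_rp <- genes$gene_class == "RP"
  rate[is_p2] <- rlnorm(sum(is_p2), meanlog = log(10), sdlog = 0.6)
  rate[is_rp] <- rlnorm(sum(is_rp), meanlog = log(25), sdlog = 0.4)
  mean_polII <- if (any(is_p2)) mean(rate[is_p2]) else 10
  rate[genes$gene_class == "tRNA"] <- config$trna_fold * mean_polII
  rate[genes$gene_class == "rDNA"] <- config$rdna_fold * mean_polII
  genes$true_rate <- rate

  ## covariates
  genes$tata_status <- "unknown"
  genes$tata_status[is_p2] <- sample(c("TATA", "TATA-like"), sum(is_p2),
                                     replace = TRUE, prob = c(0.2, 0.8))
  genes$tata_status[is_rp] <- "TATA-like"
  genes$h2az_level <- NA_real_
  genes$h2az_level[is_p2] <- runif(sum(is_p2), 0.2, 1)
  genes$h2az_level[is_rp] <- runif(sum(is_rp), 0, 0.2)

  genes$trna_family <- NA_character_
  genes$copy_number <- NA_integer_
  if (n[["tRNA"]] > 0) {
    sizes <- allocate_family_sizes(n[["tRNA"]])
    fam <- rep(sprintf("tF%02d", seq_along(sizes)), times = sizes)
    idx <- which(genes$gene_class == "tRNA")
    genes$trna_family[idx] <- fam
    genes$copy_number[idx] <- rep(sizes, times = sizes)
  }

  genes$has_intron <- FALSE
  genes$intron_u5 <- NA_integer_
  genes$intron_u3 <- NA_integer_
  p2i <- which(is_p2)
  if (length(p2i) > 0) {
    pick <- p2i[runif(length(p2i)) < 0.15]
    genes$has_intron[pick] <- TRUE
    genes$intron_u5[pick] <- genes$utr5[pick] + 100L
    genes$intron_u3[pick] <- genes$utr5[pick] + 300L
  }
  tri <- which(genes$gene_class == "tRNA")
  if (length(tri) > 0) {
    pick <- tri[seq_len(max(1L, round(0.25 * length(tri))))]
    genes$has_intron[pick] <- TRUE
    genes$intron_u5[pick] <- 40L
    genes$intron_u3[pick] <- 60L
  }

  genes$isw2_target <- FALSE
  if (length(p2i) > 0 && config$isw2_cluster_fraction > 0) {
    k <- round(config$isw2_cluster_fraction * length(p2i))
    genes$isw2_target[sample(p2i, k)] <- TRUE
  }

  ## randomize placement order, then pack along chromosomes
  ord <- sample(nrow(genes))
  genes <- genes[ord, ]
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  chrom_names <- sprintf("chr%s", utils::as.roman(seq_len(config$n_chromosomes)))
  margin <- 300L
  chrom <- character(nrow(genes))
  start <- integer(nrow(genes))
  ci <- 1L
  cursor <- margin
  for (i in seq_len(nrow(genes))) {
    gap <- sample(config$min_gap:config$max_gap, 1L)
    pos0 <- cursor + gap
    L <- genes$length[i]
    while (pos0 + L + 1L + margin > config$chrom_length) {
      ci <- ci + 1L
      if (ci > config$n_chromosomes) {
        abort(paste0(
          "genome too short to place the requested genes without overlap; ",
          "increase `chrom_length`/`n_chromosomes` or reduce gene counts."
        ))
      }
      cursor <- margin
      pos0 <- cursor + sample(config$min_gap:config$max_gap, 1L)
    }
    chrom[i] <- chrom_names[ci]
    start[i] <- pos0
    cursor <- pos0 + L + 1L
  }
  genes$chrom <- chrom

  plus <- genes$strand == "+"
  genes$tss <- as.integer(ifelse(plus, start, start + genes$length))
  genes$pa <- as.integer(ifelse(plus, start + genes$length, start))
  genes$orf_start <- as.integer(ifelse(plus,
    genes$tss + genes$utr5,
    genes$tss - genes$utr5 - genes$orf_len + 1L
  ))
  genes$orf_end <- genes$orf_start + genes$orf_len
  genes$intron_start <- NA_integer_
  genes$intron_end <- NA_integer_
  ii <- which(genes$has_intron)
  if (length(ii) > 0) {
    d <- ifelse(plus[ii], 1L, -1L)
    a <- genes$tss[ii] + d * genes$intron_u5[ii]
    b <- genes$tss[ii] + d * genes$intron_u3[ii]
    genes$intron_start[ii] <- pmin(a, b)
    genes$intron_end[ii] <- pmax(a, b)
  }
  genes$gene_id <- sprintf("%s_%04d", genes$gene_class, seq_len(nrow(genes)))

  genes <- genes |>
    select("gene_id", "chrom", "strand", "tss", "pa", "orf_start", "orf_end",
           "gene_class", "tata_status", "h2az_level", "trna_family",
           "copy_number", "has_intron", "intron_start", "intron_end",
           "isw2_target", "true_rate", "length") |>
    as_tibble()

  nucleosomes <- build_nucleosome_map(genes, config)
  list(genes = genes, nucleosomes = nucleosomes)
}

## distinct isoacceptor-family sizes summing to n (1, 2, 3, ... with the
## remainder folded into the largest family)
allocate_family_sizes <- function(n) {
  k <- 0L
  while ((k + 1L) * (k + 2L) / 2L <= n) k <- k + 1L
  sizes <- seq_len(k)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[k] <- sizes[k] + rem
  sizes
}

gene_dir <- function(strand) ifelse(strand == "+", 1L, -1L)

## dyad positions in transcription coordinates, with labels
dyads_tx <- function(gene, config) {
  L <- gene$length
  if (gene$gene_class %in% c("polII", "RP")) {
    sp <- if (gene$gene_class == "RP") config$rp_nucleosome_spacing else config$nucleosome_spacing
    down_u <- config$plus1_dyad_offset + sp * 0:3
    up_u <- L - 380L - sp * 0:2
    tibble(
      u = c(down_u, up_u),
      label = c(paste0("+", 1:4), paste0("-", 1:3))
    )
  } else {
    tibble(u = c(-90L, L + 90L), label = c("flank_up", "flank_down"))
  }
}

build_nucleosome_map <- function(genes, config) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    d <- dyads_tx(g, config)
    ## positioning fidelity decays away from the 5' array and the pA-NDR
    ## anchor: -2/-3 dyads carry per-gene positional jitter
    jitter <- ifelse(d$label %in% c("-2", "-3"), round(rnorm(nrow(d), 0, 30)), 0)
    d$u <- d$u + jitter
    d$pos <- g$tss + gene_dir(g$strand) * as.integer(round(d$u))
    d$chrom <- g$chrom
    d$gene_id <- g$gene_id
    d$occupancy <- runif(nrow(d), 0.8, 1.2)
    d[, c("chrom", "pos", "occupancy", "gene_id", "label")]
  })
  nuc <- bind_rows(rows) |> arrange(.data$chrom, .data$pos)
  dup <- nuc |> summarise(bad = anyDuplicated(.data$pos) > 0, .by = "chrom")
  if (any(dup$bad)) abort("internal error: dyad positions collide.")
  as_tibble(nuc)
}

#' Active (run-on competent) polymerase fraction along a gene
#'
#' The generator's noiseless activity model, exposed so that analyses and
#' tests can compare measured profiles against the analytic truth. For
#' pol II / RP genes the active fraction starts at `1 - backtrack_base` at
#' the TSS, decays exponentially along the gene (calibrated to lose
#' `activity_decay_drop` over `activity_decay_bp` bp), is depressed in
#' Gaussian dips of depth `backtrack_amplitude` centred
#' `backtrack_dyad_lead` bp upstream of every nucleosome dyad, and is
#' locally boosted on the +1 nucleosome (in proportion to the gene's H2AZ
#' level), at `pa_sharp_peak_offset` relative to the pA site, and in a broad
#' bump at `pa_broad_peak_offset`. tRNA/rDNA genes instead peak at the TSS
#' and decay with a 150 bp length scale, with a gain inside tRNA introns.
#' The result is clamped to `[0.02, 1]`.
#'
#' @param u Positions in transcription coordinates (bp downstream of the
#'   TSS; negative = upstream).
#' @param gene A single-row gene tibble as produced by [make_genome()].
#' @param config The [sim_config()] used to build the genome.
#' @param dyads_u Optional numeric vector of dyad positions (transcription
#'   coordinates) overriding the gene's canonical dyads — used e.g. for the
#'   *isw2* repositioning.
#' @return Numeric vector of active fractions in `(0, 1]`.
#' @export
active_fraction <- function(u, gene, config, dyads_u = NULL) {
  L <- gene$length
  if (is.null(dyads_u)) dyads_u <- dyads_tx(gene, config)$u
  dyads_u <- sort(dyads_u)
  sig <- config$backtrack_sigma
  dip <- rep(0, length(u))
  for (d in dyads_u) {
    dip <- dip + exp(-(u - (d - config$backtrack_dyad_lead))^2 / (2 * sig^2))
  }
  if (gene$gene_class %in% c("polII", "RP")) {
    tau <- config$activity_decay_bp / log(1 / (1 - config$activity_decay_drop))
    trend <- (1 - config$backtrack_base) * exp(-pmax(u, 0) / tau)
    h2az <- if (is.finite(gene$h2az_level)) gene$h2az_level else 0
    ## the +1 nucleosome is the first dyad downstream of the TSS
    plus1_u <- c(dyads_u[dyads_u >= 0], dyads_u[1])[1]
    gains <- 1 +
      config$plus1_gain * h2az *
        exp(-(u - plus1_u)^2 / (2 * config$plus1_sigma^2)) +
      config$pa_sharp_gain *
        exp(-(u - (L + config$pa_sharp_peak_offset))^2 / (2 * config$pa_sharp_sigma^2)) +
      config$pa_broad_gain *
        exp(-(u - (L + config$pa_broad_peak_offset))^2 / (2 * config$pa_broad_sigma^2))
    a <- trend * (1 - config$backtrack_amplitude * pmin(dip, 1)) * gains
  } else {
    ## short pol I/III genes: activity peaks at the TSS, decays along the body
    trend <- exp(-pmax(u, 0) / 150)
    gains <- 1
    if (isTRUE(gene$has_intron)) {
      iu <- tx_interval(gene, gene$intron_start, gene$intron_end)
      gains <- 1 + config$intron_gain * (u >= iu[1] & u < iu[2])
    }
    a <- trend * (1 - config$backtrack_amplitude * pmin(dip, 1)) * gains
  }
  pmin(pmax(a, 0.02), 1)
}

## genomic half-open [start, end) -> transcription-coordinate half-open range
tx_interval <- function(gene, start, end) {
  if (gene$strand == "+") {
    c(start - gene$tss, end - gene$tss)
  } else {
    c(gene$tss - end + 1L, gene$tss - start + 1L)
  }
}

## ORF in transcription coordinates
orf_tx <- function(gene) tx_interval(gene, gene$orf_start, gene$orf_end)

## total-occupancy level: true_rate is the mean active density over the ORF
gene_kappa <- function(gene, config, dyads_u = NULL) {
  ou <- orf_tx(gene)
  us <- seq(ou[1], ou[2] - 1)
  gene$true_rate / mean(active_fraction(us, gene, config, dyads_u))
}

sim_conditions <- c("WT", "amanitin", "isw2")
sim_assays <- c("gro", "chip", "mrna", "gdna")

#' Simulate probe-level signal tracks for one condition
#'
#' Evaluates the generator's signal model on the fixed probe grid of each
#' strand and returns the four assay tracks: `gro` (nascent run-on: total
#' occupancy times active fraction, read `runon_displacement` nt downstream
#' of the polymerase position), `chip` (total occupancy smeared with a
#' `chip_fragment` bp boxcar), `mrna` (total occupancy restricted to
#' TSS..pA) and `gdna` (flat genomic-DNA control). Within a transcribed
#' unit the probe carries the pure assay signal; outside it the `gro` and
#' `chip` tracks sit at the additive array `background` and `mrna` at zero.
#' Multiplicative lognormal noise (`noise_sd`) is applied per probe,
#' independently across probes and assays.
#'
#' Conditions: `"amanitin"` multiplies pol II / RP occupancy by
#' `amanitin_factor` (pol I / III classes untouched); `"isw2"` moves the
#' downstream (+1..+4) dyads of the Isw2-target genes `isw2_shift` bp
#' downstream before evaluating the active fraction.
#'
#' @param genes,nucleosomes As returned by [make_genome()].
#' @param config The same [sim_config()].
#' @param condition One of `"WT"`, `"amanitin"`, `"isw2"`.
#' @return Named list of [signal_track()] tibbles
#'   (`gro`, `chip`, `mrna`, `gdna`), with attribute `condition`.
#' @export
simulate_tracks <- function(genes, nucleosomes, config, condition = "WT") {
  config <- validate_sim_config(config)
  if (!condition %in% sim_conditions) {
    abort(paste0("unknown condition: '", condition, "'"))
  }
  set.seed(config$seed + 100003L * match(condition, sim_conditions))
  sp <- config$probe_spacing
  bg <- config$background
  ext5 <- config$tss_upstream_extension
  ext3 <- config$pa_downstream_extension
  half <- config$chip_fragment / 2
  shift <- config$runon_displacement
  nuc_by_gene <- split(nucleosomes[, c("pos", "label")], nucleosomes$gene_id)

  chroms <- sprintf("chr%s", utils::as.roman(seq_len(config$n_chromosomes)))
  out <- lapply(sim_assays, function(a) vector("list", 2L * length(chroms)))
  names(out) <- sim_assays
  slot <- 0L

  for (ch in chroms) {
    pos <- seq(0L, config$chrom_length - 1L, by = sp)
    for (strand in c("+", "-")) {
      slot <- slot + 1L
      val <- list(
        gro = rep(bg, length(pos)), chip = rep(bg, length(pos)),
        mrna = rep(0, length(pos)), gdna = rep(1, length(pos))
      )
      gsub <- genes[genes$chrom == ch & genes$strand == strand, ]
      for (i in seq_len(nrow(gsub))) {
        g <- gsub[i, ]
        dir <- gene_dir(g$strand)
        L <- g$length
        nd <- nuc_by_gene[[g$gene_id]]
        du <- dir * (nd$pos - g$tss)
        if (condition == "isw2" && isTRUE(g$isw2_target)) {
          du <- du + ifelse(startsWith(nd$label, "+"), config$isw2_shift, 0L)
        }
        kap <- gene_kappa(g, config, dyads_u = du)
        if (condition == "amanitin" && g$gene_class %in% c("polII", "RP")) {
          kap <- kap * config$amanitin_factor
        }
        glo <- g$tss + dir * (-ext5 - half - shift - 50)
        ghi <- g$tss + dir * (L + ext3 + half + shift + 50)
        idx <- which(pos >= min(glo, ghi) & pos <= max(glo, ghi))
        if (length(idx) == 0) next
        u <- dir * (pos[idx] - g$tss)

        ueff <- u - shift
        sel <- ueff >= -ext5 & ueff < L + ext3
        if (any(sel)) {
          val$gro[idx[sel]] <- kap * active_fraction(ueff[sel], g, config, du)
        }
        cov <- pmax(0, pmin(u + half, L + ext3) - pmax(u - half, -ext5)) /
          (2 * half)
        sel <- cov > 0
        if (any(sel)) {
          val$chip[idx[sel]] <- pmax(bg, kap * cov[sel])
        }
        sel <- u >= 0 & u < L
        if (any(sel)) val$mrna[idx[sel]] <- kap
      }
      if (config$noise_sd > 0) {
        for (a in sim_assays) {
          val[[a]] <- val[[a]] * exp(rnorm(length(pos), 0, config$noise_sd))
        }
      }
      for (a in sim_assays) {
        out[[a]][[slot]] <- tibble(chrom = ch, strand = strand,
                                   pos = pos, value = val[[a]])
      }
    }
  }
  tracks <- lapply(out, function(parts) {
    signal_track(bind_rows(parts), scale = "linear", spacing = sp)
  })
  attr(tracks, "condition") <- condition
  tracks
}

#' Nucleosome-occupancy signal on the probe grid
#'
#' Renders the dyad map as a smooth occupancy track (sum of Gaussians of
#' width `sigma` at each dyad, weighted by dyad occupancy), duplicated on
#' both strands so it can be fed to [build_matrix()] for genes of either
#' orientation. Under the `"isw2"` condition the downstream dyads of the
#' Isw2-target genes are moved `isw2_shift` bp downstream first.
#'
#' @inheritParams simulate_tracks
#' @param sigma Gaussian width in bp (roughly a third of the nucleosomal
#'   footprint).
#' @return A linear-scale [signal_track()].
#' @export
nucleosome_occupancy_track <- function(nucleosomes, genes, config,
                                       condition = "WT", sigma = 46) {
  if (!condition %in% sim_conditions) {
    abort(paste0("unknown condition: '", condition, "'"))
  }
  nuc <- left_join(nucleosomes,
                   genes[, c("gene_id", "strand", "isw2_target")],
                   by = "gene_id")
  if (condition == "isw2") {
    move <- nuc$isw2_target & startsWith(nuc$label, "+")
    nuc$pos <- nuc$pos +
      ifelse(move, gene_dir(nuc$strand) * config$isw2_shift, 0L)
  }
  sp <- config$probe_spacing
  parts <- list()
  for (ch in unique(nuc$chrom)) {
    pos <- seq(0L, config$chrom_length - 1L, by = sp)
    occ <- rep(0, length(pos))
    sub <- nuc[nuc$chrom == ch, ]
    for (j in seq_len(nrow(sub))) {
      d <- sub$pos[j]
      lo <- findInterval(d - 4 * sigma, pos) + 1L
      hi <- findInterval(d + 4 * sigma, pos)
      if (hi < lo) next
      rng <- lo:hi
      occ[rng] <- occ[rng] + sub$occupancy[j] * exp(-(pos[rng] - d)^2 / (2 * sigma^2))
    }
    parts[[ch]] <- bind_rows(
      tibble(chrom = ch, strand = "+", pos = pos, value = occ),
      tibble(chrom = ch, strand = "-", pos = pos, value = occ)
    )
  }
  signal_track(bind_rows(parts), scale = "linear", spacing = sp)
}

#' Simulate genome sequence consistent with the annotation
#'
#' Random uniform-composition chromosomes, except that for intron-containing
#' genes the exonic part of the ORF is regenerated at `exon_gc` G+C and the
#' intron at `intron_gc` G+C, giving the sequence-composition contrast that
#' [gc_intron_exon_diff()] measures. Probe intensities simulated by
#' [simulate_tracks()] are independent of this sequence by construction,
#' which is the null hypothesis probed by [uracil_bias_check()].
#'
#' @inheritParams simulate_tracks
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulate_sequences <- function(genes, config) {
  set.seed(config$seed + 424243L)
  alphabet <- c("A", "C", "G", "T")
  seqs <- lapply(seq_len(config$n_chromosomes), function(i) {
    sample(alphabet, config$chrom_length, replace = TRUE)
  })
  names(seqs) <- sprintf("chr%s", utils::as.roman(seq_len(config$n_chromosomes)))
  draw_gc <- function(n, gc) {
    sample(alphabet, n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  }
  for (i in which(genes$has_intron)) {
    g <- genes[i, ]
    v <- seqs[[g$chrom]]
    exon_idx <- setdiff(seq(g$orf_start, g$orf_end - 1L) + 1L,
                        seq(g$intron_start, g$intron_end - 1L) + 1L)
    v[exon_idx] <- draw_gc(length(exon_idx), config$exon_gc)
    intr_idx <- seq(g$intron_start, g$intron_end - 1L) + 1L
    v[intr_idx] <- draw_gc(length(intr_idx), config$intron_gc)
    seqs[[g$chrom]] <- v
  }
  Biostrings::DNAStringSet(vapply(seqs, paste0, character(1), collapse = ""))
}
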