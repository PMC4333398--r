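#' Run the full analysis pipeline on simulated (or file-based) data
#'
#' Config-driven end-to-end orchestration: simulate (or load) the
#' strand-specific assay tracks, normalize against the genomic-DNA
#' control, apply the 5' run-on-displacement correction, and compute the
#' headline metrics of the analysis — nucleosome-linked profile period,
#' nascent-vs-mature boundary extensions at TSS and pA, the two
#' pA-proximal peaks, the remodeler-mutant displacement of the affected
#' gene cluster, tRNA/pol II intensity folds, rDNA total output,
#' tRNA-family copy-number correlations and per-class alpha-amanitin
#' response. Deterministic given the configuration seed.
#'
#' @param config A [sim_config()], or the path to a YAML file readable by
#'   [read_sim_config()].
#' @param out_dir Optional directory; when given, all simulated inputs
#'   (bedGraph/GFF3/TSV/BED/YAML) and a YAML report are written there.
#' @param conditions Conditions to simulate; metrics needing a missing
#'   condition are `NA`.
#' @param files Optional named list for file mode instead of simulation:
#'   `gro`, `chip`, `mrna`, `gdna` (each a character vector of
#'   `c(plus=, minus=)` bedGraph paths), `genes_gff`, `genes_tsv`,
#'   `nucleosomes`. Only wild-type metrics are computed in file mode.
#' @param quiet Suppress progress messages.
#' @return A `run_report` list: `config`, `metrics` (named list of
#'   headline numbers), `tables` (nTR, confident gene set, condition
#'   response, family aggregates), and `paths` (files written).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         conditions = c("WT", "amanitin", "isw2"),
                         files = NULL, quiet = FALSE) {
  t0 <- Sys.time()
  if (is.character(config)) config <- read_sim_config(config)
  config <- validate_sim_config(config)
  say <- function(...) if (!quiet) inform(paste0("[pipeline] ", ...))
  paths <- list()

  ## ---- stage: inputs -------------------------------------------------
  if (is.null(files)) {
    say("simulating genome and tracks (seed ", config$seed, ")")
    genome <- make_genome(config)
    genes <- genome$genes
    nucs <- genome$nucleosomes
    tracks <- lapply(setNames(conditions, conditions), function(cond) {
      simulate_tracks(genes, nucs, config, condition = cond)
    })
  } else {
    say("loading tracks from files")
    for (a in c("gro", "gdna")) {
      if (is.null(files[[a]])) {
        abort(paste0("preprocess: required track `", a,
                     "` is missing from `files`."))
      }
    }
    read_pair <- function(p) {
      bind_rows(
        read_bedgraph(p[["plus"]], "+"),
        read_bedgraph(p[["minus"]], "-")
      ) |> signal_track()
    }
    tracks <- list(WT = lapply(files[intersect(names(files), sim_assays)],
                               read_pair))
    genes <- read_genes(files$genes_gff, files$genes_tsv)
    nucs <- if (!is.null(files$nucleosomes)) read_nucleosomes(files$nucleosomes) else NULL
    conditions <- "WT"
  }
  has <- function(cond) cond %in% names(tracks)

  if (!is.null(out_dir) && is.null(files)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$config <- file.path(out_dir, "config.yaml")
    write_sim_config(config, paths$config)
    paths$genes <- write_genes(genes,
                               file.path(out_dir, "genes.gff3"),
                               file.path(out_dir, "genes.tsv"))
    paths$nucleosomes <- write_nucleosomes(nucs, file.path(out_dir, "nucleosomes.bed"))
    for (cond in conditions) {
      for (a in names(tracks[[cond]])) {
        pre <- file.path(out_dir, paste(cond, a, sep = "_"))
        paths[[paste(cond, a, sep = "_")]] <- write_bedgraph(tracks[[cond]][[a]], pre)
      }
    }
  }

  ## ---- stage: preprocess ---------------------------------------------
  say("normalizing against gDNA and applying the ",
      config$runon_displacement, " nt 5' shift")
  norm <- lapply(tracks, function(tr) {
    out <- list()
    out$gro <- shift_5prime(normalize_by_gdna(tr$gro, tr$gdna),
                            config$runon_displacement)
    if (!is.null(tr$chip)) out$chip <- normalize_by_gdna(tr$chip, tr$gdna)
    if (!is.null(tr$mrna)) out$mrna <- normalize_by_gdna(tr$mrna, tr$gdna)
    out
  })
  gro_lin <- lapply(norm, function(x) linearize_track(x$gro))
  ## mean background: commensurate with gene-level mean nTR under the
  ## multiplicative probe noise of ratio-normalized tracks
  bg <- estimate_background(gro_lin$WT, genes, stat = "mean")
  ntr_wt <- compute_ntr(gro_lin$WT, genes)
  confident <- filter_confident_genes(ntr_wt, bg)
  say(length(confident), " confident genes (> 6x background)")

  metrics <- list()
  metrics$background <- bg$value
  metrics$n_confident_genes <- length(confident)
  tables <- list(ntr = ntr_wt, confident_genes = confident)

  p2 <- genes[genes$gene_class == "polII", ]
  mn <- min(20, nrow(p2))

  ## ---- stage: metagene + phasing -------------------------------------
  say("metagene profiles and phasing statistics")
  m_tss <- build_matrix(norm$WT$gro, p2, "tss", c(-200, 800))
  prof_tss <- average_profile(m_tss, min_n = mn)
  per <- estimate_period(prof_tss)
  metrics$period_bp <- per$period
  metrics$period_r <- per$peak_r

  if (!is.null(nucs)) {
    ## nascent activity vs nucleosome occupancy over the 5' gene body
    occ_wt <- nucleosome_occupancy_track(nucs, genes, config, "WT")
    prof_occ <- average_profile(build_matrix(occ_wt, p2, "tss", c(-200, 800)),
                                min_n = mn)
    sel <- prof_tss$offset >= 0 & prof_tss$offset <= 500
    step <- config$probe_spacing
    metrics$nucleosome_antiphase_r <- cor(
      detrend_series(prof_tss$value[sel], 250 / step),
      detrend_series(prof_occ$value[sel], 250 / step)
    )
  }

  m_tss_w <- build_matrix(norm$WT$gro, p2, "tss", c(-300, 500))
  m_tss_mrna <- build_matrix(norm$WT$mrna, p2, "tss", c(-300, 500))
  ext5 <- extension_length(average_profile(m_tss_w, min_n = mn),
                           average_profile(m_tss_mrna, min_n = mn),
                           "upstream_of_tss")
  metrics$extension_5p_bp <- ext5$extension

  m_pa <- build_matrix(norm$WT$gro, p2, "pa", c(-500, 400))
  m_pa_mrna <- build_matrix(norm$WT$mrna, p2, "pa", c(-500, 400))
  ext3 <- extension_length(average_profile(m_pa, min_n = mn),
                           average_profile(m_pa_mrna, min_n = mn),
                           "downstream_of_pa")
  metrics$extension_3p_bp <- ext3$extension

  prof_pa <- average_profile(build_matrix(norm$WT$gro, p2, "pa", c(-500, 300)),
                             min_n = mn)
  peaks <- call_peaks(prof_pa, smooth_bw = 24)
  metrics$pa_sharp_peak_nt <- if (nrow(peaks) > 0) {
    abs(peaks$offset[which.min(abs(peaks$offset))])
  } else NA_real_
  up <- peaks$offset[peaks$offset >= -400 & peaks$offset <= -100]
  metrics$pa_broad_peak_bp <- if (length(up) > 0) min(up) else NA_real_
  tables$pa_peaks <- peaks

  ## ---- stage: isw2 displacement --------------------------------------
  if (has("isw2") && is.null(files)) {
    say("isw2 cluster recovery and displacement")
    occ_mut <- nucleosome_occupancy_track(nucs, genes, config, "isw2")
    mo_wt <- build_matrix(occ_wt, p2, "tss", c(-200, 800))
    mo_mut <- build_matrix(occ_mut, p2, "tss", c(-200, 800))
    shift_cl <- cluster_condition_shift(mo_wt, mo_mut, k = 2,
                                        seed = config$seed)
    aff <- p2[p2$gene_id %in% shift_cl$shifted_genes, ]
    metrics$n_shifted_cluster_genes <- nrow(aff)
    ## displacement read over the gene body, where the phased dips live
    mna <- min(20, nrow(aff))
    g_wt <- average_profile(build_matrix(norm$WT$gro, aff, "tss", c(0, 800)),
                            min_n = mna)
    g_mut <- average_profile(build_matrix(norm$isw2$gro, aff, "tss", c(0, 800)),
                             min_n = mna)
    metrics$isw2_displacement_bp <-
      as.numeric(estimate_displacement(g_wt, g_mut, max_lag = 50))
    n_wt <- average_profile(mg_subset(mo_wt, aff$gene_id), min_n = mna)
    n_mut <- average_profile(mg_subset(mo_mut, aff$gene_id), min_n = mna)
    metrics$isw2_nucleosome_displacement_bp <-
      as.numeric(estimate_displacement(n_wt, n_mut, max_lag = 50))
    tables$shift_clusters <- shift_cl
  }

  ## ---- stage: quantify -----------------------------------------------
  say("nTR quantification and class statistics")
  trna <- genes[genes$gene_class == "tRNA", ]
  if (nrow(trna) > 0) {
    prof_trna <- average_profile(
      build_matrix(norm$WT$gro, trna, "tss", c(-200, 300)),
      min_n = min(20, nrow(trna))
    )
    sel <- prof_trna$offset >= -50 & prof_trna$offset <= 150
    peak_lin <- max(2^prof_trna$value[sel], na.rm = TRUE)
    polII_mean <- mean(ntr_wt$ntr[ntr_wt$gene_class == "polII"], na.rm = TRUE)
    metrics$trna_peak_fold <- peak_lin / polII_mean
    metrics$trna_ntr_fold <- class_fold(ntr_wt, "tRNA", "polII")$fold
    fam <- family_copy_correlation(ntr_wt)
    metrics$family_total_spearman <-
      fam$correlations$spearman[fam$correlations$relation == "total_vs_copies"]
    metrics$family_percopy_pearson <-
      fam$correlations$pearson[fam$correlations$relation == "percopy_vs_copies"]
    tables$families <- fam$families
  }
  if (any(genes$gene_class == "rDNA")) {
    rd <- class_fold(ntr_wt, "rDNA", "polII", copies = config$rdna_copies)
    metrics$rdna_percopy_fold <- rd$fold
    metrics$rdna_total_fold <- rd$fold_total
  }
  if (has("amanitin")) {
    ntr_am <- compute_ntr(gro_lin$amanitin, genes)
    resp <- condition_response(ntr_wt, ntr_am)
    cls <- resp$classes
    metrics$amanitin_median_polII <-
      cls$median_change[cls$gene_class == "polII"]
    metrics$amanitin_median_tRNA <-
      cls$median_change[cls$gene_class == "tRNA"]
    tables$amanitin_response <- cls
  }

  report <- structure(list(
    config = config, metrics = metrics, tables = tables, paths = paths,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "run_report")
  if (!is.null(out_dir)) {
    paths$report <- file.path(out_dir, "report.yaml")
    yaml::write_yaml(lapply(metrics, function(m) if (is.numeric(m)) unname(m) else m),
                     paths$report)
    report$paths <- paths
  }
  say(sprintf("done in %.1f s", report$elapsed_s))
  report
}

## restrict a metagene matrix to a gene subset, keeping attributes
mg_subset <- function(m, gene_ids) {
  out <- m[m$gene_id %in% gene_ids, ]
  for (a in c("offsets", "anchor", "scale", "spacing")) {
    attr(out, a) <- attr(m, a)
  }
  class(out) <- class(m)
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$metrics)) {
    v <- x$metrics[[nm]]
    cat(sprintf("  %-32s %s\n", nm,
                if (is.numeric(v)) format(signif(v, 5)) else as.character(v)))
  }
  invisible(x)
}
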