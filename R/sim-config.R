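#' Simulation configuration
#'
#' Builds the parameter set that drives the synthetic-data generator. The
#' defaults encode the quantitative structure the analysis pipeline is built
#' around: an ~8 bp tiling-probe grid, a canonical 165 bp nucleosomal repeat
#' (150 bp for ribosomal-protein genes) with the +1 dyad 60 bp downstream of
#' the TSS, a 25 nt downstream displacement of the run-on signal, ~300 bp
#' ChIP fragment smearing, nascent signal extending ~70 bp upstream of the
#' TSS and ~150 bp past the pA site, a sharp pA-proximal activity peak 25 nt
#' before the pA site plus a broad one centred 250 bp upstream, tRNA genes
#' ~50-fold more intense per copy than the average pol II gene, ~150 rDNA
#' repeat copies, selective pol II inhibition by alpha-amanitin, and a 15 bp
#' nucleosome repositioning in the *isw2* mutant affecting ~20% of pol II
#' genes.
#'
#' All lengths and offsets are integers in base pairs; fractions lie in
#' `[0, 1)`. Parameters of the active-fraction (backtracking) model that the
#' underlying study does not quantify (`backtrack_base`,
#' `backtrack_amplitude`, the gain amplitudes) are free generator parameters;
#' see the package vignette for the rationale behind their defaults.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param n_chromosomes,chrom_length Genome shape (bp).
#' @param n_genes Named integer vector of gene counts per class; names must
#'   be among `polII`, `RP`, `tRNA`, `rDNA`.
#' @param probe_spacing Tiling-probe spacing (bp).
#' @param nucleosome_spacing,rp_nucleosome_spacing Nucleosomal repeat length
#'   (bp) for pol II genes and for RP genes.
#' @param plus1_dyad_offset Position of the +1 nucleosome dyad downstream of
#'   the TSS (bp).
#' @param runon_displacement Average downstream displacement of the run-on
#'   signal (nt); corrected by [shift_5prime()].
#' @param chip_fragment ChIP fragment size (bp); the total-occupancy track is
#'   smeared with a boxcar of this width.
#' @param tss_upstream_extension,pa_downstream_extension How far the nascent
#'   signal extends beyond the mature-mRNA boundaries (bp).
#' @param pa_sharp_peak_offset,pa_broad_peak_offset Centres (bp, relative to
#'   the pA site; negative = upstream) of the sharp and broad pA-proximal
#'   activity peaks.
#' @param pa_sharp_gain,pa_sharp_sigma,pa_broad_gain,pa_broad_sigma Amplitude
#'   (fractional gain) and Gaussian width (bp) of the two pA-proximal peaks.
#' @param trna_fold Per-copy tRNA rate as a multiple of the mean pol II gene
#'   rate.
#' @param rdna_fold Per-copy rDNA rate as a multiple of the mean pol II gene
#'   rate.
#' @param rdna_copies Genomic copy number of the rDNA repeat used when
#'   reporting total rDNA output (the simulated genome carries only the
#'   number of repeat units requested in `n_genes`).
#' @param amanitin_factor Multiplicative factor applied to pol II / RP gene
#'   occupancy under alpha-amanitin (pol I / III genes are untouched).
#' @param isw2_shift Downstream dyad displacement (bp) in the *isw2*
#'   condition.
#' @param isw2_cluster_fraction Fraction of pol II genes whose nucleosomes
#'   Isw2 positions (i.e. that move in the mutant).
#' @param noise_sd Sigma of the multiplicative lognormal probe noise.
#' @param backtrack_base Baseline backtracked fraction at the TSS.
#' @param backtrack_amplitude Depth of the dyad-linked dips in the active
#'   fraction.
#' @param backtrack_dyad_lead Distance (bp) upstream of a dyad at which the
#'   backtracking probability peaks.
#' @param backtrack_sigma Gaussian width (bp) of the dyad-linked dips.
#' @param activity_decay_bp,activity_decay_drop Calibration of the 5'->3'
#'   decline of the active fraction: it falls by `activity_decay_drop`
#'   (fractional) over `activity_decay_bp` bp (exponential decay).
#' @param plus1_gain,plus1_sigma Amplitude and width of the activity gain on
#'   the +1 nucleosome; the amplitude is scaled per gene by its H2AZ level.
#' @param intron_gain Fractional activity gain inside tRNA introns (slower
#'   polymerase, higher active density).
#' @param background Additive array background (arbitrary linear units)
#'   visible outside transcribed units.
#' @param exon_gc,intron_gc G+C fraction used when simulating sequence for
#'   exons and introns of intron-containing genes.
#' @param min_gap,max_gap Intergenic gap range (bp) between transcribed
#'   units.
#'
#' @return A list of class `sim_config`.
#' @seealso [make_genome()], [simulate_tracks()], [read_sim_config()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = c(polII = 20, tRNA = 5))
#' cfg$nucleosome_spacing
sim_config <- function(seed = 1,
                       n_chromosomes = 4,
                       chrom_length = 300000,
                       n_genes = c(polII = 300, RP = 30, tRNA = 40, rDNA = 2),
                       probe_spacing = 8,
                       nucleosome_spacing = 165,
                       rp_nucleosome_spacing = 150,
                       plus1_dyad_offset = 60,
                       runon_displacement = 25,
                       chip_fragment = 300,
                       tss_upstream_extension = 70,
                       pa_downstream_extension = 150,
                       pa_sharp_peak_offset = -25,
                       pa_broad_peak_offset = -250,
                       pa_sharp_gain = 0.45,
                       pa_sharp_sigma = 12,
                       pa_broad_gain = 0.35,
                       pa_broad_sigma = 45,
                       trna_fold = 50,
                       rdna_fold = 50,
                       rdna_copies = 150,
                       amanitin_factor = 0.1,
                       isw2_shift = 15,
                       isw2_cluster_fraction = 0.2,
                       noise_sd = 0.3,
                       backtrack_base = 0.15,
                       backtrack_amplitude = 0.35,
                       backtrack_dyad_lead = 40,
                       backtrack_sigma = 20,
                       activity_decay_bp = 800,
                       activity_decay_drop = 0.3,
                       plus1_gain = 0.3,
                       plus1_sigma = 30,
                       intron_gain = 0.3,
                       background = 1,
                       exon_gc = 0.5,
                       intron_gc = 0.35,
                       min_gap = 500,
                       max_gap = 900) {
  cfg <- as.list(environment())
  cfg$n_genes <- resolve_gene_counts(n_genes)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

gene_classes <- c("polII", "RP", "tRNA", "rDNA")

resolve_gene_counts <- function(n_genes) {
  if (is.null(names(n_genes)) || any(!nzchar(names(n_genes)))) {
    abort("`n_genes` must be a named vector (classes polII, RP, tRNA, rDNA).")
  }
  bad <- setdiff(names(n_genes), gene_classes)
  if (length(bad) > 0) {
    abort(paste0("Unknown gene class(es): ", paste(bad, collapse = ", ")))
  }
  out <- setNames(integer(length(gene_classes)), gene_classes)
  out[names(n_genes)] <- as.integer(n_genes)
  out
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  int_fields <- c(
    "seed", "n_chromosomes", "chrom_length", "probe_spacing",
    "nucleosome_spacing", "rp_nucleosome_spacing", "plus1_dyad_offset",
    "runon_displacement", "chip_fragment", "tss_upstream_extension",
    "pa_downstream_extension", "pa_sharp_peak_offset", "pa_broad_peak_offset",
    "rdna_copies", "isw2_shift", "backtrack_dyad_lead", "min_gap", "max_gap"
  )
  for (f in int_fields) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.numeric(v) || !is.finite(v) || v != round(v)) {
      abort(paste0("`", f, "` must be a single integer value."))
    }
    cfg[[f]] <- as.integer(v)
  }
  fracs <- c("backtrack_base", "backtrack_amplitude", "isw2_cluster_fraction",
             "amanitin_factor", "exon_gc", "intron_gc")
  for (f in fracs) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.numeric(v) || v < 0 || v >= 1 + 1e-12) {
      abort(paste0("`", f, "` must be a fraction in [0, 1)."))
    }
  }
  if (cfg$probe_spacing < 1) abort("`probe_spacing` must be >= 1.")
  if (cfg$nucleosome_spacing <= 0 || cfg$rp_nucleosome_spacing <= 0) {
    abort("nucleosome spacings must be positive.")
  }
  if (cfg$trna_fold <= 0) abort("`trna_fold` must be positive.")
  if (cfg$rdna_copies < 1) abort("`rdna_copies` must be >= 1.")
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (any(cfg$n_genes < 0)) abort("gene counts must be non-negative.")
  if (cfg$min_gap < 0 || cfg$max_gap < cfg$min_gap) {
    abort("gap range must satisfy 0 <= min_gap <= max_gap.")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " genome:", x$n_chromosomes, "x", x$chrom_length, "bp\n")
  cat("  genes:", paste(names(x$n_genes), x$n_genes, sep = "=", collapse = " "), "\n")
  cat("  probe spacing:", x$probe_spacing, "bp; nucleosome repeat:",
      x$nucleosome_spacing, "bp (RP:", x$rp_nucleosome_spacing, "bp)\n")
  cat("  run-on displacement:", x$runon_displacement, "nt; noise_sd:",
      x$noise_sd, "\n")
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path File path.
#' @param config A [sim_config()] object.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  n_genes <- unlist(raw$n_genes)
  raw$n_genes <- NULL
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("Unknown config field(s): ", paste(extra, collapse = ", ")))
  }
  do.call(sim_config, c(raw, if (!is.null(n_genes)) list(n_genes = n_genes)))
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  out$n_genes <- as.list(out$n_genes)
  yaml::write_yaml(out, path)
  invisible(path)
}
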