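## shared fixtures, built in code and cached per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

## small genome for unit tests: 15 tRNA genes give 5 isoacceptor families
tiny_config <- function(seed = 11, noise_sd = 0.3, ...) {
  sim_config(
    seed = seed, n_chromosomes = 2, chrom_length = 90000,
    n_genes = c(polII = 24, RP = 3, tRNA = 15, rDNA = 1),
    noise_sd = noise_sd, ...
  )
}

tiny_sim <- function() {
  cached("tiny_sim", {
    cfg <- tiny_config()
    g <- make_genome(cfg)
    list(config = cfg, genes = g$genes, nucleosomes = g$nucleosomes,
         tracks = simulate_tracks(g$genes, g$nucleosomes, cfg, "WT"))
  })
}

## noiseless variant: exact signal values
tiny_sim0 <- function() {
  cached("tiny_sim0", {
    cfg <- tiny_config(noise_sd = 0)
    g <- make_genome(cfg)
    list(config = cfg, genes = g$genes, nucleosomes = g$nucleosomes,
         tracks = simulate_tracks(g$genes, g$nucleosomes, cfg, "WT"))
  })
}

## full-size study-condition run used by the acceptance tests
acceptance_report <- function() {
  cached("acceptance_report", run_pipeline(sim_config(seed = 1), quiet = TRUE))
}

## hand-built signal track on a regular grid
grid_track <- function(pos, value, strand = "+", chrom = "chrI",
                       scale = "linear", spacing = 8) {
  signal_track(
    tibble::tibble(chrom = chrom, strand = strand, pos = pos, value = value),
    scale = scale, spacing = spacing
  )
}

## a profile tibble with the attributes average_profile() would attach
as_profile <- function(offset, value, n = 1000, anchor = "tss",
                       scale = "log2") {
  structure(
    tibble::tibble(offset = offset, value = value, n = n),
    anchor = anchor, scale = scale, stat = "mean",
    class = c("metagene_profile", class(tibble::tibble()))
  )
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
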