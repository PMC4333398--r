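test_that("generated genomes honour the requested class counts and geometry", {
  cfg <- sim_config(seed = 4, n_chromosomes = 2, chrom_length = 150000,
                    n_genes = c(polII = 40, RP = 6))
  g <- make_genome(cfg)
  expect_equal(sum(g$genes$gene_class == "polII"), 40)
  expect_equal(sum(g$genes$gene_class == "RP"), 6)

  nuc <- g$nucleosomes
  for (i in which(g$genes$gene_class == "polII")) {
    gene <- g$genes[i, ]
    d <- nuc[nuc$gene_id == gene$gene_id & startsWith(nuc$label, "+"), ]
    expect_equal(nrow(d), 4)
    u <- sort(abs(d$pos - gene$tss))
    expect_equal(diff(u), rep(165, 3))
    expect_equal(u[1], cfg$plus1_dyad_offset)
  }
  ## RP genes use the shorter nucleosomal repeat
  for (i in which(g$genes$gene_class == "RP")) {
    gene <- g$genes[i, ]
    d <- nuc[nuc$gene_id == gene$gene_id & startsWith(nuc$label, "+"), ]
    expect_equal(diff(sort(abs(d$pos - gene$tss))), rep(150, 3))
  }
})

test_that("gene coordinates satisfy the strand-mirrored ordering invariants", {
  g <- tiny_sim()$genes
  plus <- g[g$strand == "+", ]
  expect_true(all(plus$tss < plus$orf_start & plus$orf_start <= plus$orf_end &
                    plus$orf_end < plus$pa))
  minus <- g[g$strand == "-", ]
  expect_true(all(minus$pa < minus$orf_start & minus$orf_start <= minus$orf_end &
                    minus$orf_end < minus$tss))
  ## transcribed units never overlap (any strand)
  spans <- tibble::tibble(chrom = g$chrom,
                          lo = pmin(g$tss, g$pa), hi = pmax(g$tss, g$pa)) |>
    dplyr::arrange(chrom, lo)
  by_chrom <- split(spans, spans$chrom)
  for (s in by_chrom) {
    if (nrow(s) > 1) expect_true(all(s$lo[-1] > s$hi[-nrow(s)]))
  }
})

test_that("the generator is deterministic given the configuration", {
  cfg <- tiny_config()
  a <- make_genome(cfg)
  b <- make_genome(cfg)
  expect_identical(a, b)
  ta <- simulate_tracks(a$genes, a$nucleosomes, cfg, "WT")
  tb <- simulate_tracks(b$genes, b$nucleosomes, cfg, "WT")
  expect_identical(lapply(ta, tibble::as_tibble), lapply(tb, tibble::as_tibble))
})

test_that("genome placement fails loudly when the genome is too small", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 20000,
                    n_genes = c(polII = 50))
  expect_error(make_genome(cfg), "too short")
})

test_that("alpha-amanitin suppresses pol II signal 10-fold and spares tRNA genes", {
  s <- tiny_sim0()
  wt <- s$tracks$gro
  am <- simulate_tracks(s$genes, s$nucleosomes, s$config, "amanitin")$gro
  stopifnot(identical(wt$pos, am$pos))
  probe_vals <- function(track, gene) {
    sub <- track[track$chrom == gene$chrom & track$strand == gene$strand, ]
    sub$value[sub$pos >= gene$orf_start & sub$pos < gene$orf_end]
  }
  for (i in which(s$genes$gene_class == "tRNA")) {
    expect_equal(probe_vals(am, s$genes[i, ]), probe_vals(wt, s$genes[i, ]))
  }
  for (i in which(s$genes$gene_class == "polII")[1:5]) {
    expect_equal(probe_vals(am, s$genes[i, ]),
                 0.1 * probe_vals(wt, s$genes[i, ]), tolerance = 1e-12)
  }
})

test_that("mRNA signal is confined to the TSS..pA interval", {
  s <- tiny_sim0()
  mrna <- s$tracks$mrna
  gene <- s$genes[s$genes$gene_class == "polII" & s$genes$strand == "+", ][1, ]
  sub <- mrna[mrna$chrom == gene$chrom & mrna$strand == "+", ]
  upstream <- sub$value[sub$pos >= gene$tss - 16 & sub$pos <= gene$tss - 4]
  inside <- sub$value[sub$pos >= gene$tss + 4 & sub$pos <= gene$tss + 16]
  expect_true(all(upstream == 0))
  expect_true(all(inside > 0))
})

test_that("the run-on signal is displaced 25 nt downstream and the 5' shift restores it", {
  s <- tiny_sim0()
  cfg <- s$config
  gene <- s$genes[s$genes$gene_class == "polII" & s$genes$strand == "+", ][1, ]
  raw <- s$tracks$gro
  sub <- raw[raw$chrom == gene$chrom & raw$strand == "+", ]
  ## sharpest activity feature: the pA-proximal peak at pa - 25 shows up at
  ## pa - 25 + 25 = pa in the uncorrected track
  win <- sub[sub$pos >= gene$pa - 120 & sub$pos <= gene$pa + 60, ]
  raw_peak <- win$pos[which.max(win$value)]
  expect_lte(abs(raw_peak - gene$pa), cfg$probe_spacing)

  corr <- shift_5prime(raw, cfg$runon_displacement)
  sub2 <- corr[corr$chrom == gene$chrom & corr$strand == "+", ]
  win2 <- sub2[sub2$pos >= gene$pa - 120 & sub2$pos <= gene$pa + 35, ]
  cor_peak <- win2$pos[which.max(win2$value)]
  expect_lte(abs(cor_peak - (gene$pa - 25)), cfg$probe_spacing)
})

test_that("isw2 repositioning moves the dyad-linked activity minima by exactly the shift", {
  s <- tiny_sim0()
  cfg <- s$config
  gene <- s$genes[s$genes$isw2_target, ][1, ]
  nd <- s$nucleosomes[s$nucleosomes$gene_id == gene$gene_id, ]
  du <- sort(ifelse(gene$strand == "+", 1, -1) * (nd$pos - gene$tss))
  du_shift <- du + ifelse(du >= 0, cfg$isw2_shift, 0)
  u <- seq(0, 700)
  a_wt <- active_fraction(u, gene, cfg, du)
  a_mut <- active_fraction(u, gene, cfg, du_shift)
  ## compare the positions of the first three local minima
  mins <- function(a) u[which(diff(sign(diff(a))) == 2) + 1]
  m_wt <- mins(a_wt)[1:3]
  m_mut <- mins(a_mut)[1:3]
  expect_equal(m_mut - m_wt, rep(cfg$isw2_shift, 3))
})

test_that("ChIP smearing conserves the occupancy integral over interior probes", {
  s <- tiny_sim0()
  gene <- s$genes[s$genes$gene_class == "polII", ][1, ]
  chip <- s$tracks$chip
  sub <- chip[chip$chrom == gene$chrom & chip$strand == gene$strand, ]
  dir <- if (gene$strand == "+") 1 else -1
  L <- abs(gene$pa - gene$tss)
  u <- dir * (sub$pos - gene$tss)
  sel <- u >= 160 & u < L # > chip_fragment/2 from both edges
  interior <- sub$value[sel]
  ## the boxcar conserves the flat occupancy level away from the edges, so
  ## the interior trapezoid integral equals level x span
  span <- max(u[sel]) - min(u[sel])
  trapz <- sum((interior[-1] + interior[-length(interior)]) / 2) *
    s$config$probe_spacing
  expect_equal(trapz, interior[1] * span, tolerance = 0.01)
  ## and that level is the same total-occupancy level the mRNA track carries
  msub <- s$tracks$mrna[s$tracks$mrna$chrom == gene$chrom &
                          s$tracks$mrna$strand == gene$strand, ]
  expect_equal(interior[1], msub$value[msub$pos == sub$pos[sel][1]],
               tolerance = 1e-9)
})

test_that("nucleosome occupancy track peaks on dyads and follows the isw2 shift", {
  s <- tiny_sim0()
  cfg <- s$config
  occ_wt <- nucleosome_occupancy_track(s$nucleosomes, s$genes, cfg, "WT")
  occ_mut <- nucleosome_occupancy_track(s$nucleosomes, s$genes, cfg, "isw2")
  gene <- s$genes[s$genes$isw2_target, ][1, ]
  dyad <- s$nucleosomes[s$nucleosomes$gene_id == gene$gene_id &
                          s$nucleosomes$label == "+2", ]
  near <- function(track, center) {
    sub <- track[track$chrom == gene$chrom & track$strand == "+", ]
    win <- sub[abs(sub$pos - center) <= 60, ]
    win$pos[which.max(win$value)]
  }
  expect_lte(abs(near(occ_wt, dyad$pos) - dyad$pos), cfg$probe_spacing)
  shifted <- dyad$pos + ifelse(gene$strand == "+", 1, -1) * cfg$isw2_shift
  expect_lte(abs(near(occ_mut, shifted) - shifted), cfg$probe_spacing)
})

test_that("simulated sequences carry the configured exon/intron G+C contrast", {
  s <- tiny_sim0()
  seqs <- simulate_sequences(s$genes, s$config)
  res <- gc_intron_exon_diff(s$genes, seqs)
  expect_equal(res$diff_points, 15, tolerance = 0.5) # sampling noise on short introns
  expect_true(all(res$per_gene$exon_gc > res$per_gene$intron_gc - 5))
})
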