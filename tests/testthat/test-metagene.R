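two_gene_set <- function() {
  tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chrI", strand = c("+", "-"),
    tss = c(1000L, 3000L), pa = c(1800L, 2200L)
  )
}

test_that("metagene cells read the track at strand-oriented offsets", {
  pos <- seq(0L, 4000L, 8L)
  tr <- grid_track(pos, as.numeric(pos)) # value == genomic position
  genes <- two_gene_set()[1, ]
  m <- build_matrix(tr, genes, "tss", c(-16, 16))
  expect_equal(attr(m, "offsets"), seq(-16, 16, 8))
  expect_equal(unname(mg_values(m)[1, ]), 1000 + seq(-16, 16, 8))

  ## minus-strand gene: offset +8 reads anchor - 8
  tr2 <- signal_track(tibble::tibble(chrom = "chrI", strand = "-",
                                     pos = pos, value = as.numeric(pos)),
                      spacing = 8)
  m2 <- build_matrix(tr2, two_gene_set()[2, ], "tss", c(-16, 16))
  expect_equal(mg_values(m2)[1, "8"], 3000 - 8, ignore_attr = TRUE)
})

test_that("a constant track fills every covered cell with that constant", {
  pos <- seq(0L, 4000L, 8L)
  tr <- signal_track(tidyr::expand_grid(
    chrom = "chrI", strand = c("+", "-"), pos = pos
  ) |> dplyr::mutate(value = 7), spacing = 8)
  m <- build_matrix(tr, two_gene_set(), "tss", c(-40, 40))
  v <- mg_values(m)
  expect_true(all(v[!is.na(v)] == 7))
  expect_error(build_matrix(tr, two_gene_set()[0, ], "tss", c(-40, 40)),
               "empty gene list")
})

test_that("reversing strand and mirroring the track leaves a metagene row unchanged", {
  set.seed(21)
  off <- seq(-96, 96, 8)
  vals <- runif(length(off))
  tss_p <- 1000L
  tr_p <- grid_track(tss_p + off, vals)
  row_p <- mg_values(build_matrix(
    tr_p, tibble::tibble(gene_id = "g", chrom = "chrI", strand = "+",
                         tss = tss_p, pa = tss_p + 500L),
    "tss", c(-96, 96)
  ))
  ## mirrored genome: same values at tss - offset on the minus strand
  tss_m <- 5000L
  tr_m <- signal_track(tibble::tibble(chrom = "chrI", strand = "-",
                                      pos = tss_m - off, value = vals) |>
                         dplyr::arrange(pos), spacing = 8)
  row_m <- mg_values(build_matrix(
    tr_m, tibble::tibble(gene_id = "g", chrom = "chrI", strand = "-",
                         tss = tss_m, pa = tss_m - 500L),
    "tss", c(-96, 96)
  ))
  expect_equal(row_p, row_m)
})

test_that("average profiles take per-offset means with support counts", {
  m <- structure(
    tibble::tibble(gene_id = c("a", "b"), `-8` = c(1, 3), `0` = c(1, 3),
                   `8` = c(NA, 3)),
    offsets = c(-8, 0, 8), anchor = "tss", scale = "linear", spacing = 8,
    class = c("metagene_matrix", class(tibble::tibble()))
  )
  p <- average_profile(m, min_n = 1)
  expect_equal(p$value, c(2, 2, 3))
  expect_equal(p$n, c(2, 2, 1))
  p2 <- average_profile(m, min_n = 2)
  expect_true(is.na(p2$value[3]))
  pm <- average_profile(m, stat = "median", min_n = 1)
  expect_equal(pm$value, c(2, 2, 3))
})

test_that("mean profiles are linear in the underlying matrices", {
  set.seed(31)
  base <- tibble::tibble(gene_id = letters[1:6])
  offs <- seq(0, 40, 8)
  mk <- function(vals) {
    structure(
      dplyr::bind_cols(base, stats::setNames(as.data.frame(vals), offs)),
      offsets = offs, anchor = "tss", scale = "linear", spacing = 8,
      class = c("metagene_matrix", class(tibble::tibble()))
    )
  }
  X <- matrix(runif(36), 6)
  Y <- matrix(runif(36), 6)
  pX <- average_profile(mk(X), min_n = 1)$value
  pY <- average_profile(mk(Y), min_n = 1)$value
  pZ <- average_profile(mk(2 * X + 3 * Y), min_n = 1)$value
  expect_equal(pZ, 2 * pX + 3 * pY)
})

test_that("ratio profiles divide on the linear scale", {
  p1 <- as_profile(seq(0, 80, 8), rep(3, 11), scale = "log2")
  expect_equal(ratio_profile(p1, p1)$value, rep(0, 11))
  p2 <- as_profile(seq(0, 80, 8), rep(2, 11), scale = "log2")
  expect_equal(ratio_profile(p1, p2)$value, rep(1, 11))
  p3 <- as_profile(seq(8, 88, 8), rep(2, 11), scale = "log2")
  expect_error(ratio_profile(p1, p3), "offset")
})

test_that("gene groupings cover tertiles, categories and extreme thirds", {
  g <- tibble::tibble(gene_id = letters[1:9], ntr = 1:9,
                      tata_status = "TATA")
  grp <- group_genes(g, "ntr", "tertile")
  expect_equal(grp$low, c("a", "b", "c"))
  expect_equal(grp$medium, c("d", "e", "f"))
  expect_equal(grp$high, c("g", "h", "i"))
  expect_equal(names(group_genes(g, "tata_status")), "TATA")

  g300 <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                         h2az = runif(300))
  thirds <- group_genes(g300, "h2az", "extreme_thirds")
  expect_length(thirds$top_third, 100)
  expect_length(thirds$bottom_third, 100)
  expect_error(group_genes(g[1:2, ], "ntr", "tertile"), "fewer than 3")
  g$ntr[4] <- NA
  expect_equal(group_genes(g, "ntr", "tertile")$unknown, "d")
})

test_that("heat-map ordering sorts by transcript length with a ratio variant", {
  genes <- tibble::tibble(
    gene_id = c("a", "b", "c"), chrom = "chrI", strand = "+",
    tss = c(0L, 10000L, 20000L), pa = c(2000L, 10500L, 21000L)
  )
  offs <- seq(0, 16, 8)
  mk <- function(vals) structure(
    dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id),
                     stats::setNames(as.data.frame(vals), offs)),
    offsets = offs, anchor = "tss", scale = "linear", spacing = 8,
    class = c("metagene_matrix", class(tibble::tibble()))
  )
  m <- mk(matrix(1:9, 3))
  out <- length_sorted_heatmap(m, genes)
  expect_equal(out$gene_id, c("b", "c", "a")) # 500, 1000, 2000 bp
  ratio <- length_sorted_heatmap(m, genes, ratio_with = m)
  expect_true(all(mg_values(ratio) == 0))
})

test_that("simulated nascent profiles rise across the TSS and oppose nucleosome occupancy", {
  s <- tiny_sim()
  cfg <- s$config
  norm <- shift_5prime(normalize_by_gdna(s$tracks$gro, s$tracks$gdna),
                       cfg$runon_displacement)
  p2 <- s$genes[s$genes$gene_class == "polII", ]
  mn <- min(20, nrow(p2))
  prof <- average_profile(build_matrix(norm, p2, "tss", c(-300, 500)),
                          min_n = mn)
  expect_gt(prof$value[prof$offset == 200], prof$value[prof$offset == -200])

  ## the activity dips lead the dyads by backtrack_dyad_lead, so aligning
  ## the occupancy onto the dips (lag -40) gives a strong anti-correlation
  occ <- nucleosome_occupancy_track(s$nucleosomes, s$genes, cfg, "WT")
  nprof <- average_profile(build_matrix(occ, p2, "tss",
                                        c(cfg$backtrack_dyad_lead,
                                          500 + cfg$backtrack_dyad_lead)),
                           min_n = mn)
  gprof <- average_profile(build_matrix(norm, p2, "tss", c(0, 500)),
                           min_n = mn)
  dt <- function(x) x - stats::runmed(x, 31, endrule = "median")
  expect_lt(cor(dt(gprof$value), dt(nprof$value)), -0.3)
})

test_that("full-size nascent metagenes are anti-phased with nucleosome occupancy", {
  m <- acceptance_report()$metrics
  expect_lt(m$nucleosome_antiphase_r, 0)
})

test_that("specific-activity minima sit just upstream of the nucleosome dyads", {
  s <- tiny_sim0()
  cfg <- s$config
  gro <- shift_5prime(normalize_by_gdna(s$tracks$gro, s$tracks$gdna),
                      cfg$runon_displacement)
  chip <- normalize_by_gdna(s$tracks$chip, s$tracks$gdna)
  p2 <- s$genes[s$genes$gene_class == "polII", ]
  mn <- min(20, nrow(p2))
  rp <- ratio_profile(
    average_profile(build_matrix(gro, p2, "tss", c(0, 600)), min_n = mn),
    average_profile(build_matrix(chip, p2, "tss", c(0, 600)), min_n = mn)
  )
  v <- rp$value
  mins <- rp$offset[which(diff(sign(diff(v))) == 2) + 1]
  expected <- cfg$plus1_dyad_offset + cfg$nucleosome_spacing * 0:3 -
    cfg$backtrack_dyad_lead
  for (e in expected[expected > 16 & expected < 584]) {
    expect_lte(min(abs(mins - e)), cfg$probe_spacing)
  }
})
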