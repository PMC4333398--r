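one_gene <- function(orf_start = 100L, orf_end = 200L) {
  tibble::tibble(
    gene_id = "g1", chrom = "chrI", strand = "+", tss = 50L, pa = 260L,
    orf_start = orf_start, orf_end = orf_end, gene_class = "polII"
  )
}

test_that("nTR is the mean probe intensity over the ORF", {
  pos <- seq(0L, 400L, 8L)
  tr <- grid_track(pos, rep(5, length(pos)))
  expect_equal(compute_ntr(tr, one_gene())$ntr, 5)

  tr2 <- grid_track(c(104L, 112L), c(2, 4))
  ntr2 <- compute_ntr(tr2, one_gene(100L, 120L))
  expect_equal(ntr2$ntr, 3)
  expect_equal(ntr2$n_probes, 2L)
  expect_true(ntr2$flagged) # < 3 probes

  ## ORF with no probes at all -> missing, flagged
  ntr3 <- compute_ntr(grid_track(300L, 1), one_gene())
  expect_true(is.na(ntr3$ntr) && ntr3$flagged)
})

test_that("nTR is scale-equivariant and folds are scale-free", {
  s <- tiny_sim()
  lin <- linearize_track(normalize_by_gdna(s$tracks$gro, s$tracks$gdna))
  a <- compute_ntr(lin, s$genes)
  lin5 <- signal_track(dplyr::mutate(tibble::as_tibble(lin), value = value * 5),
                       spacing = 8)
  b <- compute_ntr(lin5, s$genes)
  expect_equal(b$ntr, 5 * a$ntr)
  expect_equal(class_fold(b, "tRNA", "polII")$fold,
               class_fold(a, "tRNA", "polII")$fold)
})

test_that("class folds multiply per-copy rates up to genomic copy number", {
  ntr <- structure(
    tibble::tibble(gene_id = c("r1", "p1", "p2"),
                   gene_class = c("rDNA", "polII", "polII"),
                   ntr = c(50, 1, 1)),
    scale = "linear"
  )
  out <- class_fold(ntr, "rDNA", "polII", copies = 150)
  expect_equal(out$fold, 50)
  expect_equal(out$fold_total, 7500)
  expect_equal(class_fold(ntr, "polII", "polII")$fold, 1)
  ntr0 <- structure(
    tibble::tibble(gene_id = c("a", "b"), gene_class = c("rDNA", "polII"),
                   ntr = c(1, 0)),
    scale = "linear"
  )
  expect_error(class_fold(ntr0, "rDNA", "polII"), "zero denominator")
})

mk_family_ntr <- function(copies, rate) {
  fam <- rep(sprintf("f%02d", seq_along(copies)), times = copies)
  n <- length(fam)
  structure(
    tibble::tibble(
      gene_id = sprintf("t%03d", 1:n), gene_class = "tRNA",
      ntr = rate(rep(copies, times = copies)),
      trna_family = fam, copy_number = rep(copies, times = copies)
    ),
    scale = "linear"
  )
}

test_that("family aggregates separate copy-number scaling from per-copy rate", {
  set.seed(12)
  ## constant per-copy rate, copy numbers with wide relative gaps: the
  ## family total ranks exactly with copy number
  copies <- c(1, 2, 3, 4, 6, 8, 10, 16)
  ntr_const <- mk_family_ntr(copies, function(cp) 10 * exp(rnorm(length(cp), 0, 0.05)))
  res <- family_copy_correlation(ntr_const)
  stats <- res$correlations
  expect_equal(stats$spearman[stats$relation == "total_vs_copies"], 1.0)
  ## family totals equal the sum over members
  sums <- tapply(ntr_const$ntr, ntr_const$trna_family, sum)
  expect_equal(as.numeric(sums[res$families$family]), res$families$total_ntr)

  ## constant per-copy rate with measurement noise constructed orthogonal
  ## to copy number: the per-copy correlation is exactly zero
  eps <- rnorm(length(copies), 0, 0.03)
  cc <- copies - mean(copies)
  eps <- eps - cc * sum(eps * cc) / sum(cc^2)
  ortho <- mk_family_ntr(copies, function(cp) {
    10 * (1 + eps[match(cp, copies)])
  })
  res_o <- family_copy_correlation(ortho)
  expect_equal(res_o$correlations$pearson[
    res_o$correlations$relation == "percopy_vs_copies"], 0,
    tolerance = 1e-10)

  ## violation scenario: per-copy rate proportional to copies is detected
  ntr_prop <- ntr_const
  ntr_prop$ntr <- ntr_prop$copy_number * exp(rnorm(nrow(ntr_prop), 0, 0.05))
  res2 <- family_copy_correlation(ntr_prop)
  expect_gt(res2$correlations$pearson[2], 0.9)

  one_fam <- dplyr::filter(ntr_const, trna_family == "f08")
  attr(one_fam, "scale") <- "linear"
  expect_error(family_copy_correlation(one_fam), "families")
})

test_that("condition responses classify inhibited and resistant classes", {
  ntr <- structure(
    tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                   gene_class = rep(c("polII", "tRNA"), each = 10),
                   ntr = rep(c(10, 500), each = 10)),
    scale = "linear"
  )
  same <- condition_response(ntr, ntr)
  expect_true(all(same$per_gene$log2_change == 0))
  expect_true(all(same$classes$status == "resistant"))

  treated <- ntr
  treated$ntr[treated$gene_class == "polII"] <- 1
  resp <- condition_response(ntr, treated, epsilon = 0.01)
  cls <- resp$classes
  expect_equal(cls$status[cls$gene_class == "polII"], "inhibited")
  expect_equal(cls$status[cls$gene_class == "tRNA"], "resistant")
  expect_equal(cls$median_change[cls$gene_class == "polII"],
               log2(0.1), tolerance = 0.02)

  ## epsilon keeps zero-control genes finite
  zero <- ntr
  zero$ntr[1] <- 0
  resp0 <- condition_response(zero, treated)
  expect_true(all(is.finite(resp0$per_gene$log2_change)))

  bad <- ntr[-1, ]
  attr(bad, "scale") <- "linear"
  expect_error(condition_response(ntr, bad), "different gene sets")
})

test_that("exon/intron G+C differences count bases exactly", {
  mk_gene <- function() tibble::tibble(
    gene_id = "t1", chrom = "chrI", strand = "+", tss = 0L, pa = 60L,
    orf_start = 0L, orf_end = 60L, gene_class = "tRNA",
    has_intron = TRUE, intron_start = 20L, intron_end = 40L
  )
  ## exon 40 bp at 50% GC, intron 20 bp at 35% GC -> 15 percentage points
  exon_half <- paste(rep("GCAT", 5), collapse = "") # 20 bp, 50% GC
  intron <- paste0(paste(rep("GC", 3), collapse = ""), "G",
                   paste(rep("AT", 6), collapse = ""), "A") # 7/20 GC
  seqs <- Biostrings::DNAStringSet(c(chrI = paste0(exon_half, intron, exon_half)))
  expect_equal(gc_intron_exon_diff(mk_gene(), seqs)$diff_points, 15)

  ## degenerate contrasts
  same <- Biostrings::DNAStringSet(c(chrI = paste(rep("GCAT", 15), collapse = "")))
  expect_equal(gc_intron_exon_diff(mk_gene(), same)$diff_points, 0)
  pure <- tibble::tibble(
    gene_id = "t2", chrom = "chrI", strand = "+", tss = 0L, pa = 8L,
    orf_start = 0L, orf_end = 8L, gene_class = "tRNA",
    has_intron = TRUE, intron_start = 4L, intron_end = 8L
  )
  seqs2 <- Biostrings::DNAStringSet(c(chrI = "GCGCATAT"))
  expect_equal(gc_intron_exon_diff(pure, seqs2)$diff_points, 100)
  no_intron <- dplyr::mutate(mk_gene(), has_intron = FALSE)
  expect_error(gc_intron_exon_diff(no_intron, seqs), "no intron")
})
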