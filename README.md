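# nascentr

Analysis of strand-specific nascent-transcription (genomic run-on)
profiles, for researchers studying how RNA polymerases II and III behave
along genes — initiation, elongation through positioned nucleosomes,
backtracking, and termination around the polyadenylation (pA) site.

Run-on assays label only the RNA of *catalytically active* polymerases:
a backtracked polymerase occupies its template (and is counted by
polymerase ChIP) but cannot extend. The central quantity is therefore the
**specific activity**

```
ratio(x) = log2( nascent(x) / ChIP(x) )  ~  log2 a(x),
```

the active fraction `a(x)` of engaged polymerase at position `x`, read off
anchor-aligned metagene profiles. The package provides:

* **Preprocessing** — per-probe `log2((sample + p)/(gDNA + p))`
  normalization against a genomic-DNA control, correction of the ~25 nt
  downstream run-on displacement (`shift_5prime()`), intergenic background
  estimation and the strict `nTR > 6 x background` confident-gene filter.
* **Metagenes** — TSS- or pA-anchored, strand-oriented matrices and average
  profiles for arbitrary gene groups (`build_matrix()`,
  `average_profile()`, `ratio_profile()`, `group_genes()`,
  `length_sorted_heatmap()`).
* **Phasing statistics** — autocorrelation period of the nucleosome-linked
  undulation (`estimate_period()`), peak calling with prominence
  (`call_peaks()`), cross-condition displacement by lagged correlation
  (`estimate_displacement()`), and nascent-vs-mature boundary extensions by
  half-plateau crossing (`extension_length()`).
* **Clustering** — k-means on z-scored profile shapes and on
  between-condition difference profiles (`cluster_profiles()`,
  `cluster_condition_shift()`).
* **Quantification** — per-gene nascent transcription rate (nTR = mean
  linear signal over the ORF), gene-class folds, tRNA isoacceptor-family
  aggregates and copy-number correlations, per-class drug-response
  summaries, exon/intron G+C contrasts (`compute_ntr()`, `class_fold()`,
  `family_copy_correlation()`, `condition_response()`,
  `gc_intron_exon_diff()`).
* **A synthetic-data generator** (`sim_config()`, `make_genome()`,
  `simulate_tracks()`) that emulates tiling-array run-on experiments —
  8 bp probe grids, a 165 bp nucleosomal repeat (150 bp for RP genes),
  dyad-linked backtracking dips, the 25 nt displacement, 300 bp ChIP
  smearing, pol III/pol II intensity contrasts, alpha-amanitin and
  *isw2* nucleosome-repositioning conditions — so every stage can be
  validated against ground truth.

Everything is tidyverse-shaped: tracks, gene tables, profiles and nTR
tables are tibbles; results have `tidy()`/`glance()` methods and
`autoplot()` figures; `run_pipeline()` chains the whole analysis.

## Worked example

```r
library(nascentr)

cfg    <- sim_config(seed = 1)          # 300 polII + 30 RP + 40 tRNA + 2 rDNA genes
genome <- make_genome(cfg)
tracks <- simulate_tracks(genome$genes, genome$nucleosomes, cfg, "WT")

gro  <- shift_5prime(normalize_by_gdna(tracks$gro, tracks$gdna), 25)
p2   <- dplyr::filter(genome$genes, gene_class == "polII")
prof <- average_profile(build_matrix(gro, p2, "tss", c(-200, 800)))
glance(estimate_period(prof))
#> # A tibble: 1 × 5
#>   period peak_r periodic lag_min lag_max
#>    <dbl>  <dbl> <lgl>      <dbl>   <dbl>
#> 1   166.  0.701 TRUE         100     250
```

The profile undulates with a ~166 bp period (the planted nucleosomal
repeat is 165 bp), with a strong autocorrelation peak (r = 0.70). The full
pipeline computes every headline quantity at once:

```r
report <- run_pipeline(cfg, quiet = TRUE)
tidy(report)
#> # A tibble: 20 × 2
#>    metric                              value
#>  1 background                         1.09
#>  2 n_confident_genes                301
#>  3 period_bp                        166.
#>  5 nucleosome_antiphase_r            -0.0263
#>  6 extension_5p_bp                   68.8
#>  7 extension_3p_bp                  149.
#>  8 pa_sharp_peak_nt                  24
#>  9 pa_broad_peak_bp                -256
#> 11 isw2_displacement_bp              14.7
#> 13 trna_peak_fold                    73.0
#> 17 rdna_percopy_fold                 51.4
#> 18 rdna_total_fold                 7709.
#> 19 amanitin_median_polII             -3.24
#> 20 amanitin_median_tRNA              -0.0242
#> # (abridged)
```

Reading the numbers: the nascent signal extends ~69 bp upstream of the
mRNA boundary at the TSS and ~149 bp past it at the pA site; the
pA-anchored profile carries a sharp activity peak ~24 nt before the pA and
a broad one centred ~256 bp upstream; the *isw2* nucleosome repositioning
(truth: 15 bp) displaces the run-on peaks of the recovered 60-gene cluster
by ~14.7 bp; tRNA genes peak ~73-fold above the mean pol II gene and the
~51-fold per-copy rDNA signal amounts to a ~7700-fold total over 150
genomic copies; alpha-amanitin knocks pol II genes down by ~log2(0.1)
while tRNA genes are untouched.

See the vignette (`vignettes/nascent-run-on-analysis.Rmd`) for the signal
model, parameter meanings and the reasoning behind the numerical choices.

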