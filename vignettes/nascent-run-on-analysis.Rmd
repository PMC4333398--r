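---
title: "Analysing nascent run-on profiles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing nascent run-on profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The biology the package models

Genomic run-on assays label RNA that elongating polymerases extend *in situ*,
so the resulting signal maps only the **catalytically active** fraction of
the engaged polymerases: a backtracked polymerase — one whose RNA 3' end has
slipped out of the active site — still occupies its template (and is seen by
polymerase ChIP) but cannot run on. Comparing a run-on track against a
total-occupancy ChIP track therefore reads out the *specific activity* of
the polymerase along the gene, and its structure turns out to be dominated
by positioned nucleosomes: activity dips as the enzyme approaches each
nucleosome dyad, recovers in the linkers, declines slowly from 5' to 3', and
spikes twice near the polyadenylation (pA) site. tRNA genes, transcribed by
RNA polymerase III at per-copy rates tens of times the average pol II gene,
are insensitive to the pol II inhibitor alpha-amanitin and sit between
positioned nucleosomes.

`nascentr` implements the downstream analysis of such data — normalization,
metagene construction, phasing statistics, clustering and rate
quantification — together with a synthetic-data generator that reproduces
the statistical structure the analysis assumes. The generator is first-class
code: every stage of the pipeline can be exercised against a known ground
truth, which is how the test suite and `scripts/acceptance.R` validate the
implementation.

## The generator's signal model

A simulated genome (`make_genome()`) places non-overlapping transcribed
units of four classes (pol II, ribosomal-protein (RP), tRNA, rDNA) on a set
of chromosomes, each with a ground-truth rate and a set of positioned
nucleosome dyads:

* pol II / RP genes: dyads +1..+4 downstream of the TSS at
  `plus1_dyad_offset` (60 bp) plus multiples of the nucleosomal repeat
  (165 bp; 150 bp for RP genes, whose shorter repeat is a known feature of
  that regulon), and dyads -1..-3 upstream of a nucleosome-depleted region
  spanning the pA site. The -1 dyad is anchored 380 bp upstream of the pA;
  the -2/-3 dyads carry 30 bp of per-gene positional jitter, reflecting the
  decay of positioning fidelity away from the anchoring NDR. (With exactly
  phased -2/-3 nucleosomes the averaged 3' profile grows an
  internucleosomal ridge that real average profiles do not show; the jitter
  is the generator's way of matching the observed two-peak 3' shape.)
* tRNA / rDNA genes: flanking dyads only; the short gene body sits in the
  gap between positioned nucleosomes.

For a gene of length $L$ (TSS at $u = 0$ in transcription coordinates), the
**active fraction** of engaged polymerase is

$$
a(u) \;=\; \mathrm{clamp}\!\Big[\,
(1 - \beta_0)\, e^{-u/\tau}
\;\times\; \Big(1 - \beta_1 \sum_d g(u;\, d - \ell,\ \sigma_b)\Big)
\;\times\; \big(1 + \text{gains}(u)\big)
,\ 0.02,\ 1\Big]
$$

with $g$ an unnormalized Gaussian, and

* $\beta_0$ = `backtrack_base` (0.15) — baseline backtracked fraction at the
  TSS; $\beta_1$ = `backtrack_amplitude` (0.35) — depth of the dyad-linked
  dips. Neither is quantified by run-on data alone; they are free generator
  parameters chosen once to give clearly resolvable dips at the study's
  noise level.
* $d - \ell$: each dip is centred `backtrack_dyad_lead` = 40 bp *upstream*
  of its dyad (backtracking probability rises as the polymerase engages the
  first H2A–H2B contact), with width $\sigma_b$ = `backtrack_sigma` = 20 bp.
* $\tau$ is set so the activity declines by `activity_decay_drop` (30%) over
  `activity_decay_bp` (800 bp); the exponential form keeps $a > 0$ on long
  genes.
* gains: a bump on the +1 nucleosome scaled by the gene's H2AZ level
  (`plus1_gain` x `h2az_level`, width 30 bp) — H2AZ-rich +1 nucleosomes
  suppress backtracking; a sharp peak 25 nt before the pA
  (`pa_sharp_gain` = 0.45, $\sigma$ = 12 bp) where polymerases stop
  backtracking at the cleavage site; and a broad peak centred 250 bp
  upstream of the pA (`pa_broad_gain` = 0.35, $\sigma$ = 45 bp). The two pA
  peak centres are anchored constants of the model; their amplitudes and
  widths are free and were calibrated once so that the wide peak remains
  clearly wide (FWHM ~106 bp vs ~28 bp) while keeping a well-defined
  maximum at metagene noise levels.

tRNA/rDNA genes use $a(u) = e^{-u/150}$ (activity peaks at the TSS), with a
`intron_gain` = 30% boost inside tRNA introns (slower elongation over
A+T-rich introns means higher active-polymerase density).

Total occupancy is flat over the transcribed unit, which extends
`tss_upstream_extension` = 70 bp upstream of the TSS and
`pa_downstream_extension` = 150 bp past the pA; the per-gene level
$\kappa$ is set so that the mean active density over the ORF equals the
gene's `true_rate` — i.e. `true_rate` *is defined as* the noiseless nTR.
The four assay tracks (`simulate_tracks()`) are then:

* `gro` — $\kappa\, a(u)$ evaluated 25 nt upstream of each probe
  (`runon_displacement`: the run-on extends the nascent RNA ~25 nt, moving
  the observed signal downstream; `shift_5prime()` undoes it);
* `chip` — $\kappa$ smeared with a `chip_fragment` = 300 bp boxcar;
* `mrna` — $\kappa$ restricted to TSS..pA, zero outside;
* `gdna` — flat 1.

Outside transcribed units the `gro`/`chip` tracks sit at the additive array
`background` (1.0 arbitrary unit). Within a unit the probe carries the pure
signal — this keeps the noiseless contrasts exact (alpha-amanitin scales
pol II probes by exactly `amanitin_factor`; mRNA is exactly zero at
TSS - 10) and makes `true_rate` recoverable without deconvolution. Noise is
multiplicative lognormal per probe ($\sigma$ = `noise_sd` = 0.3),
independent across probes and assays: intensities are positive and
heteroscedastic, which is what array data look like after background
subtraction.

Class rates: pol II genes draw from lognormal(log 10, 0.6); RP genes from
lognormal(log 25, 0.4) (a uniformly high-expression class); every tRNA gene
shares the constant per-copy rate `trna_fold` (50) x the mean pol II rate,
and rDNA repeat units `rdna_fold` (50) x. tRNA genes belong to isoacceptor
families with *distinct* copy numbers (for 40 genes: 1, 2, ..., 7, 12);
distinctness is what lets the family total rank exactly with copy number.

### What the generator does *not* emulate

No sequence-dependent probe affinity (hybridization is modelled as unbiased,
which is also the null hypothesis `uracil_bias_check()` tests), no
antisense transcription, no cross-hybridization between tRNA copies, no
replicate structure (noise is collapsed into one lognormal term), no
read-level output, and no probe-grid irregularities. Passing tests on this
generator show that the *analysis* recovers the planted structure at
realistic noise; they do not certify performance against artefacts the
generator omits.

## Analysis stages and their numerical choices

**Normalization** (`normalize_by_gdna()`): per-probe
$\log_2\,(s + p)/(g + p)$ on the intersection of the probe grids. The
pseudocount default is 5% of the median control. A larger pseudocount
(e.g. 25%) visibly attenuates antilogged gene-level signal
($(s + p)/(1 + p) \approx 0.8 s$ at unit control), which would silently
shift any fold-threshold comparison downstream; 5% still bounds the log
ratio where the control dips while keeping that attenuation under ~5%.

**Background and the 6x filter** (`estimate_background()`,
`filter_confident_genes()`): background is estimated from probes more than
200 bp away from any transcribed unit; the filter keeps genes whose linear
nTR strictly exceeds 6x background. One subtlety: under multiplicative
noise in both sample and control, the *mean* of the normalized ratio is
inflated by $e^{\sigma^2}$ (~9% at $\sigma = 0.3$) while the *median* is
not. Since nTR is a mean, the pipeline uses the intergenic **mean** as the
background statistic so that both sides of the 6x comparison scale
identically; the function's default remains the more outlier-robust median
for exploratory use. The filter is applied on the linear scale — a 6x fold
has no meaning on log2 values.

**Metagenes** (`build_matrix()`, `average_profile()`): anchor-relative
offsets on the probe grid, positive downstream in transcription direction;
minus-strand genes are mirror-oriented. Cells take the nearest probe within
half a grid step (the 25 nt shift moves probes off the nominal grid, so
exact matching would discard everything); per-gene jitter is at most half a
step and averages out across genes. Averages are means (matching
average-profile figures; medians available), missing cells are excluded
rather than zero-filled, and offsets supported by fewer than `min_n` = 20
genes are masked. Ratio profiles divide *averaged* profiles (ratio of
means) on the linear scale; a per-gene (mean of ratios) variant can be had
by building a ratio matrix first — with per-probe noise at $\sigma = 0.3$
the ratio-of-means is the stabler of the two.

**Phasing** (`estimate_period()`): autocorrelation of the detrended
profile, highest local maximum in the 100–250 bp lag range, parabolic
sub-grid refinement. Detrending subtracts a **running median** (250 bp
window): the profile contains step edges (the signal boundary ~70 bp
upstream of the TSS) and a smooth 5'->3' decline, and a running mean smears
the step into the residual, tilting the ACF baseline enough to bias the
period estimate by ~8 bp; the median follows edges exactly and leaves a
clean periodic residual. The same detrender backs
`estimate_displacement()`, whose lag search is exhaustive over grid lags
within ±`max_lag` (tested against a brute-force oracle) before parabolic
refinement; positive lags mean the second profile sits downstream.

**Peak calling** (`call_peaks()`): local maxima of a running-mean-smoothed
profile (smoothing, unlike detrending, should average noise, so the mean is
right here), with peak prominence — height above the higher of the two
bounding saddles — filtering out ripples (default threshold: 5% of the
smoothed range). Plateau ties break towards the anchor.

**Boundary extensions** (`extension_length()`): the transcribed-unit
boundary of a profile is where it crosses the half-plateau level (midpoint
of a gene-body plateau estimate and a far-flank floor estimate), found by
linear interpolation walking outward from the gene-body side; the extension
is the distance between the nascent and mature boundaries. Half-plateau
crossing is the package's operationalization of a boundary that the source
figures read off heat maps by eye; it is scale-invariant and robust to the
plateau's internal undulations.

**Clustering** (`cluster_profiles()`, `cluster_condition_shift()`): rows
with more than 20% missing cells are dropped, gaps linearly interpolated,
rows z-scored (shape, not level, defines the classes), then `stats::kmeans`
with 25 random restarts keeping the best inertia — restarts make the
labelling reproducible under the stored seed. For condition shifts the
z-scored difference rows are clustered *without* re-standardization:
re-scaling would blow the noise-only rows of unmoved genes up to unit
variance and erase exactly the contrast (moved vs unmoved) the operation
exists to find. The "shifted" cluster is the one with the largest mean
absolute difference. In the pipeline the shifted cluster is recovered from
the *nucleosome occupancy* matrices (the repositioning is a chromatin
event; the run-on displacement is then measured on those genes' metagenes),
mirroring how the remodeler-mutant analysis is actually done.

**Quantification** (`compute_ntr()` and friends): nTR is the mean linear
probe intensity over the ORF (tRNA/rDNA genes: the whole gene body); genes
with fewer than 3 probes are flagged. Class folds are ratios of means (the
median-based fold is reported alongside, since "the average gene" is
ambiguous); the rDNA total fold multiplies the per-copy fold by the genomic
copy number (150). The alpha-amanitin response guard is
$\varepsilon = 0.001 \times$ median control nTR — large enough to keep
zero-control genes finite, small enough not to compress a 10-fold
inhibition (a guard at 25% of the median would report a 10-fold inhibition
as ~3.5-fold).

## Statistical power of the per-copy constancy check

With 40 tRNA genes and exact total-vs-copies ranking required, at most 8
distinct-copy families exist, and a Pearson correlation over 8 points has a
null sampling sd of $1/\sqrt{7} \approx 0.38$ *independent of the noise
level* (correlation is scale-free). A single-draw assertion that the
per-copy correlation is under 0.2 would be a coin flip by construction, so
the test suite averages the correlation over five generator seeds — the
same seed-averaging used for the tRNA-fold parameter recovery — and the
unit test uses a fixture whose noise is constructed exactly orthogonal to
copy number. With the ~42 families of a real tRNA complement the
single-draw bound would be meaningful.

## Problem sizes and determinism

The default study conditions are 300 pol II, 30 RP, 40 tRNA and 2 rDNA
genes on four 300 kb chromosomes at 8 bp probe spacing — large enough that
metagene noise per offset is ~0.03 log2 units (300-gene averages) and every
headline quantity is stable across seeds, small enough that the full
three-condition pipeline runs in well under a minute. Everything downstream
of `sim_config(seed = ...)` is deterministic: the genome, the tracks (one
RNG stream per condition), k-means (seeded, with restarts) and all
estimators; `run_pipeline()` called twice with the same configuration is
bit-identical.

```{r pipeline}
library(nascentr)
report <- run_pipeline(sim_config(seed = 1))
tidy(report)
```

## Known limitations

* The generator's flat-occupancy body means ChIP 5'->3' trends (which real
  RP genes show) are not emulated; the specific-activity ratio carries all
  the spatial structure.
* The lag-0 anti-correlation between nascent signal and nucleosome
  occupancy is weak by construction (the activity dips *lead* the dyads by
  40 bp, a quarter period), so the package reports it as a signed metric
  but the sharper statement — strong anti-correlation at the 40 bp-aligned
  lag — is the better test of the mechanism.
* File-based (non-simulated) inputs run the wild-type analyses only;
  condition contrasts require matched condition tracks.
* BigWig output is not provided; bedGraph/GFF3/BED/TSV/YAML cover all
  interchange, written at full float precision.
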