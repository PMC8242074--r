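---
title: "Copy-number profiling of shallow-WGS minibulk samples: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number profiling of shallow-WGS minibulk samples: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shallowcna)
library(dplyr)
```

## The problem

Microdissected "minibulk" tissue samples — on the order of 30–50
morphologically uniform cells captured by laser microdissection — yield
minute amounts of DNA, but shallow whole-genome sequencing at roughly
0.1× coverage (about one million mapped reads) is enough to infer
genome-wide copy-number alterations (CNAs) at megabase resolution. In
fibro-osseous lesions of the jaw this matters clinically: ossifying
fibroma frequently carries recurrent segmental gains and losses
(chromosomes 7 and 12 in particular, occasionally focal amplifications
with copy numbers near 10), while fibrous dysplasia is almost always
CNA-free, so a CNA profile can support a differential diagnosis where
morphology is ambiguous. Genomes with alterations scattered over many
chromosomes instead resemble osteosarcoma-like complexity and warrant a
warning rather than reassurance.

This package implements the complete analysis chain for such data:
binning mapped reads, GC-bias normalization, noise-based quality
control, segmentation, per-sample genome-complexity scoring, gain/loss
calling, and cohort-level aggregation. Because suitable patient data
cannot be redistributed, the package also ships a synthetic-data
generator with known ground truth; every stage is tested against that
truth.

## The model, stage by stage

### Bins and counting

The coordinate system is a fixed tiling of the 24 human chromosomes
(1–22, X, Y) into non-overlapping 1 Mb bins, each annotated with a GC
fraction and an optional positive weight. "Dynamic" mappability-scaled
bins can be emulated through the weight column, but the default is
fixed-width bins: downstream mathematics never depends on bin width, and
fixed bins are deterministic and reproducible without external tracks.
Mapped-read positions are tabulated with half-open `[start, end)`
semantics; records falling outside every bin are counted and reported,
never silently dropped.

### GC normalization

Bin counts carry a smooth, unimodal, multiplicative bias in GC content.
`gc_normalize()` fits a LOWESS regression of (weight-corrected) count
against GC across usable bins, divides each count by its fitted value,
and rescales so the median over usable autosomal bins is exactly 2 —
the diploid anchor, appropriate because these lesions are
predominantly diploid outside focal events. Defaults are a span of 0.3
with 3 robustifying iterations: wide enough to track a smooth quadratic
bias, too wide to chase megabase-scale CNA events (which occupy a few
percent of bins and are further suppressed by the robust iterations).
Normalization is strictly per sample; no panel of normals is assumed.

### Quality control: MAPD

The noise statistic is the median absolute pairwise difference,
`MAPD = median(|x[i+1] - x[i]|)`, over bins in genome order. Because it
is a median of *successive* differences, true CNA steps contribute only
a handful of large values and barely move it, while amplification and
counting noise move it directly; for Gaussian noise of standard
deviation σ it converges to σ·√2·Φ⁻¹(0.75) ≈ 0.954 σ. Successive pairs
spanning a chromosome boundary are excluded by default — they inject
step-like jumps into a noise statistic — with `genome_wide = TRUE`
restoring the literal genome-ordered reading. MAPD is computed on
linear copy-number values, matching the definition used for the
inclusion rule; a log2 option exists for cross-platform comparability.
A sample is qualified when it has **more than 100 000** mapped reads
and **MAPD < 0.23**, both boundaries strict.

### Segmentation

`cbs_segment()` is an in-house implementation of circular binary
segmentation. Per chromosome it scans all arcs (i, j] of the
circularized bin sequence for the maximal mean-difference statistic
`|mean_in - mean_out| / sqrt(1/k + 1/(n-k))`, assesses that maximum by
permuting the chromosome's values (default 1 000 permutations,
declaring a change when the permutation p-value ≤ α = 0.1), and
recurses into the resulting pieces. Design details that matter:

* **Minimum width.** A declared change is rejected if it would create
  any segment shorter than `min_width = 5` bins; the arc scan simply
  skips such candidates. Chromosomes shorter than `2 * min_width`
  usable bins are returned as a single untested segment.
* **Undo-splits.** After convergence, adjacent segments whose means
  differ by less than `undo_sd × sd_est` are merged (smallest
  difference first, means recomputed after each merge), with
  `sd_est = MAPD / (√2·0.6745)` — the sample's own noise scale. The
  undo threshold of 0.1 SD is deliberately conservative.
* **Scale.** Segmentation runs on linear copy number by default, so
  segment means live on the same scale as the calling thresholds; a
  log2 option segments `log2(x/2)` and back-transforms means as
  `2·2^mean`.
* **Determinism.** The permutation RNG is the only stochastic element;
  a seed in `cbs_config()` makes runs exactly reproducible. Ties in the
  arc scan break toward the lexicographically smallest (i, j).
* **No variance estimate.** The scan statistic omits a pooled-variance
  denominator; the permutation null calibrates the test regardless, and
  the maximizer is the least-squares changepoint pair.

An exhaustive dynamic-programming least-squares partitioner
(`oracle_segment()`, capped at 200 values and 4 segments) serves as an
independent reference in the test suite; on noisy step instances CBS
boundaries agree with it to within one bin essentially always, while at
α = 0.1 CBS adds a spurious extra split in roughly one instance in
seven — the expected size of the permutation test, verified on
pure-noise chromosomes.

### CNAscore

Genome complexity is summarised per sample as a sum over the 24
chromosomes of a jump term and a deviation term computed from segment
means `s_i`:

    CNAscore = Σ_chr [ mean(|s_i − s_{i−1}|) + 0.5·|mean(s_i) − norm| ]

where `norm` is the chromosome's neutral copy number given sex
(autosomes 2; male X and Y 1; female X 2; female Y 0). The jump term
measures within-chromosome instability (0 for a single segment); the
deviation term measures departure from neutral ploidy. `mean(s_i)` is
the **unweighted** mean over segments — the literal reading of the
formula. This makes a 5-bin supergain weigh as much as a
whole-chromosome segment in the deviation term; a length-weighted
option is provided for users who prefer size-proportional scores, but
the unweighted form is the default and is what all tests assert. A
profile that is everywhere at its neutral value scores exactly 0.

### Calling and status

Segments are called by strict thresholds: on diploid chromosomes gain
is CN > 2.4 and loss CN < 1.7; on haploid chromosomes (male X/Y) gain
is CN > 1.5 and loss CN < 0.5; chromosomes with neutral copy number 0
are never called. Segments shorter than `min_call_bins` (default: the
segmentation minimum width, 5) are not called. A sample is CNA-positive
when it has at least one call; a patient is positive when at least
`min_positive_samples` (default 1) of their QC-passed lesional samples
are positive — normal-tissue samples never count, and a patient with no
QC-passed lesional samples is reported as indeterminate rather than
negative. The aggregation rule is exposed rather than fixed because
multi-sample designs admit several defensible definitions.

### Cohort aggregation

* **Recurrence tracks** give, per bin, the fraction of samples (or
  patients) whose gain/loss calls cover it, on a shared denominator.
* **Smallest common regions** locate recurrent hotspots: for one
  chromosome and direction, an endpoint sweep finds the region covered
  by the most distinct patients (ties broken toward the widest region;
  fewer than 2 supporters yields an empty result). The reported region
  is by construction contained in every supporting patient's interval.
* **Pattern concordance** between two samples is a direction-matched
  Jaccard index over altered bins; two alteration-free samples are
  defined as concordant (1.0) with a `both_negative` annotation. The
  0.8 default "consistent" threshold is a convention, configurable.
* **Diagnostic flags** reduce a patient to three booleans: CNA
  positivity, a chromosome 7/12 pattern (the recurrent hotspots), and a
  genome-complexity warning (calls on ≥ 8 distinct chromosomes, or
  median CNAscore above a configurable cutoff). The complexity rule
  mirrors the observation that osteosarcoma-like genomes break on many
  chromosomes; it is a package convention, not a clinical rule, and the
  summary label always states that absence of CNAs rules nothing out.

## The synthetic-data generator

`simulate_sample()` draws bin counts from a Gamma–Poisson (negative
binomial) model: expectation proportional to
`weight × (CN/2) × b(GC)`, normalized so expected counts sum to the
target depth (default 1e6 mapped reads ≈ 0.1× coverage, i.e. ~325 reads
per bin on the full ~3,100-bin genome), with variance
`μ + dispersion·μ²`. The negative binomial is the standard
over-dispersion family for sequencing counts, and its single dispersion
parameter is the knob that moves MAPD; `calibrate_dispersion()` inverts
that map by monotone bisection against simulated profiles and refuses
targets below the Poisson floor at the given depth. The GC bias is a
mild positive quadratic peaking near GC 0.45 — exactly the smooth
unimodal shape LOWESS is built to remove. `make_genome()` provides
hg19-proportional chromosomes with a smoothly autocorrelated GC track
in [0.3, 0.6]; smaller `scale` values shrink every chromosome for fast
tests, but each chromosome must keep ≥ 10 bins so the segmentation
minimum width stays meaningful (hence test genomes use scales ≥ 0.25).

`simulate_cohort()` mirrors the study design: ossifying-fibroma-like
patients share a chromosome 7 segmental one-copy loss and a chromosome
12 short-arm gain with small per-patient breakpoint jitter (a
configurable fraction receive a nested focal supergain, CN ≈ 9.4);
fibrous-dysplasia-like patients are event-free; osteosarcoma-like
patients receive events on nine chromosomes. Each patient contributes
fibrous and calcified lesional samples sharing one truth, plus an
event-free normal sample.

What the generator does **not** model: read-level artifacts (duplicate
reads, insert-size structure, mappability holes), tumor–normal
admixture, subclonal mixtures, and any empirical noise structure of the
real assay beyond its MAPD. Passing tests therefore demonstrate that
the pipeline's mathematics recovers known truth under realistic count
noise — not that the assay itself performs at any particular level on
real tissue.

## Numerical choices and edge cases

* Degenerate inputs error early and explicitly: all-zero samples, bins
  out of order, overlapping events, segment sets that do not partition
  a chromosome, targets below the Poisson MAPD floor.
* Bins with zero weight or a non-positive LOWESS fit are masked out and
  excluded from MAPD, segmentation and calling; segments partition the
  *usable* bins.
* The autosomal median after normalization is exactly 2 by
  construction; multiplying all counts by a constant leaves profiles
  unchanged to floating-point precision.
* Permutation p-values use the add-one convention
  `(count + 1)/(nperm + 1)`; the permutation loop exits early once the
  decision can no longer change, which alters nothing but runtime.
* With sex `"unknown"`, X is treated as diploid (with a message) and Y
  is excluded from scoring and calling.

## Known limitations

* At the fixed analysis settings (α = 0.1, minimum width 5, loss
  threshold 1.7), an event-free sample occasionally (a few percent of
  samples) produces one marginal spurious call — a 5-bin noise dip
  whose mean lands just beyond a threshold. Patient-level
  false-positive probability therefore grows with the number of
  samples per patient; `min_positive_samples = 2` is the natural
  remedy for deeply sampled patients.
* The unweighted CNAscore deviation term lets focal events dominate
  chromosome terms (see above).
* Recurrence and hotspot analyses work in bin space; gene-level
  interpretation requires the user's own annotation intersect.
* The test-suite problem sizes (full-scale genomes for event recovery;
  scale 0.25–0.5 genomes at matched per-bin depth elsewhere; 50–200
  replicates per property) were chosen as the smallest sizes at which
  the Monte-Carlo assertions are stable.

## A worked example

```{r example, eval = FALSE}
bins <- make_genome(scale = 0.5, seed = 61)
res <- run_pipeline(
  out_dir = tempfile("run"),
  bins = bins,
  sim = list(n_of = 3, n_fd = 3, depth = 5e5, dispersion = 0.0031),
  seed = 1)

res$qc          # mapped reads, MAPD, pass/fail per sample
glance(res$segments)
res$scores      # CNAscore per sample
res$flags       # per-patient diagnostic-support flags
plot_profile(res$profile, res$segments,
             sample = res$samples$sample_id[1])
plot_recurrence(res$recurrence)
```
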