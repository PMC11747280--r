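---
title: "Models and methods behind breakscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind breakscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakscape)
```

## The scientific problem

Cohesin, the ring-shaped complex that extrudes chromatin loops between
CTCF-bound anchor sites, plays two distinguishable roles when a DNA
double-strand break (DSB) occurs: it is recruited throughout the damaged,
gamma-H2AX-marked megabase-scale domain in an ATM/SMC1A-phosphorylation
dependent manner, and its architectural activity confines broken ends so that
they do not wander into other damaged domains and mis-join. `breakscape`
implements the quantitative analyses used to dissect these roles in systems
where site-specific breaks are induced with an AsiSI restriction enzyme
(recognition site `GCGATCGC`, an 8-bp palindrome, cut upon 4OHT-driven
nuclear translocation):

1. **ChIP enrichment around breaks** — fold changes of RAD21 (cohesin) peak
   signal between damaged and undamaged conditions, stratified by distance to
   the nearest break (≤10 kb, ≤250 kb, ≤1 Mb, control) or by position inside
   versus outside called gamma-H2AX domains.
2. **Hi-C domain statistics** — observed/expected (O/E) normalization of
   contact matrices, per-domain intra-domain interaction scores, fold changes
   of inter-domain (DSB-DSB domain pair) contacts, 4C-like viewpoint tracks,
   and 5×5-bin translocation-window sums on 250 kb trans matrices.
3. **HTGTS junction analytics** — for high-throughput genome-wide
   translocation sequencing libraries anchored at a bait DSB: removal of
   bait-proximal artefacts (±20 kb), cis-deletion/translocation
   classification, damage-context assignment, per-1-kb unique-event binning,
   condition fold changes, and microhomology profiling.

Because the sequencing data behind such studies is not reproducible at desk
scale, the package ships a first-class synthetic-data generator whose
*injected* effect sizes serve as recovery targets for every analysis stage.

## Statistical conventions

Fold changes of ChIP signal use a pseudocount of 0.1 on both numerator and
denominator: `FC = (treated + 0.1) / (untreated + 0.1)`, with per-peak signal
taken as the mean per-bp coverage over the peak interval (robust to
peak-width variation, unlike summit height). Viewpoint tracks use
`log2((t + 1)/(u + 1))` on raw normalized counts; translocation-window log2
fold changes use pseudocount 0.1 on the 5×5-block sums. Group comparisons of
matched quantities (per-domain FCs against 1) use a one-tailed paired t-test;
unequal-n comparisons (category vs control peaks, inside vs outside anchors)
use a one-tailed Welch t-test — a paired test is undefined for unequal group
sizes, so Welch is the package's convention for those contrasts. Box
summaries report type-7 quartiles with whiskers one IQR beyond the box,
unclamped. Raw p-values are reported without multiple-testing correction,
with significance stars at 0.05/0.01/0.001; the package reports few,
pre-specified contrasts rather than genome-wide scans, and leaving p-values
raw keeps them comparable across analyses.

Distance categories are *disjoint shells* by default (`D250K` means
10 kb < d ≤ 250 kb) with inclusive upper bounds, which keeps the
category-vs-control tests independent; `cumulative = TRUE` switches to nested
categories (d ≤ bound) for comparison with cumulative reporting styles.

All coordinates are 0-based half-open (BED convention) internally. Published
coordinate tables, which are 1-based, should be converted on ingestion
(subtract 1 from positions); pairwise distances are unaffected. One shipped
break-pair table (`inst/extdata/asisi_cis_junctions_hg19.tsv`) lists assayed
cis junction coordinates; its first row's printed distance (68 kbp) is
inconsistent with its own coordinates (which give 64 kbp), so that row is
excluded from exact-reproduction tests.

## O/E normalization and domain scores

The expected profile of an intra-chromosomal matrix is the raw mean of
`counts[i, i + d]` over all valid `i` at each bin separation `d`, zeros
included and without smoothing; O/E divides each entry by the profile value
at its separation, masking separations whose expected value is zero.
Production Hi-C pipelines compute their expected curves internally during
normalization; the raw per-distance mean used here is the same estimator
without smoothing, and domain scores are insensitive to the difference
because they compare the same bins across conditions.

The intra-domain score is the mean O/E over unordered bin pairs (i < j) with
both bins *fully* inside the domain; the main diagonal is excluded by default
because self-bin signal is dominated by technical artefacts
(`include_diagonal = TRUE` restores it). Inter-domain pair scores average O/E
over the cross rectangle of two non-overlapping domains. Both window
operators (viewpoint and translocation windows) clip at matrix edges rather
than padding.

The Ctrl-Ctrl comparison set for inter-domain statistics is produced by
`control_pairs_matched()`: undamaged domain pairs are drawn, seeded and
without replacement, to greedily match the genomic-separation distribution of
the DSB-DSB pairs. Separation matching matters because O/E noise grows with
separation; greedy nearest-separation matching is the simplest scheme that
controls it.

## gamma-H2AX domain calling

No standard algorithm exists for calling megabase-scale damage domains, so
the package uses a transparent two-threshold scheme: tracks are aggregated to
10 kb windows, the per-window statistic is `z = (treated − untreated) /
sd(untreated)` with the sd taken per chromosome, maximal runs of `z > 1`
containing at least one `z > 2` window become domains, domains closer than
100 kb merge, and domains shorter than 100 kb are dropped. The 10 kb
aggregation is essential: at the native 100 bp rpkm resolution the
treated−untreated difference is dominated by counting noise, whereas after
aggregation the chromosome-level sd reflects regional background variability
shared by both conditions, so the null rarely crosses the seed threshold
while a plateau of damage signal exceeds it by an order of magnitude.
Identical tracks yield no domains; a constant (noise-free) untreated track
makes the statistic undefined and is refused.

DSB calling from MRE11-like coverage compares the mean signal within ±500 bp
of a candidate cut against the median of a ±5 kb local window (core
excluded); when that median is zero — sparse background — the window mean is
used instead so that the ratio test does not trigger on a single stray count.

## The synthetic-data generator

`build_layout()` constructs the study conditions once per seed; everything
downstream is a pure function of the configuration. Defaults, and what they
emulate:

* **Genome**: 2 chromosomes × 20 Mb, tiled by TADs of mean size 1 Mb
  (gamma-distributed sizes, minimum a quarter of the mean). Anchor sites sit
  at every internal TAD border plus one interior position per TAD, emulating
  CTCF/cohesin loop anchors.
* **Breaks**: 8 AsiSI recognition sites, 4 of which are cut. Sites are
  placed 2–9 kb from a randomly chosen anchor — AsiSI sites in real genomes
  frequently fall near pre-existing CTCF/cohesin sites, and this guarantees
  the ≤10 kb distance shell is populated — under a 2 Mb minimum pairwise
  spacing. Damage (gamma-H2AX) truth domains extend ±1 Mb around each cut,
  consistent with the observed megabase scale of cohesin accumulation around
  breaks. Four cuts over 40 Mb put ~20% of the genome inside damaged
  domains. This is sparser than the spacing constraint allows but still
  denser than real data (~80 breaks × 2 Mb over 3.1 Gb ≈ 5%); because the
  O/E expected curve is estimated from the same matrix that carries the
  injected effects, a dense damage fraction absorbs part of an injected
  inter-domain gain into the expected value, and at ~20% coverage an
  injected 1.16 reads as ≈ 1.14. That residual compression is a property of
  O/E at desk scale, not of the estimator's implementation.
* **ChIP tracks** (100 bp bins, rpkm-like): triangular 1 kb anchor peaks of
  height 50 with lognormal per-anchor jitter; background 1.0 modulated by a
  shared lognormal regional field (100 kb segments, log-sd 0.5) so that
  treated/untreated comparisons face realistic regional variability; Poisson
  counting noise at a configurable depth (2 counts per rpkm per bin by
  default). Under damage, anchor heights inside damaged domains are
  multiplied by the genotype's enrichment factor: 1.43 (WT), 1.17
  (SMC1A phosphorylation-deficient), 1.73 (LIG4-null, where blocked repair
  saturates recruitment), 1.0 (cohesin degron, whose residual peaks are also
  scaled to 5%). For ATM inhibition the measured enrichment is a distance
  gradient (1.30/1.11/1.02 by shell); the generator applies one uniform
  factor per domain, so its ATMi default is the average, 1.14. MRE11 peaks
  appear only at cut sites under damage; gamma-H2AX forms a plateau over
  damaged domains. The triangular 1 kb peak shape is a modelling choice —
  the true decay shape of cohesin signal away from anchors is not
  characterized.
* **Hi-C** (10 kb intra, 250 kb trans): expected intra counts follow
  `(d + 1)^-1`, doubled within TADs (the TAD boost drops to 1 in the damaged
  cohesin-degron condition, emulating depletion concurrent with break
  induction), multiplied by 1.02 for bin pairs inside the same damaged
  domain under damage, and by the genotype's clustering factor gamma for
  pairs spanning two distinct damaged domains (1.16 under cohesin depletion,
  1.04/1.03 for SMC1A_Pdef/ATMi, 1.0 for WT). Counts are Poisson around the
  expectation scaled to a per-chromosome depth (10^6 by default; the
  intra-domain 1.02 recovery uses 10^7 because a 2% effect needs ~10 times
  the counts). Trans matrices are a uniform baseline modulated by smooth
  per-bin coverage biases (lognormal, log-sd 0.5) — without them every
  bait-prey window would have the same expected score and contact-weighted
  prey sampling would be untestable — times a damaged-pair factor.
  Poisson noise is the simplest model consistent with count data; no
  overdispersion is simulated.
* **Junctions**: per library, a fraction of reads are bait-proximal
  (uniform within ±19 kb), a per-genotype translocation rate lands on other
  cut sites with probability proportional to the bait-prey contact-window
  score (so translocation frequency tracks contact frequency by
  construction), and the remainder disperses uniformly. Default
  translocation rates (WT 0.15; cohesin degron 0.645; SMC1A_Pdef 0.315;
  ATMi 0.285; LIG4-null 0.015) mirror the measured condition fold changes
  (4.3×, 2.1×, 1.9×, and near-zero NHEJ-dependent translocations in
  LIG4-null cells). Prey positions scatter around cut midpoints with 800 bp
  Gaussian sd. Microhomology lengths are geometric (p = 2/3, mean 0.5 nt,
  matching the low usage typical of NHEJ junctions), capped at 15 nt, and
  20 nt flanks are constructed by rejection so each junction embeds *exactly*
  its drawn overlap.

### What the generator does and does not emulate

It reproduces the statistical structure the analyses consume: TAD-blocked
distance decay, damage-localized enrichment on a heterogeneous background,
contact-tracking translocation frequencies, geometric microhomology. It does
not simulate reads, mappability, GC bias, replication timing, loop anchors
with orientation, overdispersed counts, or sister-chromatid effects. Passing
recovery tests therefore demonstrates that the estimators are unbiased and
correctly scaled under the stated noise model — not that they are robust to
every artefact of real sequencing data.

## Numerical and design choices

* Counts are floats throughout; normalized matrices are fractional.
* `N` bases never match in motif scanning or microhomology comparison.
* Intra-chromosomal triplet input is symmetrized on read; writing emits the
  upper triangle, sorted, zeros omitted — so write∘read is the identity on
  canonical forms.
* Bins fully contained in a domain contribute to its scores; partial edge
  bins are excluded.
* Strand is stored but ignored by all distance computations; junction
  deduplication is by exact (prey chromosome, position, strand) — a stand-in
  for molecule-level deduplication, which requires upstream barcodes.
* The "break site" context window for junctions is ±2.5 kb (configurable):
  wide enough to capture resection-scale scatter around a cut, narrow
  relative to domains.
* Each simulated condition draws from a seed derived from the base seed and
  the (module, genotype, damage) labels, so conditions are independent but
  jointly reproducible, and structural nuisance fields (regional background,
  trans coverage biases, anchor jitter) are drawn once in `build_layout()`
  and shared across conditions.
* AsiSI placement restarts from scratch when rejection sampling stalls, and
  refuses genuinely infeasible spacing configurations with guidance.

## Problem sizes used by the test suite

Unit and recovery tests run the generator at its default 2 × 20 Mb genome;
the intra-domain 1.02 recovery uses depth 10^7, the inter-domain 1.16
recovery depth 10^6 averaged over 5 seeds, and the anchor-enrichment 1.43
recovery 5 seeds at the default ChIP depth. Null calibration uses 20
replicates of a single 10 Mb chromosome at ChIP depth 10 and Hi-C depth
2 × 10^6, sizes at which estimator noise is well below the ±5% calibration
band. The junction-correlation property uses a 4-chromosome genome with 21
cut sites so that 20 prey sites are available.

## Known limitations

* O/E compression at desk-scale damage density (above) biases inter-domain
  fold-change estimates a few percent toward 1; analyses of real genomes,
  where damaged domains are rare, are essentially unaffected.
* The Welch substitution for unequal-n contrasts is a deliberate departure
  from a paired convention that cannot apply there.
* The cohesin-degron intra-TAD fold change depends on both the TAD-boost
  drop and the O/E renormalization it induces, so its numerical value is a
  qualitative (direction and rough scale) emulation rather than an injected
  target.
* `run_pipeline()` drives the simulate → call → enrich → Hi-C → junction
  chain from a config file for reproducible end-to-end runs; analyses of
  externally supplied files use the reader functions plus the same analysis
  functions directly.
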