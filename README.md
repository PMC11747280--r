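# breakscape

Quantitative analysis of chromatin architecture around DNA double-strand
breaks (DSBs), for researchers studying how cohesin and genome topology shape
break repair. The package covers the three assay families such studies
integrate — ChIP-seq enrichment around induced breaks, Hi-C domain
interaction statistics, and HTGTS (high-throughput genome-wide translocation
sequencing) junction analytics — plus a seeded synthetic-data generator so
that every estimator can be validated against known injected effect sizes
without any sequencing data.

## The statistics at its core

**ChIP enrichment.** For a peak with mean per-bp coverage *t* (damaged) and
*u* (undamaged), the fold change is

    FC = (t + 0.1) / (u + 0.1)

Peaks are stratified by distance *d* to the nearest break midpoint into
disjoint shells (d ≤ 10 kb, 10 kb < d ≤ 250 kb, 250 kb < d ≤ 1 Mb, control
chromatin beyond 1 Mb), or by whether a cohesin anchor (a RAD21 peak whose
summit lies within 500 bp of a CTCF summit) falls inside a called gamma-H2AX
domain. Category means are compared with one-tailed Welch t-tests; matched
per-domain fold changes are tested against 1 with one-tailed paired t-tests.

**Hi-C domain statistics.** Intra-chromosomal matrices are O/E-normalized:
entry (i, j) is divided by the mean contact at separation |i − j|, removing
distance decay. An intra-domain score is the mean O/E over bin pairs inside
a domain (diagonal excluded); an inter-domain pair score is the mean O/E over
the cross rectangle of two domains; per-domain fold changes are
treated/untreated ratios of these scores. 4C-like viewpoint tracks report
`log2((t + 1)/(u + 1))` of an anchor bin's contacts within ±2 Mb, and
translocation windows sum the 5×5-bin block (1.25 Mb × 1.25 Mb at 250 kb
resolution) around a bait-prey bin pair, compared across conditions as
`log2((S_t + 0.1)/(S_u + 0.1))`.

**Junction analytics.** Junctions within ±20 kb of the bait are removed as
bait-site artefacts; the rest are cis-deletions (prey on the bait
chromosome) or translocations, assigned a damage context (break site within
±2.5 kb of a cut > gamma-H2AX domain > outside), deduplicated by prey
coordinate and strand, binned at 1 kb, and compared across conditions as
library-size-normalized fold changes. Microhomology at a junction is the
longest bait-flank suffix equal to a prey-flank prefix (N never matches).

## Worked example

Simulate a wild-type experiment, call breaks from the MRE11 track, and
measure cohesin enrichment around them:

```r
library(breakscape)

cfg <- sim_config(seed = 7)           # 2 x 20 Mb genome, 4 of 8 AsiSI sites cut
sim <- build_layout(cfg)
untreated <- simulate_chip(sim, "WT", "NT")
damaged   <- simulate_chip(sim, "WT", "DSB")

dsbs <- call_dsb_sites(damaged$tracks$MRE11, sim$dsbs)
enr  <- category_fold_change(damaged$peaks$RAD21, dsbs,
                             damaged$tracks$RAD21, untreated$tracks$RAD21)
enr$summary

domains <- call_damage_domains(damaged$tracks$GH2AX, untreated$tracks$GH2AX,
                               dsbs = dsbs)
anchors <- call_anchor_sites(damaged$peaks$RAD21, damaged$peaks$CTCF)
ade <- anchor_domain_enrichment(anchors, domains,
                                damaged$tracks$RAD21, untreated$tracks$RAD21)
ade$test
```

Output:

```
  category  n mean_fc p_vs_ctrl stars
1     D10K  4   1.415  3.49e-05   ***
2    D250K  1   0.962        NA      
3      D1M 14   1.421  6.06e-08   ***
4     CTRL 69   0.991        NA      

welch t-test (one-tailed): t = 22.1627, df = 20.463, p = 4.411e-16 ***
```

All four injected cuts are recovered from the MRE11 track; anchors near
breaks show the injected ~1.43-fold cohesin gain (here 1.415 at ≤10 kb and
1.447 inside called gamma-H2AX domains, against 0.99 in control chromatin),
and the inside-vs-outside contrast is highly significant. The same object
feeds the Hi-C (`simulate_contacts()`, `intra_domain_fc()`,
`inter_domain_pair_fc()`) and junction (`simulate_junctions()`,
`annotate_junctions()`) layers; `run_pipeline()` chains everything from a
config file (see `inst/extdata/demo_config.ini`) into a deterministic output
directory with tables, a run log and a plain-text summary.

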