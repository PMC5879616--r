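---
title: "Classifying transcriptional stress-memory genes from repeated-stress expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transcriptional stress-memory genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressmem)
```

## The problem

Plants that have experienced a dehydration stress respond differently when
the stress recurs: some genes that were induced in the first stress are
induced more strongly (or now repressed) in the second, even though the
physiological starting point (leaf relative water content) is the same.
Such genes carry a *transcriptional stress memory*. The standard design for
detecting them samples four states — control (C1), first dehydration (D1),
recovery (R1), second dehydration (D2) — with two biological replicates
each, quantified as FPKM.

A gene's behaviour is summarised by two direction calls: `a` for the
D1-vs-C1 contrast and `b` for the D2-vs-D1 contrast, each one of `+`
(up), `-` (down) or `=` (no significant change), written `[a/b]`. The
nine types partition into four categories:

* **memory**: `[+/+]`, `[+/-]`, `[-/+]`, `[-/-]` — the response changes
  between stresses;
* **non-memory**: `[+/=]`, `[-/=]` — the first response is repeated;
* **late-response**: `[=/+]`, `[=/-]` — response only to the second
  stress;
* **non-response**: `[=/=]`.

## The DEG rule

A gene is called `+` or `-` in a contrast when all three of the following
hold (thresholds inclusive):

1. BH-adjusted $q \le 0.05$;
2. $|\log_2 \mathrm{FC}| \ge 1$, with
   $\log_2 \mathrm{FC} = \log_2\frac{\bar x_B + c}{\bar x_A + c}$ on
   replicate-mean FPKM and pseudocount $c = 1$;
3. the *expression floor*: the gene's mean FPKM in the stressed condition
   (for `+`) or in the baseline condition of the contrast (for `-`) is at
   least 20% of the mean FPKM over all expressed genes in that condition.

"Expressed" means a replicate-mean FPKM above zero in at least one
condition of the whole design; this fixed universe defines the floor in
every condition. For the D2-vs-D1 contrast the "control" side of the floor
rule is D1, the baseline of that contrast. Replicates are aggregated by
arithmetic mean; fold changes use a configurable pseudocount because FPKM
tables contain exact zeros.

## Choice of test

The original experiments used a count-model DE engine whose output can be
ingested directly (`method = "precomputed"`; q-values are recomputed by
Benjamini–Hochberg when absent). For self-contained analyses the package
must supply its own p-values, and the replication level dictates the
choice:

* `method = "limma"` (default): a moderated t-test on per-replicate
  $\log_2(\mathrm{FPKM}+1)$ values. With two replicates per condition a
  per-gene test has essentially no power — a per-gene exact permutation
  test over the $\binom{4}{2} = 6$ label splits cannot produce a two-sided
  p below $1/3$, and a Welch t-test has roughly 1.5 degrees of freedom —
  so borrowing variance information across genes is the only defensible
  route at this design size.
* `method = "welch"`: a per-gene Welch t-test, appropriate when replicates
  are plentiful.
* `method = "permutation"`: a two-sided permutation test on the difference
  of group means, exact (full enumeration) up to 10 replicates total and
  Monte-Carlo with a fixed seed beyond that. It is provided both as an
  assumption-free option for larger designs and as a reference whose exact
  small-$n$ behaviour is verified against brute-force enumeration in the
  test suite.

Degenerate inputs are handled deterministically: when every gene has zero
within-group variance (noiseless data), p is 0 for a non-zero mean
difference and 1 otherwise.

## Summaries, overlaps, enrichment

`summarize_memory()` reports raw counts per type and category plus the
percentage conventions of published stress-memory tables: integer percent
of each memory type among memory genes, one decimal for category ratios,
two decimals where overlap shares are quoted. Rounding is half away from
zero. Every percentage is paired with an explicit denominator — published
summary tables in this area occasionally quote totals that disagree with
their own rows, so the package never reports a ratio whose denominator it
does not also report. Overlap accounting (`venn_sets()`, `venn_counts()`)
is plain inclusion–exclusion; `enrich_terms()` is a one-sided upper-tail
hypergeometric test per annotation term with BH adjustment, taking flat
GMT-style gene sets (no ontology-graph propagation).

## Cross-species conservation

Given an ortholog map and memory assignments for two species,
`classify_pairs()` keeps each pair whose first-species gene is a memory
gene and categorises it by the second-species side:
`conserved-same-type`, `memory-different-type`, or the B-side's category.
Orthologs missing from the second species' assignment table are counted
as non-responding. Classification is per *pair* (many-to-many maps are
allowed, so ortholog counts may exceed gene counts); a per-gene rollup
("conserved if any ortholog shares the type") is reported alongside.

## qPCR and physiology

`relative_expression_ddct()` implements classic $2^{-\Delta\Delta C_T}$
quantification with amplification efficiency fixed at 2 and no
standard-curve correction. Technical replicates are averaged first;
biological replicates are aggregated on the log2 scale (mean of
$-\Delta\Delta C_T$, then exponentiated) with spread reported as the SD of
$\log_2 \mathrm{RQ}$, since RQ is log-normal by construction. Two exact
identities make good unit tests and are enforced in the suite: the
calibrator's mean RQ is exactly 1, and adding $c$ cycles to one sample
divides its RQ by $2^c$.

Memory persistence is assessed by `persistence_compare()`: a Welch t-test
on log2 RQ between trained plants (re-stressed after a replanting
interval) and untrained plants in their first stress. A multi-group
multiple-range procedure would be the fuller analysis; the two-group Welch
test is the minimal defensible comparison for a per-interval verdict, and
is what the package commits to. Fewer than two biological replicates on
either side yields `insufficient-replication` rather than a verdict.

Physiological indices are `rwc()` — relative water content,
$(\mathrm{fresh}-\mathrm{dry})/(\mathrm{turgid}-\mathrm{dry})\times100\%$,
scale-invariant, values outside $[0,100]$ flagged rather than clipped —
and `water_loss_curve()`, the fraction of initial fresh weight lost over
time after leaf detachment.

## The synthetic-data generator

`generate_expression()` is first-class, tested code, not a fixture: it
plants a known memory class per gene so that every downstream stage has
ground truth. Defaults mirror the study design: four conditions, two
biological replicates, and per-contrast planted log2 effects of 3 — well
beyond the $|\log_2\mathrm{FC}| \ge 1$ threshold, so recovery measures the
pipeline rather than boundary behaviour (boundary fixtures at exactly 1.0
are built separately in the tests). Where the design leaves values open we
fixed, once: baseline $\log_2$ FPKM $\sim N(5, 1.5^2)$ (moderately
expressed genes, a realistic bulk RNA-seq spread) and replicate noise SD
0.25 on the log2 scale, consistent with the high replicate concordance
reported for this kind of data.

Two structural guarantees are enforced at generation time. First, the
planted condition means of every differential gene are lifted until the
floor-rule side clears the 20% expression floor with 0.75 log2 units of
headroom, so the planted class is consistent with the DEG criteria at zero
noise by construction (the enforcement loop converges because the floor is
one fifth of the mean). Second, generation is a pure function of the
config — the same seed yields byte-identical artifacts.

The noise model is log-normal FPKM. It does **not** simulate counts,
library-size effects, gene-length bias, or over-dispersion, so passing
recovery tests demonstrate the correctness of the classification logic,
not robustness to every artifact of real RNA-seq. Count-level realism is
deliberately out of scope since the pipeline consumes FPKM.

`generate_ortholog_map()` plants a Bernoulli conservation rate per pair,
and `generate_ct_table()` plants a persistence decay schedule (retained
fraction of the memory effect per replanting interval) in Ct space.

## Problem sizes and numerical choices

The test suite and the acceptance script run the recovery analysis at 9
classes × 200 genes with 2 replicates (the study's replication) over
20 and 5 seeds respectively — sizes at which the limma-based pipeline
recovers 100% of planted classes at noise SD 0.25, and which keep the full
suite under a minute. Permutation enumeration comparisons use 2+2
replicates; hypergeometric brute-force comparisons use universes of at
most 12 genes, where complete subset enumeration is feasible. Ties in the
permutation statistic are counted as at least as extreme, with a $10^{-12}$
tolerance against floating-point noise. Monte-Carlo permutation p-values
use the $(1 + \#\text{extreme})/(1 + B)$ estimator.

## Limitations

* FPKM quantification from reads, and the original count-model DE engine,
  are out of scope; its tables are accepted via `method = "precomputed"`.
* Annotation enrichment treats terms as flat sets; no GO DAG or pathway
  topology.
* The ortholog map is an input; no homology inference is performed.
* Hormone quantification and fluorometry parameters are not modelled;
  physiology support covers RWC and water-loss curves.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 42)
sim <- generate_expression(cfg)
c1 <- called_contrast(sim$expr, "C1", "D1")
c2 <- called_contrast(sim$expr, "D1", "D2")
assignments <- classify_memory(c1, c2)
summarize_memory(assignments)
class_recovery(sim)$recovery
```
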