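---
title: "Methods: associating differential methylation with differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: associating differential methylation with differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methexpr)
```

## The analysis in one paragraph

methexpr asks whether genes whose promoters or bodies gain or lose DNA
methylation in a disease group also change their expression. The design it
targets is small and paired: whole-genome bisulfite counts for two
case/control pairs (a male pair and a female pair) and a 2 + 2 RNA-seq
count matrix. Methylation differences are scored per cytosine, aggregated
into hyper- and hypo-methylated regions per pair, kept only where both
pairs agree in direction, mapped onto promoter windows and gene bodies,
and finally crossed with up/down expression classes.

## Per-site model

At a site with coverage $n$ and $k$ methylated calls the methylation
frequency is $\hat f = k/n$. Because $\hat f$ from a handful of reads is
noisy, each estimate carries a 95% confidence interval from the binomial
likelihood-ratio (Wilks) criterion,
$\{p : 2[\ell(\hat f) - \ell(p)] \le \chi^2_{1,0.95}\}$, solved by
bisection on each side of the MLE to $10^{-8}$ (critical value 3.841459).
At $k = 0$ the lower bound is exactly 0, at $k = n$ the upper bound is
exactly 1.

Frequencies are then mapped through
$v = \ln\!\frac{1+f}{1-f}$,
a strictly increasing, odd transform with $v(0)=0$. Its standard deviation
is taken as one sixth of the transformed CI length,
$\mathrm{sd}(v) = [v(\mathrm{hi}) - v(\mathrm{lo})]/6$.
Since $v(1) = \infty$, frequencies and CI margins are clamped to
$[0,\, 1 - 1/(2n)]$ with the site's own coverage $n$ before transforming;
the coverage-scaled clamp keeps $v$ finite and monotone in $k$.

The control/case contrast at a site is a two-observation regression
$Y = b_0 + b_1 x$ with design $X = [[1,-1],[1,+1]]$ (control coded $-1$,
case $+1$). With two points the least-squares fit is exact:
$b_0 = (v_c + v_a)/2$, $b_1 = (v_a - v_c)/2$. Assuming independence,
$\mathrm{sd}(b_1) = \tfrac12\sqrt{\mathrm{sd}_c^2 + \mathrm{sd}_a^2}$ and
the significance of the slope is its z-score $z = b_1/\mathrm{sd}(b_1)$.
Positive slope = hyper-methylation in the case group. A unit test verifies
the closed form against the generic $(X^TX)^{-1}X^TY$ solution to
$10^{-10}$.

### Calibration of the CI/6 rule

The CI/6 rule deserves a caveat that shapes everything downstream. A 95%
interval is approximately $\pm 1.96\,\sigma$, so dividing its length by 6
estimates roughly $0.65\,\sigma$, not $\sigma$; $z$ is therefore inflated
by about $1.53$ and the per-site null rejection rate at $|z| \ge 1.96$ is
about 0.21 rather than 0.05 (the acceptance script computes it as
`site_null_rejection_rate`). We implement the rule as defined rather than
"fixing" it, because it is the method under study; users who want a
calibrated screen can simply raise the per-site threshold via `alpha`
(e.g. the observed operating point corresponds to an effective two-sided
threshold near $|z| \ge 3$). The same inflation propagates to region
calling: on a null genome the consensus step still leaves a nonzero rate
of false regions (measured by `null_consensus_dm_element_pct`), and on
strong-signal simulations sensitivity is essentially perfect while region
precision is limited by those false calls (`dmr_sensitivity`,
`dmr_precision`). The two-pair consistency requirement suppresses false
positives quadratically, but from a 21% base rate, not from 5%.

Small-sample discreteness also matters for the Wilks interval itself: its
exact coverage oscillates with $n$, e.g. below 0.93 at $(f=0.5, n=10)$ and
above 0.97 at $(f=0.1, n=10)$, converging to 0.95 only for larger $n$.
This is a property of likelihood-ratio intervals for discrete data, not of
the implementation; the acceptance suite reports the empirical coverage
per cell.

## Filtering and thresholds

* `min_coverage` (default 5): a site enters only if all four samples have
  at least this coverage. Low-coverage sites have exploding CI widths;
  5 is a floor that keeps $\mathrm{sd}(v)$ bounded. Sites with coverage 0
  are representable in the input and are excluded here, never propagated
  as NaN.
* `alpha` (default 0.05): per-site two-sided flagging level,
  $|z| \ge z_{1-\alpha/2}$, comparisons inclusive so boundary behaviour is
  deterministic.
* Methylation-call convention: the importer's `call_convention` switch
  maps column four of a cytosine report either directly to the methylated
  count (`"as_printed"`: C>T alignments on the plus strand, A>G on the
  minus strand) or to coverage minus that count (`"inverted"`, the usual
  bisulfite reading in which unconverted cytosines are methylated). The
  statistic is convention-agnostic; the choice is recorded on import.

## Region calling and pair reconciliation

Published segmentation methods for this design are not reproducible from
their description, so methexpr uses a deliberately transparent stand-in:
within one pair, chromosome and direction, maximal runs of flagged sites
whose consecutive members lie at most `max_gap` bp apart (default 500)
become regions; runs with fewer than `min_sites` sites (default 3) are
dropped; the region spans first to last contributing site and scores
$\sum z_i / \sqrt{m}$ (Stouffer). The stand-in is brute-force checkable
(the test suite re-derives it by explicit run enumeration) and monotone in
signal strength. Intervening opposite-direction sites do not break a run;
only distance does, so hyper and hypo tracks are segmented independently.

A region is *consensus* only if the male and the female pair both call it
in the same direction; the consensus interval is the overlap, its support
the smaller of the two parents'. Opposite-direction overlaps are dropped.
Gene-level status is then re-derived from consensus regions only, which is
the element-level re-check of pair consistency.

## Annotation

Coordinates are 0-based half-open internally; GFF3 is read as 1-based
inclusive and BED as-is, through a single conversion point, and all
interval outputs are BED dialect. The promoter is the window TSS
$\pm$ `flank` (default 1000 bp) around the strand-aware TSS (interval
start for `+` genes, end $-$ 1 for `-`), one position wide at
`flank = 0`. No promoter database is assumed: TSS windows are the
reproducible reading, and `flank` is configuration, not a guess. A
consensus region may hit several genes and both features of one gene; it
is tallied in both, a reporting convention that matches how promoter
categories are counted as regions while gene-body categories are counted
as genes with a *unique* (single-direction) body signal. Genes whose
bodies carry both directions are `mixed` and excluded from the unique-set
association.

## Expression classes

The built-in test is a stand-in, not a reimplementation of a published DE
pipeline: CPM normalisation, fold change
$(\bar x_{as} + 0.5)/(\bar x_{ctrl} + 0.5)$ on group CPM means (the
pseudocount gives group-exclusive genes a finite FC and drives the
`exclusive_as` / `exclusive_ctrl` flags), and a two-sided
negative-binomial score test with library-size offsets at a fixed
dispersion (default 0.1). Classes use strict inequalities: up if
$p < 0.005$ and FC $> 1.5$; down if $p < 0.005$ and FC $< 0.6$; no
multiple-testing correction is applied for classification, though BH
q-values are emitted. Because these thresholds only make sense on the
linear scale, imported logFC columns are exponentiated (base
configurable, default 2). The import path exists precisely so that output
of a full-featured DE tool can be consumed unchanged; with one sample per
group the built-in test refuses and points there.

## What the generator emulates — and what it does not

`sim_config()` defaults define the conditions under which the pipeline is
exercised: a 2 × 2 Mb genome with ~10 assayed cytosines per kb, Poisson
coverage with mean 30, per-site baseline frequencies from Beta(2, 2)
shared across samples, and 200 genes of 2–8 kb of which 12.5% + 12.5%
carry a planted hyper/hypo element (promoter or body, 50 elements in
total) shifted by 2 on the logit scale in both case samples — strong,
clean signals against which recovery is measured. Expression counts are
negative binomial (dispersion 0.1, means log-uniform on [100, 400],
geometric centre 200) with planted fold change 4. Null checks use
`effect_delta = 0`, and the element-rate null scales to 2000 genes on a
2 × 11 Mb genome. Acceptance runs use these configurations as stated;
the full default simulation finishes in seconds on one CPU.

Deliberately not modelled: read-level data and bisulfite conversion
chemistry, sequence context (CpG islands), correlated methylation of
neighbouring sites, cell-type heterogeneity (the main real-world source of
mixed gene-body signals), overdispersed (beta-binomial) methylation
counts, and SNP confounders. Passing recovery tests therefore demonstrates
the pipeline's logic and calibration under its own assumptions, not
performance on real tissue data, where between-pair disagreement and
within-element heterogeneity will be larger.

Determinism: one RNG stream per methylation track, seeded by (master
seed, track index), so adding samples never reshuffles existing tracks;
identical configuration gives bit-identical outputs, which the pipeline
level guarantees too (byte-identical report JSON on re-run).

## Degenerate inputs and tie-breaks

* $\mathrm{sd}(b_1) = 0$ with $b_1 = 0$: $z = 0$. With $b_1 \ne 0$: the
  site is degenerate-infinite, $z = \pm\infty$, treated as significant
  with the slope's sign.
* Threshold comparisons on $z$ are inclusive; DE threshold comparisons
  are strict. Both choices make boundary cases deterministic and are
  tested at the boundary.
* Zero DE genes or zero DM categories produce NA shares with an explicit
  warning, never a silent pass.

## Known limitations

The CI/6 miscalibration discussed above is the main one. Others: the
segmentation stand-in is not the published algorithm and makes no claim of
equivalence; promoter windows ignore transcript-level TSS heterogeneity;
the built-in DE test at $n = 2+2$ with fixed dispersion is a screen, not
an inference engine; and the identity summaries reproduce a mixed
unit convention (promoter categories in regions, body categories in
genes) because that is how such category totals are conventionally
combined — each count is labelled with its unit in the report.
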