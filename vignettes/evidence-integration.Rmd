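---
title: "Evidence integration for DUB function: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence integration for DUB function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dubnet)
```

## The analysis model

A query gene (here a deubiquitinating enzyme, DUB) is characterized by
four independent evidence streams computed on cell-line panels, each
producing a set of flagged partner genes:

* **Co-dependency** — pairwise-complete Pearson correlation of CRISPR
  dependency scores across cell lines. Genes whose knockouts track each
  other across a panel tend to act in one complex or pathway, so the top
  `top_k = 7` partners (by |r|) are carried forward. The query must be
  dependent (score < `dependency_threshold = -0.5`, strict) in at least
  `min_dependent_lines = 3` lines to be profiled at all: a gene with no
  dependent lines has no phenotype for the correlation to explain.
* **Perturbation similarity** — consumed tau scores in [−100, 100]; a hit
  is flagged when tau strictly exceeds `tau_threshold = 90`, the
  conventional cutoff for that scale. The package deliberately does not
  recompute compendium tau; `rank_similarity()` offers only an auxiliary
  Kendall-style concordance `(C − D) / (m(m−1)/2)` over the genes shared
  by two ranked lists.
* **Co-expression** — Pearson correlation of protein abundances over
  jointly detected lines, requiring `min_shared_lines = 100` shared
  detections before a pair may enter testing (shotgun proteomics
  missingness otherwise produces unstable correlations on small
  overlaps). Partners are significant at BH `q < 0.01` and |z| > 2.
* **Interaction databases** — union of tabular edge lists with per-edge
  provenance; a pair is flagged if any compiled source reports it.

The integrated **evidence count** of a (query, partner) pair is the number
of streams flagging it, 0–4, computed as a literal sum of the four
booleans and re-checked as an invariant on every table the package emits.
The DUB–E3 network then keeps pairs that are co-dependency-anchored *and*
whose partner carries ubiquitin-like transferase activity; the other three
flags annotate each edge. Anchoring on co-dependency (rather than any
flag) reflects that the network is meant to rank functional
DUB–ligase relationships, for which a fitness-profile correlation is the
primary signal and the other streams are corroboration.

Lineage-specific essentiality is assessed per (gene, lineage) as a Welch
two-sided t-test of the lineage's scores against all other lines.
`diff = mean_out − mean_in` is positive when the lineage is more sensitive.
Welch rather than pooled Student is used because the in-group (one tumor
type, often 5–30 lines) and out-group (hundreds of lines) have very
unequal sizes and no reason to share a variance. BH correction is applied
once across every pair tested in a scan — the whole scan is one family —
and a pair is flagged at raw `p < 0.05` and `q < 0.1`. Lines with lineage
`UNKNOWN` never form an in-group but stay in every out-group: the label
states ignorance, not a tumor type, yet those lines still carry
information about the panel-wide score distribution.

## Enrichment statistics

Over-representation uses the exact hypergeometric upper tail accumulated
in log space (`lchoose` plus log-sum-exp), which stays stable for
universes up to ~1e5 genes; the suite checks it against exhaustive draw
enumeration for every configuration with N ≤ 12. The BH step-up
adjustment is delegated to `stats::p.adjust(method = "BH")` and verified
against an independently coded textbook step-up on random vectors.

The enrichment **universe** is a real degree of freedom: published
analyses rarely state their background, and p-values are sensitive to it.
The default here is the gene set of the data source that produced the
query list (the dependency panel's columns for co-dependents), and
`run_pipeline()` echoes the choice and its size into the manifest so no
run leaves it implicit. Query genes outside the universe are dropped with
a warning, never silently.

## The z-score choice in co-expression

The significance rule "`q < 0.01` and |z| > 2" needs a definition of z.
The package standardizes **within query**: the vector of a query's
partner correlations is centered and scaled by its own sample mean and
sd. This matches how the pipeline is run (one query at a time) and makes
the flag a statement about a partner being an outlier of *that query's*
correlation distribution. Standardizing within-partner or globally are
defensible alternatives; the computation is isolated so a
Fisher-transform variant could be swapped in without touching callers.
Similarly, the per-query BH family mirrors the one-DUB-at-a-time workflow.

## What the generator emulates

`simulate_panel()` draws the five inputs from one planted structure:

* dependency scores `base_mean + λ_g f_{m(g),c} + shift·1[planted] + ε`
  with a standard-normal latent factor per complex per line, loading
  `factor_sd = 0.6` for members, noise `noise_sd = 0.3`, baseline −0.2.
  With these defaults within-complex co-dependency is r ≈ 0.8 —
  deliberately strong, comparable to well-documented complex partners in
  real panels rather than marginal ones;
* abundance from the same factor model with independent factors and
  missing-completely-at-random masking at 30%;
* interaction edges with probability 0.8 within complexes and 0.002
  elsewhere, split across two synthetic source labels to exercise
  provenance merging;
* tau of `tau_within = 95` plus unit jitter for same-complex (query, hit)
  pairs, background `N(0, 30)` truncated to [−100, 100];
* one gene set per complex plus a transferase set holding each complex's
  designated E3-role gene (its last member) and ten background genes.

Default sizes are 120 genes × 300 lines × 6 lineages with complexes of
5/5/4/4/3 — large enough that the 100-shared-line co-expression rule is
genuinely binding (expected joint detection ≈ 0.7² × 300 ≈ 147, so most
pairs pass but chance can exclude some) yet small enough that the full
pipeline, including file round-trips, runs in seconds. One lineage shift
of −0.5 is planted on the first background gene so the contrast machinery
always has signal to find without contaminating complex structure.
Lineages are assigned as a randomly permuted balanced allocation
(≈ 50 lines each), which keeps every lineage far above the minimum
in-group size while remaining exchangeable.

Known gaps between the generator and real data: proteomics missingness is
abundance-dependent in practice, not MCAR; real dependency scores have
gene-specific means and copy-number artifacts; tau is generated directly
rather than derived from expression signatures; and symbols are clean, so
the alias-reconciliation problems of real interaction databases never
arise (unmatched symbols are surfaced in logs rather than remapped).
Passing recovery tests therefore demonstrates the pipeline's statistical
plumbing, not robustness to those real-data pathologies.

## Numerical and degenerate-input choices

* All threshold comparisons that the scale conventions make one-sided
  (`score < −0.5`, `tau > 90`) are strict.
* Partners constant over the shared support have undefined correlation
  and are omitted with a log message — reporting r = 0 would silently
  convert "no information" into "no association". A constant query is an
  error.
* Co-dependency ranking ties break lexicographically by symbol, making
  top-k lists deterministic.
* Evidence tables enumerate only pairs flagged somewhere (the published
  tables likewise report flagged pairs); exhaustive zero-count
  enumeration is an explicit opt-in, used by the recovery report where
  background means need true zeros.
* A partner absent from the tau table is `not_tested`, recorded
  distinctly from `not_similar`; any perturbation type qualifies a tau
  row.
* Writers emit full-precision (`%.17g`) numbers so write→read round-trips
  are bit-exact; output TSVs are deterministic and the manifest carries
  md5 sums, making whole-pipeline reruns byte-identical.

## Problem sizes used in validation

The suite validates the hypergeometric tail by exhaustive enumeration up
to N = 12, BH on 1000 random vectors, null calibration of the lineage
scan on 2400 gene×lineage tests (400 null genes × 6 lineages, where the
fraction of raw p < 0.05 must fall within 0.05 ± 0.015), and planted
recovery on the generator defaults. These sizes were chosen as the
smallest at which each property is statistically meaningful.

## Limitations

The package consumes precomputed tau tables and does not attempt CMap's
compendium-percentile computation; gene identity is raw symbol matching;
the GO term reported per gene is the single top term by q (no redundancy
trimming or DAG traversal); and ranked-list enrichment (GSEA-style) is
out of scope — the over-representation test is the supported enrichment
path.
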