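---
title: "Methods: promoter motif enrichment for early adipogenesis regulators"
author: "adipomotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter motif enrichment for early adipogenesis regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of the
pipeline, the parameters that matter and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where the method description left the design open.

## Study design and expression clustering

The expression input is a normalized log2-scale matrix over nine
conditions in three biological replicates: day 3 untreated, and days 6
and 11 each under control, the RARβ agonist CD2314, the GSK3 inhibitor
BIO, and CD2314+BIO. Day 3 has no treatment arms and is carried but
never tested.

Genes specific to the pro-adipogenic stimulus are found by testing
CD2314 against *each* other arm at the same time point and intersecting:
a gene is CD2314-specific at a time point only when it is
FDR-significant against all three comparators there, with one direction.
The five clusters are day-6 up (1), day-6 down (2), day-11 up (3),
day-11 down (4), and both-days same-direction (5). Two open points were
resolved as follows:

* **Cluster 5 direction.** The default admits up-up and down-down genes
  (`cluster5 = "same_direction"` in `assign_clusters()`); a stricter
  `"up_only"` variant is available because the cluster is sometimes
  described as up-regulated at both days. Genes significant at both days
  with *discordant* directions get no label: one gene receives exactly
  one label, and neither a day-6-only nor a day-11-only description fits
  them.
* **FDR family.** BH control at q = 0.05 is applied per
  (time point × comparator) family across genes — six independent
  families — reading "the significance threshold in each of the tests"
  as per-test control.

**Test flavor.** `run_contrasts()` defaults to a moderated two-sample t:
per-gene pooled variances are shrunk toward a common prior estimated
across genes (`limma::squeezeVar`), and the statistic gains the prior
degrees of freedom. With three replicates per arm, a plain Welch test
carries only ~2–4 estimated df, so its p-values are bounded away from
zero regardless of effect size: at a BH cutoff near 0.005 (what a
universe with ~12% non-null genes yields at q = 0.05), roughly a fifth
of genes with a 2.0 log2-unit effect at noise sd 0.25 fail *some*
contrast, and the three-way intersection compounds the loss. Variance
moderation is the standard remedy in microarray practice and restores
near-complete recovery under the same design; the plain Welch test
remains available (`method = "welch"`) and is the flavor specified for
the exported `welch_t_test()` operation. Its degenerate-variance
conventions are explicit rather than silent: zero variance with equal
means gives p = 1; zero variance with unequal means is treated as
maximally significant with that direction and flagged `degenerate`.

## Promoter universe

Promoters are strand-aware windows from 2,000 bp upstream to 1,000 bp
downstream of each TSS. Coordinates are 0-based half-open (BED
convention) throughout, and the TSS base is the first downstream base;
minus-strand sequences are reverse-complemented, and conservation
vectors are reversed to promoter orientation. Windows are clipped at
chromosome edges; bases without a conservation record get 0 (never
conserved — the conservative choice for masking).

When two promoters overlap by **more than** 1,500 bp (strict
inequality; an exactly-1,500 bp overlap is allowed), all but one are
randomly discarded. The procedure repeatedly takes the first violating
pair in (chrom, start) order and removes one member uniformly at random
under the given seed; a final deterministic restoration pass re-adds
any removed promoter that no longer conflicts. The restoration pass
matters in chains: in an A–B–C chain where only adjacent pairs
conflict, naive pair removal can end at {C} even though A conflicts
with nothing anymore; with restoration the result is always a *maximal*
retention set ({A, C} or {B}), which is what the brute-force oracle in
the tests enumerates. Overlap is computed on genomic intervals
irrespective of strand, and deduplication is applied once to the whole
universe before any cluster/background partitioning.

## Motif scanning

JASPAR (4-row PFM) and TRANSFAC (`P0`-header column table) dialects are
parsed with counts preserved exactly; TRANSFAC frequency-style matrices
(rows summing to ~1) are scaled to a nominal count of 100. Log-odds are
in bits with a default pseudocount of 0.25 per cell against a uniform
background:

    s(b, j) = log2( (n_bj + π) / (N_j + 4π) / q_b )

Both strands are scanned at every offset and the maximum is taken —
binding sites are orientation-agnostic. Under a conservation threshold
τ ∈ {0.7, 0.8, 0.9, 1.0} a window is eligible only when **every** base
meets τ (whole-region conservation, the strictest reading; the mean
variant is not implemented). The promoter score is the best eligible
hit, or, with no conservation required, the arithmetic mean of the
three highest hits (overlapping windows allowed; fewer than three
windows average what exists). Reported hit positions tie-break to the
smallest offset, then the plus strand; the score is unaffected.

Scores are min–max normalized per matrix — raw minus the smallest
attainable log-odds sum over the attainable range — so that one score
threshold sweep is comparable across motifs of different widths and
information content. The enrichment statistic below depends only on
score *ranks* within the universe (verified by a monotone-transform
invariance test), so the absolute scale of the scanner is
inconsequential; no p-value calibration of individual hits is
attempted. Ambiguous bases (N) poison any window covering them with
−∞, so they can never be a best hit.

## Threshold-optimized hypergeometric enrichment

For a cluster of n promoters in a universe of N, each candidate
threshold t (every distinct observed score — an exhaustive sweep, which
"score ≥ t" inclusivity guarantees) yields k cluster and K universe
promoters at or above t. Significance is the hypergeometric upper tail
P(X ≥ k) for X ~ Hypergeom(N, K, n) (evaluated by `stats::phyper`,
log-space internally), Bonferroni-multiplied by the number of PWMs
tested × the number of conservation modes (5). The threshold sweep
itself is *not* separately corrected: the threshold is optimized
subject to the corrected p, which names a single correction. The
reported fold is (k/n) / ((K−k)/(N−n)) — cluster proportion versus all
*other* promoters; when K = k the fold is infinite and still eligible
if p passes. Among p-passing candidates the fold-maximizing threshold
wins, ties to the larger threshold; a best fold below 1.8 reports
nothing. Per motif, each conservation mode is optimized independently
and the mode with the lowest raw p (ties → higher fold) is reported.
Promoters ineligible under a mode still count in n and N but never
score over any threshold. The background is the universe minus the
tested cluster; members of other clusters are not excluded.

The exposed parameters and defaults: `alpha = 0.01` on the corrected p,
`min_fold = 1.8`, `correction_factor = n_pwms * n_modes` (overridable,
since the exact denominator convention is a judgment call), pseudocount
0.25.

## Interaction modules

Human interaction edges are mapped to mouse only when both endpoints
have exactly one mouse ortholog; edges are undirected, deduplicated
after mapping, and homodimer loops are preserved. A cluster's module
set is the subgraph induced at distance 0 — only edges with both
endpoints in the gene list — with connected components computed by
igraph. Isolated list members are excluded from the reported network by
default (only interacting modules are of interest) but can be kept.

## What the simulators emulate — and what they do not

`simulate_expression` draws per-gene baselines N(8, 1.5²) and i.i.d.
Gaussian replicate noise on the log2 scale (default sd 0.25), matching
the assumption of a normalized log-scale input and keeping the tests
well-specified. Planted genes shift the CD2314 arm only, at their
designated day(s), by ±2.0 log2 units by default. An optional
`shared_with` column also shifts one comparator arm, producing genes
that differ from only two of three comparators — these must never be
assigned through the intersection rule (they can only enter via a rare
false positive in the shared-arm contrast, at the per-family FDR
level). No probe-level structure, array normalization artifacts, or
gene-gene correlation is emulated; effect sizes and noise are
calibration choices, not measured values.

`simulate_genome` lays one promoter slot per gene (default 400 bp
upstream + 100 bp downstream — a deliberately scaled-down window that
keeps whole-universe scans fast while exercising every code path; the
extraction defaults remain 2,000/1,000), i.i.d. uniform background
sequence, 50/50 strands, and plants at most one motif instance per
promoter, sampled from the PWM's column distributions (not the
consensus), at foreground/background rates 0.4/0.05 by default.
Conservation is **block-structured**: 50-bp blocks are conserved with
probability 0.35, with per-base values Beta(24, 1) in conserved blocks
and Beta(1, 6) elsewhere, and planted-site bases at 0.95. The block
structure mirrors the patchy layout of phastCons-style tracks and is
essential for a fair benchmark: were only planted sites conserved, the
eligibility mask alone would reveal where sites were planted and any
matrix — including a column-shuffled decoy — would appear "enriched".
Real genomes add repeats, composition bias, CpG islands and correlated
motif occurrences that this generator does not attempt; passing
recovery tests here demonstrates correctness of the machinery, not
performance on real mouse promoters.

`simulate_ppi` samples distinct unordered protein pairs (loops allowed
once each) and assigns each human protein one mouse ortholog, or — with
the configured ambiguity probability, split evenly — none or two. The
truth table marks which edges survive the one-to-one rule, making the
filter exactly checkable. No degree structure or literature bias is
emulated.

All three simulators restore the caller's RNG state and are
byte-reproducible under a fixed seed; the pipeline fans one global seed
out to per-stage sub-seeds through a stable arithmetic derivation
(`derive_seed`), so stages are individually reproducible.

## Numerical choices

* Per-base conservation decoded from coverage vectors is rounded to six
  decimals: run-length accumulation can introduce one-ulp drift, which
  would otherwise destabilize `≥ τ` comparisons at exact track values
  such as 0.7.
* Hypergeometric tails use `phyper(k − 1, K, N − K, n, lower.tail =
  FALSE)`; the test suite checks the full lattice of valid (k, K, n)
  for N ≤ 12 against literal enumeration of all C(N, n) draws.
* Scanner scores are exact sums of matrix entries; the suite compares
  them to a naive per-window enumeration at tolerance 1e−12 over
  hundreds of random (promoter, PWM) pairs.
* Degenerate inputs fail loudly: empty score sets, groups smaller than
  two replicates, motifs wider than promoters, inconsistent
  hypergeometric counts, rates outside [0, 1].

## Problem sizes

The standard demonstration scale — 5,000 genes (200 planted per
cluster), 200 foreground + 2,000 background promoters of 500 bp, 20
PWMs (one planted, 19 column-shuffled decoys), five conservation modes,
1,000 proteins with 2,000 edges — was chosen so that a full pipeline
run, including scanning the whole universe against every matrix under
every mode, completes in well under a minute per stage on one CPU,
while keeping counts large enough for stable fold and FDR estimates.
Recovery and specificity are assessed over 10–20 seeded replicates in
the tests and the acceptance script.

## Known limitations

* The enrichment stage reports motifs, not factors: mapping motifs to
  TF families requires a user-supplied lookup table.
* The threshold sweep's selection effect is uncorrected beyond the
  single Bonferroni factor, by design; null calibration is therefore
  checked empirically (column-shuffled decoys across seeds) rather than
  guaranteed analytically.
* One TSS record means one promoter; alternative promoters per gene,
  repeat masking, and genome downloads are out of scope.
* GO/pathway annotation and visualization of interaction modules are
  not implemented; the generic enrichment engine and the network
  extraction are.
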