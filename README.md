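# adipomotif

Discovery of candidate transcriptional regulators of **early adipocyte
development** from a multi-condition expression time course, by promoter
motif enrichment and interaction-network analysis — with seeded simulators
that generate every input with known ground truth, so the whole analysis is
testable end-to-end without any external download.

## The scientific problem

Embryoid bodies derived from mouse embryonic stem cells commit to the
adipocyte lineage when treated with the RARβ-selective agonist **CD2314**
(days 3–6), and this commitment is blocked by the GSK3 inhibitor **BIO**.
Profiling expression at day 3 (untreated) and at days 6 and 11 under
control, CD2314, BIO and CD2314+BIO (nine conditions, three biological
replicates each) isolates genes specific to the pro-adipogenic stimulus.
The analysis then asks which transcription factors might drive those
programs, by testing whether their binding motifs are over-represented in
the promoters of co-regulated genes, and which of the encoded proteins
physically interact.

The package implements the full computational chain:

1. **Expression clustering.** For each time point *t* ∈ {d6, d11} and each
   comparator arm *c* ∈ {control, BIO, CD2314+BIO}, every gene is tested
   CD2314 vs *c* (moderated t by default — per-gene variances shrunk by
   empirical Bayes across genes, the standard choice for 3-replicate
   designs; plain Welch optional), with Benjamini–Hochberg control at
   q = 0.05 within each contrast family. A gene is *CD2314-specific at t*
   iff it wins **all three** comparisons with one direction. Day-6-only
   up/down → clusters 1/2, day-11-only up/down → clusters 3/4, both days
   (same direction) → cluster 5.

2. **Promoter universe.** Strand-aware windows of 2,000 bp upstream to
   1,000 bp downstream of each TSS, with aligned per-base conservation;
   when two promoters overlap by more than 1,500 bp, all but one
   (seeded-random) are discarded.

3. **Conservation-masked motif scanning.** Each JASPAR/TRANSFAC position
   weight matrix is converted to log-odds in bits,
   `s(b, j) = log2[(n_bj + π) / (N_j + 4π) / q_b]` (pseudocount π = 0.25,
   background q), and scored over both strands at every offset. Under a
   conservation threshold τ ∈ {0.7, 0.8, 0.9, 1.0} a promoter's score is
   the best hit among windows whose every base has conservation ≥ τ; with
   no conservation required, it is the mean of the three best hits.
   Scores are min–max normalized per matrix so thresholds are comparable
   across motifs.

4. **Threshold-optimized enrichment.** For cluster of size *n* in a
   universe of size *N*, and a candidate score threshold *t* (every
   observed score is a candidate), let *k* cluster promoters and *K*
   universe promoters score ≥ *t*. The fold enrichment is

       fold(t) = (k / n) / ((K − k) / (N − n))

   — the cluster proportion over the proportion among all *other*
   promoters — and the significance is the hypergeometric upper tail
   P(X ≥ k), X ~ Hypergeom(N, K, n), Bonferroni-multiplied by
   (#PWMs × #conservation modes). The threshold maximizes fold subject to
   corrected p < 0.01; motifs with fold < 1.8 are discarded, and each
   motif reports the conservation mode with its lowest raw p.

5. **Interaction modules.** Human protein-interaction edges are mapped to
   mouse only when **both** endpoints have exactly one mouse ortholog
   (homodimer loops preserved), and the network is restricted to edges
   with both endpoints in a cluster (distance 0), with connected
   components as the reported modules.

Supporting utilities include qPCR relative quantification by the ΔCt
method (`2^−(Ct_target − mean Ct_refs)`, i.e. normalization to the
geometric mean of the reference-gene expression levels).

## Worked example

The one-call demo generates all inputs and runs every stage:

```r
library(adipomotif)
res <- run_pipeline("demo_out", seed = 7)
table(res$clusters$cluster, useNA = "ifany")
#    1    2    3    4    5 <NA>
#  200  200  200  200  200 4000
res$enrichment[, c("motif_id", "conservation", "threshold", "k", "fold", "p_raw")]
#   motif_id conservation threshold  k     fold        p_raw
# 1  planted          0.7         1 21 11.66667 7.161584e-13
res$network
# interaction_network: 80 nodes, 56 edges, 25 component(s)
```

All 200 genes planted per cluster are recovered. Out of 20 PWMs (1 planted
at 40% foreground vs 5% background occurrence + 19 column-shuffled decoys)
only the planted motif passes the corrected p < 0.01, fold ≥ 1.8 criteria:
`k = 21` cluster promoters carry it above the optimized score threshold,
11.7-fold more often than the rest of the universe.

The same analysis as a narrative workflow lives under `analysis/`
(`01_simulate_inputs.R` … `05_ppi_modules.R`); each script prints what it
found and writes a summary table under `results/`. Stage 2, for example,
reports per-cluster recovery of the planted truth:

```
 cluster planted assigned recovered sensitivity
       1     200      200       200           1
       2     200      200       200           1
       ...
```

and stage 4 the enrichment table:

```
 motif_id conservation threshold  k   n     fold        p_raw p_bonferroni
  planted          0.7         1 21 200 11.66667 7.161584e-13 7.161584e-11
```

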