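# netsig

Disease-module signature discovery on integrated gene networks.

Complex-disease genes are not scattered randomly across the interactome:
they concentrate in connected neighbourhoods ("disease modules"). `netsig`
implements an integrated transcriptome–interactome analysis for finding
such modules and distilling them into expression-supported signatures. It
is aimed at systems-biology analysts who have (or want to simulate) a
protein-interaction network, a two-group RNA-seq count matrix, GWAS summary
statistics with an LD map, and annotation/eQTL/comorbidity side tables.

## What it computes

**Network construction.** A de novo co-expression network is built from
pairwise mutual information (equal-frequency binning, nats) with
ARACNE-style data-processing-inequality pruning (in a triangle of MI edges,
the strictly weakest edge is presumed indirect and removed), then merged
with the curated physical interactome. Scale-freeness is checked with the
continuous maximum-likelihood exponent
`alpha = 1 + n / sum(log(k_i / (xmin - 0.5)))`.

**Dual module discovery.**

- *DIAMOnD* expands a seed set of known disease genes by repeatedly adding
  the gene whose links to the current set are most significant under the
  hypergeometric tail `p = sum_{i>=ks} C(s,i) C(N-s,k-i) / C(N,k)` — a
  score that deliberately penalizes hubs.
- *Active modules* (jActiveModules-style) converts per-gene
  differential-expression p-values to z-scores, aggregates a subnetwork as
  `zA = sum(z)/sqrt(k)`, calibrates it to `sA = (zA - mu_k)/sigma_k`
  against random k-gene sets, and searches for high-`sA` connected
  subnetworks by simulated annealing (default schedule 1.0 → 0.01 over 1e6
  iterations), run twice so the second pass (HSN2) refines the first.

**Signatures.** Genes found by either route must additionally be
differentially expressed (BH-adjusted p < 0.05 and |log2FC| > 0.75) to
become signatures: `signatures = (DIAMOnD ∪ HSN2) ∩ DEG`.

**Validation layers.** Module topology statistics (largest-component size
S vs random expectation, z-score, relative size S/Nd, separation d_s,
Glass' Delta); LD-aware SNP-to-gene binning (r² ≥ 0.8, one hop) with
Šidák-corrected gene-level p-values; genomic inflation λ_gc; fraction
curves against 100 size-matched control gene sets; Fisher and Monte-Carlo
(size-matched SNP-set randomization, plus-one empirical p) enrichment;
Wakefield-style log Bayes factors summed over a gene's eSNPs with
permutation calibration; comorbid-disease gene-set enrichment filtered at
RR ≥ 1.5 and TF-IDF cosine symptom similarity.

**Synthetic studies.** `sim_config()` / `simulate_study()` generate a full
study — scale-free interactome with a planted connected module,
negative-binomial counts with planted fold changes and a shared
co-expression factor, GWAS summary statistics with block LD and causal
SNPs inside module genes, annotation/eQTL and comorbidity layers — with
known ground truth, so every stage can be calibration- and
recovery-tested offline.

## Worked example

```r
library(netsig)
run <- run_all(sim_config(seed = 1))
print(run)
#> netsig run (seed 1, test profile)
#>   merged network: 1000 nodes, 3063 edges
#>   DE genes: 50; DIAMOnD: 200; HSN2: 3; signatures: 28
#>   planted-module precision 1.00, recall 0.60
#>   module S = 24 (z = 23.2), lambda_gc = 1.017
print(run$topology)
#> module topology: S = 24 of Nd = 28 (85.7%)
#>   null S_rand: 2.41 +/- 0.93; z = 23.25, p_normal = 7.74e-120, p_emp = 0.002
```

Reading: of the 1,000 simulated genes, 50 pass the differential-expression
filter; DIAMOnD proposes 200 candidates and the second-pass active module 3;
their DE-supported union gives 28 signatures, all of which carry a planted
effect (precision 1.00) and which cover 60% of the 30-gene planted module.
The signatures form a 24-gene connected component where random gene sets of
the same size yield 2.4 ± 0.9 (z = 23.2), and the GWAS layer shows no
global inflation (λ_gc = 1.02).

## Layout

- `R/` — simulation, network, co-expression, DGE, module discovery,
  topology, GWAS integration, comorbidity, pipeline modules
- `src/` — C++ kernels for pairwise MI and the annealing search
- `vignettes/disease-module-signatures.Rmd` — methods vignette
- `tests/testthat/` — unit, property and acceptance suites
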