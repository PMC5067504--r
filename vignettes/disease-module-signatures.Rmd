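---
title: "Methods: disease-module signature discovery on integrated networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-module signature discovery on integrated networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and design choices behind
`netsig`. It is the place to look when a default needs justifying or a
numerical convention needs checking; empirical behaviour is established by
the test suite and `scripts/acceptance.R`, not restated here.

## The analysis model

The package operationalizes the disease-module hypothesis: genes whose
perturbation produces a common phenotype occupy a connected neighbourhood
of the molecular interaction network. Because curated physical
interactomes are incomplete, a tissue-specific co-expression network is
inferred from the study's own expression data and merged into the physical
network before module search. Two complementary searches then run on the
merged network:

- **Seed expansion (DIAMOnD).** Given `s` known disease genes among `N`
  network genes, a candidate of degree `k` with `ks` links into the
  current set is scored by the upper hypergeometric tail
  `P(X >= ks | N, s, k)`. The lowest-p candidate joins the set and the
  frontier is re-scored; 200 iterations is the default expansion depth.
  The hypergeometric conditioning on `k` is what keeps hubs from winning
  merely by being hubs. Ties are broken by larger `ks`, then
  lexicographically, making the expansion fully deterministic.
- **Active subnetworks.** Per-gene p-values become one-sided z-scores
  `z = qnorm(1 - p)` (clamped to `[1e-12, 1 - 1e-12]`); a candidate
  subnetwork of size `k` scores `zA = sum(z) / sqrt(k)`, calibrated as
  `sA = (zA - mu_k) / sigma_k`. The in/out state of every node is optimized
  by simulated annealing (single-node toggles, geometric cooling, worsening
  moves accepted with probability `exp(delta / T)`), with the state scored
  as the sum of the `n_modules = 5` best component `sA` values. The search
  runs twice; the second pass refines within the first-pass genes (HSN2).

A gene becomes a **signature** only if some search found it *and* it is
differentially expressed (BH-adjusted p < 0.05, |log2FC| > 0.75, both
strict). This DE gate is the package's stand-in for functional validation:
network proximity alone is not treated as evidence.

## Calibration of the subnetwork score

For uniformly drawn k-subsets without replacement from node scores
`z_1..z_N`, the moments of `zA` are available exactly from finite-population
sampling theory:

    mu_k    = sqrt(k) * mean(z)
    sigma_k = sqrt(popvar(z) * (N - k) / (N - 1))

The annealer uses these exact moments (fast, deterministic, no sampling
noise); `calibrate_score()` provides the equivalent Monte-Carlo estimator
and the tests verify the two agree. When `sigma_k = 0` (all scores equal, or
`k = N`) the component is scored 0 — such a component is indistinguishable
from a random draw. One consequence of the sum-of-top-5 objective is worth
knowing: when a strong stretch of genes can be split into two non-adjacent
fragments, two moderately scored components can sum higher than one intact
component, so the optimal *state* need not contain the single best
*module*. The oracle tests therefore compare the annealer against
exhaustive enumeration of states under the same objective.

## The differential-expression stand-in

`nb_wald_test()` is a deliberately simple two-group NB test: median-of-ratios
size factors, log2 fold change on normalized group means with a 0.5
pseudocount, method-of-moments dispersion (`phi = max((s2 - mu)/mu^2, 1e-8)`
pooled across groups), a delta-method Wald statistic on the log2 scale, and
a t reference with `n1 + n2 - 2` degrees of freedom as the small-sample
correction. Under the generator's null it holds its size (type-I error
close to 0.05 at alpha = 0.05; verified in the acceptance suite). It is not
a shrinkage estimator: any externally computed per-gene table
(`gene`, `log2fc`, `p`) can be supplied to `dge_stats()` instead, and that
is the recommended route for real data.

## Mutual information and DPI

MI uses equal-frequency (rank) binning with ties broken by original index,
`B = max(2, floor(sqrt(n)))` bins by default, reported in nats. The
estimator has a positive bias of roughly `(B - 1)^2 / (2n)` for independent
profiles, so with the default 20-sample cohort (`B = 4`) independent pairs
sit near 0.2 nats while the retention threshold is 1.0 nats — the threshold
is doing real work and is configurable. DPI pruning marks, in every
triangle, the strictly-smallest edge for removal when
`mi_weakest < (1 - tolerance) * min(other two)` (default tolerance 0), then
removes all marked edges simultaneously, which makes the result independent
of edge iteration order; ties remove nothing.

## What the generator emulates — and what it does not

`simulate_study()` produces, from one master seed (each stage draws from an
independent substream, so regenerating one stage never perturbs another):

- a preferential-attachment interactome (`attach_m = 3` edges per new
  node, attachment probability proportional to degree + 1), giving
  `attach_m * (n_genes - attach_m)` edges and a power-law degree tail;
- a planted module: a random-walk-induced connected subgraph of 30 genes,
  densified by extra intra-module edges with probability
  `module_wiring_prob = 0.15` per pair — the local edge density the
  disease-module hypothesis posits, and what seed expansion exploits;
- NB counts (10 cases vs 10 controls, `base_mean = 100` with log-normal
  gene means, dispersion `phi = 0.1`, typical bulk RNA-seq scales), a
  planted `log2FC = 2` on module genes and on each first neighbour with
  probability 0.1, and a shared latent factor over module genes with
  loading 0.5. The loading was chosen once so that factor variance on the
  log scale (0.25) is comparable to the NB biological noise and clearly
  below the planted effect — the regime where both the co-expression
  edges and the differential expression are recoverable, which is the
  point of the integrated design;
- GWAS summary statistics: Poisson SNP placement (mean 3 per gene body and
  per 2 kb inter-gene gap on one synthetic chromosome, 1-based inclusive
  intervals), z ~ N(0,1) with `gwas_ncp = 6` added at causal SNPs (all
  SNPs inside module genes), LD emitted within blocks of 5 consecutive
  SNPs (15% of within-block pairs at exactly r² = 1, D' = 1, none across
  blocks);
- annotation flags (odds multiplied by 10 at causal SNPs), eQTLs
  preferentially targeting module genes, and 20 comorbid gene sets drawing
  half their members from module/effect genes, with RR metadata and
  bag-of-terms symptom vectors.

The generator is the *minimal* model each downstream statistic assumes —
NB counts, Normal z-scores, block LD. Passing tests on it demonstrates
correctness and calibration of the machinery, not robustness to what real
data add: outliers and batch effects, LD derived from population history,
overlapping genes, polygenic background association, or realistic MeSH
vocabularies. Effect-size defaults are study conditions, not estimates of
any particular disease.

Recovery is scored two ways: **recall** against the planted module proper,
and **precision** against all genes carrying a planted effect (module plus
affected neighbours) — a reported gene with planted signal is a true
discovery even when it sits just outside the module. The module-only
precision is also reported (`signature_precision_module`) for the stricter
reading.

## Numerical conventions

- Empirical p-values always use the plus-one convention
  `(#exceedances + 1) / (n_rand + 1)`; they can never be zero, and the
  floor at one million draws is 1e-6.
- The Monte-Carlo SNP-set null draws size-matched sets without replacement;
  because the statistic is a count of flagged members, the null is drawn
  directly as hypergeometric variates — exactly the same distribution,
  without materializing each set.
- Gene-level GWAS p-values use the Šidák-corrected minimum
  `1 - (1 - p_min)^m` via `expm1`/`log1p`; Simes is available as an
  alternative. LD binning takes one hop only (SNP ↔ genotyped SNP inside
  the gene); only perfect LD (r² = 1 *and* D' = 1), being an equivalence,
  is closed transitively.
- λ_gc is the median 1-df χ² statistic over its null median 0.4549364.
- The power-law MLE uses the continuous approximation with the
  `xmin - 0.5` offset; a flat tail (all degrees equal to `xmin`) is a
  degenerate input and raises an error rather than returning a divergent
  estimate. For generated interactomes the tail should be fit above the
  attachment minimum (`xmin = 5` with `attach_m = 3`).
- Glass' Delta divides by the control-group SD with denominator `n - 1`.
- Gene identity is the upper-cased symbol string; no alias resolution is
  attempted anywhere.

## Problem sizes and profiles

The default (`profile = "test"`) pipeline runs the full method on a
1,000-gene study with 1e4 annealing iterations, 1e3 Monte-Carlo draws, 200
permutations and 500 topology randomizations — sizes chosen so a complete
run takes a few seconds and a 25-replicate recovery experiment stays under
a few minutes on one core. `profile = "production"` switches to the
published operating point (1e6 annealing iterations, 1e6 Monte-Carlo draws,
1e4 permutations); the report stamps which profile produced it
(`thresholds$scaled_down`).

## Known limitations

- The annealing search re-scores the full active state each iteration
  (O(V + E) in C++); for interactome-scale graphs at 1e6 iterations expect
  minutes, not seconds.
- The NB test is approximate by design (no dispersion shrinkage, no
  covariates, no outlier handling) — use an external table for production
  differential expression.
- ARACNE's permutation-calibrated MI threshold and adaptive partitioning
  are not reproduced; the fixed 1.0-nat threshold with the simple binning
  estimator is transparent but cruder.
- `overlap_threshold` filters reported modules by pairwise Jaccard index;
  since the components of one state are disjoint, it only matters when
  modules from different passes are compared.
- RR values for comorbid diseases are input metadata; no epidemiological
  estimation is performed.
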