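---
title: "Virome-bacteriome co-occurrence networks: models and methods"
author: "viromeNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virome-bacteriome co-occurrence networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromeNet)
```

# Scope and model

viromeNet analyses how gut viruses (phages and eukaryotic viruses) co-occur
with bacteria in disease cohorts profiled by whole-genome metagenomics. The
chain it implements runs from read-mapping summaries to networks and their
statistics:

1. **Abundance profiles.** Contig abundance is reads-per-kilobase,
   $a_i = x_i / L_i \times 1000$; every gene on contig $i$ inherits
   $g = a_i / n_i$ where $n_i$ is the contig's gene count, under the working
   assumption that gene abundance is approximately proportional to organism
   abundance. Taxon abundance sums gene abundances sharing an annotation and
   is closed to relative abundance per sample. Genes without an annotation
   are aggregated into an explicit `unclassified` feature so closure always
   holds; network stages drop that feature by default.
2. **Prevalence filter.** Correlations of features observed in only a few
   samples are unreliable because zero-replacement dominates them, so
   features with nonzero abundance in strictly less than 20% of a group's
   samples are removed. The boundary survives: a feature present in exactly
   20% of samples is kept, and fractional sample counts are not rounded.
3. **Compositionality-corrected correlation.** Relative abundances sum to 1,
   which biases naive correlations negative. The basis-correlation
   estimator works on the variation matrix
   $t_{ij} = \mathrm{Var}\,\log(f_i/f_j)$ and solves, under the sparsity
   approximation (most basis correlations near zero), the linear system for
   basis variances $\omega_i$, giving
   $r_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})$,
   clamped to $[-1, 1]$. Pairs whose estimated $|r|$ exceeds an exclusion
   threshold (default 0.1, the published convention for this estimator
   family) are iteratively removed from the variance system - one pair per
   iteration, strongest first - and the system re-solved, because strong
   pairs violate the sparsity approximation.
4. **Pseudo p-values.** Each of `nShuffles` (default 100) shuffled matrices
   permutes every feature's values across samples independently, destroying
   correlation while preserving marginals. The two-sided pseudo p-value is
   the add-one estimator $(1 + \#\{|r^{shuf}| \ge |r|\}) / (n + 1)$, and
   Benjamini-Hochberg q-values are taken over the upper triangle. Networks
   keep edges with $|r| \ge R$ and $q \le 0.05$; $R = 0.4$ by default and
   0.6 in small-cohort mode, where estimator noise is larger.
5. **Disease-specific networks.** Category A: links surviving the case
   network's thresholds but absent from the control network. Category B:
   links present in both networks whose difference
   $D = |r_{case} - r_{control}|$ exceeds the 95% quantile of the per-edge
   null $\{|r_{case} - r^{shuf}_k|\}$ built from the comparison arm's
   shuffled archive. Swapping the arms yields the healthy-specific network.
6. **Pan / core networks.** Group networks are mapped to the family level;
   links with equal endpoints and equal sign merge, endpoint pairs carrying
   both signs are removed, within-family self-loops are dropped. The pan-
   network pools family links across groups (the sign-conflict rule extended
   across groups); the core-network keeps links recurring with the same sign
   in at least 4 groups.
7. **Topology.** Per node: degree $d$, neighbour-edge count $a$, clustering
   coefficient $\varphi = 2a/(d(d-1))$, importance centrality
   $c = (d(d-1)+1)/(2a+1)$ - a clustering-coefficient modification that is
   well-defined even when $d < 2$ and grows with hub-likeness - and
   unnormalized betweenness. Per graph: walktrap (walk length 4) modularity
   $Q = \sum_c (e_c/m - (d_c/2m)^2)$, the scale-free index (the $r^2$ of the
   OLS fit of $\log P(d)$ on $\log d$ over observed positive degrees), and
   the average path length over reachable pairs. Null-model tests compare
   observed statistics with 1,000 G(n, m) random graphs matched on node and
   edge counts.
8. **Key viruses and enrichment.** Virus ablation recomputes modularity and
   the scale-free index after removing a viral class. Key-virus selection
   adds viruses to the bacteria-only graph in decreasing full-graph
   betweenness and reports the bacterial average path length after each
   addition; the selected set is the shortest prefix attaining the
   trajectory minimum. The link-sign permutation test draws $n_2$ of the
   $n_1$ bacteria-virus links 100,000 times and compares the per-phylum
   negative-link count with its null; Fisher's exact test (one-sided,
   greater) scores functional-category enrichment over a 16-category
   vocabulary supplied as configuration.

# The synthetic-data generator

No public sequencing data are required: every stage is exercised on
generated cohorts. The generator is a standard compositional benchmark -
latent (basis) abundances are multivariate log-normal with a planted
correlation matrix, closed to fractions per sample, then sampled as
multinomial counts at a chosen depth. This emulates exactly the features the
estimator is designed for (compositional closure, sequencing-depth noise,
planted co-abundance) and deliberately omits others: no sequence content, no
assembly artefacts, no taxon-specific zero-inflation beyond what the
multinomial induces, and no batch effects. Passing tests therefore certify
the statistical machinery, not upstream bioinformatics.

Default study conditions used by the tests:

* recovery cohorts: 30 taxa, 200 samples, depth $10^5$, one pair planted at
  $r = 0.8$; null cohorts at 200-500 samples;
* differential cohorts: a 16-taxon equicorrelated module at $r = 0.8$
  planted in one or both arms of 200 + 200-sample cohorts;
* end-to-end cohorts: 60 taxa (40 bacteria, 14 phages, 6 eukaryotic
  viruses) with mixed-sign one-factor structure and a 10-taxon case-only
  module. The bit-reproducibility check runs a dense variant (loadings
  $\pm 0.92$) at 20 + 20 samples; the demonstration run reported by the
  reproduction script uses a sparser variant (loadings $\pm 0.9$ over 18
  taxa) at 60 + 60 samples with 400 shuffles, conditions under which the
  estimator's sparsity assumption holds and the FDR floor (below) is
  comfortably cleared.

Planted structures are declared as `CorrelationStructure` objects and
validated for positive semi-definiteness at construction; invalid structures
are rejected (naming the first failing leading principal minor) rather than
silently projected, so no test ever runs on an unintended covariance.
Taxon labels (class, genus, family, phylum) are assigned deterministically
from taxon order for fixture stability.

Sample sizes above were chosen as representative of the cohorts this kind
of study uses (tens to a few hundred samples per arm) while keeping each
simulation comfortably small; the differential calibration uses 20
replicate cohorts in the tests.

# Numerical and design choices

* **Pseudocount.** The estimator adds a pseudocount (default 1) to zero
  counts only, before closure. Touching only zeros preserves exact scale
  invariance - multiplying one sample's counts by a constant leaves
  zero-free fractions, hence correlations, unchanged - and matches the
  estimator's published zero-handling. Dirichlet-resampling averaging is
  intentionally out of scope to keep the estimator deterministic for a
  given input.
* **Exclusion loop.** One pair per iteration, the pair with the largest
  $|r|$ above the threshold; the safety cap defaults to $D(D-1)/2$. A
  feature excluded from nearly every pair ($\ge D - 3$) leaves the
  exclusion pool so the linear system never degenerates silently; the
  rank-1 downdates of the system matrix are applied via Sherman-Morrison
  updates with a periodic exact re-solve to curb drift. If a basis variance
  still comes out non-positive, the feature's correlations are reported as
  `NA` with a warning rather than fabricated.
* **FDR granularity.** With 100 shuffles the smallest attainable pseudo
  p-value is $1/101$, so after BH correction across all $\binom{D}{2}$
  pairs an edge can only reach $q \le 0.05$ when enough pairs share small
  p-values (roughly $0.0099 \cdot m / k \le 0.05$). A single isolated
  association in an otherwise null matrix can therefore never pass the
  default thresholds - which is why the differential fixtures plant
  correlated modules, mirroring real genus-level data where many pairs
  co-vary. Raising `nShuffles` lowers the floor at linear cost.
* **Differential null.** The null differences are computed against the
  comparison arm's shuffled archive by default (`nullSource = "control"`);
  a pooled-arm alternative is available because the choice is genuinely
  open. The per-edge quantile uses R's default interpolated empirical
  quantile. This null is conservative for strong shared edges (the shuffled
  correlations centre on zero, so null differences concentrate near
  $|r_{case}|$), which the calibration tests reflect: flag rates under the
  null sit well below the nominal 5%.
* **Walktrap ties and isolated nodes.** Community detection uses walk
  length 4 with the implementation's merge order; isolated vertices are
  placed in singleton communities before clustering since a random walk is
  undefined there. The final cut maximizes modularity.
* **APL convention.** Unreachable pairs are excluded from the mean
  (component-wise averaging). Key-virus selection computes APL over
  bacteria pairs only, allowing paths through viruses; if the bacteria-only
  graph is disconnected the report flags that comparisons use the
  connected-pairs convention. Betweenness ties in the addition order break
  lexicographically by node name.
* **Permutation test.** Two-sided p doubles the smaller tail (add-one
  estimator, capped at 1); links are drawn without replacement, so the
  exact reference distribution is hypergeometric and the tests verify
  convergence to it. FDR correction is applied within one network; pooling
  across networks is left to the caller.
* **Fisher modes.** `complement` (subset vs background-minus-subset,
  disjoint columns) is the statistical default; `as_printed` reproduces the
  subset-vs-full-background table layout used in the field for
  comparability.
* **Seeds.** Every stochastic function takes a seed and restores the
  caller's RNG state; the pipeline derives per-stage seeds deterministically
  from one root seed, so any bundle is bit-reproducible.

# Known limitations

* The estimator inherits the sparsity approximation: when a large fraction
  of pairs is truly correlated (as in the dense demonstration cohort) basis
  variances are biased and estimates of strong correlations can be inflated;
  at small sample sizes some features fail variance estimation and are
  reported `NA`.
* The generator's multinomial sampling underestimates the zero-inflation of
  real metagenomic profiles at low depth.
* Networks are analysed unweighted (sign-annotated but not weight-
  generalized), matching the formulas implemented; weighted modularity or
  betweenness variants are out of scope.
* An externally produced sparsification (e.g. a conditional-independence
  filter) can be applied only as an edge-mask input; no such method is
  re-implemented here.
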