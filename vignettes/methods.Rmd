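---
title: "Methods: cross-species divergence of combinatorial TF occupancy at CRMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species divergence of combinatorial TF occupancy at CRMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`crmdiverge` implements a comparative analysis of where five mesodermal
transcription factors (Twi, Tin, Mef2, Bap, Bin) bind across two diverged
*Drosophila*-like species, at the level of *cis*-regulatory modules
(CRMs) rather than individual peaks. The pipeline has six analytical
layers:

1. **CRM construction** — ChIP peak summits within 400 bp of each other
   (single linkage) are clustered; the summit span is padded by 100 bp
   per side. Padding can make neighbouring clusters touch, so overlapping
   intervals are merged afterwards.
2. **Cross-species coordinate translation** — a per-base liftover through
   an alignment block map (ordered, non-overlapping, ungapped blocks; a
   defined stand-in for a whole-genome alignment chain). A CRM is
   *translated* when any base maps, and *uniquely mapped* when its mapped
   pieces fall on one target chromosome within 1 kb — the original
   criterion distinguishing uniquely from multiply mapping regions is not
   fully specified, so this rule is explicit and configurable.
3. **One-to-one orthology** — a bipartite overlap graph (>= 1 bp) between
   reference CRMs and uniquely translated CRMs; only connected components
   with exactly one CRM per species are kept, which is deliberately
   conservative.
4. **Binding conservation** — per orthologous pair, the Jaccard
   coefficient over the 14 shared (TF, time point) conditions:
   strong (J >= 0.5), intermediate (0 < J < 0.5), none (J = 0). Pairs
   bound at exactly one condition in each species are excluded as
   singletons *regardless of whether the single conditions match*
   (mismatches are flagged) — the alternative reading (exclude only
   matching singletons) would leave J in {0, 1} for those pairs and blur
   the category boundaries.
5. **Motif analyses** — patser-style PWM scanning (natural-log odds,
   pseudocount 0.001 renormalized per position, 0-order background),
   exact p-values by dynamic-programming convolution of the per-column
   score distributions discretized at 0.01; ROC threshold calibration on
   200 bp summit windows (positives) vs seeded random windows in unbound
   CRMs (negatives), choosing the smallest score with TPR in [0.70,
   0.80] and FPR <= 0.40 in the better-AUC species and matching that TPR
   in the other; TFBS densities in 100 bp summit windows (bound) or one
   random 200 bp window (unbound); early/late temporal classes (bound
   early but at no later condition, and a linear-scale signal ratio > 2);
   differential motif enrichment by total hits and Fisher's exact test
   with the |log2 R| > 1 fold filter.
6. **Occupancy model and co-divergence** — a one-free-parameter
   thermodynamic occupancy model plus permutation co-association and
   contingency co-divergence statistics, described below.

# The occupancy model

For a sequence with windows $i$ (both strands), each window contributes
relative affinity $K_i = e^{s_i}$ where $s_i$ is the log-odds score, and

$$\mathrm{occ}(\gamma) = \sum_i \frac{\gamma K_i}{1 + \gamma K_i},$$

with a single concentration-like free parameter $\gamma > 0$. Occupancy
is monotone in $\gamma$ and in any single $K_i$ and is bounded by the
window count. Training minimizes the squared error between
clip-normalized predictions and clip-normalized ChIP scores on the top
1000 peaks plus 1000 length-matched random windows; the normalization
replaces scores above $\mu + 3\sigma$ with that cap and min-max scales
to [0, 1], learned on the training set and applied forward. $\gamma$ is
fit by a log-spaced grid search ($10^{-5}$ to $10^2$, quarter-decade
steps) refined by 1-D optimization between the flanking grid points; if
the optimum sits on the grid boundary the grid is widened once, then a
warning is raised. Random training windows take the ChIP score actually
measured over them — in the synthetic benchmark that is the baseline
plus noise of the signal model, which avoids contaminating the labels
with hard zeros.

Model accuracy is assessed by 4-fold cross-validation with a seeded fold
split; the pooled held-out predictions are compared with the ChIP scores
by Pearson correlation. On the default benchmark the per-model CV PCC
averages near 0.5, and on noiseless model-generated data it exceeds 0.9
with $\gamma$ recovered within a factor of two (these are exactly the
quantities the test suite computes).

For the divergence analysis, $\Delta\mathrm{ChIP} =
\mathrm{ChIP}_{sp1} - \mathrm{ChIP}_{sp2}$ and $\Delta\mathrm{STAP}$
analogously on normalized scores, z-standardized within the analysis set
(pairs bound by the focal TF in species 1). The model scores the CRM
sequence itself; the size-S extension of each pair (S = sum of the two
CRM lengths, S/2 per side around the center) is used only for TFBS
density windows. When a TF has several time points, ΔChIP uses the
condition with maximal species-1 signal for that CRM (a `mean` mode is
available; the collapse rule is not dictated by the analysis design, so
both are implemented behind a flag). Quadrants on the z-scaled scatter:
**red** = $z_{\Delta STAP} > 1.5$ and $|z_{\Delta ChIP}| < 0.7$ (motif
lost, occupancy kept — the TF-collective signature); **green** =
$z_{\Delta ChIP} > 1.5$ and $|z_{\Delta STAP}| < 0.7$ (occupancy lost,
motif kept — cooperative recruitment by a partner). Class differences in
Spearman correlation are compared by the Fisher z-transformation, and
quadrant excess in HighBound vs Singleton classes by a one-sided Fisher
exact test.

# Co-association and co-divergence

Condition co-association uses the binary CRM x condition matrix. The
null preserves all row and column sums; it is sampled with the curveball
algorithm (`vegan::nullmodel`, seeded, burn-in 10x and thinning 1x the
row count). Curveball performs randomized trades between row pairs and
is a faster-mixing member of the same degree-preserving family as the
classical checkerboard swap; literal independent shuffles of column and
row contents cannot preserve both margins simultaneously, and degree
preservation is the stated intent of the design. z-scores are
(observed - null mean) / null SD per condition pair; columns that are
constant have undefined z and are flagged. On data drawn from the null
itself the 45 pairwise z-scores have mean ~0 and SD ~1, which the test
suite verifies.

Co-divergence between TFs 1 and 2 is assessed over the orthologous CRMs
co-bound by both in species 1 ($S_{1,2}$ of them), split into the four
species-2 outcomes. With $P_1$ and $P_2$ the observed per-TF loss
probabilities, the independence expectation for joint loss is
$S_{1,2} P_1 P_2$; dependence is tested by a two-sided Fisher exact test
on [[both conserved, TF2 lost], [TF1 lost, both lost]] with
Benjamini-Hochberg correction across the 10 TF pairs. "Loss" at the TF
level means bound at >= 1 condition in species 1 and none in species 2;
co-binding is any-condition co-binding (same-time-point co-binding
counts are additionally reported). The occupancy-loss vs motif-loss
association (TF1 ChIP rows x TF2 STAP columns) uses a z(ΔSTAP) cutoff of
1.0 to call a motif lost — the original cutoff is not stated, so it is a
documented, configurable default. Because this exact test is discrete,
its p-values are conservative by construction (they carry an atom at 1);
the module therefore also reports the Lancaster mid-p, which is the
quantity to use in calibration checks, while inference uses the exact p.

# The synthetic benchmark

The generator builds species 1 as a single chromosome of CRM loci
(length ~N(300, 50) bp) separated by spacers (>= 600 bp, so that
neighbouring CRMs can never fall within the 400 bp clustering gap),
with base composition A = T = 0.28, C = G = 0.22. Each CRM is bound by
1-5 TFs (probabilities 0.53/0.20/0.17/0.06/0.04, giving roughly the
singleton/low/high-bound proportions of the study design) at a temporal
class per TF (continuous/early/late with probabilities 0.50/0.25/0.25
over that TF's conditions; the 14-condition design is Twi and Tin at
TP1-3, Mef2 at TP1-5, Bap at TP2, Bin at TP3-4). Binding is realized as
1-3 planted motif instances sampled from the TF's PWM.

Species 2 is the species-1 sequence evolved by per-base substitutions
(default rate 0.5, the approximate per-base divergence of two genomes
at ~1.4 substitutions per neutral site) and indel events (rate 0.02,
geometric lengths with p = 0.4). Motif instances of conserved binding
events are protected from mutation (the selection proxy); lost events
(per-(CRM, TF) probability 0.3) are additionally degraded at their motif
bases so the motif is destroyed even under low substitution rates. The
maximal ungapped runs between indels become the alignment block map, so
liftover ground truth is exact. A TF whose motifs are lost keeps its
species-2 binding when at least `min_partners = 3` other TFs retain
intact motifs on the CRM — the TF-collective rescue; rescued events peak
at the (mapped) CRM center. `plant_cooccurrence()` additionally forces
joint loss of a chosen TF pair in a fraction of their co-bound CRMs;
those forced losses are not rescue-eligible, because the mechanism being
emulated is partner-dependent binding. Note that the rescue rule itself
induces dependence between TF losses at the binding level, so
independence-calibration experiments run with the rescue disabled.

The quantitative signal is `log2 signal = 1.5 x (planted sites) + 0.5 +
N(0, 0.5)` per (CRM, condition); peaks carry the signal as score, with
the summit at the strongest planted site. Activity labels are planted
with a mesoderm bias on strongly conserved CRMs, and a per-base
conservation-score track is elevated under CRMs in proportion to their
true conservation category.

What the generator does **not** emulate: read-level noise and peak-caller
artifacts, binding gains in species 2, genomic rearrangements
(translocations/inversions; all blocks are co-linear and plus-strand),
chromatin context, and condition-level (time-point) divergence within a
conserved TF — temporal patterns are conserved at the TF level. Passing
tests therefore demonstrate correctness of the statistical machinery and
recoverability of planted effects under realistic divergence, not
performance on real ChIP data.

# Numerical and design choices

- Coordinates are 0-based half-open everywhere (BED dialect on disk).
- The patser-style background takes `a:t` as the frequency of A and of T
  each; when the four per-base values do not sum to 1 they are
  normalized (the defaults A=T=0.28 with C=G=0.18 or 0.20 sum to 0.92 or
  0.96). Log-odds use natural log with pseudocount 0.001 renormalized
  per position; the p-value DP discretizes scores at 0.01, and scanned
  hits are binned with the same per-column rounding so DP p-values are
  exact for the binned score.
- `cluster_summits` pads 100 bp per side: together with the summit span
  this reproduces the reported average CRM size (~273 bp), whereas
  100 bp total would not.
- Ward clustering (`hclust`, method `ward.D`) on `1 - Pearson` row
  distance; zero-variance rows get distance 1 to everything and are
  flagged. Leaf order is `hclust`'s deterministic convention.
- Normalization is learned on training scores and applied forward;
  outputs are clamped to [0, 1] when parameters are reused.
- Per-stage seeds derive from one global seed and the stage name, so
  disabling unrelated stages does not shift a stage's randomness; every
  random step (random negative windows, fold splits, permutation chains,
  the generator itself) is seeded, and reruns produce byte-identical
  numeric artifacts.
- Problem sizes used by the tests and the acceptance analysis: 2000-CRM
  benchmarks for recovery experiments (20 replicates for co-divergence
  detection, 5 pooled replicates for the quadrant analysis — pooling
  raises the count statistics to where the Fisher test has power),
  500 x 10 matrices at 500 permutations for null calibration, and
  120-250-CRM benchmarks for end-to-end smoke and determinism checks.

# Known limitations

- The liftover is a simplified block map: no strand flips occur in the
  generator (minus-strand translation is implemented and tested, but
  synthetic data never exercises it end-to-end), and no chain/net or PSL
  parsing is provided.
- STAP here is the single-TF, non-cooperative, one-parameter form; no
  multi-motif or cooperativity terms.
- The ROC threshold rule can be infeasible on poorly performing PWMs; the
  nearest-feasible score is then used with a warning rather than failing
  the pipeline.
- Exact-test p-values are conservative on small tables (see mid-p note
  above); chi-square association tests fall back to Fisher's exact test
  when an expected cell drops below 1.
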