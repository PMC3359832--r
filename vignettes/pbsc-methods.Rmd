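---
title: "Pathway-based similarity comparison: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based similarity comparison: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsc)
```

## The problem

A treatment — here, a multi-component herbal formulation given to patients
whose leukocyte transcriptomes were profiled before and after therapy — has
an unknown mechanism. One way to generate pharmacological hypotheses is to
ask which *known* compounds produce expression changes that look like the
treatment's (mimics) or like its opposite (reversers). Connectivity-Map-style
banks supply the reference material: for each perturbation *instance* (one
compound at one dose in one cell line) a ranked list of genes from most
up-regulated to most down-regulated.

A genome-wide similarity score between a patient signature and a reference
profile mixes together every process the drug touches. The pathway-based
similarity comparison (PBSC) implemented here instead scores the match
*within each biological pathway* that the treatment demonstrably perturbs,
and then ranks reference instances by how many pathways they match
(positively or negatively). The per-pathway resolution is the point: a
compound that mimics the treatment in ten signalling pathways and reverses
it in none is a more interpretable lead than one with a single aggregate
score.

## The procedure

For one patient with a pre-treatment and a post-treatment profile (log2
scale), `pbsc()` runs four stages.

**1. Differential signature.** With one pair per patient the per-gene
effect is the difference of log2 intensities, `log2FC = post − pre`. Genes
are ranked by decreasing `log2FC` (ties broken by gene identifier so the
ranking is a deterministic total order), and the *tag signature* is the set
of genes with `|log2FC| ≥ log2(fold_threshold)`, split into an up list and
a down list, each ordered by effect magnitude. The default threshold is
2-fold, inclusive. With a single pair there is no variance estimate, hence
no moderated statistic; the ranking *is* the fold-change ranking.

**2. Enrichment gate.** Only pathways the treatment visibly affects are
scored. Two gating tests are provided:

* `ks_permutation` (default): each pathway's member genes, as one group,
  are scored against the full differential ranking with the signed KS
  statistic below; the null is generated by drawing random gene sets of
  the same size from the ranked universe, and
  `p = (1 + #{|KS_perm| ≥ |KS_obs|}) / (n_perm + 1)`. The +1 correction
  keeps p strictly positive; null samples are shared between pathways of
  equal size, which changes nothing about each p-value's marginal
  distribution but makes 100 pathways cost ~60 null samples instead
  of 100.
* `hypergeometric`: the one-sided upper tail `P(X ≥ k)` for the overlap
  `k` between the DE set (up ∪ down tags) and the pathway, within the
  measured universe.

With a single sample pair, phenotype-label permutation — the classical GSEA
null — is impossible, which is why the gate offers these two explicit
flavors instead. Pathways pass at raw `p < alpha` (default 0.05, strict
inequality, no multiple-testing correction; a Benjamini–Hochberg option
exists but is off by default). The gate is a *screen*, not an inference:
its false positives cost compute and add noise pathways that the
per-instance counting stage then scores near zero.

**3. Per-pathway connectivity.** For each selected pathway and each bank
instance, the instance's ranked profile is restricted to the pathway's
genes (order preserved, positions renumbered `1..N`). For a tag group of
size `t` at positions `V(1) < … < V(t)`:

$$p = \max_{j=1..t}\left[\tfrac{j}{t} - \tfrac{V(j)}{N}\right],\qquad
  n = \max_{j=1..t}\left[\tfrac{V(j)}{N} - \tfrac{j-1}{t}\right]$$

and the signed statistic is `p` if `p > n`, `−n` if `n > p`, `0` on a tie.
Tags clustering at the top of the reference ranking give a positive value
(the instance up-regulates what the treatment up-regulates), at the bottom
a negative one.

In the default `combined` mode the up and down groups are scored
separately and combined the classic way: if both KS values share a sign
the signature is incoherent with the profile and the score is 0; otherwise
`score = (ks_up − ks_down) / 2`, halved so the score stays in `[−1, 1]`
(a flag disables halving for the unhalved convention with range
`[−2, 2]`). If one group has no gene in the pathway the other group's KS
carries the score alone (the down group with flipped sign). `single_set`
mode scores the pooled tag list as one group.

Each cell gets a permutation p-value: tag positions are re-drawn uniformly
within the restricted list, preserving both group sizes, and the same
combination rule is applied. Because every instance of a bank shares one
gene universe, the restricted length and tag sizes — hence the null — are
identical across instances, and one null sample per pathway serves the
whole bank.

**4. Counting and report.** A pathway *counts* for an instance when its
score is nonzero, `|score| ≥ min_abs_score`, and its cell p-value is below
`count_alpha` (default 0.05; `count_alpha = 1` gives a pure sign count).
Instances are ranked by total count (positive + negative), ties broken by
the summed |score| over counted pathways and then by instance id, and the
top `k` (default 10) are reported with counts rendered in the printed
convention, e.g. `20+ 1−`.

## Numerical conventions worth knowing

* **Exact tie detection in the KS statistic.** `j/t − V(j)/N` is evaluated
  as `(jN − Vt)/(tN)`: the numerators are exact integers, so the `p` vs
  `n` comparison and the tie rule never depend on floating-point rounding.
  This matters at boundaries: a top-loaded group with `t = N − 1` has
  `p = n = 1/N` *exactly*, so the statistic is 0 by the tie rule — not the
  `1 − t/N` one might extrapolate from smaller `t`. With naive
  floating-point evaluation the same configuration returns 0 or `−1/N`
  depending on rounding direction.
* **Antisymmetry is generic, not universal.** Reversing a reference
  ranking maps a group's `(p, n)` to `(n − 1/N, p + 1/N)`. The combined
  score therefore negates exactly under profile reversal *when each
  bottom-decided group's margin `n − p` exceeds `2/N`* (about 92% of
  random configurations); at or below that margin the reversed group ties
  or changes sign and the combined score collapses toward 0. The test
  suite asserts exact negation on decisive cases only.
* **Conservative cell p-values in combined mode.** The same-sign rule puts
  a point mass at score 0, so the per-cell permutation p-value is valid
  but conservative (an atom at p = 1); in `single_set` mode it is close to
  uniform under the null.
* **Discreteness of the hypergeometric gate.** At a 2000-gene universe and
  pathway sizes 10–80 the attained level of `p < 0.05` is ≈ 0.03, not
  0.05 — inherent to discrete tails, not a calibration error.
* **Quantile normalization** delegates to `limma::normalizeQuantiles(ties
  = TRUE)`, whose convention matches the documented contract: all columns
  map onto the row-wise mean of sorted columns; ties receive the mean of
  the reference values at the tied positions; the operation is idempotent.
* **SNR filter direction.** The filter keeps genes whose best
  signal-to-noise ratio is *at least* the threshold (default 2), the
  standard reading of "robustly expressed"; `snr_keep_rule =
  "below_threshold"` reproduces the literal inverted reading found in some
  descriptions. The choice is echoed in the run log, and the filter is
  applied before normalization.
* **Degenerate inputs.** An empty tag signature (nothing beyond the fold
  threshold) is a warning, enrichment proceeds with p = 1 under the
  hypergeometric gate, and connectivity skips empty groups. A gate that
  selects nothing yields an explicit "no pathways selected" status and an
  empty, well-formed report. A patient/bank gene-universe intersection of
  zero is a fatal, diagnosed error (`validate_inputs()` reports overlap
  percentages without running anything).

## What the synthetic generator emulates

`simulate_bank()` and `simulate_patient_pair()` stand in for data that
cannot be redistributed: a perturbation bank and paired patient arrays.
The defaults define the package's reference study conditions: 2000 genes,
50 instances, 100 pathways of 10–80 genes, 50 up + 50 down signature genes
per instance planted inside 5 affected pathways, a 2 log2-unit effect and
0.5 log2 units of Gaussian noise; patient baselines are Normal(8, 1) on
the log2 scale, mimicking microarray intensities (the baseline location is
immaterial to rank-based scoring). Signatures are planted *within*
pathways deliberately — a genome-wide-uniform signature would be invisible
to a pathway-gated method, so uniform planting would test nothing. The
affected-pathway set is redrawn (up to 100 attempts) when its union cannot
hold the signature; with the default geometry a single draw fails with
probability ≈ 0.3% per instance, so a hard error there would make roughly
one bank in seven fail for a reason that is sampling luck, not a
configuration problem. A genuinely infeasible configuration still errors.

At these conditions a planted gene's fold change is Normal(±2, 0.5), so
≈ 97.7% of planted genes clear the 2-fold threshold, and ≈ 4.6% of null
genes slip in — the signature recovered from a simulated patient has
realistic contamination. The generator does **not** model probe effects,
spatial artifacts, correlated noise, or cell-type composition shifts;
passing the planted-recovery test shows the chain of
threshold → gate → KS → counting recovers a strong, pathway-concentrated
effect at moderate noise, not that the method is robust to real
microarray pathology.

## Problem sizes used in validation

The acceptance checks run the full pipeline at the default study
conditions over 20 generator seeds (planted-drug recovery, expected in the
top 3 with predominantly positive counts in ≥ 19 of 20), verify the KS
implementation against a brute-force transcription on 1000 random cases
and exhaustively against closed forms for all `N ≤ 50`, check the
normalization contract on a 500 × 6 matrix, and measure the enrichment
gate's size on 200 random pathways with null differential sets drawn at
8–16% of the universe — the call rate the 2-fold threshold actually
produces at these noise settings, and the per-patient range reported for
arrays of this kind. Null rejection rates land near 0.032
(hypergeometric, discrete) and 0.05 (permutation KS).

## Known limitations

* One pre/post pair per patient; no replicate handling or moderation.
* The gate uses a single-group KS on each pathway; a pathway whose members
  split half to the top and half to the bottom of the ranking (exactly
  what a planted two-sided signature produces) yields a weaker single-group
  statistic than a two-group test would, so small affected pathways can
  miss the gate. This is faithful to the method's published shape; expect
  recovered counts below the number of planted pathways.
* Instances are scored independently; no cross-instance normalization of
  scores, and no cell-line stratification.
* Multi-patient synthesis is by intersecting per-patient reports, not by
  joint modelling.
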