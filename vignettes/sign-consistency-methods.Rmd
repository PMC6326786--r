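---
title: "Evaluating sign consistency between regulatory networks and expression compendia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating sign consistency between regulatory networks and expression compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signcon)
```

## The question

A curated transcriptional regulatory network asserts, for each interaction,
a direction (TF regulates target) and a sign (activation or repression). A
gene expression compendium records how transcript levels actually move
across hundreds of conditions. `signcon` asks a blunt question: taken at
face value, how often does the network's sign structure agree with what the
expression data do? The package scores that agreement, compares it against
degree-preserving null models, and provides a synthetic-data generator that
reproduces the statistical regimes one meets in practice — from idealized
causal behavior to expression that is entirely decoupled from, or globally
confounded with, the network.

## The model

**Vertices and aggregation.** The network is a directed bipartite graph:
regulator vertices (TFs, or TF complexes with several member genes) point
at target vertices (genes, or transcription units with several member
genes). Genes in a TU are transcribed together, so a TU vertex's expression
is the per-sample *mean* of its members. A TF complex needs all of its
member proteins, so a complex vertex takes the per-sample *minimum* — the
scarcest subunit limits the complex. Vertices with any unmeasured member
gene are removed before analysis (`filter_by_expression()`).

**Contrasts.** Expression is compared within experiments: each experiment
designates one unperturbed reference sample, and every other (case) sample
yields one contrast, the case-minus-reference difference of log-scale
expression. Positive contrast = higher in the case. Which sample is the
reference is metadata the caller supplies; experiments without one are
excluded with a warning rather than failing the run, because real
compendium annotations are incomplete.

**Ternary labels.** For each contrast, every vertex is labeled upregulated
(+) when its log-ratio exceeds `t`, downregulated (−) below `−t`, and
unchanged (0) otherwise. The inequalities are strict: a value exactly at
the threshold is unchanged. `select_threshold()` picks one global `t` as the
quantile of the pooled absolute contrast values such that a chosen fraction
(default one half) of all values is labeled changed; any standard quantile
estimator is adequate at that calibration target, and we use R's default.

**Edge rule.** An interaction is inconsistent in a contrast exactly when
the labels contradict its sign: an activation with an upregulated TF whose
target is *not* upregulated, or a downregulated TF with an upregulated
target; a repression with an upregulated TF whose target is *not*
downregulated, or with TF and target both downregulated. An unchanged TF
never renders an edge inconsistent — without a change in the regulator the
model makes no prediction. This is deliberately conservative: marking every
mixed changed/unchanged combination inconsistent would inflate the count
with cases whose status is genuinely undefined.

**Vertex rule and load.** The inconsistency vector of edge $e$ is
$I(e) \in \{0,1\}^n$ over the $n$ contrasts. A target $v$ is inconsistent
in contrast $i$ only if every incoming regulation is,

$$J_i(v) = \prod_{e \in N^-(v)} I_i(e),$$

so one consistent regulator "explains" the target — a lower bound on
inconsistency when regulators of mixed sign compete. The **global
inconsistency load** is $\sum_v |J(v)|_1$, the total number of
(target, contrast) inconsistencies. Targets with no regulators are excluded
rather than given the empty product (which would brand them always
inconsistent).

**Binary variant.** For comparison with older present/absent-style
approaches, the binary variant labels every value + or − (split at zero)
and the rule collapses to sign agreement: activation inconsistent when
labels differ, repression when they agree.

## Null models

Both nulls preserve every vertex's in- and out-degree, because degree is a
dominant structural property of regulatory networks and must not drive the
comparison.

* `shuffle_profiles()` reassigns whole expression profiles to vertices by a
  uniform permutation. Profiles stay internally intact; only ownership is
  randomized. Shuffling is applied to vertex-level contrast rows, after
  TU/complex aggregation, so multi-gene structure is not scrambled through
  the aggregators; labels are recomputed afterwards with the same `t`
  (a row permutation leaves the pooled values, hence the threshold,
  unchanged). A gene-level shuffle can be had by shuffling the compendium
  matrix directly before aggregation.
* `rewire_edges()` performs double edge swaps: pick edges $(p,q)$ and
  $(r,s)$, propose $(p,s)$ and $(r,q)$, abort if either exists or the picks
  share an endpoint. We count $10\,|E|$ *attempts*, not successes — the
  literal protocol, and it terminates even on swap-saturated graphs such as
  complete bipartite networks, where every proposal aborts and the network
  is returned unchanged. The sign of a rewired edge travels with the
  regulator's outgoing stub, preserving each regulator's
  activator/repressor out-profile — the stronger null, and the natural
  choice where the protocol is silent on signs.

`null_distribution()` repeats either perturbation (200 replicates by
default), collects the global loads, and reports the empirical one-sided
`p`, the plain proportion of null loads at or below the observed load — at
finite replicate counts this can legitimately be zero.

## Correlation analyses

`interaction_correlations()` computes one Pearson (or Spearman) coefficient
per interaction across all samples of the raw log-expression profiles — not
the contrasts, which exist only for the sign model. Summaries are stratified
by sign and by the single-regulator subset (targets with in-degree 1, where
the pairwise TF–target relationship is unobscured by other regulators).
`background_correlations()` anchors these against the full regulator ×
target cross product (known pairs included; an exclusion flag exists), with
optional uniform pair sampling for large networks. Aggregated vertex
profiles are used throughout, consistent with the rest of the pipeline.

## The synthetic generator

`sim_config()` + `simulate_study()` produce a network and compendium with
the features the analysis depends on: heavy-tailed out-degrees (truncated
power law, tail exponent 2 by default), about 55% activating edges,
configurable fractions of 2–4-gene TUs and 2–3-gene complexes, and
experiments laid out as one reference plus several cases. Latent TF
activities are per-experiment baselines plus per-case shifts; perturbed
experiments shift more TFs more strongly (shift probabilities 0.1/0.4 and
shift SDs 0.5/2 for unperturbed/perturbed cases — fixed constants chosen to
give perturbed contrasts visibly more changed genes, as real perturbation
experiments show). In the causal regime a quarter of perturbed cases are
knockouts: one TF's activity is forced strongly negative and its gene row
clamped to baseline minus three noise SDs, mimicking knockout arrays
without a mechanistic model.

Expression is linear-Gaussian rather than a kinetic ODE simulation: target
genes respond as $\alpha + \sum_e s_e\, w\, a_{f(e)} + \varepsilon$ with
edge sign $s_e$, effect size $w$ and noise $\sigma$, which is transparent,
fast, and sufficient to produce the regimes the analyses must distinguish:

* **causal** — targets respond to their regulators; TF genes report their
  own activity. The pipeline should find signed correlations and a load
  that degrades sharply under rewiring.
* **decoupled** — every gene is independent noise around its baseline (the
  perturbation structure exists only in the metadata). The observed load
  should sit inside both null distributions and correlations should vanish.
* **confounded** — as decoupled, plus a shared per-sample factor added to
  every gene (growth rate, batch), which pushes *both* activator and
  repressor pairs toward positive correlation — the signature that
  distinguishes global co-regulation from edge-level causality.

TU member genes are the TU-level value plus i.i.d. jitter (SD 0.1), so
members co-vary without being identical. What the generator does *not*
emulate: time-series dynamics, post-translational regulation of TF
activity, saturation or combinatorial logic, and realistic
microarray-specific noise. Passing the synthetic recovery tests therefore
shows the pipeline is correct and well-calibrated, not that any particular
real network is consistent with any particular real compendium.

## Numerical and design choices

* One global threshold from pooled values, not per-contrast thresholds
  (a per-contrast mode would change what "50% changed" means; the pooled
  choice matches reporting a single `±t` for a whole compendium).
* Quantile normalization (`quantile_normalize()`, average-rank ties) is
  provided as a utility for matrices that arrive un-normalized; the
  pipeline assumes already log-scale input.
* Pairs reported with both signs in an interaction table are treated as
  dual-effect and dropped — the model admits exactly one sign per edge.
* A gene regulated both directly and via its TU stays two distinct target
  vertices; no cross-level deduplication.
* Mann–Whitney U comparisons (perturbed vs unperturbed contrasts, strong
  vs weak evidence) are two-sided with the normal approximation and tie
  correction; evidence types supporting fewer than 100 edges are excluded
  from per-type summaries.
* All randomness flows from explicit seeds; `run_pipeline()` derives
  sub-seeds for simulation, each null model and background sampling from
  one master seed, and two runs with the same configuration are
  byte-identical.

## Problem sizes

The packaged tests exercise the full pipeline on simulated studies of up to
200 TFs, 1500 targets, 4000 edges and 100 contrasts with 50 null-model
replicates — large enough that the power-law topology, multi-gene vertices
and regime signatures are all expressed, while a complete run stays
desk-scale. Unit fixtures are far smaller (tens of vertices) and verified
against brute-force oracles.

## Limitations

The model is correlational at heart: it cannot distinguish direct
regulation from shared upstream causes, and the confounded regime shows how
easily a global factor masquerades as consistency. Contrasts assume the
reference sample is truly unperturbed and contemporaneous with its cases;
time-delayed regulation is not modeled. The conservative edge rule
understates inconsistency by design, and the product rule makes the load a
lower bound whenever targets have several regulators.
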