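# signcon

Sign-consistency analysis of transcriptional regulatory networks against
gene expression compendia.

## What it does

A curated regulatory network claims, for every interaction, that a
transcription factor (TF) activates or represses a target gene or
transcription unit (TU). `signcon` quantifies how well those signed claims
agree with an expression compendium:

* **Ternary sign model.** Per-experiment contrasts (case minus reference
  log-expression) label every vertex upregulated (+), downregulated (−) or
  unchanged (0) at a threshold *t* chosen so that about half of all
  contrast values count as changed. An edge is *inconsistent* in a
  contrast when the labels contradict its sign (e.g. TF up, activation,
  target not up); an unchanged TF never votes against an edge. A target
  *v* is inconsistent only when every incoming regulation is:
  *J*ᵢ(*v*) = ∏ₑ∈N⁻(v) *I*ᵢ(*e*). The **global inconsistency load** is
  Σᵥ |*J*(*v*)|₁, the total number of (target, contrast) inconsistencies.
  A binary up/down variant is included for comparison.
* **Degree-preserving null models.** Expression-profile shuffling
  (Fisher–Yates over whole vertex profiles) and double-edge-swap rewiring
  (10·|E| attempts, signs travel with the regulator stub) give null
  distributions of the load with every vertex degree held fixed.
* **Correlation analyses.** Pearson or Spearman correlation of TF and
  target expression profiles for known interactions, stratified by sign
  and by single-regulator targets, against the all-pairs background.
* **Synthetic studies.** A generator of signed networks (heavy-tailed
  out-degrees, TUs, TF complexes) and compendia (reference + case
  experiments, perturbations, knockouts) under three regimes — `causal`,
  `decoupled`, `confounded` — so every pipeline stage is testable without
  external downloads.

Networks are read from RegulonDB-style exports (`dialect = "regulondb"`,
with dual/unknown-effect filtering and TU/complex annotations) or a plain
3-column TSV (`dialect = "simple"`). TU vertices aggregate member genes by
per-sample mean, TF complexes by per-sample minimum.

## Worked example

```r
library(signcon)

st  <- simulate_study(sim_config(seed = 7))          # causal regime
st$network
#> Signed regulatory network: 50 regulators (5 complexes), 200 targets (40 TUs), 600 interactions
#>   activation: 348, repression: 252

vex <- vertex_expression(st$compendium, st$network)
cs  <- compute_contrasts(vex, st$compendium$sample_meta)
t   <- select_threshold(cs)                          # 0.665 here: half the
                                                     # contrast values changed
model <- sign_model_config(t)
res <- evaluate_consistency(st$network, label_vertices(cs, model), model)
res
#> Sign-consistency evaluation (ternary model): 600 edges, 196 targets, 100 contrasts
#>   global inconsistency load: 540

null_distribution(st$network, cs, model, "rewire_edges",
                  repetitions = 10, seed = 3)
#> Null model (rewire_edges, 10 repetitions)
#>   observed load: 540
#>   null loads: median 838.0, mean 841.8, range [799, 888]
#>   empirical p (null <= observed): 0

interaction_correlations(st$network, vex)$strata[1:3, ]
#>     stratum   n n_missing      mean_r
#>   all_known 600         0  0.07533944
#>  activation 348         0  0.49216498
#>  repression 252         0 -0.50027679
```

Because this study is causal, the observed load (540) sits far below every
rewired-null load: randomizing the topology destroys real explanatory
structure. Activator pairs correlate positively, repressor pairs
negatively. In the `decoupled` regime the observed load lands inside the
null distributions and the correlations vanish; in the `confounded` regime
both strata turn positive — the fingerprints the analysis is built to
distinguish.

`run_pipeline()` executes all of the above (from files or a simulation
config) and writes per-edge/per-target/per-contrast TSVs, a JSON summary
and a run manifest; `inst/scripts/signcon-run.R` wraps it for shell use.
Runs are byte-reproducible under a fixed seed.

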