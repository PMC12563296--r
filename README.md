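# dama

Community detection on static undirected graphs via dynamic
propagation-aware feature modeling, for researchers studying modular
structure in networks — protein-interaction and co-expression modules,
citation topics, social circles — who want a detector that models *how
information flows* over a static topology instead of reading raw adjacency
alone.

## The method

Three stages, trained end to end as a transductive node classifier:

1. **Influence matrices.** A potential-based influence matrix scores node
   pairs by neighborhood overlap damped by distance,
   `p_ij = |Γ(v_i) ∩ Γ(v_j)| · exp(−λ d_ij)` (λ = 0.3), and is blended with
   the adjacency into an information flow matrix `IFM = βP + γA`. Since a
   nonzero entry requires a common neighbor, P is supported on distances ≤ 2
   and is computed exactly from A².
2. **Adaptive sparse sampling.** Per node, hop layers Γ⁽¹⁾…Γ⁽ᴷ⁾ (K = 3) are
   grown under a dynamic threshold `r⁽ᵏ⁾ = μ · AVG{a_jh}` over the
   frontier's incident intensities; neighbors reached only through weak
   intensities are pruned (μ = 1 by default), and expansion stops early when
   the layer mean intensity stagnates below ε.
3. **Multi-hop gated attention.** Per hop, multi-head attention with a
   learnable distance decay `Φ(d) = exp(−λd)` aggregates the retained
   members into layer-normalized hop embeddings; a dual gate — a per-node
   softmax prior over hop levels from `[deg v_i, max m_i]`, modulated by a
   batch-statistics feedback gate `tanh(W_f · Std(H_batch))` — fuses the
   hops, and an MLP classifies. The loss is cross-entropy plus an L1
   sparsity penalty κ on the final gates.

The package also provides planted-partition and LFR-style benchmark
generators with a statistics-matching calibrator, five noise-injection
modes (random/heterophilic edges, delete-and-add, label corruption,
combined), ablation switches for each stage (`no_ifm`, `no_ass`, `no_msg`),
and the repeat-and-aggregate evaluation protocol (accuracy, NMI, macro-F1,
ARI, modularity). Attention kernels are compiled (Rcpp); all gradients are
analytic and finite-difference-checked in the tests.

## A worked example

```r
library(dama)

g     <- generate_planted_partition(c(40, 40), p_in = 0.5, p_out = 0.02, seed = 1)
icfg  <- influence_config()                  # λ = 0.3, β = γ = 0.5
ifm   <- build_ifm(build_pim(g, icfg), g, icfg)
nb    <- sample_all(g, ifm, sampling_config())  # μ = 1, K = 3, ε = 1e-3
masks <- make_split(g$n_nodes, seed = 1)        # 80/20 transductive split
fit   <- train_dama(g, ifm, nb, masks, model_config(), train_config(), seed = 1)
str(evaluate_fit(fit, g, masks)[1:5])
#> List of 5
#>  $ accuracy  : num 1
#>  $ nmi       : num 1
#>  $ f1_macro  : num 1
#>  $ ari       : num 1
#>  $ modularity: num 0.456
```

The two planted blocks are recovered perfectly on the held-out 20% within
the fixed 200 epochs; the modularity line scores the *predicted* partition
of the whole graph, which here approaches the ground-truth partition's own
modularity for this edge density (cross-block edges cap it well below the
0.5 of two disjoint cliques).

YAML-driven runs and a thin CLI are included: see `read_run_config()` /
`run_pipeline()` and `inst/cli/dama.R`
(`generate | perturb | sparsify | train | evaluate | sweep | ablate`).

## Package layout

- `R/graph.R` — graph container, edge-list / citation-bundle / GML I/O,
  BFS distances, statistics, modularity
- `R/influence.R` — potential-based influence and information-flow matrices
- `R/sampling.R` — adaptive sparse neighborhood sampling
- `R/features.R` — structural + random-code + spectral node features
- `R/model.R`, `src/attention.cpp` — the gated multi-hop attention network
  and its compiled kernels
- `R/train.R`, `R/metrics.R` — transductive protocol, metrics, experiments
- `R/synthetic.R` — planted partitions, LFR generation/calibration, noise
- `R/pipeline.R`, `inst/cli/dama.R` — orchestration, YAML configs, CLI
- `vignettes/propagation-aware-community-detection.Rmd` — model, defaults,
  design decisions, limitations
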