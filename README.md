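# mirmod

MicroRNAs (miRNAs) regulate gene expression post-transcriptionally, and
panels of co-operating miRNAs are promising diagnostic biomarkers. Picking
such a panel from an expression study is hard: single-feature rankings
ignore how miRNAs work together, and expression data alone say nothing
about shared disease biology. `mirmod` addresses this for analysts working
with miRNA expression matrices (features × samples, two or three sample
groups) plus curated miRNA–disease relation tables: it finds small,
connected **miRNA modules** that discriminate the sample groups, and
combines them into a weighted-voting classifier.

## Method

The pipeline has three stages.

**1. Two network views, fused.** For every feature pair *(fᵢ, fⱼ)* the
*cooperative-regulation network* G_CR weights the edge by
−log *p* of a two-sided Mann–Whitney U test (Kruskal–Wallis for ≥3
groups) applied to the *combination feature* fᵢ − fⱼ — the pairwise
relative expression whose group-wise dysregulation signals a change in
co-regulation. The *functional-similarity network* G_FS weights the same
edge by the similarity of the two miRNAs' regulated-disease sets: disease
terms are embedded as vectors (any provider; a file-backed table and a
deterministic mock ship with the package), all pairwise cosines form a
p × q matrix M_D, and a weighted best-matching average aggregates it,

  sim(fᵢ, fⱼ) = [ Σᵤ Σᵥ η_uv · sim(b_u, b_v) + Σᵥ Σᵤ ξ_vu · sim(b_v, b_u) ] / (p + q),

with softmax weights η, ξ built from exp(|sim|) row- and column-wise. Both
views are min–max normalized and averaged edge-wise; the fused complete
graph is sparsified to its maximum spanning tree plus each node's *k*
strongest fused edges, *k* ∈ {3, 5, 7, 9} chosen by the best R² of the
log–log degree-frequency regression (power-law fit).

**2. Q-learning module search.** Seeds are the *g* features with the
highest comprehensive importance I = (I_e + I_t)/2 (min–max-normalized
single-feature test significance and closeness centrality). From each
seed an agent grows a node set over the sparse network; adding a node
earns reward R = AUC(S) × (1 + √(1/|S|)) — classification performance
times a size factor favouring small modules — and updates a tabular
Q-value toward R + γ·max Q(next). Exploration follows an ε-greedy policy
with ε = ε_f^(e/K) decaying over episodes. After training, a greedy walk
over the Q-table extracts one module per seed, stopping at AUC 1.000, a
revisited member, no positive-Q action, or the size limit.

**3. Weighted-voting ensemble.** One linear-kernel SVM per module
(unit-variance scaling learned on training data); voting weights are the
modules' inner 5-fold CV AUCs normalized to sum to one. Evaluation is
repeated stratified cross-validation in which networks, seeds, search and
classifiers are all re-fitted inside each training fold.

## Worked example

Everything below runs offline on the package's synthetic generator, which
plants a 5-member differential module (members `mir001`–`mir005`) in a
30 × 40 two-class matrix and gives those members overlapping disease
annotations:

```r
library(mirmod)

d    <- simulate_dataset(synth_spec(seed = 1))
prov <- table_embedding_provider(d$embeddings)
g_cr <- build_coop_network(d$expression)
g_fs <- build_functional_network(features(d$expression), d$relations, prov)
fn   <- build_fused_network(g_cr, g_fs)
fn
#> <fused_network> 30 nodes; k = 5; sparse edges = 121 (tree 29)

cfg  <- rl_config(episodes = 75, size_limit = 3, auc_mode = "cv5", seed = 1)
mods <- identify_modules(d$expression, fn, cfg)
mods
#> <mirna_modules> 5 modules
#>   1. seed 'mir005' (3 members, AUC 0.975): mir005, mir026, mir015
#>   2. seed 'mir004' (3 members, AUC 0.950): mir004, mir006, mir001
#>   3. seed 'mir003' (3 members, AUC 0.950): mir003, mir001, mir016
#>   4. seed 'mir002' (3 members, AUC 0.975): mir002, mir005, mir010
#>   5. seed 'mir001' (3 members, AUC 0.975): mir001, mir005, mir030
```

All five planted features are recovered as seeds; each module's AUC is
its stratified inner 5-fold estimate. The ensemble and the honest
held-out evaluation:

```r
ens <- fit_ensemble(d$expression, mods)
tidy(ens)
#> # A tibble: 5 × 4
#>   module n_features inner_auc weight
#>    <int>      <int>     <dbl>  <dbl>
#> 1      1          3     0.975  0.202
#> 2      2          3     0.95   0.197
#> 3      3          3     0.95   0.197
#> 4      4          3     0.975  0.202
#> 5      5          3     0.975  0.202

rep <- cross_validate(d$expression, d$relations, prov, cfg, repeats = 3, folds = 5)
glance(rep)
#> # A tibble: 1 × 6
#>   n_folds_total mean_auc sd_auc mean_sensitivity mean_specificity mean_mcc
#>           <int>    <dbl>  <dbl>            <dbl>            <dbl>    <dbl>
#> 1            15    0.996 0.0161            0.967            0.967    0.937
```

A mean held-out AUC of 0.996 with sensitivity/specificity near 0.97 says
the planted signal is found and generalizes across folds; weights near
0.2 say the five modules contribute almost equally. `autoplot(fn)`,
`autoplot(fn$sparse, highlight = ...)` and `autoplot(rep)` draw the
degree fit, the network and the per-repeat AUC spread.

A command-line front end wraps the same functions
(`inst/cli/mirmod.R`; subcommands `simulate`, `build-network`,
`identify`, `evaluate`, `predict`), driven by flags or a YAML/JSON
config; every run writes a manifest with the configuration hash and seed.

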