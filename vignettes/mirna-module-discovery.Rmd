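---
title: "Module biomarker discovery from fused miRNA networks: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module biomarker discovery from fused miRNA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmod)
```

This vignette is the package's own account of the science it implements:
the two network views and their fusion, the Q-learning module search, the
ensemble classifier, the synthetic data the tests rely on, and — most
importantly — where the design was genuinely open and what we chose.

## The two network views

### Cooperative regulation from expression

For features $f_i, f_j$ the *combination feature* $f_{ij} = f_i - f_j$
captures their relative expression. If the distribution of $f_{ij}$
differs between sample groups, the pair's co-regulation is dysregulated
in disease, and the edge $(f_i, f_j)$ receives weight
$w = -\log p_{ij}$ from a two-sided Mann–Whitney U test (Kruskal–Wallis
for three or more groups) on $f_{ij}$.

Numerical choices:

* **Log base.** Natural log. Any fixed base rescales all weights by a
  constant, which the subsequent min–max normalization removes, so the
  choice is inconsequential; we document it rather than expose a knob.
* **Exact vs. approximate test.** Exact enumeration when both groups
  have at most 8 samples and the difference vector is tie-free;
  otherwise the normal approximation with tie correction and no
  continuity correction. The tests pin this against an independent
  pair-counting U-statistic oracle to $10^{-9}$.
* **Degenerate input.** A difference vector constant across samples
  carries no information: $p = 1$, weight 0 — not an error, because two
  identical features are legitimate data.
* **Floor.** $p$ is floored at $10^{-16}$, capping weights at
  $-\log 10^{-16} \approx 36.8$ so they stay finite.
* **Expression scale.** Values are consumed as provided. Whether the
  source data were log-transformed is upstream of this package;
  differences of log values are log fold changes, which is the natural
  reading of "relative expression", but no transform is forced.

### Functional similarity from disease relations

MiRNAs regulating similar disease sets are functionally similar. Disease
terms are embedded as numeric vectors by an injected
`embedding_provider`; the package ships a file-backed provider (for
tables exported from a biomedical language model or any other source)
and a deterministic hash-based mock, so no model download is ever
required. Embeddings are looked up once per distinct term per network
build.

Given embedded sets $B_i$ ($p$ terms) and $B_j$ ($q$ terms), the cosine
matrix $M_D$ is aggregated by a *weighted best-matching average*: softmax
weights over $\exp(|\mathrm{sim}|)$ are formed along rows and along
columns, each weighted similarity sum is taken, and the total is divided
by $p + q$. The absolute value appears only inside the weights, not in
the averaged similarities; we implement the formula as stated and verify
it against a naive double-loop oracle to $10^{-12}$. Note the weights
make the average lean toward each term's best match, so two sets sharing
their strongest terms score high even if their remaining terms differ.

Open points we decided:

* **Features without relations** get similarity 0 on all their edges;
  their fused weight then comes entirely from the expression view. This
  is the least-assumption fallback and degrades gracefully to an
  expression-only analysis when the relation table is empty.
* **Negative similarities** are possible for arbitrary embeddings. Edge
  weights are clamped at 0 after aggregation so min–max fusion stays
  monotone; the unclamped values remain available
  (`attr(g, "raw")`) for inspection.
* **Term canonicalization** (trim, case-fold, collapse whitespace)
  happens before embedding, so cosmetic variants of a disease name share
  one vector.

### Fusion and sparsification

Each view is min–max normalized over its *full* edge set (globally, not
per node — per-node scaling would break edge-weight comparability across
the graph), and the fused weight is the per-edge mean, hence in
$[0, 1]$. The complete fused graph is then reduced to its maximum
spanning tree — guaranteeing connectivity — united with each node's $k$
strongest fused edges.

$k$ is selected from $\{3, 5, 7, 9\}$ by fitting
$\log(\text{frequency})$ against $\log(\text{degree})$ over the degree
histogram of each candidate graph and scoring by $R^2$; the best-fitting
(most scale-free-like) candidate wins, ties to the smallest $k$. The
power-law criterion could equally be fit to the complementary CDF; we
chose frequency regression as the simplest defensible statistic and log
the per-candidate scores in the `k_selection.json` sidecar so the choice
is auditable. All tie-breaks in the tree and the k-nearest lists are
lexicographic by feature id, making the sparse network a pure function
of its inputs.

## Q-learning module search

Seeds are the $g$ nodes maximizing the comprehensive importance
$I = (I_e + I_t)/2$, where $I_e$ is the min–max-normalized $-\log p$ of
the single-feature group test and $I_t$ the min–max-normalized closeness
centrality in the unweighted sparse network.

Per seed, `episodes` training episodes are run. The visited set restarts
at the seed each episode; the action space is the set of sparse-graph
neighbours of any visited node minus the visited nodes; actions are
ε-greedy with $\varepsilon = \varepsilon_f^{e/K}$; each added node earns
$R = \mathrm{AUC}(S) \times (1 + \sqrt{1/|S|})$ and updates
$Q(f_s, f_a) \mathrel{+}= \alpha (R + \gamma \max_a Q(f_a, a) - Q(f_s, f_a))$,
with the max over an empty action space defined as 0. An episode stops
at AUC 1.000, at the size limit, or when the action space empties.
Extraction is the greedy ($\varepsilon = 0$) walk over the learned
Q-table, stopping at AUC 1.000, a revisited member, no positive-Q
action, or the size limit.

Design decisions worth spelling out:

* **Episode reset.** A literal reading of the pseudocode initializes the
  visited set once, before the episode loop, which would make it grow
  monotonically across episodes and stall after the first. We
  re-initialize at each episode start — standard episodic Q-learning —
  and exclude visited nodes from the action space within an episode so
  termination conditions can actually trigger.
* **Deterministic extraction.** Reproducible biomarkers require a
  deterministic read-out, so extraction is greedy rather than
  exploratory; all remaining stochasticity sits in training and is owned
  by one seed.
* **AUC inside the loop.** Module AUC during search is either a
  deterministic stratified inner 5-fold CV (`cv5`, the default — folds
  are assigned round-robin per class precisely so that memoization and
  the RNG stream stay decoupled) or resubstitution (`resub`, one SVM fit
  instead of five, optimistic). AUC values are memoized per node set.

### Reward accumulation and the scale of the search

One property of the reward design deserves emphasis because it drives
how the parameters must scale. Reward accrues at *every* step, and an
episode ends at AUC 1.000 — so with $\gamma = 0.8$ a long walk through
mediocre additions can accumulate more discounted reward than a short
path that completes a perfect module. If the size limit $L$ is a large
fraction of the network, nearly every episode runs to the limit and the
Q-table learns to *avoid* quickly-terminating, high-quality paths. The
reference configuration ($K = 2000$ episodes, $L = 50$) serves networks
of roughly 800 features, i.e. ~2.5 episodes per feature and a limit of
~6% of the nodes — a regime where perfect-AUC termination is reached
early and the pathology does not bite.

We therefore scale both parameters with network size. For the 30-feature
synthetic problems used throughout the tests and the acceptance script:
$K = \lceil 2.5 m \rceil = 75$ episodes and
$L = \max(3, \lceil 0.1 m \rceil) = 3$, with `cv5` scoring. These sizes
were also chosen to keep the full test suite and the acceptance script
comfortably within a desktop-scale run. The package defaults remain the
reference settings ($\alpha = 0.2$, $\gamma = 0.8$, $K = 2000$,
$\varepsilon_f = 10^{-5}$, $L = 50$, $g = 5$, $k \in \{3,5,7,9\}$).

The same property shaped the toy environment
(`toy_rl_environment()`): its optimum $\{b, c\}$ has AUC 1.0 (episode
terminates immediately on reaching it) while every other multi-node set
has AUC 0.3, so the single large terminal reward beats any accumulated
chain of small ones and the optimal policy is exactly recoverable by
value reasoning — which the tests exploit.

## Ensemble and evaluation

One linear-kernel SVM per module (regularization constant 1 — the usual
default; configurable), fitted on unit-variance-scaled training data
with scaling parameters stored from the training samples only. Voting
weights are the modules' inner 5-fold CV AUCs normalized **to sum to
one**; we read "normalized average AUCs" this way rather than as min–max
normalization, which would zero out the worst module entirely (min–max
remains available via `weight_scheme = "minmax"`). Per-classifier
decision scores are mapped monotonically to $[0, 1]$ by the min–max
range of the training decision scores before voting, a minimal
calibration that preserves each classifier's ranking.

`cross_validate()` runs repeated stratified CV in which *everything*
downstream of the (label-free) relation table — cooperative network,
fusion, seed importance, Q-learning, classifiers, voting weights, the
operating threshold — is re-fitted inside each training fold; the tests
assert that perturbing held-out samples leaves the fitted fold models
bit-identical. Whether one may instead build the networks once on all
data is a fair replication question; the leak-free protocol is the
defensible default and the per-fold fits can be audited via
`keep_fits = TRUE`. Sensitivity and specificity are reported at the
Youden-optimal threshold of the *training* ROC (argmax voting for three
classes), AUC as macro one-vs-rest beyond two classes, plus the Matthews
correlation coefficient.

## Synthetic data: what it emulates, and what not

`synth_spec()` defaults describe the study condition used across the
tests: $m = 30$ features, 20 samples per class, two classes, one planted
module of five features with effect size $\delta = 2$, disease overlap
$\rho = 0.8$, residual SD 1 — a desk-scale version of the
hundreds-of-features, tens-of-samples microarray shape this method
targets.

Planted members receive class-specific mean shifts
$c \cdot \delta \cdot \mathrm{mult}_r$ with member multipliers evenly
spaced in $[0.5, 1.5]$. The multipliers matter: if every member shifted
identically, the members' pairwise differences would cancel exactly and
the within-module cooperative-regulation signal — the very thing the
combination feature is designed to detect — would vanish. Distinct
multipliers give both individual signals and member–member difference
signals, which is the biologically intended reading of dysregulated
co-regulation. Each planted module draws a shared fraction $\rho$ of its
disease terms from one disease "family"; embeddings are unit-normalized
family centres plus small isotropic noise, so intra-family similarity
dominates and the best-matching average has a real gradient.

What the generator does **not** emulate: count-distribution noise,
platform or batch effects, correlated backgrounds, missing values, or
realistic disease-ontology structure. Passing tests therefore show the
machinery is correct and recovers signal under clean planted conditions
— not that the method will perform at any particular level on real
cohorts.

## Known limitations

* The functional view is only as good as the relation table; features
  missing from it silently degrade to expression-only evidence.
* The reward/termination interaction described above means module
  quality depends on sensible $K$ and $L$ scaling; there is no automatic
  rule beyond the proportional heuristic documented here.
* Cooperative-network construction is $O(m^2)$ rank tests per fold;
  repeated CV at thousands of features is feasible but not interactive.
* The per-module classifier is deliberately fixed (linear SVM, cost 1);
  the package does no hyperparameter search.
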