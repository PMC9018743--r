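---
title: "Stratifying drugs by reconstructed signaling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying drugs by reconstructed signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugnetstrat)
```

## The modeling problem

A drug perturbation experiment measures a thin slice of the cell: a few
hundred landmark transcripts with replicates, a phosphosite panel, and a
curated set of direct targets. The proteins implicated by these read-outs
are scattered across the interactome, and the mechanistic story — which
pathways the drug actually modulates — lives in the connections *between*
them. `drugnetstrat` treats network reconstruction as a prize-collecting
Steiner forest (PCSF) problem: implicated proteins carry prizes, interactome
edges carry costs, and the optimal forest buys cheap, high-confidence paths
that collect expensive prizes, recruiting intermediate ("Steiner") proteins
that no single assay measured. Comparing the reconstructed networks then
becomes a topology problem on the shared interactome.

## Terminal prizes

For one (cell line, drug) condition:

* **Differential expression.** Each gene's treated and control replicates
  are compared with a one-way ANOVA. With two groups the F statistic is the
  squared pooled-variance t, so the implementation computes the closed form
  directly and `stats::pf` supplies the tail. The log2 fold change is taken
  on arm means (`log2(mean treated) − log2(mean control)`), matching the
  convention of averaging transcription values before the ratio. Genes below
  the significance level `alpha` (default 0.05, configurable; no
  multiple-testing correction — the raw threshold is a deliberate part of
  the procedure) form the "significantly transcribed" list.
* **Transcription factors.** A TF from the regulatory network becomes a
  terminal iff it regulates at least 3 significant genes. Its prize is the
  mean *absolute* log2 fold change of those significant targets: prizes must
  be non-negative for the prize function to be meaningful, and sign-free
  magnitude is the natural importance measure.
* **Phosphoproteins.** Sites passing p < 0.05 promote their protein to a
  terminal; multiple significant sites collapse to the maximum |fold
  change| (the strongest site speaks for the protein).
* **Assembly.** Phospho evidence wins conflicts with TF evidence
  (proteomic read-outs are more direct). Drug targets are appended with a
  uniform prize set to the mean of the omics-derived prizes — a neutral
  choice that keeps targets competitive without letting them dominate.
  A condition with no omics-derived terminal at all cannot orient a
  reconstruction and is reported as dropped, mirroring how sparse seed
  lists force conditions out of real studies.

## Interactome refinement

The reference interactome is an undirected graph with confidence weights
`w(e) ∈ (0,1]`; the solver sees costs `c(e) = 1 − w(e)`. Refinement runs in
a fixed order:

1. **Hub removal** — nodes with degree > 900 *and* more than 10 SD above
   the mean degree lose all incident edges. The conjunction matters: either
   clause alone would bite on graphs where it should not.
2. **Expression filter** — edges with an endpoint whose condition
   expression is below 2.0 (on the 0–15 fluorescence scale) are removed;
   unmeasured proteins are kept, absence of evidence not being evidence of
   absence.
3. **Link prediction** — Adamic/Adar scores over non-adjacent pairs with a
   common neighbor, natural logarithm (the usual reading of the unqualified
   "log"; a degree-1 common neighbor is impossible, so the 1/ln term is
   always finite). The top `|E(processed)|` pairs are kept, ties broken
   lexicographically for determinism, *then* localization-filtered — the
   selection-before-filtering order follows the stated procedure.
4. **Localization filter** — a prediction survives if the proteins share a
   compartment or either is unannotated.
5. **Augmentation** — surviving scores are min–max scaled onto [0, 0.5] and
   appended as `origin = "predicted"` edges. Predicted edges therefore cost
   at least 0.5 and act as a last resort, which is why they end up as a
   small fraction of reconstructed networks; a weight-0 prediction (the
   scaling minimum) is retained at cost 1 rather than discarded, since all
   filtered predictions are appended. A single surviving prediction maps to
   0.5.

## The PCSF engine

Prizes are generalized to `p′(v) = β·p(v) − μ·degree(v)`; non-terminals
have `p(v) = 0`, so μ > 0 taxes hub inclusion. The objective implemented is

```
f′(F) = Σ_{v∉F, p′>0} p′(v)  +  Σ_{v∈F} max(−p′(v), 0)  +  Σ_{e∈F} c(e)  +  ω·κ.
```

Relative to summing *all* excluded prizes this differs by the constant
Σ min(p′, 0) over the whole graph, so the minimizers are identical, but the
form above is non-negative and makes the hub tax on included Steiner nodes
explicit. (Restricting the excluded sum to positive prizes *without* adding
the included-node penalty would silently delete the hub tax — that variant
is not a constant shift.)

The solver is a deterministic root-attached cheapest-path heuristic: a
virtual root connects to every positive-prize terminal at cost ω; terminals
are processed in a fixed order and either attached to the growing forest
along the cheapest cost-plus-hub-penalty path (path search uses edge cost
plus half the endpoint hub penalties; the actual increment is re-evaluated
exactly), opened as a new tree when ω is cheaper, or skipped; node depth
from the root is capped at `D` (default 10). Strong pruning then removes
every subtree whose collected prize cannot pay its connection cost and
closes trees that cannot pay their ω. Greedy growth is order-sensitive, so
the solver tries several deterministic orderings (descending and ascending
prize, plus seeding from each of the top three terminals) and keeps the
best objective; the result is never worse than the empty forest. On
randomized 8-node instances the heuristic matches an exact
subset-enumeration oracle (`brute_force_pcsf`, ≤ 12 nodes; for a fixed node
set the optimal forest is the minimum spanning forest with every MST edge
costing ≥ ω traded for an extra tree) in ~90% of cases and never scores
below it.

The parameter grid defaults to μ ∈ {0, 0.01, 0.1}, β ∈ {2, 5, 10},
ω ∈ {1, 2, 3}, D = 10 — a desk-scale subset of the full tuning grid (the
201-value μ sweep is available by passing explicit vectors). Among grid
solutions the selection is lexicographic: most terminals, then fewest
included hubs (interactome degree > 100); all tied solutions are merged by
node/edge union into the final condition network, with node roles
(terminal_tf / terminal_phospho / drug_target / steiner) and edge origins
annotated.

## Comparing networks

The separation score `s_AB = ⟨d_AB⟩ − (⟨d_AA⟩+⟨d_BB⟩)/2` uses unweighted
hop distances on the reference interactome (the standard network-medicine
convention; weighted variants change magnitudes but not the
overlapping-vs-separated contrast). `⟨d_AB⟩` averages each node's distance
to the nearest node of the other network over both directions, with shared
proteins contributing 0 — this symmetric form guarantees `s_AB = s_BA`.
Within-set means use the nearest *other* member; a singleton set
contributes 0. Unreachable nodes are dropped from means with a warning
(the finite alternative to infinite distances); if nothing is reachable the
pair is recorded as missing. Matrices carry the four comparison classes
(T1–T4: same/different cell line × same/different MoA) and are clustered
with average linkage on Euclidean row distances, missing entries imputed at
the matrix maximum.

Overlap significance is the inclusive upper-tail hypergeometric
`P(X ≥ x)` with population = interactome size, successes = larger network,
draws = smaller network. Pathway enrichment uses the same tail against the
gene-set collection (default background: the interactome node set, the
natural universe when queries are interactome subgraphs), raw p < 0.05 —
deliberately the plain hypergeometric rather than an EASE-style adjusted
score, and deliberately uncorrected. The "signaling" substring filter on
shared pathways is configurable.

## Drug evaluation

Pairs are pooled **within cell lines** for the MoA benchmark: the reported
6217 benchmark pairs equal Σ C(n_c, 2) over the five cell-line network
counts, which identifies the pooling unambiguously (an `all` option exists).
A pair is called "similar" when `s_AB` falls strictly below the threshold;
sweeping thresholds yields ROC/PR curves, trapezoidal AUC and the MCC-best
threshold (ties to the smaller, more conservative threshold). MCC with an
empty marginal is defined as 0. The combination rating follows complementary
exposure: separated (s > 0), fewer than two shared enriched signaling
pathways, both networks > 40 nodes, one > 100; the driver rule additionally
requires ≥ 1 shared cancer driver with s > 0 ("topologically disjoint
region" is operationalized as the same s > 0 criterion the rating uses).
The sensitivity analysis keeps pairs with one negative and one positive
z-score and `s_AB > −0.45`, then reports the Pearson correlation of `s_AB`
against |Δz|; the absolute difference is used since the sign convention of
"z-score differences" is arbitrary. Resistant-side conditions are not
modeled — only drugs to which a cell line is sensitive are interpreted.

## What the synthetic cohort emulates

The generator plants a known truth so every stage is testable offline:

* **Interactome** — preferential-attachment backbone (heavy-tailed degrees,
  so the hub machinery has something to bite on at reduced thresholds) with
  `n_pathway_modules` densified high-confidence modules arranged on a ring;
  adjacent modules get a few bridge edges (pathway cross-talk). Weights:
  modules 0.75–1, bridges 0.5–0.9, backbone 0.3–0.9.
* **Conditions** — 2 cell lines × 8 drugs, 4 MoA classes owning two
  adjacent modules each; every drug perturbs its class's modules. Control
  replicates are baseline + Gaussian noise on [0, 15] (the scale that makes
  the 2.0 expression filter meaningful); treated replicates shift planted
  genes by `effect_size` (default 3.0 vs noise 1.0, a strong but not
  saturating perturbation: per-gene ANOVA power ≈ 0.9 at n = 3) with random
  sign, clamped to the range. A dedicated DMSO-style control arm exists per
  condition.
* **Annotations** — TFs are module members regulating ~6 module genes plus
  2 background genes; phospho tables cover 40% of perturbed module proteins
  plus matched background with z-test p-values (uniform under the null);
  drug targets are module members; localization follows modules with a 15%
  unannotated fraction, exercising the unknown-kept rules.
* **Sensitivity** — each cell line owns a driver module; a drug's z-score
  rises with the ring distance between its modules and the driver
  (z ≈ −2.5 + 1.2·distance + noise), so sensitivity is graded and
  mechanistically coupled to network position rather than binary.

What it does **not** emulate: inference of non-landmark genes from landmark
measurements, time-course structure, chromatin read-outs, and the dense
terminal-set overlap of real drug panels. That last point matters for one
qualitative contrast: in the real data most terminal sets share proteins,
so seed-only separation scores sit mostly in the negative range and
reconstruction shifts the distribution; here different-MoA terminal sets
are disjoint by construction, so only the same-MoA part of that contrast is
meaningful (and holds: same-MoA seed-only scores are negative and stay
negative after reconstruction). Passing tests therefore demonstrate the
machinery recovers planted structure under realistic noise, not that real
panels will show any particular effect size.

## Numerical choices and edge cases

* Degenerate ANOVA genes (zero within-group variance): p = 1 when means
  agree, p = 0 (flagged) when they differ; arm means are floored at 1e-9
  before log2.
* Path search floors effective edge weights at 1e-12 (a weight-1 edge has
  cost 0; Dijkstra needs non-negatives, exact zero is fine but the floor
  guards accumulated ties).
* Objective/oracle comparisons use a 1e-9 tolerance; oracle ties break by
  fewer edges, then the lexicographically smallest node set.
* Duplicate interactome records collapse to the highest confidence;
  duplicate predicted edges are skipped with a warning.
* All tie-breaks (AA top-k, terminal order, leaf order) are lexicographic,
  making every stage deterministic given the seed.

## Problem sizes

The shipped defaults (300 proteins, 8×15 modules, 16 conditions, 27-point
grid) run the full pipeline in well under a minute and were chosen so the
whole test suite, including the exact-oracle comparisons and the end-to-end
recovery checks, completes in a few minutes; every stage scales to larger
configurations through `cohort_config()` and the grid arguments.

## Known limitations

The solver is a heuristic — optimality is verified only against small exact
instances; message-passing or LP-based PCSF engines may find better forests
on large instances. Enrichment uses the plain hypergeometric tail rather
than DAVID's EASE-adjusted score. The MoA benchmark treats class labels as
exact ground truth, though drugs genuinely straddle mechanisms. The
combination rating thresholds (40/100 nodes, 2 pathways) are taken as given
and are scale-sensitive: on small synthetic networks they rarely trigger,
and the rule is validated on constructed cases instead.
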