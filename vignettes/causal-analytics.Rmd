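---
title: "Causal analytics on signed networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal analytics on signed networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalnets)
```

This vignette is the package's own account of the statistics it computes:
what the models assume, which tunable parameters matter, what the
synthetic benchmarks do and do not establish, and where the design was
genuinely open and a choice had to be made.

## The data model

The master object is a directed multigraph of molecules (genes, chemicals,
protein families, complexes, microRNAs) and biological processes. Edges
carry a type — `T` (transcription/expression; always into a gene), `A`
(functional activation/inhibition), `P` (process regulation; always into a
process), `B` (protein binding; direction-free, sign 0) — a causal sign in
{−1, 0, +1}, and a confidence weight in [0, 1]. Two nodes may be joined by
a `T` and an `A` edge at once, but never by two edges of the same type:
parallel raw records are merged at load time.

When an edge is backed by individual curated findings, its sign is decided
by **strict majority vote** among the nonzero finding signs and its weight
is the majority fraction (`aggregate_findings()`). A tie, or findings that
are all direction-free, yields sign 0 and weight 0. This rule is monotone
(more agreeing findings never weaken the edge), bounded in [0, 1], and
gives the weight a direct reading as confidence in the assigned direction.
It is one of the genuinely open corners of the method — there is no single
canonical aggregation — and the rest of the package depends on it only
through the (sign, weight) pair, so a user with a different rule can
supply pre-aggregated edges instead.

A dataset is a set of genes with signs ±1. Expression magnitudes are
deliberately discarded after thresholding (`load_dataset()`): the
statistics treat "how much" as a property of the upstream measurement
pipeline, not of the causal match. Genes absent from the network are
dropped with a warning before any analysis (`restrict_to_network()`).

## Upstream Regulator Analysis

Two scores answer two independent questions.

**Overlap p-value.** Whether a regulator's transcriptional target set
over-represents the dataset, under a null of datasets drawn uniformly at
fixed size from the universe of genes carrying at least one `T` edge. This
is the one-sided hypergeometric tail, computed with `phyper`. Sign-0
protein–DNA-binding edges count here: an edge whose direction is unknown
is still evidence of regulation.

**Activation Z-score.** Whether the up/down pattern matches the directions
the edges predict: z = Σwᵢxᵢ/√(Σwᵢ²), with xᵢ the product of edge sign and
dataset sign over the *signed* overlap edges. Under independent fair sign
flips each term has mean 0 and variance 1, so z is asymptotically standard
normal; the suite verifies empirically that |mean| < 0.05 and variance ∈
[0.9, 1.1] for overlaps of 30+ genes. Zero-weight edges are excluded
together with sign-0 edges: a term with w = 0 contributes nothing to either
sum, so this is an algebraic no-op that avoids a degenerate √0 when all
overlap weights vanish.

The sign-flipping null is only appropriate when neither the dataset signs
nor the regulator's edge signs are skewed. Both biases are summarized by
μ = d_D·d_R, the product of the mean dataset sign (over all dataset genes)
and the mean edge sign (over the regulator's signed target edges — sign-0
edges never enter z, so they are excluded from d_R as well). When |μ|
exceeds `mu_threshold` the regulator is flagged, and the bias-corrected
score

z_c = (Σwᵢxᵢ − μΣwᵢ) / √((1 − μ²)Σwᵢ²)

standardizes against the skewed null E[x] = μ, Var[x] = 1 − μ². At μ = 0
it reduces exactly to z. The acceptance suite checks the correction
empirically: under an 80%-up null an all-activating regulator has mean
plain z ≈ 3.8 but mean corrected z within ±0.1 of zero. μ = ±1 is rejected
as degenerate (zero null variance).

Parameters, with defaults and units:

| parameter      | default | meaning |
|----------------|---------|---------|
| `z_threshold`  | 2.0     | \|z\| needed to call activated/inhibited; ≈ two-sided 5% under the normal null |
| `mu_threshold` | 0.25    | \|μ\| above which the plain z is flagged as untrustworthy |
| `fc_cutoff`    | 1.0     | \|log-fold-change\| for dataset inclusion |
| `p_cutoff`     | none    | optional p-value gate on the input table |

Regulators whose own gene appears in the dataset are scored like any
other: self-exclusion would silently change margins and is easy to apply
upstream if wanted. Regulators with no signed overlap edge get z = NA and
sort after every finite z, with ties broken by overlap p and then id so
output order is total and reproducible.

## Mechanistic Networks

An edge r₁→r₂ between two significant regulators is credible as a relay
when the dataset genes regulated by r₁ are unusually often regulated by r₂
too. The score is the hypergeometric tail of |A₁ ∩ A₂| with margins
(|U|, |A₁|, |A₂|), where U is the set of dataset genes under at least one
`T` edge and Aᵢ the dataset targets of rᵢ. Fixing the universe to the
*dataset*-regulated genes makes the triangle statistic conditional on the
dataset — the question is "does r₂ explain r₁'s footprint", not "do their
regulons overlap in general".

The network grows by depth-first recursion: at each regulator the
outgoing `T`/`A`/`B` edges to other cutoff-passing regulators are ranked
by triangle p-value (ties by regulator id, making the build fully
deterministic), the best `breadth` children are taken, and recursion stops
at `depth` edges or when a child already lies on the current path.
Defaults `breadth = 5`, `depth = 3`, `p_cut = 0.01`, `z_cut = 2` keep
networks at most a few dozen regulators; children are ranked by the edge
p-value alone, not the child's own URA score, because the edge statistic
is what carries the relay evidence. Sign consistency along edges is not
enforced — incoherent but statistically supported edges are information,
not noise, at this stage.

## Causal Network Analysis

CNA asks the URA question at path lengths above one. The graph is first
pruned: `P`/`B` edges out, sign-0 edges out, weights below `delta`
(default 0.25) out, surviving weights set to 1. Binary weights keep
multi-step path signs well-defined without having to invent a weight
composition rule along paths.

For a root r, all *simple shortest* paths to each gene whose final hop is
a `T` edge (intermediate hops `T` or `A`) are enumerated by bounded
depth-first search up to `max_K = 3`. Explicit enumeration, rather than a
breadth-first distance pass, guards a corner case: a gene reachable early
through an `A` edge can lie on a short walk back to itself, and only true
simple paths should participate. A gene whose shortest paths agree in
composite sign (the product of edge signs) gets one *virtual edge* at that
length; disagreement suppresses the gene — this is what makes every
hypothesis network sign-consistent by construction, which the suite
asserts by re-walking the stored paths. Depth is capped at 3 because path
counts grow geometrically while the causal interpretability of longer
chains drops.

Hypotheses at K = 1..3 are scored by URA over the virtual edges (unit
weights, universe = pruned `T`-universe); K = 1 reproduces plain URA on
the pruned graph *exactly*, which the suite verifies to machine precision.
The regulated gene sets are nested over K. The Occam filter then retains a
deeper hypothesis only if it is strictly more significant than, and covers
a different gene set from, every retained shallower hypothesis of the same
root. Containment is interpreted within a root only: cross-root
containment ("r₂'s network sits inside r₁'s") is a plausible stricter
reading, but it couples the output of one root to the candidate list of
another and makes results depend on which roots the user asked about, so
it is deliberately not enforced. After pruning, the overlap universe is
the pruned `T`-universe — sign-0 binding edges do not resurrect genes that
no unambiguous edge regulates.

## Downstream Effects Analysis

Processes are scored with the URA machinery run against the *reversed*
direction: the genes carrying `P` edges into a process play the role of
the target set, the universe is the set of genes with at least one
outgoing `P` edge, and the z sign is read as increased/decreased. The
transpose symmetry is exact and tested: relabeling each `T` edge R→G of a
URA toy as a `P` edge G→process_R reproduces the URA table identically.
Bias metrics are computed for processes exactly as for regulators — the
formula is shared, and process-edge sign skew is as real as regulator-edge
skew.

## Network-bias-corrected p-value

Hub genes make overlaps look too significant: they sit under many
regulators, so their presence in a dataset is unremarkable. The corrected
p-value compares the observed overlap with overlaps of pseudo-datasets
resampled *within in-degree bins* — log₂ ranges {1}, {2,3}, {4..7},
{8..15}, {16..31}, … — drawing per bin, without replacement, exactly as
many genes as the real dataset contributes there. Every draw reproduces
the dataset's degree profile; the suite asserts this per permutation. With
one bin the procedure converges to the exact Fisher test (verified within
three Monte-Carlo standard errors at 10,000 permutations).

The estimator is (k + 1)/(n + 1) — the add-one rule guarantees p > 0 and
puts the floor at 1/10,001 for the default budget of 10,000 permutations.
Early stopping is checked once, after 1,000 permutations, and fires when
the running estimate exceeds 0.01: a p-value that large needs no further
resolution. Binning uses the `T`-subgraph in-degree, matching the URA
universe the statistic corrects.

## The synthetic generator

`generate_network()` emulates the *shape* the analyses assume — regulators
with signed `T` fans into a gene pool (fixed or power-law out-degree),
sparse regulator-to-regulator `A` edges, gene-to-process `P` edges, no
self-edges — and `plant_perturbation()` imprints the footprint of a
regulator in a known state: targets enter the dataset with the implied
sign, flipped with probability 1 − fidelity, plus background genes with
random signs drawn from the regulated universe (so enrichment margins stay
nontrivial). Defaults — fidelity 0.9, 60 background genes, out-degree 20,
activating fraction 0.7 — describe a clean, strong perturbation over a
modestly activation-biased network.

What passing tests show: the statistics are correctly calibrated, the
ground truth is recovered, and the algorithms behave per contract on
graphs of this shape. What they do not show: performance on real curated
networks, whose degree distributions are heavier-tailed, whose findings
conflict in structured ways, whose datasets carry correlated (pathway-level)
rather than independent noise, and whose identifiers need mapping. No claim
about the proprietary knowledge bases this class of method is usually run
against can be made from these benchmarks.

## Numerical and testing choices

Problem sizes were chosen so the full suite runs in well under a minute of
statistics per property: exhaustive hypergeometric enumeration up to
universe 12 (tolerance 1e−12 against `phyper`); 10,000-draw calibrations
of z and z_c; 10,000-permutation FET-agreement checks across 20 seeded
toys; 20-seed recovery experiments at 30 regulators × 500 genes. Planted
recovery and relay detection are asserted at ≥ 19/20 seeds, not 20/20, to
keep the tests honest about Monte-Carlo variation.

Ties are always broken totally (p, then lexicographic id) so every output
ordering is reproducible; all stochastic entry points take explicit seeds;
p-values below 1e−300 are floored only at the CLI formatting layer, never
inside the statistics.

## Known limitations

- Finding aggregation and the bias-corrected z follow the reconstructions
  stated above; other reasonable conventions exist (e.g. weighting
  findings by provenance, exact skewed-null tail instead of the Gaussian
  approximation).
- The activation z is asymptotic; for overlaps of a handful of genes the
  normal call threshold is approximate (the N = 4 fully concordant case
  sits exactly at z = 2).
- CNA's simple-path enumeration is exponential in `max_K`; the cap of 3 is
  also a computational guard on dense graphs.
- No multiple-testing adjustment is applied across regulators, processes
  or hypotheses: the p-values are reported raw, as screening scores, and
  the per-regulator permutation p inherits its 1/10,001 floor.
- Identifiers are opaque case-sensitive strings; species handling and
  symbol mapping belong upstream.
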