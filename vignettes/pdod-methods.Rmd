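---
title: "Scoring drugs that oppose disease gene states in a signed directed network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drugs that oppose disease gene states in a signed directed network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdod)
```

## The model

`pdod` scores drug–disease pairs by asking whether a drug's targets,
propagated through a signed directed molecular network, would push the
disease's genes *against* their altered expression states. Three layers
of directional information enter the score:

* **drug–target effect type** `i(r)`: +1 for activation-like
  interactions (agonist, activator, ...), −1 for inhibition-like
  (antagonist, blocker, ...);
* **edge signs** in the network: +1 for activation/expression relations,
  −1 for inhibition/repression;
* **disease gene state** `s(g)`: +1 for genes down-regulated in
  patients, −1 for up-regulated.

The net sign of the influence of target `r` on gene `g` is determined by
the parity of inhibition edges along shortest paths. A shortest path with
an even number of inhibition edges (zero counts as even) is
*activation-like*; odd, *inhibition-like*. Curated pathways merged from
several sources routinely disagree — both parities can coexist between
one ordered gene pair — so the two path counts `n_a` and `n_i` are
combined with the hop distance `|d|` into the conflict-adjusted distance

$$d_c(r, g) = \frac{n_a + n_i}{n_a - n_i}\,|d(r,g)|.$$

The sign of `d_c` is the majority parity. Its magnitude equals the hop
distance when all shortest paths agree and inflates without bound as the
two classes approach a tie, encoding "conflicting evidence, weak
influence". An exact tie, or an unreachable pair, yields an infinite
distance.

Distances are converted to proximity by a bell-shaped (Cauchy-type)
kernel $k(d_c) = 1/(1 + |d_c/\alpha|^2)$ and aggregated:

$$\mathrm{PDOD}(R, G) = \frac{1}{n_g n_r} \sum_{i=1}^{n_r}
\sum_{j=1}^{n_g} i(r_i)\,\mathrm{sign}(d_c(r_i,g_j))\,s(g_j)\;
k(d_c(r_i, g_j)).$$

The product of the three sign factors is +1 exactly when the drug
opposes the gene's alteration through that target. Dividing by the
number of targets `n_r` penalises drugs with many off-targets (targets
that reach no disease gene pull the average toward 0); dividing by `n_g`
makes scores comparable across diseases. Scores are bounded in
$[-1, 1]$.

The **PDD baseline** strips every piece of directional information: all
sign factors are +1 and `d_c` is replaced by the plain hop distance on
the unsigned network. Comparing the two rankings isolates the
contribution of directionality.

## Assumptions and known limitations

* **Shortest paths only.** All influence is read off minimal-hop paths;
  longer routes are ignored. This follows the usual proximity assumption
  that closer genes interact more strongly, and keeps the computation a
  single BFS per target, but discards reinforcement or interference by
  longer paths.
* **Four effect types.** Only activation, expression, inhibition and
  repression edges are interpretable as signs. Relations such as
  binding, association or phosphorylation are excluded by the KGML
  importer, which shrinks the usable network and can leave some disease
  genes disconnected.
* **Hop-weighted, not confidence-weighted.** All edges count equally;
  there is no notion of interaction strength.
* **No null model.** Scores are comparative, not inferential: the method
  ranks drugs within a disease and no significance is attached to any
  single score.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `alpha` | kernel half-width, in conflict-adjusted hops: the distance at which a pair's contribution falls to one half | 3 | typical target→disease-gene distances in curated signalling networks are a few hops; AUC on the synthetic benchmark is insensitive above ~3 (see `alpha_sweep()`) |
| `pdd_mode` | hop convention for the baseline | `"undirected"` | the baseline deliberately discards effect *direction* as well as type; a directed-but-unsigned variant is available as `"directed"` |

## Numerical and edge-case conventions

* **Infinity sentinel.** Unreachable and conflict-tied pairs carry
  `d_c = Inf` (unsigned). The kernel maps it to exactly `0`, never
  `NaN`, so such pairs contribute nothing while still diluting the
  `1/(n_r n_g)` normalisation.
* **Target on a disease gene.** A target that *is* a disease gene has
  hop 0 with one trivial activation-like path (zero inhibition edges is
  even), hence `d_c = 0`, kernel 1, and sign `+1` by convention — an
  activating drug on a down-regulated gene scores maximally. The
  convention is ours; the hop-0 case has no established treatment.
* **Parallel opposite-sign edges.** Both are retained and each
  contributes a distinct path to its parity class; a lone `+1`/`-1`
  parallel pair therefore produces an immediate conflict tie. Duplicate
  identical records collapse to one edge. A KGML relation annotated with
  both an activation-like and an inhibition-like subtype likewise emits
  both edges rather than silently preferring one.
* **Path counting.** Counts come from layered BFS dynamic programming
  over (node, parity) states — never explicit enumeration — and are held
  as doubles, exact up to 2^53 paths. The test suite pins the DP to an
  independent exhaustive-enumeration oracle on hundreds of random
  graphs.
* **Determinism.** Scoring caches one parity BFS per unique target gene;
  cached and per-pair computations sum in the same order and agree
  bitwise. Output tables print scores to six decimals; internal values
  stay full precision.
* **Normalisation count `n_r`.** `n_r` is the number of typed targets
  *remaining after restriction to the network*. A target absent from the
  network contributes no path, and the upstream filtering removes it; a
  documented alternative would be to keep the pre-filter count, which
  would only rescale scores of partially filtered drugs downward.

## The synthetic benchmark

`simulate_study()` generates a fully self-contained study:

* a directed Erdős–Rényi network (default 200 genes, edge probability
  0.02 → mean degree ≈ 4, matching the order of magnitude of sparse
  curated signalling networks), 30 % inhibition edges;
* one disease of 10 genes drawn from nodes with incoming edges, with
  random up/down states;
* a 50-drug panel in three planted classes: **therapeutic** (each
  target's effect type chosen so its summed sign-weighted kernel
  contribution over disease genes is positive, with an informative
  disease gene within 1–3 hops), **aggravating** (same target pool,
  effect flipped), and **neutral** (targets that reach no disease gene,
  scoring exactly 0). The answer set is the therapeutic class.

Plants are verified post hoc with the production scoring function —
background edges can create conflicting parallel shortest paths, so the
intended sign is checked, and targets are redrawn if spoiled. Each
generation step draws from its own stream seeded `seed`, `seed + 1`,
`seed + 2` (network, disease, drugs), so every module is independently
reproducible and the whole fixture is a pure function of the seed.

Because aggravating drugs sit at the *same distances* as therapeutic
ones and differ only in direction, the directionless PDD baseline cannot
separate them — the benchmark isolates exactly the information PDOD
adds. On the default fixture PDOD attains AUC 1.0 against PDD's 0.78
(the tests assert PDOD ≥ 0.9 and PDOD > PDD).

What the generator does **not** emulate: scale-free degree structure,
expression noise and differential-expression calling (states are emitted
directly), correlated pathway topology, or drug polypharmacology beyond
1–3 targets. Passing the synthetic recovery test shows the scoring
machinery preserves planted directional signal; it does not certify
performance on real curated networks.

## Problem sizes used in the checks

Worked-example graphs have 2–11 nodes. Property checks use 1,000 random
scoring fixtures of 5–9 nodes for the score bounds, 500 random graphs of
at most 12 nodes for the enumeration oracle, and the 200-gene / 50-drug
fixture above for the recovery benchmark; together they run in well
under a minute.
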