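---
title: "Reward-gated cluster plasticity in minicolumns: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-gated cluster plasticity in minicolumns: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minicolearn)
```

## The model

`minicolearn` simulates an abstract account of how neocortical pyramidal
cells could learn arbitrary input-to-output mappings by trial and error.
Every cell is a binary-output unit that owns a *basal tree* of synaptic
clusters. A cluster is a set of `C` distinct input sources together with a
non-negative integer weight; it stands in for a group of co-located basal
synapses whose coincident activation triggers a local NMDA spike. No
membrane potentials, spike timing or calcium dynamics are modelled — only
the abstract consequences of those events:

* a cluster is **excited** in an episode when at least `G` of its `C`
  sources are active (the default, and the setting used in all standard
  experiments, is `G = C`: every synapse active);
* a cell **fires** in training when it is selected through its apical
  tuft (the "guess" of trial-and-error learning), and in testing when it
  wins the winner-take-all competition;
* **plasticity** happens only at the coincidence of the two: every
  excited cluster of a fired cell is eligible, and the reward that follows
  the episode decides the direction. Positive or insignificant (zero)
  rewards add `potentiation_increment × magnitude` (an insignificant
  reward adds one flat unit — the absence of punishment is still an
  acceptable outcome and must not silence learning); negative rewards
  (punishments) either remove the accumulated enhancement outright
  (`reset_to_zero`, the default) or subtract a graded step
  (`decrement`). Weights can never go negative.

The behavioural-timescale eligibility window of the biological rule
collapses here to same-episode coincidence, because a simulated episode
presents one static pattern; there is no intra-episode time axis. Reward
magnitudes other than 1 and the graded weakening mode are provided because
larger rewards plausibly drive larger weight changes, but the standard
experiments use unit positive rewards throughout, so both knobs are inert
there. Homeostatic renormalisation of total synaptic strength is not
implemented: in the single-epoch experiments weights stay bounded by the
number of assigned patterns.

Memory readout is purely feed-forward: a cell's response to a pattern is
the summed weight of its excited clusters, and the minicolumn whose L5
cell has the largest response is the one that fires, ties broken uniformly
at random. Readout never changes weights.

### Selection capacity

The combinatorial side of the model asks how many distinct cells can be
individually addressed if each cell's apical tuft carries a cluster formed
by a distinct `G`-subset of `I` selection inputs. That count is exactly
`choose(I, G)`; `selection_capacity()` computes it in exact arbitrary
precision (a small base-10^6 limb arithmetic, since the counts leave
double range quickly) and reports the one-significant-figure magnitude
alongside:

```{r capacity}
selection_capacity(25, 8)
selection_capacity(50, 20)
```

The count is the pure combinatorial ceiling: it assumes a single cluster's
NMDA spike suffices to select a cell and ignores crosstalk between
overlapping clusters.

## Tree construction

A learner's tree is filled with `floor(S_max / C)` clusters (default
`S_max` = 20,000 synapses), each drawn independently. A draw picks a
source with probability proportional to its slot count — one slot per
external input, `F` slots per layer-2/3 detector input — and a draw that
repeats a source already in the cluster is rejected and redrawn. That
rejection scheme is distributionally identical to successive weighted
sampling without replacement, which is how it is implemented
(`sample.int(…, replace = FALSE, prob = w)`); when all weights are equal
the same law is produced by a much faster batch draw with whole-row
duplicate rejection, which is the path taken for `F = 0` and for all
internal-representation trees. `F` may be non-integer, which keeps sweep
grids continuous; `F = 0` reproduces "no layer-2/3 to layer-5
connectivity" exactly. Clusters own disjoint physical synapses, so the
synapse count is exactly `C × n_clusters`; identical source compositions
across clusters are allowed and do occur.

## The synthetic patterns

Inputs live on a one-dimensional line of `I` binary inputs (default 100).
Patterns are unions of 5-wide objects of two types — solid `XXXXX` (five
adjacent active inputs) and gapped `XXOXX` (two active pairs around an
inactive centre) — placed so that footprints neither overlap nor touch
(at least one inactive input between objects, no wrap-around). Placement
sets are sampled *exactly* uniformly over all valid configurations by the
stars-and-bars gap construction (the spare inactive inputs are distributed
over the gaps through a uniform random combination) rather than by
rejection, so there are no pathological rejection rates at high packing
density. Distinctness of the generated patterns is enforced by redraw with
a cap of 1,000 collisions; at `I = 100` collisions are essentially never
observed, but the cap guarantees termination.

Two experiment modes use these patterns:

* **internal representation** — `n_mc × patterns_per_mc` (default 100)
  distinct solid patterns, 10 assigned to each of 10 minicolumns. Each
  minicolumn holds an L5 learner and an L2/3 learner with independent
  trees over the external inputs; apical cross-induction fires both
  whenever the minicolumn is selected, so they learn in parallel from
  identical episodes.
* **hierarchical** — 50 distinct solid patterns plus 50 gapped twins that
  copy each solid pattern's object start positions exactly ("the same
  object locations" is read as an exact copy of starts); a twin is always
  assigned to a different minicolumn than its partner. The two prewired
  L2/3 detector cells output a pure boolean function of the pattern
  (solid-object present / gapped-object present); their own acquisition is
  taken as given and not simulated. Only the L5 trees are plastic, and
  they may sample the detector sources at factor `F`.

The number of objects per pattern in the hierarchical experiment defaults
to 5 (25% active density for solid patterns), a value consistent with the
input-density regime the model needs; it is exposed as a configuration
knob.

One wrinkle the generator makes visible: a solid pattern whose objects sit
at the minimum spacing of exactly one inactive input contains the window
`1,1,0,1,1` across the boundary, so the gapped-object detector fires on
it. This is a genuine consequence of the detector's definition, not a
bug; the test suite asserts the exact equivalence (spurious gapped
detection iff some inter-object gap is exactly one input).

What the generator does **not** emulate about real input: no noise or
jitter in object shape, no occlusion, no two-dimensional structure, no
temporal sequences, and the two object classes are perfectly balanced.
Passing tests therefore show that the learning rule and readout do what
the model claims under idealised, noise-free coding — not that the
mechanism is robust to realistic sensory variability.

## Training, testing, and the experiments

Training presents each pattern exactly once, in generation order, firing
the assigned minicolumn with a unit positive reward; every excited cluster
of the fired cells gains +1. Under this all-positive schedule the final
weights are a pure coverage count — cluster weight = number of assigned
patterns covering it — so they are invariant to presentation order (a
property the suite verifies against the closed form). Testing presents
all patterns again read-only, scores every minicolumn's L5 under its own
extended activity, and lets the largest score fire; in
internal-representation mode the L2/3 learners run an independent
winner-take-all of their own, implemented as the minimal symmetric
extension of the L5 competition, and a pattern is *simultaneously*
correct only when both layer winners equal the assigned minicolumn.
Tie-break draws are consumed in pattern order, L5 before L2/3, from the
run's dedicated tie stream, which keeps full runs bit-reproducible.

Scoring is vectorised as a sparse cluster-membership matrix multiplied by
the activity matrix; the suite checks it against a naive per-cluster
double loop on random instances.

### Seeding

Every source of randomness descends from one master seed through
`seed_ladder()`, a deterministic label hash giving each (experiment cell,
run, purpose) its own stream — `trees`, `patterns` and `ties` are separate
purposes. Two design consequences: any single run can be reproduced in
isolation, and the hierarchical sweep derives its pattern seed from the
run index but *not* from `F`, so all `F` cells of a run share an identical
pattern set and the effect of connectivity can be read as a paired
comparison.

### Problem sizes and runtime

The standard internal-representation experiment (10 minicolumns, 20,000
synapses per learner, 100 patterns, 10 runs) completes in a few seconds
on one CPU; the two-cell paired hierarchical comparison (`F` ∈ {0, 10},
50 runs each) takes under a minute. The full default grids (8 object
counts, or 8 connectivity factors × 50 runs) are a few minutes each.

```{r headline}
res <- run_internal_rep_experiment(cluster_size = 4, n_objects_grid = 5,
                                   n_runs = 10, seed = 1)
res$summary[, c("n_objects", "accuracy_simultaneous_mean",
                "accuracy_simultaneous_sd", "n_runs")]
```

With 5 objects per pattern and cluster size 4 the mean simultaneous
accuracy sits above 0.98. With a single object per pattern (4% density)
clusters of size 4 are rarely covered at all and accuracy collapses
toward the tie-breaking chance level of 1/10 — input density is what
feeds the clusters.

## Numerical and degenerate-case choices

* Weights are integers by construction (+1 per potentiation event), so no
  floating-point ties arise in scoring; score ties are exact integer ties
  and are broken uniformly at random.
* A winner-take-all over a single cell returns it without consuming a
  random draw; an empty score vector is a domain error.
* An all-zero pattern excites no cluster (for `G ≥ 1`) and therefore
  teaches nothing and scores zero everywhere.
* Infeasible object packings (`5n + (n−1) > I`) and cluster sizes
  exceeding the available distinct sources raise configuration errors
  rather than truncating silently.
* The twin-assignment constraint (a gapped twin never shares its solid
  partner's minicolumn) is satisfied by a balanced shuffle followed by a
  swap-repair loop with an iteration cap; plain rejection of whole
  assignments would succeed too rarely to be dependable.

## Known limitations

Cells are binary abstractions: no burst-versus-regular firing distinction,
no inhibitory dynamics, no eligibility-trace decay, no modelling of how
the prewired detectors learned their selectivity. The capacity count
ignores cluster crosstalk. The experiments cover one training epoch;
multi-epoch stability (and any need for homeostatic renormalisation) is
untested. The hierarchical experiment's accuracy-versus-`F` curve is
summarised only directionally (paired improvement over `F = 0`), since
the model makes no quantitative claim about its shape.
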