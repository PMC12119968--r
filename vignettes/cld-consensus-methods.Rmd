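---
title: "Consensus analysis of community-built causal loop diagrams: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus analysis of community-built causal loop diagrams: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cldtools)
library(dplyr)
```

## The analytical problem

In community-based system dynamics (CBSD), stakeholder groups build causal
loop diagrams (CLDs): signed directed graphs whose nodes are factors and
whose edges assert causal influence. A `+` edge means cause and effect move
in the same direction; a `-` edge, opposite directions. When several groups
independently map the same system — here, the drivers of dementia risk among
older Black adults — each produces a partial, noisy view. The analytical task
this package automates is fourfold:

1. **Represent and standardize** the per-group diagrams (labels elicited live
   vary in spelling and phrasing);
2. **Enumerate and classify feedback loops**, the structures that give the
   method its explanatory power;
3. **Aggregate** groups into a union model with per-edge *support* (how many
   groups drew the edge) and extract a consensus **core model** around the
   focal problem variable;
4. **Quantify leverage**: how participant-proposed *action ideas* reach core
   factors through signed pathways.

Because multi-workshop raw data of this kind is rarely deposited, the package
also ships a synthetic generator with known ground truth so that every
pipeline stage is testable, including edge-level recovery of a latent core.

## Model and conventions

**Edge identity.** An edge is the triple (cause, effect, polarity). The same
factor pair may carry both signs simultaneously — groups can disagree, and
even one group may record both — and both are retained as distinct edges.
Contradictory signs are reported (`polarity_conflicts()`), never silently
resolved, because the within-group case is empirically possible and no
principled tie-break exists.

**Self-edges are rejected.** A factor influencing itself is representable
only through multi-node loops. This matches how workshop loops are narrated
and keeps cycle semantics simple.

**Delays are annotation.** A delay mark on an edge is carried through I/O and
merging (OR-ed across duplicates) but plays no computational role: delays
affect the timing of feedback, not its existence or sign.

**Label standardization.** Raw labels pass through a synonym map
(raw → canonical) when one is supplied and otherwise through a deterministic
default: case-fold, trim, collapse internal whitespace to `_`. The default is
deliberately mechanical so that standardization is auditable; the
`label_map` attribute records every raw → canonical correspondence applied.
Canonicalization is idempotent, conserves every input edge as exactly one
output edge (modulo collapse of exact duplicates), and fails loudly if a
merge would create a self-edge.

**Loop polarity.** A feedback loop is *reinforcing* when its polarity product
is positive — equivalently, when it contains an even number of negative
edges — and *balancing* otherwise. This sign-product (negative-parity) rule
is the standard system-dynamics convention and the only rule consistent with
labelling an all-positive loop reinforcing. It is rotation-invariant, which
the tests check exhaustively over every sign pattern of lengths 2–4.

## Algorithms and numerical choices

**Cycle enumeration.** `enumerate_loops()` walks depth-first from each start
node restricted to nodes sorting at or after the start, which visits each
simple directed cycle exactly once and already in canonical rotation
(beginning at the lexicographically smallest node). Where a node pair carries
both signs, each sign combination along a cycle is a distinct loop. Defaults
`max_len = 12` and `max_count = 1e5` bound worst-case work on dense graphs:
participant-built CLD loops are short, and if the cap is hit the partial
inventory is flagged (`truncated` attribute plus a classed warning) — never
silently cut. The enumerator is validated against a brute-force oracle that
tests every node subset and rotation on hundreds of seeded random digraphs.

**Feedback edges.** An edge u→v lies on a simple cycle exactly when u and v
share a strongly connected component of size ≥ 2 (given no self-edges), so
`feedback_edges()` uses an SCC decomposition rather than enumeration; tests
confirm agreement with the union of enumerated cycle edges.

**Exogenous factors** are the in-degree-zero nodes: influenced by nothing
inside the mapped system while influencing it (systemic racism is the
canonical example in the study domain).

**Aggregation.** `union_models()` keys edges by (cause, effect, polarity)
and records the set of supporting groups, the instance count, and OR-ed
action flags. Support counts *distinct groups*, not instances: agreement
between independently built models is the consensus currency. For "edges
connected to action ideas" the package reports both the either-endpoint
count and the cause-only count, since the phrase does not fix endpoint roles;
the either-endpoint reading is the weakest faithful one.

**Core extraction.** `extract_core()` keeps edges with support ≥
`min_support` (default 2), then iterates to a fixed point: within the
surviving set, an edge stays only if it lies on a simple cycle (*feedback*)
or on a directed path that starts or ends at the focal variable
(*focal-connected*); nodes left isolated drop out. Iteration matters —
removing one edge can break the loop or path that justified another, and
stopping after one pass would leave incomplete feedback loops in the core.
"Causally connected" includes both ancestors and descendants of the focal
node because the focal problem is both effect and cause (dementia drives
out-of-pocket expenses as well as being driven by risk factors). The support
threshold is applied before structural filtering, reflecting the stage order
of the underlying workshop methodology. The filter is validated against a
brute-force fixed-point oracle using exhaustive BFS path search, and is
weakly monotone in `min_support` and idempotent on its own output.

**Indirect-path consensus.** For each aggregate edge, groups lacking the
direct edge may still encode the same claim through intervening factors:
`indirect_path_consensus()` searches each such group for a simple path from
cause to effect with 1–`max_intermediates` intervening nodes (default 2,
keeping witnesses interpretable) whose net sign equals the edge's polarity.
Witness paths are recorded per group. Indirect support is a *report about*
consensus; it never admits edges into the core, because using it for
admission would change the definition of the core model rather than measure
agreement on it.

**Action influence.** `action_influence()` enumerates simple signed paths
(≤ `max_path_len` edges, default 4) from each action idea through the *union*
graph to core nodes. Paths traverse the full aggregate rather than core
edges only, because interventions were attached wherever they could plausibly
influence the system, including through single-group linkages. Because "how
many influences" is ambiguous between distinct (action, core-node) pairs and
distinct pathways, both totals are always reported side by side.

**Determinism.** Every output — DOT, GraphML, JSON, CSV — emits nodes and
edges in lexicographic order, so identical inputs give byte-identical
artifacts; the pipeline manifest omits the run directory and wall-clock
values for the same reason. All randomness in the synthetic module is a pure
function of `(params, seed)`.

## The synthetic generator: what it emulates, and what it does not

`generate_true_system()` builds a latent signed digraph with the structures
the consensus filter is designed to find: feedback loops through the focal
node (at least one reinforcing and one balancing), upstream chains whose
heads are exogenous, downstream chains, action ideas attached by outgoing
edges, and *peripheral* edges placed so that they neither lie on cycles nor
connect causally to the focal node. That placement makes recovery well
defined: under perfect detection the consensus core equals the latent core
exactly (a property the tests assert), so precision and recall measure the
pipeline, not an ambiguous target.

`sample_group_models()` then emulates independent workshops: each latent edge
is detected with probability `p_detect` (0.85), action-idea edges with
`p_detect_action` (0.4, reflecting that action ideas overlap much less
across groups than system structure), detected signs flip with `flip_prob`
(0.02, rare transcription/elicitation disagreement), and a Poisson
`noise_rate` (40) of group-specific edges is added, mostly touching a small
pool of group-unique labels (`noise_pool_size` 12, `p_unique_noise` 0.9).
Group-unique noise is the design point: idiosyncratic content fails the
two-group support filter, which is precisely the rationale for requiring
support ≥ 2 in the first place. The `p_unique_noise < 1` remainder draws
both endpoints from shared factors, so cross-group coincidence of noise
remains possible as a stressor.

Defaults were calibrated once, by expectation arithmetic, so that emergent
per-group counts land near the reported scale of the motivating study
(about 70 factors, 110–115 edges, and roughly 9–13 action ideas per group
across 8 groups; the printed per-group edge range in the source study is
internally inconsistent — likely a typo — so the mean, not the range, was
the calibration target). Counts are emergent from the detection and noise
parameters rather than forced, which keeps the generator's invariants
simple.

What the generator does **not** emulate: semantic label drift (synonyms are
exercised with explicit maps in unit tests, not generated), participant
demographics or facilitation effects, correlated detection (groups miss
edges independently here; real groups share blind spots), and any
quantitative dynamics — the CLDs are qualitative, and simulating them is out
of scope. Passing recovery tests therefore shows the *pipeline* recovers a
latent consensus structure under independent noisy observation; it does not
certify performance under correlated human error.

**Recovery regime.** With the defaults above, a latent core edge is missed
by the two-group filter only if fewer than 2 of 8 groups record it; at
detection 0.85 × (1 − 0.02) that probability is ≈ 4·10⁻⁶ for system edges
and ≈ 0.11 for action edges at 0.4 detection — so recall is governed by the
action-edge attachment rate, and precision stays near 1 because group-unique
noise cannot reach support 2. The repository's acceptance test fixes
thresholds (median precision ≥ 0.95, median recall ≥ 0.90 over 50
replicates) recorded from a pilot run of the brute-force-validated pipeline
before the test was written; `scripts/acceptance.R` recomputes the medians
from scratch at any seed.

## Problem sizes used in the test suite

Unit and property tests run at sizes where brute-force oracles are exact and
fast: random digraphs of 2–6 nodes for cycle enumeration (the oracle tests
every subset and rotation), batteries of 3–5 groups over 8–25 shared labels
for aggregation and core extraction (BFS-based fixed-point oracle), and the
full default scale (8 groups, ~70 factors) for the generator's calibration
checks and the 50-replicate recovery experiment. These sizes were chosen so
the whole suite exercises every contract in a couple of minutes while the
oracles remain exhaustive rather than sampled.

## The bundled demo transcription

`cld_example()` ships a single-group edge list transcribed from the narrated
loops of one workshop's diagram: the trauma → substance abuse → domestic
violence triangle (R1, all positive, hence reinforcing), the health-literacy
information loop (R2), the social-isolation/criminal-justice loops (R3, R4,
R7), ignorance (R5) and poverty (R6) loops, the policy/education loop (B1),
the caregiving loops (B2, B3), the exogenous systemic-racism driver, and two
action ideas. Two transcription caveats are recorded rather than resolved:
the source narration labels loops R1–R7 and B1–B3 while its figure caption
says "six" major loops (the transcription follows the narration); and the
loop narrated as B1 transcribes to four negative edges, an even count, so
the parity rule classifies it *reinforcing* — the fixture keeps the
prose-implied signs and reports what the rule yields, illustrating why a
mechanical classification is worth having alongside narrative labels.
Because it is a single group, the demo is run with `min_support = 1`.

```{r demo}
res <- run_pipeline(
  cld_example(),
  cld_config("dementia risk", min_support = 1, output_dir = tempfile("demo_")),
  synonym_map = cld_example("workshop_demo_synonyms.csv"),
  quiet = TRUE
)
glance(res$loops)
glance(res$core)
```

## Known limitations

- Cycle enumeration is exponential in the worst case; the explicit cap and
  length bound make truncation visible but dense aggregates can exceed them.
- Indirect-path witnesses are capped at 2 intervening nodes by default;
  longer chains of agreement are not searched unless requested.
- Support is a count of groups, unweighted by group size or confidence; the
  method has no notion of partial agreement on polarity.
- Label standardization is lexical. Semantically equivalent factors with
  different wording merge only if the synonym map says so.
- The recovery experiment's independence assumptions (edge detection,
  noise) are favourable; correlated omissions across groups would lower
  recall in ways the defaults do not probe.
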