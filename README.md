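# cldtools

Consensus analysis of community-built causal loop diagrams (CLDs).

## What this is for

Community-based system dynamics (CBSD) workshops have stakeholder groups map
a complex problem — here, the drivers of dementia risk in a community facing
entrenched structural inequities — as a **signed directed graph**: nodes are
factors, an edge `x → y` asserts causal influence, and its polarity is `+`
when x and y move in the same direction, `-` when they move oppositely. When
several groups independently map the same system, the analyst must
standardize labels, find and classify feedback loops, aggregate the groups,
and distill what the groups *agree on*. `cldtools` implements that pipeline
for epidemiologists, system-dynamics practitioners, and participatory-
research teams, as a set of pipeable functions over plain edge-list tables.

The core quantities:

- **Loop polarity.** A feedback loop with negative-edge count *k* is
  *reinforcing* (R) if *k* is even — its polarity product is `+` and it
  amplifies change — and *balancing* (B) if *k* is odd. `enumerate_loops()`
  lists every simple cycle in canonical rotation; `classify_loop()` applies
  the parity rule.
- **Edge support.** For edge identity (cause, effect, polarity), support is
  the number of distinct groups whose model contains the edge
  (`union_models()`).
- **Consensus core.** The fixed point of: keep edges with support ≥ 2, then
  keep only edges on a simple cycle or on a directed path to/from the focal
  problem variable, iterating until stable and dropping isolated nodes
  (`extract_core()`). Incomplete feedback loops and exogenous stubs fall
  away.
- **Indirect consensus.** Groups lacking a direct edge may encode the same
  claim via a short sign-consistent path through intervening factors
  (`indirect_path_consensus()`).
- **Action leverage.** Signed simple paths from participant-proposed action
  ideas to core nodes (`action_influence()`), with both (action, node) pair
  and pathway counts.

A synthetic multi-group generator (`generate_true_system()`,
`sample_group_models()`) with known latent structure supports edge-level
recovery experiments (`run_recovery_experiment()`): precision and recall of
the extracted core against the latent one, sign-sensitively.

## Worked example

The package ships a one-group transcription of a workshop's narrated loops
(`cld_example()`). Reading, standardizing, aggregating and enumerating:

```r
library(cldtools)
library(dplyr)

edges <- read_group_models(cld_example(), focal = "dementia risk") |>
  canonicalize_labels(read_synonym_map(cld_example("workshop_demo_synonyms.csv")))
agg <- union_models(edges)

loops <- enumerate_loops(agg)
glance(loops)
#> # A tibble: 1 × 5
#>   n_loops n_reinforcing n_balancing max_length truncated
#>     <int>         <int>       <int>      <int> <lgl>
#> 1      19            13           6         12 FALSE

loops |> filter(length == 3) |> tidy() |> select(nodes, signs, classification)
#> # A tibble: 3 × 3
#>   nodes                                        signs classification
#>   <chr>                                        <chr> <chr>
#> 1 caregiving_quality>dementia_risk>income      --+   reinforcing
#> 2 dementia_risk>out_of_pocket_expenses>poverty +++   reinforcing
#> 3 domestic_violence>trauma>substance_abuse     +++   reinforcing
```

The third row is the narrated R1 triangle — trauma raises substance abuse,
which raises domestic violence, which feeds back into trauma; all-positive,
hence reinforcing. The diagram holds 19 loops in total, 13 reinforcing and 6
balancing. Extracting the core (single group, so `min_support = 1`) and
tracing action ideas:

```r
core <- extract_core(agg, min_support = 1)
glance(core)
#> # A tibble: 1 × 7
#>   n_nodes n_edges n_feedback n_focal_connected n_both min_support focal
#>     <int>   <int>      <int>             <int>  <int>       <int> <chr>
#> 1      39      56          0                15     41           1 dementia_risk

actions <- action_influence(agg, core)
glance(actions)
#> # A tibble: 1 × 5
#>   n_actions n_actions_with_influence n_pairs n_pathways max_path_len
#>       <int>                    <int>   <int>      <int>        <int>
#> 1         2                        2      20         22            4

exogenous_nodes(agg)
#> [1] "information_campaign" "systemic_racism"      "voter_mobilization"
```

Every core edge is justified (41 lie on loops *and* focal paths, 15 on focal
paths only); the two action ideas reach 20 core factors through 22 signed
pathways; systemic racism is exogenous — it drives the system but nothing in
the system causes it (action ideas are exogenous by construction: they are
interventions, not consequences).

`run_pipeline()` executes the whole chain and writes deterministic CSV,
JSON, DOT and GraphML reports plus a manifest;
`inst/scripts/cld_pipeline.R` wraps it for shell use.

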