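---
title: "Sign-constrained pathway convergence analysis with popnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sign-constrained pathway convergence analysis with popnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(popnet)
```

## The problem

Structurally unrelated toxicants often bind entirely different primary
receptors, yet epidemiology associates them with the same diseases. One
mechanistic explanation is convergence: a few interaction steps
downstream of their distinct primary targets, the compounds activate a
common set of genes. popnet implements that reasoning as a reproducible
pipeline over a signed, directed molecular-interaction network — the
kind of content exported from a curated pathway knowledge base as an
edge table with an effect sign (activation / inhibition / unspecified),
a mechanism label, an evidence trust level, and a directness flag per
interaction.

The package ships a small worked-example network built around three
persistent organic pollutants: TCDD, which binds and activates the aryl
hydrocarbon receptor (AhR); PCB 153, which binds and inhibits the
pregnane X receptor (PXR); and p,p'-DDE, which binds and inhibits the
androgen receptor (AR). Downstream edges connect the receptors to the
transcription factors CREB1, RelA and c-Jun and to the readouts IL-8,
IL-6, TNF-alpha, fetuin A and cyclin D1.

## The model

**Evidence tier.** Path queries run on the high-trust, direct,
known-effect slice of the network (`filter_evidence()`). Unspecified
effects and indirect or low-trust edges carry no sign information a
parity argument can use, so they are invisible to the path engine.

**Sign parity.** A directed simple path activates its endpoint iff it
contains an even number of inhibition edges: inhibition of an inhibitor
is activation. The net effect of a path is the product of its edge
signs, and `valid_sign_sequences(k, +1)` enumerates the `2^(k-1)`
admissible sign patterns of a length-`k` activating path (for two steps:
activation-activation and inhibition-inhibition; for three steps the
four patterns AAA, AII, IAI, IIA).

**Depth.** Depth is counted in edges starting at the compound, so the
compound-to-receptor binding edge is step 1 and a target "two steps
beyond the primary target" sits at depth 3. The default bound
`max_steps = 3` reflects a design philosophy rather than a computational
limit: each added step multiplies candidate mechanisms while diluting
their biological interpretability, and three steps already reaches the
transcription-factor-to-cytokine layer. The engine accepts bounds from
1 to 10.

**Paths are simple.** Node revisits are forbidden and self-loops are
never traversed; otherwise "number of steps" would be ill-defined on
cyclic signalling motifs. Parallel edges between the same ordered pair
are kept as distinct interactions (curated databases record
context-dependent opposite findings), but they give rise to distinct
paths only when their signs differ — two same-signed parallel edges
describe the same signal.

**Convergence.** A *common activation target* is an entity every query
compound reaches with net activation within the bound
(`find_common_activation_targets()`). For each target the per-source
minimal activation depths are averaged; the mean is rounded half-up to
two decimals, so the depth profile (2, 2, 3) reports 2.33 and (2, 3, 3)
reports 2.67. Rounding half-up (rather than R's banker's rounding)
matches the convention of printed arithmetic in this field.

**Concordance is strict.** If any source also reaches a target with net
inhibition within the bound, the target receives a mixed message and is
classified `conflicted`, regardless of relative path lengths. Strictness
is a deliberate choice: it is deterministic, conservative, and
independent of any tie-break between an activating and an inhibiting
route of different depths. The remaining statuses are `partial` (some
but not all sources activate) and `unreachable`.

## Network assembly and conflict removal

`build_shortest_paths_network()` takes the union, over every
(source, target) pair, of *all* minimal-length net-activation simple
paths — ties are all retained, and a shorter net-inhibition path neither
contributes edges nor redefines the minimum, because the displayed
network is meant to show only interactions that lead to downstream
activation.

`detect_conflicts()` then inspects every displayed intermediate node
(neither a source nor a terminal target): the node is conflicted when
one source signals it with net activation and another source — or the
same source along a different route — signals it with net inhibition
within the bound. Signals are evaluated over the base network rather
than only along retained path prefixes. The narrower prefix-only reading
was considered and rejected: it cannot express the canonical conflict in
which a linker on one compound's activation route is directly inhibited
by another compound's primary receptor, since that inhibiting edge lies
on no retained activation path.

`remove_conflicts()` iterates to a fixpoint: remove the conflicted nodes
and every retained path through them, drop terminal targets no longer
activation-reachable from *all* sources, re-detect. Removed molecules no
longer transmit signal in later rounds (detection excludes them from the
base network), and each round removes at least one node, so termination
is bounded by the node count. By default removal does not re-route
through edges absent from the original assembly; passing
`rerun_on_conflict = TRUE` re-runs the build with the conflicted nodes
excluded, which can recover longer concordant detours. Both behaviours
are exposed because removal-only and remove-then-requery are equally
defensible readings of a manual curation step.

Per-target subnetworks (`extract_target_subnetwork()`) default to
*all* qualifying paths, not only minimal ones, with the
`on_minimal_path` edge attribute separating the closest interactions
from the farther ones; the global assembly defaults to minimal paths
only. This mirrors the two display conventions the two views serve:
resolution per target, parsimony globally.

## Disease overlay

Disease association is membership in an annotation table, not a score;
association strength is not modelled because only membership enters the
narrowing step. Terms are canonicalised by trimming and case-folding.
The default panel is `diabetes/insulin resistance`, `obesity`,
`metabolic syndrome x`; a target associated with at least one panel
disease is a *union* gene, with all of them an *intersection* gene.
`filter_to_disease()` keeps concordantly activated union genes.

## The worked-example fixture

`pop_fixture()` returns a 14-entity, 22-edge network whose sign
structure encodes the worked receptor-mediated routes: e.g. PCB 153
reaches IL-8 in three steps by inhibiting PXR, which inhibits CREB1,
which activates IL-8 via promoter binding — two inhibitions, net
activation. On this fixture the pipeline reports IL-8, IL-6 and
cyclin D1 at mean depth 2.33, TNF-alpha at 2.67, RelA at 2.00 and
fetuin A at 3.00. Two interpretation notes are deliberately encoded and
worth flagging:

* binding signs are recorded per edge (TCDD activates its receptor; the
  other two compounds inhibit theirs) rather than assumed globally;
* the PXR-to-RelA and AR-to-c-Jun edges are encoded as inhibitions so
  that the documented inhibition-of-an-inhibitor routes net to
  activation; and the AhR/ARNT complex is traversed as the single node
  `AhR`.

The fixture's fetuin A mean of 3.00 is what its own edge list implies:
every route to fetuin A passes through RelA at depth 3. A richer
knowledge base could contain shorter routes; the fixture reports only
what it encodes. Similarly, one-step common targets are allowed by the
engine but do not occur on the fixture, because the three compounds
share no primary target.

## The planted-structure generator

`generate_network()` builds benchmark networks with known ground truth.
What it emulates: per-compound receptor binding of random sign;
receptor-mediated chains of prescribed depth whose sign sequence is
drawn uniformly from the valid patterns *conditioned on the binding
sign*, so every planted chain nets to activation exactly at its planted
depth; conflicted decoys (activation from one source, inhibition from
another); too-deep decoys (reachable only beyond the bound); genuine
common targets left unannotated; and a signed Erdős–Rényi background.
Defaults plant two groups — 6 targets with depth profile (2, 2, 3) and
35 with (2, 3, 3) — over a 100-node background with edge probability
0.02 and 30% inhibitory edges, which keeps the benchmark at the scale of
a focused query result rather than a whole knowledge base.

Background edges run only among background nodes, so they can never
create source-to-target shortcuts; a post-generation audit nevertheless
re-derives every planted minimal depth and decoy classification from the
finished network and regenerates (bounded retries) on any violation.
The ground truth returned is therefore exact by construction, and
recovery tests assert precision and recall of 1 rather than
approximations.

What the generator does *not* emulate: the degree distribution, motif
structure or annotation noise of a real curated database, correlated
evidence between parallel findings, or unspecified-effect edges.
Passing the planted-recovery tests shows the pipeline's logic is exact
under its own semantics; it says nothing about how complete or correct
any particular knowledge base is.

## Determinism and numerical choices

* All orderings are specified: paths sort by terminal, step count, node
  chain, sign chain; convergence records by mean depth then target id;
  all id sorts use C-locale radix order.
* Mean depths are rounded half-up to 2 decimals; group keys are the
  rounded values formatted to two decimals.
* The generator takes a mandatory integer seed and restores the
  caller's RNG state; identical configuration and seed reproduce
  byte-identical TSV outputs.
* Exports never embed timestamps, so re-running a pipeline rewrites
  identical files.
* Degenerate inputs are defined, not special-cased: an empty
  evidence-filtered network yields empty convergence tables; a build in
  which no (source, target) pair has a path is an error, while
  individually unreachable pairs only warn; conflict removal may
  legitimately return a network with zero targets.

## Validation scale

The test suite validates the path engine against an independent
brute-force oracle (igraph simple-path enumeration with exhaustive sign
expansion) on 1,000 random graphs of up to 8 nodes and 20 edges, and
exercises planted recovery at the 41-target and 349-target-plus-300-decoy
scales, sizes at which every run completes in seconds while still
covering all decoy classes.

## Limitations

* Unit-length edges only: no weighted shortest paths, no probabilistic
  path scoring, no enrichment statistics over disease annotations.
* Strict concordance can be aggressive on dense networks: one short
  inhibiting route disqualifies a target however many activating routes
  exist.
* The depth bound is a hard horizon; biology just beyond it is
  invisible, and results should always be read as "within k steps".
* Identifier matching is exact and case-sensitive; mapping between gene
  identifier systems is out of scope.
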