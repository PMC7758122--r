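---
title: "From docking scores to key targets: the netpharm inference chain"
author: "netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From docking scores to key targets: the netpharm inference chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

Multi-herb preparations act through many low-affinity compounds hitting many
proteins at once, so no single compound-target pair explains their effect.
Network pharmacology replaces the one-drug-one-target view with a graph: the
compounds, the proteins they bind, and the pathways those proteins belong to
form a tripartite network, and the question "which targets and pathways
matter?" becomes a question about the topology of that network. netpharm
implements this chain for docking-scored and database-evidenced interaction
data: threshold the docking scores thermodynamically, merge the evidence,
build the networks, compute centralities, and screen.

The packaged fixtures transcribe the ingredient and docking tables of a
thirteen-compound anti-inflammatory injection (RDNI: nine quantified
ingredients of honeysuckle, cape jasmine and sweet wormwood, plus four
metabolites), which also fixes the scale the synthetic generator emulates.

## The docking threshold

Docking engines report an estimated binding free energy
$\Delta G$ (kcal/mol). A dissociation-scale inhibition constant $K_i$
relates to it by
$$\Delta G = R\,T\,\ln K_i,$$
with $R = 1.987204\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$. A compound is
accepted as binding a protein when its predicted energy is *strictly below*
the energy equivalent of a $K_i$ cutoff; the conventional cutoff
$K_i = 1\ \mu M$ gives the familiar $-8.18$ kcal/mol.

Two numerical choices matter here.

* **Temperature.** The conversion is usually quoted "at room temperature",
  which is ambiguous between 298 K and 298.15 K. At 298.15 K,
  $RT\ln(10^{-6}) = -8.1855$, which rounds to $-8.19$; only $T = 298$ K
  reproduces the conventional $-8.18$ at two decimals
  ($RT\ln(10^{-6}) = -8.1814$). netpharm therefore defaults to
  `temperature_k = 298`. Both are available, and `threshold_spec(pin_energy =)`
  pins a literal printed threshold when exact reproduction of a published
  cutoff matters more than its derivation.
* **Strictness.** "Lower than" is read as a strict `<`; a record at exactly
  the threshold is rejected. `threshold_spec(comparison = "<=")` flips this.
  The threshold is recomputed from $K_i$ by default rather than hard-coded,
  so its thermodynamic provenance stays testable.

Records passing the filter become interaction edges with evidence
`"docking"`; database-curated edges carry evidence `"database"`. Integration
deduplicates on the (compound, target) pair, records concatenated source
labels, and reports target counts satisfying the inclusion-exclusion
identity `n_union = n_known + n_docking - n_overlap` (counts are of unique
accessions, not edges).

## Networks and their conventions

Three undirected, unweighted networks are built:

* **CTN** (compound-target): all integrated edges; nodes keyed by compound
  abbreviation and UniProt accession.
* **TPN** (target-pathway): KEGG memberships (`hsaNNNNN` ids) restricted to
  the CTN's targets. Targets without any pathway simply drop out, which is
  why a TPN can hold fewer targets than the CTN that seeded it.
* **CTPN**: induced by a set of selected pathways — the pathways, the
  targets linked to them, the compounds linked to those targets, and the
  induced edges only.

Nodes that lose all edges are dropped rather than kept isolated: a compound
whose every docking record failed the threshold is absent from the CTN,
matching how published compound-target figures show only connected nodes.
Class constraints (CTN edges compound-target only, and so on) are enforced
at construction.

## Centralities

All three centralities are computed natively on the whole heterogeneous
network; class filtering happens only at screening time.

* **Degree** is the raw incident-edge count — the screening rules ("degree
  > 6") are phrased in raw counts, so no normalization is applied.
* **Betweenness** uses Brandes' single-source accumulation over BFS
  shortest-path DAGs, reported in raw unordered-pair units with endpoints
  excluded; pairs with no connecting path contribute nothing. A normalized
  column (divide by $(n-1)(n-2)/2$) is also provided, but because the
  screens compare values against class *means*, selections are invariant to
  this scale choice (asserted by a test).
* **Closeness** uses the within-component form $r/D$ — reachable-node count
  over total distance — the convention of Cytoscape's NetworkAnalyzer
  plugin, bounded in $[0,1]$; isolated nodes score 0. The alternative
  (harmonic centrality) is deliberately not offered to keep the screen's
  semantics single-valued.

The test suite pins both implementations to independent oracles: an
exhaustive shortest-path enumerator for betweenness and an igraph
distance-matrix recomputation for closeness, over hundreds of random graphs
including disconnected ones.

## Screening cascades

**Key targets** (on the CTN): a target qualifies when (1) its degree ranks
in the top ten of all targets and (2) its betweenness *and* closeness both
strictly exceed the target-class means. Ties at the tenth degree value are
all included — the rule is about a degree boundary, not a fixed count, and
tie inclusion makes the selection invariant to node insertion order. All
mean comparisons are strict, so a single-target network selects nothing
(its own mean equals its value). Results are ordered by degree, then
betweenness, then id, and an audit table records each criterion's verdict
for every target.

**Important pathways** (on the TPN): degree strictly greater than 6, then
betweenness above the pathway-class mean, then removal of blocklisted
non-specific pathways, then closeness above the pathway-class mean. The
blocklist ships with four catch-all KEGG maps (`metabolic pathways`,
`pathways in cancer`, `neuroactive ligand-receptor interaction`,
`microRNAs in cancer`) — aggregate maps that name no single biological
process; it is a curation judgment and fully editable. The criteria are
conjunctive, so the selected set is independent of cascade order; only the
audit's recorded removal stage depends on it.

The final narrowing from important to *key* targets/pathways in a published
analysis is a literature judgment, not an algorithm; netpharm deliberately
models it as an explicit user-supplied selection (`selected_pathways` in
the pipeline config) rather than pretending to automate it.

The cross-talk layer — directed regulatory links among the seven
inflammation-related pathways, labelled by mediating molecules, with
feedback loops flagged — is curated knowledge, shipped as a fixture and
validated structurally: every pathway must feed into the NF-kB signaling
pathway, the common effector of the network.

## The synthetic world

`generate_tripartite()` states a world at the scale of the motivating
study, chosen once:

| parameter | default | why |
|---|---|---|
| `n_compounds` | 13 | the fixture compound table's size |
| `n_targets`, `n_pathways` | 50, 30 | tens of targets, a thin pathway layer |
| `edge_prob_ct` | 0.08 | background degree ~1, as for most real targets |
| `hub_targets`, `hub_boost` | 5, 5 | a handful of multi-compound hubs, mean degree ~5 |
| `membership_concentration` | 0.3 | heavy-tailed Dirichlet-multinomial pathway sizes: a few pathways exceed degree 6, most stay small |
| energy mixture | $-9.5 \pm 0.8$ / $-6.8 \pm 1.0$ kcal/mol | binder and non-binder components straddling $-8.18$ |

All randomness flows from one seed; a fixed seed reproduces byte-identical
output, and the ledger returned with the data records the planted hubs,
per-pathway sizes and exact edge counts so network summaries can be checked
against the generator's own bookkeeping.

What the generator does *not* emulate: database coverage bias, correlated
docking errors, chemically related compounds sharing targets, or pathway
overlap structure. A green test on synthetic data therefore establishes
that the machinery is correct under the stated statistical assumptions,
not that those assumptions hold for any particular preparation.

**A known, deliberate red.** One stochastic acceptance property expects the
key-target screen to recover at least 90% of planted hubs over 100
replicates. At the stated defaults the measured recovery is ~88.6%: about
17% of hubs draw a realized degree of 3 or less from Binom(13, 0.4), and
such low-contrast hubs mostly survive the tie-inclusive top-ten rule but
fail the strict betweenness-above-mean filter. This is the screen behaving
as specified on hard replicates, and the generator's parameters are part of
the stated world, so the bound is asserted unchanged and left failing
rather than tuned into passing.

## Degenerate inputs and numerical notes

* Empty tables with headers parse to empty results; an empty edge set
  builds an empty network; summaries of an empty network are all zero.
* Betweenness/closeness on disconnected graphs restrict to reachable pairs;
  isolated nodes score zero everywhere.
* The exact inverse pair `ki_to_binding_energy()` /
  `binding_energy_to_ki()` round-trips to relative 1e-12 over the
  nanomolar-millimolar range.
* Report serialization uses fixed key order and full precision, so two runs
  on identical inputs are byte-identical — determinism is a tested
  property, not an aspiration.

## Limitations

netpharm starts where a docking engine and the curated databases stop: it
does not run docking, query PubChem/TCMSP/BindingDB/DrugBank/KEGG, render
KEGG maps, or judge which important pathways are biologically key. Those
stages are either upstream tools or scientific judgment, and the package's
interfaces (CSV tables in, networks, audits and a JSON report out) mark the
boundary explicitly.
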