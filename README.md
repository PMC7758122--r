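# netpharm

Network-pharmacology inference for multi-component preparations: from
docking scores and curated interaction tables to key targets and important
pathways.

Traditional-medicine formulas act through many compounds binding many
proteins; their mechanism is a property of the resulting
compound–target–pathway network, not of any single pair. `netpharm`
implements the standard inference chain for such data:

1. **Thermodynamic docking filter.** A docking record is accepted when its
   binding free energy lies strictly below the energy equivalent of an
   inhibition-constant cutoff, ΔG = RT·ln(Ki) with
   R = 1.987204×10⁻³ kcal mol⁻¹ K⁻¹. At Ki = 1 μM and 298 K this is the
   conventional −8.18 kcal/mol.
2. **Evidence integration.** Docking-evidenced edges are merged with
   database-evidenced ones, deduplicated on (compound, target), with a
   target-count report satisfying n_union = n_known + n_docking − n_overlap.
3. **Network construction.** The compound–target network (CTN), the
   target–pathway network (TPN, KEGG `hsa` memberships restricted to CTN
   targets) and the pathway-induced compound–target–pathway network (CTPN),
   all as typed undirected graphs with Cytoscape-compatible SIF/GraphML
   export.
4. **Centrality.** Native degree, betweenness (Brandes, raw unordered-pair
   units) and closeness (within-component r/D, the NetworkAnalyzer
   convention), verified against exhaustive oracles in the test suite.
5. **Screening.** Key targets: degree in the top ten of all targets (ties
   included) **and** betweenness and closeness strictly above the
   target-class means. Important pathways: degree > 6, betweenness above
   the pathway mean, not on the non-specific blocklist, closeness above
   the pathway mean. Both screens return a full per-candidate audit.

A seeded synthetic generator (`generate_tripartite()`,
`generate_docking_table()`) produces tripartite data with planted hub
targets, heavy-tailed pathway sizes and a two-component Gaussian energy
mixture, so the whole chain is testable offline. The ingredient and docking
tables of the Reduning Injection (RDNI) study ship as fixtures under
`inst/extdata/`, together with a curated seven-pathway cross-talk network.

## Worked example

```r
library(netpharm)

dock <- read_docking_table(system.file("extdata", "table2_docking.csv",
                                       package = "netpharm"))
spec <- threshold_spec(ki_molar = 1e-6)
spec
#> docking threshold: Ki = 1e-06 mol/L at 298 K -> energy < -8.1814 kcal/mol

ctn <- build_ctn(filter_docking(dock, spec))
ctn
#> typed_network: 27 nodes (8 compounds, 19 targets, 0 pathways), 38 edges

res <- screen_key_targets(centrality_table(ctn))
res
#> screening_result: 5 of 19 candidates selected
#>    P51580, P14555, P06401, O43741, P37231

head(res$audit[, c("node", "degree", "betweenness", "closeness", "selected")], 7)
#>     node degree betweenness closeness selected
#> 1 P51580      6       69.49     0.511     TRUE
#> 2 P14555      4       34.31     0.453     TRUE
#> 3 P06401      4       31.48     0.436     TRUE
#> 4 O43741      4       26.59     0.453     TRUE
#> 5 P37231      3       12.93     0.421     TRUE
#> 6 P35367      3        8.80     0.407    FALSE
#> 7 P04150      2        5.39     0.381    FALSE
```

All 38 fixture records pass the 1 μM filter, yielding 19 docking-evidenced
targets across 8 compounds. The screen keeps the five targets — led by
thiopurine S-methyltransferase (P51580), docked by six compounds — whose
degree ranks top-ten *and* whose betweenness/closeness exceed the
target-class means; P35367 makes the degree cut but sits below both means.

The one-call pipeline wraps the chain and emits a machine-readable report
(plus SIF/GraphML/CSV artifacts when `out_dir` is set); configs may be R
lists or YAML/JSON files:

```r
report <- run_pipeline(list(
  docking = system.file("extdata", "table2_docking.csv", package = "netpharm")))
report
#> netpharm run report
#>   threshold: -8.1814 kcal/mol
#> targets: 0 known, 19 docking, 0 overlap -> 19 integrated
#>   CTN: 27 nodes (8 compounds, 19 targets, 0 pathways), 38 edges
#>   key targets: P51580, P14555, P06401, O43741, P37231
```

Supplying `known_edges` and `pathways` CSVs activates the integration,
TPN/CTPN and pathway-screening stages.

## Acceptance script

`scripts/acceptance.R` re-runs the installed package end to end — the full
pipeline on the packaged docking fixture, then on a seeded synthetic
dataset exercising the pathway stages — and writes its JSON output:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/network-pharmacology.Rmd`) documents the
model and its conventions: the temperature choice behind −8.18 kcal/mol,
the closeness convention, tie handling in the top-k rule, the blocklist,
the synthetic world's defaults, and known limitations.
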