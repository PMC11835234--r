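# aopnetworkr

Reconstruction and curation of **Adverse Outcome Pathway (AOP) networks**
from AOP-Wiki-shaped RDF, as an offline-friendly R library with a scriptable
command-line interface.

An AOP is a linear chain of biological events — a Molecular Initiating Event
(MIE) linked through intermediate Key Events (KEs) to an Adverse Outcome
(AO) — with each directed link a Key Event Relationship (KER). Because the
same KE can appear in many AOPs, a set of pathways retrieved from the
AOP-Wiki induces a network: join the chains on their shared KE nodes. In
practice two obstacles stand between the repository and a usable network:

1. the content is exposed as RDF and must be queried with SPARQL, and
2. functionally identical KEs are often submitted under slightly different
   names (e.g. `"N/A, Neurodegeneration"` vs `"Neurodegeneration"`), so
   pathways that should connect appear disjoint.

`aopnetworkr` addresses both. It builds parameterized SPARQL SELECT queries
against an AOP-Wiki-shaped source (a local Turtle file or a SPARQL
endpoint), assembles the retrieved pathways into a deduplicated network, and
detects near-duplicate KE labels by **Levenshtein distance**: for two
normalized labels *a*, *b* with edit distance *d(a, b)* the similarity

```
sim(a, b) = 1 - d(a, b) / max(|a|, |b|)
```

is compared against a threshold (default 0.75); pairs at or above it are
*suggested* for merging. Merges are never automatic — the expert confirms
each directive, and `apply_merge()` contracts the two nodes with full
provenance (memberships, roles, genes and source IRIs unioned; parallel
edges collapsed with their asserting AOPs unioned). Every retrieval and
network-altering operation is appended to a JSON-lines **audit log** that
both credits the original AOP authors (CC BY-SA) and serves as a recipe:
`replay()` re-executes the log against a source and reproduces the network
exactly when the source is unchanged. Networks export to Cytoscape-ready
GraphML and SIF, and to CSV/XLSX tables.

A seeded fixture generator emulates the AOP-Wiki RDF shape (linear chains,
probabilistic KE sharing, injected near-duplicate labels, statuses, authors,
gene links) with a ground-truth manifest, so the entire pipeline runs and
tests without network access.

## Worked example: the neurotoxicity case study

```r
library(aopnetworkr)

ttl <- tempfile(fileext = ".ttl")
writeLines(case_study_fixture()$turtle, ttl)
src <- rdf_source(ttl)

log <- audit_log()
bundle <- fetch_bundle(src, aop_ids = c("12", "260"), log = log)
net <- assemble(bundle, log = log)
summary(net)
#> AOP network
#>   AOPs:        2
#>   Key Events: 9 (0 shared by >1 AOP)
#>     role MIE: 2
#>     role KE: 5
#>     role AO: 2
#>   KERs:        7
#>   gene nodes:  2
```

The two pathways are disjoint — their AOs were submitted under different
names. The merge scanner finds exactly that pair:

```r
suggest_merges(net)
#>   ke_id_a ke_id_b           label_a                label_b distance similarity
#> 1     105     204 Neurodegeneration N/A, Neurodegeneration        5  0.7727273
```

The distance is 5 (deleting the `"n/a, "` prefix) over a longer normalized
length of 22, hence similarity 1 − 5/22 ≈ 0.77, above the 0.75 default.
Confirming the merge joins the networks:

```r
net <- apply_merge(net, keep_id = "105", drop_id = "204")
node_detail(net, "105")
#> KE 105: Neurodegeneration
#>   roles: AO
#>   member AOPs: 12, 260

write_graphml(net, "neuro.graphml")   # open in Cytoscape
write_log(log, "session.jsonl")       # the replayable session record
```

Replaying `session.jsonl` against the same source regenerates this network
byte-for-byte (canonical JSON comparison); against a *changed* source it
regenerates the current version of the same analysis.

The same session can be driven from a shell via the bundled CLI
(`inst/cli/aopnet`): `fetch`, `build`, `suggest`, `merge`, `neighbors`,
`export`, `replay`, … — run it with `--help` for the full list.

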