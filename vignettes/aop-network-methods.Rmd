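---
title: "Methods: assembling and curating AOP networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembling and curating AOP networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aopnetworkr)
```

This vignette documents the model behind `aopnetworkr`: what the package
computes, the choices made where the problem is genuinely open, and what the
synthetic fixtures do and do not establish about real AOP-Wiki data.

## The data model

An Adverse Outcome Pathway (AOP) is curated as a linear chain: one Molecular
Initiating Event (MIE), intermediate Key Events (KEs), and a terminal
Adverse Outcome (AO), connected by directed Key Event Relationships (KERs).
The package's containers mirror that structure:

* **KeyEvent** — one biological event node. Roles (`MIE`, `KE`, `AO`) are
  the *union over member AOPs*: the same event can be the AO of one pathway
  and an intermediate KE of another, so roles are per-node sets, not single
  tags. Gene annotations, source IRIs and AOP memberships are sets.
* **KeyEventRelationship** — a directed edge between two distinct KEs with
  the set of AOPs asserting it. After assembly there is at most one edge per
  ordered KE pair; parallel assertions collapse and their asserting-AOP sets
  union.
* **Aop** — id, title, OECD status, ordered author list, and its KE/KER id
  sets with the MIE/AO subsets.
* **AopNetwork** — the three id-keyed maps plus gene annotation nodes in a
  separate namespace. A validator (`validate_network()`) re-derives each
  KE's membership set from the Aop records and enforces referential
  integrity after every operation; the test suite runs it after each
  mutation.

Identifiers are bare numeric strings ("AOP 12", "KE 105"), stripped of their
IRI namespaces at ingest; the original IRIs are retained on each node. All
maps are kept in sorted id order, which is what makes exports, canonical
serializations and logs byte-stable.

## Retrieval

`build_query()` renders deterministic SPARQL 1.1 SELECT text per entity
kind (AOPs, KEs, KERs, gene links, authors), parameterized by ids through a
`VALUES` block and optionally filtered by OECD status. The predicate IRIs
come from a configurable vocabulary (`default_vocabulary()`) of ten logical
relations; the default mirrors the public AOP-Wiki RDF shape, and because
the mapping is data, the package survives upstream schema drift without
code changes. Unknown relation names fail loudly.

Execution is backend-split behind `rdf_source()`:

* local Turtle files are parsed (a minimal Turtle subset reader lives in the
  package, as the R dependency stack offers no RDF engine) and the query
  *plan* is evaluated directly by a small join engine;
* `memory://` endpoints parse the rendered SPARQL text back and evaluate it
  in-process — this exercises the full query-text path without a network,
  and the suite asserts that both routes return identical bundles;
* `http(s)` endpoints receive the same text over HTTP (untested in offline
  runs by construction).

Retrieval is deliberately forgiving: requested-but-absent ids become
warnings, not errors; a KER endpoint missing its KE record gets a stub node
plus a warning; AOPs whose KERs are missing entirely yield isolated KE
nodes. Only structurally contradictory input (two different records under
one id, a dangling endpoint after stubbing) is fatal. When KEs are requested
directly, their containing AOPs are fetched as *context records* — title,
status, authors and the membership of the requested KEs only — so every KE
has a pathway of origin without silently expanding the retrieval to whole
chains; KERs are fetched only for explicitly requested AOPs.

## Assembly and its invariants

`assemble()` joins AOPs on shared KE ids. Its contract, enforced by tests:

* **Deduplication** — a KE id occurring in several AOPs becomes one node;
  roles/memberships/genes union. Assembly is idempotent: a bundle
  containing each AOP twice assembles to exactly the network of the
  single-copy bundle.
* **Edge collapsing** — parallel assertions of one directed KE pair become
  one edge keeping the smallest KER id; AOP records are rewritten to the
  canonical edge ids.
* **Cycles warn, never fail.** Individual AOPs are acyclic by design, but a
  network of independently curated pathways (or a user merge) may create a
  directed cycle; treating that as an error would block exactly the
  curation work the tool exists for. The same policy covers a KE pair
  linked in both directions by two AOPs: both edges are kept, with a
  warning.

## Status filtering, node details, neighbourhoods

`filter_by_status()` keeps the AOPs whose status is in the allowed set plus
the KEs/KERs reachable from them, recomputing memberships; the input network
is untouched and an empty result is legal (with a warning). The recognised
status vocabulary defaults to `{Under Development, Under Review, Endorsed}`
— the repository's endorsement stages are not fixed for all time, so the
set is part of the configurable vocabulary rather than hard-coded.

`ego_network()` returns the induced subnetwork within distance 1 or 2 of a
seed KE set. Distance is measured on the **undirected skeleton**: the
neighbourhood view exists to show the connections of a KE in both
directions, and restricting to downstream reach would hide half of them.
Direction is preserved in the returned edges. Gene nodes are annotation
only — they live in a separate namespace, never count as a hop, never
participate in merging, and are attached to the retained KEs only on
request.

## Merge suggestion and application

Label comparison uses the Levenshtein distance, computed in C++ (iterative
dynamic programming) over labels normalized by case-folding, trimming and
whitespace collapsing. Normalization is a package choice — the comparison
could equally run on raw labels — and is documented rather than claimed
faithful to any particular upstream tool. Similarity is
`1 - d / max(nchar)`, on normalized lengths; two empty normalized labels
count as similarity 1.

The default threshold 0.75 is chosen so that the canonical near-duplicate
pattern — a `"N/A, "` prefix on a typical-length label, similarity ≈ 0.77
for `"N/A, Neurodegeneration"` vs `"Neurodegeneration"` — is suggested,
while short unrelated labels (whose normalized-length ratio inflates
quickly) are not. It is a per-call parameter and a CLI flag.

Suggestions are **pure** and all-pairs (O(n²), ample at AOP-Wiki scale of a
few thousand KEs); application is a separate, explicit directive because
name similarity is evidence, not proof — the biological judgement belongs
to the expert. `apply_merge()` contracts the dropped node into the kept
one: edges re-attach, self-loops arising from the contraction are removed,
parallel edges collapse with asserting-AOP union, node attributes union,
and every AOP record is rewritten. Node count decreases by exactly one and
the validator must pass. Which node to keep is the user's call; the CLI's
auto-pick keeps the shorter normalized label, on the view that the cleaner
name should survive (the case study's merged node is the unprefixed
`"Neurodegeneration"`). All KE-role nodes are compared regardless of role:
the canonical example merges two AOs, but nothing restricts near-duplicate
submissions to AOs.

## Audit log and replay

Every retrieval and network-altering operation appends one JSON-line entry:
gapless sequence number, UTC timestamp, action, parameters (string-valued,
so the write-read round trip is exact), affected ids, tool version. Credit
entries — one per fetched AOP, listing its authors — make the log a
self-contained attribution record under CC BY-SA; an AOP without author
triples is still credited, flagged `missing_authors`. No user identifier is
recorded unless an actor label is explicitly supplied.

The log stores parameters, not data snapshots. `replay()` therefore
re-fetches from the source: on an unchanged source the replayed network is
canonically identical to the session's (the suite verifies this over
randomly generated sessions), and on a changed source it deliberately
reflects the current data — the log is a recipe for the *current version*
of the analysis. The consequence (replay can diverge when the source
changed) is intended; timestamps play no role in replay semantics. A merge
directive whose nodes no longer exist, or a fetch whose ids have vanished,
aborts replay with the offending entry's sequence number.

Networks are compared by canonical JSON (`canonical_json()`): sorted maps,
sorted sets, no audit state, no timestamps. Two networks are operationally
identical exactly when the strings are byte-equal.

## Exports

GraphML is the primary Cytoscape interchange (natively importable), SIF the
lightweight fallback; CSV/XLSX carry node/edge tables and the raw
pre-assembly bundle tables. Multi-valued attributes are "|"-joined sorted
strings. The CSV dialect is pinned (comma, quote only when needed, UTF-8,
LF) so files are bit-reproducible; XLSX writing goes through python's
openpyxl and the suite asserts CSV/XLSX cell equality. AOP records travel
inside the GraphML as a graph-level JSON attribute, which is what makes the
GraphML write–read–write cycle byte-identical. No timestamps appear in any
artifact. Rendering, layout and styling are delegated to Cytoscape;
topological statistics are out of scope.

## The synthetic fixtures

`generate_fixture()` emulates the structural features of AOP-Wiki content
that the algorithms depend on: linear MIE→…→AO chains (length ≥ 2), KE
sharing across AOPs (`share_prob`, default 0.3 — enough sharing that
multi-AOP joins and shared-edge collapsing are routinely exercised),
injected near-duplicate labels (`near_dup_rate`, default 0.2) drawn from a
fixed perturbation menu — the `"N/A, "` prefix first, as the prototypical
real-world case, then case changes, doubled spaces and single-character
typos — each constructed to stay at or above the default suggestion
threshold so that injected pairs are recoverable with recall 1.0 by
construction, plus statuses, authors and per-KE gene links. Labels come
from a fixed vocabulary of toxicology-flavoured phrases purely for readable
exports; they carry no semantics in tests. Identical spec and seed give
byte-identical Turtle, and generation restores the caller's RNG state.

`case_study_fixture()` reconstructs a well-known neurotoxicity
demonstration deterministically: AOPs 12 and 260 with their real titles,
the two AO labels `"Neurodegeneration"` / `"N/A, Neurodegeneration"`,
disjoint chains, at least one author each, and statuses chosen so the
status filter has one match (260 Endorsed, 12 Under Development). The chain
*interiors* are synthetic — the fixture reproduces the real AOP-Wiki titles, AO
labels and the disjoint-then-merged topology, nothing more, and is labelled
accordingly.

What passing tests show, and what they do not: the fixtures prove the
machinery — retrieval correctness against a ground-truth manifest, oracle
equality for distances and neighbourhoods, idempotence, conservation under
merges, byte-stable exports, replay determinism. They do not certify
behaviour against the full heterogeneity of live AOP-Wiki RDF (datatyped
literals, schema drift, inconsistent submissions beyond the missing-KER and
near-duplicate patterns modelled here); the vocabulary indirection and the
forgiving ingest policy are the designed seams for absorbing that
heterogeneity.

## Numerical and procedural choices

* Edit distance is computed on bytes of normalized labels; fixture content
  is ASCII. Multi-byte characters in real labels would count per byte, a
  known simplification.
* Deterministic order everywhere: ids sort numerically, then
  lexicographically (byte order); suggestion lists sort by similarity then
  canonical pair; ties in edge collapsing keep the smallest KER id.
* Test problem sizes (the package's own choice of desk-scale conditions):
  200 seeded fixtures for the neighbourhood oracle, 100 for idempotence and
  merge conservation, 50 random sessions for replay, the exhaustive
  length-≤7 sweep over a three-letter alphabet for the distance (checked
  against `utils::adist`, with the naive exponential recursion exhaustive
  where tractable and a memoized recursion on 1000 random pairs up to
  length 20).
* Degenerate inputs: empty networks export and round-trip; an empty bundle
  yields five header-only raw tables; a status filter with no survivors is
  a warning; `fetch` of only-absent ids returns an empty bundle listing the
  ids in `missing`.

## Known limitations

* No write-back to the AOP-Wiki; merges live in the session and its log.
* Retrieval is id- and status-driven; there is no free-text search.
* Similarity is purely lexical; semantic/NLP comparison is out of scope.
* Live-endpoint HTTP access exists but cannot be exercised in offline test
  environments; the memory endpoint covers the query-text path.
* The CLI persists sessions as canonical JSON in the output directory — a
  deliberate substitute for the in-memory session a GUI would hold.
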