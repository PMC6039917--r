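---
title: "Aligning network layouts by attribute matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning network layouts by attribute matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copycatr)
```

## The problem

Visual differential analysis of networks — a gene-regulatory network and
the subnetwork derived from it after filtering, or homologous networks
across species — only works when both networks are drawn the same way.
A generative layout (force-directed, circular, ...) recomputed on the
second network scrambles the geometry, so nothing can be compared at a
glance. `copycatr` instead *transfers* an existing layout: a reference
(**source**) view lends its node coordinates to a **target** view wherever
a node of the target carries the same mapping-attribute value as a node of
the source. Nodes present on only one side are exactly the interesting
ones, so the package can select them (making them queryable downstream)
and park the target-side ones on a grid beside the mapped layout. The
source viewport — zoom and center — is cloned too, so both networks render
in the same frame, not merely with the same coordinates.

## The procedure

Let the source network have $N$ nodes and the target $M$. Matching is
keyed on one node-table column per network (both default to `name`); the
two columns must both be string-typed or both integer-typed. Two passes:

1. **Map building.** Walk the source nodes in stored order and hash each
   present mapping value to that node's $(x, y, z)$ view coordinates. A
   value occurring more than once is overwritten — only the *last
   encountered* source node survives. Nodes with a missing value
   contribute nothing.
2. **Transfer.** Walk the target nodes; every node whose value is in the
   map takes the mapped coordinates verbatim. Several target nodes sharing
   one value all stack at the same point. Unmatched nodes (including nodes
   with missing values) keep their coordinates.

This is $O(N + M)$ time and $O(N)$ memory, and edges never enter the
computation, so runtime is independent of edge count.

Afterwards, optionally and independently of one another:

* `select_unmapped = TRUE` clears all selection flags in both views and
  selects the unmapped target nodes and the unmatched source nodes, so the
  selection in each view equals its unmapped set exactly.
* `grid_unmapped = TRUE` lays out the unmatched target nodes row-major
  (stored node order) in a grid of $\lceil\sqrt{k}\rceil$ columns.

Finally the source viewport (zoom, center) is copied onto the target view,
unless the source view is empty, in which case the target viewport is left
alone.

### Matching is by value, not by node

The first pass erases node identity: only values survive into the map.
Consequently, when a source value is duplicated and any target node
matches it, *all* source nodes carrying that value count as mapped and
none of them is selected. A target node is unmapped when its value is
missing or absent from the map; a source node is unmapped when its value
is missing or matched by no target node. For integer columns, equality is
numeric; kinds are validated to agree beforehand, so cross-kind
coincidences (the string `"7"` against the integer `7`) cannot arise.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `source_column`, `target_column` | `"name"` | — | must share a string or integer kind |
| `select_unmapped` | `FALSE` | — | `FALSE` leaves prior selections untouched |
| `grid_unmapped` | `FALSE` | — | composes with selection; applied after it |
| `grid_spacing` | 80 | screen units | grid cell edge; also the gap between the mapped bounding box and the grid |

Coordinates follow the screen convention throughout: x grows rightward,
**y grows downward**, z defaults to 0 (transferred when present; formats
lacking z read and write it as 0). This matches `.cyjs` files produced by
Cytoscape, so round trips involve no sign flips.

## Geometry choices

"Top right portion of the target view" for the grid is a convention this
package pins down precisely: the grid anchors at
$(\max_x(\text{mapped}) + s,\ \min_y(\text{mapped}))$ where $s$ is the
spacing — immediately right of the mapped nodes' bounding box, aligned
with its top (downward-positive y makes $\min_y$ the top). With no mapped
nodes the anchor is the origin. The anchor depends only on mapped nodes,
whose coordinates are fixed by the map after pass one; this is what makes
a second identical run a strict no-op even with gridding enabled.

The viewport's "location" is modelled as a center point plus a zoom
factor. Whether a pan offset or a center is stored is irrelevant to the
cloning semantics (a straight copy), but the center-point reading keeps
`register_network()`'s default — zoom 1.0 centered on the layout's
bounding-box midpoint — well defined.

## The session model and the service

A `copycat_session()` mirrors a running Cytoscape instance: networks and
views registered under monotonically allocated session-unique identifiers
(SUIDs, starting at an arbitrary base so they never look like row
indices), plus a *current view* pointer, which is what the `"current"`
selector resolves to. Name-addressed calls (the Command endpoint) operate
on the *primary* view of the named network; if two networks share a name,
the one with the smallest SUID wins — a deterministic choice in a
situation where name addressing carries no other handle, preferred here
over raising an error.

`rest_handle()` implements the HTTP contract as a pure function
(method, path, body) → (status, body), which is how most of the contract
tests exercise it; `rest_serve()` binds it to a port. Layout calls answer
with a CIResponse envelope — `data` with `mappedNodeCount` /
`unmappedNodeCount` (plus the unmapped id lists) and an empty `errors`
array on success; on failure an empty `data` and `errors[0].status`
equal to the HTTP status: 404 for unresolvable views or networks and for
every mapping-column problem (absent column, non-matchable kind, kind
mismatch), 400 for malformed bodies and for a source view equal to the
target view. Boolean parameters arrive either as JSON booleans or as the
strings `"true"`/`"false"`, since shell clients commonly quote them. The
Command variant accepts POST only.

## What the synthetic generator emulates

`generate_pair()` produces the study conditions for the property tests:
two networks whose mapping values are zero-padded decimal strings (so
lexicographic equality is plain string equality, immune to locale), with
a controlled overlap fraction between target and source values, a
duplicate-value rate on the source side, a missing-value rate on the
target side, coordinates uniform in a ±500-unit box (a typical screen
extent), and sparse random edges (about two per node) that the expected
results ignore by construction — which is precisely what lets
edge-independence be tested by regenerating edges under a different seed.
The generator returns ground-truth expectation sets derived by set
algebra on the generated name vectors, a derivation independent of both
the production algorithm and the quadratic `brute_force_copycat()`
oracle, so three routes to the same answer are compared in the tests.

What it does *not* emulate: realistic topology (no scale-free degree
distributions), spatially structured layouts, multi-column attribute
tables, or homology-style many-to-many mappings beyond uniform value
duplication. Passing tests therefore certify the matching semantics and
counts, not any aesthetic property of real biological layouts.

Problem sizes used by the suite and the acceptance script: 200 random
pairs of up to 50 nodes for oracle equivalence (exhaustive comparison is
cheap there), 60 pairs of ~40 nodes for conservation/idempotence, 20 for
edge independence, and three decades (10³–10⁵ nodes, equal on both sides)
for the runtime-scaling fit, where a log-log slope below 1.3 is the
declared pass line for linear-time behaviour; the measured slope is
typically ~0.9.

## Numerical and degenerate-input choices

* Coordinate transfer is assignment, never arithmetic: matched
  coordinates are bit-for-bit equal to the source's, and tests assert
  `identical()`, not tolerance equality.
* File writers emit 17 significant digits (JSON and GraphML alike), which
  round-trips IEEE doubles exactly.
* An empty source network yields an empty map — every target node
  unmapped — and suppresses viewport cloning.
* An empty target network is legal: counts are (0, 0).
* `.cyjs` column typing is inferred (JSON is untyped): a column is
  integer iff every present value is an integral number, else values are
  coerced to strings. GraphML declares types; `double` columns load as
  kind `"other"` and are rejected as mapping columns, as required.
* SIF rows with two fields are hard errors (reported with their line
  number); layout-table rows naming absent nodes are skipped with a
  warning, since side-car tables commonly drift from edge lists.

## Known limitations

One view per network (the primary view model); no visual styles, edge
views, or nested groups; no generative layouts and no neighbour-based
placement of unmapped nodes; SIF output is refused because it cannot
carry coordinates. The service implements the documented endpoint set
only — no image export, no API browser pages.

## A worked session

```{r worked}
f <- figure_fixture()          # 8-node reference (A-H), 9-node derived (A-G, N, O)
res <- copycat(f$session, f$source_view_suid, f$target_view_suid,
               select_unmapped = TRUE, grid_unmapped = TRUE)
res
glance(res)
head(tidy(res))
selected_nodes(f$session, f$target_suid)
```

The same call over HTTP, without sockets:

```{r handler}
resp <- rest_handle(f$session, "PUT",
                    sprintf("/v1/apply/layouts/copycat/%d/%d",
                            f$source_view_suid, f$target_view_suid),
                    '{"selectUnmapped": true}')
cat(rest_serialize(resp$body))
```
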