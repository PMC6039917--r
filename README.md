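# copycatr

Attribute-keyed network layout alignment for visual differential analysis.

When a biologist compares two related networks — a regulatory network and
the subnetwork a filter derived from it, or homologous networks across
species — the comparison only works if both are drawn identically.
`copycatr` transfers the layout of a reference (**source**) network view
onto a **target** view by matching nodes on a shared attribute column,
clones the source viewport (zoom and center) so both render in the same
frame, and makes the disagreement between the networks explicit: nodes
left unmapped on either side can be selected (feeding downstream queries)
and unmapped target nodes can be parked on a grid beside the mapped
layout. A small HTTP service reproduces the Cytoscape Automation (CyREST)
endpoint contract for the layout, so automation scripts written in R,
Python, or plain `curl` run against it with only host, port, and
identifiers changed.

## The algorithm

For a source network of *N* nodes and a target of *M* nodes, with mapping
columns that must both be string-typed or both integer-typed (defaulting
to `name` on each side):

1. **Pass one** walks the source nodes in stored order and hashes each
   present mapping value to that node's (x, y, z) view coordinates; a
   duplicated value is overwritten, so the *last encountered* source node
   wins.
2. **Pass two** walks the target nodes and assigns the mapped coordinates
   verbatim wherever the target value is in the map; several target nodes
   with one value stack at the same point, and unmatched nodes are left
   untouched.

Matching is by *value*: a node is unmapped when its value is missing or
absent from the other side. Both passes together are O(N + M) time and
O(N) memory, and edges never enter the computation. Optional
post-processing selects the unmapped sets exactly (clearing stale
selections first) and/or grids the unmapped target nodes row-major in
⌈√k⌉ columns, anchored just right of the mapped nodes' bounding box.
Coordinates follow the screen convention: x rightward, **y downward**,
z defaults to 0.

Supported formats: Cytoscape.js JSON (`.cyjs`), GraphML, and SIF edge
lists with an optional TSV coordinate table. All writers round-trip
attributes, node order, selection flags, and coordinates exactly.

## A worked example

The package ships an eight-versus-nine-node fixture: a source network
A–H with a hand-laid grid layout, and a derived target keeping A–G and
adding N and O.

```r
library(copycatr)
f <- figure_fixture()
res <- copycat(f$session, f$source_view_suid, f$target_view_suid,
               select_unmapped = TRUE)
res
#> Copycat layout: 7 target node(s) mapped, 2 unmapped (view 53 -> 55)
#>   unmapped target ids: 8, 9
#>   unmapped source ids: 8
glance(res)
#> # A tibble: 1 × 3
#>   mapped_node_count unmapped_node_count unmapped_source_count
#>               <int>               <int>                 <int>
#> 1                 7                   2                     1
selected_nodes(f$session, f$target_suid)
#> [1] 8 9
```

Seven target nodes (A–G) now sit at exactly their source coordinates;
the two additions N and O (target node ids 8 and 9) are unmapped and
selected, as is H on the source side — the node the derivation dropped.
The same call through the service contract, as a pure function:

```r
cat(rest_serialize(rest_handle(f$session, "PUT",
  sprintf("/v1/apply/layouts/copycat/%d/%d",
          f$source_view_suid, f$target_view_suid),
  '{"selectUnmapped": true}')$body))
#> {"data":{"mappedNodeCount":7,"unmappedNodeCount":2,
#>   "unmappedNodeIds":[8,9],"unmappedSourceNodeIds":[8]},"errors":[]}
```

## Command line and HTTP service

`exec/copycat` is a thin Rscript over the package functions:

```sh
copycat apply --source ref.cyjs --target new.cyjs \
        --select-unmapped --grid-unmapped --out aligned.cyjs --report report.json
copycat serve --port 1234 ref.cyjs new.cyjs     # HTTP service on /v1
copycat synth --spec pair.json --out-dir out/   # synthetic test pairs
```

The service exposes `PUT /v1/apply/layouts/copycat/{sourceViewSUID}/{targetViewSUID}`
(SUIDs or `current`; JSON body with `sourceColumn`, `targetColumn`,
`selectUnmapped`, `gridUnmapped`), `POST /v1/commands/layout/copycat`
(network *names* in the body; booleans may be `"true"`/`"false"`
strings), plus the discovery routes `GET /v1/networks`,
`/v1/networks/{suid}/views`, `/v1/networks/{suid}/nodes/selected`, and
`/v1/networks/{suid}/tables/defaultnode/columns`. Responses use the
CIResponse envelope; unresolvable views/networks and any mapping-column
problem answer 404 with `errors[0].status` set to 404. No image-export
endpoint is provided. See the vignette (`vignettes/layout-alignment.Rmd`)
for the full semantics and design rationale.

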