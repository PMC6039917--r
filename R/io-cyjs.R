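#' @importFrom jsonlite fromJSON toJSON unbox read_json
NULL

# Column-kind inference for untyped JSON: a column is integer iff every
# present value is an integral number; anything else is coerced to string.
infer_column <- function(values) {
  present <- values[!vapply(values, is.null, logical(1))]
  if (length(present) > 0 &&
      all(vapply(present, function(v) is.numeric(v) && length(v) == 1 &&
                   !is.na(v) && v == floor(v), logical(1)))) {
    out <- vapply(values, function(v) if (is.null(v)) NA_integer_ else as.integer(v),
                  integer(1))
  } else {
    out <- vapply(values, function(v) {
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  }
  out
}

#' Read a Cytoscape.js JSON (.cyjs) network
#'
#' Expects the Cytoscape.js interchange shape: `elements.nodes[].data`
#' carrying an integer `id` plus attribute fields, and
#' `elements.nodes[].position` with `x`/`y` (and optionally `z`). Node order
#' in the file is preserved. Untyped JSON columns are typed by inspection:
#' all-integral numbers become an integer column, everything else a string
#' column. A `selected` field in `data` is read into the selection flags.
#'
#' @param path File path.
#' @return A list with `graph` (a [network_graph()]), `layout` (tibble of
#'   `node_id`, `x`, `y`, `z`) and `selected` (logical vector in node order).
#' @export
read_cyjs <- function(path) {
  doc <- tryCatch(read_json(path, simplifyVector = FALSE),
                  error = function(e) cc_format_error(
                    sprintf("malformed JSON in '%s': %s", path, conditionMessage(e))))
  nodes <- doc$elements$nodes
  if (is.null(nodes)) nodes <- list()
  edges <- doc$elements$edges
  if (is.null(edges)) edges <- list()

  ids <- integer(length(nodes))
  for (i in seq_along(nodes)) {
    id <- nodes[[i]]$data$id
    if (is.null(id)) {
      cc_format_error(sprintf("node element %d in '%s' has no data.id", i, path))
    }
    idn <- suppressWarnings(as.numeric(id))
    if (is.na(idn) || idn != floor(idn)) {
      cc_format_error(sprintf("node element %d in '%s' has non-integer id '%s'",
                              i, path, as.character(id)))
    }
    ids[[i]] <- as.integer(idn)
  }

  # attribute columns in first-appearance order, excluding bookkeeping fields
  col_names <- character()
  for (n in nodes) {
    col_names <- union(col_names, setdiff(names(n$data), c("id", "selected")))
  }
  node_tbl <- tibble(node_id = ids)
  for (nm in col_names) {
    raw_vals <- lapply(nodes, function(n) n$data[[nm]])
    node_tbl[[nm]] <- infer_column(raw_vals)
  }

  num_or <- function(v, default) if (is.null(v)) default else as.double(v)
  layout <- tibble(
    node_id = ids,
    x = vapply(nodes, function(n) num_or(n$position$x, 0), double(1)),
    y = vapply(nodes, function(n) num_or(n$position$y, 0), double(1)),
    z = vapply(nodes, function(n) num_or(n$position$z, 0), double(1))
  )
  selected <- vapply(nodes, function(n) isTRUE(n$data$selected), logical(1))

  edge_tbl <- tibble(
    source_id = vapply(edges, function(e) as.integer(as.numeric(e$data$source)), integer(1)),
    target_id = vapply(edges, function(e) as.integer(as.numeric(e$data$target)), integer(1)),
    interaction = vapply(edges, function(e) {
      v <- e$data$interaction
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  )

  nm <- doc$data$name
  graph <- network_graph(node_tbl, edge_tbl,
                         name = if (is.null(nm)) basename(path) else as.character(nm))
  list(graph = graph, layout = layout, selected = selected)
}

#' Write a network and its view as Cytoscape.js JSON
#'
#' Positions come from the view (x rightward-positive, y downward-positive,
#' z kept even when 0); each node's `selected` flag is written explicitly
#' into its `data` record so selections survive a file round trip. Numbers
#' are serialized at full precision, so `read_cyjs(write_cyjs(...))`
#' reproduces coordinates bit-for-bit.
#'
#' @param graph A [network_graph()].
#' @param view A `network_view` covering exactly the graph's nodes.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cyjs <- function(graph, view, path) {
  check_view_covers(graph, view)
  nv <- view$node_views[match(graph$nodes$node_id, view$node_views$node_id), ]
  attr_cols <- setdiff(names(graph$nodes), "node_id")
  nodes <- lapply(seq_len(nrow(graph$nodes)), function(i) {
    data <- list(id = unbox(graph$nodes$node_id[[i]]))
    for (nm in attr_cols) {
      v <- graph$nodes[[nm]][[i]]
      if (!is.na(v)) data[[nm]] <- unbox(v)
    }
    data$selected <- unbox(nv$selected[[i]])
    list(data = data,
         position = list(x = unbox(nv$x[[i]]), y = unbox(nv$y[[i]]),
                         z = unbox(nv$z[[i]])))
  })
  edges <- lapply(seq_len(nrow(graph$edges)), function(i) {
    data <- list(source = unbox(graph$edges$source_id[[i]]),
                 target = unbox(graph$edges$target_id[[i]]))
    v <- graph$edges$interaction[[i]]
    if (!is.na(v)) data$interaction <- unbox(v)
    list(data = data)
  })
  doc <- list(format_version = unbox("1.0"),
              data = list(name = unbox(graph$name)),
              elements = list(nodes = nodes, edges = edges))
  # 17 significant digits round-trip IEEE doubles exactly
  writeLines(toJSON(doc, digits = I(17), pretty = TRUE), path, useBytes = TRUE)
  invisible(path)
}

check_view_covers <- function(graph, view) {
  if (!setequal(graph$nodes$node_id, view$node_views$node_id) ||
      nrow(graph$nodes) != nrow(view$node_views)) {
    cc_invalid("view does not cover exactly the network's node set")
  }
  invisible(TRUE)
}
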