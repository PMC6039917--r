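#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# First SUID handed out by a fresh session. Arbitrary non-zero base so that
# code confusing SUIDs with row indices fails fast; never hard-code SUIDs.
SUID_BASE <- 52L

cc_not_found <- function(message) {
  abort(message, class = c("copycat_not_found", "copycat_error"))
}

cc_invalid <- function(message, class = character()) {
  abort(message, class = c(class, "copycat_validation", "copycat_error"))
}

cc_format_error <- function(message) {
  abort(message, class = c("copycat_format_error", "copycat_error"))
}

kind_of_column <- function(x) {
  if (is.character(x)) "string" else if (is.integer(x)) "integer" else "other"
}

#' Construct an attributed network
#'
#' A network holds a node table (one row per node, one typed column per
#' attribute), an edge table, and column descriptors. Only `character`
#' attribute columns (kind `"string"`) and `integer` columns (kind
#' `"integer"`) are usable as mapping keys; any other type is carried with
#' kind `"other"` for I/O fidelity. Row order of `nodes` is significant: it
#' defines which duplicate attribute value is "last encountered" during
#' matching, and the row-major order of grid placement.
#'
#' @param nodes Data frame with an integer `node_id` column (unique) plus
#'   zero or more attribute columns. Missing attribute values are `NA`.
#' @param edges Optional data frame with `source_id`, `target_id` and an
#'   optional `interaction` column; endpoints must exist in `nodes`. Edges
#'   are never consulted by the layout algorithm.
#' @param name Network name (used by name-addressed service calls).
#' @return A `network_graph` object.
#' @export
#' @examples
#' g <- network_graph(tibble::tibble(node_id = 1:2, name = c("A", "B")))
#' column_kind(g, "name")
network_graph <- function(nodes, edges = NULL, name = "network") {
  nodes <- as_tibble(nodes)
  if (!"node_id" %in% names(nodes)) {
    cc_invalid("`nodes` must have a `node_id` column")
  }
  nodes$node_id <- as.integer(nodes$node_id)
  if (anyNA(nodes$node_id)) cc_invalid("node ids must be integers")
  if (anyDuplicated(nodes$node_id)) cc_invalid("duplicate node ids")
  nodes <- nodes[, c("node_id", setdiff(names(nodes), "node_id"))]

  if (is.null(edges)) {
    edges <- tibble(source_id = integer(), target_id = integer(),
                    interaction = character())
  }
  edges <- as_tibble(edges)
  if (!all(c("source_id", "target_id") %in% names(edges))) {
    cc_invalid("`edges` must have `source_id` and `target_id` columns")
  }
  edges$source_id <- as.integer(edges$source_id)
  edges$target_id <- as.integer(edges$target_id)
  if (!"interaction" %in% names(edges)) edges$interaction <- NA_character_
  edges <- edges[, c("source_id", "target_id", "interaction")]
  bad <- !(edges$source_id %in% nodes$node_id & edges$target_id %in% nodes$node_id)
  if (any(bad)) cc_invalid("edge endpoints must reference existing nodes")

  attr_names <- setdiff(names(nodes), "node_id")
  columns <- tibble(
    name = attr_names,
    kind = vapply(attr_names, function(nm) kind_of_column(nodes[[nm]]), character(1))
  )
  structure(
    list(suid = NA_integer_, name = name, columns = columns,
         nodes = nodes, edges = edges),
    class = "network_graph"
  )
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("<network_graph> '%s' (SUID %s): %d nodes, %d edges, %d attribute column(s)\n",
              x$name, ifelse(is.na(x$suid), "unregistered", x$suid),
              nrow(x$nodes), nrow(x$edges), nrow(x$columns)))
  invisible(x)
}

#' Declared kind of a node-table column
#'
#' @param graph A `network_graph`.
#' @param column_name Column name in the node table.
#' @return `"string"`, `"integer"`, or `"other"`.
#' @export
column_kind <- function(graph, column_name) {
  i <- match(column_name, graph$columns$name)
  if (is.na(i)) {
    cc_not_found(sprintf("column '%s' not found in node table of network '%s'",
                         column_name, graph$name))
  }
  graph$columns$kind[[i]]
}

#' Start an empty layout session
#'
#' A session is the registry that HTTP and CLI calls address: networks and
#' views keyed by session-unique identifiers (SUIDs), plus a "current view"
#' pointer. It has reference semantics (an environment), mirroring a running
#' Cytoscape instance: operations such as [copycat()] mutate the views it
#' holds. SUIDs are allocated monotonically and never reused.
#'
#' @return A `copycat_session` object.
#' @export
copycat_session <- function() {
  s <- new.env(parent = emptyenv())
  s$networks <- list()
  s$views <- list()
  s$current_view <- NULL
  s$suid_counter <- SUID_BASE
  class(s) <- "copycat_session"
  s
}

#' @export
print.copycat_session <- function(x, ...) {
  cat(sprintf("<copycat_session> %d network(s), %d view(s), current view: %s\n",
              length(x$networks), length(x$views),
              if (is.null(x$current_view)) "none" else x$current_view))
  invisible(x)
}

next_suid <- function(session) {
  id <- session$suid_counter
  session$suid_counter <- id + 1L
  id
}

#' Register a network (and its view) in a session
#'
#' Assigns fresh SUIDs to the network and to a newly created view of it.
#' The view receives one coordinate record per node: coordinates come from
#' `layout` (joined on `node_id`; screen convention, x rightward-positive,
#' y DOWNWARD-positive, z defaulting to 0), nodes without a layout row sit at
#' the origin, and all selection flags start `FALSE`. The viewport defaults
#' to zoom 1.0 centered on the midpoint of the layout bounding box (the
#' origin for an empty network). The new view becomes the session's current
#' view.
#'
#' @param session A [copycat_session()].
#' @param graph A [network_graph()].
#' @param layout Optional data frame with `node_id`, `x`, `y` and optionally
#'   `z` columns.
#' @param selected Optional logical vector (one flag per node, in node-table
#'   order) of initial selection states.
#' @return A list with elements `suid` (network) and `view_suid`.
#' @export
register_network <- function(session, graph, layout = NULL, selected = NULL) {
  stopifnot(inherits(session, "copycat_session"), inherits(graph, "network_graph"))
  nv <- tibble(node_id = graph$nodes$node_id, x = 0, y = 0, z = 0,
               selected = FALSE)
  if (!is.null(layout) && nrow(as_tibble(layout)) > 0) {
    layout <- as_tibble(layout)
    if (!"z" %in% names(layout)) layout$z <- 0
    i <- match(nv$node_id, layout$node_id)
    hit <- !is.na(i)
    nv$x[hit] <- as.double(layout$x[i[hit]])
    nv$y[hit] <- as.double(layout$y[i[hit]])
    nv$z[hit] <- as.double(layout$z[i[hit]])
  }
  if (!is.null(selected)) nv$selected <- as.logical(selected)

  viewport <- if (nrow(nv) == 0) {
    list(zoom = 1.0, center_x = 0, center_y = 0)
  } else {
    list(zoom = 1.0,
         center_x = (min(nv$x) + max(nv$x)) / 2,
         center_y = (min(nv$y) + max(nv$y)) / 2)
  }

  suid <- next_suid(session)
  view_suid <- next_suid(session)
  graph$suid <- suid
  session$networks[[as.character(suid)]] <- graph
  session$views[[as.character(view_suid)]] <- structure(
    list(view_suid = view_suid, network_suid = suid,
         node_views = nv, viewport = viewport),
    class = "network_view"
  )
  session$current_view <- view_suid
  list(suid = suid, view_suid = view_suid)
}

#' @export
print.network_view <- function(x, ...) {
  cat(sprintf("<network_view> SUID %d of network %d: %d node(s), zoom %.3g center (%.4g, %.4g)\n",
              x$view_suid, x$network_suid, nrow(x$node_views),
              x$viewport$zoom, x$viewport$center_x, x$viewport$center_y))
  invisible(x)
}

#' Fetch a registered network by SUID
#' @param session A [copycat_session()].
#' @param suid Network SUID.
#' @return The `network_graph`.
#' @export
get_network <- function(session, suid) {
  g <- session$networks[[as.character(suid)]]
  if (is.null(g)) cc_not_found(sprintf("no network with SUID %s", suid))
  g
}

get_view <- function(session, view_suid) {
  v <- session$views[[as.character(view_suid)]]
  if (is.null(v)) cc_not_found(sprintf("no view with SUID %s", view_suid))
  v
}

replace_view <- function(session, view) {
  session$views[[as.character(view$view_suid)]] <- view
  invisible(view)
}

#' Resolve a view selector
#'
#' Selectors are either a view SUID or the word `"current"`, meaning the
#' session's currently selected view (the service maps a failed resolution
#' to HTTP 404).
#'
#' @param session A [copycat_session()].
#' @param selector Integer SUID, an integer-valued string, or `"current"`.
#' @return The addressed `network_view`.
#' @export
resolve_view <- function(session, selector) {
  if (is.character(selector) && length(selector) == 1 && identical(selector, "current")) {
    if (is.null(session$current_view)) {
      cc_not_found("no current view in this session")
    }
    return(get_view(session, session$current_view))
  }
  id <- suppressWarnings(as.integer(selector))
  if (length(id) != 1 || is.na(id)) {
    cc_not_found(sprintf("view selector '%s' is neither an SUID nor 'current'",
                         paste(selector, collapse = ",")))
  }
  get_view(session, id)
}

#' Set the session's current view
#'
#' @param session A [copycat_session()].
#' @param view_suid An existing view SUID.
#' @export
set_current_view <- function(session, view_suid) {
  get_view(session, view_suid)  # validates
  session$current_view <- as.integer(view_suid)
  invisible(session)
}

#' Find the primary view of a network by name
#'
#' Name-addressed calls (the Command endpoint) operate on the primary view
#' of the named network, i.e. the view registered with it. If several
#' networks share the name, the one with the smallest SUID wins — a
#' deterministic choice, since name addressing carries no other handle.
#'
#' @param session A [copycat_session()].
#' @param name Network name.
#' @return The primary `network_view`.
#' @export
find_view_by_network_name <- function(session, name) {
  suids <- vapply(session$networks, function(g) g$suid, integer(1))
  names_ <- vapply(session$networks, function(g) g$name, character(1))
  hit <- suids[names_ == name]
  if (length(hit) == 0) cc_not_found(sprintf("no network named '%s'", name))
  suid <- min(hit)
  vsuids <- vapply(session$views, function(v) v$view_suid, integer(1))
  vnet <- vapply(session$views, function(v) v$network_suid, integer(1))
  cand <- vsuids[vnet == suid]
  if (length(cand) == 0) cc_not_found(sprintf("network '%s' has no view", name))
  get_view(session, min(cand))
}

#' List network SUIDs in a session
#' @param session A [copycat_session()].
#' @return Integer vector of network SUIDs, in registration order.
#' @export
list_networks <- function(session) {
  unname(vapply(session$networks, function(g) g$suid, integer(1)))
}

#' List view SUIDs of one network
#' @param session A [copycat_session()].
#' @param network_suid Network SUID.
#' @return Integer vector of view SUIDs.
#' @export
list_views <- function(session, network_suid) {
  get_network(session, network_suid)
  vs <- Filter(function(v) v$network_suid == as.integer(network_suid), session$views)
  unname(vapply(vs, function(v) v$view_suid, integer(1)))
}

#' Node ids currently selected in a network's primary view
#' @param session A [copycat_session()].
#' @param network_suid Network SUID.
#' @return Integer vector of selected node ids.
#' @export
selected_nodes <- function(session, network_suid) {
  vs <- list_views(session, network_suid)
  if (length(vs) == 0) return(integer())
  v <- get_view(session, min(vs))
  v$node_views$node_id[v$node_views$selected]
}
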