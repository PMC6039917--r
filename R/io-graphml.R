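#' @importFrom xml2 read_xml xml_find_all xml_attr xml_text xml_name xml_children
NULL

GRAPHML_NS <- "http://graphml.graphdrawing.org/xmlns"

graphml_kind <- function(attr_type) {
  switch(attr_type,
         int = , long = , integer = "integer",
         string = "string",
         "other")
}

#' Read a GraphML network
#'
#' Node coordinates are taken from node data keyed by `attr.name` `"x"`,
#' `"y"`, `"z"` (GraphML files without them load with every node at the
#' origin); a boolean `"selected"` key is read into the selection flags.
#' Remaining node keys become attribute columns: `attr.type` `int`/`long`
#' map to the integer kind, `string` to the string kind, and everything
#' else (e.g. `double`) to kind `"other"`, which cannot be used for layout
#' matching. Document node order is preserved.
#'
#' @param path File path.
#' @return A list with `graph`, `layout` and `selected`, as [read_cyjs()].
#' @export
read_graphml <- function(path) {
  doc <- tryCatch(read_xml(path),
                  error = function(e) cc_format_error(
                    sprintf("malformed GraphML in '%s': %s", path, conditionMessage(e))))
  ns <- c(g = GRAPHML_NS)

  keys <- xml_find_all(doc, ".//g:key", ns)
  key_id <- xml_attr(keys, "id")
  key_for <- xml_attr(keys, "for")
  key_name <- xml_attr(keys, "attr.name")
  key_type <- xml_attr(keys, "attr.type")
  node_keys <- key_for %in% c("node", "all")
  reserved <- c("x", "y", "z", "selected")
  coord_ids <- key_id[node_keys & key_name %in% c("x", "y", "z")]
  coord_types <- key_type[node_keys & key_name %in% c("x", "y", "z")]
  if (length(coord_ids) > 0 &&
      any(!coord_types %in% c("double", "float", "int", "long"))) {
    cc_format_error(sprintf("coordinate keys in '%s' declared non-numeric", path))
  }

  node_els <- xml_find_all(doc, ".//g:graph/g:node", ns)
  n <- length(node_els)
  raw_ids <- xml_attr(node_els, "id")
  parsed <- suppressWarnings(as.integer(sub("^n", "", raw_ids)))
  ids <- if (n > 0 && !anyNA(parsed) && !anyDuplicated(parsed)) parsed else seq_len(n)
  id_map <- stats::setNames(ids, raw_ids)

  # per-node data values, keyed by GraphML key id
  data_of <- lapply(node_els, function(nd) {
    ch <- xml_children(nd)
    ch <- ch[xml_name(ch) == "data"]
    stats::setNames(xml_text(ch), xml_attr(ch, "key"))
  })
  value_for <- function(kid) vapply(data_of, function(d) {
    if (kid %in% names(d)) d[[kid]] else NA_character_
  }, character(1))

  coord <- function(nm) {
    kid <- key_id[node_keys & key_name == nm]
    if (length(kid) == 0) return(rep(0, n))
    v <- suppressWarnings(as.double(value_for(kid[[1]])))
    ifelse(is.na(v), 0, v)
  }
  layout <- tibble(node_id = ids, x = coord("x"), y = coord("y"), z = coord("z"))

  sel_kid <- key_id[node_keys & key_name == "selected"]
  selected <- if (length(sel_kid) > 0) {
    tolower(value_for(sel_kid[[1]])) %in% c("true", "1")
  } else rep(FALSE, n)

  node_tbl <- tibble(node_id = ids)
  attr_idx <- which(node_keys & !key_name %in% reserved)
  for (j in attr_idx) {
    v <- value_for(key_id[[j]])
    node_tbl[[key_name[[j]]]] <- switch(graphml_kind(key_type[[j]]),
      integer = suppressWarnings(as.integer(v)),
      string = v,
      suppressWarnings(as.double(v)))  # kind "other": numeric carrier
  }

  edge_els <- xml_find_all(doc, ".//g:graph/g:edge", ns)
  int_kid <- key_id[key_for %in% c("edge", "all") & key_name == "interaction"]
  edge_tbl <- tibble(
    source_id = unname(id_map[xml_attr(edge_els, "source")]),
    target_id = unname(id_map[xml_attr(edge_els, "target")]),
    interaction = if (length(int_kid) > 0) {
      vapply(edge_els, function(e) {
        ch <- xml_children(e)
        ch <- ch[xml_name(ch) == "data" & xml_attr(ch, "key") == int_kid[[1]]]
        if (length(ch) > 0) xml_text(ch[[1]]) else NA_character_
      }, character(1))
    } else rep(NA_character_, length(edge_els))
  )

  graph_el <- xml_find_all(doc, ".//g:graph", ns)
  gname <- if (length(graph_el) > 0) xml_attr(graph_el[[1]], "id") else NA
  graph <- network_graph(node_tbl, edge_tbl,
                         name = if (is.na(gname) || gname == "") basename(path) else gname)
  list(graph = graph, layout = layout, selected = selected)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

num17 <- function(x) sprintf("%.17g", x)  # shortest-lossless is overkill; 17 digits round-trips doubles

#' Write a network and its view as GraphML
#'
#' Coordinates are written under node keys `x`, `y`, `z` (`attr.type`
#' double) and selection under a boolean `selected` key; attribute columns
#' carry `attr.type` `string`, `long`, or `double` according to their kind.
#' Numeric values use 17 significant digits so a read/write cycle preserves
#' doubles exactly.
#'
#' @inheritParams write_cyjs
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, view, path) {
  check_view_covers(graph, view)
  nv <- view$node_views[match(graph$nodes$node_id, view$node_views$node_id), ]
  attr_cols <- graph$columns
  key_lines <- c(
    sprintf('  <key id="k_x" for="node" attr.name="x" attr.type="double"/>'),
    sprintf('  <key id="k_y" for="node" attr.name="y" attr.type="double"/>'),
    sprintf('  <key id="k_z" for="node" attr.name="z" attr.type="double"/>'),
    sprintf('  <key id="k_selected" for="node" attr.name="selected" attr.type="boolean"/>'),
    sprintf('  <key id="k_interaction" for="edge" attr.name="interaction" attr.type="string"/>')
  )
  attr_type <- function(kind) switch(kind, integer = "long", string = "string", "double")
  for (j in seq_len(nrow(attr_cols))) {
    key_lines <- c(key_lines, sprintf(
      '  <key id="ka_%d" for="node" attr.name="%s" attr.type="%s"/>',
      j, xml_escape(attr_cols$name[[j]]), attr_type(attr_cols$kind[[j]])))
  }

  node_lines <- character()
  for (i in seq_len(nrow(graph$nodes))) {
    dl <- c(
      sprintf('      <data key="k_x">%s</data>', num17(nv$x[[i]])),
      sprintf('      <data key="k_y">%s</data>', num17(nv$y[[i]])),
      sprintf('      <data key="k_z">%s</data>', num17(nv$z[[i]])),
      sprintf('      <data key="k_selected">%s</data>',
              if (nv$selected[[i]]) "true" else "false")
    )
    for (j in seq_len(nrow(attr_cols))) {
      v <- graph$nodes[[attr_cols$name[[j]]]][[i]]
      if (is.na(v)) next
      txt <- if (is.double(v)) num17(v) else xml_escape(as.character(v))
      dl <- c(dl, sprintf('      <data key="ka_%d">%s</data>', j, txt))
    }
    node_lines <- c(node_lines,
                    sprintf('    <node id="n%d">', graph$nodes$node_id[[i]]),
                    dl, "    </node>")
  }

  edge_lines <- character()
  for (i in seq_len(nrow(graph$edges))) {
    v <- graph$edges$interaction[[i]]
    inner <- if (!is.na(v)) {
      sprintf('      <data key="k_interaction">%s</data>', xml_escape(v))
    } else character()
    edge_lines <- c(edge_lines,
                    sprintf('    <edge source="n%d" target="n%d">',
                            graph$edges$source_id[[i]], graph$edges$target_id[[i]]),
                    inner, "    </edge>")
  }

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<graphml xmlns="%s">', GRAPHML_NS),
    key_lines,
    sprintf('  <graph id="%s" edgedefault="directed">', xml_escape(graph$name)),
    node_lines, edge_lines,
    '  </graph>', '</graphml>'
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
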