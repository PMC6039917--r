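#' @importFrom generics tidy glance
NULL

# Mapping keys for one graph/column: character vector in node order, NA for
# missing values. Integer values key by their decimal representation, which
# is injective, so integer matching is numeric equality and cross-kind
# matching is prevented upstream by validate_mapping_columns().
mapping_keys <- function(graph, column) {
  v <- graph$nodes[[column]]
  if (is.integer(v)) as.character(v) else as.character(v)
}

#' Validate the mapping columns of a source/target pair
#'
#' Both columns must exist in their node tables and must share a single
#' kind, either string or integer; columns of any other kind (doubles,
#' booleans, lists) cannot key a match.
#'
#' @param source,target [network_graph()] objects.
#' @param source_column,target_column Mapping column names.
#' @return The common kind, `"string"` or `"integer"`.
#' @export
validate_mapping_columns <- function(source, target,
                                     source_column = "name",
                                     target_column = "name") {
  sk <- column_kind(source, source_column)
  tk <- column_kind(target, target_column)
  if (!sk %in% c("string", "integer") || !tk %in% c("string", "integer")) {
    cc_invalid(sprintf(
      "mapping columns must both be string or integer types ('%s' is %s, '%s' is %s)",
      source_column, sk, target_column, tk), class = "copycat_column_error")
  }
  if (sk != tk) {
    cc_invalid(sprintf(
      "mapping column kinds differ: '%s' is %s but '%s' is %s",
      source_column, sk, target_column, tk), class = "copycat_column_error")
  }
  sk
}

#' First pass: map source attribute values to source coordinates
#'
#' Walks the source nodes in stored order and records each present mapping
#' value with that node's view coordinates. A value seen more than once is
#' overwritten, so only the last encountered source node supplies the
#' coordinates for its value. Nodes with a missing value contribute nothing.
#'
#' @param source_view The source `network_view`.
#' @param source_graph The source [network_graph()].
#' @param source_column Mapping column name.
#' @return Tibble with `key`, `x`, `y`, `z` — one row per distinct value.
#' @export
build_source_position_map <- function(source_view, source_graph,
                                      source_column = "name") {
  keys <- mapping_keys(source_graph, source_column)
  nv <- source_view$node_views[
    match(source_graph$nodes$node_id, source_view$node_views$node_id), ]
  keep <- !is.na(keys)
  k <- keys[keep]
  last <- !duplicated(k, fromLast = TRUE)
  tibble(key = k[last],
         x = nv$x[keep][last], y = nv$y[keep][last], z = nv$z[keep][last])
}

#' Second pass: transfer coordinates onto matching target nodes
#'
#' Every target node whose mapping value appears in the position map gets
#' exactly the mapped coordinates (several target nodes sharing one value
#' stack at the same point). Unmatched nodes — including nodes with a
#' missing value — are left untouched.
#'
#' @param target_view The target `network_view`.
#' @param target_graph The target [network_graph()].
#' @param target_column Mapping column name.
#' @param pmap Position map from [build_source_position_map()].
#' @return List with the updated `view`, `matched_ids`, `unmatched_ids`
#'   (disjoint, covering all target nodes, both in stored node order) and
#'   `matched_keys` (the distinct values that found a match).
#' @export
transfer_positions <- function(target_view, target_graph, target_column, pmap) {
  keys <- mapping_keys(target_graph, target_column)
  ord <- match(target_graph$nodes$node_id, target_view$node_views$node_id)
  idx <- match(keys, pmap$key)          # NA keys never match
  hit <- !is.na(idx)
  nv <- target_view$node_views
  nv$x[ord[hit]] <- pmap$x[idx[hit]]
  nv$y[ord[hit]] <- pmap$y[idx[hit]]
  nv$z[ord[hit]] <- pmap$z[idx[hit]]
  target_view$node_views <- nv
  list(view = target_view,
       matched_ids = target_graph$nodes$node_id[hit],
       unmatched_ids = target_graph$nodes$node_id[!hit],
       matched_keys = unique(keys[hit]))
}

# Source nodes counted as unmapped: value missing, or value never matched by
# any target node. Matching is by value — one target hit marks every source
# node carrying that value as mapped.
unmapped_source_ids <- function(source_graph, source_column, matched_keys) {
  keys <- mapping_keys(source_graph, source_column)
  source_graph$nodes$node_id[is.na(keys) | !(keys %in% matched_keys)]
}

#' Select unmapped nodes in both views
#'
#' Clears every selection flag in the source and target views, then selects
#' the unmapped target nodes and the source nodes whose value no target node
#' matched, so that afterwards the selection in each view equals its
#' unmapped set exactly.
#'
#' @param source_view,target_view `network_view` objects.
#' @param source_unmapped,target_unmapped Integer node-id vectors.
#' @return List with updated `source_view` and `target_view`.
#' @export
select_unmapped <- function(source_view, target_view,
                            source_unmapped, target_unmapped) {
  source_view$node_views$selected <-
    source_view$node_views$node_id %in% source_unmapped
  target_view$node_views$selected <-
    target_view$node_views$node_id %in% target_unmapped
  list(source_view = source_view, target_view = target_view)
}

#' Place unmapped target nodes on a grid
#'
#' Unmatched nodes go to the top right of the mapped layout: a row-major
#' grid of `ceiling(sqrt(k))` columns (stored node order), anchored at
#' `(max(x of mapped) + spacing, min(y of mapped))` — y grows downward, so
#' `min(y)` is the top. With no mapped nodes the anchor is the origin. The
#' z coordinate of gridded nodes is unchanged.
#'
#' @param target_view The target `network_view`.
#' @param unmatched_ids Node ids to place, in stored node order.
#' @param spacing Grid cell size in screen units (default 80).
#' @return The updated view.
#' @export
grid_unmapped <- function(target_view, unmatched_ids, spacing = 80) {
  k <- length(unmatched_ids)
  if (k == 0) return(target_view)
  nv <- target_view$node_views
  mapped <- !(nv$node_id %in% unmatched_ids)
  if (any(mapped)) {
    ax <- max(nv$x[mapped]) + spacing
    ay <- min(nv$y[mapped])
  } else {
    ax <- 0; ay <- 0
  }
  ncol <- ceiling(sqrt(k))
  pos <- match(unmatched_ids, nv$node_id)
  i <- seq_len(k) - 1L
  nv$x[pos] <- ax + (i %% ncol) * spacing
  nv$y[pos] <- ay + (i %/% ncol) * spacing
  target_view$node_views <- nv
  target_view
}

#' Clone the source viewport onto the target
#'
#' Copies zoom (scale) and center (location) so both networks render in the
#' same window frame — the piece of layout cloning that coordinate transfer
#' alone does not cover.
#'
#' @param source_view,target_view `network_view` objects.
#' @return The updated target view.
#' @export
clone_viewport <- function(source_view, target_view) {
  target_view$viewport <- source_view$viewport
  target_view
}

#' Copy a network layout from a source view to a target view
#'
#' The full alignment: resolve both views, validate the mapping columns,
#' build the source value-to-coordinates map (one pass over source nodes),
#' transfer coordinates onto matching target nodes (one pass over target
#' nodes), optionally select and/or grid the unmapped nodes, and clone the
#' source viewport. Runs in O(N + M) time for N source and M target nodes;
#' edges play no part. The session's stored views are updated in place.
#'
#' @param session A [copycat_session()].
#' @param source,target View selectors ([resolve_view()]): SUIDs or
#'   `"current"`. Must resolve to different views.
#' @param source_column,target_column Mapping column names (default
#'   `"name"`); must share a string or integer kind.
#' @param select_unmapped If `TRUE`, selection in both views is reset to
#'   exactly the unmapped node sets; if `FALSE`, selection flags are left
#'   untouched.
#' @param grid_unmapped If `TRUE`, unmatched target nodes are placed on a
#'   grid beside the mapped layout. Independent of `select_unmapped`.
#' @param grid_spacing Grid cell size in screen units.
#' @return A `copycat_result` with `mapped_node_count`,
#'   `unmapped_node_count` (target-side counts; they sum to the target node
#'   count), `unmapped_target_ids` and `unmapped_source_ids`.
#' @export
#' @examples
#' s <- copycat_session()
#' src <- network_graph(tibble::tibble(node_id = 1:2, name = c("A", "B")), name = "src")
#' tgt <- network_graph(tibble::tibble(node_id = 1:2, name = c("A", "C")), name = "tgt")
#' a <- register_network(s, src, tibble::tibble(node_id = 1:2, x = c(0, 10), y = 0))
#' b <- register_network(s, tgt)
#' copycat(s, a$view_suid, b$view_suid, select_unmapped = TRUE)
copycat <- function(session, source, target,
                    source_column = "name", target_column = "name",
                    select_unmapped = FALSE, grid_unmapped = FALSE,
                    grid_spacing = 80) {
  sv <- resolve_view(session, source)
  tv <- resolve_view(session, target)
  if (sv$view_suid == tv$view_suid) {
    cc_invalid("sourceViewSUID and targetViewSUID must reference different views")
  }
  sg <- get_network(session, sv$network_suid)
  tg <- get_network(session, tv$network_suid)
  validate_mapping_columns(sg, tg, source_column, target_column)

  pmap <- build_source_position_map(sv, sg, source_column)
  tr <- transfer_positions(tv, tg, target_column, pmap)
  tv <- tr$view
  src_unmapped <- unmapped_source_ids(sg, source_column, tr$matched_keys)

  if (isTRUE(select_unmapped)) {
    sel <- select_unmapped(sv, tv, src_unmapped, tr$unmatched_ids)
    sv <- sel$source_view
    tv <- sel$target_view
  }
  if (isTRUE(grid_unmapped)) {
    tv <- grid_unmapped(tv, tr$unmatched_ids, spacing = grid_spacing)
  }
  if (nrow(sv$node_views) > 0) {
    tv <- clone_viewport(sv, tv)
  }
  replace_view(session, sv)
  replace_view(session, tv)

  structure(
    list(mapped_node_count = length(tr$matched_ids),
         unmapped_node_count = length(tr$unmatched_ids),
         mapped_target_ids = tr$matched_ids,
         unmapped_target_ids = tr$unmatched_ids,
         unmapped_source_ids = src_unmapped,
         source_view_suid = sv$view_suid,
         target_view_suid = tv$view_suid),
    class = "copycat_result"
  )
}

#' @export
print.copycat_result <- function(x, ...) {
  cat(sprintf("Copycat layout: %d target node(s) mapped, %d unmapped (view %d -> %d)\n",
              x$mapped_node_count, x$unmapped_node_count,
              x$source_view_suid, x$target_view_suid))
  if (length(x$unmapped_target_ids)) {
    cat("  unmapped target ids:", paste(x$unmapped_target_ids, collapse = ", "), "\n")
  }
  if (length(x$unmapped_source_ids)) {
    cat("  unmapped source ids:", paste(x$unmapped_source_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a copycat result into one row per node
#'
#' @param x A `copycat_result`.
#' @param ... Unused.
#' @return Tibble with `side` (`"source"`/`"target"`), `node_id` and
#'   `mapped` (logical). Source rows cover only the unmapped side, plus the
#'   mapped target rows; source mapped nodes are those absent from
#'   `unmapped_source_ids`.
#' @export
tidy.copycat_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble(side = "target", node_id = x$mapped_target_ids, mapped = TRUE),
    tibble(side = "target", node_id = x$unmapped_target_ids, mapped = FALSE),
    tibble(side = "source", node_id = x$unmapped_source_ids, mapped = FALSE)
  )
}

#' One-row summary of a copycat result
#'
#' @param x A `copycat_result`.
#' @param ... Unused.
#' @return Tibble with `mapped_node_count`, `unmapped_node_count`,
#'   `unmapped_source_count`.
#' @export
glance.copycat_result <- function(x, ...) {
  tibble(mapped_node_count = x$mapped_node_count,
         unmapped_node_count = x$unmapped_node_count,
         unmapped_source_count = length(x$unmapped_source_ids))
}

#' Plot a network view
#'
#' Nodes at their view coordinates (y axis reversed to match the
#' downward-positive screen convention), selected nodes highlighted.
#'
#' @param object A `network_view`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.network_view <- function(object, ...) {
  nv <- object$node_views
  ggplot2::ggplot(nv, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$selected)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(title = sprintf("view %d", object$view_suid),
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
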