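#' Read a SIF (simple interaction format) edge list
#'
#' Lines are either `A interaction B [C ...]` (one edge per listed target)
#' or a bare `A` declaring an isolated node. Fields split on tabs when the
#' line contains a tab, otherwise on runs of whitespace. Nodes are numbered
#' in first-appearance order and their identifiers populate a string-kind
#' `name` column — the default mapping column.
#'
#' @param path File path.
#' @param name Network name; defaults to the file's base name.
#' @return A [network_graph()] (no coordinates; see [read_layout_table()]).
#' @export
read_sif <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  node_names <- character()
  src <- character(); tgt <- character(); inter <- character()
  see <- function(nm) {
    if (!nm %in% node_names) node_names <<- c(node_names, nm)
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    fields <- if (grepl("\t", line, fixed = TRUE)) {
      trimws(strsplit(line, "\t", fixed = TRUE)[[1]])
    } else {
      strsplit(trimws(line), "[[:space:]]+")[[1]]
    }
    fields <- fields[nzchar(fields)]
    if (length(fields) == 1) {
      see(fields[[1]])
    } else if (length(fields) == 2) {
      cc_format_error(sprintf(
        "malformed SIF line %d in '%s': 2 fields (need 1, or 3 or more)", i, path))
    } else {
      see(fields[[1]])
      for (t in fields[-(1:2)]) {
        see(t)
        src <- c(src, fields[[1]]); tgt <- c(tgt, t); inter <- c(inter, fields[[2]])
      }
    }
  }
  ids <- seq_along(node_names)
  names(ids) <- node_names
  network_graph(
    tibble(node_id = unname(ids), name = node_names),
    tibble(source_id = unname(ids[src]), target_id = unname(ids[tgt]),
           interaction = inter),
    name = name
  )
}

#' Read a side-car node coordinate table
#'
#' A TSV with header columns `name`, `x`, `y` and optionally `z` (defaulting
#' to 0), decimal point `"."`. Keys must be unique.
#'
#' @param path File path.
#' @return Tibble with `name`, `x`, `y`, `z`.
#' @export
read_layout_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "x", "y")
  if (!all(need %in% names(tbl))) {
    cc_format_error(sprintf("layout table '%s' must have columns name, x, y", path))
  }
  if (anyDuplicated(tbl$name)) {
    cc_format_error(sprintf("layout table '%s' has duplicate node keys", path))
  }
  if (!"z" %in% names(tbl)) tbl$z <- 0
  tibble(name = as.character(tbl$name), x = as.double(tbl$x),
         y = as.double(tbl$y), z = as.double(tbl$z))
}

#' Join a layout table onto a network's nodes
#'
#' Rows are matched to nodes by the `name` column. Rows naming a node that
#' does not exist are skipped with a warning (side-car tables commonly drift
#' from the edge list), so the returned layout has one row per applied table
#' row.
#'
#' @param graph A [network_graph()] with a string `name` column.
#' @param table A tibble as returned by [read_layout_table()].
#' @return Tibble with `node_id`, `x`, `y`, `z`, ready for
#'   [register_network()].
#' @export
apply_layout_table <- function(graph, table) {
  i <- match(table$name, graph$nodes$name)
  miss <- is.na(i)
  if (any(miss)) {
    warn(sprintf("skipping %d layout row(s) naming absent node(s): %s",
                 sum(miss), paste(utils::head(table$name[miss], 5), collapse = ", ")))
  }
  tibble(node_id = graph$nodes$node_id[i[!miss]],
         x = table$x[!miss], y = table$y[!miss], z = table$z[!miss])
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         cyjs = , json = "cyjs",
         graphml = , xml = "graphml",
         sif = "sif",
         cc_format_error(sprintf("cannot guess network format of '%s'", path)))
}

#' Load a network file of any supported format
#'
#' Dispatches on `format` (or the file extension): `.cyjs`/`.json` via
#' [read_cyjs()], `.graphml`/`.xml` via [read_graphml()], `.sif` via
#' [read_sif()] with an optional side-car coordinate table.
#'
#' @param path Network file path.
#' @param format `"auto"` (extension-based), `"cyjs"`, `"graphml"` or `"sif"`.
#' @param layout_table Optional path of a TSV coordinate table (SIF input).
#' @param name Network name override.
#' @return A list with `graph`, `layout` and `selected`.
#' @export
load_network <- function(path, format = "auto", layout_table = NULL, name = NULL) {
  format <- match.arg(format, c("auto", "cyjs", "graphml", "sif"))
  if (format == "auto") format <- guess_format(path)
  out <- switch(format,
    cyjs = read_cyjs(path),
    graphml = read_graphml(path),
    sif = {
      g <- read_sif(path)
      layout <- if (!is.null(layout_table)) {
        apply_layout_table(g, read_layout_table(layout_table))
      } else NULL
      list(graph = g, layout = layout, selected = NULL)
    })
  if (!is.null(name)) out$graph$name <- name
  out
}

#' Write a network and view in a chosen format
#'
#' @inheritParams write_cyjs
#' @param format `"auto"` (extension-based), `"cyjs"` or `"graphml"`. SIF
#'   carries no coordinates and is read-only here.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, view, path, format = "auto") {
  format <- match.arg(format, c("auto", "cyjs", "graphml"))
  if (format == "auto") {
    format <- guess_format(path)
    if (format == "sif") cc_invalid("SIF output would drop coordinates; use cyjs or graphml")
  }
  switch(format,
         cyjs = write_cyjs(graph, view, path),
         graphml = write_graphml(graph, view, path))
}
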