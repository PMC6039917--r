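# Small builders shared across the suite. Everything is generated in code;
# the only files on disk are the two shipped worked-example .cyjs fixtures.

named_graph <- function(names, ids = seq_along(names), edges = NULL, name = "net") {
  network_graph(tibble::tibble(node_id = ids, name = names), edges, name = name)
}

# register a named graph with coordinates given as a list of c(x, y[, z])
reg_named <- function(session, names, coords = NULL, name = "net",
                      ids = seq_along(names), edges = NULL) {
  layout <- if (!is.null(coords)) {
    m <- do.call(rbind, lapply(coords, function(p) c(p, 0)[1:3]))
    tibble::tibble(node_id = ids, x = m[, 1], y = m[, 2], z = m[, 3])
  }
  register_network(session, named_graph(names, ids, edges, name), layout)
}

# A session holding the eight-node reference layout (A-H) and the derived
# nine-node network (A-G plus N, O) with an arbitrary scrambled layout.
derived_pair_session <- function() {
  s <- copycat_session()
  src <- reg_named(s, LETTERS[1:8],
                   coords = lapply(0:7, function(i) c((i %% 3) * 120, (i %/% 3) * 120)),
                   name = "source.sif")
  tgt <- reg_named(s, c(LETTERS[1:7], "N", "O"),
                   coords = lapply(1:9, function(i) c(i * 37, 400 - i * 21)),
                   name = "target.sif")
  list(session = s, src = src, tgt = tgt)
}

# Random attributed network + view for I/O round-trip checks: a string
# column with some missing values, an integer column, fractional negative
# coordinates, and scattered selection flags.
random_io_fixture <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(1:30, 1)
    nm <- sprintf("node%03d", sample(900, n))
    nm[sample(n, max(0, n %/% 5))] <- NA
    nm[1] <- "node000"                    # at least one present value
    score <- as.integer(sample(-50:50, n, replace = TRUE))
    edges <- if (n >= 2) {
      k <- sample(0:(2 * n), 1)
      tibble::tibble(source_id = sample(n, k, replace = TRUE),
                     target_id = sample(n, k, replace = TRUE),
                     interaction = sample(c("pp", "pd", NA), k, replace = TRUE))
    }
    g <- network_graph(tibble::tibble(node_id = seq_len(n), name = nm, score = score),
                       edges, name = sprintf("fixture-%d", seed))
    layout <- tibble::tibble(node_id = seq_len(n),
                             x = stats::runif(n, -1e3, 1e3),
                             y = stats::runif(n, -1e3, 1e3),
                             z = stats::runif(n, -5, 5))
    sel <- sample(c(TRUE, FALSE), n, replace = TRUE)
    s <- copycat_session()
    ids <- register_network(s, g, layout, sel)
    list(graph = get_network(s, ids$suid), view = resolve_view(s, ids$view_suid))
  })
}

expect_same_network <- function(got, graph, view) {
  # column order may legitimately differ (first-appearance order on read)
  expect_setequal(names(got$graph$nodes), names(graph$nodes))
  for (nm in names(graph$nodes)) {
    expect_identical(got$graph$nodes[[nm]], graph$nodes[[nm]])
  }
  expect_identical(
    got$graph$columns[order(got$graph$columns$name), ],
    graph$columns[order(graph$columns$name), ])
  expect_identical(got$graph$edges, graph$edges)
  expect_identical(got$graph$name, graph$name)
  nv <- view$node_views
  expect_identical(got$layout$node_id, nv$node_id)
  expect_identical(got$layout$x, nv$x)
  expect_identical(got$layout$y, nv$y)
  expect_identical(got$layout$z, nv$z)
  expect_identical(got$selected, nv$selected)
}

view_of <- function(pair, which = c("source", "target")) {
  which <- match.arg(which)
  resolve_view(pair$session, pair[[paste0(which, "_view_suid")]])
}

graph_of <- function(pair, which = c("source", "target")) {
  which <- match.arg(which)
  get_network(pair$session, pair[[paste0(which, "_suid")]])
}

# snapshot of everything copycat may touch, for idempotence/edge-independence
session_snapshot <- function(pair) {
  list(src = view_of(pair, "source"), tgt = view_of(pair, "target"))
}
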