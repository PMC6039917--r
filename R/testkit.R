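#' Generate a seeded source/target network pair with known ground truth
#'
#' Builds two attributed, laid-out networks whose mapping-value overlap,
#' value duplication, and missing-value rate are controlled, together with
#' the expected mapped/unmapped value sets derived by set algebra on the
#' generated name vectors — independently of the layout algorithm itself.
#' Mapping values are zero-padded decimal strings, so lexicographic equality
#' is plain string equality with no locale sensitivity. Coordinates are
#' uniform in `[-coordinate_range, coordinate_range]` per axis; sparse
#' random edges are attached but never consulted by the expectations, which
#' is what lets edge-independence be tested by regenerating them.
#'
#' @param n_source,n_target Node counts.
#' @param overlap_fraction Fraction of target nodes whose value also occurs
#'   in the source (before missing values are punched in).
#' @param duplicate_rate Fraction of source nodes that repeat an earlier
#'   source value.
#' @param missing_rate Fraction of target nodes with no mapping value.
#' @param coordinate_range Half-width of the uniform coordinate box.
#' @param seed Integer seed; the same seed reproduces the pair exactly.
#' @param edge_seed Seed for edge generation only (defaults to `seed`);
#'   varying it regenerates edges without touching nodes, values, or
#'   coordinates.
#' @return A list: `session` (both networks registered), `source_suid`,
#'   `source_view_suid`, `target_suid`, `target_view_suid`, and `truth`
#'   with `mapped_values`, `unmapped_target_ids`, `unmapped_source_ids`,
#'   `mapped_count`, `unmapped_count`.
#' @export
generate_pair <- function(n_source, n_target, overlap_fraction,
                          duplicate_rate = 0, missing_rate = 0,
                          coordinate_range = 500, seed = 1L,
                          edge_seed = seed) {
  stopifnot(n_source >= 1, n_target >= 0,
            overlap_fraction >= 0, overlap_fraction <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)

  n_dup <- floor(duplicate_rate * n_source)
  if (n_dup >= n_source) n_dup <- n_source - 1L
  n_distinct_source <- n_source - n_dup
  n_shared <- round(overlap_fraction * n_target)
  if (n_shared > n_distinct_source) {
    cc_invalid(sprintf(
      "infeasible pair: overlap needs %d shared values but source has only %d distinct",
      n_shared, n_distinct_source))
  }

  pair <- withr::with_seed(seed, {
    src_base <- sprintf("s%06d", seq_len(n_distinct_source))
    dup_of <- if (n_dup > 0) sample(src_base, n_dup, replace = TRUE) else character()
    src_names <- sample(c(src_base, dup_of))            # shuffle stored order
    shared <- if (n_shared > 0) sample(src_base, n_shared) else character()
    fresh <- sprintf("t%06d", seq_len(n_target - n_shared))
    tgt_names <- sample(c(shared, fresh))
    if (missing_rate > 0 && n_target > 0) {
      gone <- sample(n_target, round(missing_rate * n_target))
      tgt_names[gone] <- NA_character_
    }
    list(
      src_names = src_names, tgt_names = tgt_names,
      src_xy = matrix(stats::runif(3 * n_source, -coordinate_range, coordinate_range),
                      ncol = 3),
      tgt_xy = matrix(stats::runif(3 * n_target, -coordinate_range, coordinate_range),
                      ncol = 3)
    )
  })

  rand_edges <- function(n, eseed) {
    if (n < 2) return(NULL)
    withr::with_seed(eseed, {
      k <- min(2L * n, n * (n - 1L) %/% 2L)
      tibble(source_id = sample(n, k, replace = TRUE),
             target_id = sample(n, k, replace = TRUE),
             interaction = "pp")
    })
  }

  src_graph <- network_graph(
    tibble(node_id = seq_len(n_source), name = pair$src_names),
    rand_edges(n_source, edge_seed), name = "synthetic-source")
  tgt_graph <- network_graph(
    tibble(node_id = seq_len(n_target), name = pair$tgt_names),
    rand_edges(n_target, edge_seed + 1L), name = "synthetic-target")

  session <- copycat_session()
  src <- register_network(session, src_graph,
                          tibble(node_id = seq_len(n_source),
                                 x = pair$src_xy[, 1], y = pair$src_xy[, 2],
                                 z = pair$src_xy[, 3]))
  tgt <- register_network(session, tgt_graph,
                          tibble(node_id = seq_len(n_target),
                                 x = pair$tgt_xy[, 1], y = pair$tgt_xy[, 2],
                                 z = pair$tgt_xy[, 3]))

  # ground truth by set algebra on the name vectors
  mapped_values <- intersect(pair$tgt_names[!is.na(pair$tgt_names)], pair$src_names)
  tgt_mapped <- !is.na(pair$tgt_names) & pair$tgt_names %in% pair$src_names
  src_unmapped <- !(pair$src_names %in% mapped_values)
  truth <- list(
    mapped_values = mapped_values,
    unmapped_target_ids = which(!tgt_mapped),
    unmapped_source_ids = which(src_unmapped),
    mapped_count = sum(tgt_mapped),
    unmapped_count = sum(!tgt_mapped)
  )

  list(session = session,
       source_suid = src$suid, source_view_suid = src$view_suid,
       target_suid = tgt$suid, target_view_suid = tgt$view_suid,
       truth = truth)
}

#' Brute-force quadratic layout matcher (test oracle)
#'
#' Re-derives the alignment naively: for each target node, scan every
#' source node in stored order and remember the last one whose mapping
#' value is equal; that node supplies the coordinates. O(N·M) — the point
#' is independence from the hashed two-pass implementation, not speed.
#'
#' @param source_graph,target_graph [network_graph()] objects.
#' @param source_view,target_view Their `network_view`s.
#' @param source_column,target_column Mapping column names.
#' @return List with `positions` (tibble of target `node_id`, `x`, `y`, `z`,
#'   `mapped`; coordinates of unmapped nodes are their current ones),
#'   `mapped_count`, `unmapped_count`, `unmapped_target_ids`,
#'   `unmapped_source_ids`.
#' @export
brute_force_copycat <- function(source_graph, source_view,
                                target_graph, target_view,
                                source_column = "name", target_column = "name") {
  sk <- mapping_keys(source_graph, source_column)
  tk <- mapping_keys(target_graph, target_column)
  snv <- source_view$node_views[
    match(source_graph$nodes$node_id, source_view$node_views$node_id), ]
  tnv <- target_view$node_views[
    match(target_graph$nodes$node_id, target_view$node_views$node_id), ]

  n_t <- nrow(target_graph$nodes)
  mapped <- logical(n_t)
  x <- tnv$x; y <- tnv$y; z <- tnv$z
  matched_source <- logical(nrow(source_graph$nodes))
  for (j in seq_len(n_t)) {
    if (is.na(tk[[j]])) next
    hit <- NA_integer_
    for (i in seq_along(sk)) {            # keep scanning: last match wins
      if (!is.na(sk[[i]]) && sk[[i]] == tk[[j]]) hit <- i
    }
    if (!is.na(hit)) {
      mapped[[j]] <- TRUE
      x[[j]] <- snv$x[[hit]]; y[[j]] <- snv$y[[hit]]; z[[j]] <- snv$z[[hit]]
    }
  }
  # value-level matching: any target hit covers all source nodes with that value
  for (i in seq_along(sk)) {
    if (!is.na(sk[[i]]) && any(!is.na(tk) & tk == sk[[i]] & mapped)) {
      matched_source[[i]] <- TRUE
    }
  }
  list(
    positions = tibble(node_id = target_graph$nodes$node_id,
                       x = x, y = y, z = z, mapped = mapped),
    mapped_count = sum(mapped),
    unmapped_count = sum(!mapped),
    unmapped_target_ids = target_graph$nodes$node_id[!mapped],
    unmapped_source_ids = source_graph$nodes$node_id[!matched_source]
  )
}

#' The worked eight-versus-nine node example session
#'
#' Loads the shipped fixture pair: a source network of nodes A–H with a
#' hand-laid layout, and a derived target network keeping A–G and adding N
#' and O. Running [copycat()] with `select_unmapped = TRUE` places A–G at
#' their source coordinates, reports 7 mapped and 2 unmapped target nodes,
#' and leaves H selected in the source and N, O in the target.
#'
#' @return As [generate_pair()]: a list with `session` and the four SUIDs.
#' @export
figure_fixture <- function() {
  dir <- system.file("extdata", "fixtures", package = "copycatr")
  src <- read_cyjs(file.path(dir, "worked-example-source.cyjs"))
  tgt <- read_cyjs(file.path(dir, "worked-example-target.cyjs"))
  session <- copycat_session()
  a <- register_network(session, src$graph, src$layout, src$selected)
  b <- register_network(session, tgt$graph, tgt$layout, tgt$selected)
  list(session = session,
       source_suid = a$suid, source_view_suid = a$view_suid,
       target_suid = b$suid, target_view_suid = b$view_suid)
}
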