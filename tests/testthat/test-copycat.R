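test_that("mapping-column validation enforces the string/integer contract", {
  str_g <- named_graph(c("a", "b"))
  int_g <- network_graph(tibble::tibble(node_id = 1:2, name = c("a", "b"),
                                        gene = c(10L, 20L)))
  dbl_g <- network_graph(tibble::tibble(node_id = 1L, name = "a", w = 0.5))
  expect_equal(validate_mapping_columns(str_g, int_g, "name", "name"), "string")
  expect_equal(validate_mapping_columns(int_g, int_g, "gene", "gene"), "integer")
  expect_error(validate_mapping_columns(str_g, int_g, "name", "gene"),
               class = "copycat_column_error")
  expect_error(validate_mapping_columns(dbl_g, str_g, "w", "name"),
               class = "copycat_column_error")
  expect_error(validate_mapping_columns(str_g, int_g, "name", "absent"),
               class = "copycat_not_found")
})

test_that("pass one: last encountered source value wins; missing contribute nothing", {
  s <- copycat_session()
  ids <- reg_named(s, c("X", "X", NA), coords = list(c(0, 0), c(5, 5), c(9, 9)))
  pmap <- build_source_position_map(resolve_view(s, ids$view_suid),
                                    get_network(s, ids$suid), "name")
  expect_equal(nrow(pmap), 1)
  expect_equal(unlist(pmap[pmap$key == "X", c("x", "y", "z")], use.names = FALSE),
               c(5, 5, 0))

  e <- register_network(s, network_graph(tibble::tibble(node_id = integer(),
                                                        name = character())))
  expect_equal(nrow(build_source_position_map(resolve_view(s, e$view_suid),
                                              get_network(s, e$suid), "name")), 0)
})

test_that("pass two: matches stack, non-matches are untouched", {
  s <- copycat_session()
  ids <- reg_named(s, c("X", "X", "Y"), coords = list(c(1, 1), c(2, 2), c(3, 3)))
  tg <- get_network(s, ids$suid)
  tv <- resolve_view(s, ids$view_suid)

  pmap <- tibble::tibble(key = "X", x = 5, y = 5, z = 0)
  tr <- transfer_positions(tv, tg, "name", pmap)
  nv <- tr$view$node_views
  expect_equal(nv$x[1:2], c(5, 5))            # both stacked on the source point
  expect_equal(nv$y[1:2], c(5, 5))
  expect_equal(unlist(nv[3, c("x", "y")], use.names = FALSE), c(3, 3))  # untouched
  expect_setequal(tr$matched_ids, 1:2)
  expect_equal(tr$unmatched_ids, 3L)

  tr0 <- transfer_positions(tv, tg, "name", tibble::tibble(key = character(),
                                                           x = double(), y = double(),
                                                           z = double()))
  expect_identical(tr0$view$node_views, tv$node_views)
  expect_length(tr0$matched_ids, 0)
  expect_equal(sort(tr0$unmatched_ids), 1:3)
})

test_that("a target equal to its source maps completely and bit-exactly", {
  withr::with_seed(7, {
    coords <- lapply(1:12, function(i) stats::runif(3, -500, 500))
  })
  s <- copycat_session()
  a <- reg_named(s, sprintf("g%02d", 1:12), coords = coords, name = "one")
  b <- reg_named(s, sprintf("g%02d", 1:12), name = "two")
  res <- copycat(s, a$view_suid, b$view_suid)
  expect_equal(res$mapped_node_count, 12)
  expect_equal(res$unmapped_node_count, 0)
  src_nv <- resolve_view(s, a$view_suid)$node_views
  tgt_nv <- resolve_view(s, b$view_suid)$node_views
  expect_identical(tgt_nv[, c("x", "y", "z")], src_nv[, c("x", "y", "z")])
})

test_that("unmapped selection is exact on both sides and value-level", {
  p <- derived_pair_session()
  res <- copycat(p$session, p$src$view_suid, p$tgt$view_suid, select_unmapped = TRUE)
  src_sel <- selected_nodes(p$session, p$src$suid)
  tgt_sel <- selected_nodes(p$session, p$tgt$suid)
  src_names <- get_network(p$session, p$src$suid)$nodes
  tgt_names <- get_network(p$session, p$tgt$suid)$nodes
  expect_equal(src_names$name[match(src_sel, src_names$node_id)], "H")
  expect_setequal(tgt_names$name[match(tgt_sel, tgt_names$node_id)], c("N", "O"))

  # identical networks: nothing selected
  s <- copycat_session()
  a <- reg_named(s, c("p", "q"), coords = list(c(0, 0), c(1, 1)), name = "a")
  b <- reg_named(s, c("p", "q"), name = "b")
  copycat(s, a$view_suid, b$view_suid, select_unmapped = TRUE)
  expect_length(selected_nodes(s, a$suid), 0)
  expect_length(selected_nodes(s, b$suid), 0)

  # duplicated source value matched once: no duplicate is selected
  s <- copycat_session()
  a <- reg_named(s, c("X", "X"), coords = list(c(0, 0), c(5, 5)), name = "dups")
  b <- reg_named(s, "X", name = "single")
  copycat(s, a$view_suid, b$view_suid, select_unmapped = TRUE)
  expect_length(selected_nodes(s, a$suid), 0)
})

test_that("select_unmapped=FALSE leaves prior selections alone, TRUE resets them", {
  s <- copycat_session()
  a <- reg_named(s, c("p", "q"), coords = list(c(0, 0), c(1, 1)), name = "a")
  b <- reg_named(s, c("p", "z"), name = "b")
  v <- resolve_view(s, b$view_suid)
  v$node_views$selected <- c(TRUE, FALSE)     # stale selection on a mapped node
  copycatr:::replace_view(s, v)

  copycat(s, a$view_suid, b$view_suid, select_unmapped = FALSE)
  expect_equal(selected_nodes(s, b$suid), 1L)  # untouched

  copycat(s, a$view_suid, b$view_suid, select_unmapped = TRUE)
  expect_equal(selected_nodes(s, b$suid), 2L)  # exactly the unmapped node
})

test_that("grid placement anchors beside the mapped bounding box", {
  s <- copycat_session()
  ids <- reg_named(s, sprintf("n%d", 1:3),
                   coords = list(c(100, 0), c(50, 40), c(-7, -3)))
  v <- resolve_view(s, ids$view_suid)

  expect_identical(grid_unmapped(v, integer())$node_views, v$node_views)

  # one unmatched node: mapped bbox max_x 100, min_y 0 -> (180, 0)
  v1 <- resolve_view(s, ids$view_suid)
  v1$node_views$y <- c(0, 40, -3)             # pin min_y of mapped nodes at 0
  v1$node_views$y[3] <- 33
  got <- grid_unmapped(v1, 3L, spacing = 80)
  expect_equal(unlist(got$node_views[3, c("x", "y")], use.names = FALSE), c(180, 0))
  expect_equal(got$node_views$z[3], v1$node_views$z[3])   # z untouched

  # five unmatched in a 3-column row-major grid, enumerated by hand
  s2 <- copycat_session()
  ids2 <- reg_named(s2, sprintf("m%d", 1:7),
                    coords = c(list(c(10, 5), c(60, 25)),
                               replicate(5, c(0, 0), simplify = FALSE)))
  v2 <- resolve_view(s2, ids2$view_suid)
  got <- grid_unmapped(v2, 3:7, spacing = 80)
  ax <- 60 + 80; ay <- 5
  want <- rbind(c(ax, ay), c(ax + 80, ay), c(ax + 160, ay),
                c(ax, ay + 80), c(ax + 80, ay + 80))
  expect_equal(as.matrix(got$node_views[3:7, c("x", "y")]), want,
               ignore_attr = TRUE)

  # no mapped nodes at all: grid anchors at the origin
  got <- grid_unmapped(v2, 1:7, spacing = 80)
  expect_equal(unlist(got$node_views[1, c("x", "y")], use.names = FALSE), c(0, 0))
})

test_that("viewport cloning is plain copy and idempotent", {
  s <- copycat_session()
  a <- reg_named(s, "a", coords = list(c(10, -5)))
  b <- reg_named(s, "b")
  sv <- resolve_view(s, a$view_suid)
  sv$viewport <- list(zoom = 2.0, center_x = 10, center_y = -5)
  tv <- clone_viewport(sv, resolve_view(s, b$view_suid))
  expect_equal(tv$viewport, sv$viewport)
  expect_equal(clone_viewport(sv, tv)$viewport, tv$viewport)
})

test_that("copycat refuses identical source and target views", {
  p <- derived_pair_session()
  expect_error(copycat(p$session, p$src$view_suid, p$src$view_suid),
               class = "copycat_validation")
})

test_that("copycat agrees with the brute-force matcher on random pairs", {
  for (seed in 1:25) {
    pair <- generate_pair(n_source = 50, n_target = 50, overlap_fraction = 0.6,
                          duplicate_rate = 0.2, missing_rate = 0.1, seed = seed)
    oracle <- brute_force_copycat(
      graph_of(pair, "source"), view_of(pair, "source"),
      graph_of(pair, "target"), view_of(pair, "target"))
    res <- copycat(pair$session, pair$source_view_suid, pair$target_view_suid,
                   select_unmapped = TRUE)
    expect_equal(res$mapped_node_count, oracle$mapped_count)
    expect_equal(res$unmapped_node_count, oracle$unmapped_count)
    expect_setequal(res$unmapped_target_ids, oracle$unmapped_target_ids)
    expect_setequal(res$unmapped_source_ids, oracle$unmapped_source_ids)
    tv <- view_of(pair, "target")$node_views
    ord <- match(oracle$positions$node_id, tv$node_id)
    expect_identical(tv$x[ord], oracle$positions$x)
    expect_identical(tv$y[ord], oracle$positions$y)
    expect_identical(tv$z[ord], oracle$positions$z)
  }
})

test_that("one 500-node pair at 60% overlap matches the oracle too", {
  pair <- generate_pair(500, 500, 0.6, seed = 99)
  oracle <- brute_force_copycat(
    graph_of(pair, "source"), view_of(pair, "source"),
    graph_of(pair, "target"), view_of(pair, "target"))
  res <- copycat(pair$session, pair$source_view_suid, pair$target_view_suid)
  expect_equal(res$mapped_node_count, oracle$mapped_count)
  tv <- view_of(pair, "target")$node_views
  ord <- match(oracle$positions$node_id, tv$node_id)
  expect_identical(tv$x[ord], oracle$positions$x)
})

test_that("running copycat twice changes nothing, with and without gridding", {
  for (grid in c(FALSE, TRUE)) {
    pair <- generate_pair(40, 40, 0.5, duplicate_rate = 0.1, missing_rate = 0.1,
                          seed = 11)
    r1 <- copycat(pair$session, pair$source_view_suid, pair$target_view_suid,
                  select_unmapped = TRUE, grid_unmapped = grid)
    snap1 <- session_snapshot(pair)
    r2 <- copycat(pair$session, pair$source_view_suid, pair$target_view_suid,
                  select_unmapped = TRUE, grid_unmapped = grid)
    snap2 <- session_snapshot(pair)
    expect_identical(snap1, snap2)
    expect_identical(r1[c("mapped_node_count", "unmapped_node_count")],
                     r2[c("mapped_node_count", "unmapped_node_count")])
  }
})

test_that("tidy and glance summarise the result consistently", {
  p <- derived_pair_session()
  res <- copycat(p$session, p$src$view_suid, p$tgt$view_suid, select_unmapped = TRUE)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$side == "target"), 9)
  expect_equal(sum(td$side == "target" & td$mapped), 7)
  gl <- glance(res)
  expect_equal(gl$mapped_node_count + gl$unmapped_node_count, 9L)
  expect_equal(gl$unmapped_source_count, 1L)
  expect_s3_class(autoplot(view_of(list(session = p$session,
                                        target_view_suid = p$tgt$view_suid),
                                   "target")), "ggplot")
})
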