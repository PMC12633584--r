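g1_index <- local({
  idx <- NULL
  function() {
    if (is.null(idx)) idx <<- build_distance_index(g1())
    idx
  }
})

test_that("zip codes spell out the snarl-tree address with distances", {
  idx <- g1_index()
  z <- compute_zipcode(graph_pos(2, "+", 0), index = idx)
  kinds <- vapply(z, `[[`, "", "kind")
  expect_equal(kinds, c("chain", "snarl", "chain", "node"))
  expect_equal(z[[1]]$offset, 3)          # gap starts after node 1's 3 bases
  expect_equal(z[[2]]$dist_start, 0)
  expect_equal(z[[2]]$dist_end, 0)
  expect_equal(z[[4]]$node, 2)
  expect_equal(z[[4]]$length, 1)
  expect_equal(z[[4]]$offset, 0)

  # a top-level node has a depth-1 address: one chain level plus the leaf
  z1 <- compute_zipcode(graph_pos(1, "+", 1), index = idx)
  expect_equal(vapply(z1, `[[`, "", "kind"), c("chain", "node"))

  # two positions on one node differ only in the leaf offset
  za <- compute_zipcode(graph_pos(4, "+", 0), index = idx)
  zb <- compute_zipcode(graph_pos(4, "+", 2), index = idx)
  expect_equal(za[-length(za)], zb[-length(zb)])
  expect_equal(zb[[length(zb)]]$offset, 2)
})

test_that("the worked fixture's zip tree reproduces hand-checked distances", {
  idx <- g1_index()
  seeds <- data.frame(node = c(1L, 4L), orient = 0L, offset = 0L)
  forest <- build_zip_forest(seeds, index = idx)
  expect_equal(length(forest), 1)
  it <- iter_seed_distances(forest[[1]], from_seed = 1)
  expect_equal(it$seed, 2L)
  expect_equal(it$distance, 4)

  # a single seed: one seed item, no edges
  f1 <- build_zip_forest(seeds[1, , drop = FALSE], index = idx)
  items <- f1[[1]]$items
  expect_equal(sum(items$kind == "seed"), 1)
  expect_true(all(is.na(items$edge_to_next[items$kind == "seed"])))
})

test_that("seeds on sibling alleles share snarl brackets but are mutually unreachable", {
  idx <- g1_index()
  seeds <- data.frame(node = c(1L, 2L, 3L, 4L), orient = 0L, offset = 0L)
  forest <- build_zip_forest(seeds, index = idx)
  expect_equal(length(forest), 1)
  tr <- forest[[1]]
  items <- tr$items
  snarl_opens <- which(items$kind == "snarl_open")
  expect_equal(length(snarl_opens), 1)  # both alleles under the same snarl
  # seeds 2 and 3 (rows in `seeds`) cannot reach each other
  i2 <- match(2L, tr$seed_rows); i3 <- match(3L, tr$seed_rows)
  d23 <- pgmap:::.zip_pair_dist_cpp(tr$levels, tr$ptr, tr$depth,
                                    min(i2, i3), max(i2, i3), tr$dir)
  expect_equal(d23, Inf)
  # but each allele seed is reachable from the boundary seed on node 1
  from1 <- iter_seed_distances(tr, from_seed = 1)
  expect_equal(sort(from1$distance[from1$seed %in% c(2L, 3L)]), c(3, 3))
  expect_equal(from1$distance[from1$seed == 4L], 4)
})

test_that("tree distances are exact on acyclic fixtures for both headings", {
  set.seed(11)
  for (seed in 1:6) {
    g <- random_dag_fixture(seed, backbone = 250)
    idx <- build_distance_index(g)
    for (orient in 0:1) {
      pos <- random_positions(g, 40)
      seeds <- data.frame(node = pos[, 1], orient = orient, offset = pos[, 3])
      seeds <- unique(seeds)
      forest <- build_zip_forest(seeds, index = idx)
      for (tr in forest) {
        if (length(tr$seed_rows) < 2) next
        for (i in head(seq_along(tr$seed_rows), -1)) {
          it <- iter_seed_distances(tr, from_seed = tr$seed_rows[i])
          a <- seeds[rep(tr$seed_rows[i], nrow(it)), ]
          b <- seeds[it$seed, ]
          want <- pgmap:::min_distances(idx, as.matrix(a), as.matrix(b))
          expect_equal(it$distance, want,
                       info = sprintf("seed %d orient %d", seed, orient))
        }
      }
    }
  }
})

test_that("tree distances never under-report on cyclic and inversion fixtures", {
  set.seed(12)
  graphs <- list(duplication_graph(), inversion_graph())
  for (s in 1:4) graphs <- c(graphs, list(
    random_fixture(s + 40, backbone = 250, inv = 0.01, dup = 0.01)))
  n_checked <- 0
  for (g in graphs) {
    idx <- build_distance_index(g)
    pos <- unique(random_positions(g, 60))
    seeds <- data.frame(node = pos[, 1], orient = pos[, 2], offset = pos[, 3])
    forest <- build_zip_forest(seeds, index = idx)
    for (tr in forest) {
      if (length(tr$seed_rows) < 2) next
      for (i in head(seq_along(tr$seed_rows), -1)) {
        it <- iter_seed_distances(tr, from_seed = tr$seed_rows[i])
        fin <- is.finite(it$distance)
        if (!any(fin)) next
        a <- seeds[rep(tr$seed_rows[i], sum(fin)), ]
        b <- seeds[it$seed[fin], ]
        want <- pgmap:::min_distances(idx, as.matrix(a), as.matrix(b))
        expect_true(all(it$distance[fin] >= want - 1e-9))
        n_checked <- n_checked + sum(fin)
      }
    }
  }
  expect_gt(n_checked, 100)
})

test_that("brackets balance and every seed appears exactly once", {
  set.seed(13)
  for (rep in 1:20) {
    g <- random_fixture(rep + 60, backbone = 200, inv = 0.005, dup = 0.005)
    pos <- unique(random_positions(g, sample(2:25, 1)))
    seeds <- data.frame(node = pos[, 1], orient = pos[, 2], offset = pos[, 3])
    idx <- build_distance_index(g)
    forest <- build_zip_forest(seeds, index = idx)
    seen <- integer(0)
    for (tr in forest) {
      items <- tr$items
      depth <- 0
      for (i in seq_len(nrow(items))) {
        k <- items$kind[i]
        if (grepl("open", k)) depth <- depth + 1
        if (grepl("close", k)) depth <- depth - 1
        expect_gte(depth, 0)
      }
      expect_equal(depth, 0)
      seen <- c(seen, tr$seed_rows)
    }
    expect_equal(sort(seen), seq_len(nrow(seeds)))
  }
})

test_that("iterating backward from the last seed mirrors forward iteration", {
  idx <- g1_index()
  seeds <- data.frame(node = c(1L, 2L, 4L), orient = 0L, offset = 0L)
  forest <- build_zip_forest(seeds, index = idx)
  tr <- forest[[1]]
  last <- tr$seed_rows[length(tr$seed_rows)]
  fwd_from_last <- iter_seed_distances(tr, from_seed = last, "forward")
  expect_equal(nrow(fwd_from_last), 0)
  back <- iter_seed_distances(tr, from_seed = last, "backward")
  expect_equal(sort(back$seed), sort(setdiff(tr$seed_rows, last)))
})
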