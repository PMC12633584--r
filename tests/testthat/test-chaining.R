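test_that("gap cost follows the minimap2-style formula", {
  p <- chaining_params(gap_scale = 0.19)
  expect_equal(gap_cost(57, 57, p), 0)
  expect_equal(gap_cost(10, Inf, p), Inf)
  expect_equal(gap_cost(10, 18, p), 0.19 * 8 + 0.5 * 3)  # g = 8
  expect_equal(gap_cost(0, 5, p), 0.19 * 5 + 0.5 * log2(5))
})

test_that("chain DP equals exhaustive enumeration on random instances", {
  set.seed(99)
  k <- 10
  for (rep in 1:120) {
    n <- sample(2:9, 1)
    off <- sort(sample(0:150, n))
    D <- matrix(Inf, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- if (runif(1) < 0.15) Inf
      else max(0, (off[j] - off[i]) + sample(-12:12, 1))
    }
    got <- dp_top_score(off, k, D)
    want <- oracle_best_chain(off, k, D, 0.19, 0.5, 1000)
    expect_equal(got, want, info = sprintf("rep %d", rep))
  }
})

test_that("adding a seed never decreases the top chain score", {
  set.seed(123)
  k <- 10
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    off <- sort(sample(0:120, n + 1))
    D <- matrix(Inf, n + 1, n + 1)
    for (i in 1:n) for (j in (i + 1):(n + 1))
      D[i, j] <- max(0, (off[j] - off[i]) + sample(-10:10, 1))
    drop <- sample(n + 1, 1)
    full <- dp_top_score(off, k, D)
    sub <- dp_top_score(off[-drop], k, D[-drop, -drop, drop = FALSE])
    expect_gte(full + 1e-9, sub)
  }
})

test_that("an error-free read along a haplotype chains every seed with zero gap cost", {
  g <- g1()
  idx <- build_distance_index(g)
  mi <- build_minimizer_index(g, minimizer_params(k = 3, w = 2))
  seeds <- find_seeds(mi, "GATATACA")
  seeds$len <- 3L
  forest <- build_zip_forest(seeds, index = idx)
  chains <- chain_seeds(forest, chaining_params(top_chains = 2))
  expect_gt(length(chains), 0)
  top <- chains[[1]]
  # perfect colinearity: graph gaps equal read gaps, score equals coverage
  expect_equal(top$transitions$read_gap, top$transitions$graph_gap)
  expect_equal(top$score, top$coverage)
  # the top chain spans every forward-strand minimizer with no gap cost
  fwd_reads <- seeds$read_offset[seeds$strand == 0]
  expect_equal(top$read_start, min(fwd_reads))
  expect_equal(top$read_end, max(fwd_reads) + 3)
})

test_that("a crossing seed out of graph order is dropped from the top chain", {
  # four co-linear seeds plus one whose graph position conflicts (reachable
  # only with a huge gap): the chain keeps the majority
  k <- 10
  off <- c(0, 20, 40, 60, 30)
  ordr <- order(off)  # tree order must follow graph order: crossing seed last
  off_t <- c(0, 20, 40, 60, 95)  # crossing seed read offset 95, graph pos mid
  D <- matrix(Inf, 5, 5)
  for (i in 1:4) for (j in 1:4) if (i < j) D[i, j] <- off_t[j] - off_t[i]
  # crossing seed (5) sits between 2 and 3 in the graph: unreachable from 3,4
  D[1, 5] <- 25; D[2, 5] <- 5
  got <- dp_top_score(off_t, k, D)
  # best is the 4 co-linear seeds: 10 + 3*10 = 40; adding 5 via 2 loses 3,4
  expect_equal(got, 40)
})

test_that("chained seeds are co-linear under the distance index directly", {
  set.seed(5)
  g <- random_dag_fixture(17, backbone = 400, nh = 4)
  idx <- build_distance_index(g)
  mi <- build_minimizer_index(g, minimizer_params(k = 9, w = 5))
  sp <- spell_walk(g, 2)
  for (read in c(substr(sp, 30, 220), reverse_complement(substr(sp, 100, 300)))) {
    seeds <- find_seeds(mi, read)
    seeds$len <- 9L
    forest <- build_zip_forest(seeds, index = idx)
    chains <- chain_seeds(forest)
    expect_gt(length(chains), 0)
    for (ch in chains) {
      s <- ch$seeds
      if (nrow(s) < 2) next
      expect_true(all(diff(s$read_offset) > 0))
      d <- pgmap:::min_distances(idx,
        as.matrix(s[-nrow(s), c("node", "orient", "offset")]),
        as.matrix(s[-1, c("node", "orient", "offset")]))
      expect_true(all(is.finite(d)))
    }
  }
})

test_that("an empty forest yields an empty chain list", {
  expect_equal(chain_seeds(structure(list(), class = "zip_forest"),
                           seeds = data.frame()), list())
})
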