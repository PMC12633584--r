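test_that("w=1 selects every k-mer and dedupes shared positions across walks", {
  g <- g1()
  idx <- build_minimizer_index(g, minimizer_params(k = 3, w = 1))
  # every 3-mer of both haplotype spellings must be present in the index
  for (sp in c("GATATACA", "GATCTACA")) {
    for (i in 1:(nchar(sp) - 2)) {
      km <- substr(sp, i, i + 2)
      rc <- reverse_complement(km)
      canon <- min(km, rc)
      expect_false(is.null(idx$occ[[canon]]),
                   info = sprintf("missing %s", canon))
    }
  }
  # the occurrence of GAT at (1,+,0), shared by both walks, appears once
  rec <- idx$occ[[min("GAT", reverse_complement("GAT"))]]
  at_origin <- rec[, 1] == 1 & rec[, 2] == 0 & rec[, 3] == 0
  expect_equal(sum(at_origin), 1)
})

test_that("a homopolymer walk yields one record with every occurrence", {
  g <- variation_graph(data.frame(id = 1, seq = strrep("A", 50)),
                       walks = list(walk("H1", 1)))
  idx <- build_minimizer_index(g, minimizer_params(k = 3, w = 5))
  expect_equal(idx$n_kmers, 1)
  rec <- idx$occ[["AAA"]]
  expect_equal(nrow(rec), 48)
})

test_that("index selection equals the naive per-window scan oracle", {
  for (seed in c(2, 9)) {
    g <- random_fixture(seed, backbone = 120, nh = 3)
    p <- minimizer_params(k = 5, w = 4)
    raw <- pgmap:::.index_minimizers_cpp(
      vapply(seq_along(g$walks), function(i) spell_walk(g, i), ""),
      p$k, p$w, p$weight_threshold)
    for (wi in seq_along(g$walks)) {
      want <- oracle_minimizer_scan(spell_walk(g, wi), p$k, p$w)
      expect_equal(sort(raw$per_walk[[wi]]$offset), want,
                   info = sprintf("seed %d walk %d", seed, wi))
    }
  }
})

test_that("window coverage holds: every window contains a selected span", {
  g <- random_fixture(4, backbone = 200, nh = 2)
  p <- minimizer_params(k = 7, w = 5)
  raw <- pgmap:::.index_minimizers_cpp(
    vapply(seq_along(g$walks), function(i) spell_walk(g, i), ""),
    p$k, p$w, p$weight_threshold)
  for (wi in seq_along(g$walks)) {
    m <- nchar(spell_walk(g, wi)) - p$k + 1
    sel <- sort(raw$per_walk[[wi]]$offset)
    for (start in seq(0, m - p$w, by = 7)) {
      expect_true(any(sel >= start & sel < start + p$w),
                  info = sprintf("window at %d", start))
    }
  }
})

test_that("seeds on an exact read spell the read k-mer at their graph position", {
  g <- g1()
  idx <- build_minimizer_index(g, minimizer_params(k = 3, w = 2))
  read <- "GATATACA"  # H1 spelling
  seeds <- find_seeds(idx, read)
  expect_gt(nrow(seeds), 0)
  for (i in seq_len(nrow(seeds))) {
    km <- substr(read, seeds$read_offset[i] + 1, seeds$read_offset[i] + 3)
    spelled <- walk_kmers_at(g, seeds$node[i], seeds$orient[i],
                             seeds$offset[i], 3)
    expect_true(km %in% spelled,
                info = sprintf("seed %d (%d,%d,%d)", i, seeds$node[i],
                               seeds$orient[i], seeds$offset[i]))
  }
})

test_that("seed truthfulness holds on random fixtures and both strands", {
  set.seed(31)
  g <- random_fixture(13, backbone = 250, nh = 4)
  p <- minimizer_params(k = 7, w = 3)
  idx <- build_minimizer_index(g, p)
  sp <- spell_walk(g, 2)
  for (read in c(substr(sp, 20, 90), reverse_complement(substr(sp, 35, 110)))) {
    seeds <- find_seeds(idx, read)
    expect_gt(nrow(seeds), 0)
    for (i in seq_len(nrow(seeds))) {
      km <- substr(read, seeds$read_offset[i] + 1, seeds$read_offset[i] + p$k)
      spelled <- walk_kmers_at(g, seeds$node[i], seeds$orient[i],
                               seeds$offset[i], p$k)
      expect_true(km %in% spelled)
    }
  }
})

test_that("degenerate reads and the hit cap produce empty seed lists", {
  g <- g1()
  idx <- build_minimizer_index(g, minimizer_params(k = 3, w = 2))
  expect_equal(nrow(find_seeds(idx, strrep("N", 40))), 0)
  expect_equal(nrow(find_seeds(idx, "GA")), 0)  # shorter than k, not an error

  gh <- variation_graph(data.frame(id = 1, seq = strrep("A", 50)),
                        walks = list(walk("H1", 1)))
  idxh <- build_minimizer_index(gh, minimizer_params(k = 3, w = 5,
                                                     hard_hit_cap = 1))
  expect_equal(nrow(find_seeds(idxh, strrep("A", 20))), 0)
})

test_that("seeding is deterministic", {
  g <- random_fixture(6, backbone = 200)
  idx1 <- build_minimizer_index(g, minimizer_params(k = 9, w = 5))
  idx2 <- build_minimizer_index(g, minimizer_params(k = 9, w = 5))
  read <- substr(spell_walk(g, 1), 10, 160)
  expect_identical(find_seeds(idx1, read), find_seeds(idx2, read))
})
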