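test_that("wavefront alignment scores identity and substitution directly", {
  sc <- scoring_params()
  r <- wfa_align("ACGT", "ACGT", sc)
  expect_equal(r$score, 4)
  expect_equal(r$edits, data.frame(op = "=", len = 4L))
  r2 <- wfa_align("ACGT", "AGGT", sc)
  expect_equal(r2$score, -1)  # 3 matches + 1 mismatch
  expect_equal(paste0(r2$edits$len, r2$edits$op, collapse = ""), "1=1X2=")
})

test_that("wavefront alignment equals full gap-affine DP on random pairs", {
  set.seed(201)
  sc <- scoring_params()
  for (i in 1:200) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(2:300, 1), TRUE),
               collapse = "")
    b <- mutate_seq(a, 0.15)
    r <- wfa_align(a, b, sc)
    expect_true(r$ok)
    expect_equal(r$score, unname(oracle_global_score(a, b, sc)),
                 info = sprintf("pair %d", i))
    # cigar internally consistent: rescoring the ops reproduces the score
    expect_equal(pgmap:::cigar_score(r$edits, sc), r$score)
    expect_equal(sum(r$edits$len[r$edits$op %in% c("=", "X", "I")]), nchar(a))
    expect_equal(sum(r$edits$len[r$edits$op %in% c("=", "X", "D")]), nchar(b))
  }
})

test_that("the wavefront aligner declares failure beyond its cost budget", {
  sc <- scoring_params(wfa_max_cost = 3)
  r <- wfa_align("AAAAAAAA", "CCCCCCCC", sc)
  expect_false(r$ok)
  expect_true(is.na(r$score))
})

test_that("anchored mode pins the start and takes the best-scoring end", {
  sc <- scoring_params()
  r <- wfa_align("ACGTACGT", "ACGTACGTTTTTTTT", sc, mode = "anchored_prefix")
  expect_equal(r$score, 8)
  expect_equal(r$q_end, 8)
  expect_equal(r$t_end, 8)
  # a query that degrades mid-way ends early
  r2 <- wfa_align("ACGTGGGGGG", "ACGTACACAC", sc, mode = "anchored_prefix")
  expect_equal(r2$score, 4)
  expect_equal(r2$q_end, 4)
})

test_that("the banded graph aligner picks the right allele through bubbles", {
  g <- g1()
  sc <- scoring_params()
  # bases strictly between (1,+,1) and (4,+,1) via node 2: "TAT"
  r <- banded_graph_global("TAT", g, graph_pos(1, "+", 1), graph_pos(4, "+", 1),
                           sc, band = 10)
  expect_equal(r$score, 3)
  expect_equal(r$walk$node, c(1, 2, 4))
  expect_equal(paste0(r$edits$len, r$edits$op, collapse = ""), "3=")
  # the other allele: "TCTA" via node 3
  r2 <- banded_graph_global("TCTA", g, graph_pos(1, "+", 1),
                            graph_pos(4, "+", 2), sc, band = 10)
  expect_equal(r2$score, 4)
  expect_equal(r2$walk$node, c(1, 3, 4))
  # empty read segment with adjacent anchors: pure deletion of one allele base
  r3 <- banded_graph_global("", g, graph_pos(1, "+", 2), graph_pos(4, "+", 0),
                            sc, band = 10)
  expect_equal(r3$score, sc$gap_open + sc$gap_extend)
  expect_equal(paste0(r3$edits$len, r3$edits$op, collapse = ""), "1D")
})

test_that("the graph aligner equals path enumeration + linear DP on bubble graphs", {
  set.seed(77)
  sc <- scoring_params()
  n_checked <- 0
  for (seed in 1:6) {
    g <- random_fixture(seed + 200, backbone = 60, nh = 3,
                        snv = 0.05, ind = 0.02, inv = 0.01, dup = 0.01)
    if (nrow(g$nodes) > 30) next
    sp <- spell_walk(g, 1)
    w <- g$walks[[1]]
    lens <- nchar(g$nodes$seq)[match(w$steps$node, g$nodes$id)]
    cum <- cumsum(c(0, lens))
    for (rep in 1:6) {
      # anchors on the first walk, a random stretch apart
      t1 <- sample(0:(nchar(sp) - 20), 1)
      t2 <- t1 + sample(5:15, 1)
      pos_at <- function(t) {
        stp <- findInterval(t, cum)
        graph_pos(w$steps$node[stp], c("+", "-")[w$steps$orient[stp] + 1],
                  t - cum[stp])
      }
      a <- pos_at(t1); b <- pos_at(t2)
      # segment: sometimes the walk's own bases, sometimes mutated
      q <- substr(sp, t1 + 2, t2)
      if (rep %% 2 == 0) q <- mutate_seq(q, 0.2)
      band <- nchar(q) + 15
      got <- banded_graph_global(q, g, a, b, sc, band = band)
      spellings <- oracle_segment_spellings(g, a, b, nchar(q) + band)
      expect_gt(length(spellings), 0)
      want <- max(vapply(spellings, function(t0)
        unname(oracle_global_score(q, t0, sc)), 0))
      expect_equal(got$score, want,
                   info = sprintf("seed %d rep %d", seed, rep))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("X-drop tails extend exact continuations fully and clip junk", {
  g <- g1()
  sc <- scoring_params()
  xt <- xdrop_tail("ATATACA", g, graph_pos(1, "+", 0), "right", sc)
  expect_equal(xt$score, 7)
  expect_equal(xt$aligned, 7)
  expect_equal(paste0(xt$edits$len, xt$edits$op, collapse = ""), "7=")
  junk <- xdrop_tail("GGGGGGGG", g, graph_pos(1, "+", 0), "right", sc)
  expect_equal(junk$aligned, 0)
  expect_equal(junk$score, 0)
  # left tail: extend backwards from the last base of node 4
  lt <- xdrop_tail("GATATAC", g, graph_pos(4, "+", 3), "left", sc)
  expect_equal(lt$score, 7)
  expect_equal(lt$walk$node[length(lt$walk$node)], 4)
})

test_that("X-drop equals the unrestricted extension oracle inside the envelope", {
  set.seed(88)
  sc <- scoring_params()
  for (seed in 1:4) {
    g <- random_dag_fixture(seed + 300, backbone = 80, nh = 2)
    sp <- spell_walk(g, 1)
    w <- g$walks[[1]]
    lens <- nchar(g$nodes$seq)[match(w$steps$node, g$nodes$id)]
    cum <- cumsum(c(0, lens))
    t0 <- sample(2:(nchar(sp) %/% 2), 1)
    stp <- findInterval(t0, cum)
    anchor <- graph_pos(w$steps$node[stp], "+", t0 - cum[stp])
    tail_len <- min(25, nchar(sp) - t0 - 2)
    tail_seq <- mutate_seq(substr(sp, t0 + 2, t0 + 1 + tail_len), 0.08)
    got <- xdrop_tail(tail_seq, g, anchor, "right", sc)
    spellings <- oracle_segment_spellings(
      g, anchor, graph_pos(w$steps$node[nrow(w$steps)], "+",
                           lens[length(lens)] - 1),
      nchar(tail_seq) + 40)
    if (!length(spellings)) next
    want <- max(vapply(spellings, function(t1)
      oracle_extend_score(tail_seq, t1, sc), 0))
    expect_gte(got$score + 1e-9, want - sc$xdrop)
    if (got$score == want) succeed()
  }
})

test_that("extending a perfect chain reproduces the haplotype walk", {
  g <- g1()
  idx <- build_distance_index(g)
  mi <- build_minimizer_index(g, minimizer_params(k = 3, w = 2))
  sc <- scoring_params()
  seeds <- find_seeds(mi, "GATATACA"); seeds$len <- 3L
  chains <- chain_seeds(build_zip_forest(seeds, index = idx))
  aln <- extend_chain(chains[[1]], "GATATACA", g, idx, sc)
  expect_equal(aln$walk$node, c(1, 2, 4))
  expect_equal(aln$walk$orient, c(0, 0, 0))
  expect_equal(aln$score, 8)
  expect_equal(paste0(aln$edits$len, aln$edits$op, collapse = ""), "8=")
  expect_equal(c(aln$q_start, aln$q_end), c(0, 8))
})

test_that("a single mismatch yields a full-length alignment with one X", {
  g <- g1()
  idx <- build_distance_index(g)
  mi <- build_minimizer_index(g, minimizer_params(k = 3, w = 2))
  aln <- local({
    seeds <- find_seeds(mi, "GATATGCA"); seeds$len <- 3L
    chains <- chain_seeds(build_zip_forest(seeds, index = idx))
    extend_chain(chains[[1]], "GATATGCA", g, idx, scoring_params())
  })
  expect_equal(aln$walk$node, c(1, 2, 4))
  expect_equal(aln$score, 3)  # 7 matches - 4
  expect_equal(sum(aln$edits$len[aln$edits$op == "X"]), 1)
  expect_equal(c(aln$q_start, aln$q_end), c(0, 8))
})

test_that("alignments rescore exactly and account for every read base", {
  set.seed(99)
  sc <- scoring_params()
  g <- random_dag_fixture(21, backbone = 500, nh = 4)
  idx <- build_distance_index(g)
  mi <- build_minimizer_index(g, minimizer_params(k = 9, w = 5))
  ctxs <- pgmap:::hap_contexts(g)
  sim <- simulate_reads(g, read_sim_params(n_reads = 12, read_length = 150,
                                           mismatch_rate = 0.03,
                                           insertion_rate = 0.01,
                                           deletion_rate = 0.01, seed = 5))
  for (i in seq_along(sim$reads)) {
    read <- unname(sim$reads[i])
    seeds <- find_seeds(mi, read)
    if (!nrow(seeds)) next
    seeds$len <- 9L
    chains <- chain_seeds(build_zip_forest(seeds, index = idx))
    if (!length(chains)) next
    aln <- extend_chain(chains[[1]], read, g, idx, sc, ctxs)
    if (is.null(aln)) next
    rs <- pgmap:::rescore_alignment(g, aln, read)
    expect_true(rs$ok, info = sprintf("read %d", i))
    expect_equal(rs$score, aln$score, info = sprintf("read %d", i))
    # soft-clipped + aligned read bases = read length
    aligned <- sum(aln$edits$len[aln$edits$op %in% c("=", "X", "I")])
    expect_equal(aligned, aln$q_end - aln$q_start)
    expect_equal(aln$q_start + aligned + (nchar(read) - aln$q_end),
                 nchar(read))
  }
})
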