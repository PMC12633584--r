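test_that("degenerate simulation parameters give the expected graphs", {
  g0 <- simulate_graph(graph_sim_params(backbone_length = 80,
                                        n_haplotypes = 3,
                                        snv_bubble_rate = 0,
                                        indel_bubble_rate = 0,
                                        inversion_rate = 0,
                                        tandem_duplication_rate = 0, seed = 1))
  expect_equal(nrow(g0$nodes), 1)
  expect_equal(length(g0$walks), 3)
  sp <- vapply(1:3, function(i) spell_walk(g0, i), "")
  expect_equal(length(unique(sp)), 1)

  gs <- simulate_graph(graph_sim_params(backbone_length = 400,
                                        n_haplotypes = 4,
                                        snv_bubble_rate = 0.03,
                                        indel_bubble_rate = 0,
                                        inversion_rate = 0,
                                        tandem_duplication_rate = 0, seed = 2))
  tree <- decompose_snarls(gs)
  expect_gt(length(tree$snarls), 0)
  for (s in tree$snarls) {
    expect_equal(length(s$child_chains), 2)  # two-allele substitution bubbles
    expect_false(s$cyclic)
    for (ci in s$child_chains)
      expect_equal(length(tree$chains[[ci]]$nodes), 1)
  }
})

test_that("graph simulation is byte-deterministic under a fixed seed", {
  p <- graph_sim_params(backbone_length = 300, n_haplotypes = 4, seed = 77)
  expect_identical(write_gfa(simulate_graph(p)), write_gfa(simulate_graph(p)))
  g <- simulate_graph(p)
  s1 <- simulate_reads(g, read_sim_params(n_reads = 10, read_length = 80,
                                          mismatch_rate = 0.05, seed = 5))
  s2 <- simulate_reads(g, read_sim_params(n_reads = 10, read_length = 80,
                                          mismatch_rate = 0.05, seed = 5))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("error-free reads are exact substrings of walk spellings", {
  g <- random_fixture(55, backbone = 400, nh = 3)
  sim <- simulate_reads(g, read_sim_params(n_reads = 30, read_length = 60,
                                           seed = 8))
  spells <- vapply(seq_along(g$walks), function(i) spell_walk(g, i), "")
  names(spells) <- vapply(g$walks, `[[`, "", "name")
  for (i in seq_len(nrow(sim$truth))) {
    t <- sim$truth[i, ]
    sub <- substr(spells[t$hap], t$start + 1, t$end)
    want <- if (t$strand == "-") reverse_complement(sub) else sub
    expect_equal(unname(sim$reads[t$name]), unname(want))
  }
})

test_that("error rates are rejected outside bounds and realized near expectation", {
  expect_error(read_sim_params(deletion_rate = 1.0), "rates")
  expect_error(read_sim_params(mismatch_rate = 0.5), "rates")
  g <- simulate_graph(graph_sim_params(backbone_length = 3000,
                                       n_haplotypes = 1,
                                       snv_bubble_rate = 0, seed = 3))
  n <- 60; rl <- 500; mr <- 0.05
  sim <- simulate_reads(g, read_sim_params(n_reads = n, read_length = rl,
                                           mismatch_rate = mr, seed = 10))
  # with substitutions only, read lengths are unchanged; count mismatches
  spell <- spell_walk(g, 1)
  mm <- 0
  for (i in seq_len(n)) {
    t <- sim$truth[i, ]
    ref <- substr(spell, t$start + 1, t$end)
    if (t$strand == "-") ref <- reverse_complement(ref)
    a <- strsplit(unname(sim$reads[i]), "")[[1]]
    b <- strsplit(unname(ref), "")[[1]]
    mm <- mm + sum(a != b)
  }
  # mismatches resampled to a different base always differ; 3-sigma check
  exp_mm <- n * rl * mr
  sd_mm <- sqrt(n * rl * mr * (1 - mr))
  expect_lt(abs(mm - exp_mm), 3 * sd_mm + 1)
})

test_that("evaluation judges perfect and shifted alignments correctly", {
  g <- random_dag_fixture(66, backbone = 500, nh = 3)
  ix <- build_graph_indexes(g, minimizer_params(k = 11, w = 7))
  sim <- simulate_reads(g, read_sim_params(n_reads = 20, read_length = 120,
                                           seed = 2))
  res <- map_reads(sim$reads, ix)
  gaf <- read_gaf(write_gaf(res, g, sim$reads), g)
  ev <- evaluate_mapping(gaf, sim$truth, g)
  expect_gte(mean(ev$per_read$correct), 0.9)
  expect_true(all(ev$by_mapq$cum_precision >= 0 & ev$by_mapq$cum_precision <= 1))

  # deliberately shift every alignment to a different region: all wrong
  spoiled <- gaf
  n_nodes <- nrow(g$nodes)
  for (i in seq_len(nrow(spoiled))) {
    len <- length(spoiled$path_nodes[[i]])
    # replace with a path over the final backbone node, far from the origin
    spoiled$path_nodes[[i]] <- rep(g$nodes$id[n_nodes], 1)
    spoiled$path_orients[[i]] <- 0L
    spoiled$path_start[i] <- 0L
    spoiled$path_end[i] <- min(5L, nchar(g$nodes$seq[n_nodes]))
  }
  # reads whose truth interval touches that node may still overlap; drop them
  keep <- vapply(seq_len(nrow(spoiled)), function(i) {
    t <- sim$truth[match(spoiled$name[i], sim$truth$name), ]
    w <- g$walks[[match(t$hap, vapply(g$walks, `[[`, "", "name"))]]
    iv <- pgmap:::walk_slice_intervals(g, w, t$start, t$end)
    !(g$nodes$id[n_nodes] %in% iv$node)
  }, TRUE)
  ev2 <- evaluate_mapping(spoiled[keep, , drop = FALSE],
                          sim$truth, g)
  expect_equal(sum(ev2$per_read$correct), 0)
})

test_that("a hand-adjudicated fixture matches the correctness criterion", {
  # two walks differing at one substitution bubble; reads from each allele
  g <- g1()
  truth <- data.frame(name = c("a", "b"), hap = c("H1", "H2"),
                      start = 0L, end = 8L, strand = "+")
  aln <- data.frame(name = c("a", "b"), qlen = 8L, qstart = 0L, qend = 8L,
                    strand = "+", path = c(">1>2>4", ">1>3>4"),
                    path_len = 8L, path_start = 0L, path_end = 8L,
                    matches = 8L, block = 8L, mapq = 60L, score = 8L,
                    cigar = "8=")
  aln$path_nodes <- list(c(1L, 2L, 4L), c(1L, 3L, 4L))
  aln$path_orients <- list(c(0L, 0L, 0L), c(0L, 0L, 0L))
  ev <- evaluate_mapping(aln, truth, g)
  expect_true(all(ev$per_read$correct))
  # swap the two paths: each still shares 7 of 8 node-bases (>= 50%)
  aln2 <- aln
  aln2$path_nodes <- rev(aln2$path_nodes)
  ev2 <- evaluate_mapping(aln2, truth, g)
  expect_true(all(ev2$per_read$correct))
  # an alignment over only the wrong allele node shares 0 bases
  aln3 <- aln[1, , drop = FALSE]
  aln3$path_nodes <- list(3L)
  aln3$path_orients <- list(0L)
  aln3$path_start <- 0L; aln3$path_end <- 1L
  ev3 <- evaluate_mapping(aln3, truth[1, , drop = FALSE], g)
  expect_false(any(ev3$per_read$correct))
  # a read absent from the truth table is an error
  aln4 <- aln; aln4$name <- c("a", "zz")
  expect_error(evaluate_mapping(aln4, truth, g), "missing")
})
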