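g1_indexes <- local({
  ix <- NULL
  function() {
    if (is.null(ix)) ix <<- build_graph_indexes(
      g1(), minimizer_params(k = 3, w = 2))
    ix
  }
})

test_that("a haplotype read maps to its walk with no competing placement", {
  ix <- g1_indexes()
  res <- map_read("GATATACA", ix, "r1")
  expect_false(is.null(res$primary))
  expect_equal(res$primary$walk$node, c(1, 2, 4))
  expect_equal(res$primary$walk$orient, c(0, 0, 0))
  expect_equal(res$primary$score, 8)
  expect_gt(res$mapq, 0)
})

test_that("an all-N read is unmapped", {
  ix <- g1_indexes()
  res <- map_read(strrep("N", 30), ix, "rN")
  expect_null(res$primary)
  expect_equal(res$mapq, 0)
})

test_that("a read from an exact two-copy repeat gets ambiguous MAPQ", {
  # the same 40 bp cassette occurs at two loci of the backbone
  set.seed(1)
  seg <- pgmap:::random_dna(40)
  nodes <- data.frame(id = 1:5,
                      seq = c(pgmap:::random_dna(50), seg, pgmap:::random_dna(50), seg,
                              pgmap:::random_dna(50)))
  g <- variation_graph(nodes, walks = list(walk("H1", 1:5)))
  ix <- build_graph_indexes(g, minimizer_params(k = 9, w = 5))
  read <- seg  # fits entirely inside either cassette copy
  res <- map_read(read, ix, "amb")
  expect_false(is.null(res$primary))
  expect_lte(res$mapq, 3)
})

test_that("MAPQ follows the score-difference formula with a cap of 60", {
  expect_equal(compute_mapq(100, 100), 0L)
  expect_equal(compute_mapq(100, numeric(0)), 60L)
  expect_equal(compute_mapq(50, 45, match = 1), 30L)
  expect_equal(compute_mapq(10, 4), 36L)
})

test_that("GAF output matches the worked fixture and round-trips", {
  ix <- g1_indexes()
  reads <- c(r1 = "GATATACA")
  res <- map_reads(reads, ix)
  lines <- write_gaf(res, ix$graph, reads)
  expect_equal(length(lines), 1)
  f <- strsplit(lines, "\t")[[1]]
  expect_equal(f[1], "r1")
  expect_equal(as.integer(f[2]), 8)
  expect_equal(f[6], ">1>2>4")
  expect_equal(as.integer(f[7]), 8)   # path length
  expect_equal(as.integer(f[10]), 8)  # residue matches
  expect_equal(as.integer(f[11]), 8)  # block length
  expect_equal(as.integer(f[12]), res[[1]]$mapq)
  expect_true("AS:i:8" %in% f)
  expect_true("cs:Z::8" %in% f)

  back <- read_gaf(lines, ix$graph)
  expect_equal(back$path_nodes[[1]], c(1, 2, 4))
  expect_equal(back$path_orients[[1]], c(0, 0, 0))
  expect_equal(back$qstart, 0)
  expect_equal(back$qend, 8)
  expect_equal(back$score, 8)

  # unmapped reads yield no GAF line
  res2 <- map_reads(c(rN = strrep("N", 20)), ix)
  expect_equal(length(write_gaf(res2, ix$graph, c(rN = strrep("N", 20)))), 0)
})

test_that("mapping is deterministic: identical runs give identical GAF", {
  set.seed(4)
  g <- random_dag_fixture(31, backbone = 400, nh = 3)
  sim <- simulate_reads(g, read_sim_params(n_reads = 8, read_length = 120,
                                           mismatch_rate = 0.02, seed = 9))
  ix1 <- build_graph_indexes(g, minimizer_params(k = 9, w = 5))
  ix2 <- build_graph_indexes(g, minimizer_params(k = 9, w = 5))
  gaf1 <- write_gaf(map_reads(sim$reads, ix1), g, sim$reads)
  gaf2 <- write_gaf(map_reads(sim$reads, ix2), g, sim$reads)
  expect_identical(gaf1, gaf2)
})

test_that("mapped reads from simulated haplotypes evaluate as correct", {
  set.seed(6)
  g <- random_fixture(41, backbone = 600, nh = 4, snv = 0.01, ind = 0.002,
                      inv = 0, dup = 0)
  ix <- build_graph_indexes(g, minimizer_params(k = 11, w = 7))
  sim <- simulate_reads(g, read_sim_params(n_reads = 25, read_length = 150,
                                           seed = 3))
  res <- map_reads(sim$reads, ix)
  gaf <- write_gaf(res, g, sim$reads)
  ev <- evaluate_mapping(read_gaf(gaf, g), sim$truth, g)
  expect_gte(mean(ev$per_read$correct), 0.95)
  expect_lte(ev$n_unmapped, 1)
})
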