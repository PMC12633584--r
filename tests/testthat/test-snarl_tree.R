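test_that("separability matches the split-graph component oracle on the bubble fixture", {
  g <- g1()
  r <- is_separable(g, node_side(1, "R"), node_side(4, "L"))
  expect_true(r$separable)
  expect_equal(r$contents, c(2L, 3L))
  r2 <- is_separable(g, node_side(1, "R"), node_side(2, "L"))
  expect_true(r2$separable)
  expect_equal(r2$contents, integer(0))
  r3 <- is_separable(g, node_side(1, "L"), node_side(4, "L"))
  expect_false(r3$separable)
  # agreement with the igraph oracle on all side pairs
  for (a in 1:4) for (sa in 0:1) for (b in 1:4) for (sb in 0:1) {
    if (b <= a) next
    got <- is_separable(g, node_side(a, sa), node_side(b, sb))
    want <- oracle_separable(g, a, sa, b, sb)
    expect_equal(got$separable, want$separable)
    expect_equal(got$contents, want$contents)
  }
})

test_that("the bubble fixture decomposes into one snarl with two allele chains", {
  tree <- decompose_snarls(g1())
  expect_equal(length(tree$snarls), 1)
  s <- tree$snarls[[1]]
  expect_equal(s$start, c(1L, 1L))  # right side of node 1
  expect_equal(s$end, c(4L, 0L))    # left side of node 4
  expect_false(s$cyclic)
  root <- tree$chains[[tree$node_chain[1]]]
  expect_equal(root$nodes, c(1L, 4L))
  expect_equal(root$gaps, 1L)
  kid_nodes <- sort(vapply(s$child_chains, function(ci) tree$chains[[ci]]$nodes, 0L))
  expect_equal(kid_nodes, c(2L, 3L))
})

test_that("a single-node graph is one root chain with no snarls", {
  g <- variation_graph(data.frame(id = 1, seq = "ACGT"),
                       walks = list(walk("H1", 1)))
  tree <- decompose_snarls(g)
  expect_equal(length(tree$snarls), 0)
  expect_equal(length(tree$chains), 1)
  expect_equal(tree$chains[[1]]$nodes, 1L)
})

test_that("a plain backbone is a single chain with no snarl objects", {
  tree <- decompose_snarls(backbone_graph(5))
  expect_equal(length(tree$snarls), 0)
  expect_equal(length(tree$chains), 1)
  expect_equal(tree$chains[[1]]$nodes, 1:5)
  expect_true(all(is.na(tree$chains[[1]]$gaps)))
})

test_that("an insertion carrying a SNP nests snarl-chain-snarl", {
  tree <- decompose_snarls(nested_graph())
  expect_equal(length(tree$snarls), 2)
  anc <- snarl_ancestry(tree, 3)  # an inner SNP allele
  expect_equal(length(anc), 5)
  expect_equal(vapply(anc, `[[`, "", "kind"),
               c("chain", "snarl", "chain", "snarl", "chain"))
  expect_equal(tree$chains[[anc[[5]]$id]]$parent_snarl, 0L)
})

test_that("ancestry is innermost-first and ends at a root chain", {
  tree <- decompose_snarls(g1())
  anc2 <- snarl_ancestry(tree, 2)
  expect_equal(length(anc2), 3)
  expect_equal(tree$chains[[anc2[[1]]$id]]$nodes, 2L)
  expect_equal(anc2[[2]]$kind, "snarl")
  anc1 <- snarl_ancestry(tree, 1)
  expect_equal(length(anc1), 1)
  expect_error(snarl_ancestry(tree, 99), "unknown node")
})

test_that("inversion and duplication bubbles decompose with correct cyclic flags", {
  ti <- decompose_snarls(inversion_graph())
  expect_equal(length(ti$snarls), 1)
  expect_equal(ti$snarls[[1]]$contents, 2L)
  expect_false(ti$snarls[[1]]$cyclic)
  td <- decompose_snarls(duplication_graph())
  expect_equal(length(td$snarls), 1)
  expect_equal(td$snarls[[1]]$contents, 2L)
  expect_true(td$snarls[[1]]$cyclic)
})

test_that("decomposition equals the exhaustive oracle on random pangenomes", {
  for (seed in 1:25) {
    g <- random_fixture(seed, backbone = sample(c(80, 150, 250), 1),
                        nh = sample(2:6, 1))
    expect_equal(pgmap:::canonical_tree(decompose_snarls(g)),
                 oracle_decompose(g), info = sprintf("seed %d", seed))
  }
})

test_that("every node occurs in exactly one chain and consecutive snarls share boundary nodes", {
  for (seed in 1:15) {
    g <- random_fixture(seed + 100, backbone = 300)
    tree <- decompose_snarls(g)
    all_nodes <- unlist(lapply(tree$chains, `[[`, "nodes"))
    expect_equal(sort(all_nodes), sort(g$nodes$id))
    expect_false(anyDuplicated(all_nodes) > 0)
    for (ch in tree$chains) {
      gs <- ch$gaps
      for (i in seq_along(gs)) {
        if (is.na(gs[i])) next
        s <- tree$snarls[[gs[i]]]
        expect_equal(s$start[1], ch$nodes[i])
        expect_equal(s$end[1], ch$nodes[i + 1])
        if (i < length(gs) && !is.na(gs[i + 1])) {
          s2 <- tree$snarls[[gs[i + 1]]]
          # shared node approached from opposite sides
          expect_equal(s$end[1], s2$start[1])
          expect_equal(s$end[2], 1L - s2$start[2])
        }
      }
    }
  }
})

test_that("decomposition refuses isolated walk-free components", {
  g <- g1()
  g$nodes <- rbind(g$nodes, data.frame(id = 9L, seq = "TTTT", name = "9"))
  expect_error(decompose_snarls(g), "no walk")
})
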