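# Shared fixtures built in code.

# The running 4-node example: one substitution bubble between nodes 1 and 4.
g1_gfa <- function() {
  c("H\tVN:Z:1.1",
    "S\t1\tGAT", "S\t2\tA", "S\t3\tC", "S\t4\tTACA",
    "L\t1\t+\t2\t+\t0M", "L\t1\t+\t3\t+\t0M",
    "L\t2\t+\t4\t+\t0M", "L\t3\t+\t4\t+\t0M",
    "P\tH1\t1+,2+,4+\t*", "P\tH2\t1+,3+,4+\t*")
}

g1 <- function() parse_gfa(g1_gfa())

# An insertion bubble whose inserted allele contains a SNP bubble:
# 1 -(optionally: 2, 3|4, 5)- 6, i.e. nested snarl-in-chain-in-snarl.
nested_graph <- function() {
  variation_graph(
    nodes = data.frame(id = 1:6,
                       seq = c("GGA", "TT", "A", "C", "GT", "ACC")),
    walks = list(
      walk("H1", c(1, 2, 3, 5, 6)),
      walk("H2", c(1, 2, 4, 5, 6)),
      walk("H3", c(1, 6))))
}

# A linear backbone with no variation: one chain, no snarls.
backbone_graph <- function(n = 4) {
  variation_graph(
    nodes = data.frame(id = seq_len(n), seq = rep("ACGT", n)),
    walks = list(walk("H1", seq_len(n))))
}

# Inversion bubble: node 2 traversed forward by H1, reversed by H2.
inversion_graph <- function() {
  variation_graph(
    nodes = data.frame(id = 1:3, seq = c("GATT", "ACA", "TTCA")),
    walks = list(walk("H1", 1:3),
                 walk("H2", 1:3, c("+", "-", "+"))))
}

# Tandem duplication: node 2 visited twice by H2 (back edge 2R-2L).
duplication_graph <- function() {
  variation_graph(
    nodes = data.frame(id = 1:3, seq = c("GATT", "ACA", "TTCA")),
    walks = list(walk("H1", 1:3),
                 walk("H2", c(1, 2, 2, 3))))
}

random_fixture <- function(seed, backbone = 300L, nh = 4L,
                           snv = 0.02, ind = 0.004, inv = 0.001, dup = 0.001) {
  simulate_graph(graph_sim_params(
    backbone_length = backbone, n_haplotypes = nh, snv_bubble_rate = snv,
    indel_bubble_rate = ind, inversion_rate = inv,
    tandem_duplication_rate = dup, seed = seed))
}

# DAG-shaped fixture (no inversions/duplications) for exactness properties.
random_dag_fixture <- function(seed, backbone = 300L, nh = 4L) {
  random_fixture(seed, backbone, nh, snv = 0.02, ind = 0.005, inv = 0, dup = 0)
}
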