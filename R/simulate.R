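#' Parameters for synthetic pangenome simulation
#'
#' The simulator lays variant sites along a random DNA backbone and realizes
#' them as bubbles over a configurable number of haplotype walks: SNV
#' substitution bubbles, insertion bubbles (1-50 bp, with a deletion edge
#' for the non-carrying haplotypes), inversion bubbles (a segment some
#' haplotypes traverse reverse-complemented) and tandem duplications (a
#' back edge creating a cycle, traversed twice by carrier haplotypes).
#' Rates are per backbone base; a fixed seed makes the output byte-identical
#' across runs.
#'
#' @param backbone_length backbone length in bp.
#' @param n_haplotypes number of haplotype walks (2-32 is typical).
#' @param snv_bubble_rate,indel_bubble_rate,inversion_rate,tandem_duplication_rate
#'   per-base probabilities of starting each bubble type.
#' @param seed RNG seed fixing all randomness.
#' @return a `graph_sim_params` list.
#' @export
graph_sim_params <- function(backbone_length = 5000L, n_haplotypes = 8L,
                             snv_bubble_rate = 0.005, indel_bubble_rate = 0.001,
                             inversion_rate = 0.0002,
                             tandem_duplication_rate = 0.0002, seed = 1L) {
  rates <- c(snv_bubble_rate, indel_bubble_rate, inversion_rate,
             tandem_duplication_rate)
  stopifnot(backbone_length >= 1, n_haplotypes >= 1,
            all(rates >= 0), all(rates <= 1))
  structure(list(backbone_length = as.integer(backbone_length),
                 n_haplotypes = as.integer(n_haplotypes),
                 snv_bubble_rate = snv_bubble_rate,
                 indel_bubble_rate = indel_bubble_rate,
                 inversion_rate = inversion_rate,
                 tandem_duplication_rate = tandem_duplication_rate,
                 seed = as.integer(seed)),
            class = "graph_sim_params")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

#' Simulate a pangenome variation graph
#'
#' @param params a [graph_sim_params()].
#' @return a [variation_graph()] whose haplotype walks realize the requested
#'   bubbles. Alleles carried by no haplotype are dropped, so every node is
#'   touched by at least one walk and the edge set equals the walk-supported
#'   adjacencies.
#' @export
simulate_graph <- function(params) {
  stopifnot(inherits(params, "graph_sim_params"))
  with_seed(params$seed, simulate_graph_impl(params))
}

simulate_graph_impl <- function(params) {
  L <- params$backbone_length
  nh <- params$n_haplotypes
  backbone <- strsplit(random_dna(L), "")[[1]]

  # lay out sites: sample candidate starts per type, then enforce spacing
  types <- c("snv", "ins", "inv", "dup")
  rates <- c(params$snv_bubble_rate, params$indel_bubble_rate,
             params$inversion_rate, params$tandem_duplication_rate)
  cand <- data.frame(pos = integer(), type = character())
  for (t in seq_along(types)) {
    k <- rbinom(1, L, rates[t])
    if (k > 0 && L > 4)
      cand <- rbind(cand, data.frame(pos = sample(2:(L - 3), min(k, L - 4)),
                                     type = types[t]))
  }
  cand <- cand[order(cand$pos, cand$type), , drop = FALSE]
  sites <- list()
  prev_end <- 0L
  for (i in seq_len(nrow(cand))) {
    p <- cand$pos[i]; ty <- cand$type[i]
    span <- switch(ty, snv = 1L, ins = 0L,
                   inv = sample(3:20, 1), dup = sample(3:20, 1))
    if (p < prev_end + 2L) next            # keep >=1 backbone base between sites
    if (p + span > L) next                 # keep a final backbone segment
    sites <- c(sites, list(list(pos = p, type = ty, span = span)))
    prev_end <- p + span - 1L
    if (ty == "ins") prev_end <- p - 1L
  }

  # allele per haplotype per site (1 = alt); keep sites polymorphic when
  # possible but tolerate fixed alleles
  nodes <- data.frame(id = integer(), seq = character())
  new_node <- function(seq) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, seq)
    id
  }
  hap_steps <- replicate(nh, list(node = integer(), orient = integer()),
                         simplify = FALSE)
  add_step <- function(h, node, orient = 0L) {
    hap_steps[[h]]$node <<- c(hap_steps[[h]]$node, node)
    hap_steps[[h]]$orient <<- c(hap_steps[[h]]$orient, orient)
  }
  add_all <- function(node, orient = 0L) for (h in seq_len(nh)) add_step(h, node, orient)

  pos <- 1L
  for (s in sites) {
    if (s$pos > pos) {  # shared backbone segment before the site
      seg <- new_node(paste(backbone[pos:(s$pos - 1L)], collapse = ""))
      add_all(seg)
    }
    alt <- rbinom(nh, 1, runif(1, 0.2, 0.8))
    switch(s$type,
      snv = {
        refb <- backbone[s$pos]
        altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
        ref_id <- if (any(alt == 0)) new_node(refb) else NA_integer_
        alt_id <- if (any(alt == 1)) new_node(altb) else NA_integer_
        for (h in seq_len(nh))
          add_step(h, if (alt[h] == 1) alt_id else ref_id)
      },
      ins = {
        if (any(alt == 1)) {
          ins_id <- new_node(random_dna(sample(1:50, 1)))
          for (h in seq_len(nh)) if (alt[h] == 1) add_step(h, ins_id)
        }
      },
      inv = {
        seg_id <- new_node(paste(backbone[s$pos:(s$pos + s$span - 1L)],
                                 collapse = ""))
        for (h in seq_len(nh)) add_step(h, seg_id, if (alt[h] == 1) 1L else 0L)
      },
      dup = {
        seg_id <- new_node(paste(backbone[s$pos:(s$pos + s$span - 1L)],
                                 collapse = ""))
        for (h in seq_len(nh)) {
          add_step(h, seg_id)
          if (alt[h] == 1) add_step(h, seg_id)
        }
      })
    pos <- s$pos + s$span
  }
  if (pos <= L) add_all(new_node(paste(backbone[pos:L], collapse = "")))
  if (nrow(nodes) == 0L) { add_all(new_node(paste(backbone, collapse = ""))) }

  walks <- lapply(seq_len(nh), function(h)
    walk(sprintf("H%d", h), hap_steps[[h]]$node,
         ifelse(hap_steps[[h]]$orient == 1L, "-", "+"),
         role = if (h == 1L) "reference" else "haplotype"))
  variation_graph(nodes, walks)
}

#' Parameters for read simulation
#'
#' Reads are drawn uniformly over haplotype walk positions on both strands;
#' errors are applied base-by-base as independent substitutions, insertions
#' and deletions.
#'
#' @param n_reads number of reads.
#' @param read_length read length in bp, or a length-2 range sampled
#'   uniformly.
#' @param mismatch_rate,insertion_rate,deletion_rate per-base error
#'   probabilities, each in `[0, 0.3]`.
#' @param seed RNG seed.
#' @return a `read_sim_params` list.
#' @export
read_sim_params <- function(n_reads = 100L, read_length = 1000L,
                            mismatch_rate = 0, insertion_rate = 0,
                            deletion_rate = 0, seed = 1L) {
  rates <- c(mismatch_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates > 0.3))
    stop("error rates must lie in [0, 0.3]")
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 mismatch_rate = mismatch_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate reads from a graph's haplotype walks
#'
#' @param graph a [variation_graph()] with at least one walk.
#' @param params a [read_sim_params()].
#' @return list with `reads` (named character vector of read sequences),
#'   and `truth` (data.frame: `name`, `hap`, `start`, `end` half-open
#'   interval on the forward walk spelling, `strand`).
#' @export
simulate_reads <- function(graph, params) {
  stopifnot(inherits(params, "read_sim_params"), length(graph$walks) >= 1)
  with_seed(params$seed, simulate_reads_impl(graph, params))
}

simulate_reads_impl <- function(graph, params) {
  spells <- vapply(seq_along(graph$walks), function(i) spell_walk(graph, i), "")
  wlens <- nchar(spells)
  rl_range <- rep_len(params$read_length, 2)
  reads <- character(params$n_reads)
  truth <- data.frame(name = character(params$n_reads), hap = character(params$n_reads),
                      start = integer(params$n_reads), end = integer(params$n_reads),
                      strand = character(params$n_reads))
  for (i in seq_len(params$n_reads)) {
    repeat {
      rl <- if (rl_range[1] == rl_range[2]) rl_range[1]
            else sample(rl_range[1]:rl_range[2], 1)
      w <- sample(seq_along(graph$walks), 1)
      if (rl <= wlens[w]) break
    }
    start <- sample(0:(wlens[w] - rl), 1)          # 0-based
    strand <- sample(c("+", "-"), 1)
    seq0 <- substring(spells[w], start + 1L, start + rl)
    if (strand == "-") seq0 <- reverse_complement(seq0)
    reads[i] <- apply_errors(seq0, params)
    nm <- sprintf("read%05d", i)
    truth[i, ] <- list(nm, graph$walks[[w]]$name, start, start + rl, strand)
  }
  names(reads) <- truth$name
  list(reads = reads, truth = truth)
}

apply_errors <- function(seq, params) {
  if (params$mismatch_rate == 0 && params$insertion_rate == 0 &&
      params$deletion_rate == 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  out <- character(0)
  abc <- c("A", "C", "G", "T")
  u <- runif(length(bases)); v <- runif(length(bases)); z <- runif(length(bases))
  for (j in seq_along(bases)) {
    b <- bases[j]
    if (u[j] < params$deletion_rate) next
    if (v[j] < params$mismatch_rate) b <- sample(setdiff(abc, b), 1)
    out <- c(out, b)
    if (z[j] < params$insertion_rate) out <- c(out, sample(abc, 1))
  }
  if (!length(out)) return(substring(seq, 1, 1))
  paste(out, collapse = "")
}

#' Write reads as FASTQ
#'
#' @param reads named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
  writeLines(as.vector(rbind(paste0("@", names(reads)), unname(reads),
                             "+", qual)), path)
  invisible(path)
}

#' Evaluate mapping accuracy against simulation truth
#'
#' A read is judged correct if its reported walk shares at least half of its
#' node-bases with the truth walk slice (the node bases covered by the
#' source interval of the read). Results are stratified by MAPQ with
#' cumulative precision from high to low MAPQ, the usual ROC-style view of
#' simulated-read accuracy.
#'
#' @param alignments a data.frame of GAF records from [read_gaf()] (or a GAF
#'   file path).
#' @param truth truth table from [simulate_reads()].
#' @param graph the [variation_graph()] mapped against.
#' @return list with `per_read` (name, mapq, correct) and `by_mapq`
#'   (mapq bin; reads; correct; incorrect; unmapped; cumulative precision).
#' @export
evaluate_mapping <- function(alignments, truth, graph) {
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- read_gaf(alignments)
  aln <- alignments[!duplicated(alignments$name), , drop = FALSE]  # primary only
  if (!all(aln$name %in% truth$name)) stop("alignment for read missing from truth")
  walk_names <- vapply(graph$walks, `[[`, "", "name")

  correct <- logical(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    t <- truth[match(aln$name[i], truth$name), ]
    w <- graph$walks[[match(t$hap, walk_names)]]
    tr_iv <- walk_slice_intervals(graph, w, t$start, t$end)
    rp_iv <- path_intervals(graph, aln$path_nodes[[i]], aln$path_orients[[i]],
                            aln$path_start[i], aln$path_end[i])
    shared <- interval_overlap(tr_iv, rp_iv)
    correct[i] <- nrow(rp_iv) > 0 && shared >= 0.5 * sum(rp_iv$hi - rp_iv$lo)
  }
  per_read <- data.frame(name = aln$name, mapq = aln$mapq, correct = correct)
  unmapped <- setdiff(truth$name, aln$name)

  bins <- sort(unique(per_read$mapq), decreasing = TRUE)
  by_mapq <- do.call(rbind, lapply(bins, function(q) {
    at <- per_read$mapq == q
    data.frame(mapq = q, reads = sum(at), correct = sum(per_read$correct[at]),
               incorrect = sum(!per_read$correct[at]))
  }))
  if (is.null(by_mapq)) by_mapq <- data.frame(mapq = integer(), reads = integer(),
                                              correct = integer(), incorrect = integer())
  by_mapq$cum_precision <- cumsum(by_mapq$correct) / pmax(1, cumsum(by_mapq$reads))
  by_mapq$unmapped <- length(unmapped)
  list(per_read = per_read, by_mapq = by_mapq, n_unmapped = length(unmapped))
}

# forward-strand per-node base intervals covered by walk spelling interval
# [start, end) (0-based walk coordinates)
walk_slice_intervals <- function(graph, w, start, end) {
  lens <- nchar(graph$nodes$seq)[match(w$steps$node, graph$nodes$id)]
  offs <- cumsum(c(0, lens))
  out <- data.frame(node = integer(), lo = integer(), hi = integer())
  for (i in seq_along(lens)) {
    a <- max(start, offs[i]); b <- min(end, offs[i + 1])
    if (a >= b) next
    lo <- a - offs[i]; hi <- b - offs[i]
    if (w$steps$orient[i] == 1L) { tmp <- lo; lo <- lens[i] - hi; hi <- lens[i] - tmp }
    out <- rbind(out, data.frame(node = w$steps$node[i], lo = lo, hi = hi))
  }
  out
}

path_intervals <- function(graph, nodes, orients, pstart, pend) {
  lens <- nchar(graph$nodes$seq)[match(nodes, graph$nodes$id)]
  offs <- cumsum(c(0, lens))
  out <- data.frame(node = integer(), lo = integer(), hi = integer())
  for (i in seq_along(lens)) {
    a <- max(pstart, offs[i]); b <- min(pend, offs[i + 1])
    if (a >= b) next
    lo <- a - offs[i]; hi <- b - offs[i]
    if (orients[i] == 1L) { tmp <- lo; lo <- lens[i] - hi; hi <- lens[i] - tmp }
    out <- rbind(out, data.frame(node = nodes[i], lo = lo, hi = hi))
  }
  out
}

interval_overlap <- function(a, b) {
  tot <- 0L
  for (i in seq_len(nrow(a))) {
    j <- which(b$node == a$node[i])
    for (k in j) tot <- tot + max(0L, min(a$hi[i], b$hi[k]) - max(a$lo[i], b$lo[k]))
  }
  tot
}
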