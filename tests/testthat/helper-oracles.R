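# Independent oracles used by the test suite. These deliberately avoid the
# package's C++ code paths: components come from igraph on explicitly built
# side-adjacency graphs, and the tree is assembled by a separate
# implementation that is compared structurally with the package's.

side_v <- function(node, side) 2L * (node - 1L) + side + 1L  # 1-based vertex

# igraph over node sides with internal edges for all nodes except `cuts`
oracle_side_graph <- function(graph, cuts = integer(0)) {
  n <- max(graph$nodes$id)
  e <- graph$edges
  from <- side_v(e$from, e$from_side)
  to <- side_v(e$to, e$to_side)
  keep <- setdiff(graph$nodes$id, cuts)
  from <- c(from, side_v(keep, 0L))
  to <- c(to, side_v(keep, 1L))
  igraph::graph_from_edgelist(cbind(from, to), directed = FALSE) +
    igraph::vertices(setdiff(seq_len(2L * n), c(from, to)))
}

oracle_separable <- function(graph, a_node, a_side, b_node, b_side) {
  g <- oracle_side_graph(graph, cuts = c(a_node, b_node))
  comp <- igraph::components(g)$membership
  u <- side_v(a_node, a_side); v <- side_v(b_node, b_side)
  if (comp[u] != comp[v]) return(list(separable = FALSE, contents = integer(0)))
  inner <- comp == comp[u]
  outer <- comp == comp[side_v(a_node, 1L - a_side)] |
           comp == comp[side_v(b_node, 1L - b_side)]
  ids <- setdiff(graph$nodes$id, c(a_node, b_node))
  contents <- ids[vapply(ids, function(nd) {
    (inner[side_v(nd, 0L)] || inner[side_v(nd, 1L)]) &&
      !(outer[side_v(nd, 0L)] || outer[side_v(nd, 1L)])
  }, TRUE)]
  list(separable = TRUE, contents = sort(contents))
}

oracle_cyclic <- function(graph, contents) {
  if (!length(contents)) return(FALSE)
  n <- max(graph$nodes$id)
  e <- graph$edges
  keep <- e$from %in% contents & e$to %in% contents
  if (!any(keep)) return(FALSE)
  e <- e[keep, , drop = FALSE]
  # directed: leaving face f, crossing to face h, passing through to h^1
  from <- c(side_v(e$from, e$from_side), side_v(e$to, e$to_side))
  h <- c(side_v(e$to, e$to_side), side_v(e$from, e$from_side))
  to <- ifelse(h %% 2L == 0L, h - 1L, h + 1L)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  !igraph::is_dag(g)
}

# exhaustive enumeration of separable side pairs with contents; a pair can
# only be separable if each face reaches the other in the graph with just
# its own node split, so single-deletion components prune the candidates
# before the full per-pair test
oracle_separable_pairs <- function(graph) {
  ids <- graph$nodes$id
  n <- max(ids)
  full <- oracle_side_graph(graph)   # all internal edges present
  reach <- vector("list", 2L * n)
  for (a in ids) {
    gcut <- oracle_side_graph(graph, cuts = a)
    comp <- igraph::components(gcut)$membership
    for (sa in 0:1) {
      u <- side_v(a, sa)
      reach[[u]] <- which(comp == comp[u])
    }
  }
  out <- list()
  for (a in ids) for (sa in 0:1) for (b in ids) for (sb in 0:1) {
    if (b <= a) next
    u <- side_v(a, sa); v <- side_v(b, sb)
    if (!(v %in% reach[[u]]) || !(u %in% reach[[v]])) next
    r <- oracle_separable(graph, a, sa, b, sb)
    if (r$separable)
      out[[paste(u, v, sep = "_")]] <-
        list(u = c(a, sa), v = c(b, sb), contents = r$contents)
  }
  out
}

oracle_scope <- function(p) {
  c(side_v(p$u[1], p$u[2]), side_v(p$v[1], p$v[2]),
    unlist(lapply(p$contents, function(nd) c(side_v(nd, 0L), side_v(nd, 1L)))))
}

# keep separable-minimal nontrivial pairs: a pair is dropped if a single
# through-node splits it exactly (node partition and interior-edge cover)
oracle_minimal_snarls <- function(graph, pairs = oracle_separable_pairs(graph)) {
  e <- graph$edges
  ex <- side_v(e$from, e$from_side); ey <- side_v(e$to, e$to_side)
  keep <- list()
  for (p in pairs) {
    if (!length(p$contents)) next
    removable <- FALSE
    for (cn in p$contents) {
      for (cs in 0:1) {
        for (ends in list(c(1, 2), c(2, 1))) {
          a <- if (ends[1] == 1) p$u else p$v
          b <- if (ends[1] == 1) p$v else p$u
          ku <- sort(c(side_v(a[1], a[2]), side_v(cn, cs)))
          kv <- sort(c(side_v(cn, 1L - cs), side_v(b[1], b[2])))
          q <- pairs[[paste(ku[1], ku[2], sep = "_")]]
          r <- pairs[[paste(kv[1], kv[2], sep = "_")]]
          if (is.null(q) || is.null(r)) next
          parts <- c(q$contents, cn, r$contents)
          if (length(parts) != length(p$contents)) next
          if (!setequal(parts, p$contents) || anyDuplicated(parts)) next
          sp <- oracle_scope(p); sq <- oracle_scope(q); sr <- oracle_scope(r)
          interior <- ex %in% sp & ey %in% sp
          covered <- (ex %in% sq & ey %in% sq) | (ex %in% sr & ey %in% sr)
          if (all(covered[interior])) { removable <- TRUE; break }
        }
        if (removable) break
      }
      if (removable) break
    }
    if (!removable) keep[[length(keep) + 1L]] <- p
  }
  # canonical selection: the decomposition is not unique, so order pairs by
  # (min boundary, max boundary, contents size) and accept each only if it
  # is disjoint from or properly nested with everything already accepted
  if (length(keep) > 1) {
    pref <- order(vapply(keep, function(p) min(p$u[1], p$v[1]), 0),
                  vapply(keep, function(p) max(p$u[1], p$v[1]), 0),
                  vapply(keep, function(p) length(p$contents), 0L))
    acc <- list()
    for (i in pref) {
      p <- keep[[i]]
      pb <- c(p$u[1], p$v[1])
      compatible <- TRUE
      for (q in acc) {
        qb <- c(q$u[1], q$v[1])
        disj <- !length(intersect(p$contents, q$contents)) &&
          !length(intersect(pb, q$contents)) && !length(intersect(qb, p$contents))
        pin <- all(c(p$contents, pb) %in% q$contents)
        qin <- all(c(q$contents, qb) %in% p$contents)
        if (!(disj || pin || qin)) { compatible <- FALSE; break }
      }
      if (compatible) acc <- c(acc, list(p))
    }
    keep <- acc
  }
  keep
}

# independent nested-chain assembly, producing the same canonical nested
# structure as pgmap:::canonical_tree
oracle_decompose <- function(graph) {
  snarls <- oracle_minimal_snarls(graph)
  ids <- graph$nodes$id
  size <- vapply(snarls, function(p) length(p$contents), 0L)
  ord <- order(size)
  parent <- rep(0L, length(snarls))
  for (i in seq_along(snarls)) {
    need <- c(snarls[[i]]$contents, snarls[[i]]$u[1], snarls[[i]]$v[1])
    for (j in ord) {
      if (j == i || size[j] <= size[i]) next
      if (all(need %in% snarls[[j]]$contents)) { parent[i] <- j; break }
    }
  }
  region <- rep(0L, max(ids))
  for (j in ord) for (nd in snarls[[j]]$contents)
    if (region[nd] == 0L) region[nd] <- j

  e <- graph$edges
  comp <- igraph::components(igraph::graph_from_edgelist(
    cbind(e$from, e$to), directed = FALSE) +
      igraph::vertices(setdiff(ids, c(e$from, e$to))))$membership

  build_region <- function(region_id, members) {
    kids <- which(parent == region_id &
                    vapply(snarls, function(p) p$u[1] %in% members, TRUE))
    # links between region members
    link <- list()
    slot_key <- function(nd, s) paste(nd, s)
    slots <- new.env()
    add <- function(nd1, s1, nd2, s2, what) {
      link[[length(link) + 1L]] <<- list(a = c(nd1, s1), b = c(nd2, s2), what = what)
      assign(slot_key(nd1, s1), length(link), envir = slots)
      assign(slot_key(nd2, s2), length(link), envir = slots)
    }
    skey <- character(0)
    for (j in kids) {
      p <- snarls[[j]]
      add(p$u[1], p$u[2], p$v[1], p$v[2], j)
      skey <- c(skey, paste(side_v(p$u[1], p$u[2]), side_v(p$v[1], p$v[2])))
    }
    for (i in seq_len(nrow(e))) {
      nd1 <- e$from[i]; s1 <- e$from_side[i]; nd2 <- e$to[i]; s2 <- e$to_side[i]
      if (nd1 == nd2) next
      if (!(nd1 %in% members) || !(nd2 %in% members)) next
      if (region[nd1] != region_id || region[nd2] != region_id) next
      if (paste(side_v(nd1, s1), side_v(nd2, s2)) %in% skey) next
      add(nd1, s1, nd2, s2, NA_integer_)
    }
    # assemble chains
    done <- c()
    chains <- list()
    for (start in sort(members)) {
      if (start %in% done) next
      follow <- function(nd, s, seen) {
        seqn <- integer(0); gaps <- list()
        repeat {
          li <- mget(slot_key(nd, s), envir = slots, ifnotfound = NA)[[1]]
          if (is.na(li)) break
          l <- link[[li]]
          if (l$a[1] == nd && l$a[2] == s) { nx <- l$b } else { nx <- l$a }
          if (nx[1] %in% seen) break
          seqn <- c(seqn, nx[1]); gaps <- c(gaps, list(l$what))
          seen <- c(seen, nx[1]); nd <- nx[1]; s <- 1L - nx[2]
        }
        list(seqn = seqn, gaps = gaps)
      }
      rgt <- follow(start, 1L, start)
      lft <- follow(start, 0L, c(start, rgt$seqn))
      nodes_seq <- c(rev(lft$seqn), start, rgt$seqn)
      gaps <- c(rev(lft$gaps), rgt$gaps)
      if (length(nodes_seq) > 1) {
        a <- nodes_seq; b <- rev(nodes_seq)
        if (!isTRUE(all(a == b))) {
          cmp <- which(a != b)[1]
          if (a[cmp] > b[cmp]) { nodes_seq <- b; gaps <- rev(gaps) }
        }
      }
      done <- c(done, nodes_seq)
      items <- list()
      for (i in seq_along(nodes_seq)) {
        items <- c(items, list(nodes_seq[i]))
        if (i < length(nodes_seq)) {
          gp <- gaps[[i]]
          if (!is.na(gp)) {
            p <- snarls[[gp]]
            # orient by chain direction
            if (p$u[1] == nodes_seq[i]) { st <- p$u; en <- p$v } else { st <- p$v; en <- p$u }
            sub_members <- p$contents[region[p$contents] == gp]
            kids_chains <- build_region(gp, sub_members)
            items <- c(items, list(list(start = unname(st), end = unname(en),
                                        cyclic = oracle_cyclic(graph, p$contents),
                                        children = kids_chains)))
          }
        }
      }
      chains <- c(chains, list(items))
    }
    chains[order(vapply(chains, function(ch) min(unlist(lapply(ch, function(x)
      if (is.numeric(x) && length(x) == 1) x else Inf))), 0))]
  }

  roots <- list()
  for (cc in sort(unique(comp[ids]))) {
    members <- ids[comp[ids] == cc & region[ids] == 0L]
    roots <- c(roots, build_region(0L, members))
  }
  roots[order(vapply(roots, function(ch)
    min(unlist(lapply(ch, function(x)
      if (is.numeric(x) && length(x) == 1) x else Inf))), 0))]
}

# Base-level BFS distance oracle: every base of every node in each
# orientation is a vertex of a digraph; distances are unweighted BFS.
oracle_base_graph <- function(graph) {
  ids <- graph$nodes$id
  lens <- setNames(nchar(graph$nodes$seq), ids)
  off <- setNames(cumsum(c(0, lens[-length(lens)])), ids)
  B <- sum(lens)
  vid <- function(node, orient, o) {  # 1-based igraph vertex
    off[as.character(node)] + o + 1L + orient * B
  }
  from <- integer(0); to <- integer(0)
  for (nd in ids) {
    l <- lens[as.character(nd)]
    if (l > 1) {
      from <- c(from, vid(nd, 0, 0:(l - 2)), vid(nd, 1, 0:(l - 2)))
      to <- c(to, vid(nd, 0, 1:(l - 1)), vid(nd, 1, 1:(l - 1)))
    }
  }
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    for (swap in c(FALSE, TRUE)) {
      an <- if (swap) e$to[i] else e$from[i]
      as_ <- if (swap) e$to_side[i] else e$from_side[i]
      bn <- if (swap) e$from[i] else e$to[i]
      bs <- if (swap) e$from_side[i] else e$to_side[i]
      # leaving an via face as_: last base of fwd (if as_==1) or rev (as_==0)
      src <- vid(an, if (as_ == 1L) 0L else 1L, lens[as.character(an)] - 1L)
      dst <- vid(bn, if (bs == 0L) 0L else 1L, 0L)
      from <- c(from, src); to <- c(to, dst)
    }
  }
  g <- igraph::graph_from_edgelist(unique(cbind(from, to)), directed = TRUE)
  n_v <- 2L * B
  if (igraph::vcount(g) < n_v) g <- g + igraph::vertices(seq_len(n_v - igraph::vcount(g)) + igraph::vcount(g))
  list(g = g, vid = vid)
}

# pairs: list of list(a = c(node, orient, offset), b = ...)
oracle_min_distance <- function(graph, a_mat, b_mat) {
  bg <- oracle_base_graph(graph)
  av <- mapply(function(n, o, f) bg$vid(n, o, f), a_mat[, 1], a_mat[, 2], a_mat[, 3])
  bv <- mapply(function(n, o, f) bg$vid(n, o, f), b_mat[, 1], b_mat[, 2], b_mat[, 3])
  us <- unique(av)
  D <- igraph::distances(bg$g, v = us, mode = "out")
  D[cbind(match(av, us), bv)]
}

random_positions <- function(graph, k) {
  lens <- nchar(graph$nodes$seq)
  nd <- sample(graph$nodes$id, k, replace = TRUE)
  o <- sample(0:1, k, replace = TRUE)
  f <- vapply(nd, function(x) sample(0:(lens[match(x, graph$nodes$id)] - 1L), 1), 0L)
  cbind(nd, o, f)
}

# --- naive minimizer scan oracle -------------------------------------------
# Independent 64-bit arithmetic on 16-bit limbs (exact in doubles) so the
# splitmix64 order can be reproduced without the package's C++ code.

u64 <- function(lo = 0, l1 = 0, l2 = 0, hi = 0) c(lo, l1, l2, hi)

u64_norm <- function(x) {
  for (i in 1:3) { c0 <- x[i] %/% 65536; x[i] <- x[i] %% 65536; x[i + 1] <- x[i + 1] + c0 }
  x[4] <- x[4] %% 65536
  x
}

u64_add <- function(a, b) u64_norm(a + b)

u64_mul <- function(a, b) {
  r <- numeric(4)
  for (i in 1:4) for (j in 1:4) {
    if (i + j - 1 > 4) next
    r[i + j - 1] <- r[i + j - 1] + a[i] * b[j]
    r <- u64_norm(r)
  }
  u64_norm(r)
}

u64_xor <- function(a, b) {
  vapply(1:4, function(i) bitwXor(as.integer(a[i]), as.integer(b[i])), 0) * 1
}

u64_shr <- function(a, n) {
  # shift right by n bits (n < 64)
  bits <- as.vector(vapply(1:4, function(i)
    as.integer(intToBits(as.integer(a[i]))[1:16] == 1), integer(16)))
  out <- c(bits[-(1:n)], rep(0L, n))
  vapply(1:4, function(i) sum(out[(16 * (i - 1) + 1):(16 * i)] * 2^(0:15)), 0)
}

u64_hex <- function(s) {  # from hex string
  v <- strtoi(c(substr(s, 13, 16), substr(s, 9, 12), substr(s, 5, 8),
                substr(s, 1, 4)), 16L)
  as.numeric(v)
}

splitmix64_r <- function(x) {
  x <- u64_add(x, u64_hex("9E3779B97F4A7C15"))
  x <- u64_mul(u64_xor(x, u64_shr(x, 30)), u64_hex("BF58476D1CE4E5B9"))
  x <- u64_mul(u64_xor(x, u64_shr(x, 27)), u64_hex("94D049BB133111EB"))
  u64_xor(x, u64_shr(x, 31))
}

u64_lt <- function(a, b) {
  for (i in 4:1) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

kmer_u64 <- function(kmer) {
  code <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T")) - 1
  x <- u64(0, 0, 0, 0)
  for (c0 in code) x <- u64_norm(u64_mul(x, u64(4)) + u64(c0))
  x
}

# naive per-window scan over one sequence; returns 0-based selected offsets
oracle_minimizer_scan <- function(seq, k, w, frequent = character(0)) {
  n <- nchar(seq)
  m <- n - k + 1
  if (m < 1) return(integer(0))
  kmers <- substring(seq, 1:m, k:n)
  valid <- !grepl("N", kmers, fixed = TRUE)
  canon <- kmers
  rc <- reverse_complement(kmers)
  flip <- rc < kmers
  canon[flip] <- rc[flip]
  keys <- vector("list", m)
  for (i in seq_len(m)) {
    if (!valid[i]) next
    keys[[i]] <- list(freq = as.numeric(canon[i] %in% frequent),
                      h = splitmix64_r(kmer_u64(canon[i])))
  }
  key_lt <- function(a, b) {
    if (a$freq != b$freq) return(a$freq < b$freq)
    u64_lt(a$h, b$h)
  }
  sel <- logical(m)
  for (start in seq_len(max(1, m - w + 1))) {
    idx <- start:min(start + w - 1, m)
    idx <- idx[valid[idx]]
    if (!length(idx)) next
    best <- idx[1]
    for (i in idx[-1]) if (key_lt(keys[[i]], keys[[best]])) best <- i
    for (i in idx) if (!key_lt(keys[[best]], keys[[i]]) &&
                       !key_lt(keys[[i]], keys[[best]])) sel[i] <- TRUE
  }
  which(sel) - 1L
}

# all k-mers spelled by haplotype walks starting at a given oriented graph
# position (following each walk that passes through it)
walk_kmers_at <- function(graph, node, orient, offset, k) {
  out <- character(0)
  for (w0 in graph$walks) {
    for (w in list(w0, reverse_walk(w0))) {
      lens <- nchar(graph$nodes$seq)[match(w$steps$node, graph$nodes$id)]
      cum <- cumsum(c(0, lens))
      sp <- spell_walk(graph, w)
      for (j in seq_along(lens)) {
        if (w$steps$node[j] != node || w$steps$orient[j] != orient) next
        t <- cum[j] + offset  # 0-based walk coordinate
        if (t + k <= nchar(sp)) out <- c(out, substr(sp, t + 1, t + k))
      }
    }
  }
  unique(out)
}

# --- alignment oracles ------------------------------------------------------

# random mutated copy of a sequence (substitutions + indels)
mutate_seq <- function(s, rate = 0.15) {
  b <- strsplit(s, "")[[1]]
  abc <- c("A", "C", "G", "T")
  out <- character(0)
  for (x in b) {
    u <- runif(1)
    if (u < rate / 3) next                      # deletion
    if (u < 2 * rate / 3) x <- sample(abc, 1)   # substitution
    out <- c(out, x)
    if (u >= 2 * rate / 3 && u < rate) out <- c(out, sample(abc, 1))
  }
  if (!length(out)) out <- sample(abc, 1)
  paste(out, collapse = "")
}

# independent global affine alignment score via Biostrings
oracle_global_score <- function(q, t, sc = scoring_params()) {
  if (nchar(q) == 0 && nchar(t) == 0) return(0)
  if (nchar(q) == 0) return(sc$gap_open + sc$gap_extend * nchar(t))
  if (nchar(t) == 0) return(sc$gap_open + sc$gap_extend * nchar(q))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = sc$match,
                                                  mismatch = sc$mismatch)
  Biostrings::pairwiseAlignment(q, t, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = -sc$gap_open,
                                gapExtension = -sc$gap_extend,
                                scoreOnly = TRUE)
}

# plain-R pinned-start free-end affine extension DP (score only)
oracle_extend_score <- function(q, t, sc = scoring_params()) {
  n <- nchar(q); m <- nchar(t)
  qb <- strsplit(q, "")[[1]]; tb <- strsplit(t, "")[[1]]
  oe <- sc$gap_open + sc$gap_extend; ge <- sc$gap_extend
  S <- matrix(-Inf, n + 1, m + 1); E <- S; F <- S
  S[1, 1] <- 0
  for (j in seq_len(m)) S[1, j + 1] <- oe + ge * (j - 1)
  for (i in seq_len(n)) S[i + 1, 1] <- oe + ge * (i - 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- if (qb[i] == tb[j]) sc$match else sc$mismatch
    E[i + 1, j + 1] <- max(S[i + 1, j] + oe, E[i + 1, j] + ge)
    F[i + 1, j + 1] <- max(S[i, j + 1] + oe, F[i, j + 1] + ge)
    S[i + 1, j + 1] <- max(S[i, j] + sub, E[i + 1, j + 1], F[i + 1, j + 1])
  }
  max(S)
}

# enumerate the spellings of all walks between two anchored positions
# (bases strictly between them), up to max_len bases; independent of the
# package's graph aligner
oracle_segment_spellings <- function(graph, start_pos, end_pos, max_len) {
  lens <- setNames(nchar(graph$nodes$seq), graph$nodes$id)
  seqs <- setNames(graph$nodes$seq, graph$nodes$id)
  orient_seq <- function(node, dir) {
    if (dir == 0) seqs[as.character(node)]
    else reverse_complement(seqs[as.character(node)])
  }
  e <- graph$edges
  succ <- function(node, dir) {
    face_side <- if (dir == 0) 1L else 0L
    out <- list()
    for (i in seq_len(nrow(e))) {
      if (e$from[i] == node && e$from_side[i] == face_side)
        out <- c(out, list(c(e$to[i], if (e$to_side[i] == 0) 0L else 1L)))
      if (e$to[i] == node && e$to_side[i] == face_side)
        out <- c(out, list(c(e$from[i], if (e$from_side[i] == 0) 0L else 1L)))
    }
    out
  }
  found <- character(0)
  recurse <- function(node, dir, prefix) {
    if (node == end_pos$node && dir == end_pos$orient) {
      seg <- substr(orient_seq(node, dir), 1, end_pos$offset)
      found <<- unique(c(found, paste0(prefix, seg)))
      # a cyclic path may pass through and come back; keep exploring
    }
    full <- paste0(prefix, orient_seq(node, dir))
    if (nchar(full) > max_len) return()
    for (s in succ(node, dir)) recurse(s[1], s[2], full)
  }
  first <- substr(orient_seq(start_pos$node, start_pos$orient),
                  start_pos$offset + 2, lens[as.character(start_pos$node)])
  if (start_pos$node == end_pos$node && start_pos$orient == end_pos$orient &&
      end_pos$offset > start_pos$offset) {
    found <- substr(orient_seq(start_pos$node, start_pos$orient),
                    start_pos$offset + 2, end_pos$offset)
  }
  if (nchar(first) <= max_len || TRUE)
    for (s in succ(start_pos$node, start_pos$orient))
      recurse(s[1], s[2], first)
  found
}

# --- chaining oracles -------------------------------------------------------

# exhaustive single-pass oracle over all ordered subsets of seeds
oracle_best_chain <- function(off, k, D, a, b, max_gap) {
  n <- length(off)
  best <- k  # a single seed
  for (mask in 1:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) < 1) next
    sc <- k
    ok <- TRUE
    if (length(sel) > 1) {
      for (t in 2:length(sel)) {
        i <- sel[t - 1]; j <- sel[t]
        rg <- off[j] - off[i]; gdist <- D[i, j]
        if (rg <= 0 || !is.finite(gdist)) { ok <- FALSE; break }
        g <- abs(rg - gdist)
        if (rg > max_gap || gdist > max_gap || g > max_gap) { ok <- FALSE; break }
        cost <- if (g == 0) 0 else a * g + b * log2(g)
        sc <- sc + min(k, rg) - cost
      }
    }
    if (ok) best <- max(best, sc)
  }
  best
}

dp_top_score <- function(off, k, D, a = 0.19, b = 0.5, max_gap = 1000) {
  n <- length(off)
  ci <- cj <- integer(0); gd <- numeric(0)
  for (j in seq_len(n)) for (i in seq_len(j - 1)) {
    ci <- c(ci, i - 1L); cj <- c(cj, j - 1L); gd <- c(gd, D[i, j])
  }
  dp <- pgmap:::.chain_dp_cpp(off, off + k, rep(k, n), ci, cj, gd,
                              a, b, max_gap, FALSE)
  max(dp$score)
}

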