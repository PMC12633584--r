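#' Test whether two node sides bound a snarl candidate
#'
#' Two node sides are separable if, after cutting both their nodes into
#' disconnected half-vertices (every other node keeps its two sides
#' connected), the two tested faces lie in the same component of the
#' side-adjacency graph. The separated node set is the set of nodes of that
#' component that cannot be reached from either boundary node's opposite
#' face — the subgraph "between" the two sides, cut off from the rest of the
#' graph.
#'
#' @param graph a [variation_graph()].
#' @param side_a,side_b [node_side()] objects on distinct nodes.
#' @return list with `separable` (logical) and `contents` (integer node ids,
#'   empty for a trivial candidate).
#' @export
is_separable <- function(graph, side_a, side_b) {
  stopifnot(inherits(side_a, "node_side"), inherits(side_b, "node_side"))
  if (side_a$node == side_b$node) stop("sides must be on distinct nodes")
  ids <- graph$nodes$id
  if (!(side_a$node %in% ids) || !(side_b$node %in% ids)) stop("unknown node")
  em <- edge_matrix(graph)
  r <- .separable_cpp(max(ids), em, side_a$node, side_a$side,
                      side_b$node, side_b$side)
  list(separable = r$separable, contents = sort(as.integer(r$contents)))
}

edge_matrix <- function(graph) {
  e <- graph$edges
  m <- cbind(e$from, e$from_side, e$to, e$to_side)
  storage.mode(m) <- "integer"
  m
}

#' Decompose a variation graph into its snarl tree
#'
#' Finds all separable-minimal side pairs (the snarls, sites of variation
#' where walks diverge into alleles), merges consecutive snarls into chains
#' (maximal runs of nodes with snarls between them), and nests chains inside
#' snarls to build the snarl tree. Trivial snarls — adjacent chain nodes
#' with nothing between them — are represented implicitly as chain
#' adjacency. The decomposition is canonicalized: chains are traversed so
#' the lower node id comes first, and snarl boundaries with identical
#' contents prefer the pair with the smallest (min id, max id).
#'
#' @param graph a non-empty [variation_graph()] in which every connected
#'   component is touched by at least one walk.
#' @return a `snarl_tree` with elements `chains`, `snarls`, `node_chain`
#'   and `node_item` (see package vignette for the layout).
#' @export
decompose_snarls <- function(graph) {
  if (!nrow(graph$nodes)) stop("cannot decompose an empty graph")
  ids <- graph$nodes$id
  n <- max(ids)
  comp <- node_components(graph)
  walked <- unique(unlist(lapply(graph$walks, function(w) w$steps$node)))
  for (cc in unique(comp[ids])) {
    members <- ids[comp[ids] == cc]
    if (!any(members %in% walked))
      stop(sprintf("component containing node %d has no walk", min(members)))
  }

  found <- .find_snarls_cpp(n, edge_matrix(graph))
  sn <- found$snarls
  contents <- lapply(found$contents, sort)
  cyclic <- as.logical(found$cyclic)

  # The decomposition is not unique: alternative boundary pairs (for
  # example, the two allele sides of a bubble facing outward) can also be
  # separable-minimal. Canonicalize by preferring pairs with the smallest
  # (min boundary id, max boundary id) and keeping a pair only if it is
  # disjoint from, or properly nested with, every pair kept before it.
  sel <- select_consistent_snarls(
    lapply(seq_len(nrow(sn)), function(i)
      list(b = c(sn[i, 1], sn[i, 3]), contents = contents[[i]])))
  sn <- sn[sel, , drop = FALSE]
  contents <- contents[sel]
  cyclic <- cyclic[sel]

  build_snarl_tree(graph, sn, contents, cyclic, comp)
}

# greedy canonical selection among overlapping snarl candidates; `cands`
# is a list of list(b = boundary node ids, contents); returns kept indices
# in the original order
select_consistent_snarls <- function(cands) {
  if (!length(cands)) return(integer(0))
  ord <- order(vapply(cands, function(p) min(p$b), 0L),
               vapply(cands, function(p) max(p$b), 0L),
               vapply(cands, function(p) length(p$contents), 0L))
  kept <- integer(0)
  for (i in ord) {
    p <- cands[[i]]
    ok <- TRUE
    for (j in kept) {
      q <- cands[[j]]
      disjoint <- !length(intersect(p$contents, q$contents)) &&
        !length(intersect(p$b, q$contents)) &&
        !length(intersect(q$b, p$contents))
      p_in_q <- all(c(p$contents, p$b) %in% q$contents)
      q_in_p <- all(c(q$contents, q$b) %in% p$contents)
      if (!(disjoint || p_in_q || q_in_p)) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

node_components <- function(graph) {
  ids <- graph$nodes$id
  n <- max(ids)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    a <- find(e$from[i]); b <- find(e$to[i])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, 0L)
}

build_snarl_tree <- function(graph, sn, contents, cyclic, comp) {
  ids <- graph$nodes$id
  ns <- nrow(sn)
  size <- lengths(contents)
  ord <- order(size)

  # nesting: parent snarl = smallest snarl whose contents strictly contain
  # this snarl's contents plus boundaries
  parent_snarl <- rep(0L, ns)
  for (i in seq_len(ns)) {
    need <- c(contents[[i]], sn[i, 1], sn[i, 3])
    for (j in ord) {
      if (j == i || size[j] <= size[i]) next
      if (all(need %in% contents[[j]])) { parent_snarl[i] <- j; break }
    }
  }

  # innermost enclosing snarl per node (0 = root region of its component)
  region_of <- rep(0L, max(ids))
  if (ns) {
    for (j in ord) for (nd in contents[[j]])
      if (region_of[nd] == 0L) region_of[nd] <- j
  }

  # links per region: child snarls + trivial adjacencies between region nodes
  slot <- matrix(NA_integer_, nrow = max(ids), ncol = 2)  # link id per (node, side+1)
  links <- list()  # each: list(u, su, v, sv, snarl = id or NA)
  add_link <- function(u, su, v, sv, snarl_id) {
    links[[length(links) + 1L]] <<- list(u = u, su = su, v = v, sv = sv, snarl = snarl_id)
    li <- length(links)
    for (p in list(c(u, su), c(v, sv))) {
      if (!is.na(slot[p[1], p[2] + 1L]))
        stop(sprintf("ambiguous chain link at node %d side %d", p[1], p[2]))
      slot[p[1], p[2] + 1L] <<- li
    }
  }
  snarl_pair_key <- character(0)
  for (i in seq_len(ns)) {
    add_link(sn[i, 1], sn[i, 2], sn[i, 3], sn[i, 4], i)
    snarl_pair_key <- c(snarl_pair_key,
                        paste(sn[i, 1], sn[i, 2], sn[i, 3], sn[i, 4], sep = "_"))
  }
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    u <- e$from[i]; su <- e$from_side[i]; v <- e$to[i]; sv <- e$to_side[i]
    if (u == v) next                                   # self edge: inside a snarl
    if (region_of[u] != region_of[v]) next             # crosses a snarl boundary
    k <- paste(u, su, v, sv, sep = "_")
    if (k %in% snarl_pair_key) next                    # the snarl already links these
    add_link(u, su, v, sv, NA_integer_)
  }

  # assemble chains by following links
  chains <- list()
  chain_of <- rep(NA_integer_, max(ids))
  item_of <- rep(NA_integer_, max(ids))
  visited <- rep(FALSE, max(ids))
  extend <- function(node, via_side, seen) {
    out <- list(nodes = integer(0), links = list(), sides = integer(0), circ = FALSE)
    cur <- node; side <- via_side
    repeat {
      li <- slot[cur, side + 1L]
      if (is.na(li)) break
      l <- links[[li]]
      if (l$u == cur && l$su == side) { nxt <- l$v; nside <- l$sv }
      else { nxt <- l$u; nside <- l$su }
      if (nxt %in% seen) { out$circ <- TRUE; break }
      out$nodes <- c(out$nodes, nxt)
      out$links <- c(out$links, list(l))
      out$sides <- c(out$sides, nside)   # side by which nxt was entered
      seen <- c(seen, nxt)
      cur <- nxt; side <- 1L - nside
    }
    out
  }
  link_snarl <- function(ls) vapply(ls, function(l) l$snarl, 0L)
  for (start in ids) {
    if (visited[start]) next
    right <- extend(start, 1L, start)
    if (right$circ) {
      # circular chain: all members found going one way; break at lowest id
      nodes_seq <- c(start, right$nodes)
      entry_seq <- c(0L, right$sides)
      closing <- links[[slot[start, 1L]]]
      gaps_all <- c(link_snarl(right$links), closing$snarl)
      k <- length(nodes_seq)
      r <- which.min(nodes_seq)
      idx <- ((seq_len(k) + r - 2L) %% k) + 1L
      nodes_seq <- nodes_seq[idx]
      entry_seq <- entry_seq[idx]
      gap_snarls <- gaps_all[((seq_len(k - 1L) + r - 2L) %% k) + 1L]
      circular <- TRUE
    } else {
      left <- extend(start, 0L, c(start, right$nodes))
      nodes_seq <- c(rev(left$nodes), start, right$nodes)
      entry_seq <- c(1L - rev(left$sides), 0L, right$sides)
      gap_snarls <- c(rev(link_snarl(left$links)), link_snarl(right$links))
      circular <- left$circ
    }
    # canonical direction: lexicographically smallest id sequence
    if (length(nodes_seq) > 1) {
      fwd <- nodes_seq; rev_ <- rev(nodes_seq)
      flip <- FALSE
      for (z in seq_along(fwd)) {
        if (fwd[z] < rev_[z]) break
        if (fwd[z] > rev_[z]) { flip <- TRUE; break }
      }
      if (flip) {
        nodes_seq <- rev(nodes_seq)
        entry_seq <- 1L - rev(entry_seq)
        gap_snarls <- rev(gap_snarls)
      }
    }
    ci <- length(chains) + 1L
    chains[[ci]] <- list(id = ci, nodes = nodes_seq, gaps = gap_snarls,
                         entry_side = entry_seq,
                         parent_snarl = region_of[start],
                         circular = circular,
                         component = comp[start])
    visited[nodes_seq] <- TRUE
    chain_of[nodes_seq] <- ci
    item_of[nodes_seq] <- seq_along(nodes_seq)
  }

  # deterministic chain ids: order by (parent region depth handled later) min id
  ordc <- order(vapply(chains, function(ch) min(ch$nodes), 0L))
  remap <- integer(length(chains)); remap[ordc] <- seq_along(chains)
  chains <- chains[ordc]
  for (i in seq_along(chains)) chains[[i]]$id <- i
  chain_of[!is.na(chain_of)] <- remap[chain_of[!is.na(chain_of)]]

  snarls <- vector("list", ns)
  for (i in seq_len(ns)) {
    pc <- chain_of[sn[i, 1]]
    kids <- sort(unique(chain_of[contents[[i]]][
      vapply(chain_of[contents[[i]]], function(cc)
        chains[[cc]]$parent_snarl == i, TRUE)]))
    # orient boundary in parent-chain direction
    ch <- chains[[pc]]
    ia <- match(sn[i, 1], ch$nodes); ib <- match(sn[i, 3], ch$nodes)
    if (!is.na(ia) && !is.na(ib) && ia > ib) {
      st <- c(sn[i, 3], sn[i, 4]); en <- c(sn[i, 1], sn[i, 2])
    } else {
      st <- c(sn[i, 1], sn[i, 2]); en <- c(sn[i, 3], sn[i, 4])
    }
    snarls[[i]] <- list(id = i, start = st, end = en,
                        contents = contents[[i]], cyclic = cyclic[i],
                        parent_chain = pc, child_chains = kids)
  }
  structure(list(chains = chains, snarls = snarls,
                 node_chain = chain_of, node_item = item_of),
            class = "snarl_tree")
}

#' Snarl-tree ancestry of a node
#'
#' @param tree a `snarl_tree` from [decompose_snarls()].
#' @param node node id.
#' @return list of enclosing records from innermost to root, alternating
#'   `list(kind = "chain", id = ...)` and `list(kind = "snarl", id = ...)`;
#'   the last element is always a root chain.
#' @export
snarl_ancestry <- function(tree, node) {
  node <- as.integer(node)
  if (node > length(tree$node_chain) || is.na(tree$node_chain[node]))
    stop(sprintf("unknown node %d", node))
  out <- list()
  ci <- tree$node_chain[node]
  repeat {
    out <- c(out, list(list(kind = "chain", id = ci)))
    ps <- tree$chains[[ci]]$parent_snarl
    if (ps == 0L) break
    out <- c(out, list(list(kind = "snarl", id = ps)))
    ci <- tree$snarls[[ps]]$parent_chain
  }
  out
}

#' Dump snarls as JSON lines
#'
#' One snarl per line with boundaries, contents, cyclic flag and parent
#' chain, for debugging.
#'
#' @param tree a `snarl_tree`.
#' @param path optional file; if `NULL`, returns the lines.
#' @return character vector of JSON lines, invisibly.
#' @export
write_snarl_json <- function(tree, path = NULL) {
  lines <- vapply(tree$snarls, function(s) {
    jsonlite::toJSON(list(
      start = paste0(s$start[1], c("L", "R")[s$start[2] + 1]),
      end = paste0(s$end[1], c("L", "R")[s$end[2] + 1]),
      contents = s$contents, cyclic = s$cyclic,
      parent_chain = s$parent_chain), auto_unbox = TRUE)
  }, "")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.snarl_tree <- function(x, ...) {
  cat(sprintf("snarl_tree: %d chains, %d snarls (%d cyclic)\n",
              length(x$chains), length(x$snarls),
              sum(vapply(x$snarls, `[[`, TRUE, "cyclic"))))
  invisible(x)
}

# canonical nested representation used for oracle comparison and tests
canonical_tree <- function(tree) {
  chain_repr <- function(ci) {
    ch <- tree$chains[[ci]]
    items <- list()
    for (i in seq_along(ch$nodes)) {
      items <- c(items, list(ch$nodes[i]))
      if (i < length(ch$nodes) && !is.na(ch$gaps[i])) {
        s <- tree$snarls[[ch$gaps[i]]]
        items <- c(items, list(list(
          start = unname(s$start), end = unname(s$end), cyclic = s$cyclic,
          children = lapply(s$child_chains, chain_repr))))
      }
    }
    items
  }
  roots <- which(vapply(tree$chains, function(ch) ch$parent_snarl == 0L, TRUE))
  roots <- roots[order(vapply(roots, function(ci) min(tree$chains[[ci]]$nodes), 0L))]
  lapply(roots, chain_repr)
}
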