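#' Build a minimum-distance index for a variation graph
#'
#' The index holds, per chain, prefix coordinates of every chain item in
#' both traversal directions (snarl gaps contribute their minimal
#' through-distance) and, per snarl, distance tables from each child chain's
#' two ends to the snarl boundaries, computed by Dijkstra restricted to the
#' snarl's interior. These structures drive zip codes and the zip code
#' tree. Point-to-point queries are answered exactly on the directed
#' node-side graph, so cyclic snarls (duplications) and inversions are
#' handled without enumerating cycles more than once: a minimum distance
#' never benefits from an extra loop.
#'
#' Distances are in base steps: consecutive bases are at distance 1 and
#' `d(A, A) = 0`. Unreachable pairs are reported as `Inf`.
#'
#' @param graph a [variation_graph()].
#' @param tree its snarl tree from [decompose_snarls()]; computed if
#'   missing.
#' @return a `distance_index`.
#' @export
build_distance_index <- function(graph, tree = NULL) {
  if (is.null(tree)) tree <- decompose_snarls(graph)
  n <- max(graph$nodes$id)
  node_len <- integer(n)
  node_len[graph$nodes$id] <- nchar(graph$nodes$seq)
  em <- edge_matrix(graph)

  # per-snarl boundary tables
  snarl_tab <- vector("list", length(tree$snarls))
  for (si in seq_along(tree$snarls)) {
    s <- tree$snarls[[si]]
    kids <- s$child_chains
    allowed <- s$contents
    ends <- lapply(kids, function(ci) chain_end_faces(tree, ci))
    start_face <- s$start            # (node, side), side faces into snarl
    end_entry_vertex <- dir_vertex(s$end[1], enter_dir(s$end[2]))

    dfwd <- .restricted_dist_cpp(n, node_len, em, start_face[1], start_face[2],
                                 allowed)
    through <- dfwd[end_entry_vertex]
    dstart <- dstart_rev <- dend <- dend_rev <- numeric(length(kids))
    for (j in seq_along(kids)) {
      e <- ends[[j]]
      dstart[j] <- dfwd[dir_vertex(e$first_node, enter_dir(e$first_face))]
      dstart_rev[j] <- dfwd[dir_vertex(e$last_node, enter_dir(e$last_face))]
      dl <- .restricted_dist_cpp(n, node_len, em, e$last_node, e$last_face, allowed)
      dend[j] <- dl[end_entry_vertex]
      dr <- .restricted_dist_cpp(n, node_len, em, e$first_node, e$first_face_rev,
                                 allowed)
      dend_rev[j] <- dr[end_entry_vertex]
    }
    snarl_tab[[si]] <- list(through = through, dstart = dstart, dend = dend,
                            dstart_rev = dstart_rev, dend_rev = dend_rev)
  }

  # per-chain prefix coordinates (entry point of each node item)
  chain_coord <- vector("list", length(tree$chains))
  for (ci in seq_along(tree$chains)) {
    ch <- tree$chains[[ci]]
    k <- length(ch$nodes)
    C <- numeric(k)
    if (k > 1) {
      for (i in 2:k) {
        gap <- ch$gaps[i - 1]
        gl <- if (is.na(gap)) 0 else snarl_tab[[gap]]$through
        C[i] <- C[i - 1] + node_len[ch$nodes[i - 1]] + gl
      }
    }
    chain_coord[[ci]] <- list(C = C, total = C[k] + node_len[ch$nodes[k]])
  }

  structure(list(n = n, node_len = node_len, edges = em, tree = tree,
                 chain_coord = chain_coord, snarl_tab = snarl_tab),
            class = "distance_index")
}

# faces of a chain in its canonical direction: entry face of the first node,
# exit face of the last node (plus the reversed-entry exit face)
chain_end_faces <- function(tree, ci) {
  ch <- tree$chains[[ci]]
  k <- length(ch$nodes)
  list(first_node = ch$nodes[1], first_face = ch$entry_side[1],
       first_face_rev = ch$entry_side[1],   # leaving back out the entry face
       last_node = ch$nodes[k], last_face = flip_side(ch$entry_side[k]))
}

flip_side <- function(s) 1L - s

# directed vertex id (1-based) for entering `node` traveling `dir`
# (0 forward, 1 reverse)
dir_vertex <- function(node, dir) 2L * (node - 1L) + dir + 1L

# entering via face side 0 (left) means traveling forward
enter_dir <- function(side) ifelse(side == 0L, 0L, 1L)

#' Minimum base-step distance between oriented graph positions
#'
#' @param index a [build_distance_index()] result.
#' @param pos_a,pos_b [graph_pos()] objects (or lists with `node`, `orient`,
#'   `offset`).
#' @return numeric distance (0 for identical positions, `Inf` if `pos_b`
#'   cannot be reached from `pos_a` by any valid walk).
#' @export
min_distance <- function(index, pos_a, pos_b) {
  min_distances(index,
                matrix(unlist(pos_a[c("node", "orient", "offset")]), 1),
                matrix(unlist(pos_b[c("node", "orient", "offset")]), 1))
}

# batch interface: a, b are k x 3 (node, orient, offset) matrices
min_distances <- function(index, a, b) {
  storage.mode(a) <- "integer"; storage.mode(b) <- "integer"
  bad_a <- a[, 3] < 0 | a[, 3] >= index$node_len[a[, 1]]
  bad_b <- b[, 3] < 0 | b[, 3] >= index$node_len[b[, 1]]
  if (any(bad_a, bad_b)) stop("position offset out of node bounds")
  .min_distance_cpp(index$n, index$node_len, index$edges, a, b)
}

#' @export
print.distance_index <- function(x, ...) {
  cat(sprintf("distance_index: %d nodes, %d chains, %d snarl tables\n",
              x$n, length(x$chain_coord), length(x$snarl_tab)))
  invisible(x)
}
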