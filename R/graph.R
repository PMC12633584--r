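#' Bidirected variation graphs with embedded haplotype walks
#'
#' A variation graph is a bidirected sequence graph: nodes carry DNA
#' sequences, each node has a left and a right side, and edges join node
#' sides. A walk visits nodes with an orientation (a reverse visit spells the
#' reverse complement), entering and exiting opposite sides. Haplotypes and
#' reference sequences are stored as named walks embedded in the graph.
#' Following GBZ semantics, the edge set of a well-formed graph is exactly
#' the set of adjacencies supported by at least one walk; extra edges read
#' from GFA L lines are retained but flagged as non-haplotype.
#'
#' @param nodes data.frame with columns `id` (positive integer, unique),
#'   `seq` (non-empty string over A,C,G,T,N) and optionally `name` (the
#'   original GFA segment name; defaults to `as.character(id)`).
#' @param walks list of walks as returned by [walk()].
#' @param extra_edges optional data.frame of additional edges (columns
#'   `from`, `from_side`, `to`, `to_side` with sides `0` = left, `1` =
#'   right) that are not supported by any walk; they are kept and flagged.
#' @return An object of class `variation_graph` with elements `nodes`,
#'   `edges` (columns `from, from_side, to, to_side, haplotype`) and
#'   `walks`.
#' @examples
#' g <- variation_graph(
#'   nodes = data.frame(id = 1:4, seq = c("GAT", "A", "C", "TACA")),
#'   walks = list(
#'     walk("H1", c(1, 2, 4), c("+", "+", "+")),
#'     walk("H2", c(1, 3, 4), c("+", "+", "+"))
#'   )
#' )
#' spell_walk(g, "H1")
#' @export
variation_graph <- function(nodes, walks, extra_edges = NULL) {
  stopifnot(is.data.frame(nodes), all(c("id", "seq") %in% names(nodes)))
  nodes$id <- as.integer(nodes$id)
  nodes$seq <- toupper(as.character(nodes$seq))
  if (is.null(nodes$name)) nodes$name <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (any(nodes$id <= 0L)) stop("node ids must be positive")
  if (any(nchar(nodes$seq) == 0L)) stop("node sequences must be non-empty")
  if (any(grepl("[^ACGTN]", nodes$seq))) stop("node sequences must be over {A,C,G,T,N}")
  nodes <- nodes[order(nodes$id), c("id", "seq", "name"), drop = FALSE]
  rownames(nodes) <- NULL

  walks <- lapply(walks, as_walk)
  wedges <- do.call(rbind, c(list(empty_edges()), lapply(walks, walk_adjacencies)))
  wedges <- unique(wedges)
  edges <- wedges
  edges$haplotype <- rep(TRUE, nrow(edges))
  if (!is.null(extra_edges) && nrow(extra_edges)) {
    xe <- canonical_edges(extra_edges)
    new <- !(edge_key(xe, max(nodes$id)) %in% edge_key(edges, max(nodes$id)))
    if (any(new)) {
      xe <- xe[new, , drop = FALSE]
      xe$haplotype <- FALSE
      edges <- rbind(edges, xe)
    }
  }
  edges <- edges[order(edges$from, edges$from_side, edges$to, edges$to_side), , drop = FALSE]
  rownames(edges) <- NULL

  g <- structure(list(nodes = nodes, edges = edges, walks = walks),
                 class = "variation_graph")
  validate_variation_graph(g)
  g
}

#' Construct a haplotype walk
#'
#' @param name walk name. For walks parsed from GFA W lines the PanSN-style
#'   name `sample#haplotype#contig` is used.
#' @param nodes integer vector of node ids visited, in order.
#' @param orients orientations, `"+"` (forward) or `"-"` (reverse
#'   complement), recycled if length 1.
#' @param role `"haplotype"` or `"reference"`.
#' @param wline optional list of W-line metadata (`sample`, `hap_index`,
#'   `seq_id`, `seq_start`, `seq_end`) preserved for round-trip output.
#' @return A `pg_walk` object.
#' @export
walk <- function(name, nodes, orients = "+", role = "haplotype", wline = NULL) {
  nodes <- as.integer(nodes)
  orients <- rep_len(as.character(orients), length(nodes))
  if (!all(orients %in% c("+", "-"))) stop("orients must be '+' or '-'")
  structure(list(name = as.character(name),
                 steps = data.frame(node = nodes,
                                    orient = as.integer(orients == "-")),
                 role = match.arg(role, c("haplotype", "reference")),
                 wline = wline),
            class = "pg_walk")
}

as_walk <- function(w) {
  if (inherits(w, "pg_walk")) return(w)
  stop("walks must be built with walk()")
}

empty_edges <- function() {
  data.frame(from = integer(), from_side = integer(),
             to = integer(), to_side = integer())
}

# Sides: 0 = left, 1 = right. A forward visit exits right/enters left.
step_exit_side <- function(orient) ifelse(orient == 0L, 1L, 0L)
step_entry_side <- function(orient) ifelse(orient == 0L, 0L, 1L)

walk_adjacencies <- function(w) {
  s <- w$steps
  n <- nrow(s)
  if (n < 2L) return(empty_edges())
  canonical_edges(data.frame(
    from = s$node[-n], from_side = step_exit_side(s$orient[-n]),
    to = s$node[-1L], to_side = step_entry_side(s$orient[-1L])))
}

# Edges are unordered pairs of node sides; store with the smaller
# (node, side) endpoint first.
canonical_edges <- function(e) {
  e <- as.data.frame(e)
  ka <- e$from * 2L + e$from_side
  kb <- e$to * 2L + e$to_side
  swap <- kb < ka
  data.frame(
    from = ifelse(swap, e$to, e$from),
    from_side = as.integer(ifelse(swap, e$to_side, e$from_side)),
    to = ifelse(swap, e$from, e$to),
    to_side = as.integer(ifelse(swap, e$from_side, e$to_side)))
}

edge_key <- function(e, maxid) {
  (e$from * 2 + e$from_side) * (2 * (maxid + 1)) + (e$to * 2 + e$to_side)
}

validate_variation_graph <- function(g) {
  ids <- g$nodes$id
  e <- g$edges
  if (nrow(e) && !all(c(e$from, e$to) %in% ids))
    stop("edge endpoint names unknown node")
  for (w in g$walks) {
    if (!all(w$steps$node %in% ids))
      stop(sprintf("walk '%s' visits unknown node", w$name))
    we <- walk_adjacencies(w)
    if (nrow(we)) {
      bad <- !(edge_key(we, max(ids)) %in% edge_key(e, max(ids)))
      if (any(bad))
        stop(sprintf("walk '%s' step %d -> %d not supported by an edge",
                     w$name, we$from[which(bad)[1]], we$to[which(bad)[1]]))
    }
  }
  invisible(g)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A,C,G,T,N (case preserved as
#'   upper case in the result; other characters become N).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) .rc_cpp(toupper(as.character(x)))

#' Sequence of a node in a given orientation
#'
#' A forward traversal spells the stored node sequence; a reverse traversal
#' spells its reverse complement.
#'
#' @param graph a [variation_graph()].
#' @param node node id.
#' @param orient `"+"` or `"-"`.
#' @return single string.
#' @export
oriented_sequence <- function(graph, node, orient = "+") {
  i <- match(as.integer(node), graph$nodes$id)
  if (is.na(i)) stop(sprintf("unknown node %s", node))
  s <- graph$nodes$seq[i]
  if (identical(orient, "+") || identical(orient, 0L)) s else reverse_complement(s)
}

#' Spell the DNA sequence of a walk
#'
#' Concatenates the oriented sequences of the walk's nodes, checking that
#' every consecutive step pair is supported by an edge.
#'
#' @param graph a [variation_graph()].
#' @param walk a `pg_walk`, a walk name present in the graph, or an index
#'   into `graph$walks`.
#' @return single DNA string.
#' @export
spell_walk <- function(graph, walk) {
  w <- resolve_walk(graph, walk)
  we <- walk_adjacencies(w)
  if (nrow(we)) {
    bad <- !(edge_key(we, max(graph$nodes$id)) %in%
               edge_key(graph$edges, max(graph$nodes$id)))
    if (any(bad)) stop("walk step not supported by an edge")
  }
  idx <- match(w$steps$node, graph$nodes$id)
  if (anyNA(idx)) stop("walk visits unknown node")
  seqs <- graph$nodes$seq[idx]
  rev <- w$steps$orient == 1L
  seqs[rev] <- reverse_complement(seqs[rev])
  paste(seqs, collapse = "")
}

resolve_walk <- function(graph, walk) {
  if (inherits(walk, "pg_walk")) return(walk)
  if (is.character(walk)) {
    i <- match(walk, vapply(graph$walks, `[[`, "", "name"))
    if (is.na(i)) stop(sprintf("no walk named '%s'", walk))
    return(graph$walks[[i]])
  }
  graph$walks[[walk]]
}

#' Reverse a walk
#'
#' The reverse of a walk visits the same nodes in opposite order with
#' flipped orientations; it spells the reverse complement of the original.
#'
#' @param w a `pg_walk`.
#' @return the reversed `pg_walk`.
#' @export
reverse_walk <- function(w) {
  w <- as_walk(w)
  w$steps <- data.frame(node = rev(w$steps$node),
                        orient = 1L - rev(w$steps$orient))
  w$name <- paste0(w$name, "_rev")
  w
}

node_lengths <- function(graph) {
  setNames(nchar(graph$nodes$seq), graph$nodes$id)
}

#' @export
print.variation_graph <- function(x, ...) {
  cat(sprintf("variation_graph: %d nodes (%d bp), %d edges, %d walks\n",
              nrow(x$nodes), sum(nchar(x$nodes$seq)), nrow(x$edges),
              length(x$walks)))
  for (w in head(x$walks, 8))
    cat(sprintf("  walk %-20s %5d steps [%s]\n", w$name, nrow(w$steps), w$role))
  if (length(x$walks) > 8) cat(sprintf("  ... and %d more\n", length(x$walks) - 8))
  invisible(x)
}

#' @export
print.pg_walk <- function(x, ...) {
  cat(sprintf("walk '%s' (%s): %d steps\n", x$name, x$role, nrow(x$steps)))
  invisible(x)
}

#' A node side
#'
#' @param node node id.
#' @param side `"L"` or `"R"` (or 0/1).
#' @return a `node_side` object.
#' @export
node_side <- function(node, side) {
  if (is.character(side)) side <- match(toupper(side), c("L", "R")) - 1L
  structure(list(node = as.integer(node), side = as.integer(side)),
            class = "node_side")
}

#' @export
print.node_side <- function(x, ...) {
  cat(sprintf("%d%s\n", x$node, c("L", "R")[x$side + 1L])); invisible(x)
}

#' An oriented base position in the graph
#'
#' Offsets are 0-based and measured in the traversal orientation: offset 0 of
#' a reverse position is the last stored base of the node.
#'
#' @param node node id.
#' @param orient `"+"` or `"-"`.
#' @param offset 0-based offset, `0 <= offset < node length`.
#' @return a `graph_pos` object.
#' @export
graph_pos <- function(node, orient = "+", offset = 0L) {
  structure(list(node = as.integer(node),
                 orient = as.integer(identical(orient, "-") || identical(orient, 1L)),
                 offset = as.integer(offset)),
            class = "graph_pos")
}

#' @export
print.graph_pos <- function(x, ...) {
  cat(sprintf("(%d,%s,%d)\n", x$node, c("+", "-")[x$orient + 1L], x$offset))
  invisible(x)
}
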