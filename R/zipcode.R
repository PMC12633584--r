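#' Zip code of a graph position
#'
#' A zip code is the root-to-leaf snarl-tree address of an oriented graph
#' position, annotated with the distances needed to compare two positions
#' in a single pass: at each chain level the prefix-sum offset and rank of
#' the item holding the position, at each snarl level the child chain rank
#' and the distances from the child chain's two ends to the snarl
#' boundaries, and at the leaf the node, its length, the offset and the
#' orientation.
#'
#' @param position a [graph_pos()].
#' @param tree a `snarl_tree` (taken from `index` if omitted).
#' @param index a [build_distance_index()] result.
#' @return a `zip_code`: list of levels, root chain first.
#' @export
compute_zipcode <- function(position, tree = NULL, index) {
  if (is.null(tree)) tree <- index$tree
  node <- position$node
  ci <- tree$node_chain[node]
  if (is.na(ci)) stop(sprintf("unknown node %d", node))
  item <- tree$node_item[node]
  item_is_gap <- FALSE
  levels <- list(list(kind = "node", node = node,
                      length = unname(index$node_len[node]),
                      offset = position$offset,
                      orient = c("+", "-")[position$orient + 1]))
  repeat {
    cc <- index$chain_coord[[ci]]
    off <- if (item_is_gap)
      unname(cc$C[item]) + unname(index$node_len[tree$chains[[ci]]$nodes[item]])
    else unname(cc$C[item])
    levels <- c(list(list(kind = "chain", id = ci, offset = off, rank = item)),
                levels)
    ps <- tree$chains[[ci]]$parent_snarl
    if (ps == 0L) break
    s <- tree$snarls[[ps]]
    crank <- match(ci, s$child_chains)
    tab <- index$snarl_tab[[ps]]
    levels <- c(list(list(kind = "snarl", id = ps, child_rank = crank,
                          dist_start = unname(tab$dstart[crank]),
                          dist_end = unname(tab$dend[crank]))), levels)
    ci <- s$parent_chain
    item <- match(ps, tree$chains[[ci]]$gaps)
    item_is_gap <- TRUE
  }
  structure(levels, class = "zip_code")
}

#' @export
print.zip_code <- function(x, ...) {
  for (lv in x) {
    if (lv$kind == "chain")
      cat(sprintf("chain %d (offset %s, rank %d)\n", lv$id,
                  format(lv$offset), lv$rank))
    else if (lv$kind == "snarl")
      cat(sprintf("  snarl %d (child rank %d, d_start %s, d_end %s)\n",
                  lv$id, lv$child_rank, format(lv$dist_start),
                  format(lv$dist_end)))
    else
      cat(sprintf("    node %d (len %d, offset %d, %s)\n", lv$node,
                  lv$length, lv$offset, lv$orient))
  }
  invisible(x)
}

# --- internal level tables used for ordering and distances -----------------

# one matrix row per level, root-first; see src/zip.cpp for the layout
zip_level_rows <- function(index, node, orient, offset) {
  tree <- index$tree
  ci <- tree$node_chain[node]
  item <- tree$node_item[node]
  ch <- tree$chains[[ci]]
  len <- index$node_len[node]
  o_chain <- ch$entry_side[item]          # node orientation within chain
  fwd_idx <- if (orient == 0L) offset else len - 1L - offset
  idx <- if (o_chain == 0L) fwd_idx else len - 1L - fwd_idx
  h <- if (orient == o_chain) 0L else 1L  # heading vs chain direction
  C <- index$chain_coord[[ci]]$C
  lo <- C[item]; hi <- lo + len
  rows <- list(c(0, ci, item, -1, lo, hi,
                 if (h == 0L) idx else Inf, if (h == 0L) len - idx else Inf,
                 if (h == 1L) len - 1 - idx else Inf,
                 if (h == 1L) idx + 1 else Inf))
  repeat {
    ps <- tree$chains[[ci]]$parent_snarl
    if (ps == 0L) break
    r <- rows[[length(rows)]]
    L <- index$chain_coord[[ci]]$total
    fs_f <- r[5] + r[7];  te_f <- r[8] + (L - r[6])
    fs_r <- (L - r[6]) + r[9]; te_r <- r[10] + r[5]
    s <- tree$snarls[[ps]]
    crank <- match(ci, s$child_chains)
    tab <- index$snarl_tab[[ps]]
    FSf <- min(tab$dstart[crank] + fs_f, tab$dstart_rev[crank] + fs_r)
    TEf <- min(te_f + tab$dend[crank], te_r + tab$dend_rev[crank])
    FSr <- min(tab$dend[crank] + fs_r, tab$dend_rev[crank] + fs_f)
    TEr <- min(te_r + tab$dstart[crank], te_f + tab$dstart_rev[crank])
    pc <- s$parent_chain
    g <- match(ps, tree$chains[[pc]]$gaps)
    Cp <- index$chain_coord[[pc]]$C
    u <- tree$chains[[pc]]$nodes[g]
    lo_g <- Cp[g] + index$node_len[u]
    hi_g <- Cp[g + 1]
    rows <- c(rows, list(c(1, pc, g, ci, lo_g, hi_g, FSf, TEf, FSr, TEr)))
    ci <- pc
  }
  do.call(rbind, rev(rows))
}

# heading of the seed at the root level: 0 forward, 1 reverse
zip_root_dir <- function(rows) {
  if (is.finite(rows[1, 7]) || is.finite(rows[1, 8])) 0L else 1L
}

zip_sort_key <- function(rows, dir) {
  sgn <- if (dir == 0L) 1 else -1
  key <- numeric(0)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    inner <- if (r[1] == 0) {
      if (is.finite(r[7])) r[7] else r[10] - 1  # node index either heading
    } else 0
    key <- c(key, sgn * r[5], r[1], if (r[1] == 1) r[4] else 0, sgn * inner)
  }
  key
}

#' Build the zip code forest over a read's seeds
#'
#' Seeds are sorted by zip code — a pre-and-post-order traversal of the
#' snarl tree, with chain prefix offsets ordering children along chains and
#' snarl children ordered by rank — and bracketed by the snarl and chain
#' boundaries that contain them. Seeds on different graph components, and
#' seeds whose traversal direction conflicts with the tree's, are split
#' into separate trees of the forest. Consecutive items carry the minimum
#' distance between them derived from the zip codes.
#'
#' @param seeds data.frame from [find_seeds()] (columns `node`, `orient`,
#'   `offset`, and optionally `read_offset`).
#' @param tree a `snarl_tree` (defaults to the one inside `index`).
#' @param index a [build_distance_index()].
#' @param items also build the bracketed item sequence per tree (skippable
#'   for speed when only chaining distances are needed).
#' @return a `zip_forest`: list of trees, each with `dir`, `seed_rows`
#'   (row indices into `seeds` in tree order), `items` (bracketed item
#'   sequence) and internal level tables.
#' @export
build_zip_forest <- function(seeds, tree = NULL, index, items = TRUE) {
  if (is.null(tree)) tree <- index$tree
  stopifnot(nrow(seeds) >= 1)
  n <- nrow(seeds)
  rows_list <- vector("list", n)
  for (i in seq_len(n))
    rows_list[[i]] <- zip_level_rows(index, seeds$node[i], seeds$orient[i],
                                     seeds$offset[i])
  root_chain <- vapply(rows_list, function(r) r[1, 2], 0)
  dirs <- vapply(rows_list, zip_root_dir, 0L)

  forest <- list()
  for (rc in sort(unique(root_chain))) {
    for (dd in 0:1) {
      sel <- which(root_chain == rc & dirs == dd)
      if (!length(sel)) next
      keys <- lapply(sel, function(i) zip_sort_key(rows_list[[i]], dd))
      maxlen <- max(lengths(keys))
      km <- do.call(rbind, lapply(keys, function(k) c(k, rep(0, maxlen - length(k)))))
      ord <- do.call(order, c(as.data.frame(km), list(sel)))
      sorted <- sel[ord]
      lv <- rows_list[sorted]
      levels <- do.call(rbind, lv)
      depth <- vapply(lv, nrow, 0L)
      ptr <- cumsum(c(1L, depth[-length(depth)]))
      tr <- list(dir = dd, seed_rows = sorted, levels = levels,
                 ptr = as.integer(ptr), depth = as.integer(depth))
      if (items) tr$items <- zip_tree_items(tr, seeds)
      forest[[length(forest) + 1L]] <- tr
    }
  }
  forest <- structure(forest, class = "zip_forest")
  attr(forest, "seeds") <- seeds
  forest
}

# bracketed item sequence: chain/snarl boundaries around runs of seeds
zip_tree_items <- function(tr, seeds) {
  paths <- lapply(seq_along(tr$seed_rows), function(i) {
    r0 <- tr$ptr[i]; d <- tr$depth[i]
    m <- tr$levels[r0:(r0 + d - 1), , drop = FALSE]
    # path elements: chain id, then (gap designation, child chain) pairs
    out <- character(0)
    for (j in seq_len(nrow(m))) {
      out <- c(out, paste0("chain:", m[j, 2]))
      if (m[j, 1] == 1) out <- c(out, paste0("snarl:", m[j, 2], ":", m[j, 3]))
    }
    out
  })
  items <- data.frame(kind = character(0), payload = character(0),
                      edge_to_next = numeric(0))
  add <- function(kind, payload, edge = NA_real_)
    items[nrow(items) + 1L, ] <<- list(kind, as.character(payload), edge)
  prev <- character(0)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    common <- 0
    while (common < length(prev) && common < length(p) &&
           prev[common + 1] == p[common + 1]) common <- common + 1
    if (length(prev) > common)
      for (j in length(prev):(common + 1))
        add(if (grepl("^chain", prev[j])) "chain_close" else "snarl_close", prev[j])
    if (length(p) > common)
      for (j in (common + 1):length(p))
        add(if (grepl("^chain", p[j])) "chain_open" else "snarl_open", p[j])
    edge <- if (i < length(paths))
      .zip_pair_dist_cpp(tr$levels, tr$ptr, tr$depth, i, i + 1L, tr$dir)
    else NA_real_
    add("seed", tr$seed_rows[i], edge)
    prev <- p
  }
  for (j in rev(seq_along(prev)))
    add(if (grepl("^chain", prev[j])) "chain_close" else "snarl_close", prev[j])
  items
}

#' Seed-to-seed distances along a zip code tree
#'
#' Streams every seed after (or before) `from_seed` in tree order together
#' with the zip-derived minimum graph distance. Distances across snarls
#' take the minimum over the recorded child-chain boundary distances. On
#' acyclic graph regions with no reverse traversals these equal the exact
#' minimum distance; on cyclic or inverted regions they never
#' under-report it.
#'
#' @param tree one tree of a [build_zip_forest()] result.
#' @param from_seed a seed row index present in `tree$seed_rows`.
#' @param direction `"forward"` (seeds after, with distance from
#'   `from_seed` to each) or `"backward"` (seeds before, with distance
#'   from each seed to `from_seed`).
#' @return data.frame with `seed` (row index into the original seed table)
#'   and `distance`.
#' @export
iter_seed_distances <- function(tree, from_seed, direction = "forward") {
  direction <- match.arg(direction, c("forward", "backward"))
  i <- match(from_seed, tree$seed_rows)
  if (is.na(i)) stop("from_seed not in tree")
  n <- length(tree$seed_rows)
  if (direction == "forward") {
    js <- if (i < n) (i + 1L):n else integer(0)
    ia <- rep(i, length(js)); ib <- js
  } else {
    js <- if (i > 1) 1L:(i - 1L) else integer(0)
    ia <- js; ib <- rep(i, length(js))
  }
  if (!length(js))
    return(data.frame(seed = integer(0), distance = numeric(0)))
  d <- .zip_pair_dist_cpp(tree$levels, tree$ptr, tree$depth,
                          as.integer(ia), as.integer(ib), tree$dir)
  data.frame(seed = tree$seed_rows[js], distance = d)
}

#' @export
print.zip_forest <- function(x, ...) {
  cat(sprintf("zip_forest: %d tree(s)\n", length(x)))
  for (tr in x)
    cat(sprintf("  dir=%s, %d seeds\n", c("fwd", "rev")[tr$dir + 1],
                length(tr$seed_rows)))
  invisible(x)
}

#' Indented debug dump of a zip forest
#'
#' @param forest a [build_zip_forest()] result.
#' @return character lines, invisibly.
#' @export
format_zip_forest <- function(forest) {
  out <- character(0)
  for (ti in seq_along(forest)) {
    tr <- forest[[ti]]
    out <- c(out, sprintf("tree %d (%s)", ti, c("forward", "reverse")[tr$dir + 1]))
    depth <- 1
    for (i in seq_len(nrow(tr$items))) {
      it <- tr$items[i, ]
      if (grepl("close", it$kind)) depth <- depth - 1
      lab <- if (it$kind == "seed" && !is.na(it$edge_to_next))
        sprintf("%s %s  --%s-->", it$kind, it$payload, format(it$edge_to_next))
      else paste(it$kind, it$payload)
      out <- c(out, paste0(strrep("  ", depth), lab))
      if (grepl("open", it$kind)) depth <- depth + 1
    }
  }
  invisible(out)
}
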