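#' Minimizer seeding parameters
#'
#' Defaults follow common long-read practice: k = 19, window w = 11. A
#' k-mer whose total count across the indexed haplotypes exceeds
#' `weight_threshold` is down-weighted so that rarer k-mers win minimizer
#' windows; a minimizer with more than `hard_hit_cap` index occurrences
#' yields no seeds at all. The short-read profile `k = 29, w = 11` is a
#' matter of configuration, not code.
#'
#' @param k k-mer length (3 to 31).
#' @param w window size, in k-mer starts.
#' @param weight_threshold occurrence count above which a k-mer's hash
#'   order is penalized.
#' @param hard_hit_cap maximum occurrences for a seed-producing minimizer.
#' @return a `minimizer_params` list.
#' @export
minimizer_params <- function(k = 19L, w = 11L, weight_threshold = 256L,
                             hard_hit_cap = 500L) {
  stopifnot(k >= 3, k <= 31, w >= 1)
  structure(list(k = as.integer(k), w = as.integer(w),
                 weight_threshold = as.integer(weight_threshold),
                 hard_hit_cap = as.integer(hard_hit_cap)),
            class = "minimizer_params")
}

#' Build a minimizer index over a graph's haplotype walks
#'
#' Every window of `w` consecutive k-mer starts in every walk spelling
#' contributes its minimum k-mer under the weighted hash order; k-mers
#' containing N are never selected. Occurrences are mapped back through
#' each walk's steps to oriented graph positions and deduplicated across
#' walks, so shared haplotype sequence is not double-counted.
#'
#' @param graph a [variation_graph()] with at least one walk.
#' @param params a [minimizer_params()].
#' @return a `minimizer_index`.
#' @export
build_minimizer_index <- function(graph, params = minimizer_params()) {
  stopifnot(length(graph$walks) >= 1)
  spells <- vapply(seq_along(graph$walks), function(i) spell_walk(graph, i), "")
  raw <- .index_minimizers_cpp(spells, params$k, params$w,
                               params$weight_threshold)
  occ <- new.env(hash = TRUE, parent = emptyenv())
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (wi in seq_along(graph$walks)) {
    pw <- raw$per_walk[[wi]]
    if (!length(pw$offset)) next
    ord <- order(pw$offset)
    pos <- walk_offset_positions(graph, graph$walks[[wi]],
                                 pw$offset[ord], params$k)
    kms <- pw$kmer[ord]; strs <- pw$strand[ord]
    for (j in seq_along(kms)) {
      key <- paste(kms[j], pos$fwd[j, 1], pos$fwd[j, 2], pos$fwd[j, 3], strs[j])
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      rec <- occ[[kms[j]]]
      row <- c(pos$fwd[j, ], pos$rev[j, ], strs[j])
      occ[[kms[j]]] <- if (is.null(rec)) matrix(row, nrow = 1) else rbind(rec, row)
    }
  }
  node_len <- integer(max(graph$nodes$id))
  node_len[graph$nodes$id] <- nchar(graph$nodes$seq)
  structure(list(occ = occ, params = params,
                 frequent = as.character(raw$frequent),
                 node_len = node_len,
                 n_kmers = length(ls(occ))),
            class = "minimizer_index")
}

# graph positions for k-mers starting at walk offsets (0-based, forward walk
# coordinates): `fwd` = first base in walk orientation; `rev` = last base of
# the k-mer with flipped orientation (the anchor when the read matches the
# opposite strand)
walk_offset_positions <- function(graph, w, offsets, k) {
  lens <- nchar(graph$nodes$seq)[match(w$steps$node, graph$nodes$id)]
  cum <- cumsum(c(0, lens))
  place <- function(os) {
    step <- findInterval(os, cum, rightmost.closed = FALSE)
    cbind(w$steps$node[step], w$steps$orient[step], os - cum[step])
  }
  fwd <- place(offsets)
  last <- place(offsets + k - 1L)
  lens_last <- nchar(graph$nodes$seq)[match(last[, 1], graph$nodes$id)]
  rev <- cbind(last[, 1], 1L - last[, 2], lens_last - 1L - last[, 3])
  list(fwd = fwd, rev = rev)
}

#' Find minimizer seeds for a read
#'
#' Read minimizers are computed with the same parameters and weighted hash
#' order as the index (including its frequent-k-mer set) and matched against
#' it. A minimizer whose index count exceeds the hard hit cap produces no
#' seeds. Each seed's graph position is oriented along the read: following
#' it forward spells the read k-mer.
#'
#' @param index a [build_minimizer_index()] result.
#' @param read read sequence (a single string).
#' @return data.frame of seeds: `read_offset` (0-based), `node`, `orient`
#'   (0 forward / 1 reverse), `offset`, `strand` (read strand of the match:
#'   0 = read k-mer matches the walk direction of the occurrence).
#' @export
find_seeds <- function(index, read) {
  p <- index$params
  empty <- data.frame(read_offset = integer(), node = integer(),
                      orient = integer(), offset = integer(),
                      node_end = integer(), orient_end = integer(),
                      offset_end = integer(), strand = integer())
  if (nchar(read) < p$k) return(empty)
  rm_ <- .read_minimizers_cpp(toupper(read), p$k, p$w, index$frequent)
  if (!length(rm_$offset)) return(empty)
  flip_pos <- function(m, lens) cbind(m[, 1], 1L - m[, 2], lens - 1L - m[, 3])
  out <- vector("list", length(rm_$offset))
  for (j in seq_along(rm_$offset)) {
    rec <- index$occ[[rm_$kmer[j]]]
    if (is.null(rec) || nrow(rec) > p$hard_hit_cap) next
    s_r <- rm_$strand[j]
    same <- rec[, 7] == s_r
    pos <- rbind(rec[same, 1:3, drop = FALSE], rec[!same, 4:6, drop = FALSE])
    # position of the k-mer's last base, read orientation: the flip of the
    # stored opposite-strand anchor
    lens_same <- index$node_len[rec[same, 4]]
    lens_opp <- index$node_len[rec[!same, 1]]
    pend <- rbind(flip_pos(rec[same, 4:6, drop = FALSE], lens_same),
                  flip_pos(rec[!same, 1:3, drop = FALSE], lens_opp))
    out[[j]] <- data.frame(read_offset = rm_$offset[j], node = pos[, 1],
                           orient = pos[, 2], offset = pos[, 3],
                           node_end = pend[, 1], orient_end = pend[, 2],
                           offset_end = pend[, 3],
                           strand = rep(c(0L, 1L), c(sum(same), sum(!same))))
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(empty)
  out <- out[order(out$read_offset, out$node, out$orient, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.minimizer_index <- function(x, ...) {
  cat(sprintf("minimizer_index: k=%d w=%d, %d distinct k-mers, %d down-weighted\n",
              x$params$k, x$params$w, x$n_kmers, length(x$frequent)))
  invisible(x)
}
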