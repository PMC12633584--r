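#' Alignment scoring parameters
#'
#' Defaults follow common long-read mapping practice: match +1,
#' mismatch -4, gap open -6, gap extend -1, X-drop 20. `wfa_max_len` is the
#' problem size above which between-seed alignment goes straight to the
#' banded graph aligner instead of the wavefront haplotype aligner;
#' `wfa_max_cost` is the wavefront memory/time proxy — exceeding it is a
#' declared failure that triggers the same fallback.
#'
#' @param match match bonus (> 0).
#' @param mismatch,gap_open,gap_extend penalties (<= 0).
#' @param xdrop X-drop threshold for tail extension.
#' @param band_padding extra band width for the banded graph aligner.
#' @param wfa_max_len maximum segment length for haplotype wavefront
#'   alignment.
#' @param wfa_max_cost maximum wavefront penalty before declaring failure
#'   (`NULL` = no limit).
#' @return a `scoring_params` list.
#' @export
scoring_params <- function(match = 1, mismatch = -4, gap_open = -6,
                           gap_extend = -1, xdrop = 20, band_padding = 10,
                           wfa_max_len = 8192, wfa_max_cost = NULL) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0,
            xdrop > 0, band_padding >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, xdrop = xdrop,
                 band_padding = band_padding, wfa_max_len = wfa_max_len,
                 wfa_max_cost = wfa_max_cost),
            class = "scoring_params")
}

# penalty-space transform making min-cost global WFA equivalent to
# max-score alignment: x = 2(M+|mm|), o = 2|go|, e = 2|ge| + M
wfa_penalties <- function(sc) {
  list(x = 2 * (sc$match - sc$mismatch), o = -2 * sc$gap_open,
       e = -2 * sc$gap_extend + sc$match)
}

cigar_df <- function(cig) {
  if (is.null(cig)) return(data.frame(op = character(0), len = integer(0)))
  data.frame(op = as.character(cig$op), len = as.integer(cig$len))
}

cigar_score <- function(edits, sc) {
  s <- 0
  for (i in seq_len(nrow(edits))) {
    l <- edits$len[i]
    s <- s + switch(edits$op[i],
                    "=" = sc$match * l,
                    "X" = sc$mismatch * l,
                    "I" = sc$gap_open + sc$gap_extend * l,
                    "D" = sc$gap_open + sc$gap_extend * l)
  }
  s
}

#' Pairwise sequence alignment via the wavefront algorithm
#'
#' `mode = "global"` computes an optimal gap-affine global alignment with a
#' wavefront search in an equivalent penalty space; the score is identical
#' to a full dynamic-programming matrix. `mode = "anchored_prefix"` pins
#' the alignment start and takes the best-scoring end anywhere (used for
#' read tails against haplotype continuations); it is computed by an
#' extension DP.
#'
#' @param query,target DNA strings.
#' @param scoring a [scoring_params()].
#' @param mode `"global"` or `"anchored_prefix"`.
#' @return list with `ok` (FALSE = declared failure: the wavefront cost
#'   exceeded `wfa_max_cost`), `score`, `edits` (data.frame `op`/`len`
#'   with `=`, `X`, `I` read-insertion, `D` read-deletion) and, for the
#'   anchored mode, `q_end`/`t_end`.
#' @export
wfa_align <- function(query, target, scoring = scoring_params(),
                      mode = c("global", "anchored_prefix")) {
  mode <- match.arg(mode)
  query <- toupper(query); target <- toupper(target)
  n <- nchar(query); m <- nchar(target)
  if (mode == "anchored_prefix") {
    r <- .extend_dp_cpp(query, target, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend, -1)
    return(list(ok = TRUE, score = r$score, edits = cigar_df(r$cigar),
                q_end = r$q_end, t_end = r$t_end))
  }
  if (n == 0 && m == 0)
    return(list(ok = TRUE, score = 0, edits = cigar_df(NULL)))
  if (n == 0)
    return(list(ok = TRUE, score = scoring$gap_open + scoring$gap_extend * m,
                edits = data.frame(op = "D", len = m)))
  if (m == 0)
    return(list(ok = TRUE, score = scoring$gap_open + scoring$gap_extend * n,
                edits = data.frame(op = "I", len = n)))
  p <- wfa_penalties(scoring)
  max_cost <- if (is.null(scoring$wfa_max_cost)) Inf else scoring$wfa_max_cost
  r <- .wfa_global_cpp(query, target, p$x, p$o, p$e, max_cost)
  if (!isTRUE(r$ok)) return(list(ok = FALSE, score = NA_real_,
                                 edits = cigar_df(NULL)))
  score <- (scoring$match * (n + m) - r$cost) / 2
  list(ok = TRUE, score = score, edits = cigar_df(r$cigar))
}

#' Banded global alignment of a read segment against the graph
#'
#' Aligns an entire read segment between two anchored graph positions,
#' exploring the graph by unrolling node visits into layers by graph
#' offset (so cycles are expanded only as far as the band allows) and
#' running an affine-gap DP restricted to the band
#' `|graph offset - read offset| <= band`.
#'
#' @param read_segment read bases between the anchors.
#' @param graph a [variation_graph()].
#' @param start_pos [graph_pos()] of the last anchored base before the
#'   segment (alignment starts just after it).
#' @param end_pos [graph_pos()] of the first anchored base after the
#'   segment (alignment ends just before it; must be reachable).
#' @param scoring a [scoring_params()].
#' @param band band width; the caller should use at least
#'   `|read length - minimum graph distance| + band_padding`.
#' @return list with `walk` (data.frame `node`, `orient` of visited
#'   nodes), `edits`, `score`.
#' @export
banded_graph_global <- function(read_segment, graph, start_pos, end_pos,
                                scoring = scoring_params(), band = NULL) {
  n <- max(graph$nodes$id)
  seqs <- character(n)
  seqs[graph$nodes$id] <- graph$nodes$seq
  if (is.null(band)) band <- nchar(read_segment) + scoring$band_padding
  o_max <- nchar(read_segment) + band + 1
  r <- .graph_align_cpp(toupper(read_segment), n, edge_matrix(graph), seqs,
                        start_pos$node, start_pos$orient, start_pos$offset,
                        TRUE, end_pos$node, end_pos$orient, end_pos$offset,
                        scoring$match, scoring$mismatch, scoring$gap_open,
                        scoring$gap_extend, band, -1, as.integer(o_max))
  if (!isTRUE(r$ok)) stop("end position unreachable within the band")
  list(walk = data.frame(node = r$walk_nodes, orient = r$walk_dirs),
       edits = cigar_df(r$cigar), score = r$score)
}

#' X-drop tail extension against the graph
#'
#' Extends a read tail from an anchored position into the graph, stopping
#' once the score falls more than X below the best seen; the unextended
#' remainder is soft-clipped. `direction = "left"` extends leftwards by
#' aligning the reverse complement against the mirrored anchor.
#'
#' @param read_tail tail bases, in read orientation (for `"left"` the bases
#'   before the anchor, for `"right"` the bases after it).
#' @param graph a [variation_graph()].
#' @param anchor_pos [graph_pos()] of the anchored base adjacent to the
#'   tail.
#' @param direction `"right"` or `"left"`.
#' @param scoring a [scoring_params()].
#' @return list with `walk`, `edits`, `score`, `aligned` (number of tail
#'   bases aligned; the rest are clipped). For `"left"`, walk and edits are
#'   given in read orientation (walk ending at the anchor).
#' @export
xdrop_tail <- function(read_tail, graph, anchor_pos,
                       direction = c("right", "left"),
                       scoring = scoring_params()) {
  direction <- match.arg(direction)
  n <- max(graph$nodes$id)
  seqs <- character(n)
  seqs[graph$nodes$id] <- graph$nodes$seq
  lens <- nchar(seqs)
  if (direction == "left") {
    tail_seq <- reverse_complement(read_tail)
    anchor <- graph_pos(anchor_pos$node, c("+", "-")[2 - anchor_pos$orient],
                        lens[anchor_pos$node] - 1L - anchor_pos$offset)
  } else {
    tail_seq <- toupper(read_tail)
    anchor <- anchor_pos
  }
  o_max <- nchar(tail_seq) + ceiling(scoring$xdrop / -min(-1, scoring$gap_extend)) + 50
  r <- .graph_align_cpp(tail_seq, n, edge_matrix(graph), seqs,
                        anchor$node, anchor$orient, anchor$offset,
                        FALSE, 0L, 0L, 0L,
                        scoring$match, scoring$mismatch, scoring$gap_open,
                        scoring$gap_extend, 0, scoring$xdrop,
                        as.integer(o_max))
  walk <- data.frame(node = r$walk_nodes, orient = r$walk_dirs)
  edits <- cigar_df(r$cigar)
  if (direction == "left" && nrow(walk)) {
    walk <- data.frame(node = rev(walk$node), orient = 1L - rev(walk$orient))
    edits <- edits[rev(seq_len(nrow(edits))), , drop = FALSE]
    rownames(edits) <- NULL
  }
  list(walk = walk, edits = edits, score = r$score, aligned = r$q_end)
}

# --- haplotype context: map graph positions to walk coordinates ------------

# every walk in both directions, with cumulative starts and spelling
hap_contexts <- function(graph) {
  ctxs <- list()
  for (wi in seq_along(graph$walks)) {
    for (d in 0:1) {
      w <- if (d == 0) graph$walks[[wi]] else reverse_walk(graph$walks[[wi]])
      lens <- nchar(graph$nodes$seq)[match(w$steps$node, graph$nodes$id)]
      stepmap <- split(seq_len(nrow(w$steps)),
                       paste(w$steps$node, w$steps$orient))
      ctxs[[length(ctxs) + 1L]] <- list(
        walk = wi, dir = d, steps = w$steps, lens = lens,
        cum = cumsum(c(0, lens)), spell = spell_walk(graph, w),
        stepmap = stepmap)
    }
  }
  ctxs
}

# walk coordinates of a graph position within a context (0-based; possibly
# several for repeated node visits)
ctx_coords <- function(ctx, pos) {
  hits <- ctx$stepmap[[paste(pos$node, pos$orient)]]
  if (is.null(hits)) return(numeric(0))
  ctx$cum[hits] + pos$offset
}

# position of a context coordinate (0-based) as a graph position in the
# context's direction
ctx_pos_at <- function(ctx, coord) {
  step <- findInterval(coord, ctx$cum, rightmost.closed = FALSE)
  graph_pos(ctx$steps$node[step],
            c("+", "-")[ctx$steps$orient[step] + 1],
            coord - ctx$cum[step])
}

# walk steps covering context coordinates [a, b] (0-based, inclusive)
ctx_slice <- function(ctx, a, b) {
  if (b < a) return(data.frame(node = integer(0), orient = integer(0)))
  i1 <- findInterval(a, ctx$cum, rightmost.closed = FALSE)
  i2 <- findInterval(b, ctx$cum, rightmost.closed = FALSE)
  ctx$steps[i1:i2, c("node", "orient"), drop = FALSE]
}

flip_gp <- function(pos, node_len) {
  graph_pos(pos$node, c("+", "-")[2 - pos$orient],
            node_len[pos$node] - 1L - pos$offset)
}

seed_gp <- function(s, what = c("start", "end")) {
  what <- match.arg(what)
  if (what == "start") graph_pos(s$node, c("+", "-")[s$orient + 1], s$offset)
  else graph_pos(s$node_end, c("+", "-")[s$orient_end + 1], s$offset_end)
}

# find a haplotype context spelling an anchor's whole k-mer (both endpoint
# positions must lie on the walk and the walk must spell the read k-mer —
# a different allele can share the endpoints); returns list(ctx index,
# coord of the k-mer start) or NULL
anchor_context <- function(ctxs, s, k, kmer) {
  ps <- seed_gp(s, "start"); pe <- seed_gp(s, "end")
  for (ci in seq_along(ctxs)) {
    cs <- ctx_coords(ctxs[[ci]], ps)
    if (!length(cs)) next
    ce <- ctx_coords(ctxs[[ci]], pe)
    for (t0 in cs) {
      if (!((t0 + k - 1) %in% ce)) next
      if (substr(ctxs[[ci]]$spell, t0 + 1, t0 + k) == kmer)
        return(list(ctx = ci, coord = t0))
    }
  }
  NULL
}

#' Extend a seed chain into a base-level graph alignment
#'
#' Between consecutive anchor seeds the read segment is aligned by the
#' wavefront aligner against each haplotype spelling consistent with both
#' flanking anchors, keeping the best; if no such haplotype exists, the
#' segment is longer than `wfa_max_len`, or the wavefront aligner declares
#' failure, the banded global graph aligner is used instead. Tails beyond
#' the first and last anchors are extended against haplotype continuations
#' with the X-drop rule, falling back to the graph X-drop aligner;
#' unextended tail bases are soft-clipped.
#'
#' @param chain a `chain_result` from [chain_seeds()].
#' @param read the full read sequence.
#' @param graph a [variation_graph()].
#' @param index a [build_distance_index()] result.
#' @param scoring a [scoring_params()].
#' @param ctxs haplotype contexts from `hap_contexts(graph)` (recomputed if
#'   missing; pass them when aligning many reads).
#' @return a `graph_alignment`: `walk` (node/orient data.frame),
#'   `q_start`/`q_end` (aligned read interval, 0-based half-open),
#'   `p_start`/`p_end` (aligned interval on the walk spelling), `edits`,
#'   `score`, `read_len`; or `NULL` when no anchor could be placed.
#' @export
extend_chain <- function(chain, read, graph, index, scoring = scoring_params(),
                         ctxs = NULL) {
  if (is.null(ctxs)) ctxs <- hap_contexts(graph)
  seeds <- chain$seeds
  k <- if (!is.null(seeds$len)) seeds$len[1] else index$tree$k
  read <- toupper(read)

  # anchor selection: non-overlapping seeds with a haplotype path and
  # finite end-to-start graph distances
  anchors <- list()
  last_end_pos <- NULL; last_off <- -Inf
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (s$read_offset < last_off + k) next
    actx <- anchor_context(ctxs, s, k,
                           substr(read, s$read_offset + 1, s$read_offset + k))
    if (is.null(actx)) next
    if (length(anchors)) {
      d <- min_distance(index, seed_gp(anchors[[length(anchors)]]$seed, "end"),
                        seed_gp(s, "start"))
      # anchors must not overlap on the graph (d = 0 means the previous
      # k-mer's last base is this one's first base)
      if (!is.finite(d) || d < 1) next
    }
    anchors[[length(anchors) + 1L]] <- list(seed = s, ctx = actx$ctx,
                                            coord = actx$coord)
    last_off <- s$read_offset
  }
  if (!length(anchors)) return(NULL)

  walk <- data.frame(node = integer(0), orient = integer(0))
  edits <- data.frame(op = character(0), len = integer(0))
  score <- 0
  p_head <- 0L
  node_len <- index$node_len
  append_edits <- function(e2) {
    for (r in seq_len(nrow(e2))) {
      ne <- nrow(edits)
      if (ne > 0 && edits$op[ne] == e2$op[r])
        edits$len[ne] <<- edits$len[ne] + e2$len[r]
      else edits[ne + 1L, ] <<- list(e2$op[r], e2$len[r])
    }
  }
  # merge-aware walk append: a piece whose first node equals the current
  # last node continues the same visit only if that visit is not yet fully
  # consumed — otherwise (tandem loops) it is a genuine second visit
  append_walk <- function(w2) {
    if (!nrow(w2)) return()
    if (nrow(walk)) {
      consumed <- p_head + sum(edits$len[edits$op %in% c("=", "X", "D")])
      before_last <- sum(node_len[walk$node]) - node_len[walk$node[nrow(walk)]]
      filled <- consumed - before_last
      if (w2$node[1] == walk$node[nrow(walk)] &&
          w2$orient[1] == walk$orient[nrow(walk)] &&
          filled < node_len[walk$node[nrow(walk)]])
        w2 <- w2[-1, , drop = FALSE]
    }
    if (nrow(w2)) walk <<- rbind(walk, w2)
  }

  # left tail
  a1 <- anchors[[1]]
  q_start <- a1$seed$read_offset
  if (q_start > 0) {
    lt <- align_tail(read, a1, "left", graph, index, scoring, ctxs, k)
    q_start <- a1$seed$read_offset - lt$aligned
    p_head <- lt$head_offset
    append_walk(lt$walk)
    append_edits(lt$edits)
    score <- score + lt$score
  }

  # anchors and between-anchor segments
  for (ai in seq_along(anchors)) {
    a <- anchors[[ai]]
    ctx <- ctxs[[a$ctx]]
    aw <- ctx_slice(ctx, a$coord, a$coord + k - 1L)
    if (!nrow(walk)) p_head <- ctx_pos_at(ctx, a$coord)$offset
    append_walk(aw)
    append_edits(data.frame(op = "=", len = k))
    score <- score + k * scoring$match
    if (ai == length(anchors)) break
    b <- anchors[[ai + 1]]
    seg <- align_segment(read, a, b, graph, index, scoring, ctxs, k)
    append_walk(seg$walk)
    append_edits(seg$edits)
    score <- score + seg$score
  }

  # right tail
  alast <- anchors[[length(anchors)]]
  q_end <- alast$seed$read_offset + k
  if (q_end < nchar(read)) {
    rt <- align_tail(read, alast, "right", graph, index, scoring, ctxs, k)
    q_end <- q_end + rt$aligned
    append_walk(rt$walk)
    append_edits(rt$edits)
    score <- score + rt$score
  }

  rownames(walk) <- NULL
  plen_total <- sum(node_len[walk$node])
  g_bases <- sum(edits$len[edits$op %in% c("=", "X", "D")])
  p_start <- p_head
  structure(list(walk = walk, q_start = q_start, q_end = q_end,
                 p_start = p_start, p_end = p_start + g_bases,
                 path_len = plen_total, edits = edits, score = score,
                 read_len = nchar(read), dir = chain$dir),
            class = "graph_alignment")
}

# align one between-anchor read segment (haplotype WFA, graph fallback)
align_segment <- function(read, a, b, graph, index, scoring, ctxs, k) {
  off_a <- a$seed$read_offset; off_b <- b$seed$read_offset
  q <- substr(read, off_a + k + 1L, off_b)
  end_a <- seed_gp(a$seed, "end"); start_b <- seed_gp(b$seed, "start")
  d_between <- min_distance(index, end_a, start_b) - 1

  # haplotype spellings consistent with both anchors
  cands <- list()
  for (ci in seq_along(ctxs)) {
    ctx <- ctxs[[ci]]
    ce <- ctx_coords(ctx, end_a); cs <- ctx_coords(ctx, start_b)
    for (te in ce) for (ts in cs) {
      tl <- ts - te - 1
      if (tl < 0 || tl > scoring$wfa_max_len) next
      if (tl > 3 * max(10, nchar(q))) next   # implausibly long detour
      cands[[length(cands) + 1L]] <- list(ctx = ci, te = te, ts = ts, len = tl)
    }
  }
  if (length(cands)) {
    lens <- vapply(cands, `[[`, 0, "len")
    cands <- cands[order(abs(lens - nchar(q)))]
    cands <- cands[!duplicated(vapply(cands, function(cc)
      substr(ctxs[[cc$ctx]]$spell, cc$te + 2, cc$ts), ""))]
    cands <- head(cands, 8)
    best <- NULL
    for (cc in cands) {
      target <- substr(ctxs[[cc$ctx]]$spell, cc$te + 2, cc$ts)
      r <- wfa_align(q, target, scoring, "global")
      if (isTRUE(r$ok) && (is.null(best) || r$score > best$score))
        best <- list(score = r$score, edits = r$edits, cc = cc)
    }
    if (!is.null(best)) {
      cc <- best$cc
      w <- if (cc$len > 0) ctx_slice(ctxs[[cc$ctx]], cc$te + 1, cc$ts - 1)
           else data.frame(node = integer(0), orient = integer(0))
      return(list(walk = w, edits = best$edits, score = best$score))
    }
  }
  # graph fallback; widen the band once if the end proves unreachable
  band <- abs(nchar(q) - max(0, d_between)) + scoring$band_padding +
    ceiling(0.2 * nchar(q))
  g <- tryCatch(banded_graph_global(q, graph, end_a, start_b, scoring, band),
                error = function(e)
                  banded_graph_global(q, graph, end_a, start_b, scoring,
                                      2 * band + max(0, d_between) + 20))
  w <- g$walk
  if (nrow(w) >= 1) w <- w[-1, , drop = FALSE]            # the anchor nodes
  if (nrow(w) >= 1) w <- w[-nrow(w), , drop = FALSE]
  list(walk = w, edits = g$edits, score = g$score)
}

# align a tail with X-drop against haplotype continuations (graph X-drop
# fallback); returns walk/edits in read orientation plus head_offset (for
# left tails: offset of the alignment start within the first walk node)
align_tail <- function(read, anchor, side, graph, index, scoring, ctxs, k) {
  node_len <- index$node_len
  if (side == "right") {
    tail_seq <- substr(read, anchor$seed$read_offset + k + 1L, nchar(read))
    apos <- seed_gp(anchor$seed, "end")
  } else {
    tail_seq <- reverse_complement(substr(read, 1, anchor$seed$read_offset))
    apos <- flip_gp(seed_gp(anchor$seed, "start"), node_len)
  }
  pad <- 50L + ceiling(0.25 * nchar(tail_seq))
  cands <- list(); seen_targets <- character(0)
  for (ci in seq_along(ctxs)) {
    ctx <- ctxs[[ci]]
    for (ta in ctx_coords(ctx, apos)) {
      avail <- nchar(ctx$spell) - ta - 1
      if (avail <= 0) next
      target <- substr(ctx$spell, ta + 2, min(nchar(ctx$spell),
                                              ta + 1 + nchar(tail_seq) + pad))
      if (target %in% seen_targets) next
      seen_targets <- c(seen_targets, target)
      cands[[length(cands) + 1L]] <- list(ctx = ci, ta = ta, target = target)
      if (length(cands) >= 6) break
    }
    if (length(cands) >= 6) break
  }
  best <- NULL
  for (cc in cands) {
    # prefer a full-length tail alignment when it stays within the X-drop
    # envelope of the best local extension; otherwise soft-clip
    free <- .extend_dp_cpp(tail_seq, cc$target, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend,
                           scoring$xdrop, FALSE)
    full <- .extend_dp_cpp(tail_seq, cc$target, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend,
                           scoring$xdrop, TRUE)
    r <- if (is.finite(full$score) && full$score >= free$score - scoring$xdrop)
      full else free
    if (is.null(best) || r$score > best$score ||
        (r$score == best$score && r$q_end > best$r$q_end))
      best <- list(score = r$score, r = r, ctx = cc$ctx, ta = cc$ta)
  }
  if (is.null(best)) {
    xt <- xdrop_tail(if (side == "right") tail_seq else
                       reverse_complement(tail_seq),
                     graph, if (side == "right") apos else
                       flip_gp(apos, node_len),
                     direction = side, scoring = scoring)
    ho <- if (side == "left" && nrow(xt$walk))
      node_len[xt$walk$node[1]] - 1L  # conservative: unknown head offset
    else 0L
    return(list(walk = xt$walk, edits = xt$edits, score = xt$score,
                aligned = xt$aligned, head_offset = ho))
  }
  r <- best$r
  ctx <- ctxs[[best$ctx]]
  w <- if (r$t_end > 0) ctx_slice(ctx, best$ta + 1, best$ta + r$t_end)
       else data.frame(node = integer(0), orient = integer(0))
  e <- cigar_df(r$cigar)
  head_offset <- 0L
  if (side == "left") {
    if (r$t_end > 0) {
      last_pos <- ctx_pos_at(ctx, best$ta + r$t_end)  # farthest-left base
      head_offset <- node_len[last_pos$node] - 1L - last_pos$offset
      w <- data.frame(node = rev(w$node), orient = 1L - rev(w$orient))
    }
    e <- e[rev(seq_len(nrow(e))), , drop = FALSE]
    rownames(e) <- NULL
  }
  list(walk = w, edits = e, score = r$score, aligned = r$q_end,
       head_offset = head_offset)
}

#' @export
print.graph_alignment <- function(x, ...) {
  cat(sprintf(
    "graph_alignment: read [%d,%d)/%d, %d nodes, score %.1f\n",
    x$q_start, x$q_end, x$read_len, nrow(x$walk), x$score))
  invisible(x)
}

# recompute score and verify base-level agreement of (walk, edits) with
# the read; used by tests and by MAPQ-independent sanity checks
rescore_alignment <- function(graph, aln, read) {
  sc <- scoring_params()
  idx <- match(aln$walk$node, graph$nodes$id)
  seqs <- graph$nodes$seq[idx]
  rev <- aln$walk$orient == 1L
  seqs[rev] <- reverse_complement(seqs[rev])
  spell <- paste(seqs, collapse = "")
  gseq <- substr(spell, aln$p_start + 1, aln$p_end)
  rseq <- substr(toupper(read), aln$q_start + 1, aln$q_end)
  qi <- 0L; gi <- 0L; s <- 0
  for (i in seq_len(nrow(aln$edits))) {
    op <- aln$edits$op[i]; l <- aln$edits$len[i]
    if (op == "=") {
      if (substr(rseq, qi + 1, qi + l) != substr(gseq, gi + 1, gi + l))
        return(list(ok = FALSE, score = NA_real_))
      qi <- qi + l; gi <- gi + l; s <- s + sc$match * l
    } else if (op == "X") {
      a <- strsplit(substr(rseq, qi + 1, qi + l), "")[[1]]
      b <- strsplit(substr(gseq, gi + 1, gi + l), "")[[1]]
      if (any(a == b)) return(list(ok = FALSE, score = NA_real_))
      qi <- qi + l; gi <- gi + l; s <- s + sc$mismatch * l
    } else if (op == "I") {
      qi <- qi + l; s <- s + sc$gap_open + sc$gap_extend * l
    } else {
      gi <- gi + l; s <- s + sc$gap_open + sc$gap_extend * l
    }
  }
  ok <- (qi == nchar(rseq)) && (gi == nchar(gseq))
  list(ok = ok, score = s)
}
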