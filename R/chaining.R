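#' Chaining parameters
#'
#' The gap cost follows minimap2's shape: for a gap
#' `g = |read_gap - graph_gap|` between consecutive seeds the cost is
#' `a * g + b * log2(g)` (0 when g = 0). The default linear scale is
#' `0.01 * k` for seed length k, applied when `gap_scale` is left `NULL`.
#'
#' @param gap_scale linear gap cost scale `a`; `NULL` = 0.01 x seed length.
#' @param gap_log_scale logarithmic scale `b`.
#' @param max_lookback candidate predecessors per item, counted back in
#'   tree order (accuracy/speed knob).
#' @param max_gap read gap, graph gap or gap difference beyond which a
#'   transition is forbidden.
#' @param fragment_max_gap pass-1 read-gap limit for merging co-diagonal
#'   seeds into fragments.
#' @param top_chains number of ranked chains carried on to base-level
#'   alignment.
#' @return a `chaining_params` list.
#' @export
chaining_params <- function(gap_scale = NULL, gap_log_scale = 0.5,
                            max_lookback = 64L, max_gap = 10000,
                            fragment_max_gap = 200, top_chains = 4L) {
  stopifnot(is.null(gap_scale) || gap_scale >= 0, gap_log_scale >= 0,
            max_lookback >= 1, max_gap >= 0, fragment_max_gap >= 0,
            top_chains >= 1)
  structure(list(gap_scale = gap_scale, gap_log_scale = gap_log_scale,
                 max_lookback = as.integer(max_lookback), max_gap = max_gap,
                 fragment_max_gap = fragment_max_gap,
                 top_chains = as.integer(top_chains)),
            class = "chaining_params")
}

#' Gap cost between consecutive chained seeds
#'
#' @param read_gap distance between seed starts in the read (>= 0).
#' @param graph_gap minimum graph distance between the seed positions
#'   (`Inf` if unreachable).
#' @param params a [chaining_params()]; `gap_scale` must be set (the
#'   mapper derives it from the seed length).
#' @return non-negative cost; `Inf` forbids the transition.
#' @export
gap_cost <- function(read_gap, graph_gap, params = chaining_params(gap_scale = 0.19)) {
  stopifnot(read_gap >= 0)
  if (!is.finite(graph_gap)) return(Inf)
  g <- abs(read_gap - graph_gap)
  if (g == 0) return(0)
  params$gap_scale * g + params$gap_log_scale * log2(g)
}

#' Chain seeds through the zip code forest
#'
#' Two dynamic-programming passes: pass 1 links tree-order-consecutive
#' seeds on a common diagonal (equal read and graph gaps) into fragments;
#' pass 2 chains fragments — and every seed as a singleton, so optimality
#' is never lost to fragment boundaries — under the full gap cost. Seeds
#' must be reachable in the graph from their predecessors (infinite
#' zip-tree distances forbid transitions) and strictly increase in read
#' offset. Returns up to `top_chains` chains whose read intervals overlap
#' pairwise by at most 50%.
#'
#' @param forest a [build_zip_forest()] result built from seeds carrying a
#'   `read_offset` column (the seed table is attached to the forest).
#' @param params a [chaining_params()].
#' @param seeds optional explicit seed table (defaults to the one attached
#'   to the forest).
#' @return list of `chain_result` objects, ranked by score: each has
#'   `seeds` (seed table rows in chain order), `score`, `read_start`,
#'   `read_end`, `coverage`, `transitions` (read_gap, graph_gap per step),
#'   and the tree direction.
#' @export
chain_seeds <- function(forest, params = chaining_params(), seeds = NULL) {
  if (is.null(seeds)) seeds <- attr(forest, "seeds")
  if (is.null(seeds)) stop("no seed table attached to forest; pass `seeds`")
  if (!length(forest) || !nrow(seeds)) return(list())
  k <- if (!is.null(seeds$len)) seeds$len[1] else 19L
  a <- if (is.null(params$gap_scale)) 0.01 * k else params$gap_scale
  results <- list()
  for (tr in forest) {
    res <- chain_tree(tr, seeds, k, a, params)
    results <- c(results, res)
  }
  rank_chains(results, params$top_chains)
}

chain_tree <- function(tr, seeds, k, a, params) {
  n <- length(tr$seed_rows)
  off <- seeds$read_offset[tr$seed_rows]
  if (is.null(off) || n == 0) return(list())

  lb <- params$max_lookback
  pair_i <- pair_j <- integer(0)
  for (j in seq_len(n)) {
    is_ <- seq(max(1L, j - lb), j - 1L)
    if (j > 1) { pair_i <- c(pair_i, is_); pair_j <- c(pair_j, rep(j, length(is_))) }
  }
  gd <- if (length(pair_i))
    .zip_pair_dist_cpp(tr$levels, tr$ptr, tr$depth, pair_i, pair_j, tr$dir)
  else numeric(0)

  # pass 1: fragments from consecutive co-diagonal seeds
  frag_id <- integer(n); frag_id[1] <- 1L
  if (n > 1) {
    consec <- match(paste(1:(n - 1), 2:n), paste(pair_i, pair_j))
    for (j in 2:n) {
      d <- gd[consec[j - 1]]
      rg <- off[j] - off[j - 1]
      if (is.finite(d) && rg > 0 && rg <= params$fragment_max_gap && d == rg)
        frag_id[j] <- frag_id[j - 1]
      else frag_id[j] <- frag_id[j - 1] + 1L
    }
  }

  # pass 2 items: fragments plus singleton seeds (tree order by first seed)
  items <- list()
  for (f in unique(frag_id)) {
    mem <- which(frag_id == f)
    if (length(mem) > 1) {
      cov <- k + sum(pmin(k, diff(off[mem])))
      items[[length(items) + 1L]] <- list(first = mem[1], last = mem[length(mem)],
                                          members = mem, base = cov)
    }
  }
  for (j in seq_len(n))
    items[[length(items) + 1L]] <- list(first = j, last = j, members = j, base = k)
  ord <- order(vapply(items, `[[`, 0L, "first"),
               -vapply(items, function(x) length(x$members), 0L))
  items <- items[ord]
  m <- length(items)
  start <- vapply(items, function(x) off[x$first], 0)
  end <- vapply(items, function(x) off[x$last] + k, 0)
  base <- vapply(items, `[[`, 0, "base")

  # candidate transitions between items: end seed of i -> first seed of j
  ti <- tj <- integer(0)
  for (j in seq_len(m)) {
    is_ <- seq(max(1L, j - lb), j - 1L)
    if (j > 1) { ti <- c(ti, is_); tj <- c(tj, rep(j, length(is_))) }
  }
  tg <- if (length(ti)) {
    si <- vapply(items, `[[`, 0L, "last")[ti]
    sj <- vapply(items, `[[`, 0L, "first")[tj]
    keep_dir <- si < sj  # must advance in tree order
    d <- rep(Inf, length(ti))
    if (any(keep_dir))
      d[keep_dir] <- .zip_pair_dist_cpp(tr$levels, tr$ptr, tr$depth,
                                        si[keep_dir], sj[keep_dir], tr$dir)
    d
  } else numeric(0)

  dp <- .chain_dp_cpp(start, end, base, as.integer(ti - 1L), as.integer(tj - 1L),
                      tg, a, params$gap_log_scale, params$max_gap, FALSE)

  # assemble chain results by traceback from every item, deduped later
  out <- list()
  ord_score <- order(-dp$score, start, end)
  for (e in ord_score) {
    path <- integer(0); cur <- e
    repeat {
      path <- c(cur, path)
      p <- dp$parent[cur] + 1L
      if (p == 0L) break
      cur <- p
    }
    seed_idx <- unlist(lapply(items[path], `[[`, "members"))
    seed_idx <- seed_idx[!duplicated(seed_idx)]
    rows <- tr$seed_rows[seed_idx]
    trans <- NULL
    if (length(seed_idx) > 1) {
      d <- .zip_pair_dist_cpp(tr$levels, tr$ptr, tr$depth,
                              seed_idx[-length(seed_idx)], seed_idx[-1], tr$dir)
      trans <- data.frame(read_gap = diff(off[seed_idx]), graph_gap = d)
    }
    out[[length(out) + 1L]] <- structure(list(
      seeds = seeds[rows, , drop = FALSE],
      seed_rows = rows,
      score = dp$score[e],
      read_start = off[seed_idx[1]],
      read_end = off[seed_idx[length(seed_idx)]] + k,
      coverage = chain_coverage(off[seed_idx], k),
      transitions = trans,
      dir = tr$dir), class = "chain_result")
    if (length(out) >= 4 * 8) break  # plenty for ranking
  }
  out
}

chain_coverage <- function(offs, k) {
  if (!length(offs)) return(0)
  k + sum(pmin(k, diff(offs)))
}

rank_chains <- function(results, top_chains) {
  if (!length(results)) return(list())
  ord <- order(-vapply(results, `[[`, 0, "score"),
               -vapply(results, function(x) x$read_end - x$read_start, 0),
               vapply(results, `[[`, 0, "read_start"))
  chosen <- list()
  competing <- 0  # best filtered-out chain at a genuinely different placement
  for (i in ord) {
    r <- results[[i]]
    ok <- TRUE
    for (c0 in chosen) {
      ov <- min(r$read_end, c0$read_end) - max(r$read_start, c0$read_start)
      len <- r$read_end - r$read_start
      same <- identical(c0$seed_rows, r$seed_rows)
      if (same || (ov > 0.5 * len)) { ok <- FALSE; break }
    }
    if (ok) {
      if (length(chosen) < top_chains) chosen <- c(chosen, list(r))
    } else {
      shares <- vapply(chosen, function(c0)
        length(intersect(c0$seed_rows, r$seed_rows)) /
          max(1, length(r$seed_rows)), 0)
      if (all(shares < 0.5) && r$score > competing) {
        competing <- r$score
        attr(chosen, "competing_chain") <- r
      }
    }
  }
  attr(chosen, "competing_score") <- competing
  chosen
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("chain: %d seeds, read [%d, %d), score %.2f, coverage %d\n",
              nrow(x$seeds), x$read_start, x$read_end, x$score, x$coverage))
  invisible(x)
}
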