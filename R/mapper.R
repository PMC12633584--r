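#' Build all indexes needed to map reads against a graph
#'
#' Bundles the snarl tree, the distance index, the weighted-minimizer
#' index and the haplotype contexts, together with the parameter sets used
#' by the downstream stages.
#'
#' @param graph a [variation_graph()].
#' @param minimizer a [minimizer_params()].
#' @param chaining a [chaining_params()].
#' @param scoring a [scoring_params()].
#' @return a `graph_indexes` bundle.
#' @export
build_graph_indexes <- function(graph, minimizer = minimizer_params(),
                                chaining = chaining_params(),
                                scoring = scoring_params()) {
  tree <- decompose_snarls(graph)
  dist <- build_distance_index(graph, tree)
  mini <- build_minimizer_index(graph, minimizer)
  structure(list(graph = graph, tree = tree, dist = dist, mini = mini,
                 ctxs = hap_contexts(graph), minimizer = minimizer,
                 chaining = chaining, scoring = scoring),
            class = "graph_indexes")
}

#' @export
print.graph_indexes <- function(x, ...) {
  cat(sprintf("graph_indexes: %d nodes, %d walks, k=%d w=%d\n",
              nrow(x$graph$nodes), length(x$graph$walks),
              x$minimizer$k, x$minimizer$w))
  invisible(x)
}

#' Mapping quality from primary and competing scores
#'
#' `mapq = clamp(0, 60, round(6 (primary - best_secondary) / match))`, with
#' the best secondary defaulting to the chain score of the best unextended
#' chain, or 0 when nothing competes. The cap of 60 is the conventional
#' ceiling for confidently mapped reads.
#'
#' @param primary_score primary alignment score.
#' @param secondary_scores numeric vector of competing scores (secondary
#'   alignments and/or unextended chain scores); may be empty.
#' @param match match bonus of the scoring scheme.
#' @return integer MAPQ in `[0, 60]`.
#' @export
compute_mapq <- function(primary_score, secondary_scores = numeric(0),
                         match = 1) {
  # a competitor scoring below zero is no more evidence than no competitor
  best_sec <- max(0, secondary_scores)
  as.integer(max(0, min(60, round(6 * (primary_score - best_sec) / match))))
}

#' Map a single read
#'
#' The deterministic pipeline: minimizer seeding, zip code forest,
#' two-pass chaining, base-level extension of the top chains, ranking by
#' alignment score and MAPQ assignment. Reads with no seeds, or whose
#' chains cannot be anchored, are reported unmapped.
#'
#' @param read read sequence.
#' @param indexes a [build_graph_indexes()] bundle.
#' @param name read name recorded in the result.
#' @return a `mapping_result` with `primary` (a `graph_alignment` or
#'   `NULL`), `secondaries`, `mapq` and `counters` (per-stage statistics).
#' @export
map_read <- function(read, indexes, name = "read") {
  read <- toupper(unname(read))
  counters <- c(seeds = 0L, chains = 0L, extended = 0L)
  unmapped <- function() structure(list(name = name, read_len = nchar(read),
                                        primary = NULL, secondaries = list(),
                                        mapq = 0L, counters = counters),
                                   class = "mapping_result")
  seeds <- find_seeds(indexes$mini, read)
  counters["seeds"] <- nrow(seeds)
  if (!nrow(seeds)) return(unmapped())
  seeds$len <- indexes$minimizer$k
  forest <- build_zip_forest(seeds, index = indexes$dist, items = FALSE)
  chains <- chain_seeds(forest, indexes$chaining)
  counters["chains"] <- length(chains)
  if (!length(chains)) return(unmapped())

  chain_scores <- vapply(chains, `[[`, 0, "score")
  extend_these <- which(chain_scores >= 0.5 * max(chain_scores))
  extend_these <- head(extend_these, indexes$chaining$top_chains)
  to_extend <- chains[extend_these]
  # a strong chain at a different placement that lost the read-overlap
  # filter is the ambiguity evidence: extend it too (its alignment decides
  # whether it is a genuine alternative or the same placement rediscovered,
  # e.g. via second-copy seeds of a tandem duplication)
  comp_chain <- attr(chains, "competing_chain")
  comp_extended <- !is.null(comp_chain) &&
    comp_chain$score >= 0.5 * max(chain_scores)
  if (comp_extended) to_extend <- c(to_extend, list(comp_chain))
  alns <- list()
  for (ch in to_extend) {
    a <- tryCatch(extend_chain(ch, read, indexes$graph, indexes$dist,
                               indexes$scoring, indexes$ctxs),
                  error = function(e) NULL)
    if (!is.null(a)) alns[[length(alns) + 1L]] <- a
  }
  # collapse identical placements
  akey <- vapply(alns, function(a)
    paste(a$q_start, a$q_end, a$p_start,
          paste(a$walk$node, a$walk$orient, collapse = ";")), "")
  alns <- alns[!duplicated(akey)]
  counters["extended"] <- length(alns)
  if (!length(alns)) return(unmapped())

  ord <- order(-vapply(alns, `[[`, 0, "score"),
               -vapply(alns, function(a) a$q_end - a$q_start, 0),
               vapply(alns, `[[`, 0, "q_start"))
  alns <- alns[ord]
  primary <- alns[[1]]
  secondaries <- alns[-1]
  competing <- c(vapply(secondaries, `[[`, 0, "score"),
                 chain_scores[setdiff(seq_along(chains), extend_these)],
                 if (!comp_extended) attr(chains, "competing_score"))
  mapq <- compute_mapq(primary$score, competing, indexes$scoring$match)
  structure(list(name = name, read_len = nchar(read), primary = primary,
                 secondaries = secondaries, mapq = mapq,
                 counters = counters),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  if (is.null(x$primary)) cat(sprintf("%s: unmapped\n", x$name))
  else cat(sprintf("%s: score %.0f mapq %d, read [%d,%d)/%d\n", x$name,
                   x$primary$score, x$mapq, x$primary$q_start,
                   x$primary$q_end, x$read_len))
  invisible(x)
}

#' Map a set of reads
#'
#' @param reads named character vector of read sequences.
#' @param indexes a [build_graph_indexes()] bundle.
#' @param progress print a counter to stderr every `progress` reads
#'   (0 = silent).
#' @return list of `mapping_result` objects.
#' @export
map_reads <- function(reads, indexes, progress = 0L) {
  nm <- names(reads)
  if (is.null(nm)) nm <- sprintf("read%05d", seq_along(reads))
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    out[[i]] <- map_read(reads[[i]], indexes, nm[i])
    if (progress > 0 && i %% progress == 0)
      message(sprintf("mapped %d/%d reads", i, length(reads)))
  }
  out
}

# --- GAF --------------------------------------------------------------------

gaf_path_string <- function(graph, walk) {
  nm <- graph$nodes$name[match(walk$node, graph$nodes$id)]
  paste0(ifelse(walk$orient == 0L, ">", "<"), nm, collapse = "")
}

# cs:Z difference string (needs read and path sequences)
cs_string <- function(graph, aln, read) {
  idx <- match(aln$walk$node, graph$nodes$id)
  seqs <- graph$nodes$seq[idx]
  rev <- aln$walk$orient == 1L
  seqs[rev] <- reverse_complement(seqs[rev])
  gseq <- substr(paste(seqs, collapse = ""), aln$p_start + 1, aln$p_end)
  rseq <- substr(read, aln$q_start + 1, aln$q_end)
  qi <- 0L; gi <- 0L; out <- character(0)
  for (i in seq_len(nrow(aln$edits))) {
    op <- aln$edits$op[i]; l <- aln$edits$len[i]
    if (op == "=") {
      out <- c(out, paste0(":", l)); qi <- qi + l; gi <- gi + l
    } else if (op == "X") {
      for (j in seq_len(l))
        out <- c(out, paste0("*", tolower(substr(gseq, gi + j, gi + j)),
                             tolower(substr(rseq, qi + j, qi + j))))
      qi <- qi + l; gi <- gi + l
    } else if (op == "I") {
      out <- c(out, paste0("+", tolower(substr(rseq, qi + 1, qi + l))))
      qi <- qi + l
    } else {
      out <- c(out, paste0("-", tolower(substr(gseq, gi + 1, gi + l))))
      gi <- gi + l
    }
  }
  paste(out, collapse = "")
}

#' Write mapping results as GAF
#'
#' One line per alignment: the standard 12 GAF columns plus `AS:i`
#' (alignment score), `cg:Z` (CIGAR over `=`,`X`,`I`,`D`) and `cs:Z`
#' (difference string) tags. Unmapped reads produce no line.
#'
#' @param results list of `mapping_result` from [map_reads()] (a single
#'   result is accepted), or a list of reads' results.
#' @param graph the [variation_graph()] mapped against.
#' @param reads named character vector of read sequences (for the cs tag).
#' @param path output file, or `NULL` to return the lines.
#' @param secondary also emit secondary alignments.
#' @return the GAF lines, invisibly.
#' @export
write_gaf <- function(results, graph, reads, path = NULL, secondary = FALSE) {
  if (inherits(results, "mapping_result")) results <- list(results)
  lines <- character(0)
  for (res in results) {
    if (is.null(res$primary)) next
    alns <- c(list(res$primary), if (secondary) res$secondaries)
    read <- toupper(unname(reads[[res$name]]))
    for (ai in seq_along(alns)) {
      a <- alns[[ai]]
      matches <- sum(a$edits$len[a$edits$op == "="])
      block <- sum(a$edits$len)
      cg <- paste0(a$edits$len, a$edits$op, collapse = "")
      lines <- c(lines, paste(
        res$name, res$read_len, a$q_start, a$q_end, "+",
        gaf_path_string(graph, a$walk), a$path_len, a$p_start, a$p_end,
        matches, block, if (ai == 1) res$mapq else 255L,
        sprintf("AS:i:%d", as.integer(round(a$score))),
        sprintf("cg:Z:%s", cg),
        sprintf("cs:Z:%s", cs_string(graph, a, read)),
        sep = "\t"))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a GAF file back into a table
#'
#' @param x GAF file path or character vector of lines.
#' @param graph the [variation_graph()] the alignments refer to (used to
#'   map segment names back to node ids).
#' @return data.frame with one row per line: `name`, `qlen`, `qstart`,
#'   `qend`, `path` (string), `path_len`, `path_start`, `path_end`,
#'   `matches`, `block`, `mapq`, `score`, `cigar`, plus list columns
#'   `path_nodes` and `path_orients`.
#' @export
read_gaf <- function(x, graph) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  id_of <- setNames(graph$nodes$id, graph$nodes$name)
  out <- data.frame(name = character(length(lines)), qlen = integer(length(lines)),
                    qstart = integer(length(lines)), qend = integer(length(lines)),
                    strand = character(length(lines)), path = character(length(lines)),
                    path_len = integer(length(lines)), path_start = integer(length(lines)),
                    path_end = integer(length(lines)), matches = integer(length(lines)),
                    block = integer(length(lines)), mapq = integer(length(lines)),
                    score = integer(length(lines)), cigar = character(length(lines)))
  pn <- vector("list", length(lines)); po <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    toks <- regmatches(f[6], gregexpr("[<>][^<>]+", f[6]))[[1]]
    nodes <- unname(id_of[substring(toks, 2)])
    orients <- ifelse(substring(toks, 1, 1) == ">", 0L, 1L)
    tags <- f[-(1:12)]
    as_tag <- sub("^AS:i:", "", grep("^AS:i:", tags, value = TRUE))
    cg_tag <- sub("^cg:Z:", "", grep("^cg:Z:", tags, value = TRUE))
    out[i, ] <- list(f[1], as.integer(f[2]), as.integer(f[3]), as.integer(f[4]),
                     f[5], f[6], as.integer(f[7]), as.integer(f[8]),
                     as.integer(f[9]), as.integer(f[10]), as.integer(f[11]),
                     as.integer(f[12]),
                     if (length(as_tag)) as.integer(as_tag) else NA_integer_,
                     if (length(cg_tag)) cg_tag else NA_character_)
    pn[[i]] <- nodes; po[[i]] <- orients
  }
  out$path_nodes <- pn
  out$path_orients <- po
  out
}
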