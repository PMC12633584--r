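#' Parse a GFA v1.1 graph
#'
#' Reads S (segment), L (link), P (path) and W (walk) lines. Segment names
#' are mapped to dense integer node ids in order of appearance, with the
#' original names preserved in `nodes$name` and used again on output. P-line
#' and W-line haplotypes are both accepted; a W line's sample, haplotype
#' index and contig are concatenated into the walk name with `#` separators
#' (PanSN style) and its coordinates are kept as walk metadata. Link
#' overlaps must be `0M` or `*`. Edges present in L lines but supported by
#' no walk are retained and flagged `haplotype = FALSE`.
#'
#' @param x a file path, a single string containing GFA text, or a character
#'   vector of lines.
#' @return a [variation_graph()]. An empty input yields an empty graph.
#' @export
parse_gfa <- function(x) {
  lines <- gfa_lines(x)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_variation_graph())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(fields, `[[`, "", 1L)

  s_idx <- which(types == "S")
  seg_names <- character(0)
  seqs <- character(0)
  for (i in s_idx) {
    f <- fields[[i]]
    if (length(f) < 3L) stop(sprintf("GFA parse error at line %d: malformed S line", i))
    seg_names <- c(seg_names, f[2L])
    seqs <- c(seqs, toupper(f[3L]))
  }
  if (anyDuplicated(seg_names)) stop("duplicate segment names in GFA")
  id_of <- setNames(seq_along(seg_names), seg_names)

  seg_id <- function(name, line) {
    id <- id_of[name]
    if (is.na(id)) stop(sprintf("GFA parse error at line %d: unknown segment '%s'", line, name))
    unname(id)
  }

  l_edges <- empty_edges()
  for (i in which(types == "L")) {
    f <- fields[[i]]
    if (length(f) < 5L) stop(sprintf("GFA parse error at line %d: malformed L line", i))
    if (!(f[2L] %in% seg_names) || !(f[4L] %in% seg_names))
      stop(sprintf("GFA parse error at line %d: L line references unknown segment", i))
    if (!(f[3L] %in% c("+", "-")) || !(f[5L] %in% c("+", "-")))
      stop(sprintf("GFA parse error at line %d: bad orientation", i))
    ov <- if (length(f) >= 6L) f[6L] else "*"
    if (!(ov %in% c("0M", "*")))
      stop(sprintf("GFA parse error at line %d: only 0M or * overlaps supported", i))
    l_edges <- rbind(l_edges, data.frame(
      from = seg_id(f[2L], i), from_side = if (f[3L] == "+") 1L else 0L,
      to = seg_id(f[4L], i), to_side = if (f[5L] == "+") 0L else 1L))
  }

  walks <- list()
  for (i in which(types == "P")) {
    f <- fields[[i]]
    if (length(f) < 3L) stop(sprintf("GFA parse error at line %d: malformed P line", i))
    steps <- strsplit(f[3L], ",", fixed = TRUE)[[1L]]
    m <- regmatches(steps, regexec("^(.*)([+-])$", steps))
    if (any(lengths(m) != 3L))
      stop(sprintf("GFA parse error at line %d: bad P-line step", i))
    nodes <- vapply(m, function(z) seg_id(z[2L], i), 0)
    ors <- vapply(m, `[[`, "", 3L)
    walks <- c(walks, list(walk(f[2L], nodes, ors)))
  }

  for (i in which(types == "W")) {
    f <- fields[[i]]
    if (length(f) < 7L) stop(sprintf("GFA parse error at line %d: malformed W line", i))
    wstr <- f[7L]
    toks <- regmatches(wstr, gregexpr("[<>][^<>]+", wstr))[[1L]]
    if (!length(toks) || paste(toks, collapse = "") != wstr)
      stop(sprintf("GFA parse error at line %d: bad walk string", i))
    nodes <- vapply(toks, function(t) seg_id(substring(t, 2L), i), 0)
    ors <- ifelse(substring(toks, 1L, 1L) == ">", "+", "-")
    nm <- paste(f[2L], f[3L], f[4L], sep = "#")
    walks <- c(walks, list(walk(nm, nodes, ors, wline = list(
      sample = f[2L], hap_index = f[3L], seq_id = f[4L],
      seq_start = f[5L], seq_end = f[6L]))))
  }

  bad <- !(types %in% c("S", "L", "P", "W", "H", "#"))
  if (any(bad))
    stop(sprintf("GFA parse error at line %d: unsupported record type '%s'",
                 which(bad)[1L], types[which(bad)[1L]]))

  nodes <- data.frame(id = seq_along(seg_names), seq = seqs, name = seg_names)
  variation_graph(nodes, walks, extra_edges = l_edges)
}

gfa_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) return(readLines(x))
  if (length(x) == 1L && grepl("\n", x)) return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  as.character(x)
}

empty_variation_graph <- function() {
  structure(list(
    nodes = data.frame(id = integer(), seq = character(), name = character()),
    edges = cbind(empty_edges(), data.frame(haplotype = logical())),
    walks = list()),
    class = "variation_graph")
}

#' Serialize a variation graph to GFA v1.1
#'
#' Walks parsed from W lines are written back as W lines (their coordinate
#' metadata preserved); all other walks are written as P lines. Parsing the
#' output reproduces the graph exactly.
#'
#' @param graph a [variation_graph()].
#' @param path optional output file; if `NULL` the GFA text lines are
#'   returned invisibly.
#' @return character vector of GFA lines, invisibly.
#' @export
write_gfa <- function(graph, path = NULL) {
  out <- c("H\tVN:Z:1.1")
  nm <- setNames(graph$nodes$name, graph$nodes$id)
  if (nrow(graph$nodes))
    out <- c(out, sprintf("S\t%s\t%s", graph$nodes$name, graph$nodes$seq))
  e <- graph$edges
  if (nrow(e)) {
    out <- c(out, sprintf("L\t%s\t%s\t%s\t%s\t0M",
                          nm[as.character(e$from)], ifelse(e$from_side == 1L, "+", "-"),
                          nm[as.character(e$to)], ifelse(e$to_side == 0L, "+", "-")))
  }
  for (w in graph$walks) {
    o <- w$steps$orient
    if (is.null(w$wline)) {
      out <- c(out, sprintf("P\t%s\t%s\t*", w$name,
                            paste0(nm[as.character(w$steps$node)],
                                   ifelse(o == 0L, "+", "-"), collapse = ",")))
    } else {
      wl <- w$wline
      out <- c(out, sprintf("W\t%s\t%s\t%s\t%s\t%s\t%s",
                            wl$sample, wl$hap_index, wl$seq_id, wl$seq_start, wl$seq_end,
                            paste0(ifelse(o == 0L, ">", "<"),
                                   nm[as.character(w$steps$node)], collapse = "")))
    }
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
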