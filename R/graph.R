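# Graph representation and file I/O.
#
# Graphs are plain igraph objects: undirected, simple (no loops or multi
# edges), with every vertex carrying a `name` attribute. Node identifiers are
# opaque strings preserved verbatim from the input file; all functions treat
# graphs as immutable values.

#' Validate a graph for use with senet
#'
#' Checks that `g` is an undirected, simple igraph object with named
#' vertices. All user-facing functions call this on entry.
#'
#' @param g An igraph object.
#' @return The graph, invisibly, with vertex names guaranteed present.
#' @keywords internal
check_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph object", call. = FALSE)
  if (igraph::is_directed(g)) stop("`g` must be undirected", call. = FALSE)
  if (any(igraph::which_loop(g)) || any(igraph::which_multiple(g)))
    stop("`g` must be simple: no self-loops or duplicate edges", call. = FALSE)
  if (is.null(igraph::V(g)$name))
    stop("`g` must have named vertices", call. = FALSE)
  invisible(g)
}

#' Order node identifiers deterministically
#'
#' Node ids are opaque strings. When every id parses as a number they are
#' ordered numerically; when every id is a common prefix plus a number
#' (`v1`, `v2`, ..., `v12`) they are ordered by prefix then number; any
#' other ids fall back to lexicographic radix order (locale independent).
#' Used for component ordering and all tie-breaks so output is
#' reproducible.
#'
#' @param ids Character vector of node identifiers.
#' @return An integer permutation, as from [order()].
#' @keywords internal
order_node_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) return(order(num, ids, method = "radix"))
  m <- regmatches(ids, regexec("^(\\D*)(\\d+)$", ids))
  if (all(lengths(m) == 3L)) {
    pre <- vapply(m, `[`, "", 2L)
    suf <- as.numeric(vapply(m, `[`, "", 3L))
    return(order(pre, suf, ids, method = "radix"))
  }
  order(ids, method = "radix")
}

#' Build a graph from an edge matrix
#'
#' @param edges Two-column character matrix, one edge per row.
#' @param nodes Optional character vector of node ids; ids appearing only
#'   here become isolated nodes.
#' @param quiet Suppress the message about dropped self-loops/duplicates.
#' @return An undirected simple igraph object.
#' @export
graph_from_edges <- function(edges, nodes = NULL, quiet = FALSE) {
  edges <- matrix(as.character(edges), ncol = 2)
  loops <- edges[, 1] == edges[, 2]
  n_loops <- sum(loops)
  edges <- edges[!loops, , drop = FALSE]
  # canonicalize unordered pairs, then drop duplicates (incl. reversed)
  key <- apply(edges, 1L, function(e) paste(sort(e), collapse = "\r"))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  ids <- unique(c(t(edges), as.character(nodes)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  if (!quiet && (n_loops > 0 || n_dup > 0))
    message(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_loops, n_dup))
  g
}

#' Read an undirected graph from an edge-list file
#'
#' Supports plain edge lists (two whitespace-separated node ids per line,
#' `#` comments) and Konect-style TSV files (`%`-prefixed metadata header
#' lines; only the first two columns are read). Self-loops and duplicate
#' edges -- including reversed duplicates -- are dropped with a message.
#' Node identifiers are kept exactly as written.
#'
#' @param path Path to the edge-list file.
#' @param dialect `"plain"` or `"konect"`.
#' @param quiet Suppress the dropped-edge message.
#' @return An undirected simple igraph object.
#' @examples
#' f <- tempfile()
#' writeLines(c("1 2", "2 3"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g)  # 3
#' @export
read_edge_list <- function(path, dialect = c("plain", "konect"), quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|%|#)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0)
    stop(sprintf("malformed line %d in %s: expected at least 2 tokens",
                 idx[bad[1]], path), call. = FALSE)
  edges <- t(vapply(toks, function(tk) tk[1:2], character(2)))
  graph_from_edges(edges, quiet = quiet)
}

#' Write a graph as an edge-list file
#'
#' Round-trips with [read_edge_list()]: reading the written file yields a
#' graph with the same labelled edge set. Isolated nodes cannot be
#' represented in an edge list and trigger a warning.
#'
#' @param g Graph to write.
#' @param path Output path.
#' @param dialect `"plain"` (space separated) or `"konect"` (tab separated,
#'   with a `%` header line).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, dialect = c("plain", "konect")) {
  dialect <- match.arg(dialect)
  check_graph(g)
  if (any(igraph::degree(g) == 0))
    warning("isolated nodes are not representable in an edge list and were omitted")
  el <- igraph::as_edgelist(g, names = TRUE)
  sep <- if (dialect == "konect") "\t" else " "
  lines <- if (nrow(el) > 0) paste(el[, 1], el[, 2], sep = sep) else character(0)
  if (dialect == "konect") lines <- c("% sym unweighted", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Remove a node and its incident edges
#'
#' Returns a new graph; the input is unchanged.
#'
#' @param g Graph.
#' @param v A node identifier present in `g`.
#' @return The graph without `v`.
#' @export
remove_node <- function(g, v) {
  check_graph(g)
  v <- as.character(v)
  if (!v %in% igraph::V(g)$name)
    stop("unknown node: ", v, call. = FALSE)
  igraph::delete_vertices(g, v)
}

#' Connected components of a graph
#'
#' Decomposes `g` into its connected components, reported in a
#' deterministic order (ascending by the smallest node id each contains).
#' Singleton components are included with an edge count of zero.
#'
#' @param g Graph.
#' @return An object of class `component_decomposition`: a list with
#'   `components` (list of node-id vectors), `sizes`, `edge_counts` and the
#'   component count `s`.
#' @export
connected_components <- function(g) {
  check_graph(g)
  ids <- igraph::V(g)$name
  memb <- igraph::components(g)$membership
  comps <- split(ids, memb)
  # edges per component: both endpoints always share a membership label
  el <- igraph::as_edgelist(g, names = TRUE)
  ec <- table(factor(memb[el[, 1]], levels = names(comps)))
  # deterministic order: by smallest contained node id
  mins <- vapply(comps, function(x) x[order_node_ids(x)[1]], character(1))
  ord <- order_node_ids(mins)
  comps <- lapply(comps[ord], function(x) x[order_node_ids(x)])
  structure(list(
    components  = unname(comps),
    sizes       = vapply(comps, length, 1L, USE.NAMES = FALSE),
    edge_counts = as.integer(ec)[ord],
    s           = length(comps)
  ), class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("Component decomposition: %d component(s)\n", x$s))
  cat("  sizes:       ", paste(x$sizes, collapse = " "), "\n")
  cat("  edge counts: ", paste(x$edge_counts, collapse = " "), "\n")
  invisible(x)
}

#' Unweighted shortest-path distances from one node
#'
#' Breadth-first distances from `source`; unreachable nodes are absent from
#' the result.
#'
#' @param g Graph.
#' @param source Node id.
#' @param cutoff Optional hop limit; only nodes within `cutoff` hops are
#'   returned.
#' @return Named numeric vector of hop counts, including `source` at 0.
#' @export
bfs_distances <- function(g, source, cutoff = NULL) {
  check_graph(g)
  source <- as.character(source)
  if (!source %in% igraph::V(g)$name)
    stop("unknown node: ", source, call. = FALSE)
  d <- igraph::distances(g, v = source, algorithm = "unweighted")[1, ]
  d <- d[is.finite(d)]
  if (!is.null(cutoff)) d <- d[d <= cutoff]
  d
}

#' Topological summary of a graph
#'
#' Reports node count, edge count, mean and maximum degree, and the mean
#' local clustering coefficient, where a node's local clustering is
#' 2*T_i / (d_i (d_i - 1)) with T_i the number of edges among its
#' neighbours, taken as 0 for nodes of degree 0 or 1.
#'
#' @param g Graph with at least one node.
#' @return A one-row data frame with columns `n`, `m`, `mean_degree`,
#'   `max_degree`, `mean_clustering`.
#' @export
graph_summary <- function(g) {
  check_graph(g)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph", call. = FALSE)
  deg <- igraph::degree(g)
  ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  ci[deg <= 1] <- 0
  data.frame(
    n = n,
    m = igraph::ecount(g),
    mean_degree = mean(deg),
    max_degree = max(deg),
    mean_clustering = mean(ci)
  )
}
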