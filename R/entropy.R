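# Structure entropy: the score at the heart of the package.
#
# Removing a node splits a graph into connected components C_1..C_s. Each
# component gets a probability distribution over its nodes,
#
#   p(v_t) = sum_{v_j in N(v_t)} d_j  /  sum_{v_x in C_i} d_x^2 ,
#
# with degrees taken in the post-removal graph (a singleton component gets
# the degenerate distribution (1)). The local entropy LE(C_i) is the base-2
# Shannon entropy of that distribution, and the node's global structure
# entropy is the edge-count-weighted sum SE(v) = sum_i |E_i| LE(C_i).
# Removing a structurally critical node shatters the graph into small,
# low-entropy components, so SMALL SE means HIGH importance.

#' Shannon entropy of a probability vector
#'
#' Base-2 entropy, with the convention 0*log2(0) = 0. The vector is not
#' required to sum to one.
#'
#' @param p Numeric vector of non-negative entries.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.5))           # 1
#' shannon_entropy(rep(0.25, 4))          # 2
#' @export
shannon_entropy <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  pos <- p[p > 0]
  -sum(pos * log2(pos))
}

#' Degree-derived probability distribution of a connected component
#'
#' For a component of the post-removal graph with more than one node,
#' p(v_t) is the sum of the degrees of v_t's neighbours divided by the sum
#' of squared degrees over the component; these probabilities sum to one.
#' A singleton component gets the distribution (1).
#'
#' @param g_removed The graph after node removal.
#' @param component Character vector of node ids forming one maximal
#'   connected set of `g_removed`.
#' @return An object of class `component_probability`: list with `node_ids`
#'   and `probs` in matching order.
#' @export
component_probability <- function(g_removed, component) {
  check_graph(g_removed)
  component <- as.character(component)
  ids <- igraph::V(g_removed)$name
  if (!all(component %in% ids))
    stop("component contains nodes absent from the graph", call. = FALSE)
  # must be exactly the maximal connected set containing its members
  memb <- igraph::components(g_removed)$membership
  full <- ids[memb == memb[[component[1]]]]
  if (!setequal(full, component))
    stop("`component` is not a maximal connected set of the graph", call. = FALSE)
  if (length(component) == 1L) {
    return(structure(list(node_ids = component, probs = 1),
                     class = "component_probability"))
  }
  deg <- igraph::degree(g_removed)
  denom <- sum(deg[component]^2)
  num <- vapply(component, function(v) {
    sum(deg[igraph::neighbors(g_removed, v)$name])
  }, numeric(1))
  structure(list(node_ids = component, probs = unname(num) / denom),
            class = "component_probability")
}

#' @export
print.component_probability <- function(x, ...) {
  cat("Component probability over", length(x$node_ids), "node(s)\n")
  print(stats::setNames(x$probs, x$node_ids))
  invisible(x)
}

#' Local structure entropy of a component
#'
#' Base-2 Shannon entropy of the component's degree-derived distribution.
#' Always non-negative; zero for singletons; invariant under permutation of
#' the distribution.
#'
#' @param cp A `component_probability` object.
#' @return Entropy in bits.
#' @export
local_entropy <- function(cp) {
  if (!inherits(cp, "component_probability"))
    stop("`cp` must be a component_probability object", call. = FALSE)
  shannon_entropy(cp$probs)
}

#' Global structure entropy of one node
#'
#' Removes `v`, decomposes the remainder into connected components and
#' returns the sum of local entropies weighted by each component's edge
#' count. Singleton components contribute nothing (zero weight and zero
#' entropy). A removal that leaves the graph connected is the s = 1 case:
#' SE = (m - d_v) * LE of the single remaining component.
#'
#' @param g Graph.
#' @param v Node id.
#' @return SE(v), a non-negative scalar in bits*edges.
#' @export
global_entropy <- function(g, v) {
  gr <- remove_node(g, v)
  cd <- connected_components(gr)
  se <- 0
  for (i in seq_len(cd$s)) {
    if (cd$sizes[i] == 1L) next
    le <- local_entropy(component_probability(gr, cd$components[[i]]))
    se <- se + cd$edge_counts[i] * le
  }
  se
}

#' Structure entropy of every node
#'
#' Applies [global_entropy()] to each node in turn (direct per-node
#' recomputation, O(n) component decompositions). Smaller scores mark more
#' important nodes.
#'
#' @param g Graph.
#' @return Named numeric vector of SE scores, one per node.
#' @seealso [rank_nodes()] for the ranking built on these scores.
#' @export
structure_entropy <- function(g) {
  check_graph(g)
  ids <- igraph::V(g)$name
  stats::setNames(vapply(ids, function(v) global_entropy(g, v), numeric(1)), ids)
}
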