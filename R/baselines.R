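# The five benchmark centralities used for comparison with structure
# entropy. All of them are reward-style scores: larger means more important.

#' Degree centrality
#'
#' @param g Graph.
#' @return Named numeric vector: each node's degree.
#' @export
degree_centrality <- function(g) {
  check_graph(g)
  igraph::degree(g)
}

#' Closeness centrality
#'
#' CC(v) = 1 / sum of shortest-path distances from v to every other node it
#' can reach. On a disconnected graph the sum runs over v's component only;
#' an isolated node scores 0.
#'
#' @param g Graph.
#' @return Named numeric vector of closeness scores.
#' @export
closeness_centrality <- function(g) {
  check_graph(g)
  d <- igraph::distances(g, algorithm = "unweighted")
  apply(d, 1L, function(row) {
    s <- sum(row[is.finite(row)])   # includes the 0 to itself
    if (s == 0) 0 else 1 / s
  })
}

#' K-shell (k-core) index
#'
#' Classical k-shell decomposition: nodes of residual degree <= 1 are
#' stripped and assigned Ks = 1, then residual degree <= 2 for Ks = 2, and
#' so on. Equivalent to the graph-theoretic coreness; isolated nodes get 0.
#'
#' @param g Graph.
#' @return Named integer vector of shell indices.
#' @export
kshell <- function(g) {
  check_graph(g)
  igraph::coreness(g)
}

#' Iterative k-shell (IKS) index
#'
#' At each iteration the cohort of nodes with the current minimum residual
#' degree is deleted and assigned the iteration number as its score, so a
#' node whose degree collapses late in the peeling gets a strictly higher
#' score than the cohort that exposed it. Isolated input nodes form the
#' first (degree-0) cohort and receive the minimum score.
#'
#' @param g Graph.
#' @return Named integer vector of iteration indices (larger = removed
#'   later = more important).
#' @export
iks <- function(g) {
  check_graph(g)
  ids <- igraph::V(g)$name
  score <- stats::setNames(integer(length(ids)), ids)
  h <- g
  it <- 0L
  while (igraph::vcount(h) > 0) {
    it <- it + 1L
    deg <- igraph::degree(h)
    cohort <- names(deg)[deg == min(deg)]
    score[cohort] <- it
    h <- igraph::delete_vertices(h, cohort)
  }
  score
}

#' Edge-weight centrality
#'
#' WR(v) = sum over neighbours j of d_v * d_j, i.e. the total degree-product
#' weight of v's incident edges. Isolated nodes score 0.
#'
#' @param g Graph.
#' @return Named numeric vector.
#' @export
weight_of_edges <- function(g) {
  check_graph(g)
  deg <- igraph::degree(g)
  vapply(igraph::V(g)$name, function(v) {
    nb <- igraph::neighbors(g, v)$name
    if (length(nb) == 0) 0 else deg[[v]] * sum(deg[nb])
  }, numeric(1))
}

#' Gravity-model centrality
#'
#' GM(v) = sum over nodes j within three hops of v of
#' Ks(v) * Ks(j) / d(v,j)^2, with Ks the classical k-shell index and d the
#' hop distance. Nodes farther than three hops contribute nothing.
#'
#' @param g Graph.
#' @return Named numeric vector.
#' @export
gravity_model <- function(g) {
  check_graph(g)
  ks <- kshell(g)
  d <- igraph::distances(g, algorithm = "unweighted")
  ids <- igraph::V(g)$name
  vapply(ids, function(v) {
    dv <- d[v, ]
    within <- names(dv)[is.finite(dv) & dv >= 1 & dv <= 3]
    if (length(within) == 0) return(0)
    sum(ks[[v]] * ks[within] / dv[within]^2)
  }, numeric(1))
}
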