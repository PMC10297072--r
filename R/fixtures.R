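# Deterministic fixtures: the 12-node worked example and parametric
# synthetic graph generators.

#' The 12-node worked-example graph
#'
#' A connected graph of 12 nodes and 14 edges built around a hub, `v5`,
#' whose removal splits it into three components: a 4-clique missing one
#' edge (nodes v1-v4, 5 edges, degrees 3,3,2,2), a triangle (v6-v8) and a
#' 4-node star (centre v9, leaves v10-v12). The hub carries one edge into
#' each component (to v1, v6 and v9). Removing v5 reproduces the component
#' probability vectors (6/26, 7/26, 7/26, 6/26), (4/12, 4/12, 4/12) and
#' (1/4, 1/4, 1/4, 1/4), local entropies 1.9957, 1.5850 and 2.0000 bits,
#' and SE(v5) = 20.7335. Only this post-removal structure is pinned down;
#' the wiring inside the original graph is one concrete choice (it also
#' keeps deg(v3) = deg(v5) = 3 and leaves the graph connected when v3 is
#' removed instead).
#'
#' @return An undirected simple igraph object, n = 12, m = 14.
#' @export
worked_example_graph <- function() {
  edges <- rbind(
    # C1: K4 minus the v2-v4 edge
    c("v1", "v2"), c("v2", "v3"), c("v3", "v4"), c("v4", "v1"), c("v1", "v3"),
    # C2: triangle
    c("v6", "v7"), c("v7", "v8"), c("v8", "v6"),
    # C3: star centred on v9
    c("v9", "v10"), c("v9", "v11"), c("v9", "v12"),
    # hub
    c("v5", "v1"), c("v5", "v6"), c("v5", "v9")
  )
  graph_from_edges(edges, quiet = TRUE)
}

# run fn() under a fixed RNG seed without disturbing the caller's stream
with_rng <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  fn()
}

#' Synthetic graph generators
#'
#' Deterministic parametric graphs for property testing. Available
#' families:
#' \describe{
#'   \item{`star(k)`}{one centre, `k` leaves (nodes `1..k+1`, centre `1`).}
#'   \item{`cycle(k)`}{cycle on `k >= 3` nodes.}
#'   \item{`complete(k)`}{complete graph on `k` nodes.}
#'   \item{`path(k)`}{path on `k` nodes.}
#'   \item{`erdos_renyi(n, p, seed)`}{G(n, p) random graph.}
#'   \item{`pref_attach(n, m0, seed)`}{preferential-attachment growth,
#'     `m0` edges per arriving node.}
#' }
#' Random families are bit-reproducible: the same `seed` always yields the
#' same edge set, and the caller's RNG stream is left untouched.
#'
#' @param family One of `"star"`, `"cycle"`, `"complete"`, `"path"`,
#'   `"erdos_renyi"`, `"pref_attach"`.
#' @param ... Family parameters as above.
#' @return An undirected simple igraph object with node ids `"1"`, `"2"`,
#'   ...
#' @examples
#' make_graph("star", 3)
#' make_graph("erdos_renyi", n = 20, p = 0.2, seed = 7)
#' @export
make_graph <- function(family = c("star", "cycle", "complete", "path",
                                  "erdos_renyi", "pref_attach"), ...) {
  family <- match.arg(family)
  args <- list(...)
  g <- switch(family,
    star = {
      k <- args[[1]]
      if (k < 1) stop("star needs k >= 1 leaves", call. = FALSE)
      igraph::make_star(k + 1, mode = "undirected", center = 1)
    },
    cycle = {
      k <- args[[1]]
      if (k < 3) stop("cycle needs k >= 3 nodes", call. = FALSE)
      igraph::make_ring(k)
    },
    complete = {
      k <- args[[1]]
      if (k < 1) stop("complete needs k >= 1 nodes", call. = FALSE)
      igraph::make_full_graph(k)
    },
    path = {
      k <- args[[1]]
      if (k < 1) stop("path needs k >= 1 nodes", call. = FALSE)
      igraph::make_ring(k, circular = FALSE)
    },
    erdos_renyi = {
      n <- args$n; p <- args$p; seed <- args$seed
      if (is.null(n)) n <- args[[1]]
      if (is.null(p)) p <- args[[2]]
      if (is.null(seed)) seed <- args[[3]]
      if (n < 1 || p < 0 || p > 1) stop("need n >= 1 and p in [0, 1]", call. = FALSE)
      with_rng(seed, function() igraph::sample_gnp(n, p))
    },
    pref_attach = {
      n <- args$n; m0 <- args$m0; seed <- args$seed
      if (is.null(n)) n <- args[[1]]
      if (is.null(m0)) m0 <- args[[2]]
      if (is.null(seed)) seed <- args[[3]]
      if (n < 1 || m0 < 1) stop("need n >= 1 and m0 >= 1", call. = FALSE)
      with_rng(seed, function()
        igraph::sample_pa(n, m = m0, directed = FALSE))
    }
  )
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}
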