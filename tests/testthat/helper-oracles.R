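# Independent brute-force oracles, written in base R against a plain
# adjacency matrix. They deliberately share no code path with the package:
# components come from union-find, distances from a hand-rolled BFS queue,
# entropy scores from direct evaluation of the defining formulas.

# adjacency matrix (named, 0/1) extracted from a graph's edge list
oracle_adjacency <- function(g) {
  ids <- igraph::V(g)$name
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) > 0) {
    A[el] <- 1L
    A[el[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

# connected components by union-find; returns list of node-id vectors
oracle_components <- function(A) {
  n <- nrow(A)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (A[i, j] == 1L) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(rownames(A), roots))
}

# BFS hop distances from src; unreachable nodes absent
oracle_bfs <- function(A, src) {
  ids <- rownames(A)
  dist <- stats::setNames(rep(NA_real_, length(ids)), ids)
  dist[src] <- 0
  queue <- src
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in ids[A[v, ] == 1L]) {
      if (is.na(dist[w])) { dist[w] <- dist[v] + 1; queue <- c(queue, w) }
    }
  }
  dist[!is.na(dist)]
}

# naive structure entropy of every node, straight from the formulas
oracle_se_scores <- function(A) {
  ids <- rownames(A)
  vapply(stats::setNames(ids, ids), function(v) {
    B <- A[setdiff(ids, v), setdiff(ids, v), drop = FALSE]
    deg <- rowSums(B)
    se <- 0
    for (comp in oracle_components(B)) {
      if (length(comp) < 2) next
      denom <- sum(deg[comp]^2)
      p <- vapply(comp, function(t) sum(deg[names(which(B[t, ] == 1L))]), 0) / denom
      le <- -sum(p * log2(p))
      mE <- sum(B[comp, comp]) / 2
      se <- se + mE * le
    }
    se
  }, numeric(1))
}

# brute-force k-shell peeling
oracle_kshell <- function(A) {
  ids <- rownames(A)
  ks <- stats::setNames(rep(0L, length(ids)), ids)
  alive <- ids
  k <- 0L
  while (length(alive) > 0) {
    deg <- rowSums(A[alive, alive, drop = FALSE])
    if (min(deg) > k) { k <- k + 1L; next }
    drop <- alive[deg <= k]
    ks[drop] <- k
    alive <- setdiff(alive, drop)
  }
  ks
}

# random test graph: deterministic G(n, p) via the package generator
random_test_graph <- function(n, p, seed) make_graph("erdos_renyi", n = n, p = p, seed = seed)
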