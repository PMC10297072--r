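test_that("edge-list parsing handles comments, duplicates, self-loops and dialects", {
  f <- withr::local_tempfile()
  writeLines(c("1 2", "2 3"), f)
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)

  writeLines(c("1 2", "2 1", "2 2"), f)
  expect_message(g <- read_edge_list(f), "dropped 1 self-loop")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)

  writeLines(c("% sym unweighted", "1\t2"), f)
  g <- read_edge_list(f, dialect = "konect")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)

  # node ids preserved verbatim, "#" comments skipped, extra columns ignored
  writeLines(c("# a comment", "alice bob 37", "bob carol 12"), f)
  g <- read_edge_list(f)
  expect_setequal(igraph::V(g)$name, c("alice", "bob", "carol"))

  writeLines(c("1 2", "orphan"), f)
  expect_error(read_edge_list(f), "line 2")
  expect_error(read_edge_list(file.path(tempdir(), "no-such-file")), "cannot read")
})

test_that("writing then reading an edge list preserves the labelled graph", {
  g <- worked_example_graph()
  for (dialect in c("plain", "konect")) {
    f <- withr::local_tempfile()
    write_edge_list(g, f, dialect = dialect)
    g2 <- read_edge_list(f, dialect = dialect)
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    el <- function(x) {
      e <- igraph::as_edgelist(x, names = TRUE)
      sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    }
    expect_identical(el(g2), el(g))
  }
  # konect writer emits the "%" header
  f <- withr::local_tempfile()
  write_edge_list(make_graph("complete", 2), f, dialect = "konect")
  expect_match(readLines(f)[1], "^%")
})

test_that("remove_node deletes the node and its edges without touching the input", {
  star <- make_graph("star", 3)
  h <- remove_node(star, "1")
  expect_equal(igraph::vcount(h), 3)
  expect_equal(igraph::ecount(h), 0)
  expect_equal(igraph::ecount(star), 3)  # value semantics

  tri <- make_graph("complete", 3)
  h <- remove_node(tri, "2")
  expect_equal(igraph::vcount(h), 2)
  expect_equal(igraph::ecount(h), 1)

  g <- worked_example_graph()
  h <- remove_node(g, "v5")
  expect_equal(igraph::vcount(h), 11)
  expect_equal(igraph::ecount(h), 11)

  expect_error(remove_node(g, "nope"), "unknown node")
})

test_that("connected_components reports deterministic ordering, sizes and edge counts", {
  g <- graph_from_edges(rbind(c("1", "2"), c("2", "3"), c("1", "3")),
                        nodes = "4", quiet = TRUE)
  cd <- connected_components(g)
  expect_equal(cd$s, 2)
  expect_equal(cd$sizes, c(3L, 1L))
  expect_equal(cd$edge_counts, c(3L, 0L))

  iso <- make_graph("erdos_renyi", n = 5, p = 0, seed = 1)
  expect_equal(connected_components(iso)$s, 5)

  cd <- connected_components(remove_node(worked_example_graph(), "v5"))
  expect_equal(cd$s, 3)
  expect_setequal(cd$sizes, c(4L, 3L, 4L))
  expect_setequal(cd$edge_counts, c(5L, 3L, 3L))
  # ordered by smallest contained node id: v1... before v10... before v6...
  expect_equal(vapply(cd$components, `[`, "", 1), c("v1", "v6", "v9"))
})

test_that("components partition the graph and match a union-find oracle on random graphs", {
  for (seed in 1:15) {
    g <- random_test_graph(n = 5 + (seed %% 6) * 9, p = 0.08 * (1 + seed %% 3), seed = seed)
    cd <- connected_components(g)
    expect_equal(sum(cd$sizes), igraph::vcount(g))
    expect_equal(sum(cd$edge_counts), igraph::ecount(g))
    # handshake after a mutation
    v <- igraph::V(g)$name[1]
    h <- remove_node(g, v)
    expect_equal(sum(igraph::degree(h)), 2 * igraph::ecount(h))
    got <- connected_components(h)$components
    want <- oracle_components(oracle_adjacency(h))
    expect_setequal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("bfs_distances gives hop counts, honours cutoffs and the triangle inequality", {
  p3 <- make_graph("path", 3)
  expect_equal(bfs_distances(p3, "1"), c("1" = 0, "2" = 1, "3" = 2))

  two <- graph_from_edges(rbind(c("a", "b"), c("c", "d")), quiet = TRUE)
  expect_named(bfs_distances(two, "a"), c("a", "b"))

  c4 <- make_graph("cycle", 4)
  d <- bfs_distances(c4, "1", cutoff = 1)
  expect_equal(sum(d == 1), 2)

  expect_error(bfs_distances(p3, "9"), "unknown node")

  g <- random_test_graph(30, 0.15, seed = 42)
  ids <- igraph::V(g)$name
  dm <- sapply(ids, function(v) {
    d <- bfs_distances(g, v)
    unname(d[ids])
  })
  rownames(dm) <- ids
  set.seed(7)
  for (i in 1:50) {
    tr <- sample(ids, 3)
    dab <- dm[tr[2], tr[1]]; dbc <- dm[tr[3], tr[2]]; dac <- dm[tr[3], tr[1]]
    if (!is.na(dab) && !is.na(dbc)) expect_true(!is.na(dac) && dac <= dab + dbc)
  }
  # cross-check against the independent BFS oracle
  A <- oracle_adjacency(g)
  expect_equal(bfs_distances(g, ids[1]), oracle_bfs(A, ids[1])[names(bfs_distances(g, ids[1]))])
})

test_that("graph_summary computes degree and clustering statistics", {
  s <- graph_summary(make_graph("complete", 3))
  expect_equal(s$mean_degree, 2)
  expect_equal(s$max_degree, 2)
  expect_equal(s$mean_clustering, 1)

  expect_equal(graph_summary(make_graph("star", 3))$mean_clustering, 0)

  g <- worked_example_graph()
  s <- graph_summary(g)
  expect_equal(s$n, 12)
  expect_equal(s$m, 14)
  expect_equal(s$mean_degree, 2 * 14 / 12)

  expect_error(graph_summary(igraph::make_empty_graph(directed = FALSE)))
})
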