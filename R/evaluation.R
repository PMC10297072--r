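# Evaluation protocols for node rankings: monotonicity, rank CCDF,
# targeted-attack robustness and SIR spreading ability.

#' Monotonicity of a ranking
#'
#' Penalizes tie groups: with n nodes and tie-group sizes n_r,
#' M(R) = 1 - sum_r n_r (n_r - 1) / (n (n - 1)). M = 1 when every node has
#' its own rank order, M = 0 when all nodes are tied. `squared = TRUE`
#' squares the whole expression (the Bae-Kim form); both variants agree at
#' the two endpoints.
#'
#' Depends only on the tie-group sizes, never on score magnitudes.
#'
#' @param ranking A `node_ranking` (n >= 2).
#' @param squared Use the squared variant.
#' @return A value in \[0, 1\].
#' @export
monotonicity <- function(ranking, squared = FALSE) {
  stopifnot(inherits(ranking, "node_ranking"))
  n <- ranking$n
  if (n < 2) stop("monotonicity needs at least 2 nodes", call. = FALSE)
  nr <- lengths(ranking$tie_groups)
  m <- 1 - sum(nr * (nr - 1)) / (n * (n - 1))
  if (squared) m^2 else m
}

#' Complementary cumulative distribution of nodes over rank orders
#'
#' CCDF(r) = (n - number of nodes in the first r tie groups) / n, for
#' r = 0..|tie groups|. Starts at 1, ends at 0, and drops by n_r / n at
#' step r.
#'
#' @param ranking A `node_ranking`.
#' @return Data frame with columns `r` and `ccdf`.
#' @export
ccdf <- function(ranking) {
  stopifnot(inherits(ranking, "node_ranking"))
  nr <- lengths(ranking$tie_groups)
  vals <- (ranking$n - cumsum(c(0L, nr))) / ranking$n
  data.frame(r = seq_along(vals) - 1L, ccdf = vals)
}

#' Targeted-attack robustness curve
#'
#' For each removal fraction p, deletes the k = floor(p * n) most important
#' nodes of the ranking (boundary ties are already broken by node id inside
#' the ranking) and records xi, the number of connected components among
#' the remaining nodes (singletons counted), and tau, the size of the
#' largest remaining component divided by the ORIGINAL node count. A
#' ranking that finds structurally critical nodes drives tau down and xi up
#' quickly.
#'
#' @param g Graph the ranking was computed on.
#' @param ranking A `node_ranking` over the nodes of `g`.
#' @param fractions Removal proportions in (0, 1).
#' @return An `attack_curve`: data frame with columns `fraction`, `k`,
#'   `xi`, `tau`.
#' @export
attack_curve <- function(g, ranking, fractions = seq(0.1, 0.9, by = 0.1)) {
  check_graph(g)
  stopifnot(inherits(ranking, "node_ranking"))
  ids <- igraph::V(g)$name
  if (!setequal(ids, ranking$order))
    stop("ranking and graph cover different node sets", call. = FALSE)
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie strictly between 0 and 1", call. = FALSE)
  n <- length(ids)
  res <- lapply(fractions, function(p) {
    k <- floor(p * n)
    h <- if (k > 0) igraph::delete_vertices(g, ranking$order[seq_len(k)]) else g
    if (igraph::vcount(h) == 0) {
      data.frame(fraction = p, k = k, xi = 0L, tau = 0)
    } else {
      comp <- igraph::components(h)
      data.frame(fraction = p, k = k, xi = comp$no,
                 tau = max(comp$csize) / n)
    }
  })
  structure(do.call(rbind, res), class = c("attack_curve", "data.frame"))
}

#' Epidemic threshold infection probability
#'
#' The SIR spreading protocol runs at the threshold beta = 1 / (<d> - 1)
#' with recovery probability 1, where <d> is the mean degree: below it an
#' outbreak tends to die out, far above it everything burns regardless of
#' the seeds, so the threshold is where seed quality matters most.
#'
#' @param g Graph with mean degree > 1.
#' @return Infection probability in (0, 1\].
#' @export
threshold_beta <- function(g) {
  check_graph(g)
  dbar <- mean(igraph::degree(g))
  if (dbar <= 1) stop("mean degree must exceed 1", call. = FALSE)
  min(1, 1 / (dbar - 1))
}

#' Discrete-time SIR spreading from a seed set
#'
#' Synchronous susceptible-infected-recovered dynamics: at each step every
#' infected node independently infects each susceptible neighbour with
#' probability `beta`, then recovers with probability `gamma` (so
#' `gamma = 1` means each node is infectious for exactly one step). A run
#' ends when no infected nodes remain; its outcome is the fraction of nodes
#' ever infected (seeds included). The propagation ability F is the mean
#' outcome over `n_reps` independent repetitions.
#'
#' @param g Graph.
#' @param seeds Node ids initially infected.
#' @param beta Infection probability per contact per step, in \[0, 1\].
#' @param gamma Recovery probability per step, in \[0, 1\].
#' @param n_reps Number of repetitions.
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `sir_result`: list with `seeds`, `beta`,
#'   `gamma`, `n_reps`, `propagation` (mean F), `sd` and `per_rep`.
#' @examples
#' g <- make_graph("star", 3)
#' sir_propagation(g, seeds = "1", beta = 0, gamma = 1, n_reps = 10)$propagation
#' @export
sir_propagation <- function(g, seeds, beta, gamma, n_reps = 1000, seed = NULL) {
  check_graph(g)
  seeds <- as.character(seeds)
  ids <- igraph::V(g)$name
  if (!all(seeds %in% ids)) stop("unknown seed node(s)", call. = FALSE)
  if (length(seeds) == 0) stop("need at least one seed", call. = FALSE)
  if (beta < 0 || beta > 1 || gamma < 0 || gamma > 1)
    stop("beta and gamma must lie in [0, 1]", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(ids)
  nbr <- igraph::adjacent_vertices(g, ids)
  nbr <- lapply(nbr, as.integer)           # neighbour indices per node
  names(nbr) <- NULL
  seed_idx <- match(seeds, ids)
  per_rep <- vapply(seq_len(n_reps), function(rep) {
    # 0 = susceptible, 1 = infected, 2 = recovered
    state <- integer(n)
    state[seed_idx] <- 1L
    infected <- seed_idx
    while (length(infected) > 0) {
      targets <- unlist(nbr[infected], use.names = FALSE)
      targets <- targets[state[targets] == 0L]
      if (length(targets) > 0) {
        hit <- targets[stats::runif(length(targets)) < beta]
        state[hit] <- 1L                   # duplicates collapse harmlessly
      }
      recov <- stats::runif(length(infected)) < gamma
      state[infected[recov]] <- 2L
      infected <- which(state == 1L)
    }
    sum(state != 0L) / n
  }, numeric(1))
  structure(list(
    seeds = seeds, beta = beta, gamma = gamma, n_reps = n_reps,
    propagation = mean(per_rep), sd = stats::sd(per_rep), per_rep = per_rep
  ), class = "sir_result")
}

#' @export
print.sir_result <- function(x, ...) {
  cat(sprintf(
    "SIR spread: %d seed(s), beta = %.4f, gamma = %.2f, %d rep(s)\n",
    length(x$seeds), x$beta, x$gamma, x$n_reps))
  cat(sprintf("  propagation ability F = %.4f (sd %.4f)\n", x$propagation,
              if (is.na(x$sd)) 0 else x$sd))
  invisible(x)
}

#' @export
plot.attack_curve <- function(x, which = c("tau", "xi"), ...) {
  which <- match.arg(which)
  graphics::plot(x$fraction, x[[which]], type = "b",
                 xlab = "fraction of nodes removed",
                 ylab = if (which == "tau") expression(tau) else expression(xi),
                 ...)
  invisible(x)
}
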