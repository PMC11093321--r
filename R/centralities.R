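#' Thirteen classical node centralities for a residue network
#'
#' Computes the centrality panel `C1`-`C13` following the standard published
#' definitions (degree, eigenvector, closeness, betweenness, current-flow
#' closeness, current-flow betweenness, communicability betweenness, load,
#' subgraph, harmonic, second-order, Laplacian, and Katz centrality).
#' Affinity-style scores whose definitions extend naturally to edge weights
#' (`C1`, `C2`, `C9`, `C12`, `C13`) are computed on the full weighted
#' contact map; shortest-path / walk-distance scores (`C3`, `C4`, `C5`,
#' `C6`, `C7`, `C8`, `C10`, `C11`) are computed on the pruned unweighted
#' network, whose forced backbone edges guarantee the connectivity they
#' require.
#'
#' @param map A [contact_map()] (weighted scores).
#' @param network A `binary_network` from [prune_to_unweighted()]
#'   (unweighted scores). Defaults to pruning `map` at 0.1.
#' @param katz_alpha_factor Katz attenuation as a fraction of
#'   `1 / lambda_max` of the weighted map; must be `< 1` for the Katz series
#'   to converge (default 0.85).
#' @return A named list `C1` ... `C13` of numeric vectors of length
#'   `n_residues`.
#' @export
centrality_suite <- function(map, network = prune_to_unweighted(map),
                             katz_alpha_factor = 0.85) {
  stopifnot(inherits(map, "contact_map"), inherits(network, "binary_network"))
  if (map$n_residues != network$n_residues) {
    stop_hotspotr("Map and pruned network have different sizes.",
                  "hotspotr_shape_error")
  }
  n <- map$n_residues
  A <- network$adjacency
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  if (!igraph::is_connected(g)) {
    stop_hotspotr("Pruned network is disconnected; centralities need a connected graph.",
                  "hotspotr_validation_error")
  }

  run <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_hotspotr(sprintf("Centrality %s failed: %s", name, conditionMessage(e)),
                    "hotspotr_numeric_error")
    })
  }

  list(
    C1 = run("C1 (degree)", power_degree(map, 1) / (n - 1)),
    C2 = run("C2 (eigenvector)", limit_degree(map)),
    C3 = run("C3 (closeness)",
             as.numeric(igraph::closeness(g, normalized = TRUE))),
    C4 = run("C4 (betweenness)",
             as.numeric(igraph::betweenness(g)) / ((n - 1) * (n - 2) / 2)),
    C5 = run("C5 (current-flow closeness)", current_flow_closeness(A)),
    C6 = run("C6 (current-flow betweenness)", current_flow_betweenness(A)),
    C7 = run("C7 (communicability betweenness)", communicability_betweenness(A)),
    C8 = run("C8 (load)", load_centrality(A, g)),
    C9 = run("C9 (subgraph)", subgraph_centrality_weighted(map$P)),
    C10 = run("C10 (harmonic)",
              as.numeric(igraph::harmonic_centrality(g, normalized = FALSE))),
    C11 = run("C11 (second-order)", second_order_centrality(A)),
    C12 = run("C12 (Laplacian)", laplacian_centrality_weighted(map$P)),
    C13 = run("C13 (Katz)", katz_centrality_weighted(map$P, katz_alpha_factor))
  )
}

# Matrix exponential of a symmetric matrix via eigen-decomposition.
expm_sym <- function(A) {
  es <- eigen(A, symmetric = TRUE)
  es$vectors %*% (exp(es$values) * t(es$vectors))
}

# Current-flow (information) closeness: reciprocal of the summed effective
# resistances to all other nodes, computed from the Laplacian pseudo-inverse.
current_flow_closeness <- function(A) {
  n <- nrow(A)
  L <- diag(rowSums(A)) - A
  Tm <- MASS::ginv(L)
  # sum_w R(v, w) = n T_vv + tr(T) - 2 sum_w T_vw
  res_sum <- n * diag(Tm) + sum(diag(Tm)) - 2 * rowSums(Tm)
  1 / res_sum
}

# Current-flow (random-walk) betweenness, Brandes-Fleischer accumulation:
# for each edge, the potential-difference row over injection nodes is sorted
# once and pair currents are accumulated in O(n log n).
current_flow_betweenness <- function(A) {
  n <- nrow(A)
  if (n < 3) return(rep(0, n))
  L <- diag(rowSums(A)) - A
  Tm <- MASS::ginv(L)
  idx0 <- 0:(n - 1)
  b <- numeric(n)
  edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    s <- edges[e, 1]; t <- edges[e, 2]
    row <- A[s, t] * (Tm[s, ] - Tm[t, ])
    pos <- integer(n)
    pos[order(row, decreasing = TRUE)] <- idx0
    b[s] <- b[s] + sum((idx0 - pos) * row)
    b[t] <- b[t] + sum((n - 1 - idx0 - pos) * row)
  }
  (b - idx0) * 2 / ((n - 1) * (n - 2))
}

# Communicability betweenness (Estrada-Higham-Hatano): fraction of weighted
# closed walks between every pair that pass through a node, from matrix
# exponentials of the 0/1 adjacency with and without the node's edges.
communicability_betweenness <- function(A) {
  n <- nrow(A)
  A <- (A != 0) * 1
  expA <- expm_sym(A)
  cbc <- numeric(n)
  for (v in seq_len(n)) {
    Av <- A
    Av[v, ] <- 0
    Av[, v] <- 0
    B <- (expA - expm_sym(Av)) / expA
    B[v, ] <- 0
    B[, v] <- 0
    diag(B) <- 0
    cbc[v] <- sum(B)
  }
  if (n > 2) cbc <- cbc / ((n - 1)^2 - (n - 1))
  cbc
}

# Load centrality: like betweenness but flow from each target back towards
# the source splits *equally* among shortest-path predecessors rather than
# proportionally to path counts.
load_centrality <- function(A, g = NULL) {
  n <- nrow(A)
  if (n < 3) return(rep(0, n))
  g <- g %||% igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  D <- igraph::distances(g)
  b <- numeric(n)
  for (s in seq_len(n)) {
    d <- D[s, ]
    between <- rep(1, n)
    for (v in order(d, decreasing = TRUE)) {
      if (d[v] <= 0) next
      # shortest-path predecessors; the source itself never accumulates load
      preds <- which(A[v, ] > 0 & d == d[v] - 1)
      preds <- preds[preds != s]
      if (length(preds) > 0) {
        between[preds] <- between[preds] + between[v] / length(preds)
      }
    }
    b <- b + between - 1
  }
  b / ((n - 1) * (n - 2))
}

# Subgraph centrality on the weighted map: diagonal of exp(P).
subgraph_centrality_weighted <- function(P) {
  es <- eigen(P, symmetric = TRUE)
  as.numeric((es$vectors^2) %*% exp(es$values))
}

# Second-order centrality (Kermarrec et al.): standard deviation of return
# times of an unbiased perpetual random walk, analytic form. The graph is
# degree-balanced with self-loops before building the transition matrix.
# Lower values mean more central nodes.
second_order_centrality <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  dmax <- max(deg)
  Pm <- (A + diag(dmax - deg)) / dmax
  I <- diag(n)
  ones <- rep(1, n)
  vapply(seq_len(n), function(i) {
    Q <- Pm
    Q[, i] <- 0
    M <- solve(I - Q, ones)
    sqrt(2 * sum(M) - n * (n + 1))
  }, numeric(1))
}

# Laplacian centrality on the weighted map: normalized drop in Laplacian
# energy (sum of squared entries of L) after deleting a node.
laplacian_centrality_weighted <- function(P) {
  n <- nrow(P)
  L <- diag(rowSums(P)) - P
  full_energy <- sum(L^2)
  di <- diag(L)
  vapply(seq_len(n), function(i) {
    keep <- setdiff(seq_len(n), i)
    L2 <- L[keep, keep, drop = FALSE]
    diag(L2) <- (di - abs(L[, i]))[keep]
    (full_energy - sum(L2^2)) / full_energy
  }, numeric(1))
}

# Katz centrality on the weighted map, direct linear solve, beta = 1,
# normalized to unit Euclidean norm with a positive entry sum.
katz_centrality_weighted <- function(P, alpha_factor = 0.85) {
  n <- nrow(P)
  lmax <- max(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
  if (lmax <= 0) {
    stop_hotspotr("Katz centrality needs a map with positive spectral radius.",
                  "hotspotr_numeric_error")
  }
  alpha <- alpha_factor / lmax
  x <- solve(diag(n) - alpha * P, rep(1, n))
  x / (sign(sum(x)) * sqrt(sum(x^2)))
}
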