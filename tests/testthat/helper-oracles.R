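# Brute-force oracles and toy fixtures. Every oracle here recomputes a
# quantity by a route independent of the package implementation it checks.

# two 5-cliques joined by a single bridge edge: the classic modular toy
toy_two_cliques <- function() {
  ids <- c(paste0("a", 1:5), paste0("b", 1:5))
  ed <- rbind(t(combn(paste0("a", 1:5), 2)),
              t(combn(paste0("b", 1:5), 2)),
              c("a1", "b1"))
  anatomical_network(ids, ed, name = "two_cliques")
}

toy_path <- function(n = 3) {
  ids <- paste0("p", seq_len(n))
  anatomical_network(ids, cbind(ids[-n], ids[-1]))
}

toy_star <- function(n_leaves = 3) {
  ids <- c("hub", paste0("leaf", seq_len(n_leaves)))
  anatomical_network(ids, cbind("hub", ids[-1]))
}

toy_complete <- function(n) {
  ids <- paste0("k", seq_len(n))
  anatomical_network(ids, t(combn(ids, 2)))
}

toy_triangle <- function() toy_complete(3)

# random connected Erdos-Renyi network (uses the current RNG state)
random_connected_net <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) >= 2) break
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- paste0("n", seq_len(n))
  anatomical_network(ids, cbind(ids[el[, 1]], ids[el[, 2]]))
}

# all-pairs shortest paths by Floyd-Warshall on the dense adjacency matrix
oracle_path_length <- function(net) {
  A <- adjacency_matrix(net)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  mean(D[upper.tri(D)])
}

# mean local clustering by direct neighbour-pair triangle counting
oracle_clustering <- function(net) {
  A <- adjacency_matrix(net)
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      t_i <- t_i + A[nb[a], nb[b]]
    ci[i] <- 2 * t_i / (k * (k - 1))
  }
  mean(ci)
}

# Newman-Girvan modularity via the centered adjacency ("B-matrix") route
oracle_modularity <- function(net, memb) {
  A <- adjacency_matrix(net)
  if (is.null(names(memb))) names(memb) <- rownames(A)
  memb <- memb[rownames(A)]
  K <- sum(A) / 2
  d <- rowSums(A)
  B <- A - outer(d, d) / (2 * K)
  same <- outer(memb, memb, `==`)
  sum(B[same]) / (2 * K)
}

# every set partition of n elements, as restricted-growth strings
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(pref, mx) {
    if (length(pref) == n) {
      out[[length(out) + 1L]] <<- pref
      return()
    }
    for (v in seq_len(mx + 1L)) rec(c(pref, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# jackknife SE of Q by explicitly materializing each leave-one-link network
oracle_jackknife_se <- function(net, assignment) {
  K <- nrow(net$edges)
  qj <- vapply(seq_len(K), function(i) {
    sub <- anatomical_network(net$nodes$id, net$edges[-i, , drop = FALSE],
                              tissue = net$nodes$tissue)
    modularity_q(sub, assignment)
  }, numeric(1))
  sqrt((K - 1) / K * sum((qj - mean(qj))^2))
}

# BM covariance by per-pair MRCA path summation (independent of the
# edge-accumulation route used by the package)
oracle_bm_covariance <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m <- if (i == j) i else ape::getMRCA(tree, c(i, j))
    C[i, j] <- depth[m]
  }
  diag(C) <- depth[seq_len(n)]
  C
}
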