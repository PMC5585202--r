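#' Walktrap merge dendrogram
#'
#' Agglomerative community detection from short random walks (the
#' Pons-Latapy walktrap algorithm). The probability profile of a `t`-step
#' random walk started at node `i` is the `i`-th row of `P^t`, where `P` is
#' the row-normalized adjacency matrix; walks this short tend to stay inside
#' the walker's own module, so nodes in one module have similar profiles. The
#' distance between nodes (and, via averaged profiles, between communities)
#' is
#' \deqn{r_{ij} = \sqrt{ \sum_k (P^t_{ik} - P^t_{jk})^2 / k_k },}
#' the degree-weighted Euclidean distance between profiles. A self-loop is
#' added to every node before the walk (the lazy walk of the reference
#' formulation, which makes the chain aperiodic). Starting from
#' singletons, the two *adjacent* communities whose merger least increases
#' the mean within-community squared distance (a Ward-style criterion,
#' \eqn{\Delta\sigma = \frac{1}{n}\frac{|C_1||C_2|}{|C_1|+|C_2|} r^2_{C_1 C_2}})
#' are merged, for `N - 1` merges in total.
#'
#' @param net a connected [anatomical_network()].
#' @param steps random-walk length `t` (default 3, the value appropriate for
#'   anatomical networks of ~100 nodes).
#' @return an object of class `walktrap_dendrogram`: list with `merges`
#'   (data frame with columns `a`, `b`, `id`, `height`; communities `1..N`
#'   are the nodes in order, merged communities get ids `N+1, ...`, and
#'   `height` is the cumulative within-community squared-distance cost, which
#'   is non-decreasing), `labels` (node ids) and `steps`.
#' @details Ties in the merge criterion are broken toward the candidate pair
#'   with the lowest community indices, so the result is deterministic given
#'   the network, its node order and `steps`.
#' @seealso [best_partition()], [walktrap_modules()]
#' @export
walktrap_dendrogram <- function(net, steps = 3) {
  stopifnot(inherits(net, "anatomical_network"))
  if (steps < 1) stop("'steps' must be >= 1")
  conn <- is_connected(net)
  if (!conn$connected)
    stop("walktrap requires a connected network (component sizes: ",
         paste(conn$component_sizes, collapse = ", "), ")")
  n <- nrow(net$nodes)
  ids <- net$nodes$id
  if (n == 1)
    return(structure(list(
      merges = data.frame(a = integer(0), b = integer(0), id = integer(0),
                          height = numeric(0)),
      labels = ids, steps = steps), class = "walktrap_dendrogram"))

  # a self-loop on every node makes the walk lazy (hence aperiodic), per the
  # reference formulation of the algorithm
  A <- adjacency_matrix(net) + diag(n)
  deg <- rowSums(A)
  P <- A / deg
  Pt <- P
  if (steps > 1) for (s in seq_len(steps - 1)) Pt <- Pt %*% P

  n_tot <- 2L * n - 1L
  prof <- matrix(NA_real_, n_tot, n)   # community random-walk profiles
  prof[1:n, ] <- Pt
  size <- numeric(n_tot); size[1:n] <- 1
  adj <- matrix(FALSE, n_tot, n_tot)   # community adjacency
  ei <- match(net$edges[, 1], ids); ej <- match(net$edges[, 2], ids)
  adj[cbind(ei, ej)] <- TRUE; adj[cbind(ej, ei)] <- TRUE
  active <- c(rep(TRUE, n), rep(FALSE, n - 1))
  delta <- matrix(Inf, n_tot, n_tot)   # merge costs, upper triangle i < j

  dsigma <- function(i, j) {
    (size[i] * size[j] / (size[i] + size[j])) *
      sum((prof[i, ] - prof[j, ])^2 / deg) / n
  }
  for (e in which(upper.tri(adj) & adj, arr.ind = FALSE)) {
    j <- ((e - 1L) %/% n_tot) + 1L
    i <- e - (j - 1L) * n_tot
    delta[i, j] <- dsigma(i, j)
  }

  merges <- data.frame(a = integer(n - 1), b = integer(n - 1),
                       id = integer(n - 1), height = numeric(n - 1))
  height <- 0
  for (step in seq_len(n - 1)) {
    best <- which(delta == min(delta))[1]
    j <- ((best - 1L) %/% n_tot) + 1L
    i <- best - (j - 1L) * n_tot
    m <- n + step
    height <- height + delta[i, j]
    merges$a[step] <- i; merges$b[step] <- j
    merges$id[step] <- m; merges$height[step] <- height

    prof[m, ] <- (size[i] * prof[i, ] + size[j] * prof[j, ]) /
      (size[i] + size[j])
    size[m] <- size[i] + size[j]
    nbr <- which((adj[i, ] | adj[j, ]) & active)
    nbr <- setdiff(nbr, c(i, j))
    active[c(i, j)] <- FALSE
    active[m] <- TRUE
    delta[i, ] <- Inf; delta[, i] <- Inf
    delta[j, ] <- Inf; delta[, j] <- Inf
    adj[m, nbr] <- TRUE; adj[nbr, m] <- TRUE
    for (c in nbr) delta[min(c, m), max(c, m)] <- dsigma(c, m)
  }
  structure(list(merges = merges, labels = ids, steps = steps),
            class = "walktrap_dendrogram")
}

#' @export
print.walktrap_dendrogram <- function(x, ...) {
  cat("walktrap dendrogram:", length(x$labels), "nodes,",
      nrow(x$merges), "merges, t =", x$steps, "\n")
  invisible(x)
}

#' Newman-Girvan modularity Q
#'
#' For a partition of the network into modules,
#' \deqn{Q = \sum_m \left( \frac{e_m}{K} - \left(\frac{d_m}{2K}\right)^2 \right),}
#' where `e_m` is the number of links inside module `m`, `d_m` the summed
#' degree of its nodes and `K` the total link count. `Q` near 0 means the
#' within-module link fraction is no better than the random expectation;
#' strongly modular networks typically score 0.3-0.7.
#'
#' @param net an [anatomical_network()] with `K >= 1`.
#' @param assignment module membership: an integer/character vector either
#'   named by node id or given in node order, with one entry per node; or a
#'   `module_partition` object.
#' @return modularity score in `[-1, 1]`.
#' @export
modularity_q <- function(net, assignment) {
  stopifnot(inherits(net, "anatomical_network"))
  memb <- normalize_assignment(net, assignment)
  K <- nrow(net$edges)
  if (K < 1) stop("modularity is undefined for a network without links")
  m1 <- memb[net$edges[, 1]]
  m2 <- memb[net$edges[, 2]]
  mods <- sort(unique(memb))
  e_m <- vapply(mods, function(m) sum(m1 == m & m2 == m), numeric(1))
  deg <- degree_sequence(net)$degree
  d_m <- vapply(mods, function(m) sum(deg[memb[net$nodes$id] == m]),
                numeric(1))
  sum(e_m / K - (d_m / (2 * K))^2)
}

normalize_assignment <- function(net, assignment) {
  if (inherits(assignment, "module_partition"))
    assignment <- assignment$assignment
  ids <- net$nodes$id
  if (is.null(names(assignment))) {
    if (length(assignment) != length(ids))
      stop("unnamed assignment must have one entry per node")
    names(assignment) <- ids
  }
  missing <- setdiff(ids, names(assignment))
  if (length(missing))
    stop("node(s) missing from assignment: ",
         paste(utils::head(missing, 5), collapse = ", "))
  assignment[ids]
}

#' Best modularity cut of a walktrap dendrogram
#'
#' Evaluates `Q` at every cut level of the merge sequence (from `N`
#' singletons down to one community) and returns the partition maximizing
#' `Q`; ties are broken toward fewer modules. Per-module summary statistics,
#' the jackknife standard error of `Q` and the per-module Wilcoxon tests are
#' filled in.
#'
#' @param net the connected [anatomical_network()] the dendrogram was built
#'   on.
#' @param dendro a [walktrap_dendrogram()] of `net`.
#' @return an object of class `module_partition`: list with `assignment`
#'   (named integer vector, module indices numbered by first appearance in
#'   node order), `M` (module count), `Q`, `Q_se` (delete-one-link jackknife
#'   standard error, see [jackknife_q_se()]) and `module_stats` (data frame
#'   with columns `module`, `size`, `internal`, `external`, `wilcoxon_p`).
#' @export
best_partition <- function(net, dendro) {
  stopifnot(inherits(dendro, "walktrap_dendrogram"))
  if (!identical(dendro$labels, net$nodes$id))
    stop("dendrogram was not built on this network (node sets differ)")
  n <- nrow(net$nodes)
  memb_levels <- cut_levels(dendro, n)
  qs <- vapply(memb_levels, function(m) modularity_q(net, m), numeric(1))
  nmod <- vapply(memb_levels, function(m) length(unique(m)), numeric(1))
  best <- which(qs >= max(qs) - 1e-12)
  best <- best[which.min(nmod[best])]
  as_module_partition(net, memb_levels[[best]])
}

# membership vectors (in node order, named) after 0 .. n-1 merges
cut_levels <- function(dendro, n) {
  comm <- seq_len(n)
  out <- vector("list", n)
  out[[1]] <- stats::setNames(comm, dendro$labels)
  if (n >= 2) for (s in seq_len(n - 1)) {
    comm[comm %in% c(dendro$merges$a[s], dendro$merges$b[s])] <-
      dendro$merges$id[s]
    out[[s + 1]] <- stats::setNames(comm, dendro$labels)
  }
  lapply(out, function(m) stats::setNames(match(m, unique(m)), names(m)))
}

#' Assemble a module partition object from an assignment
#'
#' Computes `Q`, its jackknife standard error and the per-module link counts
#' and Wilcoxon p-values for an arbitrary module assignment (not necessarily
#' one found by walktrap).
#'
#' @param net an [anatomical_network()].
#' @param assignment as in [modularity_q()].
#' @return a `module_partition` object (see [best_partition()]).
#' @export
as_module_partition <- function(net, assignment) {
  memb <- normalize_assignment(net, assignment)
  memb <- stats::setNames(match(memb, unique(memb)), names(memb))
  mods <- sort(unique(memb))
  m1 <- memb[net$edges[, 1]]
  m2 <- memb[net$edges[, 2]]
  internal <- vapply(mods, function(m) sum(m1 == m & m2 == m), integer(1))
  external <- vapply(mods, function(m) sum(xor(m1 == m, m2 == m)), integer(1))
  stats_df <- data.frame(
    module = mods,
    size = as.integer(table(factor(memb, levels = mods))),
    internal = internal,
    external = external,
    wilcoxon_p = NA_real_)
  part <- structure(
    list(assignment = memb, M = length(mods),
         Q = modularity_q(net, memb), Q_se = NA_real_,
         module_stats = stats_df),
    class = "module_partition")
  part$Q_se <- jackknife_q_se(net, part)
  part$module_stats$wilcoxon_p <-
    vapply(mods, function(m) module_wilcoxon(net, part, m), numeric(1))
  part
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module partition: M = %d, Q = %.4f (jackknife SE %.4f)\n",
              x$M, x$Q, x$Q_se))
  print(x$module_stats, row.names = FALSE)
  invisible(x)
}

#' Jackknife standard error of modularity Q
#'
#' Treats every link as an independent observation: each link in turn is
#' deleted, `Q` of the *same* partition is recomputed on the reduced network,
#' and the delete-one jackknife standard error
#' \deqn{SE = \sqrt{ \frac{K-1}{K} \sum_i (Q_{(i)} - \bar Q)^2 }}
#' is returned. The partition is held fixed across deletions (re-running the
#' detection per deletion would change the statistic being resampled).
#' Deleting a bridge may disconnect the network, but `Q` only needs link and
#' degree counts, so this needs no special handling.
#'
#' @param net an [anatomical_network()] with `K >= 2`.
#' @param partition a `module_partition` or an assignment as in
#'   [modularity_q()].
#' @param redetect if `TRUE`, walktrap is re-run on each reduced network and
#'   the best-cut `Q` is used instead (the alternative reading; much slower).
#' @param steps walktrap steps, used only when `redetect = TRUE`.
#' @return nonnegative standard error.
#' @export
jackknife_q_se <- function(net, partition, redetect = FALSE, steps = 3) {
  K <- nrow(net$edges)
  if (K < 2) stop("jackknife requires at least two links")
  if (redetect) {
    qjack <- vapply(seq_len(K), function(i) {
      sub <- anatomical_network(net$nodes$id, net$edges[-i, , drop = FALSE],
                                tissue = net$nodes$tissue, name = net$name)
      best_partition_q_only(sub, steps)
    }, numeric(1))
  } else {
    memb <- normalize_assignment(net, partition)
    mods <- sort(unique(memb))
    m1 <- match(memb[net$edges[, 1]], mods)
    m2 <- match(memb[net$edges[, 2]], mods)
    deg <- degree_sequence(net)$degree
    e_m <- vapply(seq_along(mods),
                  function(m) sum(m1 == m & m2 == m), numeric(1))
    d_m <- vapply(seq_along(mods), function(m)
      sum(deg[match(memb[net$nodes$id], mods) == m]), numeric(1))
    qjack <- vapply(seq_len(K), function(i) {
      e2 <- e_m; d2 <- d_m
      if (m1[i] == m2[i]) {
        e2[m1[i]] <- e2[m1[i]] - 1
        d2[m1[i]] <- d2[m1[i]] - 2
      } else {
        d2[m1[i]] <- d2[m1[i]] - 1
        d2[m2[i]] <- d2[m2[i]] - 1
      }
      sum(e2 / (K - 1) - (d2 / (2 * (K - 1)))^2)
    }, numeric(1))
  }
  sqrt((K - 1) / K * sum((qjack - mean(qjack))^2))
}

best_partition_q_only <- function(net, steps) {
  conn <- is_connected(net)
  if (!conn$connected) {
    # per-component dendrograms are overkill here: fall back to the
    # all-in-one partition of each component
    comp <- igraph::components(as_igraph(net))$membership
    return(modularity_q(net, stats::setNames(comp, net$nodes$id)))
  }
  d <- walktrap_dendrogram(net, steps)
  n <- nrow(net$nodes)
  max(vapply(cut_levels(d, n), function(m) modularity_q(net, m), numeric(1)))
}

#' Per-module Wilcoxon rank-sum test
#'
#' Tests whether the nodes of a module are more connected among themselves
#' than to the rest of the network. For every node of the module, its links
#' to nodes inside the module (internal connections) and to nodes outside
#' (external connections) are counted; a one-sided two-sample Wilcoxon
#' rank-sum (Mann-Whitney) test of `H_A: internal > external` is applied to
#' the two count vectors. A low p-value supports the module being a genuine
#' connectivity module rather than a random grouping.
#'
#' @param net an [anatomical_network()].
#' @param partition a `module_partition` or assignment.
#' @param module module index to test.
#' @return one-sided p-value; `NA` (not testable) for singleton modules.
#' @details For combined sample sizes up to 20 the exact permutation null of
#'   the rank sum is enumerated (valid under ties, which are pervasive in
#'   count data); larger samples use the tie-corrected normal approximation.
#' @export
module_wilcoxon <- function(net, partition, module) {
  memb <- normalize_assignment(net, partition)
  inside <- names(memb)[memb == module]
  if (length(inside) < 2) return(NA_real_)
  m1 <- net$edges[, 1] %in% inside
  m2 <- net$edges[, 2] %in% inside
  deg_in <- stats::setNames(integer(length(inside)), inside)
  deg_out <- deg_in
  both <- m1 & m2
  for (col in 1:2) {
    ends <- net$edges[, col]
    tab_in <- table(factor(ends[both], levels = inside))
    tab_out <- table(factor(ends[xor(m1, m2)], levels = inside))
    deg_in <- deg_in + as.integer(tab_in)
    deg_out <- deg_out + as.integer(tab_out)
  }
  wilcoxon_greater(as.numeric(deg_in), as.numeric(deg_out))
}

# one-sided rank-sum p-value, exact by enumeration for small samples
wilcoxon_greater <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  if (n <= 20) {
    combos <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    mean(w_all >= w_obs - 1e-9)
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                         correct = TRUE)$p.value)
  }
}

#' One-call module detection
#'
#' Runs [walktrap_dendrogram()] and [best_partition()] in sequence.
#'
#' @inheritParams walktrap_dendrogram
#' @return a `module_partition` (see [best_partition()]).
#' @examples
#' net <- generate_limb_network(limb_config(seed = 7))$network
#' part <- walktrap_modules(net)
#' part$M
#' @export
walktrap_modules <- function(net, steps = 3) {
  best_partition(net, walktrap_dendrogram(net, steps))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two node groupings; 1 for identical
#' partitions, ~0 for independent ones. Used to compare detected modules with
#' a planted ground truth.
#'
#' @param a,b membership vectors over the same elements (named vectors are
#'   aligned by name).
#' @return adjusted Rand index (<= 1).
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b)))
    b <- b[names(a)]
  stopifnot(length(a) == length(b), !anyNA(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
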