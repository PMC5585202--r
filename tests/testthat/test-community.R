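test_that("modularity Q matches hand values and the centered-matrix oracle", {
  net <- toy_two_cliques()
  clique_split <- setNames(rep(1:2, each = 5), net$nodes$id)
  expect_equal(modularity_q(net, clique_split), 2 * (10 / 21 - (21 / 42)^2))
  # all in one module
  expect_equal(modularity_q(net, setNames(rep(1, 10), net$nodes$id)), 0)
  # triangle, every node its own module
  tri <- toy_triangle()
  expect_equal(modularity_q(tri, setNames(1:3, tri$nodes$id)), -1 / 3)
  set.seed(17)
  for (i in 1:20) {
    rnet <- random_connected_net(sample(8:25, 1), 0.3)
    memb <- setNames(sample(3, nrow(rnet$nodes), replace = TRUE),
                     rnet$nodes$id)
    expect_equal(modularity_q(rnet, memb), oracle_modularity(rnet, memb),
                 tolerance = 1e-12)
    g <- as_igraph(rnet)
    expect_equal(modularity_q(rnet, memb),
                 igraph::modularity(g, memb[rnet$nodes$id]),
                 tolerance = 1e-12)
  }
  expect_error(modularity_q(net, setNames(1, "a1")), "missing")
})

test_that("walktrap splits the two-clique toy at its best cut", {
  net <- toy_two_cliques()
  dend <- walktrap_dendrogram(net, 3)
  expect_identical(nrow(dend$merges), 9L)
  expect_true(all(diff(dend$merges$height) >= -1e-14))
  part <- best_partition(net, dend)
  expect_identical(part$M, 2L)
  expect_equal(part$Q, 2 * (10 / 21 - (21 / 42)^2))
  expect_setequal(names(part$assignment)[part$assignment == 1],
                  paste0("a", 1:5))
})

test_that("complete graphs and stars do not split", {
  k6 <- toy_complete(6)
  p <- best_partition(k6, walktrap_dendrogram(k6, 3))
  expect_identical(p$M, 1L)
  expect_equal(p$Q, 0)
  # exhaustive check on the 6-node star: no partition beats all-in-one
  st <- toy_star(5)
  qs <- vapply(all_set_partitions(6),
               function(pp) modularity_q(st, pp), numeric(1))
  expect_true(max(qs) <= 0 + 1e-12)
  ps <- best_partition(st, walktrap_dendrogram(st, 3))
  expect_identical(ps$M, 1L)
})

test_that("walktrap merge sequence reproduces the reference implementation", {
  set.seed(23)
  for (i in 1:10) {
    net <- random_connected_net(sample(8:20, 1), 0.3)
    g <- as_igraph(net)
    dend <- walktrap_dendrogram(net, 3)
    wt <- igraph::cluster_walktrap(g, steps = 3)
    mine_merges <- t(apply(as.matrix(dend$merges[, c("a", "b")]), 1, sort))
    ref_merges <- t(apply(wt$merges, 1, sort))
    expect_equal(unname(mine_merges) + 0, unname(ref_merges) + 0)
    mine <- best_partition(net, dend)
    q_ig <- max(vapply(seq_len(nrow(net$nodes)), function(k)
      igraph::modularity(g, igraph::cut_at(wt, k)), numeric(1)))
    expect_equal(mine$Q, q_ig, tolerance = 1e-12)
  }
})

test_that("walktrap is deterministic given network, node order and t", {
  out <- generate_limb_network(limb_config(seed = 6))
  d1 <- walktrap_dendrogram(out$network, 3)
  d2 <- walktrap_dendrogram(out$network, 3)
  expect_identical(d1, d2)
  expect_identical(best_partition(out$network, d1)$assignment,
                   best_partition(out$network, d2)$assignment)
})

test_that("link conservation holds for every partition", {
  set.seed(97)
  for (i in 1:10) {
    out <- generate_limb_network(limb_config(
      n_regions = 3, bones_per_region = 3, muscles_per_region = 6,
      p_in = 0.4, p_out = 0.05, seed = i))
    part <- walktrap_modules(out$network)
    K <- unname(network_size(out$network)["K"])
    expect_identical(sum(part$module_stats$internal) +
                       sum(part$module_stats$external) %/% 2L, K)
    expect_identical(part$M, length(unique(part$assignment)))
    expect_true(part$Q >= 0)
  }
})

test_that("jackknife SE matches explicit leave-one-link materialization", {
  net <- toy_two_cliques()
  part <- walktrap_modules(net)
  expect_equal(jackknife_q_se(net, part),
               oracle_jackknife_se(net, part$assignment), tolerance = 1e-12)
  # one-module partition: every leave-one-out Q is 0
  one <- setNames(rep(1, 10), net$nodes$id)
  expect_equal(jackknife_q_se(net, one), 0)
  set.seed(3)
  rnet <- random_connected_net(15, 0.25)
  memb <- setNames(sample(3, 15, replace = TRUE), rnet$nodes$id)
  expect_equal(jackknife_q_se(rnet, memb), oracle_jackknife_se(rnet, memb),
               tolerance = 1e-12)
})

test_that("jackknife SE is invariant under node relabelling", {
  net <- toy_two_cliques()
  part <- walktrap_modules(net)
  perm <- sample(10)
  relab <- anatomical_network(net$nodes$id[perm], net$edges)
  expect_equal(jackknife_q_se(relab, part$assignment),
               jackknife_q_se(net, part$assignment))
})

test_that("module Wilcoxon test: exact enumeration, ties, and power", {
  # 5-clique module with no external links: only one of choose(10,5) rank
  # splits puts all internal counts on top
  ids <- c(paste0("c", 1:5), paste0("d", 1:5))
  net <- anatomical_network(ids, rbind(t(combn(paste0("c", 1:5), 2)),
                                       t(combn(paste0("d", 1:5), 2))))
  # treat the two cliques as one 10-node network with a disconnected check
  # bypassed: build the partition by hand
  part <- setNames(rep(1:2, each = 5), ids)
  expect_equal(module_wilcoxon(net, part, 1), 1 / choose(10, 5))
  # identical internal and external per-node counts: no evidence for H_A.
  # module = 5-cycle, each node also linked to two outside nodes
  cyc <- function(v) cbind(v, v[c(2:5, 1)])
  net_tie <- anatomical_network(ids, rbind(
    cyc(paste0("c", 1:5)), cyc(paste0("d", 1:5)),
    cbind(paste0("c", 1:5), paste0("d", 1:5)),
    cbind(paste0("c", 1:5), paste0("d", c(2:5, 1)))))
  expect_true(module_wilcoxon(net_tie, part, 1) >= 0.5)
  # singleton module is not testable
  bridge <- toy_two_cliques()
  expect_true(is.na(module_wilcoxon(bridge, setNames(c(1, rep(2, 9)),
                                                     bridge$nodes$id), 1)))
})

test_that("small-sample Wilcoxon path agrees with the exact distribution", {
  # tie-free case: compare against the exact Mann-Whitney null
  x <- c(9, 7, 5, 11)
  y <- c(2, 1, 4, 3, 6)
  expect_equal(annet:::wilcoxon_greater(x, y),
               stats::wilcox.test(x, y, alternative = "greater",
                                  exact = TRUE)$p.value)
})

test_that("planted modules are significant and recovered", {
  set.seed(11)
  hits <- 0L
  n_mod <- 0L
  for (s in 1:10) {
    out <- generate_limb_network(limb_config(seed = 400 + s))
    part <- walktrap_modules(out$network)
    ps <- part$module_stats$wilcoxon_p
    hits <- hits + sum(ps < 0.05, na.rm = TRUE)
    n_mod <- n_mod + sum(!is.na(ps))
    expect_gte(adjusted_rand_index(part$assignment, out$truth), 0.8)
  }
  expect_gte(hits / n_mod, 0.9)
})

test_that("adjusted Rand index agrees with an independent implementation", {
  set.seed(40)
  for (i in 1:10) {
    a <- sample(4, 30, replace = TRUE)
    b <- sample(3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("redetection jackknife variant runs and differs sensibly", {
  net <- toy_two_cliques()
  part <- walktrap_modules(net)
  se_fixed <- jackknife_q_se(net, part)
  se_re <- jackknife_q_se(net, part, redetect = TRUE)
  expect_true(is.finite(se_re) && se_re >= 0)
  expect_true(is.finite(se_fixed) && se_fixed >= 0)
})
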