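test_that("BM covariance: shared path lengths, against an MRCA oracle", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(bm_covariance(t2)), diag(2))
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C3 <- bm_covariance(t3)
  expect_equal(C3["A", "B"], 1)
  expect_equal(C3["A", "C"], 0)
  expect_equal(unname(diag(C3)), rep(2, 3))
  for (seed in 1:5) {
    tr <- generate_yule_tree(12, 1, seed = seed)
    expect_equal(bm_covariance(tr), oracle_bm_covariance(tr),
                 tolerance = 1e-12)
  }
  # and against the standard vcv construction
  tr <- generate_yule_tree(25, 1, seed = 77)
  V <- ape::vcv(tr)
  expect_equal(bm_covariance(tr), V[rownames(bm_covariance(tr)),
                                    colnames(bm_covariance(tr))],
               tolerance = 1e-12)
})

test_that("BM fit reduces to iid normal on a star tree and is optimal", {
  set.seed(1)
  n <- 12; v <- 2.5
  x <- setNames(rnorm(n, 5), paste0("t", 1:n))
  fit <- fit_bm(x, diag(v, n))
  expect_equal(fit$mu, mean(x))
  expect_equal(fit$sigma2, mean((x - mean(x))^2) / v)
  # ML point beats perturbed parameters
  set.seed(19)
  for (i in 1:20) {
    tr <- generate_yule_tree(10, 1, seed = 100 + i)
    y <- simulate_bm(tr, sigma2 = 0.5, root = 1, seed = 200 + i)
    C <- bm_covariance(tr)
    f <- fit_bm(y, C)
    ll <- function(mu, s2) {
      ch <- chol(C)
      r <- y - mu
      q <- sum(r * backsolve(ch, forwardsolve(t(ch), r)))
      -0.5 * (length(y) * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + q / s2)
    }
    expect_equal(f$loglik, ll(f$mu, f$sigma2), tolerance = 1e-9)
    for (j in 1:5) {
      mu_p <- f$mu + rnorm(1, sd = 0.3)
      s2_p <- f$sigma2 * exp(rnorm(1, sd = 0.3))
      expect_gte(f$loglik, ll(mu_p, s2_p) - 1e-9)
    }
  }
  # constant trait flags the degenerate boundary
  const <- fit_bm(setNames(rep(1, 5), paste0("t", 1:5)), diag(5))
  expect_true(const$degenerate)
  expect_equal(const$sigma2, 0)
})

test_that("BM rate is recovered from simulated data", {
  s2 <- vapply(1:200, function(i) {
    tr <- generate_yule_tree(128, 1, seed = 3000 + i)
    x <- simulate_bm(tr, sigma2 = 1, seed = 4000 + i)
    fit_bm(x, bm_covariance(tr))$sigma2
  }, numeric(1))
  expect_gte(mean(s2), 0.9)
  expect_lte(mean(s2), 1.1)
})

test_that("lambda transform and boundary conventions", {
  tr <- generate_yule_tree(10, 1, seed = 5)
  C <- bm_covariance(tr)
  expect_equal(unname(annet:::lambda_transform(C, 0)), diag(unname(diag(C))))
  expect_equal(annet:::lambda_transform(C, 1), C)
  x <- simulate_bm(tr, sigma2 = 1, seed = 6)
  res <- fit_pagel_lambda(x, tr)
  expect_true(res$estimate >= 0 && res$estimate <= 1)
  expect_gte(res$alt_loglik, res$null_loglik - 1e-9)
  res_mix <- fit_pagel_lambda(x, tr, boundary = "mixture")
  expect_lte(res_mix$p_value, res$p_value + 1e-12)
  expect_error(fit_pagel_lambda(setNames(rep(1, 10), tr$tip.label), tr),
               "constant")
})

test_that("lambda profile likelihood matches the reference implementation", {
  for (seed in c(3, 8)) {
    tr <- generate_yule_tree(40, 1, seed = seed)
    # moderate signal so the optimum is interior
    x <- simulate_bm(tr, sigma2 = 1, lambda = 0.6, seed = seed + 50)
    mine <- fit_pagel_lambda(x, tr)
    ref <- phytools::phylosig(tr, x, method = "lambda", test = TRUE)
    if (ref$lambda <= 1) {
      expect_equal(mine$estimate, ref$lambda, tolerance = 1e-3)
      expect_equal(mine$alt_loglik, ref$logL, tolerance = 1e-4)
    }
    expect_equal(mine$null_loglik, ref$logL0, tolerance = 1e-6)
  }
})

test_that("Blomberg's K matches the reference implementation exactly", {
  for (seed in c(2, 9)) {
    tr <- generate_yule_tree(30, 1, seed = seed)
    x <- simulate_bm(tr, sigma2 = 1, seed = seed + 10)
    mine <- blomberg_k(x, tr, n_perm = 200, seed = 1)
    ref <- phytools::phylosig(tr, x, method = "K")
    expect_equal(mine$estimate, as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("K is invariant to affine transformation of the trait", {
  tr <- generate_yule_tree(20, 1, seed = 14)
  x <- simulate_bm(tr, sigma2 = 2, seed = 15)
  k1 <- blomberg_k(x, tr, n_perm = 50, seed = 3)$estimate
  k2 <- blomberg_k(3.7 * x - 11, tr, n_perm = 50, seed = 3)$estimate
  expect_equal(k1, k2, tolerance = 1e-10)
})

test_that("K permutation p-values are reproducible and bounded below", {
  tr <- generate_yule_tree(16, 1, seed = 21)
  x <- simulate_bm(tr, sigma2 = 1, seed = 22)
  r1 <- blomberg_k(x, tr, n_perm = 99, seed = 7)
  r2 <- blomberg_k(x, tr, n_perm = 99, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 100)
  expect_error(blomberg_k(x, tr, n_perm = 99), "seed")
})

test_that("ancestral states: weighted means, convexity and degenerate limit", {
  # 2-tip tree: root is the inverse-branch-length weighted mean
  t2 <- ape::read.tree(text = "(A:2,B:1);")
  anc <- ancestral_states(setNames(c(0, 3), c("A", "B")), t2)
  expect_equal(anc$states$estimate, (0 / 2 + 3 / 1) / (1 / 2 + 1 / 1))
  # symmetric case
  t2e <- ape::read.tree(text = "(A:1,B:1);")
  anc_e <- ancestral_states(setNames(c(0, 2), c("A", "B")), t2e)
  expect_equal(anc_e$states$estimate, 1)
  expect_equal(anc_e$states$ci_high - 1, 1 - anc_e$states$ci_low)
  # internal estimates stay inside the observed range; CI brackets estimate
  for (i in 1:50) {
    tr <- generate_yule_tree(12, 1, seed = 6000 + i)
    x <- simulate_bm(tr, sigma2 = 1, seed = 7000 + i)
    a <- ancestral_states(x, tr)
    expect_true(all(a$states$estimate >= min(x) - 1e-9))
    expect_true(all(a$states$estimate <= max(x) + 1e-9))
    expect_true(all(a$states$ci_low <= a$states$estimate))
    expect_true(all(a$states$ci_high >= a$states$estimate))
  }
  # sigma2 -> 0: the constant truth is recovered everywhere with zero width
  tr <- generate_yule_tree(8, 1, seed = 31)
  x0 <- simulate_bm(tr, sigma2 = 0, root = 4.2, seed = 1)
  a0 <- ancestral_states(x0, tr)
  expect_equal(a0$states$estimate, rep(4.2, tr$Nnode))
  expect_equal(a0$states$ci_high, a0$states$ci_low)
})

test_that("ancestral estimates match the reference implementation", {
  tr <- generate_yule_tree(20, 1, seed = 44)
  x <- simulate_bm(tr, sigma2 = 1, root = 2, seed = 45)
  mine <- ancestral_states(x, tr)
  ref <- phytools::fastAnc(tr, x)
  expect_equal(mine$states$estimate, as.numeric(ref), tolerance = 1e-8)
})

test_that("phenogram segments have one row per non-root node at exact coords", {
  tr <- generate_yule_tree(9, 1, seed = 12)
  x <- simulate_bm(tr, sigma2 = 1, seed = 13)
  anc <- ancestral_states(x, tr)
  n_nodes <- length(tr$tip.label) + tr$Nnode
  expect_identical(nrow(anc$phenogram), n_nodes - 1L)
  depth <- ape::node.depth.edgelength(tr)
  tips <- anc$phenogram$node <= length(tr$tip.label)
  expect_equal(anc$phenogram$t1[tips],
               depth[anc$phenogram$node[tips]])
  expect_equal(anc$phenogram$y1[tips],
               unname(x[tr$tip.label[anc$phenogram$node[tips]]]))
  # 2-tip toy: both segments share the root endpoint
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  a2 <- ancestral_states(setNames(c(0, 2), c("A", "B")), t2)
  expect_identical(nrow(a2$phenogram), 2L)
  expect_equal(a2$phenogram$t0, c(0, 0))
  expect_equal(a2$phenogram$y0, rep(a2$states$estimate, 2))

  seg_path <- tempfile(fileext = ".csv")
  phenogram_export(a2, seg_path)
  expect_identical(nrow(utils::read.csv(seg_path)), 2L)
  q <- utils::read.csv(paste0(sub("\\.csv$", "", seg_path), "_quartiles.csv"))
  expect_equal(q$value, c(0, 0.5, 1, 1.5, 2))
})

test_that("trait names are matched permissively against tip labels", {
  tr <- ape::read.tree(text = "(Homo_sapiens:1,Pan_troglodytes:1);")
  x <- c("homo sapiens" = 1, "PAN TROGLODYTES" = 2)
  expect_equal(unname(align_traits(x, tr)), c(1, 2))
  y <- c("Homo habilis" = 1, "Pan paniscus" = 2)
  expect_warning(aligned <- align_traits(y, tr), "genus")
  expect_equal(unname(aligned), c(1, 2))
  expect_error(align_traits(c(Gorilla = 1, Pongo = 2), tr), "missing")
})

test_that("Newick round-trip and validation", {
  tr <- generate_yule_tree(7, 1, seed = 3)
  p <- tempfile(fileext = ".nwk")
  write_phylogeny(tr, p)
  back <- read_phylogeny(p)
  expect_identical(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(max(ape::node.depth.edgelength(back)),
               max(ape::node.depth.edgelength(tr)), tolerance = 1e-8)
  no_bl <- tempfile(fileext = ".nwk")
  writeLines("(A,(B,C));", no_bl)
  expect_error(read_phylogeny(no_bl), "branch length")
})
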