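#' Read and validate a phylogeny from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces what the comparative
#' methods here require: a rooted tree with unique tip labels and nonnegative
#' branch lengths in (time) units.
#'
#' @param path Newick file path.
#' @return an [ape::phylo] tree.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_phylogeny(tree)
  tree
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; time-calibrated branches are required")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  invisible(tree)
}

#' Write a phylogeny to a Newick file
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylogeny <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Match trait names against tree tip labels
#'
#' Permissive name normalization: comparison is case-insensitive and treats
#' underscores as spaces; if that fails for some tips, a genus-only (first
#' word) match is attempted with a warning.
#'
#' @param x named numeric trait vector.
#' @param tree an [ape::phylo] tree.
#' @return `x` reordered and renamed to `tree$tip.label`.
#' @export
align_traits <- function(x, tree) {
  stopifnot(is.numeric(x), !is.null(names(x)))
  norm <- function(s) tolower(gsub("_", " ", trimws(s)))
  tips <- tree$tip.label
  hit <- match(norm(tips), norm(names(x)))
  if (anyNA(hit)) {
    genus <- function(s) sub(" .*$", "", norm(s))
    gh <- match(genus(tips), genus(names(x)))
    fix <- is.na(hit) & !is.na(gh) & !duplicated(gh)
    if (any(fix)) {
      warning("matched ", sum(fix), " taxon/taxa by genus only: ",
              paste(tips[fix], collapse = ", "))
      hit[fix] <- gh[fix]
    }
  }
  if (anyNA(hit))
    stop("trait values missing for tip(s): ",
         paste(tips[is.na(hit)], collapse = ", "))
  stats::setNames(as.numeric(x[hit]), tips)
}

#' Brownian-motion covariance matrix of a tree
#'
#' Under Brownian motion the covariance of the trait values of two tips is
#' proportional to the shared path length from the root to their most recent
#' common ancestor; the diagonal holds root-to-tip distances. Built here by
#' accumulating, for every edge, its length into all pairs of tips descending
#' from it.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return symmetric positive-semidefinite matrix with tip labels as
#'   dimnames.
#' @export
bm_covariance <- function(tree) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  if (sum(tree$edge.length) <= 0) stop("tree has zero total depth")
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  desc <- tips_below(tree)
  for (e in seq_len(nrow(tree$edge))) {
    tips <- desc[[tree$edge[e, 2]]]
    C[tips, tips] <- C[tips, tips] + tree$edge.length[e]
  }
  C
}

# tip indices below each node (a node is below itself if it is a tip);
# edges visited in postorder so children are resolved before parents
tips_below <- function(tree) {
  n <- length(tree$tip.label)
  n_all <- n + tree$Nnode
  desc <- vector("list", n_all)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Maximum-likelihood Brownian-motion fit
#'
#' Closed-form generalized-least-squares estimates of the BM root state and
#' rate for a trait on a tree:
#' `mu = (1' C^-1 x) / (1' C^-1 1)`, `sigma2 = (x - mu)' C^-1 (x - mu) / n`,
#' with the exact multivariate-normal log-likelihood at the optimum.
#'
#' @param x named numeric trait vector (one value per tip).
#' @param C positive-definite BM covariance, as from [bm_covariance()]
#'   (possibly lambda-transformed).
#' @return list with `mu`, `sigma2`, `loglik`, and `degenerate` (`TRUE` when
#'   the trait is constant and `sigma2 = 0`, where the likelihood is
#'   unbounded).
#' @export
fit_bm <- function(x, C) {
  n <- length(x)
  if (n < 2) stop("need at least two tips")
  if (!is.null(names(x)) && !is.null(rownames(C)))
    C <- C[names(x), names(x)]
  ch <- tryCatch(chol(C), error = function(e)
    stop("covariance matrix is singular or not positive definite"))
  one <- rep(1, n)
  Ci_x <- backsolve(ch, forwardsolve(t(ch), x))
  Ci_1 <- backsolve(ch, forwardsolve(t(ch), one))
  mu <- sum(Ci_x) / sum(Ci_1)
  resid <- x - mu
  q <- sum(resid * backsolve(ch, forwardsolve(t(ch), resid)))
  sigma2 <- q / n
  logdetC <- 2 * sum(log(diag(ch)))
  degenerate <- sigma2 <= 0
  loglik <- if (degenerate) Inf else
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetC + n)
  list(mu = mu, sigma2 = sigma2, loglik = loglik, degenerate = degenerate)
}

lambda_transform <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Pagel's lambda test of phylogenetic signal
#'
#' Pagel's lambda multiplies all off-diagonal entries of the BM covariance:
#' `lambda = 0` removes the tree structure entirely (phylogenetic
#' independence) and `lambda = 1` leaves pure Brownian motion. The estimate
#' maximizes the profile likelihood over `[0, lambda_max]` by bounded 1-D
#' optimization (tolerance 1e-8); the p-value is a likelihood-ratio test of
#' the estimate against `lambda = 0` on one degree of freedom.
#'
#' @param x named numeric trait vector; names must match the tips (see
#'   [align_traits()]).
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param lambda_max upper bound of the search (default 1; values above 1 are
#'   only defined while the transformed covariance stays positive definite).
#' @param boundary p-value convention at the `lambda = 0` boundary:
#'   `"chisq1"` (default) uses the plain chi-square with 1 df, matching the
#'   convention of the standard comparative-methods implementations;
#'   `"mixture"` uses the 50:50 point-mass/chi-square boundary mixture.
#' @return object of class `phylo_signal`: list with `method = "lambda"`,
#'   `estimate`, `p_value`, `null_loglik` (at `lambda = 0`), `alt_loglik`
#'   (at the estimate) and `n`.
#' @export
fit_pagel_lambda <- function(x, tree, lambda_max = 1,
                             boundary = c("chisq1", "mixture")) {
  boundary <- match.arg(boundary)
  x <- align_traits(x, tree)
  if (length(x) < 3) stop("need at least three tips")
  if (stats::sd(x) == 0) stop("trait is constant; lambda is unidentifiable")
  C <- bm_covariance(tree)
  prof <- function(l) fit_bm(x, lambda_transform(C, l))$loglik
  opt <- stats::optimize(prof, c(0, lambda_max), maximum = TRUE,
                         tol = 1e-8)
  # optimize() can miss an optimum at the interval ends; check them
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, prof(0)),
                c(lambda_max, prof(lambda_max)))
  best <- cand[which.max(cand[, 2]), ]
  null_ll <- cand[2, 2]
  lr <- max(0, 2 * (best[2] - null_ll))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  if (boundary == "mixture") p <- if (lr == 0) 1 else p / 2
  structure(list(method = "lambda", estimate = unname(best[1]),
                 p_value = unname(p), null_loglik = unname(null_ll),
                 alt_loglik = unname(best[2]), n = length(x)),
            class = "phylo_signal")
}

#' Blomberg's K test of phylogenetic signal
#'
#' K compares the observed ratio of the mean squared tip deviation (from the
#' phylogenetically corrected mean) to the GLS mean squared error, against
#' the ratio expected under Brownian motion on the given tree:
#' `K = (MSE0 / MSE) / E[MSE0 / MSE]`, with
#' `E[MSE0/MSE] = (tr(C) - n / sum(C^-1)) / (n - 1)`. `K ~ 1` indicates
#' Brownian-like signal, `K < 1` less signal than BM. Significance comes
#' from a tip-label permutation test: signal makes the GLS `MSE` small, so
#' the p-value is the proportion of permutations (the observed data counted
#' among them) whose `MSE` is at most the observed one.
#'
#' @inheritParams fit_pagel_lambda
#' @param n_perm number of random tip-label permutations (default 1000).
#' @param seed RNG seed for the permutations (required, so that reported
#'   p-values are reproducible).
#' @return object of class `phylo_signal`: list with `method = "K"`,
#'   `estimate`, `p_value`, `n_permutations` and `n`.
#' @export
blomberg_k <- function(x, tree, n_perm = 1000, seed) {
  if (missing(seed)) stop("'seed' is required for the permutation test")
  x <- align_traits(x, tree)
  if (stats::sd(x) == 0) stop("trait is constant; K is undefined")
  n <- length(x)
  C <- bm_covariance(tree)
  Ci <- chol2inv(chol(C))
  w <- colSums(Ci)                  # C^-1 1
  sw <- sum(w)
  mse_pair <- function(v) {
    a <- sum(w * v) / sw
    r <- v - a
    c(mse0 = sum(r * r) / (n - 1),
      mse = sum(r * (Ci %*% r)) / (n - 1))
  }
  obs <- mse_pair(x)
  expected <- (sum(diag(C)) - n / sw) / (n - 1)
  K <- (obs[["mse0"]] / obs[["mse"]]) / expected

  set.seed(seed)
  X <- vapply(seq_len(n_perm), function(i) sample(x), numeric(n))
  a <- colSums(w * X) / sw
  R <- X - rep(a, each = n)
  mse_perm <- colSums(R * (Ci %*% R)) / (n - 1)
  p <- (sum(mse_perm <= obs[["mse"]] + 1e-12) + 1) / (n_perm + 1)
  structure(list(method = "K", estimate = unname(K), p_value = p,
                 n_permutations = n_perm, n = n),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("phylogenetic signal (%s): estimate = %.4f, p = %.4g (n = %d)\n",
              if (x$method == "lambda") "Pagel's lambda" else "Blomberg's K",
              x$estimate, x$p_value, x$n))
  invisible(x)
}

# depth (time from root) of every node
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

# covariance of every node (tips + internal) with every node: shared
# root-to-MRCA path length, by explicit ancestor-path intersection
full_node_covariance <- function(tree) {
  n <- length(tree$tip.label)
  n_all <- n + tree$Nnode
  root <- n + 1L
  parent <- integer(n_all)
  elen <- numeric(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  depth <- node_depths(tree)
  anc <- vector("list", n_all)       # ancestors incl. self
  anc[[root]] <- root
  for (e in rev(ape::postorder(tree))) {  # preorder: parents first
    ch <- tree$edge[e, 2]
    anc[[ch]] <- c(anc[[tree$edge[e, 1]]], ch)
  }
  Cfull <- matrix(0, n_all, n_all)
  for (i in seq_len(n_all)) for (j in i:n_all) {
    common <- intersect(anc[[i]], anc[[j]])
    Cfull[i, j] <- Cfull[j, i] <- max(depth[common])
  }
  Cfull
}

#' Maximum-likelihood ancestral state reconstruction under Brownian motion
#'
#' GLS/ML estimates of the trait value at every internal node, with 95%
#' confidence intervals, plus the straight-line (time, trait) segments that
#' make up a phenogram (traitgram). For internal node `a` with tip-covariance
#' vector `w_a` the estimate is `mu + w_a' V^-1 (x - mu)` and its variance is
#' `sigma2 (C_aa - w_a' V^-1 w_a + (1 - 1' V^-1 w_a)^2 / (1' V^-1 1))`,
#' where `V` is the tip covariance, and `mu`, `sigma2` are the GLS/ML
#' Brownian-motion estimates; the last term carries the uncertainty in the
#' root state through to the node estimates. For a 2-tip tree this reduces
#' to the inverse-branch-length weighted mean of the two tip values.
#'
#' @inheritParams fit_pagel_lambda
#' @return object of class `ancestral_states`: list with `states` (data
#'   frame: `node`, `estimate`, `ci_low`, `ci_high` for internal nodes),
#'   `phenogram` (data frame of per-edge segments: `node`, `parent`, `t0`,
#'   `t1`, `y0`, `y1`, `ci_low`, `ci_high` — child-node CI, `NA` for tips),
#'   `fit` (the [fit_bm()] result), `tree` and `trait` (the aligned tip
#'   values).
#' @export
ancestral_states <- function(x, tree) {
  x <- align_traits(x, tree)
  n <- length(x)
  C <- bm_covariance(tree)
  fit <- fit_bm(x, C)
  Cfull <- full_node_covariance(tree)
  Vi <- chol2inv(chol(Cfull[seq_len(n), seq_len(n)]))
  one <- rep(1, n)
  Vi1 <- Vi %*% one
  s11 <- sum(Vi1)
  resid <- x - fit$mu
  internal <- (n + 1L):(n + tree$Nnode)
  W <- Cfull[internal, seq_len(n), drop = FALSE]   # node-to-tip covariances
  est <- as.numeric(fit$mu + W %*% (Vi %*% resid))
  WVi <- W %*% Vi
  var_a <- fit$sigma2 *
    (diag(Cfull)[internal] - rowSums(WVi * W) +
       (1 - as.numeric(W %*% Vi1))^2 / s11)
  var_a <- pmax(var_a, 0)
  half <- 1.96 * sqrt(var_a)
  states <- data.frame(node = internal, estimate = est,
                       ci_low = est - half, ci_high = est + half)

  depth <- node_depths(tree)
  yval <- c(unname(x), est)
  ci_lo <- c(rep(NA_real_, n), states$ci_low)
  ci_hi <- c(rep(NA_real_, n), states$ci_high)
  ch <- tree$edge[, 2]; pa <- tree$edge[, 1]
  phen <- data.frame(node = ch, parent = pa,
                     t0 = depth[pa], t1 = depth[ch],
                     y0 = yval[pa], y1 = yval[ch],
                     ci_low = ci_lo[ch], ci_high = ci_hi[ch])
  structure(list(states = states, phenogram = phen, fit = fit,
                 tree = tree, trait = x),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf("BM ancestral states: %d internal nodes (sigma2 = %.4g)\n",
              nrow(x$states), x$fit$sigma2))
  print(utils::head(x$states), row.names = FALSE)
  invisible(x)
}

#' Export a phenogram as CSV line segments
#'
#' Writes one row per non-root node: the straight segment from its parent's
#' (time, trait) point to its own, with the child's 95% CI bounds, followed
#' (in a side file) by the quartiles of the tip-value distribution — the
#' numbers behind the slim box plot conventionally drawn beside a phenogram.
#'
#' @param anc an [ancestral_states()] object.
#' @param path output CSV path for the segments.
#' @param quartile_path output CSV for the tip-distribution summary; default
#'   replaces the extension of `path` with `_quartiles.csv`.
#' @return `path`, invisibly.
#' @export
phenogram_export <- function(anc, path, quartile_path = NULL) {
  stopifnot(inherits(anc, "ancestral_states"))
  utils::write.csv(anc$phenogram, path, row.names = FALSE)
  if (is.null(quartile_path))
    quartile_path <- paste0(sub("\\.[^.]*$", "", path), "_quartiles.csv")
  qs <- stats::quantile(anc$trait, c(0, 0.25, 0.5, 0.75, 1))
  utils::write.csv(data.frame(quantile = names(qs), value = unname(qs)),
                   quartile_path, row.names = FALSE)
  invisible(path)
}

#' Plot a phenogram
#'
#' Projects the tree into (time, trait) space: each branch is a straight
#' segment from the parent's reconstructed state to the child's state (or
#' observed tip value), with a shaded 95% CI band at internal nodes and a
#' slim box of the tip-value distribution in the right margin.
#'
#' @param anc an [ancestral_states()] object.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @return `anc`, invisibly.
#' @export
plot_phenogram <- function(anc, main = "", ...) {
  ph <- anc$phenogram
  xlim <- range(c(ph$t0, ph$t1))
  xlim[2] <- xlim[2] + 0.08 * diff(xlim)
  ylim <- range(c(ph$y0, ph$y1, ph$ci_low, ph$ci_high), na.rm = TRUE)
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "time from root",
                 ylab = "trait value", main = main, ...)
  ok <- !is.na(ph$ci_low)
  graphics::segments(ph$t1[ok], ph$ci_low[ok], ph$t1[ok], ph$ci_high[ok],
                     col = "#9ecae1", lwd = 4)
  graphics::segments(ph$t0, ph$y0, ph$t1, ph$y1)
  graphics::boxplot(anc$trait, at = xlim[2], add = TRUE, boxwex = 0.05 *
                      diff(xlim), axes = FALSE, outline = FALSE)
  invisible(anc)
}
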