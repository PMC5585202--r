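#' Configuration for the limb-like network generator
#'
#' @param n_regions number of proximo-distal anatomical regions (modules to
#'   plant). Default 5, giving a thorax/shoulder-arm-forearm-carpus-hand
#'   style series.
#' @param bones_per_region bones in each region's scaffold (default 4).
#' @param muscles_per_region muscles assigned to each region (default 16).
#' @param p_in probability that a muscle attaches to any given bone of its
#'   own region (default 0.3).
#' @param p_out probability of attaching to any given bone of another region
#'   (default 0.02). Must satisfy `0 <= p_out < p_in <= 1`.
#' @param seed RNG seed; the generator is deterministic given the full
#'   configuration.
#' @return a `limb_config` list.
#' @seealso [generate_limb_network()]
#' @export
limb_config <- function(n_regions = 5, bones_per_region = 4,
                        muscles_per_region = 16, p_in = 0.3, p_out = 0.02,
                        seed = 1) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    stop("need 0 <= p_out < p_in <= 1")
  if (n_regions < 1 || bones_per_region < 1 || muscles_per_region < 0)
    stop("invalid region/bone/muscle counts")
  structure(list(n_regions = n_regions, bones_per_region = bones_per_region,
                 muscles_per_region = muscles_per_region, p_in = p_in,
                 p_out = p_out, seed = seed), class = "limb_config")
}

#' Generate a limb-like modular musculoskeletal network
#'
#' Emulates the gross structure of a forelimb network: a connected bone
#' scaffold of serially arranged regions (each region's bones form a chain;
#' adjacent regions share one articulation link, like joints along the
#' proximo-distal axis; the terminal region branches from a base bone into up
#' to five digit-like rays), with muscles attached to other structures of
#' their own region with probability `p_in` per candidate and to structures
#' of other regions with probability `p_out`, so the regions are planted
#' connectivity modules. Links are any physical contact, as in real
#' musculoskeletal networks: muscle-bone attachments and muscle-muscle
#' (fascial) contacts are drawn; bone-bone articulations are the
#' deterministic scaffold. Every muscle attaches to at least two bones (an
#' origin and an insertion): bone draws with fewer attachments are
#' resampled. The default configuration yields 100 nodes, inside the 90-110
#' range typical of real forelimb musculoskeletal networks.
#'
#' @param cfg a [limb_config()].
#' @param max_retries resampling bound per muscle before giving up.
#' @return list with `network` (an [anatomical_network()], connected,
#'   tissue-typed) and `truth` (named integer vector: the planted
#'   node-to-region assignment).
#' @examples
#' out <- generate_limb_network(limb_config(seed = 42))
#' network_size(out$network)
#' @export
generate_limb_network <- function(cfg, max_retries = 1000) {
  stopifnot(inherits(cfg, "limb_config"))
  set.seed(cfg$seed)
  nb <- cfg$bones_per_region
  bones <- outer(seq_len(nb), seq_len(cfg$n_regions),
                 function(b, r) sprintf("bone_r%d_%02d", r, b))
  edges <- list()
  add_edge <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)

  for (r in seq_len(cfg$n_regions)) {
    terminal <- r == cfg$n_regions && nb >= 3
    if (terminal) {
      # base bone plus up to 5 digit-like rays
      rays <- min(5L, nb - 1L)
      ray_of <- rep(seq_len(rays), length.out = nb - 1L)
      prev <- rep(bones[1, r], rays)   # ray roots articulate with the base
      for (b in 2:nb) {
        add_edge(prev[ray_of[b - 1L]], bones[b, r])
        prev[ray_of[b - 1L]] <- bones[b, r]
      }
    } else if (nb >= 2) {
      for (b in 2:nb) add_edge(bones[b - 1, r], bones[b, r])
    }
    if (r > 1) add_edge(bones[nb, r - 1], bones[1, r])  # inter-region joint
  }

  muscle_ids <- character(0)
  truth_m <- integer(0)
  if (cfg$muscles_per_region > 0) {
    for (r in seq_len(cfg$n_regions)) for (m in seq_len(cfg$muscles_per_region)) {
      id <- sprintf("muscle_r%d_%02d", r, m)
      own <- bones[, r]
      other <- c(bones[, -r])
      for (try in seq_len(max_retries)) {
        att <- c(own[stats::runif(length(own)) < cfg$p_in],
                 other[stats::runif(length(other)) < cfg$p_out])
        if (length(att) >= 2) break
        if (try == max_retries)
          stop("could not draw >= 2 bone attachments for ", id,
               " within ", max_retries, " retries; increase p_in")
      }
      for (b in att) add_edge(id, b)
      # fascial contacts with muscles drawn before this one
      same <- truth_m == r
      touch <- stats::runif(length(muscle_ids)) <
        ifelse(same, cfg$p_in, cfg$p_out)
      for (mm in muscle_ids[touch]) add_edge(id, mm)
      muscle_ids <- c(muscle_ids, id)
      truth_m <- c(truth_m, r)
    }
  }

  ids <- c(c(bones), muscle_ids)
  tissue <- c(rep("bone", length(bones)), rep("muscle", length(muscle_ids)))
  region <- c(rep(seq_len(cfg$n_regions), each = nb), truth_m)
  net <- anatomical_network(
    ids, do.call(rbind, edges), tissue = tissue,
    region = as.character(region),
    name = sprintf("synthetic_limb_seed%d", cfg$seed))
  list(network = net,
       truth = stats::setNames(as.integer(region), ids))
}

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation with exponential waiting times: with `k` extant
#' lineages the time to the next speciation is `Exp(k * birth_rate)`, and a
#' uniformly chosen lineage splits, until `n_tips` lineages exist; a final
#' `Exp(n_tips * birth_rate)` interval is appended so all tips end at the
#' same age (the tree is ultrametric).
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per unit time (> 0).
#' @param seed RNG seed.
#' @return an ultrametric [ape::phylo] tree with tips `t1 ... tn`.
#' @export
generate_yule_tree <- function(n_tips, birth_rate = 1, seed) {
  if (n_tips < 2) stop("need at least 2 tips")
  if (birth_rate <= 0) stop("birth rate must be positive")
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  # lineage i alive since time start[i]; splits recorded as (parent-lineage,
  # new-lineage, time)
  split_parent <- integer(0); split_child <- integer(0); split_time <- numeric(0)
  t_now <- 0
  k <- 1L
  n_lin <- 1L
  alive <- 1L
  while (k < n_tips) {
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
    who <- alive[sample.int(k, 1)]
    n_lin <- n_lin + 1L
    split_parent <- c(split_parent, who)
    split_child <- c(split_child, n_lin)
    split_time <- c(split_time, t_now)
    alive <- c(alive, n_lin)
    k <- k + 1L
  }
  t_end <- t_now + stats::rexp(1, rate = n_tips * birth_rate)
  # build Newick recursively from the split records
  build <- function(lineage, born, upto) {
    kids <- which(split_parent == lineage & split_time > born &
                    split_time <= upto)
    if (!length(kids)) {
      return(sprintf("t%d:%.10f", lineage, upto - born))
    }
    first <- kids[which.min(split_time[kids])]
    ts <- split_time[first]
    sprintf("(%s,%s):%.10f",
            build(lineage, ts, upto), build(split_child[first], ts, upto),
            ts - born)
  }
  nwk <- paste0(sub(":[0-9.]+$", ";", build(1L, 0, t_end)))
  tree <- ape::read.tree(text = nwk)
  validate_phylogeny(tree)
  tree
}

# forward Yule simulation to a fixed horizon; returns the number of extant
# lineages at time t_max (shares the waiting-time scheme of the tree builder)
yule_tip_count <- function(birth_rate, t_max) {
  k <- 1L
  t_now <- stats::rexp(1, rate = k * birth_rate)
  while (t_now <= t_max) {
    k <- k + 1L
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
  }
  k
}

#' Simulate trait evolution under Brownian motion
#'
#' For `lambda = 1`, a preorder recursion: each child's value is its parent's
#' value plus a `Normal(0, sigma2 * branch length)` increment. For
#' `lambda < 1`, tips are drawn jointly from the multivariate normal with the
#' lambda-transformed covariance (off-diagonals scaled by `lambda`), which
#' interpolates between Brownian motion and phylogenetically independent
#' noise at `lambda = 0`.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param sigma2 BM rate (variance per unit time, >= 0).
#' @param root root (ancestral) state.
#' @param lambda signal strength in `[0, 1]` (default 1, pure BM).
#' @param seed RNG seed.
#' @return named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root = 0, lambda = 1, seed) {
  validate_phylogeny(tree)
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  n <- length(tree$tip.label)
  if (sigma2 == 0)
    return(stats::setNames(rep(root, n), tree$tip.label))
  if (lambda == 1) {
    n_all <- n + tree$Nnode
    val <- numeric(n_all)
    val[n + 1L] <- root
    for (e in rev(ape::postorder(tree))) {  # preorder: parents first
      ch <- tree$edge[e, 2]
      val[ch] <- val[tree$edge[e, 1]] +
        stats::rnorm(1, sd = sqrt(sigma2 * tree$edge.length[e]))
    }
    return(stats::setNames(val[seq_len(n)], tree$tip.label))
  }
  C <- lambda_transform(bm_covariance(tree), lambda)
  z <- stats::rnorm(n)
  stats::setNames(root + as.numeric(t(chol(sigma2 * C)) %*% z),
                  tree$tip.label)
}

#' Read a trait table
#'
#' @param path CSV with a taxon-label column (first column or one named
#'   `taxon`) and one or more numeric trait columns.
#' @return data frame with `taxon` first.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tc <- if ("taxon" %in% colnames(df)) "taxon" else colnames(df)[1]
  df <- df[c(tc, setdiff(colnames(df), tc))]
  colnames(df)[1] <- "taxon"
  df
}

#' Extract one trait as a named vector
#'
#' @param traits data frame as from [read_trait_table()].
#' @param trait trait column name (e.g. `"H"`).
#' @return named numeric vector (names = taxa).
#' @export
trait_vector <- function(traits, trait) {
  if (!trait %in% colnames(traits))
    stop("no trait column '", trait, "'")
  stats::setNames(as.numeric(traits[[trait]]), traits$taxon)
}
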