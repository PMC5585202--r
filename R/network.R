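#' Construct an anatomical network
#'
#' An anatomical network is a simple, undirected, unweighted graph whose nodes
#' are anatomical structures (bones and muscles) and whose links are physical
#' contacts between them (articulations between bones, attachments of muscles
#' onto bones). It is the basic data structure of anatomical network analysis
#' (AnNA).
#'
#' @param node_ids character vector of unique, non-empty node labels. Node
#'   order is preserved and is meaningful (it fixes matrix row order and the
#'   deterministic behaviour of downstream algorithms).
#' @param edges two-column character matrix (or data frame) of node-id pairs.
#'   Edges are undirected: `(a, b)` and `(b, a)` denote the same link, and
#'   duplicates collapse to a single link. Self-loops are rejected.
#' @param tissue optional character vector, same length as `node_ids`, with
#'   values `"bone"`, `"muscle"` or `"unknown"`.
#' @param region optional character vector of free-text anatomical region tags.
#' @param name taxon (or other) label for the network.
#'
#' @return An object of class `anatomical_network`: a list with elements
#'   `nodes` (data frame with columns `id`, `tissue`, `region`), `edges`
#'   (two-column character matrix in canonical sorted order) and `name`.
#'
#' @details Edges are stored canonically: within each pair the two ids are
#' sorted by node order, and the rows are sorted, so two networks with the
#' same node set and link set compare equal regardless of input order.
#'
#' @examples
#' net <- anatomical_network(c("humerus", "radius", "biceps"),
#'                           rbind(c("humerus", "radius"),
#'                                 c("biceps", "humerus"),
#'                                 c("biceps", "radius")),
#'                           tissue = c("bone", "bone", "muscle"))
#' network_size(net)
#' @export
anatomical_network <- function(node_ids, edges = NULL, tissue = NULL,
                               region = NULL, name = "") {
  node_ids <- as.character(node_ids)
  if (length(node_ids) == 0L)
    stop("network must have at least one node")
  if (any(is.na(node_ids) | !nzchar(trimws(node_ids))))
    stop("node ids must be non-empty strings")
  dup <- unique(node_ids[duplicated(node_ids)])
  if (length(dup))
    stop("duplicate node label(s): ", paste(dup, collapse = ", "))

  if (is.null(tissue)) tissue <- rep("unknown", length(node_ids))
  tissue <- as.character(tissue)
  if (length(tissue) != length(node_ids))
    stop("'tissue' must have one entry per node")
  bad <- setdiff(unique(tissue), c("bone", "muscle", "unknown"))
  if (length(bad))
    stop("invalid tissue class(es): ", paste(bad, collapse = ", "))
  if (is.null(region)) region <- rep(NA_character_, length(node_ids))

  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2,
                 dimnames = list(NULL, c("from", "to")))
  } else {
    em <- as.matrix(edges)
    if (ncol(em) < 2) stop("'edges' must have two columns")
    em <- cbind(as.character(em[, 1]), as.character(em[, 2]))
    missing_ep <- setdiff(c(em), node_ids)
    if (length(missing_ep))
      stop("edge endpoint(s) not in node set: ",
           paste(missing_ep, collapse = ", "))
    loops <- em[, 1] == em[, 2]
    if (any(loops))
      stop("self-loop(s) not allowed: ",
           paste(unique(em[loops, 1]), collapse = ", "))
    em <- canonical_edges(em, node_ids)
    colnames(em) <- c("from", "to")
  }

  structure(
    list(nodes = data.frame(id = node_ids, tissue = tissue, region = region,
                            stringsAsFactors = FALSE),
         edges = em,
         name = as.character(name)),
    class = "anatomical_network")
}

# canonical form: endpoints ordered by node rank within each pair, rows sorted,
# duplicates dropped
canonical_edges <- function(em, node_ids) {
  r1 <- match(em[, 1], node_ids)
  r2 <- match(em[, 2], node_ids)
  swap <- r1 > r2
  a <- ifelse(swap, r2, r1)
  b <- ifelse(swap, r1, r2)
  o <- order(a, b)
  a <- a[o]; b <- b[o]
  keep <- !duplicated(cbind(a, b))
  cbind(node_ids[a[keep]], node_ids[b[keep]])
}

#' @export
print.anatomical_network <- function(x, ...) {
  tis <- table(factor(x$nodes$tissue, levels = c("bone", "muscle", "unknown")))
  cat("anatomical network",
      if (nzchar(x$name)) paste0("'", x$name, "'") else "", "\n")
  cat("  nodes:", nrow(x$nodes),
      sprintf("(%d bone, %d muscle, %d unknown)",
              tis[["bone"]], tis[["muscle"]], tis[["unknown"]]), "\n")
  cat("  links:", nrow(x$edges), "\n")
  invisible(x)
}

#' @export
`==.anatomical_network` <- function(e1, e2) {
  identical(e1$nodes$id, e2$nodes$id) &&
    identical(e1$nodes$tissue, e2$nodes$tissue) &&
    identical(unname(e1$edges), unname(e2$edges))
}

#' Number of nodes and links
#'
#' @param net an [anatomical_network()].
#' @return `network_size()` returns a named vector `c(N = nodes, K = links)`.
#' @export
network_size <- function(net) {
  stopifnot(inherits(net, "anatomical_network"))
  c(N = nrow(net$nodes), K = nrow(net$edges))
}

#' Convert an anatomical network to an igraph object
#'
#' Used internally for standard graph statistics and exports; node order and
#' the `tissue`/`region` attributes are preserved.
#'
#' @param net an [anatomical_network()].
#' @return an [igraph::igraph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "anatomical_network"))
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes$id)
  g <- igraph::set_vertex_attr(g, "tissue", value = net$nodes$tissue)
  if (nrow(net$edges))
    g <- igraph::add_edges(g, t(matrix(match(net$edges, net$nodes$id),
                                       ncol = 2)))
  g
}

#' Dense adjacency matrix of a network
#'
#' @param net an [anatomical_network()].
#' @return symmetric 0/1 integer matrix with node labels as dimnames.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "anatomical_network"))
  ids <- net$nodes$id
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    i <- match(net$edges[, 1], ids)
    j <- match(net$edges[, 2], ids)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  A
}

#' Degree sequence
#'
#' Number of links incident to each node, in node order. The degrees of an
#' anatomical network count articulations/attachments per structure and are
#' the raw material of the heterogeneity parameter.
#'
#' @param net an [anatomical_network()].
#' @return data frame with columns `id` and `degree`; degrees sum to `2 * K`
#'   (handshake lemma).
#' @export
degree_sequence <- function(net) {
  stopifnot(inherits(net, "anatomical_network"))
  ids <- net$nodes$id
  deg <- integer(length(ids))
  if (nrow(net$edges)) {
    tab <- table(factor(c(net$edges[, 1], net$edges[, 2]), levels = ids))
    deg <- as.integer(tab)
  }
  data.frame(id = ids, degree = deg, stringsAsFactors = FALSE)
}

#' Connectivity check
#'
#' @param net an [anatomical_network()].
#' @return list with `connected` (logical; `TRUE` iff one component spans all
#'   nodes) and `component_sizes` (integer vector, descending).
#' @export
is_connected <- function(net) {
  stopifnot(inherits(net, "anatomical_network"))
  comp <- igraph::components(as_igraph(net))
  list(connected = comp$no == 1L,
       component_sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}
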